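#' Annotation map: gene -> annotated terms with evidence codes
#'
#' Lightweight container pairing a long-format annotation table with the
#' namespace it was read for. Rows are (gene, term, evidence) triples of
#' direct (non-propagated) annotations.
#'
#' @param table data.frame with character columns `gene`, `term`,
#'   `evidence`.
#' @param namespace namespace tag of the companion graph.
#' @return object of class `annotation_map` with elements `table`,
#'   `namespace`, `genes` (unique gene ids).
#' @export
annotation_map <- function(table, namespace = "BP") {
  stopifnot(is.data.frame(table),
            all(c("gene", "term", "evidence") %in% names(table)))
  table <- unique(table[, c("gene", "term", "evidence")])
  table[] <- lapply(table, as.character)
  table$evidence <- toupper(table$evidence)
  structure(list(table = table, namespace = namespace,
                 genes = sort(unique(table$gene))),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("annotation_map [", x$namespace, "]: ", length(x$genes), " genes, ",
      nrow(x$table), " annotations\n", sep = "")
  invisible(x)
}

#' Direct annotation term set of a gene
#'
#' @param map an [annotation_map()].
#' @param gene gene identifier.
#' @return character vector of directly annotated terms (possibly empty).
#' @export
gene_terms <- function(map, gene) {
  unique(map$table$term[map$table$gene == gene])
}

.ASPECT_OF <- c(BP = "P", CC = "C", MF = "F")

#' Read gene annotations from a GAF 2.x file
#'
#' Reads a 17-column tab-separated Gene Association File, keeping rows whose
#' aspect column matches the graph's namespace. Rows with qualifier `NOT`
#' are dropped (they deny function rather than assert it). Under evidence
#' mode `"IEA-"`, rows with evidence code `IEA` are dropped; `"IEA+"` keeps
#' them. Rows annotating terms absent from the graph (e.g. obsolete or
#' other-namespace terms) are dropped and counted; alternate ids are
#' resolved to primary terms first.
#'
#' @param path path to a GAF file (comment lines start with `!`).
#' @param graph the companion [ontology_graph()].
#' @param evidence_mode `"IEA+"` (keep electronic annotations) or `"IEA-"`.
#' @param gene_key `"symbol"` (GAF column 3, default) or `"id"` (column 2).
#' @return an [annotation_map()] with attribute `n_dropped_terms` counting
#'   rows dropped for unknown terms. Warns (and returns an empty map) if no
#'   row survives filtering.
#' @export
parse_gaf <- function(path, graph, evidence_mode = c("IEA+", "IEA-"),
                      gene_key = c("symbol", "id")) {
  evidence_mode <- match.arg(evidence_mode)
  gene_key <- match.arg(gene_key)
  if (!file.exists(path)) stop("GAF file not found: ", path)

  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  # sentinel keeps trailing empty fields from being dropped by strsplit
  fields <- strsplit(paste0(lines, "\t\x03"), "\t", fixed = TRUE)
  nf <- lengths(fields) - 1L
  if (any(nf != 17L))
    stop("GAF parse error: expected 17 tab-separated columns, got ",
         nf[nf != 17L][1], " at data row ", which(nf != 17L)[1])

  m <- do.call(rbind, lapply(fields, `[`, 1:17))
  gene <- m[, if (gene_key == "symbol") 3L else 2L]
  qualifier <- m[, 4L]
  term <- m[, 5L]
  evidence <- toupper(m[, 7L])
  aspect <- m[, 9L]

  keep <- aspect == .ASPECT_OF[[graph$namespace]]
  keep <- keep & !grepl("(^|\\|)NOT($|\\|)", qualifier)
  if (evidence_mode == "IEA-") keep <- keep & evidence != "IEA"

  gene <- gene[keep]; term <- term[keep]; evidence <- evidence[keep]
  term <- resolve_aliases(term, graph)
  known <- term %in% graph$terms
  n_dropped <- sum(!known)

  tab <- data.frame(gene = gene[known], term = term[known],
                    evidence = evidence[known], stringsAsFactors = FALSE)
  if (nrow(tab) == 0L)
    warning("no annotations retained after filtering (namespace ",
            graph$namespace, ", mode ", evidence_mode, ")")
  map <- annotation_map(tab, namespace = graph$namespace)
  attr(map, "n_dropped_terms") <- n_dropped
  map
}

#' Write an annotation map as a GAF 2.2 file
#'
#' Emits 17-column rows (unused columns empty or placeholder) that
#' [parse_gaf()] reads back to the same (gene, term, evidence) triples.
#'
#' @param map an [annotation_map()].
#' @param path output file path.
#' @param db database label for column 1.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(map, path, db = "SYNTH") {
  aspect <- .ASPECT_OF[[map$namespace]]
  tab <- map$table
  rows <- paste(db, tab$gene, tab$gene, "", tab$term, "REF:0000001",
                tab$evidence, "", aspect, "", "", "protein",
                "taxon:0000", "20260101", db, "", "", sep = "\t")
  writeLines(c("!gaf-version: 2.2", rows), path)
  invisible(path)
}
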