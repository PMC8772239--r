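.NAMESPACE_TAGS <- c(BP = "biological_process",
                     CC = "cellular_component",
                     MF = "molecular_function")

#' Read a Gene Ontology namespace from an OBO flat file
#'
#' Parses the OBO 1.2/1.4 stanza format and returns the subgraph of one
#' namespace as a validated [ontology_graph()]. Only `is_a:` lines and
#' `relationship: part_of` lines become edges; any other relationship type
#' (`regulates`, `occurs_in`, ...) is ignored and counted. Obsolete terms
#' (`is_obsolete: true`) are excluded. `alt_id:` identifiers are recorded as
#' aliases resolving to their primary term, so downstream code only ever
#' sees primary identifiers. Edges whose endpoints fall in different
#' namespaces are dropped.
#'
#' @param path path to an OBO file.
#' @param namespace `"BP"`, `"CC"` or `"MF"`; terms are assigned by their
#'   `namespace:` line (falling back to the file's `default-namespace`).
#' @return an [ontology_graph()] with attributes `n_obsolete` (obsolete
#'   terms skipped) and `n_other_relations` (non-is_a/part_of relationship
#'   lines ignored).
#' @export
parse_obo <- function(path, namespace = c("BP", "CC", "MF")) {
  namespace <- match.arg(namespace)
  ns_tag <- .NAMESPACE_TAGS[[namespace]]
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  default_ns <- sub("^default-namespace: *", "",
                    grep("^default-namespace:", lines, value = TRUE)[1])

  term_starts <- grep("^\\[Term\\]$", lines)
  other_stanzas <- grep("^\\[(?!Term\\])", lines, perl = TRUE)
  bounds <- sort(c(term_starts, other_stanzas, length(lines) + 1L))

  ids <- character(); ns_of <- character(); obsolete <- logical()
  edges_p <- character(); edges_c <- character(); edges_r <- character()
  alias_from <- character(); alias_to <- character()
  n_other_rel <- 0L

  for (s in term_starts) {
    e <- min(bounds[bounds > s]) - 1L
    body <- lines[(s + 1L):e]
    id <- sub("^id: *", "", grep("^id:", body, value = TRUE)[1])
    if (is.na(id))
      stop("malformed stanza at line ", s, ": missing id")
    if (!grepl("^\\S+$", id))
      stop("malformed stanza at line ", s, ": bad id '", id, "'")
    ns <- sub("^namespace: *", "", grep("^namespace:", body, value = TRUE)[1])
    if (is.na(ns)) ns <- default_ns
    obs <- any(grepl("^is_obsolete: *true", body))

    ids <- c(ids, id); ns_of <- c(ns_of, ns); obsolete <- c(obsolete, obs)
    if (obs) next

    isa <- grep("^is_a:", body, value = TRUE)
    if (length(isa)) {
      p <- sub("^is_a: *([^ !]+).*$", "\\1", isa)
      edges_p <- c(edges_p, p); edges_c <- c(edges_c, rep(id, length(p)))
      edges_r <- c(edges_r, rep("is_a", length(p)))
    }
    rel <- grep("^relationship:", body, value = TRUE)
    if (length(rel)) {
      rtype <- sub("^relationship: *(\\S+) .*$", "\\1", rel)
      keep <- rtype == "part_of"
      n_other_rel <- n_other_rel + sum(!keep)
      if (any(keep)) {
        p <- sub("^relationship: *\\S+ +([^ !]+).*$", "\\1", rel[keep])
        edges_p <- c(edges_p, p); edges_c <- c(edges_c, rep(id, length(p)))
        edges_r <- c(edges_r, rep("part_of", length(p)))
      }
    }
    alt <- grep("^alt_id:", body, value = TRUE)
    if (length(alt)) {
      a <- sub("^alt_id: *([^ !]+).*$", "\\1", alt)
      alias_from <- c(alias_from, a); alias_to <- c(alias_to, rep(id, length(a)))
    }
  }

  if (anyDuplicated(ids[!obsolete]))
    stop("duplicate term id: ", ids[!obsolete][duplicated(ids[!obsolete])][1])

  in_ns <- !obsolete & ns_of == ns_tag
  keep_ids <- ids[in_ns]
  if (length(keep_ids) == 0L)
    stop("no terms in namespace ", namespace, " (", ns_tag, ")")

  ed <- data.frame(parent = edges_p, child = edges_c, relation = edges_r,
                   stringsAsFactors = FALSE)
  ed <- ed[ed$parent %in% keep_ids & ed$child %in% keep_ids, , drop = FALSE]

  aliases <- stats::setNames(alias_to, alias_from)
  aliases <- aliases[aliases %in% keep_ids]

  g <- ontology_graph(ed, namespace = namespace, nodes = keep_ids,
                      aliases = aliases)
  attr(g, "n_obsolete") <- sum(obsolete)
  attr(g, "n_other_relations") <- n_other_rel
  g
}

#' Serialize an ontology graph to OBO
#'
#' Writes a minimal OBO 1.2 file (one `[Term]` stanza per term with its
#' `is_a` and `relationship: part_of` lines) that [parse_obo()] reads back
#' to the identical node and edge sets.
#'
#' @param graph an [ontology_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  ns_tag <- .NAMESPACE_TAGS[[graph$namespace]]
  if (is.null(ns_tag) || is.na(ns_tag)) ns_tag <- graph$namespace
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format-version: 1.2",
               paste0("default-namespace: ", ns_tag), ""), con)
  for (t in graph$terms) {
    out <- c("[Term]", paste0("id: ", t), paste0("name: ", t),
             paste0("namespace: ", ns_tag))
    ed <- graph$edges[graph$edges$child == t, , drop = FALSE]
    if (nrow(ed)) {
      isa <- ed$parent[ed$relation == "is_a"]
      po <- ed$parent[ed$relation == "part_of"]
      out <- c(out, paste0("is_a: ", isa),
               if (length(po)) paste0("relationship: part_of ", po))
    }
    alt <- names(graph$aliases)[graph$aliases == t]
    if (length(alt)) out <- c(out, paste0("alt_id: ", alt))
    writeLines(c(out, ""), con)
  }
  invisible(path)
}
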