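#' Information-content table
#'
#' Holds one IC value per term under a named model, together with the
#' depth/ancestor/descendant indices the models are computed from. The root
#' has IC 0 under every model; when `normalized` is `TRUE` all values lie
#' in [0, 1] with maximum 1 (obtained by dividing the raw scores by their
#' maximum). Natural logarithms are used throughout.
#'
#' @param values named numeric vector, one IC (>= 0) per term.
#' @param model model label (`"ste"`, `"corpus"`, `"sanchez"`, or
#'   `"injected"` for externally supplied values as in the worked example).
#' @param graph the companion [ontology_graph()]; indices are built from it.
#' @param normalized whether `values` are already on the [0, 1] scale.
#' @return object of class `ic_table`: list with `model`, `values`,
#'   `normalized`, `depth`, `N` (term count).
#' @export
ic_table <- function(values, model, graph, normalized = FALSE) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  missing <- setdiff(graph$terms, names(values))
  if (length(missing))
    stop("IC values missing for term(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  values <- values[graph$terms]
  if (any(values < 0)) stop("negative IC value")
  structure(list(model = model, values = values, normalized = normalized,
                 depth = term_depths(graph), N = length(graph$terms)),
            class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat("ic_table [", x$model, "]: ", x$N, " terms, ",
      if (x$normalized) "normalized" else "raw",
      ", max IC ", format(max(x$values), digits = 4), "\n", sep = "")
  invisible(x)
}

.normalize_ic <- function(values) {
  m <- max(values)
  if (m > 0) values / m else values
}

#' Structural IC from term and edge specificity (STE model)
#'
#' For a non-root term t the raw score is
#' \deqn{IC(t) = \log(depth(t)) \cdot \big(\log\textstyle\sum_{a \in Ance(t)}
#'   depth(a) + 1\big) \cdot \big(1 - \log(|Desc(t)|+1)/\log(N+1)\big)}
#' where depth is the longest-root-path depth (root = 1), Ance(t) is the
#' ancestor set excluding t, Desc(t) the descendant set excluding t, and N
#' the number of terms in the namespace. The `+1` in the descendant factor
#' makes leaves (|Desc| = 0) attain the maximal specificity factor 1 and
#' keeps the factor defined everywhere; the root has IC 0 since
#' log(depth) = 0. With `normalize = TRUE` (default) values are divided by
#' the maximum so the most informative term scores 1.
#'
#' @param graph an [ontology_graph()].
#' @param normalize divide by the maximum raw value (default `TRUE`).
#' @return an [ic_table()] with model `"ste"`.
#' @export
#' @examples
#' g <- ontology_graph(data.frame(parent = "r", child = "x", relation = "is_a"))
#' ste_ic(g, normalize = FALSE)$values  # r = 0, x = log(2)
ste_ic <- function(graph, normalize = TRUE) {
  N <- length(graph$terms)
  if (N == 0L) stop("empty graph")
  depth <- term_depths(graph)
  anc <- graph$.anc; if (is.null(anc)) anc <- term_ancestors(graph)
  des <- graph$.des; if (is.null(des)) des <- term_descendants(graph)

  vals <- vapply(graph$terms, function(t) {
    if (depth[t] == 1L) return(0)  # root: log(1) factor vanishes
    anc_depth_sum <- sum(depth[anc[[t]]])
    f1 <- log(depth[t])
    f2 <- log(anc_depth_sum) + 1
    f3 <- 1 - log(length(des[[t]]) + 1) / log(N + 1)
    stopifnot(f3 >= 0)
    f1 * f2 * f3
  }, numeric(1))

  if (normalize) vals <- .normalize_ic(vals)
  ic_table(vals, "ste", graph, normalized = normalize)
}

#' Corpus-based IC from annotation frequency
#'
#' IC(t) = -log p(t) where p(t) is the fraction of annotated genes whose
#' ancestor-closed annotation set contains t, relative to the genes
#' annotated to the root (i.e. all genes with at least one annotation).
#' Terms annotating no gene have undefined IC; they are assigned the
#' maximum observed finite IC and flagged in the `unseen` attribute of the
#' result, keeping downstream arithmetic finite.
#'
#' @param annotations an [annotation_map()].
#' @param graph an [ontology_graph()].
#' @param normalize divide by the maximum value (default `TRUE`).
#' @return an [ic_table()] with model `"corpus"` and attribute `unseen`
#'   (character vector of never-annotated terms).
#' @export
corpus_ic <- function(annotations, graph, normalize = TRUE) {
  if (length(annotations$genes) == 0L) stop("empty annotation corpus")
  counts <- stats::setNames(integer(length(graph$terms)), graph$terms)
  for (g in annotations$genes) {
    closed <- ancestor_closure(gene_terms(annotations, g), graph)
    counts[closed] <- counts[closed] + 1L
  }
  n_root <- counts[[graph$root]]
  stopifnot(n_root == length(annotations$genes))
  p <- counts / n_root
  vals <- ifelse(p > 0, -log(p), NA_real_)
  unseen <- names(vals)[is.na(vals)]
  if (length(unseen)) {
    mx <- max(vals, na.rm = TRUE)
    vals[is.na(vals)] <- mx
  }
  if (normalize) vals <- .normalize_ic(vals)
  out <- ic_table(vals, "corpus", graph, normalized = normalize)
  attr(out, "unseen") <- unseen
  out
}

#' Structural IC from leaves and subsumers (Sanchez model)
#'
#' IC(t) = -log[ (|leaves(t)|/|subsumers(t)| + 1) / (max_leaves + 1) ],
#' where leaves(t) are the leaf descendants of t (a leaf's own leaf set is
#' itself), subsumers(t) are the ancestors of t including t, and max_leaves
#' is the number of leaves in the namespace. The root scores 0 exactly.
#'
#' @param graph an [ontology_graph()].
#' @param normalize divide by the maximum value (default `TRUE`).
#' @return an [ic_table()] with model `"sanchez"`.
#' @export
sanchez_ic <- function(graph, normalize = TRUE) {
  anc <- graph$.anc; if (is.null(anc)) anc <- term_ancestors(graph)
  des <- graph$.des; if (is.null(des)) des <- term_descendants(graph)
  leaves <- graph$terms[lengths(graph$children[graph$terms]) == 0L]
  max_leaves <- length(leaves)

  vals <- vapply(graph$terms, function(t) {
    lv <- if (t %in% leaves) 1L else sum(des[[t]] %in% leaves)
    subs <- length(anc[[t]]) + 1L  # subsumers include the term itself
    -log((lv / subs + 1) / (max_leaves + 1))
  }, numeric(1))
  vals[graph$root] <- 0  # |leaves|/1 = max_leaves exactly; avoid -0
  if (normalize) vals <- .normalize_ic(vals)
  ic_table(vals, "sanchez", graph, normalized = normalize)
}

#' Histogram of IC values over [0, 1]
#'
#' Bins the (normalized) IC values of all terms into equal-width bins on
#' [0, 1]; used to inspect whether most terms carry intermediate IC.
#'
#' @param table a normalized [ic_table()].
#' @param bins number of bins (default 10).
#' @return data.frame with columns `bin_lo`, `bin_hi`, `count`; counts sum
#'   to the number of terms.
#' @export
ic_distribution <- function(table, bins = 10L) {
  stopifnot(inherits(table, "ic_table"), bins >= 1L)
  if (!table$normalized)
    stop("ic_distribution expects a normalized ic_table")
  edges <- seq(0, 1, length.out = bins + 1L)
  idx <- findInterval(table$values, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
             count = tabulate(idx, nbins = bins))
}
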