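#' Labeled gene-pair set (e.g. positive/negative protein interactions)
#'
#' @param geneA,geneB character vectors of gene identifiers.
#' @param label vector coercible to 0/1 (`"positive"`/`"negative"`, logical
#'   or 0/1 numeric).
#' @param note free-text provenance note.
#' @return object of class `labeled_pairs`: data.frame with columns
#'   `geneA`, `geneB`, `label` (integer 0/1). Duplicate unordered pairs are
#'   an error.
#' @export
labeled_pairs <- function(geneA, geneB, label, note = "") {
  lab <- if (is.character(label)) as.integer(label == "positive")
         else as.integer(label)
  stopifnot(all(lab %in% c(0L, 1L)))
  key <- paste(pmin(geneA, geneB), pmax(geneA, geneB))
  if (anyDuplicated(key))
    stop("duplicate unordered pair: ", key[duplicated(key)][1])
  out <- data.frame(geneA = as.character(geneA),
                    geneB = as.character(geneB),
                    label = lab, stringsAsFactors = FALSE)
  attr(out, "note") <- note
  class(out) <- c("labeled_pairs", "data.frame")
  out
}

#' Read labeled pairs / expression-similarity pairs from TSV
#'
#' Expected columns: geneA, geneB, and either a label (`positive`/
#' `negative` or 0/1) or a numeric expression-similarity value.
#'
#' @param path TSV file with a header row.
#' @return [labeled_pairs()] or a data.frame (`geneA`, `geneB`, `value`).
#' @export
read_labeled_pairs <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  labeled_pairs(d[[1]], d[[2]], d[[3]], note = path)
}

#' @rdname read_labeled_pairs
#' @export
read_expression_pairs <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(geneA = as.character(d[[1]]),
                    geneB = as.character(d[[2]]),
                    value = as.numeric(d[[3]]), stringsAsFactors = FALSE)
  if (any(!is.finite(out$value))) stop("non-finite expression value")
  out
}

.match_pairs <- function(scores, pairs) {
  skey <- paste(pmin(scores$geneA, scores$geneB),
                pmax(scores$geneA, scores$geneB))
  pkey <- paste(pmin(pairs$geneA, pairs$geneB),
                pmax(pairs$geneA, pairs$geneB))
  idx <- match(pkey, skey)
  data.frame(score = scores$score[idx],
             defined = !is.na(idx) & scores$defined[idx])
}

#' ROC AUC of similarity scores against binary pair labels
#'
#' Computes the area under the ROC curve by the rank (Wilcoxon/Mann-
#' Whitney) formula with midranks for ties, equivalent to the trapezoid
#' rule on the empirical ROC. Pairs without a defined score are dropped and
#' counted, never silently.
#'
#' @param scores a `similarity_result` from [sim_pairs()].
#' @param labels a [labeled_pairs()] set over (a subset of) those pairs.
#' @return list with `auc`, `n_used`, `n_dropped`. Errors if only one
#'   class remains.
#' @export
roc_auc <- function(scores, labels) {
  m <- .match_pairs(scores, labels)
  keep <- m$defined
  s <- m$score[keep]; y <- labels$label[keep]
  if (length(unique(y)) < 2L)
    stop("need both positive and negative labels with defined scores")
  r <- rank(s)  # midranks for ties
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(auc = auc, n_used = length(s), n_dropped = sum(!keep))
}

#' Pearson correlation of similarity scores with expression similarity
#'
#' @param scores a `similarity_result` from [sim_pairs()].
#' @param expr data.frame (`geneA`, `geneB`, `value`), e.g. from
#'   [read_expression_pairs()].
#' @return list with `r` (Pearson correlation; `NA` flagged if either
#'   vector has zero variance), `n_used`, `n_dropped`.
#' @export
pearson_eval <- function(scores, expr) {
  m <- .match_pairs(scores, expr)
  keep <- m$defined
  s <- m$score[keep]; v <- expr$value[keep]
  if (length(s) < 3L) stop("need at least 3 overlapping defined pairs")
  r <- if (stats::sd(s) == 0 || stats::sd(v) == 0) NA_real_
       else stats::cor(s, v)
  list(r = r, n_used = length(s), n_dropped = sum(!keep))
}

#' Functional-classification similarity matrix with class summaries
#'
#' All-vs-all similarity for genes carrying class labels (e.g. EC
#' numbers), summarized as the mean similarity within classes versus
#' between classes. Genes of similar function (same class) are expected to
#' score higher within than between.
#'
#' @param genes character vector of gene identifiers (>= 2 classes among
#'   them).
#' @param classes vector of class labels, parallel to `genes`.
#' @inheritParams sim_pairs
#' @return list with `matrix` (symmetric, unit diagonal where defined),
#'   `within_mean`, `between_mean`, `difference`, and `singleton_classes`
#'   (classes with one member, whose within-mean is undefined).
#' @export
classification_matrix <- function(genes, classes, method = .SIM_METHODS,
                                  annotations, graph, ic = NULL,
                                  weights = NULL) {
  method <- match.arg(method)
  stopifnot(length(genes) == length(classes))
  if (length(unique(classes)) < 2L) stop("need at least 2 classes")
  m <- pairwise_matrix(genes, method, annotations, graph, ic, weights)
  same <- outer(classes, classes, "==")
  off <- upper.tri(m)
  within <- m[off & same]; between <- m[off & !same]
  list(matrix = m,
       within_mean = mean(within, na.rm = TRUE),
       between_mean = mean(between, na.rm = TRUE),
       difference = mean(within, na.rm = TRUE) - mean(between, na.rm = TRUE),
       singleton_classes = names(which(table(classes) == 1L)))
}
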