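.closed_set <- function(map, gene, graph) {
  direct <- gene_terms(map, gene)
  if (length(direct) == 0L) return(NULL)
  ancestor_closure(direct, graph)
}

#' Gene functional similarity by IC overlap ratio (STE)
#'
#' Both genes' direct annotation sets are ancestor-closed (true path rule);
#' the score is the set IC of the intersection of the closed sets divided
#' by the set IC of their union,
#' \deqn{sim(G_1, G_2) = IC(T_{G_1} \cap T_{G_2}) / IC(T_{G_1} \cup T_{G_2}).}
#' Intersections and unions of ancestor-closed sets are themselves closed,
#' so the decomposition underlying [set_ic()] is well defined on both.
#' Identical closed sets score exactly 1; closed sets meeting only at the
#' root score 0. A gene without annotations yields `NA` (undefined, never
#' silently 0).
#'
#' @param geneA,geneB gene identifiers.
#' @param annotations an [annotation_map()].
#' @param graph an [ontology_graph()].
#' @param ic an [ic_table()].
#' @param weights an `edge_weight_table` for the same IC model.
#' @return similarity in [0, 1], or `NA_real_` if either gene is
#'   unannotated.
#' @export
sim_ste <- function(geneA, geneB, annotations, graph, ic, weights) {
  A <- .closed_set(annotations, geneA, graph)
  B <- .closed_set(annotations, geneB, graph)
  if (is.null(A) || is.null(B)) return(NA_real_)
  if (setequal(A, B)) return(1)
  num <- set_ic(intersect(A, B), graph, ic, weights)
  den <- set_ic(union(A, B), graph, ic, weights)
  if (den == 0) return(NA_real_)  # degenerate: no off-root information
  num / den
}

#' Gene similarity by Resnik term similarity with best-match averaging
#'
#' Term-pair similarity is the maximum IC over the common ancestors of the
#' two terms (each term counts among its own ancestors), the standard
#' realization of the most-informative common ancestor in a DAG. Gene-level
#' similarity aggregates the term-pair matrix over the two direct
#' annotation sets by the best-match average: half the mean of row maxima
#' plus half the mean of column maxima.
#'
#' @inheritParams sim_ste
#' @param ic an [ic_table()], normally a normalized corpus table.
#' @return score in [0, 1] for normalized IC; `NA_real_` if either gene is
#'   unannotated.
#' @export
sim_resnik_bma <- function(geneA, geneB, annotations, graph, ic) {
  SA <- gene_terms(annotations, geneA)
  SB <- gene_terms(annotations, geneB)
  if (length(SA) == 0L || length(SB) == 0L) return(NA_real_)
  anc <- graph$.anc; if (is.null(anc)) anc <- term_ancestors(graph)
  icv <- ic$values
  self_anc <- function(t) c(t, anc[[t]])
  m <- outer(SA, SB, Vectorize(function(a, b) {
    common <- intersect(self_anc(a), self_anc(b))
    max(icv[common])
  }))
  (mean(apply(m, 1L, max)) + mean(apply(m, 2L, max))) / 2
}

#' Gene similarity as Jaccard index of closed annotation sets (simUI)
#'
#' @inheritParams sim_ste
#' @return |intersection| / |union| over ancestor-closed sets, or `NA`.
#' @export
sim_ui <- function(geneA, geneB, annotations, graph) {
  A <- .closed_set(annotations, geneA, graph)
  B <- .closed_set(annotations, geneB, graph)
  if (is.null(A) || is.null(B)) return(NA_real_)
  length(intersect(A, B)) / length(union(A, B))
}

#' Gene similarity as cosine of one-hot annotation vectors (VSM)
#'
#' Each gene is a binary vector over the namespace's terms with ones at
#' its ancestor-closed annotations; the score is the cosine of the two
#' vectors, |A intersect B| / sqrt(|A| |B|). Always positive after closure
#' since both sets contain the root.
#'
#' @inheritParams sim_ste
#' @return cosine similarity in (0, 1], or `NA`.
#' @export
sim_vsm <- function(geneA, geneB, annotations, graph) {
  A <- .closed_set(annotations, geneA, graph)
  B <- .closed_set(annotations, geneB, graph)
  if (is.null(A) || is.null(B)) return(NA_real_)
  length(intersect(A, B)) / sqrt(length(A) * length(B))
}

#' Gene similarity as IC-weighted Jaccard of closed sets (simGIC)
#'
#' Sum of plain (not own) IC over the intersection of the closed sets
#' divided by the sum over their union.
#'
#' @inheritParams sim_ste
#' @return score in [0, 1], or `NA` (also when the union carries zero IC).
#' @export
sim_gic <- function(geneA, geneB, annotations, graph, ic) {
  A <- .closed_set(annotations, geneA, graph)
  B <- .closed_set(annotations, geneB, graph)
  if (is.null(A) || is.null(B)) return(NA_real_)
  if (setequal(A, B)) return(1)
  icv <- ic$values
  den <- sum(icv[union(A, B)])
  if (den == 0) return(NA_real_)
  sum(icv[intersect(A, B)]) / den
}

.SIM_METHODS <- c("ste", "resnik", "simui", "vsm", "simgic")

.sim_dispatch <- function(method, geneA, geneB, annotations, graph, ic,
                          weights) {
  switch(method,
         ste = sim_ste(geneA, geneB, annotations, graph, ic, weights),
         resnik = sim_resnik_bma(geneA, geneB, annotations, graph, ic),
         simui = sim_ui(geneA, geneB, annotations, graph),
         vsm = sim_vsm(geneA, geneB, annotations, graph),
         simgic = sim_gic(geneA, geneB, annotations, graph, ic),
         stop("unknown method: ", method))
}

#' Similarity scores for a list of gene pairs
#'
#' @param pairs data.frame with character columns `geneA`, `geneB`.
#' @param method one of `"ste"`, `"resnik"`, `"simui"`, `"vsm"`,
#'   `"simgic"`.
#' @param annotations an [annotation_map()].
#' @param graph an [ontology_graph()].
#' @param ic an [ic_table()] (unused by simui/vsm).
#' @param weights an `edge_weight_table` (used by ste only).
#' @return object of class `similarity_result`: the input pairs with
#'   columns `score` and `defined` added, plus attributes `method` and
#'   `config`.
#' @export
sim_pairs <- function(pairs, method = .SIM_METHODS, annotations, graph,
                      ic = NULL, weights = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("geneA", "geneB") %in% names(pairs)))
  score <- mapply(function(a, b)
    .sim_dispatch(method, a, b, annotations, graph, ic, weights),
    pairs$geneA, pairs$geneB, USE.NAMES = FALSE)
  out <- data.frame(geneA = pairs$geneA, geneB = pairs$geneB,
                    score = score, defined = !is.na(score),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "config") <- list(namespace = graph$namespace,
                              ic_model = if (!is.null(ic)) ic$model)
  class(out) <- c("similarity_result", "data.frame")
  out
}

#' All-vs-all gene similarity matrix
#'
#' @param genes character vector of at least two gene identifiers.
#' @inheritParams sim_pairs
#' @return symmetric numeric matrix with unit diagonal where defined;
#'   undefined entries are `NA`.
#' @export
pairwise_matrix <- function(genes, method = .SIM_METHODS, annotations,
                            graph, ic = NULL, weights = NULL) {
  method <- match.arg(method)
  stopifnot(length(genes) >= 2L)
  n <- length(genes)
  m <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- .sim_dispatch(method, genes[i], genes[j], annotations, graph,
                         ic, weights)
      m[i, j] <- m[j, i] <- s
    }
  }
  m
}
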