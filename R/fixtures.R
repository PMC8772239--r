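.WE_TERMS <- sprintf("GO:%07d", 1:8)
.WE_LABELS <- paste0("t", 1:8)
.WE_EDGES <- data.frame(
  parent = c(1L, 1L, 2L, 3L, 3L, 4L, 4L, 5L, 6L, 7L),
  child  = c(2L, 3L, 4L, 4L, 5L, 6L, 7L, 7L, 8L, 8L))
.WE_IC <- c(0.0, 0.01, 0.02, 0.04, 0.05, 0.07, 0.09, 0.18)
.WE_OMEGA <- c(0.85, 0.98, 0.97, 0.84, 0.71, 0.65, 0.71, 0.72, 0.67, 0.84)

#' The eight-term worked-example DAG
#'
#' A small rooted DAG of eight terms (t1 ... t8, root t1) with ten is_a
#' edges, published term IC values and edge specificity weights. The IC
#' and weight tables are injected as given inputs — the weights were
#' derived on the full ontology, not this excerpt, so they are not
#' recomputable from the eight-term IC values — making the fixture a
#' self-contained test bed for the inherited/own IC decomposition and
#' term-set IC accumulation.
#'
#' Terms use synthetic GO-style identifiers `GO:0000001` ... `GO:0000008`
#' mapped to labels t1 ... t8.
#'
#' @return list with elements `graph` (an [ontology_graph()]), `ic` (an
#'   [ic_table()] with model `"injected"`, treated as normalized), `weights`
#'   (an [edge_weight_table()]), `labels` (named character: term id ->
#'   label), and `terms` (the eight ids in t1..t8 order).
#' @export
#' @examples
#' we <- worked_example()
#' set_ic_trace(we$terms, we$graph, we$ic, we$weights)
worked_example <- function() {
  edges <- data.frame(parent = .WE_TERMS[.WE_EDGES$parent],
                      child = .WE_TERMS[.WE_EDGES$child],
                      relation = "is_a", stringsAsFactors = FALSE)
  graph <- ontology_graph(edges, namespace = "BP")
  ic <- ic_table(stats::setNames(.WE_IC, .WE_TERMS), model = "injected",
                 graph = graph, normalized = TRUE)
  weights <- edge_weight_table(parent = edges$parent, child = edges$child,
                               omega = .WE_OMEGA)
  list(graph = graph, ic = ic, weights = weights,
       labels = stats::setNames(.WE_LABELS, .WE_TERMS), terms = .WE_TERMS)
}

#' Generate a random rooted ontology-like DAG
#'
#' Builds a layered random DAG that always passes [ontology_graph()]
#' validation: a single root at depth 1, every other node attached to one
#' parent in the layer directly above (so its longest-path depth equals
#' its layer), plus optional extra parents from any shallower layer. Layer
#' sizes follow a symmetric binomial profile over depths 2 ... max_depth,
#' so the depth distribution is unimodal with an interior mode — echoing
#' the shape of the real ontologies, where most terms sit at intermediate
#' depth.
#'
#' @param n_terms total number of terms (>= 2).
#' @param max_depth deepest layer (<= n_terms; defaults to
#'   `min(6, n_terms)`).
#' @param multi_parent_prob probability that a node at depth >= 3 gains a
#'   second parent from a strictly shallower layer.
#' @param prop_part_of proportion of edges labeled `part_of` rather than
#'   `is_a`.
#' @param seed integer seed; the generator is reproducible given the seed.
#' @return an [ontology_graph()] (namespace `"BP"`), indexed via
#'   [index_graph()].
#' @export
generate_ontology <- function(n_terms, max_depth = 6L,
                              multi_parent_prob = 0.2,
                              prop_part_of = 0.1, seed = 1L) {
  stopifnot(n_terms >= 2L)
  if (missing(max_depth)) max_depth <- min(6L, n_terms)
  else if (max_depth > n_terms) stop("max_depth exceeds n_terms")
  max_depth <- max(2L, min(max_depth, n_terms))
  set.seed(seed)

  ids <- sprintf("GO:%07d", seq_len(n_terms))
  # unimodal layer profile over depths 2..max_depth, each layer nonempty
  k <- max_depth - 1L
  w <- stats::dbinom(0:(k - 1L), size = k - 1L, prob = 0.5)
  sizes <- pmax(1L, round(w / sum(w) * (n_terms - 1L)))
  while (sum(sizes) > n_terms - 1L) {
    i <- which.max(sizes); sizes[i] <- sizes[i] - 1L
  }
  while (sum(sizes) < n_terms - 1L) {
    i <- which.max(w); sizes[i] <- sizes[i] + 1L
  }
  depth_of <- rep.int(seq.int(2L, max_depth), times = sizes)

  parent <- character(); child <- character()
  layer <- split(ids[-1L], depth_of)
  above <- list(`1` = ids[1L])
  for (d in seq.int(2L, max_depth)) {
    nodes <- layer[[as.character(d)]]
    pool_direct <- above[[as.character(d - 1L)]]
    shallower <- unlist(above, use.names = FALSE)
    for (v in nodes) {
      p1 <- sample(pool_direct, 1L)
      parent <- c(parent, p1); child <- c(child, v)
      if (d >= 3L && stats::runif(1) < multi_parent_prob) {
        cand <- setdiff(shallower, p1)
        if (length(cand)) {
          p2 <- cand[sample.int(length(cand), 1L)]
          parent <- c(parent, p2); child <- c(child, v)
        }
      }
    }
    above[[as.character(d)]] <- nodes
  }
  relation <- ifelse(stats::runif(length(parent)) < prop_part_of,
                     "part_of", "is_a")
  g <- ontology_graph(data.frame(parent = parent, child = child,
                                 relation = relation,
                                 stringsAsFactors = FALSE),
                      namespace = "BP")
  index_graph(g)
}

#' Generate a synthetic annotation map over an ontology
#'
#' Each gene draws `rpois(mean_terms - 1) + 1` direct terms without
#' replacement, with sampling probability proportional to term depth —
#' emulating real annotation corpora, which mostly annotate specific
#' (deep) terms. Each annotation carries evidence code `IEA` with
#' probability `iea_fraction` and `EXP` otherwise, supporting IEA+/IEA-
#' stratification tests.
#'
#' @param graph an [ontology_graph()].
#' @param n_genes number of genes (>= 1).
#' @param mean_terms mean number of direct terms per gene (>= 1).
#' @param iea_fraction probability an annotation is electronic (`IEA`).
#' @param seed integer seed.
#' @return an [annotation_map()] with genes named `g001`, `g002`, ...
#' @export
generate_annotations <- function(graph, n_genes, mean_terms = 4,
                                 iea_fraction = 0.3, seed = 1L) {
  stopifnot(n_genes >= 1L, mean_terms >= 1)
  set.seed(seed)
  depth <- term_depths(graph)
  prob <- depth / sum(depth)
  genes <- sprintf("g%03d", seq_len(n_genes))
  rows <- lapply(genes, function(g) {
    k <- min(stats::rpois(1L, mean_terms - 1) + 1L, length(graph$terms))
    terms <- sample(graph$terms, k, prob = prob)
    data.frame(gene = g, term = terms,
               evidence = ifelse(stats::runif(k) < iea_fraction,
                                 "IEA", "EXP"),
               stringsAsFactors = FALSE)
  })
  annotation_map(do.call(rbind, rows), namespace = graph$namespace)
}
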