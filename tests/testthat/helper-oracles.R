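# Brute-force oracles, deliberately independent of the package's indexed
# implementations: everything here works by explicit path enumeration or
# per-term recursion over the raw edge list.

# all ancestors of `term` by recursive parent walk over the edge data.frame
bf_ancestors <- function(term, edges) {
  parents <- edges$parent[edges$child == term]
  if (length(parents) == 0L) return(character())
  unique(c(parents, unlist(lapply(parents, bf_ancestors, edges = edges))))
}

bf_descendants <- function(term, edges) {
  kids <- edges$child[edges$parent == term]
  if (length(kids) == 0L) return(character())
  unique(c(kids, unlist(lapply(kids, bf_descendants, edges = edges))))
}

bf_closure <- function(terms, edges) {
  sort(unique(c(terms, unlist(lapply(terms, bf_ancestors, edges = edges)))))
}

# longest-path depth (root = 1) by enumerating all root->term paths
bf_depth <- function(term, edges, root) {
  if (term == root) return(1L)
  parents <- edges$parent[edges$child == term]
  1L + max(vapply(parents, bf_depth, integer(1), edges = edges, root = root))
}

# inherited/own/set IC by explicit parent enumeration, per term, no
# topological machinery; termset must be ancestor-closed
bf_own <- function(term, edges, icv, omega) {
  parents <- edges$parent[edges$child == term]
  inh <- if (length(parents) == 0L) 0 else
    sum(vapply(parents, function(p) omega[[paste(p, term)]] * icv[[p]],
               numeric(1)))
  max(0, icv[[term]] - inh)
}

bf_set_ic <- function(termset, edges, icv, omega) {
  closed <- bf_closure(termset, edges)
  sum(vapply(closed, bf_own, numeric(1), edges = edges, icv = icv,
             omega = omega))
}

# accumulate own IC along an arbitrary supplied processing order
bf_set_ic_in_order <- function(order, edges, icv, omega) {
  sum(vapply(order, bf_own, numeric(1), edges = edges, icv = icv,
             omega = omega))
}

# a random valid topological order of `terms` w.r.t. the edge list
random_topo_order <- function(terms, edges) {
  remaining <- terms
  out <- character()
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(t) {
      !any(edges$parent %in% remaining & edges$child == t)
    }, logical(1))]
    pick <- ready[sample.int(length(ready), 1L)]
    out <- c(out, pick)
    remaining <- setdiff(remaining, pick)
  }
  out
}

# random small rooted DAG (arbitrary shape, single root "n01"), plus random
# IC (root 0) and random edge weights in (0, 1]
random_small_dag <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  parent <- character(); child <- character()
  for (i in 2:n) {
    k <- sample.int(min(2L, i - 1L), 1L)
    p <- sample(ids[seq_len(i - 1L)], k)
    parent <- c(parent, p); child <- c(child, rep(ids[i], k))
  }
  edges <- data.frame(parent = parent, child = child, relation = "is_a",
                      stringsAsFactors = FALSE)
  graph <- ontology_graph(edges, namespace = "BP")
  icv <- stats::setNames(round(stats::runif(n, 0, 2), 3), ids)
  icv[graph$root] <- 0
  omega <- stats::setNames(round(stats::runif(nrow(edges), 0.05, 1), 3),
                           paste(edges$parent, edges$child))
  wt <- edge_weight_table(edges$parent, edges$child,
                          omega[paste(edges$parent, edges$child)])
  list(graph = graph, edges = edges,
       ic = ic_table(icv, "injected", graph), weights = wt, icv = icv,
       omega = omega)
}

we_label_ids <- function(we, labels) {
  names(we$labels)[match(labels, we$labels)]
}
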