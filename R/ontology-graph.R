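#' Construct and validate an ontology graph
#'
#' An `ontology_graph` is a rooted directed acyclic graph of ontology terms
#' for a single namespace. Edges point from parent (more general) to child
#' (more specific) and carry one of the two relation types considered,
#' `is_a` or `part_of`. Validation enforces acyclicity, a unique root (the
#' only node without parents), and reachability of the root from every node.
#'
#' @param edges data.frame with character columns `parent`, `child` and
#'   `relation` (values in `"is_a"`, `"part_of"`). One row per edge.
#' @param namespace one of `"BP"`, `"CC"`, `"MF"` (or any single tag).
#' @param nodes optional character vector of term identifiers; defaults to
#'   the identifiers appearing in `edges`. Isolated extra nodes are only
#'   allowed when the graph has a single node in total.
#' @param aliases named character vector mapping alternate identifiers to
#'   primary term identifiers (as produced by [parse_obo()] for `alt_id`).
#'
#' @return An object of class `ontology_graph`: a list with elements
#'   `namespace`, `terms`, `edges`, `root`, `parents` (named list of direct
#'   parents per term), `children`, `topo` (topological order, parents
#'   first), and `aliases`.
#' @seealso [parse_obo()], [ancestor_closure()], [term_depths()]
#' @export
#' @examples
#' g <- ontology_graph(data.frame(parent = "GO:0000001", child = "GO:0000002",
#'                                relation = "is_a"), namespace = "BP")
#' g$root
ontology_graph <- function(edges, namespace = "BP", nodes = NULL,
                           aliases = character()) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0) {
    need <- c("parent", "child", "relation")
    if (!all(need %in% names(edges)))
      stop("edges must have columns parent, child, relation")
    edges <- edges[, need]
    edges[] <- lapply(edges, as.character)
    bad <- setdiff(unique(edges$relation), c("is_a", "part_of"))
    if (length(bad))
      stop("unsupported relation type(s): ", paste(bad, collapse = ", "))
    if (any(edges$parent == edges$child))
      stop("self-loop edge on term ", edges$parent[edges$parent == edges$child][1])
    edges <- unique(edges)
  } else {
    edges <- data.frame(parent = character(), child = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }

  terms <- sort(unique(c(nodes, edges$parent, edges$child)))
  if (length(terms) == 0L) stop("ontology graph has no terms")

  if (nrow(edges) > 0) {
    ig <- igraph::graph_from_data_frame(edges[, c("parent", "child")],
                                        directed = TRUE, vertices = terms)
    if (!igraph::is_dag(ig)) {
      scc <- igraph::components(ig, mode = "strong")
      member <- igraph::V(ig)$name[which(scc$membership %in%
                                           which(scc$csize > 1))][1]
      if (is.na(member)) member <- terms[1]
      stop("cycle detected in ontology graph involving term ", member)
    }
    topo <- igraph::V(ig)$name[as.integer(igraph::topo_sort(ig, mode = "out"))]
  } else {
    topo <- terms
  }

  parents <- split(edges$parent, factor(edges$child, levels = terms))
  children <- split(edges$child, factor(edges$parent, levels = terms))

  roots <- terms[lengths(parents) == 0L]
  if (length(roots) != 1L)
    stop("expected exactly one root, found ", length(roots), ": ",
         paste(utils::head(roots, 5), collapse = ", "))

  # every node must reach the root via child -> parent edges; with a unique
  # parentless node in a DAG this is equivalent to connectivity of the DAG
  if (length(terms) > 1L) {
    reach <- igraph::subcomponent(ig, roots, mode = "out")
    if (length(reach) != length(terms)) {
      orphan <- setdiff(terms, igraph::V(ig)$name[as.integer(reach)])[1]
      stop("term ", orphan, " cannot reach the root ", roots)
    }
  }

  structure(
    list(namespace = namespace, terms = terms, edges = edges, root = roots,
         parents = parents, children = children, topo = topo,
         aliases = aliases),
    class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph [", x$namespace, "]: ", length(x$terms), " terms, ",
      nrow(x$edges), " edges, root ", x$root, "\n", sep = "")
  invisible(x)
}

#' Resolve alternate identifiers to primary term identifiers
#'
#' @param terms character vector of term identifiers, possibly alternates.
#' @param graph an [ontology_graph()].
#' @return character vector with alternates replaced by their primary ids.
#' @export
resolve_aliases <- function(terms, graph) {
  hit <- terms %in% names(graph$aliases)
  terms[hit] <- unname(graph$aliases[terms[hit]])
  terms
}

#' Term depths (longest root path, root = 1)
#'
#' The depth of a term is the number of nodes on the longest path from the
#' root to the term, so the root itself has depth 1. Computed in one pass
#' over the topological order.
#'
#' @param graph an [ontology_graph()].
#' @return named integer vector of depths over all terms.
#' @export
#' @examples
#' g <- ontology_graph(data.frame(parent = c("a", "a", "b"),
#'                                child = c("b", "c", "c"),
#'                                relation = "is_a"))
#' term_depths(g)  # a=1 b=2 c=3
term_depths <- function(graph) {
  depth <- stats::setNames(rep.int(1L, length(graph$terms)), graph$terms)
  for (t in graph$topo) {
    p <- graph$parents[[t]]
    if (length(p)) depth[t] <- 1L + max(depth[p])
  }
  depth
}

#' Ancestor and descendant sets for every term
#'
#' Full transitive closure over the parent (respectively child) relation,
#' excluding the term itself, accumulated along the topological order.
#'
#' @param graph an [ontology_graph()].
#' @return named list of character vectors, one per term.
#' @export
term_ancestors <- function(graph) {
  anc <- stats::setNames(vector("list", length(graph$terms)), graph$terms)
  for (t in graph$topo) {
    p <- graph$parents[[t]]
    anc[[t]] <- if (length(p)) unique(c(p, unlist(anc[p], use.names = FALSE)))
                else character()
  }
  anc
}

#' @rdname term_ancestors
#' @export
term_descendants <- function(graph) {
  des <- stats::setNames(vector("list", length(graph$terms)), graph$terms)
  for (t in rev(graph$topo)) {
    ch <- graph$children[[t]]
    des[[t]] <- if (length(ch)) unique(c(ch, unlist(des[ch], use.names = FALSE)))
                else character()
  }
  des
}

#' Ancestor closure of a term set (true path rule)
#'
#' Under the true path rule, a gene annotated to a term is implicitly
#' annotated to every ancestor of that term. This returns the input terms
#' together with all their ancestors, up to and including the root.
#'
#' @param terms character vector of term identifiers, all present in `graph`.
#' @param graph an [ontology_graph()].
#' @return character vector (sorted, unique) of the closed set.
#' @export
#' @examples
#' g <- ontology_graph(data.frame(parent = c("a", "b"), child = c("b", "c"),
#'                                relation = "is_a"))
#' ancestor_closure("c", g)  # "a" "b" "c"
ancestor_closure <- function(terms, graph) {
  terms <- resolve_aliases(unique(as.character(terms)), graph)
  unknown <- setdiff(terms, graph$terms)
  if (length(unknown))
    stop("unknown term(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  anc <- graph$.anc
  if (is.null(anc)) anc <- term_ancestors(graph)
  sort(unique(c(terms, unlist(anc[terms], use.names = FALSE))))
}

#' Attach cached ancestor/descendant indices to a graph
#'
#' Convenience for repeated closure/similarity computation on the same
#' graph: stores the [term_ancestors()] and [term_descendants()] lists and
#' the depth vector inside the graph object.
#'
#' @param graph an [ontology_graph()].
#' @return the graph with `.anc`, `.des` and `.depth` fields populated.
#' @export
index_graph <- function(graph) {
  graph$.anc <- term_ancestors(graph)
  graph$.des <- term_descendants(graph)
  graph$.depth <- term_depths(graph)
  graph
}
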