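#' Edge specificity weights
#'
#' For each parent -> child edge the weight is the ratio of descendant IC
#' mass below the child to that below the parent,
#' \deqn{\omega_{ij} = \sum_{t \in Desc(t_j)} IC(t) \big/
#'   \sum_{t \in Desc(t_i)} IC(t),}
#' with the descendant sets taken self-inclusively (each node counts its
#' own IC). Self-inclusion guarantees the numerator set is a subset of the
#' denominator set, so 0 < omega <= 1 whenever the denominator is positive;
#' an all-zero-IC subgraph (denominator 0) yields omega = 1 by convention.
#'
#' @param graph an [ontology_graph()].
#' @param ic an [ic_table()] covering every node of the graph.
#' @return object of class `edge_weight_table`: a data.frame with columns
#'   `parent`, `child`, `relation`, `omega`, carrying the IC model label as
#'   attribute `ic_model`.
#' @export
edge_weights <- function(graph, ic) {
  stopifnot(inherits(ic, "ic_table"))
  missing <- setdiff(unique(c(graph$edges$parent, graph$edges$child)),
                     names(ic$values))
  if (length(missing))
    stop("edge endpoint missing from IC table: ", missing[1])
  des <- graph$.des; if (is.null(des)) des <- term_descendants(graph)
  # self-inclusive descendant IC mass per node, in one reverse-topo pass
  mass <- vapply(graph$terms,
                 function(t) ic$values[[t]] + sum(ic$values[des[[t]]]),
                 numeric(1))
  num <- mass[graph$edges$child]
  den <- mass[graph$edges$parent]
  omega <- ifelse(den > 0, num / den, 1)
  out <- data.frame(parent = graph$edges$parent, child = graph$edges$child,
                    relation = graph$edges$relation, omega = unname(omega),
                    stringsAsFactors = FALSE)
  attr(out, "ic_model") <- ic$model
  class(out) <- c("edge_weight_table", "data.frame")
  out
}

#' Construct an edge-weight table from given values
#'
#' Used to inject externally supplied weights (e.g. the worked-example
#' table) in place of [edge_weights()].
#'
#' @param parent,child character vectors defining the edges.
#' @param omega numeric weights in (0, 1].
#' @param relation relation labels (recycled).
#' @return an `edge_weight_table`.
#' @export
edge_weight_table <- function(parent, child, omega, relation = "is_a") {
  stopifnot(length(parent) == length(child), length(child) == length(omega),
            all(omega > 0), all(omega <= 1))
  out <- data.frame(parent = as.character(parent),
                    child = as.character(child),
                    relation = rep_len(relation, length(parent)),
                    omega = as.numeric(omega), stringsAsFactors = FALSE)
  class(out) <- c("edge_weight_table", "data.frame")
  out
}

.omega_lookup <- function(weights) {
  stats::setNames(weights$omega, paste(weights$parent, weights$child))
}

#' Inherited/own IC decomposition of an ancestor-closed term set
#'
#' Processes the terms of an ancestor-closed set in topological order and
#' splits each term's IC into the part inherited from its direct parents,
#' \deqn{IC_{inh}(t_j) = \sum_{t_i \in Parent(t_j)} \omega_{ij} IC(t_i),}
#' and the residual own IC, own(t) = IC(t) - inherited(t). Own values that
#' would be negative (possible for multi-parent terms whose inherited sum
#' exceeds their IC) are clamped to 0 and flagged; the root always has own
#' IC 0. Because the set is ancestor-closed, every parent needed by the sum
#' is itself in the set.
#'
#' @param termset character vector of term ids, ancestor-closed in `graph`.
#' @param graph an [ontology_graph()].
#' @param ic an [ic_table()].
#' @param weights an `edge_weight_table` (from [edge_weights()] or
#'   [edge_weight_table()]).
#' @return data.frame with one row per term, in topological order: `term`,
#'   `ic`, `inherited`, `own`, `clamped` (logical).
#' @export
own_ic <- function(termset, graph, ic, weights) {
  termset <- unique(as.character(termset))
  unknown <- setdiff(termset, graph$terms)
  if (length(unknown)) stop("unknown term(s): ", unknown[1])
  # closure check: every parent of a member must be a member
  for (t in termset) {
    out <- setdiff(graph$parents[[t]], termset)
    if (length(out))
      stop("term set is not ancestor-closed: parent ", out[1],
           " of ", t, " is missing")
  }
  ord <- graph$topo[graph$topo %in% termset]
  om <- .omega_lookup(weights)
  icv <- ic$values
  inh <- own <- stats::setNames(numeric(length(ord)), ord)
  clamped <- stats::setNames(logical(length(ord)), ord)
  for (t in ord) {
    p <- graph$parents[[t]]
    if (length(p)) {
      w <- om[paste(p, t)]
      if (anyNA(w))
        stop("edge weight missing for edge ", p[is.na(w)][1], " -> ", t)
      inh[t] <- sum(w * icv[p])
    }
    raw <- icv[[t]] - inh[t]
    clamped[t] <- raw < 0
    own[t] <- max(0, raw)
  }
  data.frame(term = ord, ic = unname(icv[ord]), inherited = unname(inh),
             own = unname(own), clamped = unname(clamped),
             stringsAsFactors = FALSE)
}

#' IC of a term set
#'
#' Applies the ancestor closure to the set, decomposes each member's IC
#' into inherited and own parts ([own_ic()]), and returns the sum of own
#' IC over the closed set. Summing own rather than total IC avoids double
#' counting semantics shared through the hierarchy.
#'
#' @param termset nonempty character vector of term ids.
#' @param graph an [ontology_graph()].
#' @param ic an [ic_table()].
#' @param weights an `edge_weight_table`.
#' @return a single numeric IC value (full precision).
#' @seealso [set_ic_trace()] for the step-by-step accumulation.
#' @export
set_ic <- function(termset, graph, ic, weights) {
  if (length(termset) == 0L) stop("empty term set")
  closed <- ancestor_closure(termset, graph)
  sum(own_ic(closed, graph, ic, weights)$own)
}

#' Half-up decimal rounding
#'
#' Rounds halves away from zero at `digits` decimals (unlike [round()],
#' which rounds halves to even). A 1e-9 guard absorbs binary floating-point
#' representation error so that values printed as exact halves round up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

#' Step-by-step term-set IC accumulation trace
#'
#' Runs the same accumulation as [set_ic()] but reports each step: the term
#' processed, its IC, its own IC, and the running cumulative set IC. With
#' `digits` set (default 3), each own value is rounded half-up to that many
#' decimals before being added, reproducing the convention of printed
#' worked examples; with `digits = NULL` the trace is full precision.
#'
#' @inheritParams set_ic
#' @param digits decimals for half-up rounding of own values, or `NULL`.
#' @return data.frame with columns `step`, `term`, `ic`, `own`,
#'   `cumulative`, rows in topological order of the closed set.
#' @export
set_ic_trace <- function(termset, graph, ic, weights, digits = 3L) {
  if (length(termset) == 0L) stop("empty term set")
  closed <- ancestor_closure(termset, graph)
  dec <- own_ic(closed, graph, ic, weights)
  own <- if (is.null(digits)) dec$own else round_half_up(dec$own, digits)
  cum <- cumsum(own)
  if (!is.null(digits)) cum <- round_half_up(cum, digits)
  data.frame(step = seq_len(nrow(dec)), term = dec$term, ic = dec$ic,
             own = own, cumulative = cum, stringsAsFactors = FALSE)
}
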