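---
title: "Term and edge specificity: the model behind steGO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Term and edge specificity: the model behind steGO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steGO)
```

## The problem

Two genes are functionally similar when the Gene Ontology (GO) terms that
annotate them describe overlapping biology. Quantifying that overlap needs
two ingredients: a measure of how *specific* each term is — its information
content (IC) — and a way to score the overlap of two *term sets* without
double-counting semantics that the sets share only because the ontology is
a hierarchy. steGO implements a group-wise similarity built on the
specificity of both terms and edges (STE), plus the standard baselines it
is usually compared against.

Only `is_a` and `part_of` edges are considered; both connect a specific
child to a more general parent, and the two are treated identically
throughout (nothing downstream distinguishes them, and the edge-weight
model is relation-agnostic).

## Term IC from graph structure

For a term $t$ in a namespace with $N$ terms,

$$IC(t) = \log(depth(t)) \cdot \Big(\log \sum_{a \in Ance(t)} depth(a) + 1\Big)
  \cdot \Big(1 - \frac{\log(|Desc(t)|+1)}{\log(N+1)}\Big)$$

where $depth$ is the longest-path depth with $depth(root)=1$, $Ance(t)$
excludes $t$, and $Desc(t)$ excludes $t$. The three factors reward depth,
depth-weighted ancestry, and scarcity of descendants; the root scores 0
because $\log(1)=0$.

Several conventions here are genuine design choices, fixed once and kept
behind `ste_ic()`:

* **Natural logarithm** everywhere. Every downstream quantity is a ratio
  or max-normalized, so the base only rescales.
* **`+1` in the descendant factor** (equivalently, a self-inclusive
  descendant count). Without it the factor is undefined for leaves
  ($\log 0$); with it leaves attain the maximal specificity factor 1,
  consistent with deeper terms carrying more specific meaning.
* **`depth(root) = 1`**, which forces $IC(root) = 0$ under every model —
  the anchor the set-IC decomposition below relies on.
* **Max-normalization** (`normalize = TRUE`, the default) divides by the
  largest raw score so values live on $[0,1]$ with maximum exactly 1. The
  raw formula is unbounded, so normalization is the minimal reading under
  which IC is a $[0,1]$ quantity; raw mode is kept for hand-checked tests.

Two comparison IC models ship alongside: the corpus model
$IC(t) = -\log p(t)$, with $p(t)$ the fraction of genes whose
ancestor-closed annotations contain $t$ (terms annotating no gene get the
maximum observed IC, flagged, rather than $+\infty$, keeping arithmetic
finite), and the Sánchez structural model
$-\log\big[(|leaves(t)|/|subsumers(t)| + 1)/(max\_leaves + 1)\big]$ with
subsumers including the term itself.

## Edge weights and the inherited/own decomposition

Each edge $t_i \to t_j$ carries a specificity weight

$$\omega_{ij} = \frac{\sum_{t \in Desc(t_j)} IC(t)}
                     {\sum_{t \in Desc(t_i)} IC(t)}$$

with self-inclusive descendant sets. Self-inclusion is load-bearing: with
exclusive sets every edge into a leaf would have numerator 0, making
leaves inherit nothing, and the ratio could be $0/0$ at the bottom of the
graph. Self-inclusively, the numerator set is contained in the denominator
set, so $\omega \in (0, 1]$; an all-zero-IC subgraph yields $\omega = 1$
by convention.

A term's IC then splits into what it inherits from its direct parents and
what is its own:

$$IC_{inh}(t_j) = \sum_{t_i \in Parent(t_j)} \omega_{ij}\, IC(t_i),
\qquad IC_{own}(t_j) = IC(t_j) - IC_{inh}(t_j).$$

For multi-parent terms the inherited sum can exceed $IC(t_j)$; `own_ic()`
clamps such residuals at 0 and flags them, so own-IC values are always
usable as non-negative semantic increments. The IC of an ancestor-closed
term set $T$ is then simply $IC(T) = \sum_{t \in T} IC_{own}(t)$ —
summing increments avoids double-counting semantics shared through the
hierarchy. The closure precondition is what makes the parent lookups in
the inherited sum total; `set_ic()` applies it internally. Because own-IC
is a per-term function, the accumulated total is independent of which
topological order the terms are processed in.

### The bundled worked example

`worked_example()` returns an eight-term DAG with ten edges together with
*injected* term-IC and edge-weight tables. The weights are not
recomputable from the eight IC values because they were derived on the
full ontology, of which the fixture is an excerpt — so the fixture treats
both tables as given inputs and exercises exactly the decomposition and
accumulation stages:

```{r}
we <- worked_example()
set_ic_trace(we$terms, we$graph, we$ic, we$weights)
```

The trace formatter rounds each own value half-up to 3 decimals before
accumulating, the convention used when such traces are printed by hand;
internal arithmetic (`set_ic()`) is always full precision. Half-up
rounding is implemented with a $10^{-9}$ guard so values that are exact
halves after decimal printing (but sit just below the half in binary)
still round up.

## Gene similarity

With $T_G$ the ancestor closure of gene $G$'s direct annotations,

$$sim_{STE}(G_1, G_2) = \frac{IC(T_{G_1} \cap T_{G_2})}
                             {IC(T_{G_1} \cup T_{G_2})}.$$

Intersections and unions of closed sets are closed, so both set-IC values
are well defined. Closure-first is the only workable order: intersecting
direct sets before closing would usually produce an empty numerator.
Identical closed sets score exactly 1; sets meeting only at the root score
0 (the root's own IC is 0). A gene without annotations yields a flagged
`NA`, never a silent 0 — 0 is a meaningful score.

Baselines, all operating on the same closed sets (the root stays in; its
IC is 0, so it only affects the counting denominators, as those methods
are defined): simUI (Jaccard), VSM (cosine of one-hot vectors), simGIC
(plain-IC-weighted Jaccard), and Resnik with best-match averaging over the
*direct* sets, where the "lowest" common ancestor is realized as the
maximum-IC common ancestor — the standard reading when a DAG offers
several.

## Evaluation harnesses

`roc_auc()` scores how well a similarity separates positive from negative
gene pairs, using the midrank (Wilcoxon) formula — equivalent to the
trapezoid rule on the empirical ROC and well defined under ties.
`pearson_eval()` correlates similarity with an expression-derived
similarity table. Both drop pairs with undefined scores and report the
count; they never silently shrink their input. `classification_matrix()`
summarizes an all-vs-all similarity matrix as mean within-class versus
between-class similarity for genes carrying functional class labels.

Published benchmark values for these protocols depend on specific
ontology, annotation, interaction and expression releases (and on a
random subsample of pairs), so the harnesses here are validated by their
calibration properties instead: AUC is invariant under monotone score
transforms and sits at $0.50$ on label-independent scores; Pearson $r$ is
invariant under positive affine maps and vanishes on independent vectors.

## The synthetic generator

`generate_ontology()` builds layered random DAGs: one root, layer sizes
following a symmetric binomial profile over depths $2..max\_depth$
(unimodal with an interior mode, echoing real GO namespaces where most
terms sit at intermediate depth), each node anchored to a parent in the
layer above — so longest-path depth equals layer — plus optional extra
parents from shallower layers (`multi_parent_prob`, default 0.2; roughly
the flavor of multiple inheritance in real GO). A fraction of edges
(default 0.1) is labeled `part_of`.

`generate_annotations()` gives each gene $\mathrm{Pois}(\mu-1)+1$ direct
terms (mean $\mu$, default 4 — a typical direct-annotation set size),
sampled with probability proportional to depth, because real corpora
mostly annotate specific terms; evidence codes are `IEA` with probability
`iea_fraction` (default 0.3), else `EXP`, supporting IEA+/IEA−
stratification.

What the generator does *not* emulate: correlated annotations between
related genes, realistic term-name text, skewed gene-annotation richness,
and the sheer size of real namespaces. Passing tests on synthetic data
therefore demonstrate correctness of the algebra and calibration of the
harnesses, not performance claims on real corpora. Test and example
problem sizes (hundreds of terms, tens of genes) are chosen to keep every
property checkable in seconds while still exercising multi-parent,
multi-path topology.

## Degenerate inputs and numerical notes

* Empty term set: an error in `set_ic()` (distinct from the legitimate
  value 0 for `{root}`).
* All-zero IC below an edge: $\omega = 1$ by convention.
* `sim_ste` with a zero-IC union (no off-root information): flagged `NA`.
* Corpus IC of never-annotated terms: maximum observed IC, flagged.
* Unknown or obsolete terms in annotation input: dropped and counted,
  never silently kept; unknown terms in direct API calls raise errors
  naming the term.
* All validation (acyclicity, unique root, connectivity) happens at graph
  construction, so downstream code can assume a well-formed DAG.

## Limitations

* Cross-namespace similarity is out of scope; one graph, one namespace.
* Relations beyond `is_a`/`part_of` are ignored (with a count), so
  regulatory structure contributes nothing to IC here.
* The clamp on negative own-IC residuals discards the (rare) signal that
  a term's IC model and its parents' disagree; clamp counts are reported
  so heavy clamping is visible.
* Resnik/BMA scores are bounded by the maximum IC of the annotation sets,
  so self-similarity below 1 is expected behavior for that baseline, not
  a defect.
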