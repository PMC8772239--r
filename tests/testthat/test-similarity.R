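# two genes on the worked DAG: direct sets {t6} and {t7};
# closed sets {t1,t2,t3,t4,t6} and {t1,...,t5,t7}
we_map <- function(we) {
  annotation_map(data.frame(
    gene = c("gA", "gB", "gC"),
    term = c("GO:0000006", "GO:0000007", "GO:0000006"),
    evidence = "EXP"), namespace = "BP")
}

test_that("group-wise scores on the worked fixture match direct counting", {
  we <- worked_example()
  map <- we_map(we)

  # closure counting on the edge list: |A| = 5, |B| = 6, overlap 4,
  # union 7 (consistent with the simGIC union mass over t1..t7 below)
  expect_equal(sim_ui("gA", "gB", map, we$graph), 4 / 7)
  expect_equal(sim_vsm("gA", "gB", map, we$graph), 4 / sqrt(5 * 6))
  # simGIC: shared IC mass {t1..t4} over union mass {t1..t7}
  expect_equal(sim_gic("gA", "gB", map, we$graph, we$ic), 0.07 / 0.28)

  inter <- set_ic(sprintf("GO:%07d", 1:4), we$graph, we$ic, we$weights)
  uni <- set_ic(sprintf("GO:%07d", 1:7), we$graph, we$ic, we$weights)
  got <- sim_ste("gA", "gB", map, we$graph, we$ic, we$weights)
  expect_equal(got, inter / uni)
  # cross-check both set-IC values with the brute-force oracle
  omega <- stats::setNames(we$weights$omega,
                           paste(we$weights$parent, we$weights$child))
  expect_equal(got,
               bf_set_ic(sprintf("GO:%07d", 1:4), we$graph$edges,
                         we$ic$values, omega) /
                 bf_set_ic(sprintf("GO:%07d", 1:7), we$graph$edges,
                           we$ic$values, omega))
})

test_that("identical annotation sets score 1; root-only overlap scores 0", {
  we <- worked_example()
  map <- we_map(we)
  for (fn in list(
    function(a, b) sim_ste(a, b, map, we$graph, we$ic, we$weights),
    function(a, b) sim_ui(a, b, map, we$graph),
    function(a, b) sim_vsm(a, b, map, we$graph),
    function(a, b) sim_gic(a, b, map, we$graph, we$ic)))
    expect_equal(fn("gA", "gC"), 1)

  # sibling leaves under the root share only the root after closure
  g <- ontology_graph(data.frame(parent = c("r", "r"),
                                 child = c("x", "y"), relation = "is_a"))
  ic <- ic_table(c(r = 0, x = 1, y = 1), "injected", g)
  w <- edge_weights(g, ic)
  m <- annotation_map(data.frame(gene = c("g1", "g2"), term = c("x", "y"),
                                 evidence = "EXP"))
  expect_equal(sim_ste("g1", "g2", m, g, ic, w), 0)
  expect_equal(sim_gic("g1", "g2", m, g, ic), 0)
  expect_gt(sim_ui("g1", "g2", m, g), 0)   # shared root still counts
  expect_gt(sim_vsm("g1", "g2", m, g), 0)
})

test_that("unannotated genes yield flagged NA, never 0", {
  we <- worked_example()
  map <- we_map(we)
  expect_true(is.na(sim_ste("gA", "nope", map, we$graph, we$ic,
                            we$weights)))
  expect_true(is.na(sim_ui("nope", "gA", map, we$graph)))
  res <- sim_pairs(data.frame(geneA = c("gA", "gA"),
                              geneB = c("gB", "nope")),
                   "ste", map, we$graph, we$ic, we$weights)
  expect_equal(res$defined, c(TRUE, FALSE))
})

test_that("Resnik/BMA uses the most informative common ancestor", {
  we <- worked_example()
  g <- we$graph
  # ancestor pair: max-IC common ancestor of (t2, t4) is t2 itself
  m <- annotation_map(data.frame(gene = c("u", "v", "w", "z"),
                                 term = c("GO:0000002", "GO:0000004",
                                          "GO:0000006", "GO:0000005"),
                                 evidence = "EXP"))
  expect_equal(sim_resnik_bma("u", "v", m, g, we$ic), 0.01)
  # singleton self-comparison returns the term's own IC
  expect_equal(sim_resnik_bma("v", "v", m, g, we$ic), 0.04)
  # t6 vs t5: common ancestors {t1, t3}; max IC = IC(t3)
  expect_equal(sim_resnik_bma("w", "z", m, g, we$ic), 0.02)
  # leaves meeting only at the root score 0
  g2 <- ontology_graph(data.frame(parent = c("r", "r"),
                                  child = c("x", "y"), relation = "is_a"))
  ic2 <- ic_table(c(r = 0, x = 1, y = 1), "injected", g2)
  m2 <- annotation_map(data.frame(gene = c("g1", "g2"),
                                  term = c("x", "y"), evidence = "EXP"))
  expect_equal(sim_resnik_bma("g1", "g2", m2, g2, ic2), 0)
})

test_that("when all own-IC increments are equal, the STE score reduces to
           Jaccard over non-root terms", {
  # tree with IC(t) = depth - 1 and unit edge weights: own(t) = 1 off root
  g <- generate_ontology(40, max_depth = 5, multi_parent_prob = 0,
                         seed = 9)
  depth <- term_depths(g)
  ic <- ic_table(depth - 1, "injected", g)
  w <- edge_weight_table(g$edges$parent, g$edges$child,
                         omega = rep(1, nrow(g$edges)))
  map <- generate_annotations(g, n_genes = 12, mean_terms = 3, seed = 9)
  for (i in 1:10) {
    pair <- sample(map$genes, 2)
    A <- ancestor_closure(gene_terms(map, pair[1]), g)
    B <- ancestor_closure(gene_terms(map, pair[2]), g)
    expected <- (length(intersect(A, B)) - 1) / (length(union(A, B)) - 1)
    expect_equal(sim_ste(pair[1], pair[2], map, g, ic, w), expected)
  }
})

test_that("pairwise matrix is symmetric with unit diagonal", {
  we <- worked_example()
  map <- we_map(we)
  m <- pairwise_matrix(c("gA", "gB", "gC"), "ste", map, we$graph, we$ic,
                       we$weights)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), c(1, 1, 1))
  expect_equal(m["gA", "gC"], 1)  # identical annotation sets
  m2 <- pairwise_matrix(c("gA", "gA"), "simui", map, we$graph)
  expect_equal(m2, matrix(1, 2, 2, dimnames = list(c("gA", "gA"),
                                                   c("gA", "gA"))))
})
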