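fake_scores <- function(geneA, geneB, score) {
  out <- data.frame(geneA = geneA, geneB = geneB, score = score,
                    defined = !is.na(score), stringsAsFactors = FALSE)
  class(out) <- c("similarity_result", "data.frame")
  out
}

test_that("AUC: perfect separation, single top positive, class errors", {
  g <- sprintf("p%02d", 1:20)
  pairs <- data.frame(geneA = g[1:10], geneB = g[11:20])
  lab <- labeled_pairs(pairs$geneA, pairs$geneB, rep(c(1, 0), each = 5))
  expect_equal(roc_auc(fake_scores(pairs$geneA, pairs$geneB,
                                   rep(c(1, 0), each = 5)), lab)$auc, 1)
  one_top <- labeled_pairs(pairs$geneA, pairs$geneB, c(1, rep(0, 9)))
  expect_equal(roc_auc(fake_scores(pairs$geneA, pairs$geneB,
                                   c(0.9, stats::runif(9, 0, 0.5))),
                       one_top)$auc, 1)
  allpos <- labeled_pairs(pairs$geneA, pairs$geneB, rep(1, 10))
  expect_error(roc_auc(fake_scores(pairs$geneA, pairs$geneB,
                                   stats::runif(10)), allpos),
               "both positive and negative")
})

test_that("AUC is invariant under strictly monotone score transforms and
           counts dropped pairs", {
  set.seed(1)
  n <- 200
  a <- sprintf("a%03d", 1:n); b <- sprintf("b%03d", 1:n)
  s <- stats::runif(n)
  lab <- labeled_pairs(a, b, as.integer(s + stats::rnorm(n, 0, 0.3) > 0.5))
  auc1 <- roc_auc(fake_scores(a, b, s), lab)
  auc2 <- roc_auc(fake_scores(a, b, exp(5 * s)), lab)
  expect_equal(auc1$auc, auc2$auc)

  s_na <- s; s_na[1:10] <- NA
  dropped <- roc_auc(fake_scores(a, b, s_na), lab)
  expect_equal(dropped$n_dropped, 10L)
  expect_equal(dropped$n_used, n - 10L)
})

test_that("AUC with midrank tie handling agrees with an independent ROC
           implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  n <- 500
  y <- stats::rbinom(n, 1, 0.5)
  s <- round(stats::runif(n), 1)  # heavy ties
  a <- sprintf("a%03d", 1:n); b <- sprintf("b%03d", 1:n)
  got <- roc_auc(fake_scores(a, b, s), labeled_pairs(a, b, y))$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("Pearson harness: exact endpoints, affine invariance, flags", {
  a <- sprintf("a%02d", 1:30); b <- sprintf("b%02d", 1:30)
  set.seed(2)
  v <- stats::rnorm(30)
  expr <- data.frame(geneA = a, geneB = b, value = v)
  expect_equal(pearson_eval(fake_scores(a, b, v), expr)$r, 1)
  expect_equal(pearson_eval(fake_scores(a, b, -v), expr)$r, -1)
  expect_equal(pearson_eval(fake_scores(a, b, 3 * v + 2), expr)$r, 1)
  flat <- pearson_eval(fake_scores(a, b, rep(0.5, 30)), expr)
  expect_true(is.na(flat$r))
  expect_error(pearson_eval(fake_scores(a[1:2], b[1:2], v[1:2]),
                            expr[1:2, ]), "at least 3")
})

test_that("classification summary separates within from between classes", {
  # two term-disjoint clades; class 1 genes on one, class 2 on the other
  g <- ontology_graph(data.frame(
    parent = c("r", "r", "x", "y"), child = c("x", "y", "x1", "y1"),
    relation = "is_a"))
  ic <- ic_table(c(r = 0, x = 0.5, y = 0.5, x1 = 1, y1 = 1), "injected", g)
  w <- edge_weights(g, ic)
  map <- annotation_map(data.frame(
    gene = c("g1", "g2", "g3", "g4"),
    term = c("x1", "x1", "y1", "y1"), evidence = "EXP"))
  res <- classification_matrix(c("g1", "g2", "g3", "g4"),
                               c("A", "A", "B", "B"), "ste", map, g, ic, w)
  expect_equal(res$within_mean, 1)
  expect_equal(res$between_mean, 0)
  expect_equal(res$difference, 1)
  expect_equal(res$matrix, t(res$matrix))
  expect_equal(unname(diag(res$matrix)), rep(1, 4))
  expect_error(classification_matrix(c("g1", "g2"), c("A", "A"), "simui",
                                     map, g), "at least 2 classes")
  single <- classification_matrix(c("g1", "g2", "g3"), c("A", "A", "B"),
                                  "simui", map, g)
  expect_equal(single$singleton_classes, "B")
})

test_that("shuffled class labels give no within/between separation", {
  g <- generate_ontology(60, seed = 13)
  map <- generate_annotations(g, n_genes = 20, mean_terms = 3, seed = 13)
  set.seed(13)
  res <- classification_matrix(map$genes,
                               sample(rep(c("A", "B"), 10)), "simui",
                               map, g)
  expect_lt(abs(res$difference), 0.15)
})

test_that("labeled pair sets reject duplicate unordered pairs", {
  expect_error(labeled_pairs(c("a", "b"), c("b", "a"), c(1, 0)),
               "duplicate")
  lp <- labeled_pairs(c("a", "a"), c("b", "c"), c("positive", "negative"))
  expect_equal(lp$label, c(1L, 0L))
})

test_that("pair tables round-trip through TSV readers", {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(geneA = c("a", "b"), geneB = c("c", "d"),
                                label = c("positive", "negative")),
                     f, sep = "\t", row.names = FALSE, quote = FALSE)
  lp <- read_labeled_pairs(f)
  expect_equal(lp$label, c(1L, 0L))
  f2 <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(geneA = "a", geneB = "b", value = 0.25),
                     f2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_expression_pairs(f2)$value, 0.25)
})
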