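fake_profiles <- function(n, seed = 1, shift = 0, groups = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(NULL, c("N", "K", "D", "C", "L", "H", "A", "P")))
  if (!is.null(groups)) x[groups == levels(factor(groups))[2], ] <-
      x[groups == levels(factor(groups))[2], ] + shift
  data.frame(specimen_id = sprintf("s%02d", seq_len(n)), x,
             stringsAsFactors = FALSE)
}

test_that("variance fractions are non-increasing and sum to one", {
  prof <- fake_profiles(12, seed = 2)
  ms <- pca_profiles(prof)
  expect_equal(sum(ms$variance_fraction), 1, tolerance = 1e-10)
  expect_true(all(diff(ms$variance_fraction) <= 1e-12))
  expect_lte(ncol(ms$scores), min(nrow(prof) - 1, 8))
})

test_that("a cohort with two distinct rows is rank one: PC1 explains 100%", {
  prof <- fake_profiles(3, seed = 3)
  prof[3, -1] <- prof[1, -1]   # only two distinct specimens
  ms <- pca_profiles(prof)
  expect_equal(ms$variance_fraction[1], 1, tolerance = 1e-10)
})

test_that("zero-variance columns are rejected by name", {
  prof <- fake_profiles(6, seed = 4)
  prof$D <- 0.3
  err <- tryCatch(pca_profiles(prof), skullnet_zero_variance = function(e) e)
  expect_match(conditionMessage(err), "D")
})

test_that("scores are reproducible under specimen reordering and sign-fixed", {
  prof <- fake_profiles(10, seed = 5)
  ms1 <- pca_profiles(prof)
  perm <- sample(nrow(prof))
  ms2 <- pca_profiles(prof[perm, ])
  expect_equal(ms2$scores[order(perm), ], ms1$scores, tolerance = 1e-8)
  expect_equal(ms2$loadings, ms1$loadings, tolerance = 1e-8)
  for (j in seq_len(ncol(ms1$loadings)))
    expect_gt(ms1$loadings[which.max(abs(ms1$loadings[, j])), j], 0)
})

test_that("pseudo-F from distances equals the classical trace formula", {
  set.seed(8)
  x <- matrix(rnorm(12 * 4), 12, 4)
  g <- rep(c("u", "v"), each = 6)
  pm <- permanova(x, g, n_perm = 9, seed = 1)
  expect_equal(pm$F, o_trace_F(x, g), tolerance = 1e-10)
  expect_equal(pm$df_between, 1)
  expect_equal(pm$df_within, 10)
  expect_gte(pm$R2, 0); expect_lte(pm$R2, 1)
})

test_that("permanova agrees with vegan::adonis2 on F and R2", {
  skip_if_not_installed("vegan")
  set.seed(9)
  x <- matrix(rnorm(15 * 5), 15, 5)
  g <- factor(rep(c("a", "b", "c"), each = 5))
  pm <- permanova(x, g, n_perm = 99, seed = 2)
  ad <- vegan::adonis2(stats::dist(x) ~ g, permutations = 99)
  expect_equal(pm$F, ad$F[1], tolerance = 1e-10)
  expect_equal(pm$R2, ad$R2[1], tolerance = 1e-10)
})

test_that("exact permutation mode enumerates all distinct labelings", {
  set.seed(10)
  x <- matrix(rnorm(6 * 3), 6, 3)
  g <- rep(c("a", "b"), each = 3)
  pm <- permanova(x, g, permutations = "exact")
  expect_equal(pm$n_perm, 20)   # C(6,3) distinct assignments
  expect_gte(pm$p, 1 / 20)
})

test_that("permanova input guards fire", {
  x <- matrix(rnorm(10 * 2), 10, 2)
  expect_error(permanova(x, c(rep("a", 9), "b"), n_perm = 9),
               class = "skullnet_bad_input")       # singleton group
  expect_error(permanova(x, rep("a", 10), n_perm = 9),
               class = "skullnet_bad_input")       # one group
  xc <- matrix(1, 6, 2)
  expect_error(permanova(xc, rep(c("a", "b"), 3), n_perm = 9),
               class = "skullnet_degenerate")      # constant distances
})

test_that("p-values are seed-reproducible and F is seed-independent", {
  set.seed(11)
  x <- matrix(rnorm(14 * 4), 14, 4)
  g <- rep(c("a", "b"), each = 7)
  p1 <- permanova(x, g, n_perm = 199, seed = 5)
  p2 <- permanova(x, g, n_perm = 199, seed = 5)
  p3 <- permanova(x, g, n_perm = 199, seed = 6)
  expect_identical(p1$p, p2$p)
  expect_identical(p1$F, p3$F)
})

test_that("grouping suite emits one row per scheme and respects subsamples", {
  md <- data.frame(specimen_id = sprintf("s%02d", 1:12),
                   group = rep(c("g1", "g2"), each = 6),
                   stage = rep(c("adult", "juvenile"), 6),
                   neornithes = rep(c(FALSE, TRUE), each = 6),
                   stringsAsFactors = FALSE)
  prof <- fake_profiles(12, seed = 12, shift = 3, groups = md$group)
  res <- run_grouping_suite(prof, md, schemes = c("group", "stage"),
                            subsamples = "all", n_perm = 99, seed = 1)
  expect_equal(nrow(res), 2)
  # excluding modern birds leaves only g1, so 'group' collapses
  expect_message(
    res2 <- run_grouping_suite(prof, md, schemes = c("group", "stage"),
                               subsamples = "no-birds", n_perm = 99, seed = 1),
    "skipped")
  expect_equal(res2$scheme, "stage")
  expect_equal(res2$n, 6)
})

test_that("a large planted group effect is detected with high power", {
  md <- data.frame(specimen_id = sprintf("s%02d", 1:16),
                   group = rep(c("g1", "g2"), each = 8),
                   stringsAsFactors = FALSE)
  prof <- fake_profiles(16, seed = 13, shift = 4, groups = md$group)
  res <- run_grouping_suite(prof, md, schemes = "group",
                            subsamples = "all", n_perm = 999, seed = 2)
  expect_lte(res$p, 0.01)
})
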