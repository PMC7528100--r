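test_that("template skull has the expected size, symmetry and sparsity", {
  tpl <- make_template_skull(n_half = 10, n_midline = 4, seed = 2)
  expect_equal(n_bones(tpl), 24)   # 2*10 + 4
  d <- net_density(tpl)
  expect_gt(d, 0.1); expect_lt(d, 0.5)
  # side-swap relabeling is an isomorphism: identical metric values
  swap <- function(x) ifelse(startsWith(x, "L."), sub("^L\\.", "R.", x),
                             ifelse(startsWith(x, "R."),
                                    sub("^R\\.", "L.", x), x))
  e <- tpl$articulations
  mirror <- skull_network(cbind(swap(e[, 1]), swap(e[, 2])))
  expect_equal(sort(mirror$bones), sort(tpl$bones))
  for (f in list(net_density, net_clustering, net_path_length,
                 net_heterogeneity))
    expect_equal(f(mirror), f(tpl), tolerance = 1e-12)
  # a fixed seed reproduces the template exactly
  expect_identical(tpl$articulations,
                   make_template_skull(10, 4, seed = 2)$articulations)
  expect_error(make_template_skull(10, 0, seed = 1),
               class = "skullnet_bad_input")
})

test_that("fusion trajectories decrease N by exactly one per event", {
  tpl <- make_template_skull(n_half = 8, n_midline = 3, seed = 5)
  traj <- simulate_fusion_trajectory(tpl, 6, bias = 2, seed = 7)
  sizes <- vapply(traj, n_bones, integer(1))
  expect_true(all(diff(sizes) == -1))
  expect_equal(sizes[1], n_bones(tpl) - 1)
  expect_equal(n_bones(traj[[length(traj)]]),
               n_bones(tpl) - attr(traj, "n_events"))
  expect_gte(attr(traj, "n_events"), 6)
})

test_that("strong within-module bias concentrates fusions inside modules", {
  tpl <- make_template_skull(n_half = 12, n_midline = 4, seed = 1)
  fracs <- vapply(1:40, function(s) {
    traj <- simulate_fusion_trajectory(tpl, 5, bias = 50, mirror_prob = 0,
                                       seed = s)
    attr(traj, "within_module_fraction")
  }, numeric(1))
  expect_gt(mean(fracs), 0.8)
})

test_that("planted partitions reproduce their blocks in the limit case", {
  pp <- planted_partition_network(c(5, 5, 5), 1, 0, seed = 3)
  ms <- detect_modules(pp$network, seed = 4)
  part <- factor(ms$partition[pp$network$bones])
  nmi <- igraph::compare(as.integer(part), as.integer(pp$truth),
                         method = "nmi")
  expect_equal(nmi, 1)
  expect_error(planted_partition_network(c(5, 5), 0.1, 0.5, seed = 1),
               class = "skullnet_bad_input")
})

test_that("planted edge counts match the binomial expectation", {
  sizes <- c(8, 8, 8); p_in <- 0.5; p_out <- 0.1
  n_within <- sum(choose(sizes, 2))
  n_between <- choose(sum(sizes), 2) - n_within
  mu <- n_within * p_in + n_between * p_out
  sdev <- sqrt(n_within * p_in * (1 - p_in) + n_between * p_out * (1 - p_out))
  ks <- vapply(1:200, function(s) {
    pp <- planted_partition_network(sizes, p_in, p_out, seed = s)
    n_articulations(pp$network) - pp$n_bridges
  }, integer(1))
  expect_lt(abs(mean(ks) - mu), 3 * sdev / sqrt(200))
})

test_that("cohorts have the requested size, group effect and reproducibility", {
  groups <- list(
    list(label = "juv", n = 6, fusions = c(0, 2),
         meta = list(stage = "juvenile", neornithes = TRUE)),
    list(label = "ad", n = 6, fusions = c(10, 14),
         meta = list(stage = "adult", neornithes = TRUE)))
  ch <- make_cohort(groups, n_half = 10, n_midline = 4, seed = 21)
  expect_equal(length(ch$networks), 12)
  expect_equal(nrow(ch$metadata), 12)
  d <- vapply(ch$networks, net_density, numeric(1))
  grp <- ch$metadata$group[match(names(ch$networks),
                                 ch$metadata$specimen_id)]
  # fusion raises density on these templates
  expect_gt(mean(d[grp == "ad"]), mean(d[grp == "juv"]))
  # bit-identical regeneration from the master seed
  ch2 <- make_cohort(groups, n_half = 10, n_midline = 4, seed = 21)
  expect_identical(lapply(ch$networks, `[[`, "articulations"),
                   lapply(ch2$networks, `[[`, "articulations"))
  # every generated network satisfies the invariants
  for (net in ch$networks)
    expect_s3_class(validate_skull_network(net), "skull_network")
})

test_that("PERMANOVA power is monotone in the fusion gap between groups", {
  gap_p <- vapply(c(0, 8, 16), function(gap) {
    groups <- list(
      list(label = "g1", n = 6, fusions = c(2, 4), meta = list()),
      list(label = "g2", n = 6, fusions = c(2 + gap, 4 + gap), meta = list()))
    ch <- make_cohort(groups, n_half = 12, n_midline = 4,
                      seed = 31 + gap)
    prof <- suppressWarnings(profiles_table(ch$networks, seed = 3))
    ms <- pca_profiles(prof)
    permanova(ms$scores, ch$metadata$group, n_perm = 199, seed = 4)$p
  }, numeric(1))
  expect_true(all(diff(gap_p) <= 0.05))
  expect_lt(gap_p[3], 0.05)
})
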