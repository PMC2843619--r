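test_that("nested ANOVA reproduces the hand-worked fixture", {
  # batches {1,3} and {5,7}: MS_W = 2, MS_B = 16, n0 = 2 -> s2 = 2, s2_A = 7
  x <- make_em(matrix(c(1, 3, 5, 7), 1, 4))
  plan <- make_plan(sample_ids(x), c("r1", "r1", "r2", "r2"))
  vc <- nested_anova(x, plan)
  expect_equal(vc$sigma2_within, 2)
  expect_equal(vc$sigma2_between, 7)
  expect_equal(vc$mu, 4)
  # all-identical values give zero components
  xc <- make_em(matrix(5, 3, 4))
  vc0 <- nested_anova(xc, plan)
  expect_true(all(vc0$sigma2_between == 0))
  expect_true(all(vc0$sigma2_within == 0))
})

test_that("nested ANOVA equals the brute-force oracle on random fixtures", {
  set.seed(51)
  for (rep in 1:100) {
    b <- sample(2:4, 1)
    sizes <- sample(1:4, b, replace = TRUE)
    if (all(sizes < 2)) sizes[1] <- 2
    batch <- rep(paste0("r", seq_len(b)), sizes)
    G <- 5
    v <- matrix(rnorm(G * length(batch), 8), G, length(batch))
    x <- make_em(v)
    plan <- make_plan(sample_ids(x), batch)
    vc <- nested_anova(x, plan)
    for (g in seq_len(G)) {
      oracle <- brute_varcomp(v[g, ], batch)
      expect_equal(vc$sigma2_within[g], oracle$sigma2_within,
                   tolerance = 1e-10)
      expect_equal(vc$sigma2_between[g], oracle$sigma2_between,
                   tolerance = 1e-10)
    }
  }
})

test_that("the between-batch component truncates at zero on pure noise", {
  set.seed(52)
  x <- make_em(matrix(rnorm(500 * 10, 8, 0.2), 500, 10))
  plan <- make_plan(sample_ids(x), rep(c("r1", "r2"), each = 5))
  vc <- nested_anova(x, plan)
  expect_gt(mean(vc$sigma2_between == 0), 0)
  expect_lt(median(vc$sigma2_between), 0.005)
  expect_true(all(vc$between_share_sd >= 0 & vc$between_share_sd <= 1))
})

test_that("nested ANOVA recovers the planted variance components", {
  med_a <- med_w <- numeric(5)
  for (s in 1:5) {
    sim <- simulate_experiment(sim_config(n_genes = 2000, seed = s))
    lg <- log2_transform(sim$expr)
    vc <- nested_anova(lg, sim$plan, role = "reference")
    med_a[s] <- median(vc$sd_between)
    med_w[s] <- median(vc$sd_within)
  }
  expect_lt(abs(median(med_a) - 0.22) / 0.22, 0.15)
  expect_lt(abs(median(med_w) - 0.18) / 0.18, 0.10)
})

test_that("pairwise correlations behave on degenerate inputs", {
  set.seed(53)
  base <- rnorm(30, 8)
  v <- cbind(base, base, 16 - base)  # duplicate and mirrored samples
  x <- make_em(v)
  r <- pairwise_correlation(x)
  expect_equal(r["s01", "s02"], 1)
  expect_equal(r["s01", "s03"], -1)
  expect_true(isSymmetric(r))
  expect_true(all(diag(r) == 1))
  vz <- cbind(base, rep(2, 30))
  expect_warning(rz <- pairwise_correlation(make_em(vz)), "zero-variance")
  expect_true(is.na(rz["s01", "s02"]))
})

test_that("batch correction closes the within/between-run correlation gap", {
  gaps <- sapply(1:3, function(s) {
    sim <- simulate_experiment(sim_config(n_genes = 800, seed = s + 60))
    refs <- sim$plan$sample_id[sim$plan$role == "reference"]
    lg <- quantile_normalize(log2_transform(em_subset(sim$expr,
                                                      samples = refs)))
    runs <- sim$plan$run_id[match(refs, sim$plan$sample_id)]
    gap <- function(m) {
      r <- pairwise_correlation(m)
      same <- outer(runs, runs, "==") & upper.tri(r)
      diff <- outer(runs, runs, "!=") & upper.tri(r)
      mean(r[same]) - mean(r[diff])
    }
    g_qn <- gap(lg)
    g_cb <- gap(eb_batch_correct(lg, sim$plan)$expr)
    c(g_qn, g_cb)
  })
  expect_true(all(gaps[1, ] > 0))                 # within-run > between-run
  expect_true(all(1 - gaps[2, ] / gaps[1, ] >= 0.8))  # CB closes >= 80%
})

test_that("replicate differences summarise signed pair differences", {
  v <- cbind(rep(8, 10), rep(8, 10), rep(8.5, 10))
  x <- make_em(v)
  same <- replicate_differences(x, data.frame(id1 = "s01", id2 = "s02"))
  expect_equal(same$mean, 0); expect_equal(same$sd, 0)
  shift <- replicate_differences(x, data.frame(id1 = "s03", id2 = "s01"))
  expect_equal(shift$mean, 0.5); expect_equal(shift$sd, 0)
  expect_error(replicate_differences(x, data.frame(id1 = "nope", id2 = "s01")),
               "unknown sample")
  # antisymmetry of the pooled mean under pair reversal
  set.seed(54)
  xr <- make_em(matrix(rnorm(80, 8), 20, 4))
  fwd <- replicate_differences(xr, data.frame(id1 = c("s01", "s02"),
                                              id2 = c("s03", "s04")))
  rev <- replicate_differences(xr, data.frame(id1 = c("s03", "s04"),
                                              id2 = c("s01", "s02")))
  expect_equal(fwd$mean, -rev$mean)
  expect_equal(fwd$sd, rev$sd)
})

test_that("ComBat-corrected inter-run differences are tighter than QN-only", {
  narrower <- sapply(1:5, function(s) {
    sim <- simulate_experiment(sim_config(n_genes = 500, seed = s + 70))
    refs <- sim$plan$sample_id[sim$plan$role == "reference"]
    lg <- quantile_normalize(log2_transform(em_subset(sim$expr,
                                                      samples = refs)))
    inter <- replicate_pairs(sim$plan, "reference", "inter")
    sd_qn <- replicate_differences(lg, inter[, c("id1", "id2")])$sd
    cb <- eb_batch_correct(lg, sim$plan)$expr
    sd_cb <- replicate_differences(cb, inter[, c("id1", "id2")])$sd
    sd_cb < sd_qn
  })
  expect_true(all(narrower))
})

test_that("coefficient of variation matches hand-computed values", {
  x13 <- make_em(matrix(c(1, 3), 1, 2), scale = "linear")
  expect_equal(coefficient_of_variation(x13)$mean_cv, 100 * sqrt(2) / 2,
               tolerance = 1e-10)
  x4 <- make_em(matrix(c(10, 10, 10, 20), 1, 4), scale = "linear")
  expect_equal(coefficient_of_variation(x4)$mean_cv, 40.0)
  ident <- make_em(matrix(7, 5, 3), scale = "linear")
  expect_equal(coefficient_of_variation(ident)$mean_cv, 0)
})

test_that("detection consistency fractions partition the probes", {
  expect_equal(detection_consistency(matrix(1, 4, 3))[["all_detected"]], 1)
  expect_equal(detection_consistency(matrix(0, 4, 3))[["all_undetected"]], 1)
  d <- rbind(c(0.9, 0.9), c(0.9, 0.1), c(0.1, 0.1))
  f <- detection_consistency(d, call_threshold = 0.8)
  expect_equal(unname(f), c(1, 1, 1) / 3)
  expect_equal(sum(f), 1)
})
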