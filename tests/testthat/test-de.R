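test_that("duplicate splitting keeps complete pre/post pairs per group", {
  plan <- default_study_plan()
  g <- suppressMessages(split_duplicates(plan))
  expect_equal(nrow(g$A), 21L)
  expect_equal(nrow(g$B), 21L)
  expect_equal(nrow(g$C), 42L)
  # a subject lacking its tag-b post sample drops out of B but stays in A
  drop_id <- plan$sample_id[plan$subject_id %in% "P01" &
                              plan$condition == "post" &
                              plan$replicate_tag == "b"]
  plan2 <- hyb_plan(as.data.frame(plan)[plan$sample_id != drop_id, ])
  g2 <- suppressMessages(split_duplicates(plan2))
  expect_true("P01.a" %in% g2$A$pair_id)
  expect_false("P01.b" %in% g2$B$pair_id)
  expect_equal(nrow(g2$B), 20L)
  # plan without duplicates errors
  refs_only <- hyb_plan(as.data.frame(plan)[plan$role == "reference", ])
  expect_error(split_duplicates(refs_only), "no duplicate")
})

test_that("moderated t handles all-zero genes and recovers the ordinary t", {
  dat <- make_paired_data(50, 8, effect = c(rep(0.6, 5), rep(0, 45)),
                          seed = 61)
  dat$x$values["g0001", ] <- 8          # constant gene: all differences zero
  r <- moderated_paired_t(dat$x, dat$pairs)
  expect_equal(r$logfc[1], 0)
  expect_equal(r$stat[1], 0)
  expect_equal(r$p[1], 1)
  # with the prior forced off, the statistic is the textbook paired t
  r0 <- moderated_paired_t(dat$x, dat$pairs, prior_df = 0)
  d <- dat$x$values[, dat$pairs$post] - dat$x$values[, dat$pairs$pre]
  for (g in c(2, 10, 30)) {
    expect_equal(r0$stat[g], unname(t.test(d[g, ])$statistic),
                 tolerance = 1e-9)
  }
  expect_error(moderated_paired_t(dat$x, dat$pairs[1, ]), "at least 2")
})

test_that("moderated t matches the limma empirical-Bayes fit", {
  skip_if_not_installed("limma")
  dat <- make_paired_data(400, 10, effect = c(rep(0.5, 30), rep(0, 370)),
                          seed = 62)
  r <- moderated_paired_t(dat$x, dat$pairs)
  d <- dat$x$values[, dat$pairs$post] - dat$x$values[, dat$pairs$pre]
  fit <- limma::eBayes(limma::lmFit(d))
  expect_equal(attr(r, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(r, "s02"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(r$stat, unname(fit$t[, 1]), tolerance = 1e-9)
  expect_equal(r$p, unname(fit$p.value[, 1]), tolerance = 1e-9)
})

test_that("moderated t is calibrated under the null", {
  rates <- sapply(1:5, function(s) {
    dat <- make_paired_data(2000, 21, sigma = 0.25, seed = 100 + s)
    mean(moderated_paired_t(dat$x, dat$pairs)$p < 0.05)
  })
  expect_lt(abs(mean(rates) - 0.05), 0.02)
})

test_that("BH adjustment equals the brute-force step-up procedure", {
  set.seed(63)
  for (rep in 1:10) {
    p <- runif(sample(5:50, 1))
    dat <- make_paired_data(length(p), 4, seed = rep)
    r <- moderated_paired_t(dat$x, dat$pairs)
    expect_equal(r$adj_p, brute_bh(r$p))
  }
})

test_that("SAM with few pairs enumerates sign patterns deterministically", {
  dat <- make_paired_data(60, 3, effect = c(rep(1, 6), rep(0, 54)), seed = 64)
  r1 <- sam_paired(dat$x, dat$pairs)
  r2 <- sam_paired(dat$x, dat$pairs)
  expect_identical(r1$q, r2$q)               # no seed needed: exhaustive
  expect_equal(attr(r1, "n_perm_used"), 8L)  # 2^3 patterns
  expect_error(sam_paired(dat$x, dat$pairs, n_perm = 5), "at least 10")
})

test_that("SAM q-values are monotone and controlled under the null", {
  # monotone non-increasing in |d|
  dat <- make_paired_data(300, 12, effect = c(rep(0.7, 20), rep(0, 280)),
                          seed = 65)
  r <- sam_paired(dat$x, dat$pairs, n_perm = 100, seed = 1)
  ord <- order(abs(r$stat), decreasing = TRUE)
  expect_true(all(diff(r$q[ord]) >= 0))
  # null control: no planted genes, realised FDR at q <= 0.05 is bounded
  false_calls <- sapply(1:10, function(s) {
    datn <- make_paired_data(400, 21, sigma = 0.25, seed = 200 + s)
    rn <- sam_paired(datn$x, datn$pairs, n_perm = 100, seed = s)
    sum(rn$q <= 0.05)
  })
  expect_lte(mean(false_calls / 400), 0.10)
})

test_that("SAM recovers strongly planted effects", {
  G <- 500; n_de <- 40
  dat <- make_paired_data(G, 21, effect = c(rep(0.8, n_de), rep(0, G - n_de)),
                          sigma = 0.18, seed = 66)
  r <- sam_paired(dat$x, dat$pairs, n_perm = 200, seed = 2)
  gl <- gene_list(r, fc = 1.5, fdr = 0.05)
  recall <- length(intersect(gl$probes, sprintf("g%04d", 1:n_de))) / n_de
  expect_gt(recall, 0.9)
})

test_that("gene-list thresholds are inclusive and monotone in fold change", {
  r <- structure(
    data.frame(probe_id = c("a", "b", "c"),
               logfc = c(log2(1.5), 0.3, 1),
               stat = c(3, 1, 5),
               p = c(0.001, 0.2, 1e-5),
               adj_p = c(0.01, 0.3, 1e-4)),
    class = c("de_result", "data.frame"), method = "moderated_t")
  gl <- gene_list(r, fc = 1.5, alpha = 0.01)
  expect_setequal(gl$probes, c("a", "c"))   # boundary gene 'a' included
  loose <- gene_list(r, fc = 1.2, alpha = 0.01)
  expect_true(all(gl$probes %in% loose$probes))
  empty <- structure(
    data.frame(probe_id = character(), logfc = numeric(), stat = numeric(),
               p = numeric(), adj_p = numeric()),
    class = c("de_result", "data.frame"), method = "moderated_t")
  expect_length(gene_list(empty)$probes, 0)
})

test_that("consensus is the rounded Jaccard percentage", {
  expect_equal(consensus_from_counts(192, 30, 23)$consensus, 11.6)
  expect_equal(consensus_from_counts(260, 211, 188)$consensus, 66.4)
  a <- chipbatch:::new_gene_list
  same <- a(c("x", "y")); other <- a(c("p", "q"))
  expect_equal(consensus(same, same)$consensus, 100)
  expect_equal(consensus(same, other)$consensus, 0)
  expect_equal(consensus(same, other)$n_overlap, 0)
  # symmetry
  l1 <- a(sprintf("g%d", 1:40)); l2 <- a(sprintf("g%d", 25:70))
  expect_equal(consensus(l1, l2)$consensus, consensus(l2, l1)$consensus)
  # empty/empty convention
  e <- consensus(a(character()), a(character()))
  expect_equal(e$consensus, 0)
  expect_true(e$empty)
})

test_that("three-group consensus matches brute-force Venn enumeration", {
  gl <- chipbatch:::new_gene_list
  set.seed(67)
  pool <- sprintf("g%03d", 1:120)
  A <- sample(pool, 50); B <- sample(pool, 40); C <- sample(pool, 60)
  rep3 <- three_group_consensus(gl(A), gl(B), gl(C))
  u <- union(union(A, B), C)
  brute <- table(factor(paste0(ifelse(u %in% A, "a", ""),
                               ifelse(u %in% B, "b", ""),
                               ifelse(u %in% C, "c", "")),
                        levels = c("a", "b", "c", "ab", "ac", "bc", "abc")))
  expect_equal(unname(rep3$venn), as.vector(brute))
  same <- three_group_consensus(gl(A), gl(A), gl(A))
  expect_equal(same$pct_all_three_of_union, 100)
  disj <- three_group_consensus(gl(pool[1:5]), gl(pool[6:10]), gl(pool[11:15]))
  expect_equal(disj$pct_all_three_of_union, 0)
})

test_that("the method-dependence chi-square behaves like Pearson's test", {
  res <- method_dependence_chisq(rbind(c(192, 30), c(225, 222), c(260, 211)))
  expect_equal(res$df, 2)
  expect_lt(res$p, 0.001)
  prop <- method_dependence_chisq(rbind(c(10, 20), c(20, 40), c(30, 60)))
  expect_equal(prop$statistic, 0, tolerance = 1e-12)
  expect_equal(prop$p, 1)
  # hand-computed sum((O-E)^2/E) for a 2x2 table
  hand <- method_dependence_chisq(rbind(c(10, 20), c(30, 40)))
  expect_equal(hand$statistic, 0.7936508, tolerance = 1e-6)
  expect_error(method_dependence_chisq(rbind(c(0, 0), c(1, 2))),
               "zero marginal")
})
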