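# small in-code fixtures shared across test files

make_em <- function(v, scale = "log2", detection = NULL,
                    probes = sprintf("p%02d", seq_len(nrow(v))),
                    samples = sprintf("s%02d", seq_len(ncol(v)))) {
  dimnames(v) <- list(probes, samples)
  if (!is.null(detection)) dimnames(detection) <- dimnames(v)
  expression_matrix(v, scale, detection)
}

# a flat plan: one chip per sample, run assignment as given
make_plan <- function(sample_ids, runs, role = "study",
                      condition = "none", subject = NA, tag = "none") {
  hyb_plan(data.frame(
    sample_id = sample_ids,
    chip_id = paste0("c", seq_along(sample_ids)),
    array_slot = 1L,
    run_id = runs,
    role = role, subject_id = subject, replicate_tag = tag,
    condition = condition, stringsAsFactors = FALSE))
}

# brute-force one-way random-effects variance components for a single gene:
# two explicit loops over batches and observations
brute_varcomp <- function(values, batch) {
  batch <- as.factor(batch)
  b <- nlevels(batch)
  N <- length(values)
  grand <- mean(values)
  ssw <- 0; ssb <- 0; sum_ni2 <- 0
  for (lev in levels(batch)) {
    xi <- values[batch == lev]
    ni <- length(xi)
    sum_ni2 <- sum_ni2 + ni^2
    ssb <- ssb + ni * (mean(xi) - grand)^2
    for (x in xi) ssw <- ssw + (x - mean(xi))^2
  }
  msw <- ssw / (N - b)
  msb <- ssb / (b - 1)
  n0 <- (N - sum_ni2 / N) / (b - 1)
  list(sigma2_within = msw, sigma2_between = max(0, (msb - msw) / n0))
}

# brute-force Benjamini-Hochberg step-up
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# brute-force detection filter rule: count failing samples per probe
brute_filter_drop <- function(detection, conf, frac) {
  drop <- logical(nrow(detection))
  for (g in seq_len(nrow(detection))) {
    n_fail <- 0
    for (j in seq_len(ncol(detection))) {
      if (detection[g, j] <= conf) n_fail <- n_fail + 1
    }
    drop[g] <- (n_fail / ncol(detection)) > frac
  }
  drop
}

# paired-difference matrix with planted effects, for DE tests
make_paired_data <- function(G, n, effect = numeric(G), sigma = 0.25,
                             seed = 1) {
  set.seed(seed)
  pre <- matrix(rnorm(G * n, 8, 1), G, n)
  post <- pre + effect + matrix(rnorm(G * n, 0, sigma), G, n)
  v <- cbind(pre, post)
  dimnames(v) <- list(sprintf("g%04d", seq_len(G)),
                      c(paste0("pre", seq_len(n)), paste0("post", seq_len(n))))
  list(x = expression_matrix(v, "log2"),
       pairs = data.frame(pre = paste0("pre", seq_len(n)),
                          post = paste0("post", seq_len(n))))
}
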