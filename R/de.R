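# half-up rounding to `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Split duplicate hybridisations into independent analysis groups
#'
#' Duplicate a/b study hybridisations are split into group A (all 'a'
#' replicates) and group B (all 'b' replicates), plus the pooled group C
#' containing both. Each group retains complete pre/post subject pairs only;
#' subjects missing a condition in a group are dropped from that group with
#' a message.
#'
#' @param plan A [hyb_plan()] with duplicate-tagged study samples.
#' @return A list of class `duplicate_split` with elements `A`, `B`, `C`:
#'   each a data frame of paired samples with columns `pair_id`, `pre`,
#'   `post` (sample ids). In `C` each subject contributes one pair per
#'   replicate tag.
#' @export
split_duplicates <- function(plan) {
  st <- plan[plan$role == "study" & plan$replicate_tag %in% c("a", "b"), ]
  if (!nrow(st)) stop("plan contains no duplicate-tagged study samples",
                      call. = FALSE)
  pairs_for <- function(tag) {
    g <- st[st$replicate_tag == tag, ]
    pre <- g[g$condition == "pre", ]
    post <- g[g$condition == "post", ]
    subj <- intersect(pre$subject_id, post$subject_id)
    dropped <- setdiff(unique(g$subject_id), subj)
    if (length(dropped)) {
      message("group ", toupper(tag), ": dropped subject(s) without a complete ",
              "pre/post pair: ", paste(sort(dropped), collapse = ", "))
    }
    subj <- sort(subj)
    data.frame(pair_id = paste(subj, tag, sep = "."),
               pre = pre$sample_id[match(subj, pre$subject_id)],
               post = post$sample_id[match(subj, post$subject_id)],
               stringsAsFactors = FALSE)
  }
  a <- pairs_for("a")
  b <- pairs_for("b")
  structure(list(A = a, B = b, C = rbind(a, b)), class = "duplicate_split")
}

# Newton inversion of the trigamma function (y > 0 -> x with trigamma(x)=y)
trigamma_inverse <- function(y) {
  out <- y
  for (k in seq_along(y)) {
    yy <- y[k]
    if (!is.finite(yy) || yy <= 0) { out[k] <- NA_real_; next }
    if (yy > 1e7) { out[k] <- 1 / sqrt(yy); next }
    if (yy < 1e-6) { out[k] <- 1 / yy; next }
    x <- 0.5 + 1 / yy
    for (it in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif) / x < 1e-8) break
    }
    out[k] <- x
  }
  out
}

# paired difference matrix (genes x pairs): post minus pre
paired_diffs <- function(x, pairs) {
  pairs <- as.data.frame(pairs)
  need <- c("pre", "post")
  if (!all(need %in% names(pairs))) {
    stop("`pairs` must have columns 'pre' and 'post'", call. = FALSE)
  }
  unknown <- setdiff(c(pairs$pre, pairs$post), sample_ids(x))
  if (length(unknown)) {
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  x$values[, pairs$post, drop = FALSE] - x$values[, pairs$pre, drop = FALSE]
}

#' Moderated paired t-test
#'
#' Empirical-Bayes moderated one-sample t-test on paired log2 differences
#' (post minus pre). Per gene the differences give mean `m` and variance
#' `s^2` on `n - 1` degrees of freedom; a prior df `d0` and prior variance
#' `s0^2` are estimated by moment-matching the marginal distribution of
#' `log(s^2)` (scaled F), via digamma/trigamma inversion. The posterior
#' variance `(d0*s0^2 + (n-1)*s^2) / (d0 + n - 1)` replaces `s^2` in the t
#' statistic, tested on `d0 + n - 1` df, with Benjamini-Hochberg adjustment
#' across genes.
#'
#' @param x A log2-scale `expr_matrix`.
#' @param pairs Data frame with columns `pre` and `post` (sample ids), one
#'   row per subject pair; at least 2 rows.
#' @param prior_df Optional override of the estimated prior df `d0`
#'   (0 recovers the ordinary paired t-test; `Inf` fully shrinks to the
#'   prior variance).
#' @return A data frame of class `de_result` with per-gene `probe_id`,
#'   `logfc` (mean paired log2 difference), `stat`, `p`, `adj_p`;
#'   attributes `method = "moderated_t"`, `n_pairs`, `d0`, `s02`.
#' @export
moderated_paired_t <- function(x, pairs, prior_df = NULL) {
  if (x$scale != "log2") stop("expected log2-scale data", call. = FALSE)
  d <- paired_diffs(x, pairs)
  n <- ncol(d)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  df <- n - 1
  m <- rowMeans(d)
  s2 <- rowSums((d - m)^2) / df

  z <- log(s2)
  ok <- is.finite(z)
  if (any(ok)) {
    e <- z[ok] - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    evar <- stats::var(e) - trigamma(df / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s02 <- exp(emean)
    }
  } else {
    d0 <- Inf
    s02 <- 0
  }
  if (!is.null(prior_df)) d0 <- prior_df
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + df * s2) / (d0 + df)
  se <- sqrt(s2_post / n)
  stat <- ifelse(se > 0, m / se, ifelse(m == 0, 0, sign(m) * Inf))
  df_total <- d0 + df
  p <- 2 * stats::pt(-abs(stat), df = df_total)
  p[se == 0 & m == 0] <- 1
  res <- data.frame(probe_id = rownames(d), logfc = m, stat = stat, p = p,
                    adj_p = stats::p.adjust(p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, class = c("de_result", "data.frame"),
            method = "moderated_t", n_pairs = n, d0 = d0, s02 = s02)
}

#' SAM-style paired test with sign-flip permutation FDR
#'
#' Regularised paired statistic `d = m / (se + s0)` with the fudge factor
#' `s0` set to the median per-gene standard error. The null distribution is
#' generated by sign-flips of the paired difference vectors (exhaustive
#' `2^n` patterns when `n <= 10`, otherwise `n_perm` random draws; `s0` is
#' held at its observed value across permutations so the run is
#' deterministic given the seed). Per gene,
#' `q = pi0 * median_perm(#{|d*| >= |d|}) / #{genes with |d'| >= |d|}`,
#' monotonised to be non-increasing in `|d|` and capped at 1; `pi0` is
#' `min(1, 2 * mean(p > 0.5))` from a moderated-t pass on the same data.
#'
#' @inheritParams moderated_paired_t
#' @param n_perm Number of random sign-flip draws when `n > 10`
#'   (default 1000; must be at least 10).
#' @param seed Integer seed for the random draws; ignored for exhaustive
#'   enumeration.
#' @return A `de_result` data frame with per-gene `probe_id`, `logfc`,
#'   `stat` (the regularised d), `q`; attributes `method = "sam"`,
#'   `n_pairs`, `s0`, `pi0`, `n_perm_used`.
#' @export
sam_paired <- function(x, pairs, n_perm = 1000L, seed = NULL) {
  if (x$scale != "log2") stop("expected log2-scale data", call. = FALSE)
  if (n_perm < 10) stop("n_perm must be at least 10", call. = FALSE)
  d <- paired_diffs(x, pairs)
  n <- ncol(d)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  G <- nrow(d)
  ss <- rowSums(d^2)
  m <- rowMeans(d)
  se_of <- function(mm) sqrt(pmax(ss - n * mm^2, 0) / (n - 1)) / sqrt(n)
  se <- se_of(m)
  s0 <- stats::median(se)
  dstat <- m / (se + s0)

  pmod <- moderated_paired_t(x, pairs)$p
  pi0 <- min(1, 2 * mean(pmod > 0.5))

  if (n <= 10) {
    flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    if (!is.null(seed)) set.seed(seed)
    flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                    nrow = n_perm, ncol = n)
  }
  abs_obs <- abs(dstat)
  sorted_obs <- sort(abs_obs)
  obs_ge <- G - findInterval(abs_obs, sorted_obs, left.open = TRUE)
  cnt <- matrix(0L, G, nrow(flips))
  for (p_i in seq_len(nrow(flips))) {
    mm <- as.vector(d %*% flips[p_i, ]) / n
    dd <- abs(mm / (se_of(mm) + s0))
    cnt[, p_i] <- G - findInterval(abs_obs, sort(dd), left.open = TRUE)
  }
  med_cnt <- apply(cnt, 1, stats::median)
  q <- pmin(1, pi0 * med_cnt / obs_ge)
  ord <- order(abs_obs, decreasing = TRUE)
  q[ord] <- cummax(q[ord])

  res <- data.frame(probe_id = rownames(d), logfc = m, stat = dstat, q = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, class = c("de_result", "data.frame"), method = "sam",
            n_pairs = n, s0 = s0, pi0 = pi0, n_perm_used = nrow(flips))
}

new_gene_list <- function(probes, criteria = list()) {
  structure(list(probes = unique(as.character(probes)), criteria = criteria),
            class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("<gene_list> %d probes (%s)\n", length(x$probes),
              paste(names(x$criteria), unlist(lapply(x$criteria, format)),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Threshold a DE result into a gene list
#'
#' Selection is inclusive at the thresholds: the moderated-t path keeps
#' genes with `|logfc| >= log2(fc)` and BH-adjusted `p <= alpha`; the SAM
#' path keeps genes with `|logfc| >= log2(fc)` and `q <= fdr`.
#'
#' @param r A `de_result` from [moderated_paired_t()] or [sam_paired()].
#' @param fc Minimum fold change, ratio scale (default 1.5).
#' @param alpha Maximum BH-adjusted p-value, moderated-t path
#'   (default 0.01).
#' @param fdr Maximum q-value, SAM path (default 0.05).
#' @return A `gene_list` carrying its selection criteria.
#' @export
gene_list <- function(r, fc = 1.5, alpha = 0.01, fdr = 0.05) {
  stopifnot(inherits(r, "de_result"), fc > 0, alpha > 0, fdr > 0)
  method <- attr(r, "method")
  big <- abs(r$logfc) >= log2(fc)
  keep <- if (method == "sam") big & r$q <= fdr else big & r$adj_p <= alpha
  new_gene_list(r$probe_id[keep],
                list(method = method, fc_threshold = fc,
                     alpha = if (method == "sam") NA_real_ else alpha,
                     fdr = if (method == "sam") fdr else NA_real_))
}

#' Consensus between two gene lists
#'
#' The reproducibility metric for duplicate analyses:
#' `100 * |A intersect B| / |A union B|`, rounded half-up to one decimal.
#' Two empty lists give consensus 0.0 with `empty = TRUE`.
#'
#' @param a,b `gene_list` objects.
#' @return One-row data frame of class `consensus_row`: `n_a`, `n_b`,
#'   `n_overlap`, `consensus`, `empty`.
#' @export
consensus <- function(a, b) {
  stopifnot(inherits(a, "gene_list"), inherits(b, "gene_list"))
  sa <- a$probes; sb <- b$probes
  ov <- length(intersect(sa, sb))
  un <- length(union(sa, sb))
  pct <- if (un == 0) 0 else round_half_up(100 * ov / un, 1)
  structure(data.frame(n_a = length(sa), n_b = length(sb), n_overlap = ov,
                       consensus = pct, empty = un == 0),
            class = c("consensus_row", "data.frame"))
}

#' Consensus computed from printed list sizes
#'
#' Convenience wrapper for published summary tables that report only
#' `|A|`, `|B|` and the overlap: constructs explicit gene lists with those
#' cardinalities and runs [consensus()] on them.
#'
#' @param n_a,n_b,n_overlap List sizes and intersection size
#'   (`n_overlap <= min(n_a, n_b)`).
#' @return A `consensus_row` (see [consensus()]).
#' @export
consensus_from_counts <- function(n_a, n_b, n_overlap) {
  stopifnot(n_overlap <= min(n_a, n_b), n_overlap >= 0)
  shared <- sprintf("shared%06d", seq_len(n_overlap))
  a <- new_gene_list(c(shared, sprintf("onlyA%06d", seq_len(n_a - n_overlap))))
  b <- new_gene_list(c(shared, sprintf("onlyB%06d", seq_len(n_b - n_overlap))))
  consensus(a, b)
}

#' Three-group consensus with all Venn regions
#'
#' Extends [consensus()] to three lists (typically the two duplicate groups
#' plus the pooled group): reports all seven Venn region counts, the
#' percentage of the union found in all three lists, and the fraction of the
#' third list confirmed by all three.
#'
#' @param a,b,c `gene_list` objects.
#' @return A list of class `three_group_report`: `venn` (named counts
#'   `a_only`, `b_only`, `c_only`, `ab`, `ac`, `bc`, `abc`),
#'   `pct_all_three_of_union`, `pct_all_three_of_c` (both rounded half-up to
#'   one decimal; 0 when the relevant denominator is empty).
#' @export
three_group_consensus <- function(a, b, c) {
  sa <- a$probes; sb <- b$probes; sc <- c$probes
  u <- union(union(sa, sb), sc)
  mem <- cbind(a = u %in% sa, b = u %in% sb, c = u %in% sc)
  region <- paste0(ifelse(mem[, 1], "a", ""), ifelse(mem[, 2], "b", ""),
                   ifelse(mem[, 3], "c", ""))
  cnt <- function(r) sum(region == r)
  venn <- c(a_only = cnt("a"), b_only = cnt("b"), c_only = cnt("c"),
            ab = cnt("ab"), ac = cnt("ac"), bc = cnt("bc"), abc = cnt("abc"))
  n_abc <- venn[["abc"]]
  structure(list(
    venn = venn,
    pct_all_three_of_union = if (length(u)) round_half_up(100 * n_abc / length(u), 1) else 0,
    pct_all_three_of_c = if (length(sc)) round_half_up(100 * n_abc / length(sc), 1) else 0),
    class = "three_group_report")
}

#' Chi-square test of dependence between method and duplicate group
#'
#' Pearson chi-square (no continuity correction) on a methods-by-groups
#' table of gene-list sizes, testing whether the number of reported genes
#' depends on the processing method.
#'
#' @param counts Numeric matrix of counts (e.g. 3 corrections x 2 duplicate
#'   groups); all expected cell counts must be positive.
#' @return A list: `statistic`, `df`, `p`.
#' @export
method_dependence_chisq <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal in the counts table", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(ht$expected <= 0)) {
    stop("non-positive expected cell count", call. = FALSE)
  }
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
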