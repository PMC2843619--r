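#' Per-gene nested ANOVA variance components
#'
#' Decomposes each gene's variance into inter-batch and intra-batch parts
#' under the one-way random-effects model `X_ij = mu + A_i + eps_ij`, using
#' method-of-moments estimation for the (possibly unbalanced) design:
#' `MS_within = SS_within / (N - b)`, `MS_between = SS_between / (b - 1)`,
#' `n0 = (N - sum(n_i^2)/N) / (b - 1)`, `sigma2_within = MS_within`,
#' `sigma2_between = max(0, (MS_between - MS_within) / n0)`.
#'
#' @param x A log2-scale `expr_matrix`.
#' @param plan A [hyb_plan()] covering the samples of `x`.
#' @param role Optional role filter (`"reference"` or `"study"`); default
#'   uses all samples of `x`.
#' @return A data frame of class `variance_components`, one row per gene:
#'   `probe_id`, `mu` (grand mean), `sigma2_between`, `sigma2_within`,
#'   `sd_between`, `sd_within`, `between_share_sd`
#'   (`sd_between / (sd_between + sd_within)`, 0 when both vanish),
#'   `between_share_var`, and `truncated` (TRUE where the raw
#'   between-component estimate was negative). Attributes `n_batches` and
#'   `batch_sizes` record the design.
#' @export
nested_anova <- function(x, plan, role = NULL) {
  validate_expr_matrix(x)
  if (x$scale != "log2") stop("nested_anova expects log2-scale data",
                              call. = FALSE)
  keep <- rep(TRUE, ncol(x$values))
  if (!is.null(role)) {
    idx <- match(sample_ids(x), plan$sample_id)
    keep <- plan$role[idx] == role
  }
  v <- x$values[, keep, drop = FALSE]
  batch <- droplevels(plan_batches(plan, colnames(v)))
  b <- nlevels(batch)
  if (b < 2) stop("need at least 2 batches", call. = FALSE)
  n_i <- as.vector(table(batch))
  N <- sum(n_i)
  if (all(n_i < 2)) {
    stop("all batches are singletons: within-batch variance is inestimable",
         call. = FALSE)
  }
  grand <- rowMeans(v)
  bmean <- t(rowsum(t(v), batch) / n_i)                    # G x B
  ss_within <- rowSums((v - bmean[, as.integer(batch), drop = FALSE])^2)
  ss_between <- as.vector((bmean - grand)^2 %*% n_i)
  ms_w <- ss_within / (N - b)
  ms_b <- ss_between / (b - 1)
  n0 <- (N - sum(n_i^2) / N) / (b - 1)
  raw_a <- (ms_b - ms_w) / n0
  s2a <- pmax(0, raw_a)
  sd_a <- sqrt(s2a); sd_w <- sqrt(ms_w)
  tot <- sd_a + sd_w
  share_sd <- ifelse(tot > 0, sd_a / tot, 0)
  tot_var <- s2a + ms_w
  share_var <- ifelse(tot_var > 0, s2a / tot_var, 0)
  out <- data.frame(probe_id = rownames(v), mu = grand,
                    sigma2_between = s2a, sigma2_within = ms_w,
                    sd_between = sd_a, sd_within = sd_w,
                    between_share_sd = share_sd,
                    between_share_var = share_var,
                    truncated = raw_a < 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_batches") <- b
  attr(out, "batch_sizes") <- n_i
  class(out) <- c("variance_components", "data.frame")
  out
}

#' Summarise variance components across genes
#' @param vc A `variance_components` data frame from [nested_anova()].
#' @return A one-row data frame with the across-gene means of `sd_between`,
#'   `sd_within`, `between_share_sd` and `between_share_var`, plus the
#'   medians of the two SDs.
#' @export
variance_summary <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  data.frame(mean_sd_between = mean(vc$sd_between),
             mean_sd_within = mean(vc$sd_within),
             mean_between_share_sd = mean(vc$between_share_sd),
             mean_between_share_var = mean(vc$between_share_var),
             median_sd_between = stats::median(vc$sd_between),
             median_sd_within = stats::median(vc$sd_within))
}

#' Pairwise sample correlation matrix
#'
#' @param x An `expr_matrix` (log2 scale recommended).
#' @param plan Optional [hyb_plan()]; with `role` set, restricts to samples
#'   of that role.
#' @param role Optional role filter.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Symmetric sample-by-sample correlation matrix with unit diagonal.
#'   Pairs involving a zero-variance sample are `NA` with a warning.
#' @export
pairwise_correlation <- function(x, plan = NULL, role = NULL,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  v <- x$values
  if (!is.null(plan) && !is.null(role)) {
    idx <- match(colnames(v), plan$sample_id)
    v <- v[, plan$role[idx] == role, drop = FALSE]
  }
  if (ncol(v) < 2) stop("need at least 2 samples", call. = FALSE)
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance sample(s): ",
            paste(colnames(v)[sds == 0], collapse = ", "),
            "; their correlations are NA", call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(v, method = method))
  diag(r) <- 1
  r
}

#' Replicate-difference summary
#'
#' Pools the per-probe signed expression differences (first minus second)
#' over a set of replicate sample pairs and summarises their mean and SD —
#' the numeric content of a replicate-difference histogram.
#'
#' @param x An `expr_matrix`.
#' @param pairs Two-column data frame or matrix of sample-id pairs (columns
#'   `id1`, `id2` or positional).
#' @param label Optional label for the pair set (e.g. "inter-run reference").
#' @return A list of class `difference_summary`: `label`, `n_pairs`,
#'   `mean`, `sd`.
#' @export
replicate_differences <- function(x, pairs, label = "") {
  pairs <- as.data.frame(pairs)
  id1 <- as.character(pairs[[1]]); id2 <- as.character(pairs[[2]])
  unknown <- setdiff(c(id1, id2), sample_ids(x))
  if (length(unknown)) {
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  d <- x$values[, id1, drop = FALSE] - x$values[, id2, drop = FALSE]
  structure(list(label = label, n_pairs = length(id1),
                 mean = mean(d), sd = stats::sd(as.vector(d))),
            class = "difference_summary")
}

#' @export
print.difference_summary <- function(x, ...) {
  cat(sprintf("<difference_summary> %s: %d pairs, mean = %.4f, sd = %.4f\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$n_pairs, x$mean, x$sd))
  invisible(x)
}

#' Per-probe coefficient of variation over replicate sets
#'
#' CV is computed on the linear intensity scale (`100 * sd / mean` over each
#' replicate set); log2 input is back-transformed first. Probes with zero
#' mean in a set are excluded from that set's summary and counted.
#'
#' @param x An `expr_matrix`.
#' @param sets A list of character vectors of sample ids (each a replicate
#'   set), or a single character vector; default uses all samples as one set.
#' @return A list: `per_probe` (probes x sets matrix of CV \%, `NA` where
#'   undefined), `mean_cv` (grand mean over defined entries), `n_excluded`.
#' @export
coefficient_of_variation <- function(x, sets = NULL) {
  if (x$scale == "log2") x <- unlog2(x)
  if (is.null(sets)) sets <- list(all = sample_ids(x))
  if (is.character(sets)) sets <- list(set1 = sets)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  cvm <- sapply(sets, function(ids) {
    v <- x$values[, ids, drop = FALSE]
    m <- rowMeans(v)
    s <- apply(v, 1, stats::sd)
    ifelse(m == 0, NA_real_, 100 * s / m)
  })
  cvm <- matrix(cvm, nrow = nrow(x$values),
                dimnames = list(probe_ids(x), names(sets)))
  n_excl <- sum(is.na(cvm))
  if (n_excl > 0) {
    message(n_excl, " zero-mean probe/set combination(s) excluded from CV")
  }
  list(per_probe = cvm, mean_cv = mean(cvm, na.rm = TRUE),
       n_excluded = n_excl)
}

#' Detection-call consistency across arrays
#'
#' A probe is called detected on an array iff its confidence exceeds
#' `call_threshold`. Reports the fractions of probes consistently called
#' detected on all arrays, consistently undetected on all arrays, and mixed.
#'
#' @param detection An `expr_matrix` with a detection matrix, or a plain
#'   numeric matrix of confidences.
#' @param call_threshold Confidence above which a probe is called detected
#'   (default 0.8).
#' @return Named numeric vector `all_detected`, `all_undetected`, `mixed`
#'   summing to 1.
#' @export
detection_consistency <- function(detection, call_threshold = 0.8) {
  d <- if (inherits(detection, "expr_matrix")) {
    if (is.null(detection$detection)) {
      stop("no detection matrix present", call. = FALSE)
    }
    detection$detection
  } else detection
  calls <- d > call_threshold
  n_det <- rowSums(calls)
  k <- ncol(d)
  c(all_detected = mean(n_det == k),
    all_undetected = mean(n_det == 0),
    mixed = mean(n_det > 0 & n_det < k))
}
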