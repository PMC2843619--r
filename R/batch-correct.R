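# shared helpers ------------------------------------------------------------

# Normalise the covariates argument to a data frame of factors (or NULL).
as_cov_df <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  if (is.data.frame(covariates)) {
    df <- covariates
  } else if (is.list(covariates)) {
    df <- as.data.frame(covariates, stringsAsFactors = TRUE)
  } else {
    df <- data.frame(cov1 = covariates)
  }
  if (nrow(df) != n) {
    stop("covariates must have one entry per sample (", n, ")", call. = FALSE)
  }
  df[] <- lapply(df, function(v) if (is.factor(v)) droplevels(v) else v)
  df
}

check_full_rank <- function(design, context) {
  r <- qr(design)$rank
  if (r < ncol(design)) {
    stop(sprintf(paste0("design matrix is rank-deficient (rank %d < %d ",
                        "columns): covariates are confounded with %s"),
                 r, ncol(design), context), call. = FALSE)
  }
}

# ---------------------------------------------------------------------------

#' Mean-centring batch correction
#'
#' Per gene, shifts each batch so that its mean equals the gene's grand mean
#' across all samples. With covariates, an additive least-squares model with
#' the covariate factors plus a sum-to-zero batch factor is fitted per gene
#' and only the estimated batch effects are subtracted.
#'
#' @param x A log2-scale `expr_matrix`.
#' @param plan A [hyb_plan()] assigning every sample of `x` to a run.
#' @param covariates Optional factor, list of factors, or data frame (one row
#'   per sample of `x`) of biological covariates to protect.
#' @return The corrected `expr_matrix`.
#' @export
mean_center <- function(x, plan, covariates = NULL) {
  validate_expr_matrix(x)
  if (x$scale != "log2") stop("mean_center expects log2-scale data",
                              call. = FALSE)
  batch <- droplevels(plan_batches(plan, sample_ids(x)))
  if (any(table(batch) < 1)) {
    stop("every batch must contain at least one sample", call. = FALSE)
  }
  if (nlevels(batch) < 2) return(x)  # nothing to centre
  v <- x$values
  covdf <- as_cov_df(covariates, ncol(v))
  if (is.null(covdf)) {
    grand <- rowMeans(v)
    # rowsum works sample-wise on t(v): batch sums per gene
    bsum <- rowsum(t(v), batch)                 # B x G
    bn <- as.vector(table(batch))
    bmean <- bsum / bn
    out <- v - t(bmean[as.integer(batch), , drop = FALSE]) + grand
  } else {
    mm_cov <- stats::model.matrix(~ ., data = covdf)
    cb <- stats::contr.sum(nlevels(batch))[as.integer(batch), , drop = FALSE]
    design <- cbind(mm_cov, cb)
    check_full_rank(design, "batch")
    beta <- qr.coef(qr(design), t(v))           # p x G
    bidx <- ncol(mm_cov) + seq_len(ncol(cb))
    batch_part <- cb %*% beta[bidx, , drop = FALSE]  # N x G
    out <- v - t(batch_part)
  }
  expression_matrix(out, "log2", x$detection)
}

#' Empirical-Bayes location/scale batch correction
#'
#' Parametric empirical-Bayes adjustment of per-(batch, gene) additive
#' location and multiplicative scale effects. Per gene: (1) least-squares
#' fit of batch means (constrained to average out, weighted by batch size)
#' plus optional covariates, with a pooled variance across all samples;
#' (2) residual standardisation; (3) raw per-batch location (batch mean of
#' standardised data) and scale (batch variance); (4) hyperpriors estimated
#' by method of moments across genes within each batch — Normal for
#' locations, inverse-gamma for scales; (5) coupled posterior updates of the
#' shrunk location and scale iterated to convergence; (6) standardised data
#' adjusted by the shrunk effects and restored to the original scale and
#' fitted means. Fully deterministic.
#'
#' @inheritParams mean_center
#' @param max_iter Maximum posterior-update iterations per (batch, gene)
#'   block (default 1000; small batches converge slowly because the scale
#'   posterior is prior-dominated).
#' @param tol Convergence tolerance on the maximum absolute change of the
#'   shrunk location and squared-scale parameters (default 1e-4).
#' @return A list with `expr` (corrected `expr_matrix`) and `model` (class
#'   `batch_model`: fitted means, pooled variances, raw and shrunk batch
#'   parameters, hyperparameters, iteration counts).
#' @export
eb_batch_correct <- function(x, plan, covariates = NULL, max_iter = 1000L,
                             tol = 1e-4) {
  validate_expr_matrix(x)
  if (x$scale != "log2") {
    stop("eb_batch_correct expects log2-scale data", call. = FALSE)
  }
  batch <- droplevels(plan_batches(plan, sample_ids(x)))
  B <- nlevels(batch)
  if (B < 2) stop("need at least 2 batches", call. = FALSE)
  bn <- as.vector(table(batch))
  if (any(bn < 2)) {
    stop("batch of size 1 (", paste(levels(batch)[bn < 2], collapse = ", "),
         "): scale not estimable; use mean_center instead", call. = FALSE)
  }
  v <- x$values
  G <- nrow(v); N <- ncol(v)
  covdf <- as_cov_df(covariates, N)

  batch_design <- stats::model.matrix(~ batch - 1)
  design <- batch_design
  if (!is.null(covdf)) {
    mm_cov <- stats::model.matrix(~ ., data = covdf)[, -1, drop = FALSE]
    design <- cbind(batch_design, mm_cov)
  }
  check_full_rank(design, "batch")
  qd <- qr(design)
  beta <- qr.coef(qd, t(v))                     # p x G
  grand <- as.vector((bn / N) %*% beta[seq_len(B), , drop = FALSE])
  var_pooled <- rowMeans((v - t(design %*% beta))^2)

  stand_mean <- matrix(grand, G, N)
  if (!is.null(covdf) && ncol(design) > B) {
    cov_part <- design[, -seq_len(B), drop = FALSE] %*%
      beta[-seq_len(B), , drop = FALSE]         # N x G
    stand_mean <- stand_mean + t(cov_part)
  }
  sd_pooled <- sqrt(var_pooled)
  degenerate <- sd_pooled <= 0
  sd_pooled[degenerate] <- 1
  z <- (v - stand_mean) / sd_pooled

  gamma_hat <- t(rowsum(t(z), batch) / bn)      # G x B
  delta2_hat <- matrix(0, G, B)
  for (i in seq_len(B)) {
    zi <- z[, batch == levels(batch)[i], drop = FALSE]
    delta2_hat[, i] <- rowSums((zi - gamma_hat[, i])^2) / (bn[i] - 1)
  }

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  hyper <- data.frame(batch = levels(batch), gamma_bar = NA_real_,
                      tau2 = NA_real_, lambda = NA_real_, theta = NA_real_,
                      iterations = NA_integer_)
  floor_var <- 1e-8
  for (i in seq_len(B)) {
    g <- gamma_hat[, i]
    d2 <- delta2_hat[, i]
    gamma_bar <- mean(g)
    tau2 <- stats::var(g)
    if (!is.finite(tau2) || tau2 < floor_var) {
      warning("prior location variance floored for batch ", levels(batch)[i],
              call. = FALSE)
      tau2 <- floor_var
    }
    m <- mean(d2); s2 <- stats::var(d2)
    if (is.finite(s2) && s2 > 0) {
      lambda <- (2 * s2 + m^2) / s2
      theta <- (m * s2 + m^3) / s2
    } else {
      lambda <- 1; theta <- 0   # uninformative fallback: posterior = MLE
    }
    ni <- bn[i]
    zi <- z[, batch == levels(batch)[i], drop = FALSE]
    g_star <- g
    d2_star <- pmax(d2, floor_var)
    it <- 0L
    repeat {
      it <- it + 1L
      g_new <- (ni * tau2 * g + d2_star * gamma_bar) / (ni * tau2 + d2_star)
      ss <- rowSums((zi - g_new)^2)
      d2_new <- pmax((theta + 0.5 * ss) / (ni / 2 + lambda - 1), floor_var)
      change <- max(abs(g_new - g_star), abs(d2_new - d2_star))
      g_star <- g_new
      d2_star <- d2_new
      if (change < tol) break
      if (it >= max_iter) {
        stop(sprintf("EB updates did not converge in %d iterations (max change %.3g)",
                     max_iter, change), call. = FALSE)
      }
    }
    gamma_star[, i] <- g_star
    delta2_star[, i] <- d2_star
    hyper$gamma_bar[i] <- gamma_bar
    hyper$tau2[i] <- tau2
    hyper$lambda[i] <- lambda
    hyper$theta[i] <- theta
    hyper$iterations[i] <- it
  }

  bi <- as.integer(batch)
  z_adj <- (z - gamma_star[, bi, drop = FALSE]) /
    sqrt(delta2_star)[, bi, drop = FALSE]
  out <- z_adj * sd_pooled + stand_mean
  dimnames(out) <- dimnames(v)
  dimnames(gamma_star) <- dimnames(delta2_star) <-
    dimnames(gamma_hat) <- dimnames(delta2_hat) <-
    list(rownames(v), levels(batch))
  model <- structure(list(
    grand_mean = stats::setNames(grand, rownames(v)),
    pooled_var = stats::setNames(var_pooled, rownames(v)),
    gamma_hat = gamma_hat, delta2_hat = delta2_hat,
    gamma_star = gamma_star, delta2_star = delta2_star,
    hyper = hyper, max_iter = max_iter, tol = tol,
    converged = TRUE), class = "batch_model")
  list(expr = expression_matrix(out, "log2", x$detection), model = model)
}

#' @export
print.batch_model <- function(x, ...) {
  cat(sprintf("<batch_model> %d genes x %d batches; iterations per batch: %s\n",
              nrow(x$gamma_star), ncol(x$gamma_star),
              paste(x$hyper$iterations, collapse = ", ")))
  invisible(x)
}

#' Batch correction with the reference sample as inter-batch calibrator
#'
#' Runs the chosen correction on the pooled reference-plus-study matrix with
#' the sample group (reference vs study, and pre/post condition within
#' study) as a protected covariate factor, then returns the corrected study
#' sub-matrix. The reference columns inform the batch-effect estimates but
#' are dropped from the result.
#'
#' @param x A log2-scale `expr_matrix` containing both reference and study
#'   samples (co-normalised).
#' @param plan The [hyb_plan()].
#' @param method `"mean_center"` or `"combat"` (the empirical-Bayes
#'   correction).
#' @return The corrected study-only `expr_matrix`.
#' @export
apply_correction_with_calibrator <- function(x, plan,
                                             method = c("mean_center", "combat")) {
  method <- match.arg(method)
  ids <- sample_ids(x)
  idx <- match(ids, plan$sample_id)
  if (anyNA(idx)) {
    stop("samples absent from plan: ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  role <- plan$role[idx]
  if (!any(role == "reference")) {
    stop("no reference samples present: nothing to calibrate with",
         call. = FALSE)
  }
  group <- factor(ifelse(role == "reference", "reference",
                         paste0("study.", plan$condition[idx])))
  if (method == "mean_center") {
    batch <- plan$run_id[idx]
    ref_only <- setdiff(unique(batch), unique(batch[role == "study"]))
    if (length(ref_only)) {
      stop("batch(es) with no study samples: ",
           paste(ref_only, collapse = ", "), call. = FALSE)
    }
    corrected <- mean_center(x, plan, covariates = group)
  } else {
    corrected <- eb_batch_correct(x, plan, covariates = group)$expr
  }
  em_subset(corrected, samples = role == "study")
}
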