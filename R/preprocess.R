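#' Detection-confidence filter
#'
#' Removes probes that fail to be detected in too many samples: probe g is
#' removed iff the fraction of samples with detection confidence `<= conf`
#' exceeds `frac` (defaults: confidence at most 80\% in more than 25\% of the
#' samples). Retained values are untouched and sample order is unchanged.
#'
#' @param x An `expr_matrix` with a detection matrix.
#' @param conf Confidence threshold; a sample "fails" a probe when its
#'   confidence is `<=` this value (default 0.80).
#' @param frac Fraction of failing samples above which the probe is removed
#'   (strictly greater; default 0.25).
#' @return A list with elements `expr` (the filtered `expr_matrix`) and
#'   `report` (class `filter_report`: counts, removed ids and thresholds).
#' @export
detection_filter <- function(x, conf = 0.80, frac = 0.25) {
  validate_expr_matrix(x)
  if (is.null(x$detection)) {
    stop("no detection matrix present; read the data with detection columns ",
         "(read_probe_profile) before filtering", call. = FALSE)
  }
  n <- ncol(x$values)
  fail_frac <- rowMeans(x$detection <= conf)
  drop <- fail_frac > frac
  report <- structure(list(
    n_probes_in = nrow(x$values),
    n_probes_removed = sum(drop),
    removed_ids = rownames(x$values)[drop],
    threshold_confidence = conf,
    threshold_sample_fraction = frac), class = "filter_report")
  list(expr = em_subset(x, probes = !drop), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("<filter_report> removed %d of %d probes ",
                     "(confidence <= %.2f in > %.0f%% of samples)\n"),
              x$n_probes_removed, x$n_probes_in, x$threshold_confidence,
              100 * x$threshold_sample_fraction))
  invisible(x)
}

#' Log2 transform
#'
#' Floors values at `floor` (guarding zeros and corrupt negatives) and takes
#' log2. Refuses to transform data already on the log2 scale.
#'
#' @param x A linear-scale `expr_matrix`.
#' @param floor Values below this are raised to it before the log
#'   (default 1.0). Negative input cells trigger a warning with the count of
#'   floored cells.
#' @return The transformed `expr_matrix` with `scale = "log2"`.
#' @export
log2_transform <- function(x, floor = 1.0) {
  stopifnot(floor > 0)
  if (x$scale == "log2") {
    stop("data are already log2 scale; refusing to transform twice",
         call. = FALSE)
  }
  v <- x$values
  n_floored <- sum(v < floor)
  if (any(v < 0)) {
    warning(sprintf("%d cell(s) below the floor of %g (including negatives) were raised to it",
                    n_floored, floor), call. = FALSE)
  }
  v[v < floor] <- floor
  expression_matrix(log2(v), "log2", x$detection)
}

#' Back-transform log2 data to the linear intensity scale
#' @param x A log2-scale `expr_matrix`.
#' @return The `expr_matrix` with `values = 2^values`, `scale = "linear"`.
#' @export
unlog2 <- function(x) {
  if (x$scale != "log2") stop("input is not log2 scale", call. = FALSE)
  expression_matrix(2^x$values, "linear", x$detection)
}

# Rank-mean quantile normalisation of a plain matrix; ties within a column
# receive the mean of the reference values over the tied rank range.
qn_matrix <- function(v) {
  n <- nrow(v)
  ref <- rowMeans(apply(v, 2, sort, method = "quick"))
  cref <- cumsum(ref)
  out <- v
  for (j in seq_len(ncol(v))) {
    rmin <- rank(v[, j], ties.method = "min")
    rmax <- rank(v[, j], ties.method = "max")
    out[, j] <- (cref[rmax] - c(0, cref)[rmin]) / (rmax - rmin + 1)
  }
  out
}

#' Quantile normalisation
#'
#' Classical rank-mean algorithm: each column's sorted values are replaced by
#' the across-column mean of sorted values, assigned back by rank; ties
#' within a column receive the average of the reference values across the
#' tied rank range. Afterwards every column has the same sorted value
#' multiset.
#'
#' @param x An `expr_matrix` (any scale) with at least 2 samples and no
#'   missing values.
#' @return The normalised `expr_matrix` (same scale tag, detection carried
#'   through unchanged).
#' @export
quantile_normalize <- function(x) {
  validate_expr_matrix(x)
  if (anyNA(x$values)) stop("missing values are not supported", call. = FALSE)
  if (ncol(x$values) < 2) {
    warning("single sample: quantile normalisation is the identity",
            call. = FALSE)
    return(x)
  }
  expression_matrix(qn_matrix(x$values), x$scale, x$detection)
}

#' Median normalisation
#'
#' Shifts each column so that its median equals the grand median of the
#' column medians. A simple comparator for quantile normalisation.
#'
#' @param x An `expr_matrix`; normally log2 scale (shifting linear
#'   intensities below zero is refused).
#' @return The normalised `expr_matrix` (scale tag preserved).
#' @export
median_normalize <- function(x) {
  validate_expr_matrix(x)
  med <- apply(x$values, 2, stats::median)
  target <- stats::median(med)
  v <- sweep(x$values, 2, med - target)
  if (x$scale == "linear" && any(v < 0)) {
    stop("median shift drives linear intensities negative; log-transform first",
         call. = FALSE)
  }
  expression_matrix(v, x$scale, x$detection)
}
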