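#' Construct an expression matrix
#'
#' The central container of the package: a probes x samples matrix of
#' fluorescence intensities with a scale tag and an optional parallel matrix
#' of detection confidences.
#'
#' @param values Numeric matrix (probes x samples) with row and column names
#'   giving probe and sample identifiers.
#' @param scale Either `"linear"` (raw intensities, all values >= 0) or
#'   `"log2"` (log2 intensities, unconstrained sign).
#' @param detection Optional numeric matrix of detection confidences in
#'   \[0, 1\], with dimensions identical to `values`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `scale` and `detection`.
#' @export
#' @examples
#' m <- matrix(2^rnorm(12, 8), 4, 3,
#'             dimnames = list(paste0("p", 1:4), paste0("s", 1:3)))
#' x <- expression_matrix(m, "linear")
#' dim(x)
expression_matrix <- function(values, scale = c("linear", "log2"),
                              detection = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry probe ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  x <- structure(list(values = values, scale = scale, detection = detection),
                 class = "expr_matrix")
  validate_expr_matrix(x)
  x
}

validate_expr_matrix <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (anyDuplicated(rownames(v))) {
    dup <- unique(rownames(v)[duplicated(rownames(v))])
    stop("duplicate probe ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(v))) {
    dup <- unique(colnames(v)[duplicated(colnames(v))])
    stop("duplicate sample ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!x$scale %in% c("linear", "log2")) {
    stop("scale must be 'linear' or 'log2'", call. = FALSE)
  }
  if (x$scale == "linear" && any(v < 0, na.rm = TRUE)) {
    stop("linear-scale values must be non-negative", call. = FALSE)
  }
  if (!is.null(x$detection)) {
    d <- x$detection
    if (!identical(dim(d), dim(v))) {
      stop("detection matrix dimensions must equal values dimensions",
           call. = FALSE)
    }
    if (any(d < 0 | d > 1, na.rm = TRUE)) {
      stop("detection confidences must lie in [0, 1]", call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d probes x %d samples, scale = %s, detection = %s\n",
              nrow(x$values), ncol(x$values), x$scale,
              if (is.null(x$detection)) "absent" else "present"))
  invisible(x)
}

#' Probe identifiers of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of probe ids in matrix order.
#' @export
probe_ids <- function(x) rownames(x$values)

#' Sample identifiers of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of sample ids in matrix order.
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an expression matrix by probes and/or samples
#'
#' Keeps `values` and `detection` aligned and preserves the scale tag.
#'
#' @param x An `expr_matrix`.
#' @param probes,samples Index vectors (logical, integer or character)
#'   understood by `[`; missing means keep all.
#' @return The subsetted `expr_matrix`.
#' @export
em_subset <- function(x, probes = NULL, samples = NULL) {
  if (is.null(probes)) probes <- seq_len(nrow(x$values))
  if (is.null(samples)) samples <- seq_len(ncol(x$values))
  v <- x$values[probes, samples, drop = FALSE]
  d <- if (is.null(x$detection)) NULL else
    x$detection[probes, samples, drop = FALSE]
  expression_matrix(v, x$scale, d)
}
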