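#' Read a probe-profile expression table
#'
#' Reads the tab-delimited export format with one probe-identifier column
#' (`PROBE_ID`) and, per sample, a `<sample_id>.AVG_Signal` column and an
#' optional `<sample_id>.Detection` column. Detection values are normalised
#' at this boundary to *confidences* in \[0, 1\]: if the export stores
#' detection p-values, pass `detection_semantics = "pvalue"` and the stored
#' confidence becomes `1 - p`, so that downstream thresholds always operate
#' on confidences.
#'
#' @param path Path to the tab-delimited file.
#' @param detection_semantics `"confidence"` (stored as-is) or `"pvalue"`
#'   (stored as 1 - p).
#' @return An [expression_matrix()] with `scale = "linear"`, probes and
#'   samples in file order.
#' @export
read_probe_profile <- function(path,
                               detection_semantics = c("confidence", "pvalue")) {
  detection_semantics <- match.arg(detection_semantics)
  lines <- readLines(path)
  if (!length(lines)) stop("empty probe-profile file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1])) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged row in probe profile at line %d (%d fields, expected %d)",
                 bad, nf[bad], nf[1]), call. = FALSE)
  }
  header <- fields[[1]]
  if (header[1] != "PROBE_ID") {
    stop("first column must be PROBE_ID, found '", header[1], "'",
         call. = FALSE)
  }
  sig_cols <- grep("\\.AVG_Signal$", header)
  det_cols <- grep("\\.Detection$", header)
  sids <- sub("\\.AVG_Signal$", "", header[sig_cols])
  if (!length(sig_cols)) stop("no <sample>.AVG_Signal columns found", call. = FALSE)
  body <- fields[-1]
  probes <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(probes)) {
    dup <- unique(probes[duplicated(probes)])
    stop("duplicate probe ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  cell <- function(cols) {
    m <- matrix(as.numeric(unlist(lapply(body, `[`, cols), use.names = FALSE)),
                nrow = length(body), ncol = length(cols), byrow = TRUE)
    dimnames(m) <- list(probes, NULL)
    m
  }
  values <- cell(sig_cols)
  colnames(values) <- sids
  detection <- NULL
  if (length(det_cols)) {
    det_sids <- sub("\\.Detection$", "", header[det_cols])
    missing_det <- setdiff(sids, det_sids)
    if (length(missing_det)) {
      warning("signal columns without matching detection columns: ",
              paste(missing_det, collapse = ", "),
              "; detection matrix not stored", call. = FALSE)
    } else {
      detection <- cell(det_cols[match(sids, det_sids)])
      colnames(detection) <- sids
      if (detection_semantics == "pvalue") detection <- 1 - detection
    }
  }
  expression_matrix(values, "linear", detection)
}

#' Write a probe-profile expression table
#'
#' Inverse of [read_probe_profile()]. Numeric cells are written with fixed
#' 6-decimal formatting so that diffs between runs are stable.
#'
#' @param x An `expr_matrix` (any scale; values written as stored).
#' @param path Output path.
#' @param detection_semantics How to encode the detection matrix on disk:
#'   as confidences or as p-values (`1 - confidence`).
#' @return `path`, invisibly.
#' @export
write_probe_profile <- function(x, path,
                                detection_semantics = c("confidence", "pvalue")) {
  detection_semantics <- match.arg(detection_semantics)
  sids <- sample_ids(x)
  header <- "PROBE_ID"
  for (s in sids) {
    header <- c(header, paste0(s, ".AVG_Signal"))
    if (!is.null(x$detection)) header <- c(header, paste0(s, ".Detection"))
  }
  n <- nrow(x$values)
  cols <- vector("list", length(header))
  cols[[1]] <- probe_ids(x)
  k <- 1L
  for (j in seq_along(sids)) {
    k <- k + 1L
    cols[[k]] <- sprintf("%.6f", x$values[, j])
    if (!is.null(x$detection)) {
      k <- k + 1L
      d <- x$detection[, j]
      if (detection_semantics == "pvalue") d <- 1 - d
      cols[[k]] <- sprintf("%.6f", d)
    }
  }
  lines <- c(paste(header, collapse = "\t"),
             do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a hybridisation-plan sheet
#'
#' @param path Tab-delimited sheet with columns `sample_id`, `chip_id`,
#'   `array_slot`, `run_id`, `role`, `subject_id`, `replicate_tag`,
#'   `condition`.
#' @return A validated [hyb_plan()]; rows in file order.
#' @export
read_plan <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  hyb_plan(df)
}

#' Write a hybridisation-plan sheet
#' @param plan A `hyb_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  utils::write.table(as.data.frame(plan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a gene list
#'
#' Probe identifiers are written sorted, one per line under a `probe_id`
#' header, with the selection criteria recorded as `#` comment lines, so the
#' output is deterministic and diff-stable.
#'
#' @param gl A `gene_list` object (see [gene_list()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(gl, path) {
  stopifnot(inherits(gl, "gene_list"))
  crit <- gl$criteria
  hdr <- sprintf("# %s = %s", names(crit),
                 vapply(crit, function(v) paste(format(v), collapse = ","),
                        character(1)))
  writeLines(c(hdr, "probe_id", sort(gl$probes)), path)
  invisible(path)
}

#' Read a gene list written by [write_gene_list()]
#' @param path Path to the file.
#' @return A `gene_list` (criteria restored as character strings).
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (!length(body) || body[1] != "probe_id") {
    stop("not a gene-list file (missing probe_id header): ", path,
         call. = FALSE)
  }
  crit <- list()
  for (m in meta) {
    kv <- strsplit(sub("^# ", "", m), " = ", fixed = TRUE)[[1]]
    if (length(kv) == 2) crit[[kv[1]]] <- kv[2]
  }
  new_gene_list(body[-1], crit)
}

#' Write a consensus report as a tab-delimited table
#'
#' One row per analysis, mirroring the standard duplicate-list summary layout:
#' method, correction, |A|, |B|, overlap and consensus percentage.
#'
#' @param report Data frame of class `consensus_report` or a plain data frame
#'   with those columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  df <- as.data.frame(report)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.6f", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
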