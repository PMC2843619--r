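# deterministic per-stage seed derived from the root seed and a stage name
stage_seed <- function(root, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(root) * 1009L + h) %% .Machine$integer.max
}

#' Pipeline configuration
#'
#' Bundles every stage parameter of the full workflow. All randomness flows
#' from the single `seed` via named per-stage substreams.
#'
#' @param sim A [sim_config()] used to generate the input experiment, or
#'   `NULL` to supply `expr`/`plan` directly to [run_pipeline()].
#' @param corrections Subset of `c("QN", "MC", "CB")`: quantile-normalised
#'   only, mean-centred, empirical-Bayes corrected.
#' @param methods Subset of `c("moderated_t", "sam")`.
#' @param calibrator Logical vector: run without and/or with the reference
#'   samples as inter-batch calibrator (default `c(FALSE, TRUE)`).
#' @param fc,alpha,fdr Gene-list thresholds (see [gene_list()]).
#' @param filter_conf,filter_frac Detection-filter thresholds (see
#'   [detection_filter()]).
#' @param sam_n_perm Sign-flip draws for the SAM-style test.
#' @param seed Root seed.
#' @param out_dir Optional directory; when set, every report is written as
#'   TSV.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), corrections = c("QN", "MC", "CB"),
                            methods = c("moderated_t", "sam"),
                            calibrator = c(FALSE, TRUE),
                            fc = 1.5, alpha = 0.01, fdr = 0.05,
                            filter_conf = 0.80, filter_frac = 0.25,
                            sam_n_perm = 200L, seed = 1L, out_dir = NULL) {
  corrections <- match.arg(corrections, several.ok = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(sim = sim, corrections = corrections, methods = methods,
                 calibrator = calibrator, fc = fc, alpha = alpha, fdr = fdr,
                 filter_conf = filter_conf, filter_frac = filter_frac,
                 sam_n_perm = as.integer(sam_n_perm), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

# Prepare one duplicate group's matrix: subset, filter, log2, quantile
# normalise. With use_calibrator, reference samples on the group's runs are
# pooled in (co-normalised) and the correction is run through the
# calibrator path.
prepare_group <- function(expr, plan, group_pairs, cfg, correction,
                          use_calibrator) {
  ids <- c(group_pairs$pre, group_pairs$post)
  if (use_calibrator) {
    runs <- unique(plan$run_id[match(ids, plan$sample_id)])
    refs <- plan$sample_id[plan$role == "reference" & plan$run_id %in% runs]
    ids <- c(refs, ids)
  }
  sub <- em_subset(expr, samples = ids)
  filt <- detection_filter(sub, cfg$filter_conf, cfg$filter_frac)
  lg <- log2_transform(filt$expr)
  qn <- quantile_normalize(lg)
  idx <- match(sample_ids(qn), plan$sample_id)
  is_study <- plan$role[idx] == "study"
  if (use_calibrator) {
    corrected <- switch(correction,
      QN = em_subset(qn, samples = is_study),
      MC = apply_correction_with_calibrator(qn, plan, "mean_center"),
      CB = apply_correction_with_calibrator(qn, plan, "combat"))
  } else {
    cond <- factor(plan$condition[idx])
    corrected <- switch(correction,
      QN = qn,
      MC = mean_center(qn, plan),
      CB = eb_batch_correct(qn, plan, covariates = cond)$expr)
  }
  corrected
}

#' Run the full analysis workflow
#'
#' Executes the default stage order — simulate (or take supplied data),
#' split duplicates, detection-filter, log2, quantile-normalise, batch-
#' correct, test for differential expression, threshold, and score the
#' consensus between the duplicate groups — for every requested combination
#' of method, correction and calibrator use. Reference-sample variation
#' diagnostics (nested ANOVA before/after each correction) are computed
#' alongside.
#'
#' @param config A [pipeline_config()].
#' @param expr,plan Input data when `config$sim` is `NULL`: an
#'   [expression_matrix()] (linear scale with detection) and its
#'   [hyb_plan()].
#' @return A list of class `pipeline_result`:
#'   \describe{
#'     \item{report}{data frame with one row per method x calibrator x
#'       correction: `method`, `calibrator`, `correction`, `n_a`, `n_b`,
#'       `n_overlap`, `consensus`.}
#'     \item{three_group}{per analysis row, the [three_group_consensus()]
#'       report including the pooled group C.}
#'     \item{gene_lists}{nested list of the A/B/C `gene_list`s.}
#'     \item{varcomp}{across-gene [variance_summary()] of the reference
#'       samples per correction.}
#'     \item{manifest}{config, seeds and package version — sufficient to
#'       reproduce the bundle bit-identically.}
#'   }
#' @export
run_pipeline <- function(config = pipeline_config(), expr = NULL, plan = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$sim)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- stage_seed(config$seed, "simulate")
    sim <- simulate_experiment(sim_cfg)
    expr <- sim$expr; plan <- sim$plan
  } else if (is.null(expr) || is.null(plan)) {
    stop("without a sim config, both `expr` and `plan` must be supplied",
         call. = FALSE)
  }
  groups <- split_duplicates(plan)

  # reference-sample variance diagnostics per correction
  ref_ids <- plan$sample_id[plan$role == "reference"]
  varcomp <- NULL
  if (length(ref_ids) >= 4) {
    ref <- em_subset(expr, samples = ref_ids)
    reff <- detection_filter(ref, config$filter_conf, config$filter_frac)$expr
    refq <- quantile_normalize(log2_transform(reff))
    vlist <- list(QN = refq)
    if ("MC" %in% config$corrections) vlist$MC <- mean_center(refq, plan)
    if ("CB" %in% config$corrections) {
      vlist$CB <- eb_batch_correct(refq, plan)$expr
    }
    varcomp <- do.call(rbind, lapply(names(vlist), function(nm) {
      cbind(correction = nm,
            variance_summary(nested_anova(vlist[[nm]], plan)))
    }))
  }

  rows <- list(); threes <- list(); lists <- list()
  for (cal in config$calibrator) {
    for (corr in config$corrections) {
      mats <- lapply(groups[c("A", "B", "C")], function(gp)
        prepare_group(expr, plan, gp, config, corr, cal))
      for (met in config$methods) {
        gl <- lapply(c(A = "A", B = "B", C = "C"), function(g) {
          de <- if (met == "sam") {
            sam_paired(mats[[g]], groups[[g]], n_perm = config$sam_n_perm,
                       seed = stage_seed(config$seed,
                                         paste("sam", g, corr, cal)))
          } else {
            moderated_paired_t(mats[[g]], groups[[g]])
          }
          gene_list(de, fc = config$fc, alpha = config$alpha,
                    fdr = config$fdr)
        })
        cons <- consensus(gl$A, gl$B)
        key <- paste(met, corr, if (cal) "cal" else "nocal", sep = ".")
        rows[[key]] <- data.frame(method = met, calibrator = cal,
                                  correction = corr, n_a = cons$n_a,
                                  n_b = cons$n_b, n_overlap = cons$n_overlap,
                                  consensus = cons$consensus)
        threes[[key]] <- three_group_consensus(gl$A, gl$B, gl$C)
        lists[[key]] <- gl
      }
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  result <- structure(list(
    report = report, three_group = threes, gene_lists = lists,
    varcomp = varcomp,
    manifest = list(config = config, seed = config$seed,
                    package_version = as.character(utils::packageVersion("chipbatch")),
                    r_version = R.version.string)),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(config$out_dir, "consensus_report.tsv"))
    if (!is.null(varcomp)) {
      write_report(varcomp, file.path(config$out_dir, "varcomp_summary.tsv"))
    }
    for (key in names(lists)) {
      for (g in names(lists[[key]])) {
        write_gene_list(lists[[key]][[g]],
                        file.path(config$out_dir,
                                  sprintf("genes_%s_%s.tsv", key, g)))
      }
    }
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$report)
  invisible(x)
}
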