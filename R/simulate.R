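#' Simulation configuration for a BeadChip-like experiment
#'
#' Encodes the study design the generator emulates: multi-array chips
#' processed in a small number of runs (batches), one technical-reference
#' array per chip, and duplicate a/b hybridisations of paired pre/post study
#' biopsies placed so that duplicates straddle runs. Effects are planted on
#' the log2 scale: a per-(batch, gene) additive location shift, a
#' per-(batch, gene) multiplicative noise scale, and a treatment shift on a
#' fraction of genes.
#'
#' @param n_genes Number of probes to simulate.
#' @param n_chips Number of chips (default 18).
#' @param arrays_per_chip Arrays per chip (default 8; slot 1 holds the
#'   reference sample).
#' @param run_sizes Chips per processing run; must sum to `n_chips`
#'   (default `c(4, 4, 4, 4, 2)`).
#' @param sigma_batch SD of the per-(batch, gene) additive location shift,
#'   log2 units (default 0.22).
#' @param sigma_noise SD of array-level measurement noise, log2 units
#'   (default 0.18). The defaults put the between-run share of total SD near
#'   60\% and the total per-gene SD near 0.28.
#' @param delta_scale_sd SD of the log of the per-(batch, gene)
#'   multiplicative noise scale (default 0.1); set to 0 for a purely additive
#'   batch model.
#' @param frac_de Fraction of genes carrying a treatment effect
#'   (default 0.05).
#' @param effect_size_log2 Magnitude of the post-vs-pre shift for affected
#'   genes, log2 units (default 0.8); sign is randomised per gene.
#' @param baseline_mean,baseline_sd Normal distribution of per-gene baseline
#'   log2 expression (defaults 8 and 2).
#' @param detection_midpoint True log2 signal at which detection confidence
#'   is 0.5 (default 6).
#' @param detection_scale Logistic scale (log2 units) of the
#'   signal-to-confidence curve (default 0.5).
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_chips = 18L, arrays_per_chip = 8L,
                       run_sizes = c(4L, 4L, 4L, 4L, 2L),
                       sigma_batch = 0.22, sigma_noise = 0.18,
                       delta_scale_sd = 0.1, frac_de = 0.05,
                       effect_size_log2 = 0.8,
                       baseline_mean = 8, baseline_sd = 2,
                       detection_midpoint = 6, detection_scale = 0.5,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_chips = as.integer(n_chips),
              arrays_per_chip = as.integer(arrays_per_chip),
              run_sizes = as.integer(run_sizes), sigma_batch = sigma_batch,
              sigma_noise = sigma_noise, delta_scale_sd = delta_scale_sd,
              frac_de = frac_de, effect_size_log2 = effect_size_log2,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              detection_midpoint = detection_midpoint,
              detection_scale = detection_scale, seed = as.integer(seed))
  if (sum(cfg$run_sizes) != cfg$n_chips) {
    stop("run_sizes must sum to n_chips", call. = FALSE)
  }
  if (any(c(cfg$sigma_batch, cfg$sigma_noise, cfg$delta_scale_sd,
            cfg$baseline_sd) < 0)) {
    stop("all SDs must be >= 0", call. = FALSE)
  }
  if (cfg$frac_de < 0 || cfg$frac_de > 1) {
    stop("frac_de must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_genes < 1 || cfg$n_chips < 1 || cfg$arrays_per_chip < 2) {
    stop("need n_genes >= 1, n_chips >= 1, arrays_per_chip >= 2",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Build the hybridisation plan implied by a sim_config.
#
# Slot 1 of every chip carries the reference sample. The study slots hold
# duplicate a/b hybridisations of biopsies (= subject-condition pairs):
# biopsies assigned to the last run get both replicates there (intra-run
# duplicates); every other biopsy has its 'a' replicate in the first half of
# the remaining chips and its 'b' replicate in the second half, so those
# duplicates straddle runs. A third of the biopsies are paired pre/post
# subjects; the remainder are pre-only singletons placed last, so the last
# run's intra-run duplicates are singletons and every complete pre/post pair
# straddles runs in both duplicate groups. Within each duplicate chip set the
# conditions are partially confounded with the two chip halves — two of
# every three subjects have their pre biopsy in the first half (emulating the
# chronological flow of clinical sample processing), the third the reverse —
# so runs carry a condition imbalance without being fully confounded.
build_plan <- function(cfg) {
  S <- cfg$arrays_per_chip - 1L     # study slots per chip
  n_runs <- length(cfg$run_sizes)
  chip_run <- rep(seq_len(n_runs), cfg$run_sizes)
  chips <- sprintf("chip%02d", seq_len(cfg$n_chips))
  runs <- sprintf("run%d", chip_run)

  last_chips <- which(chip_run == n_runs)
  other_chips <- which(chip_run != n_runs)
  n_last_slots <- length(last_chips) * S
  if (n_last_slots %% 2L != 0L || length(other_chips) %% 2L != 0L) {
    stop(sprintf(paste0("cannot pair duplicates on this layout: the last run",
                        " offers %d study arrays (need an even number) and %d",
                        " chips remain (need an even number)"),
                 n_last_slots, length(other_chips)), call. = FALSE)
  }
  n_intra <- n_last_slots %/% 2L                 # biopsies duplicated in last run
  n_straddle <- (length(other_chips) %/% 2L) * S # biopsies straddling runs
  n_biopsies <- n_straddle + n_intra
  n_pair_subj <- n_biopsies %/% 3L               # subjects with pre AND post
  n_single <- n_biopsies - 2L * n_pair_subj
  subj_pair <- sprintf("P%02d", seq_len(n_pair_subj))
  subj_single <- sprintf("P%02d", n_pair_subj + seq_len(n_single))
  biopsy <- data.frame(
    subject_id = c(subj_pair, subj_pair, subj_single),
    condition = c(rep("pre", n_pair_subj), rep("post", n_pair_subj),
                  rep("pre", n_single)),
    stringsAsFactors = FALSE)

  a_chips <- other_chips[seq_len(length(other_chips) %/% 2L)]
  b_chips <- other_chips[-seq_len(length(other_chips) %/% 2L)]
  slot_of <- function(chip_set, k) {
    # k-th study slot over the given chips, filled chip by chip
    chip <- chip_set[(k - 1L) %/% S + 1L]
    cbind(chip = chip, slot = (k - 1L) %% S + 2L)
  }
  rows <- list()
  # reference samples, slot 1 of every chip
  rows[[1]] <- data.frame(
    sample_id = sprintf("C%02d", seq_len(cfg$n_chips)),
    chip_id = chips, array_slot = 1L, run_id = runs,
    role = "reference", subject_id = NA_character_,
    replicate_tag = "none", condition = "none", stringsAsFactors = FALSE)
  mk_study <- function(b_idx, tag, place) {
    data.frame(
      sample_id = sprintf("S_%s_%s_%s", biopsy$subject_id[b_idx],
                          biopsy$condition[b_idx], tag),
      chip_id = chips[place[, "chip"]], array_slot = as.integer(place[, "slot"]),
      run_id = runs[place[, "chip"]], role = "study",
      subject_id = biopsy$subject_id[b_idx], replicate_tag = tag,
      condition = biopsy$condition[b_idx], stringsAsFactors = FALSE)
  }
  if (n_straddle > 0L) {
    # biopsy indices: pre of pair subjects = 1..n_pair, post = n_pair+1..2n_pair,
    # singletons follow. Build a placement order whose first half holds pre of
    # odd subjects, post of even subjects, and half the singletons; the second
    # half holds the complements. With the default run sizes the halves
    # coincide with the two runs of each duplicate chip set.
    np <- min(n_pair_subj, n_straddle %/% 2L)
    pre_first <- seq_len(np) %% 3L != 0L
    pair_first <- ifelse(pre_first, seq_len(np), n_pair_subj + seq_len(np))
    pair_second <- ifelse(pre_first, n_pair_subj + seq_len(np), seq_len(np))
    singles <- setdiff(seq_len(n_straddle), c(pair_first, pair_second))
    ns1 <- (length(singles) + 1L) %/% 2L
    ord <- c(pair_first, singles[seq_len(ns1)],
             pair_second, singles[-seq_len(ns1)])
    k <- seq_len(n_straddle)
    rows[[2]] <- mk_study(ord, "a", slot_of(a_chips, k))
    rows[[3]] <- mk_study(ord, "b", slot_of(b_chips, k))
  }
  if (n_intra > 0L) {
    b_idx <- n_straddle + seq_len(n_intra)
    place <- slot_of(last_chips, seq_len(n_last_slots))
    rows[[4]] <- mk_study(b_idx, "a", place[seq_len(n_intra), , drop = FALSE])
    rows[[5]] <- mk_study(b_idx, "b",
                          place[n_intra + seq_len(n_intra), , drop = FALSE])
  }
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  hyb_plan(df, arrays_per_chip = cfg$arrays_per_chip)
}

#' Default study hybridisation plan
#'
#' The 144-sample layout of the emulated design: 18 chips of 8 arrays in 5
#' runs of 4/4/4/4/2 chips; one reference sample per chip (25 intra-run and
#' 128 inter-run reference pairs) and 63 duplicate a/b study biopsies, of
#' which 7 have both replicates in the last run and 56 straddle runs.
#'
#' @return A [hyb_plan()].
#' @export
default_study_plan <- function() build_plan(sim_config())

#' Simulate a BeadChip-like experiment
#'
#' Generates linear-scale intensities with a parallel detection-confidence
#' matrix and the hybridisation plan of the configured design. On the log2
#' scale the signal of gene g on array j in batch i is
#' `y = mu_g + treat_g * I(post & DE) + gamma_ig + delta_ig * eps`, with
#' `eps ~ N(0, sigma_noise^2)`, `gamma_ig ~ N(0, sigma_batch^2)` and
#' `log(delta_ig) ~ N(0, delta_scale_sd^2)`. All reference samples share one
#' fixed baseline profile; study biopsies share a second. Emitted values are
#' `2^y`; detection confidence is logistic in `y` around
#' `detection_midpoint`. Identical configs (including seed) give
#' bit-identical output.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `expr` ([expression_matrix()], linear scale,
#'   detection present), `plan` ([hyb_plan()]) and `truth` (class
#'   `sim_truth`: planted DE probe ids and signs, the batch location matrix
#'   `gamma` (runs x genes), the batch scale matrix `delta`, per-gene noise
#'   SD, and the baseline profiles).
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  plan <- build_plan(cfg)
  G <- cfg$n_genes
  genes <- sprintf("P%05d", seq_len(G))
  runs <- sort(unique(plan$run_id))
  B <- length(runs)
  N <- nrow(plan)

  set.seed(cfg$seed)
  mu_ref <- stats::rnorm(G, cfg$baseline_mean, cfg$baseline_sd)
  mu_study <- stats::rnorm(G, cfg$baseline_mean, cfg$baseline_sd)
  n_de <- round(cfg$frac_de * G)
  de_idx <- if (n_de > 0) sort(sample.int(G, n_de)) else integer(0)
  de_sign <- if (n_de > 0) sample(c(-1, 1), n_de, replace = TRUE) else numeric(0)
  treat <- numeric(G)
  treat[de_idx] <- de_sign * cfg$effect_size_log2
  gamma <- matrix(stats::rnorm(B * G, 0, cfg$sigma_batch), B, G,
                  dimnames = list(runs, genes))
  delta <- matrix(exp(stats::rnorm(B * G, 0, cfg$delta_scale_sd)), B, G,
                  dimnames = list(runs, genes))
  eps <- matrix(stats::rnorm(G * N, 0, cfg$sigma_noise), G, N)

  batch_i <- match(plan$run_id, runs)
  is_ref <- plan$role == "reference"
  is_post <- plan$condition == "post"
  y <- matrix(0, G, N, dimnames = list(genes, plan$sample_id))
  for (j in seq_len(N)) {
    mu <- if (is_ref[j]) mu_ref else mu_study
    y[, j] <- mu + (if (is_post[j]) treat else 0) +
      gamma[batch_i[j], ] + delta[batch_i[j], ] * eps[, j]
  }
  detection <- stats::plogis((y - cfg$detection_midpoint) / cfg$detection_scale)
  expr <- expression_matrix(2^y, "linear", detection)
  truth <- structure(list(
    true_de_probe_ids = genes[de_idx],
    de_sign = stats::setNames(de_sign, genes[de_idx]),
    treat = stats::setNames(treat, genes),
    gamma = gamma, delta = delta,
    sigma_noise = stats::setNames(rep(cfg$sigma_noise, G), genes),
    mu_ref = stats::setNames(mu_ref, genes),
    mu_study = stats::setNames(mu_study, genes),
    config = cfg), class = "sim_truth")
  list(expr = expr, plan = plan, truth = truth)
}

#' Enumerate replicate sample pairs of a plan
#'
#' Lists unordered pairs of technical replicates — reference samples (all
#' mutual replicates) or duplicate a/b study hybridisations of the same
#' biopsy — split by whether the two samples sit in the same run.
#'
#' @param plan A [hyb_plan()].
#' @param role `"reference"` or `"study"`.
#' @param which `"inter"` (different runs), `"intra"` (same run) or `"all"`.
#' @return Data frame with columns `id1`, `id2`, `run1`, `run2`.
#' @export
replicate_pairs <- function(plan, role = c("reference", "study"),
                            which = c("all", "inter", "intra")) {
  role <- match.arg(role)
  which <- match.arg(which)
  if (role == "reference") {
    ids <- plan$sample_id[plan$role == "reference"]
    if (length(ids) < 2) stop("fewer than two reference samples", call. = FALSE)
    cmb <- utils::combn(ids, 2)
    pairs <- data.frame(id1 = cmb[1, ], id2 = cmb[2, ],
                        stringsAsFactors = FALSE)
  } else {
    st <- plan[plan$role == "study" & plan$replicate_tag %in% c("a", "b"), ]
    key <- paste(st$subject_id, st$condition)
    a <- st[st$replicate_tag == "a", ]
    b <- st[st$replicate_tag == "b", ]
    common <- intersect(paste(a$subject_id, a$condition),
                        paste(b$subject_id, b$condition))
    if (!length(common)) stop("no duplicate a/b study pairs in plan",
                              call. = FALSE)
    ia <- match(common, paste(a$subject_id, a$condition))
    ib <- match(common, paste(b$subject_id, b$condition))
    pairs <- data.frame(id1 = a$sample_id[ia], id2 = b$sample_id[ib],
                        stringsAsFactors = FALSE)
  }
  pairs$run1 <- plan$run_id[match(pairs$id1, plan$sample_id)]
  pairs$run2 <- plan$run_id[match(pairs$id2, plan$sample_id)]
  switch(which,
         all = pairs,
         inter = pairs[pairs$run1 != pairs$run2, , drop = FALSE],
         intra = pairs[pairs$run1 == pairs$run2, , drop = FALSE])
}
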