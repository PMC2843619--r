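#' Construct a hybridisation plan
#'
#' The design sheet of a BeadChip experiment: one row per sample mapping it to
#' its chip, array slot on the chip, processing run (batch), role (technical
#' reference vs study sample), and — for study samples — subject, replicate
#' tag and treatment condition.
#'
#' @param df A data frame with columns `sample_id`, `chip_id`, `array_slot`,
#'   `run_id`, `role` (`reference`/`study`), `subject_id` (may be `NA`),
#'   `replicate_tag` (`a`/`b`/`none`), `condition` (`pre`/`post`/`none`).
#' @param arrays_per_chip Upper bound for `array_slot` (default 8, the
#'   HumanRef-8 layout).
#'
#' @return A validated data frame of class `hyb_plan`.
#' @export
hyb_plan <- function(df, arrays_per_chip = 8L) {
  required <- c("sample_id", "chip_id", "array_slot", "run_id", "role",
                "subject_id", "replicate_tag", "condition")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("plan is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[required]
  df$sample_id <- as.character(df$sample_id)
  df$chip_id <- as.character(df$chip_id)
  df$array_slot <- as.integer(df$array_slot)
  df$run_id <- as.character(df$run_id)
  df$role <- as.character(df$role)
  df$subject_id <- as.character(df$subject_id)
  df$replicate_tag <- as.character(df$replicate_tag)
  df$condition <- as.character(df$condition)
  attr(df, "arrays_per_chip") <- as.integer(arrays_per_chip)
  class(df) <- c("hyb_plan", "data.frame")
  validate_hyb_plan(df)
  df
}

validate_hyb_plan <- function(plan) {
  stopifnot(inherits(plan, "hyb_plan"))
  apc <- attr(plan, "arrays_per_chip")
  if (is.null(apc)) apc <- 8L
  if (anyDuplicated(plan$sample_id)) {
    stop("duplicate sample_id in plan: ",
         paste(unique(plan$sample_id[duplicated(plan$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad_slot <- which(is.na(plan$array_slot) | plan$array_slot < 1L |
                      plan$array_slot > apc)
  if (length(bad_slot)) {
    stop(sprintf("array_slot out of range 1..%d at row(s) %s", apc,
                 paste(bad_slot, collapse = ", ")), call. = FALSE)
  }
  key <- paste(plan$chip_id, plan$array_slot, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    parts <- strsplit(d, "\r", fixed = TRUE)[[1]]
    stop(sprintf("two samples occupy chip %s, slot %s", parts[1], parts[2]),
         call. = FALSE)
  }
  check_enum <- function(col, allowed) {
    bad <- which(!plan[[col]] %in% allowed)
    if (length(bad)) {
      stop(sprintf("unknown %s token '%s' at row %d (allowed: %s)",
                   col, plan[[col]][bad[1]], bad[1],
                   paste(allowed, collapse = ", ")), call. = FALSE)
    }
  }
  check_enum("role", c("reference", "study"))
  check_enum("replicate_tag", c("a", "b", "none"))
  check_enum("condition", c("pre", "post", "none"))
  # each chip must sit in exactly one run
  chip_runs <- unique(plan[, c("chip_id", "run_id")])
  if (anyDuplicated(chip_runs$chip_id)) {
    bad <- unique(chip_runs$chip_id[duplicated(chip_runs$chip_id)])
    stop("chip assigned to more than one run: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  # duplicate study samples: (subject, condition, tag) unique
  dup <- plan$role == "study" & plan$replicate_tag %in% c("a", "b")
  if (any(dup)) {
    trip <- paste(plan$subject_id[dup], plan$condition[dup],
                  plan$replicate_tag[dup])
    if (anyDuplicated(trip)) {
      stop("duplicate (subject_id, condition, replicate_tag) triple: ",
           trip[duplicated(trip)][1], call. = FALSE)
    }
  }
  invisible(plan)
}

#' @export
print.hyb_plan <- function(x, ...) {
  cat(sprintf("<hyb_plan> %d samples, %d chips, %d runs (%d reference, %d study)\n",
              nrow(x), length(unique(x$chip_id)), length(unique(x$run_id)),
              sum(x$role == "reference"), sum(x$role == "study")))
  NextMethod()
}

# batch factor for a set of sample ids, in that order
plan_batches <- function(plan, ids) {
  idx <- match(ids, plan$sample_id)
  if (anyNA(idx)) {
    stop("sample ids absent from plan: ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  factor(plan$run_id[idx])
}
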