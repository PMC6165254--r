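#' Hard-tissue fraction of a lesion
#'
#' The proportion of lesion pixels classified as hard (red); the malignancy
#' indicator of the system.
#'
#' @param masks A `hard_soft` object from [segment_hard()].
#' @param lesion The `lesion_mask` the masks partition.
#' @return A proportion in \[0, 1\].
#' @export
hard_fraction <- function(masks, lesion) {
  stopifnot(inherits(masks, "hard_soft"))
  n <- sum(lesion)
  if (n < 1L) abort("Lesion mask is empty.", class = "elastocad_invalid_input")
  if (sum(masks$hard) + sum(masks$soft) != n) {
    abort("Hard and soft masks do not partition the lesion.",
          class = "elastocad_invalid_input")
  }
  sum(masks$hard) / n
}

#' Three-level elasticity score from the hard fraction
#'
#' Score 1 (soft) for a red area strictly below `soft_cut` of the lesion,
#' score 2 (intermediate) between the cuts inclusive, score 3 (hard) strictly
#' above `hard_cut`. With the defaults, exactly 50% and exactly 75% both
#' score 2.
#'
#' @param fraction Numeric vector of hard fractions in \[0, 1\].
#' @param config A [cad_config] supplying `soft_cut` and `hard_cut`.
#' @return Integer vector of scores in \{1, 2, 3\}.
#' @examples
#' assign_score(c(0.30, 0.60, 0.80))
#' @export
assign_score <- function(fraction, config = cad_config()) {
  if (anyNA(fraction) || any(fraction < 0 | fraction > 1)) {
    abort("`fraction` must lie in [0, 1].", class = "elastocad_invalid_input")
  }
  ifelse(fraction < config$soft_cut, 1L,
         ifelse(fraction > config$hard_cut, 3L, 2L))
}

#' Binary diagnostic call from the elasticity score
#'
#' Soft and intermediate lesions (scores 1-2) are called benign; hard lesions
#' (score 3) malignant.
#'
#' @param score Integer vector with values in \{1, 2, 3\}.
#' @return Character vector, `"benign"` or `"malignant"`.
#' @export
binary_call <- function(score) {
  if (anyNA(score) || !all(score %in% 1:3)) {
    abort("`score` must contain only 1, 2 or 3.",
          class = "elastocad_invalid_input")
  }
  ifelse(score == 3L, "malignant", "benign")
}

#' Sweep the hard cut-off and tabulate AUC
#'
#' Re-scores every lesion at each candidate upper cut-off and reports the AUC
#' of the resulting 3-level score against the reference diagnosis. Because
#' the ROC variable is the ordinal score, the AUC depends on the cut-off;
#' this is how the best cut is selected.
#'
#' @param data A data frame with one row per lesion.
#' @param fraction,truth Columns of `data` holding the hard fraction and the
#'   reference label (`"benign"`/`"malignant"`); tidy-evaluated.
#' @param hard_cuts Candidate upper cut-offs to sweep.
#' @param soft_cut Lower cut-off, held fixed.
#' @return A tibble with columns `hard_cut` and `auc`.
#' @examples
#' d <- tibble::tibble(
#'   hard_fraction = c(0.2, 0.4, 0.6, 0.8, 0.9, 0.95),
#'   truth = rep(c("benign", "malignant"), each = 3)
#' )
#' cutoff_sweep(d)
#' @export
cutoff_sweep <- function(data, fraction = hard_fraction, truth = truth,
                         hard_cuts = c(0.70, 0.75, 0.80, 0.90),
                         soft_cut = 0.50) {
  f <- dplyr::pull(data, {{ fraction }})
  lab <- dplyr::pull(data, {{ truth }})
  if (length(unique(lab)) < 2L) {
    abort("Both classes must be present to compute AUC.",
          class = "elastocad_invalid_input")
  }
  purrr::map_dfr(hard_cuts, function(hc) {
    cfg <- cad_config(soft_cut = soft_cut, hard_cut = hc)
    tibble(hard_cut = hc,
           auc = roc_auc(assign_score(f, cfg), lab))
  })
}
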