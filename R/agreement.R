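#' Pairwise delineation agreement across observers
#'
#' For every ordered pair of observers, averages per-lesion Jaccard,
#' undersegmentation and oversegmentation over the lesions, with the first
#' observer of the pair taken as the reference mask. The layout mirrors the
#' familiar delineation-agreement table: one row per pair with mean and SD
#' of each measure.
#'
#' @param mask_sets Named list, one element per observer; each element a list
#'   of `lesion_mask`s over the same lesions in the same order.
#' @return A tibble with one row per observer pair.
#' @export
delineation_agreement <- function(mask_sets) {
  if (length(mask_sets) < 2L) {
    abort("Need masks from at least 2 observers.",
          class = "elastocad_invalid_input")
  }
  if (is.null(names(mask_sets))) {
    names(mask_sets) <- paste0("observer_", seq_along(mask_sets))
  }
  n_lesions <- unique(lengths(mask_sets))
  if (length(n_lesions) != 1L) {
    abort("All observers must delineate the same lesions.",
          class = "elastocad_invalid_input")
  }
  pairs <- utils::combn(names(mask_sets), 2L, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    per <- purrr::map2_dfr(mask_sets[[p[2]]], mask_sets[[p[1]]], mask_agreement)
    tibble(
      observer_a = p[1], observer_b = p[2], n_lesions = n_lesions,
      jsi_mean = mean(per$jsi), jsi_sd = sd(per$jsi),
      aum_mean = mean(per$aum), aum_sd = sd(per$aum),
      avm_mean = mean(per$avm), avm_sd = sd(per$avm)
    )
  })
}

#' Pairwise diagnostic agreement across observers
#'
#' Cohen's kappa on the binary calls for every pair of observers, plus the
#' single-rater absolute-agreement ICC on the ordinal scores across all
#' observers.
#'
#' @param calls A data frame or matrix, lesions in rows and one column of
#'   `"benign"`/`"malignant"` calls per observer.
#' @param scores Optional numeric matrix of the same shape holding the
#'   3-level scores, used for the ICC; when `NULL` the ICC is skipped.
#' @return An `agreement_report`: list with `diagnosis` (pairwise kappa
#'   tibble) and `icc`.
#' @export
diagnosis_agreement <- function(calls, scores = NULL) {
  calls <- as.data.frame(calls)
  if (ncol(calls) < 2L) {
    abort("Need calls from at least 2 observers.",
          class = "elastocad_invalid_input")
  }
  pairs <- utils::combn(names(calls), 2L, simplify = FALSE)
  kap <- purrr::map_dfr(pairs, function(p) {
    k <- cohens_kappa(calls[[p[1]]], calls[[p[2]]])
    tibble(observer_a = p[1], observer_b = p[2],
           kappa = k$kappa, band = k$band)
  })
  icc <- if (!is.null(scores)) icc_agreement(as.matrix(scores)) else NA_real_
  structure(list(diagnosis = kap, icc = icc), class = "agreement_report")
}

#' Full observer-agreement report
#'
#' Convenience wrapper combining [delineation_agreement()] on the masks with
#' [diagnosis_agreement()] on calls and scores.
#'
#' @inheritParams delineation_agreement
#' @inheritParams diagnosis_agreement
#' @return An `agreement_report` with `delineation`, `diagnosis` and `icc`.
#' @export
observer_agreement <- function(mask_sets = NULL, calls = NULL, scores = NULL) {
  if (is.null(mask_sets) && is.null(calls)) {
    abort("Supply `mask_sets` and/or `calls`.", class = "elastocad_invalid_input")
  }
  delin <- if (!is.null(mask_sets)) delineation_agreement(mask_sets) else NULL
  diag <- if (!is.null(calls)) diagnosis_agreement(calls, scores) else
    structure(list(diagnosis = NULL, icc = NA_real_), class = "agreement_report")
  structure(list(delineation = delin, diagnosis = diag$diagnosis,
                 icc = diag$icc),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  if (!is.null(x$delineation)) {
    cat(sprintf("  delineation: %d observer pairs, mean JSI %.3f\n",
                nrow(x$delineation), mean(x$delineation$jsi_mean)))
  }
  if (!is.null(x$diagnosis)) {
    cat(sprintf("  diagnosis: %d pairs, kappa %.3f-%.3f\n",
                nrow(x$diagnosis), min(x$diagnosis$kappa), max(x$diagnosis$kappa)))
  }
  if (!is.na(x$icc)) cat(sprintf("  ICC(2,1): %.3f\n", x$icc))
  invisible(x)
}

#' Simulate an observer's re-delineation of a contour
#'
#' Perturbs a contour the way a second reader would redraw it: a smooth
#' low-order radial modulation about the centroid (readers disagree on where
#' the margin lies, not pixel by pixel), a small global rescale and a
#' translation. Useful for inter-observer experiments on phantoms.
#'
#' @param contour A [lesion_contour].
#' @param radial_sd SD of the low-order radial modulation coefficients
#'   (relative; 0.05 means ~5% local radius changes).
#' @param shift_sd SD of the random translation, in pixels.
#' @param seed Integer seed.
#' @return A perturbed [lesion_contour].
#' @export
jitter_contour <- function(contour, radial_sd = 0.05, shift_sd = 2, seed) {
  stopifnot(inherits(contour, "lesion_contour"))
  v <- contour$vertices
  ctr <- colMeans(v)
  withr::with_seed(as.integer(seed), {
    theta <- atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])
    coef <- rnorm(5, 0, radial_sd)
    mult <- 1 + coef[1] +
      coef[2] * sin(theta) + coef[3] * cos(theta) +
      coef[4] * sin(2 * theta) + coef[5] * cos(2 * theta)
    mult <- pmax(mult, 0.5)
    shift <- rnorm(2, 0, shift_sd)
    x <- ctr[1] + (v[, 1] - ctr[1]) * mult + shift[1]
    y <- ctr[2] + (v[, 2] - ctr[2]) * mult + shift[2]
    lesion_contour(x, y, frame = contour$frame, id = contour$id)
  })
}
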