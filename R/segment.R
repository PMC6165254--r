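#' Pipeline configuration
#'
#' Collects the tunable parameters of the classification pipeline.
#'
#' @param soft_cut Hard-fraction cut below which a lesion scores 1 (soft).
#' @param hard_cut Hard-fraction cut above which a lesion scores 3 (hard);
#'   `soft_cut < hard_cut`, both strictly inside (0, 1).
#' @param red_floor_a Minimum mean a* (CIELab units) a candidate pixel class
#'   must have to count as red/hard. Otsu always splits a distribution, so
#'   without a floor an all-soft lesion would spuriously yield a hard class.
#' @param blue_floor_b Minimum b* for a pixel to be a hard candidate at all.
#'   Saturated blue has a* comparable to red's (both ~ +80) but b* ~ -108, so
#'   the a* axis only discriminates along the green-red hue limb; pixels with
#'   b* below this floor are blue-hued and always soft.
#' @param n_bins Histogram bins for [otsu_threshold()].
#' @param n_boot Bootstrap replicates for confidence intervals (>= 100).
#' @param seed Integer seed for all stochastic operations (`NULL` = caller
#'   must supply one where randomness is used).
#' @param panel_offset `c(dx, dy)` B-mode to elastogram translation for
#'   side-by-side composites.
#' @return A `cad_config` list.
#' @export
cad_config <- function(soft_cut = 0.50, hard_cut = 0.75,
                       red_floor_a = 20, blue_floor_b = 0,
                       n_bins = 256L, n_boot = 2000L, seed = NULL,
                       panel_offset = c(0, 0)) {
  if (!(soft_cut > 0 && soft_cut < hard_cut && hard_cut < 1)) {
    abort("Cut-offs must satisfy 0 < soft_cut < hard_cut < 1.",
          class = "elastocad_invalid_input")
  }
  if (n_boot < 100L) {
    abort("`n_boot` must be at least 100.", class = "elastocad_invalid_input")
  }
  structure(
    list(soft_cut = soft_cut, hard_cut = hard_cut,
         red_floor_a = red_floor_a, blue_floor_b = blue_floor_b,
         n_bins = as.integer(n_bins), n_boot = as.integer(n_boot),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         panel_offset = as.numeric(panel_offset)),
    class = "cad_config"
  )
}

#' @export
print.cad_config <- function(x, ...) {
  cat("<cad_config>\n")
  cat(sprintf("  cut-offs: soft < %.2f <= intermediate <= %.2f < hard\n",
              x$soft_cut, x$hard_cut))
  cat(sprintf("  red_floor_a %.1f, blue_floor_b %.1f, n_bins %d, n_boot %d, seed %s\n",
              x$red_floor_a, x$blue_floor_b, x$n_bins, x$n_boot,
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

#' Segment the hard (red) region inside a lesion
#'
#' Delineates red tissue by Otsu thresholding of the a* channel restricted to
#' the lesion mask. Pixels with b* below `blue_floor_b` are blue-hued and are
#' excluded from hard candidacy (blue shares red's large positive a*; only
#' along the green-red hue limb does a* order softness to hardness). The Otsu
#' split of the remaining a* values is then vetted by the red floor:
#' \itemize{
#'   \item if the upper class's mean a* is at or below `red_floor_a`, the
#'     lesion contains no red and the hard mask is empty;
#'   \item if the lower class's mean a* also exceeds the floor, the whole
#'     candidate set is red (a unimodal all-hard lesion) and everything is
#'     hard;
#'   \item otherwise pixels above the threshold are hard.
#' }
#' Degenerate (constant) a* distributions resolve the same way: all hard when
#' the mean exceeds the floor, else all soft.
#'
#' @param lab A `lab_image` from [rgb_to_cielab()].
#' @param lesion A `lesion_mask` (logical matrix) of the same shape.
#' @param config A [cad_config].
#' @return A `hard_soft` object: list with logical matrices `hard` and `soft`
#'   partitioning the lesion, and `otsu` (an `otsu_result`, or `NULL` when no
#'   split was performed).
#' @export
segment_hard <- function(lab, lesion, config = cad_config()) {
  stopifnot(inherits(lab, "lab_image"), inherits(config, "cad_config"))
  if (!identical(dim(lab$a), dim(unclass(lesion)))) {
    abort("Lab image and lesion mask shapes differ.",
          class = "elastocad_shape_error")
  }
  lesion_l <- unclass(lesion)
  n_lesion <- sum(lesion_l)
  if (n_lesion < 1L) {
    abort("Lesion mask is empty.", class = "elastocad_invalid_input")
  }
  a <- lab$a[lesion_l]
  b <- lab$b[lesion_l]
  candidate <- b >= config$blue_floor_b

  hard_flat <- rep(FALSE, n_lesion)
  ot <- NULL
  av <- a[candidate]
  if (length(av) >= 1L) {
    if (length(av) < 2L || diff(range(av)) <= 0) {
      # constant distribution: one class, hard iff red enough
      if (mean(av) > config$red_floor_a) hard_flat[candidate] <- TRUE
    } else {
      ot <- otsu_threshold(av, n_bins = config$n_bins)
      upper <- av > ot$threshold
      if (mean(av[upper]) > config$red_floor_a) {
        if (mean(av[!upper]) > config$red_floor_a) {
          hard_flat[candidate] <- TRUE      # unimodal red lesion
        } else {
          hard_flat[candidate] <- upper
        }
      }                                      # else: no red class, all soft
    }
  }

  hard <- soft <- matrix(FALSE, nrow(lab$a), ncol(lab$a))
  hard[lesion_l] <- hard_flat
  soft[lesion_l] <- !hard_flat
  structure(list(hard = hard, soft = soft, otsu = ot), class = "hard_soft")
}

#' @export
print.hard_soft <- function(x, ...) {
  cat(sprintf("<hard_soft> %d hard / %d soft pixels\n", sum(x$hard), sum(x$soft)))
  invisible(x)
}
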