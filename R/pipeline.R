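#' Classify one lesion on an elastogram
#'
#' Runs the full per-lesion pipeline: rasterize the contour (transferring it
#' from the B-mode panel first when a layout is given), convert the image to
#' CIELab, segment the hard region by Otsu thresholding of a* within the
#' lesion, and derive the hard fraction, 3-level score and binary call.
#'
#' @param image An [rgb_image] (the elastogram panel).
#' @param contour A [lesion_contour]; if its frame is `"b_mode"`, `layout`
#'   must be supplied.
#' @param config A [cad_config].
#' @param layout Optional [panel_layout] for B-mode contours.
#' @return A `hardness_result`: list with `lesion_id`, `hard_fraction`,
#'   `score`, `call`, `otsu_threshold` (`NA` when no split was performed),
#'   `lesion_area_px`, `hard_area_px`, plus the `lesion_mask` and the
#'   `hard`/`soft` masks for review. Use [tidy()] for the tabular row.
#' @export
classify_lesion <- function(image, contour, config = cad_config(),
                            layout = NULL) {
  stopifnot(inherits(image, "rgb_image"), inherits(contour, "lesion_contour"))
  if (contour$frame == "b_mode") {
    if (is.null(layout)) {
      layout <- panel_layout(config$panel_offset,
                             c(dim(image)[2], dim(image)[1]))
    }
    contour <- transfer_contour(contour, layout)
  }
  lesion <- polygon_to_mask(contour, dim(image)[1:2])
  lab <- rgb_to_cielab(image)
  masks <- segment_hard(lab, lesion, config)
  f <- hard_fraction(masks, lesion)
  score <- assign_score(f, config)
  structure(
    list(lesion_id = contour$id,
         hard_fraction = f,
         score = score,
         call = binary_call(score),
         otsu_threshold = if (is.null(masks$otsu)) NA_real_ else masks$otsu$threshold,
         lesion_area_px = mask_area(lesion),
         hard_area_px = sum(masks$hard),
         lesion_mask = lesion,
         masks = masks,
         image = image),
    class = "hardness_result"
  )
}

#' @export
print.hardness_result <- function(x, ...) {
  cat(sprintf("<hardness_result> '%s': %.1f%% hard (%d / %d px) -> score %d, %s\n",
              x$lesion_id, 100 * x$hard_fraction, x$hard_area_px,
              x$lesion_area_px, x$score, x$call))
  invisible(x)
}

#' Classify a cohort of phantom studies
#'
#' Maps [classify_lesion()] over a list of `phantom_study` objects and joins
#' the per-study ground truth, giving the tabular input expected by
#' [evaluate_performance()], [cutoff_sweep()] and the agreement functions.
#'
#' @param studies A list of `phantom_study` objects (see [generate_cohort()]).
#' @param config A [cad_config].
#' @return A tibble with one row per lesion: the measured `hard_fraction`,
#'   `score`, `call`, `otsu_threshold`, areas, and the ground-truth
#'   `true_hard_fraction` and `truth` label.
#' @export
classify_cohort <- function(studies, config = cad_config()) {
  purrr::map_dfr(studies, function(st) {
    res <- classify_lesion(st$image, st$contour, config)
    dplyr::bind_cols(
      tidy(res),
      tibble(true_hard_fraction = st$true_hard_fraction, truth = st$label)
    )
  })
}
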