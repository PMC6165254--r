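#' Tidy a per-lesion hardness result
#'
#' @param x A `hardness_result` from [classify_lesion()].
#' @param ... Unused.
#' @return A one-row tibble: `lesion_id`, `hard_fraction`, `hard_pct`
#'   (fraction x 100, 1 decimal, as shown to users), `score`, `call`,
#'   `otsu_threshold`, `lesion_area_px`, `hard_area_px`.
#' @exportS3Method generics::tidy
#' @export
tidy.hardness_result <- function(x, ...) {
  tibble(
    lesion_id = x$lesion_id,
    hard_fraction = x$hard_fraction,
    hard_pct = round(100 * x$hard_fraction, 1),
    score = x$score,
    call = x$call,
    otsu_threshold = x$otsu_threshold,
    lesion_area_px = x$lesion_area_px,
    hard_area_px = x$hard_area_px
  )
}

#' Tidy a performance evaluation
#'
#' @param x A `cad_eval` from [evaluate_performance()].
#' @param ... Unused.
#' @return A long tibble of metrics (`metric`, `value`), with sensitivity and
#'   specificity in percent.
#' @exportS3Method generics::tidy
#' @export
tidy.cad_eval <- function(x, ...) {
  tibble(
    metric = c("sensitivity", "specificity", "auc", "auc_ci_low",
               "auc_ci_high", "tp", "fp", "tn", "fn"),
    value = c(x$sensitivity, x$specificity, x$roc$auc, x$roc$ci_low,
              x$roc$ci_high, x$confusion$tp, x$confusion$fp,
              x$confusion$tn, x$confusion$fn)
  )
}

#' @rdname tidy.cad_eval
#' @return `glance()` returns a one-row tibble of the headline metrics.
#' @exportS3Method generics::glance
#' @export
glance.cad_eval <- function(x, ...) {
  tibble(
    n = x$n,
    sensitivity = x$sensitivity,
    specificity = x$specificity,
    auc = x$roc$auc,
    auc_ci_low = x$roc$ci_low,
    auc_ci_high = x$roc$ci_high,
    n_boot = x$roc$n_boot
  )
}

#' Tidy a bootstrap ROC summary
#'
#' @param x A `roc_summary` from [bootstrap_auc_ci()].
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.roc_summary <- function(x, ...) {
  tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
         n_boot = x$n_boot, seed = x$seed)
}

#' Tidy a kappa result
#'
#' @param x A `kappa_result` from [cohens_kappa()].
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.kappa_result <- function(x, ...) {
  tibble(kappa = x$kappa, band = x$band, p_o = x$p_o, p_e = x$p_e, n = x$n)
}

#' Tidy an agreement report
#'
#' @param x An `agreement_report` from [observer_agreement()].
#' @param ... Unused.
#' @return A list-free long tibble combining the delineation and diagnosis
#'   tables (`measure` column distinguishes them); the ICC appears as its
#'   own row with both observers `"all"`.
#' @exportS3Method generics::tidy
#' @export
tidy.agreement_report <- function(x, ...) {
  out <- list()
  if (!is.null(x$delineation)) {
    out$delin <- tidyr_longer_delin(x$delineation)
  }
  if (!is.null(x$diagnosis)) {
    out$diag <- dplyr::transmute(x$diagnosis,
                                 observer_a = .data$observer_a,
                                 observer_b = .data$observer_b,
                                 measure = "kappa", value = .data$kappa)
  }
  if (!is.na(x$icc)) {
    out$icc <- tibble(observer_a = "all", observer_b = "all",
                      measure = "icc", value = x$icc)
  }
  dplyr::bind_rows(out)
}

tidyr_longer_delin <- function(d) {
  purrr::map_dfr(c("jsi_mean", "jsi_sd", "aum_mean", "aum_sd",
                   "avm_mean", "avm_sd"), function(mm) {
    tibble(observer_a = d$observer_a, observer_b = d$observer_b,
           measure = mm, value = d[[mm]])
  })
}

#' Plot the ROC curve of an evaluation
#'
#' @param object A `cad_eval` from [evaluate_performance()].
#' @param ... Unused.
#' @return A ggplot object: the empirical ROC of the stored scores with the
#'   chance diagonal and the AUC in the subtitle.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.cad_eval <- function(object, ...) {
  pts <- roc_points(object$scores, object$labels)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#b2182b") +
    ggplot2::geom_point(size = 1.6, colour = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = "ROC of the 3-level elasticity score",
      subtitle = sprintf("AUC = %.3f (n = %d)", object$roc$auc, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a phantom study
#'
#' @param object A `phantom_study`.
#' @param ... Unused.
#' @return A ggplot object: the synthetic elastogram with the lesion contour
#'   overlaid.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.phantom_study <- function(object, ...) {
  img <- unclass(object$image)
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- tibble(
    x = rep(0:(w - 1), each = h),
    y = rep(0:(h - 1), times = w),
    fill = grDevices::rgb(as.vector(img[, , 1]), as.vector(img[, , 2]),
                          as.vector(img[, , 3]), maxColorValue = 255)
  )
  v <- object$contour$vertices
  ct <- tibble(x = c(v[, 1], v[1, 1]), y = c(v[, 2], v[1, 2]))
  ggplot2::ggplot(px, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::geom_path(data = ct, colour = "white", linewidth = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = object$spec$lesion_id,
      subtitle = sprintf("true hard fraction %.2f (%s)",
                         object$true_hard_fraction, object$label)
    ) +
    ggplot2::theme_void()
}

#' Plot a classified lesion with its hard region highlighted
#'
#' @param object A `hardness_result` from [classify_lesion()].
#' @param ... Unused.
#' @return A ggplot object: the elastogram with the segmented hard region
#'   outlined in white (hard pixels re-painted solid red, mirroring the
#'   system's reviewable output).
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.hardness_result <- function(object, ...) {
  over <- mask_overlay(object$image, object$masks$hard)
  img <- unclass(over)
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- tibble(
    x = rep(0:(w - 1), each = h),
    y = rep(0:(h - 1), times = w),
    fill = grDevices::rgb(as.vector(img[, , 1]), as.vector(img[, , 2]),
                          as.vector(img[, , 3]), maxColorValue = 255)
  )
  ggplot2::ggplot(px, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s: %.1f%% hard, score %d (%s)", object$lesion_id,
                      100 * object$hard_fraction, object$score, object$call)
    ) +
    ggplot2::theme_void()
}
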