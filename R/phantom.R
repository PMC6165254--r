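#' Strain colormap of the synthetic elastograms
#'
#' Piecewise-linear blue-green-red map emulating a colour strain overlay:
#' 0 (softest, highest strain) maps to pure blue, 0.5 to green and 1
#' (hardest, no strain) to pure red. Vendor colormaps are proprietary; this
#' emulation is self-consistent with the rest of the phantom module.
#'
#' @param strain Numeric vector in \[0, 1\], 0 = softest, 1 = hardest.
#' @return A numeric matrix with `length(strain)` rows and columns
#'   `r`, `g`, `b` in \[0, 255\].
#' @examples
#' strain_colormap(c(0, 0.5, 1))
#' @export
strain_colormap <- function(strain) {
  if (anyNA(strain) || any(strain < 0 | strain > 1)) {
    abort("`strain` must lie in [0, 1].", class = "elastocad_invalid_input")
  }
  r <- ifelse(strain < 0.5, 0, (strain - 0.5) * 2 * 255)
  g <- ifelse(strain < 0.5, strain * 2 * 255, (1 - strain) * 2 * 255)
  b <- ifelse(strain < 0.5, (1 - 2 * strain) * 255, 0)
  cbind(r = r, g = g, b = b)
}

#' Specification of a synthetic elastography study
#'
#' Describes one phantom: an elliptical lesion on a uniform soft background,
#' with a spatially coherent hard (red) region covering a known fraction of
#' the lesion.
#'
#' @param image_size `c(width, height)` in pixels.
#' @param center Ellipse center `c(x, y)` in 0-based pixel coordinates;
#'   defaults to the image center.
#' @param semi_axes Ellipse semi-axes `c(a, b)` in pixels.
#' @param rotation Ellipse rotation in radians.
#' @param target_hard_fraction Intended hard fraction in \[0, 1\]; the
#'   constructed fraction is `round(target * area) / area`, recorded exactly.
#' @param hard_region_geometry `"blob"` (a compact region grown around an
#'   interior point) or `"band"` (a half-plane cut across the lesion).
#' @param chroma_noise_sd SD of the per-channel Gaussian noise, in 8-bit
#'   counts, applied after colormapping and clipped to \[0, 255\].
#' @param background_strain Strain of the tissue outside the lesion.
#' @param seed Integer seed driving all randomness of the study.
#' @param lesion_id Identifier used in contours and reports.
#' @param label Reference diagnosis; when `NULL`, inferred as malignant iff
#'   `target_hard_fraction > 0.75`.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = c(200, 200), center = NULL,
                         semi_axes = c(45, 34), rotation = 0,
                         target_hard_fraction = 0.5,
                         hard_region_geometry = c("blob", "band"),
                         chroma_noise_sd = 0, background_strain = 0.15,
                         seed = 1L, lesion_id = "phantom-1", label = NULL) {
  hard_region_geometry <- match.arg(hard_region_geometry)
  if (is.na(target_hard_fraction) ||
      target_hard_fraction < 0 || target_hard_fraction > 1) {
    abort("`target_hard_fraction` must lie in [0, 1].",
          class = "elastocad_invalid_input")
  }
  w <- image_size[1]; h <- image_size[2]
  if (is.null(center)) center <- c((w - 1) / 2, (h - 1) / 2)
  r <- max(semi_axes)
  if (center[1] - r < 0 || center[1] + r > w - 1 ||
      center[2] - r < 0 || center[2] + r > h - 1) {
    abort("Lesion ellipse must lie fully inside the image.",
          class = "elastocad_invalid_input")
  }
  if (!is.null(label) && !label %in% c("benign", "malignant")) {
    abort("`label` must be 'benign' or 'malignant'.",
          class = "elastocad_invalid_input")
  }
  structure(
    list(image_size = as.numeric(image_size), center = as.numeric(center),
         semi_axes = as.numeric(semi_axes), rotation = rotation,
         target_hard_fraction = target_hard_fraction,
         hard_region_geometry = hard_region_geometry,
         chroma_noise_sd = chroma_noise_sd,
         background_strain = background_strain,
         seed = as.integer(seed), lesion_id = lesion_id, label = label),
    class = "phantom_spec"
  )
}

# exact ellipse membership at pixel centers; returns logical h x w matrix
.ellipse_mask <- function(spec) {
  w <- spec$image_size[1]; h <- spec$image_size[2]
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  dx <- xs - spec$center[1]; dy <- ys - spec$center[2]
  ct <- cos(spec$rotation); st <- sin(spec$rotation)
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  (u / spec$semi_axes[1])^2 + (v / spec$semi_axes[2])^2 <= 1
}

#' Generate one synthetic elastography study
#'
#' Builds the study deterministically from its seed: the elliptical lesion
#' mask at pixel centers, a hard region of exactly
#' `round(target_hard_fraction * area)` lesion pixels (a compact blob or a
#' band, never salt-and-pepper, so the a* distribution is realistically
#' bimodal), strain values drawn uniformly in \[0.85, 1\] for hard and
#' \[0, 0.35\] for soft pixels, the colormapped 8-bit image with optional
#' chroma noise, and a 64-vertex polygon tracing the ellipse boundary.
#'
#' @param spec A [phantom_spec].
#' @return A `phantom_study`: list with `image` ([rgb_image]), `contour`
#'   ([lesion_contour] in the elastogram frame), `lesion_mask` (the exact
#'   ellipse truth mask), `truth_mask_hard`, `true_hard_fraction` (the exact
#'   constructed pixel ratio), `label` and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lesion <- .ellipse_mask(spec)
  area <- sum(lesion)
  if (area < 1L) {
    abort("Lesion rasterizes to zero pixels.", class = "elastocad_degenerate")
  }
  k <- round(spec$target_hard_fraction * area)
  w <- spec$image_size[1]; h <- spec$image_size[2]

  withr::with_seed(spec$seed, {
    idx <- which(lesion)
    rows <- (idx - 1) %% h
    cols <- (idx - 1) %/% h
    hard_sel <- logical(area)
    if (k > 0) {
      if (spec$hard_region_geometry == "band") {
        phi <- runif(1, 0, 2 * pi)
        proj <- cols * cos(phi) + rows * sin(phi)
        hard_sel[order(proj, decreasing = TRUE)[seq_len(k)]] <- TRUE
      } else {
        # blob: the k lesion pixels nearest a random interior point
        t0 <- runif(1, 0, 2 * pi); r0 <- sqrt(runif(1, 0, 0.25))
        cx <- spec$center[1] + r0 * spec$semi_axes[1] * cos(t0)
        cy <- spec$center[2] + r0 * spec$semi_axes[2] * sin(t0)
        d2 <- (cols - cx)^2 + (rows - cy)^2
        hard_sel[order(d2)[seq_len(k)]] <- TRUE
      }
    }
    strain <- matrix(spec$background_strain, h, w)
    strain[idx[!hard_sel]] <- runif(area - k, 0, 0.35)
    strain[idx[hard_sel]] <- runif(k, 0.85, 1)
    rgb <- strain_colormap(as.vector(strain))
    if (spec$chroma_noise_sd > 0) {
      rgb <- rgb + matrix(rnorm(length(rgb), 0, spec$chroma_noise_sd),
                          nrow(rgb), ncol(rgb))
    }
    rgb <- round(pmin(255, pmax(0, rgb)))
    img <- rgb_image(array(rgb, dim = c(h, w, 3)))

    theta <- seq(0, 2 * pi, length.out = 65)[-65]
    ct <- cos(spec$rotation); st <- sin(spec$rotation)
    ex <- spec$semi_axes[1] * cos(theta); ey <- spec$semi_axes[2] * sin(theta)
    contour <- lesion_contour(
      spec$center[1] + ex * ct - ey * st,
      spec$center[2] + ex * st + ey * ct,
      frame = "elastogram", id = spec$lesion_id
    )

    truth_hard <- matrix(FALSE, h, w)
    truth_hard[idx[hard_sel]] <- TRUE
    label <- spec$label %||%
      if (spec$target_hard_fraction > 0.75) "malignant" else "benign"

    structure(
      list(image = img, contour = contour,
           lesion_mask = structure(lesion, class = c("lesion_mask", "matrix"),
                                   area_px = area),
           truth_mask_hard = truth_hard,
           true_hard_fraction = k / area,
           label = label, spec = spec),
      class = "phantom_study"
    )
  })
}

#' @export
print.phantom_study <- function(x, ...) {
  cat(sprintf("<phantom_study> '%s': %g x %g px, lesion %d px, true hard fraction %.3f (%s)\n",
              x$spec$lesion_id, x$spec$image_size[1], x$spec$image_size[2],
              mask_area(x$lesion_mask), x$true_hard_fraction, x$label))
  invisible(x)
}

#' Generate a synthetic cohort of elastography studies
#'
#' Draws per-lesion target hard fractions from class-specific Beta
#' distributions (benign lesions mostly soft, malignant mostly hard),
#' jitters lesion geometry, and generates each study from its own derived
#' seed. Fully reproducible from `seed`.
#'
#' @param n_benign,n_malignant Number of lesions per class (>= 1; a
#'   single-class cohort is allowed here but will be rejected by the
#'   evaluation layer).
#' @param benign_shape,malignant_shape `c(alpha, beta)` parameters of the
#'   Beta distributions for the target hard fractions.
#' @param chroma_noise_sd Per-channel noise SD passed to every study.
#' @param image_size Image size for every study.
#' @param seed Master integer seed.
#' @return A list of `phantom_study` objects, benign first.
#' @export
generate_cohort <- function(n_benign, n_malignant,
                            benign_shape = c(2, 5),
                            malignant_shape = c(5, 1.5),
                            chroma_noise_sd = 5,
                            image_size = c(200, 200), seed) {
  if (n_benign < 0 || n_malignant < 0 || n_benign + n_malignant < 1) {
    abort("Cohort must contain at least one lesion.",
          class = "elastocad_invalid_input")
  }
  n <- n_benign + n_malignant
  labels <- rep(c("benign", "malignant"), c(n_benign, n_malignant))
  specs <- withr::with_seed(as.integer(seed), {
    fr <- c(rbeta(n_benign, benign_shape[1], benign_shape[2]),
            rbeta(n_malignant, malignant_shape[1], malignant_shape[2]))
    purrr::map(seq_len(n), function(i) {
      a <- runif(1, 32, 48); b <- runif(1, 24, 38)
      phantom_spec(
        image_size = image_size,
        center = c(runif(1, 0.4, 0.6) * (image_size[1] - 1),
                   runif(1, 0.4, 0.6) * (image_size[2] - 1)),
        semi_axes = c(a, b), rotation = runif(1, 0, pi),
        target_hard_fraction = fr[i],
        hard_region_geometry = sample(c("blob", "band"), 1),
        chroma_noise_sd = chroma_noise_sd,
        seed = sample.int(.Machine$integer.max - 1L, 1),
        lesion_id = sprintf("%s-%03d", labels[i],
                            i - if (labels[i] == "malignant") n_benign else 0L),
        label = labels[i]
      )
    })
  })
  purrr::map(specs, generate_phantom)
}

#' Write a study bundle to disk
#'
#' Exports the elastogram PNG, the contour CSV (shared dialect), a truth CSV
#' `lesion_id,true_hard_fraction,label` and the spec as JSON.
#'
#' @param study A `phantom_study`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_study_bundle <- function(study, dir) {
  stopifnot(inherits(study, "phantom_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- study$spec$lesion_id
  write_elastogram(study$image, file.path(dir, paste0(id, ".png")))
  write_contours(study$contour, file.path(dir, paste0(id, "_contour.csv")))
  readr::write_csv(
    tibble(lesion_id = id, true_hard_fraction = study$true_hard_fraction,
           label = study$label),
    file.path(dir, paste0(id, "_truth.csv"))
  )
  jsonlite::write_json(study$spec[setdiff(names(study$spec), "label")],
                       file.path(dir, paste0(id, "_spec.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
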