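test_that("the strain colormap hits its anchor colors", {
  cm <- strain_colormap(c(0, 0.5, 1))
  expect_equal(unname(cm[1, ]), c(0, 0, 255))
  expect_equal(unname(cm[2, ]), c(0, 255, 0))
  expect_equal(unname(cm[3, ]), c(255, 0, 0))
  expect_error(strain_colormap(1.2), class = "elastocad_invalid_input")
  expect_error(strain_colormap(-0.1), class = "elastocad_invalid_input")
})

test_that("phantoms are deterministic and keep exact ground truth", {
  spec <- phantom_spec(target_hard_fraction = 0.37, chroma_noise_sd = 4,
                       seed = 99)
  st1 <- generate_phantom(spec)
  st2 <- generate_phantom(spec)
  expect_identical(unclass(st1$image), unclass(st2$image))
  expect_identical(st1$truth_mask_hard, st2$truth_mask_hard)

  area <- mask_area(st1$lesion_mask)
  k <- sum(st1$truth_mask_hard)
  expect_identical(k, as.integer(round(0.37 * area)))
  expect_identical(st1$true_hard_fraction, k / area)
  # hard pixels live inside the lesion
  expect_false(any(st1$truth_mask_hard & !unclass(st1$lesion_mask)))
  # contour polygon has >= 32 vertices and stays in the elastogram frame
  expect_gte(nrow(st1$contour$vertices), 32)
  expect_identical(st1$contour$frame, "elastogram")
})

test_that("zero-fraction phantoms have no red anywhere in the lesion", {
  st <- generate_phantom(phantom_spec(target_hard_fraction = 0,
                                      chroma_noise_sd = 0, seed = 5))
  expect_identical(sum(st$truth_mask_hard), 0L)
  res <- classify_lesion(st$image, st$contour)
  expect_identical(res$hard_fraction, 0)
})

test_that("band geometry produces a single contiguous hard region", {
  st <- generate_phantom(phantom_spec(target_hard_fraction = 0.4,
                                      hard_region_geometry = "band",
                                      chroma_noise_sd = 0, seed = 12))
  hard <- st$truth_mask_hard
  # flood fill from one hard pixel must reach all of them (4-connectivity)
  idx <- which(hard, arr.ind = TRUE)
  visited <- matrix(FALSE, nrow(hard), ncol(hard))
  queue <- list(idx[1, ])
  visited[idx[1, 1], idx[1, 2]] <- TRUE
  while (length(queue) > 0) {
    p <- queue[[1]]; queue <- queue[-1]
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      q <- p + d
      if (q[1] >= 1 && q[1] <= nrow(hard) && q[2] >= 1 && q[2] <= ncol(hard) &&
          hard[q[1], q[2]] && !visited[q[1], q[2]]) {
        visited[q[1], q[2]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  expect_identical(sum(visited), sum(hard))
})

test_that("noiseless recovery is within 2% across random specs", {
  set.seed(71)
  errs <- vapply(1:20, function(i) {
    st <- generate_phantom(phantom_spec(
      image_size = c(140, 140),
      semi_axes = c(runif(1, 28, 40), runif(1, 22, 30)),
      rotation = runif(1, 0, pi),
      target_hard_fraction = runif(1),
      hard_region_geometry = sample(c("blob", "band"), 1),
      chroma_noise_sd = 0, seed = 1000 + i
    ))
    expect_gte(mask_area(st$lesion_mask), 2000)
    res <- classify_lesion(st$image, st$contour)
    abs(res$hard_fraction - st$true_hard_fraction)
  }, numeric(1))
  expect_lt(max(errs), 0.02)
})

test_that("chroma noise up to sd 10 shifts the measured fraction by < 0.05", {
  for (f in c(0.2, 0.6, 0.9)) {
    clean <- generate_phantom(phantom_spec(target_hard_fraction = f,
                                           chroma_noise_sd = 0, seed = 81))
    noisy <- generate_phantom(phantom_spec(target_hard_fraction = f,
                                           chroma_noise_sd = 10, seed = 81))
    r0 <- classify_lesion(clean$image, clean$contour)
    r1 <- classify_lesion(noisy$image, noisy$contour)
    expect_lt(abs(r1$hard_fraction - r0$hard_fraction), 0.05)
  }
})

test_that("cohorts are reproducible and class-labelled", {
  c1 <- generate_cohort(3, 4, seed = 14, image_size = c(120, 120))
  c2 <- generate_cohort(3, 4, seed = 14, image_size = c(120, 120))
  expect_identical(length(c1), 7L)
  expect_identical(purrr::map_chr(c1, "label"),
                   rep(c("benign", "malignant"), c(3, 4)))
  expect_identical(purrr::map(c1, function(s) unclass(s$image)),
                   purrr::map(c2, function(s) unclass(s$image)))
  expect_error(generate_cohort(0, 0, seed = 1), class = "elastocad_invalid_input")
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(target_hard_fraction = 1.2),
               class = "elastocad_invalid_input")
  expect_error(phantom_spec(center = c(10, 10), semi_axes = c(45, 34)),
               class = "elastocad_invalid_input")
})

test_that("study bundles round-trip through plain-text formats", {
  st <- generate_phantom(phantom_spec(image_size = c(80, 80),
                                      semi_axes = c(20, 15),
                                      target_hard_fraction = 0.8,
                                      chroma_noise_sd = 3, seed = 23,
                                      lesion_id = "bundle-test"))
  dir <- withr::local_tempdir()
  write_study_bundle(st, dir)
  img <- read_elastogram(file.path(dir, "bundle-test.png"))
  expect_equal(unclass(img), unclass(st$image), ignore_attr = TRUE,
               tolerance = 1 / 255)
  cts <- read_contours(file.path(dir, "bundle-test_contour.csv"))
  expect_equal(cts[["bundle-test"]]$vertices, st$contour$vertices,
               tolerance = 1e-9)
  truth <- readr::read_csv(file.path(dir, "bundle-test_truth.csv"),
                           show_col_types = FALSE)
  expect_identical(truth$label, "malignant")
  expect_equal(truth$true_hard_fraction, st$true_hard_fraction)
  spec_json <- jsonlite::read_json(file.path(dir, "bundle-test_spec.json"))
  expect_identical(spec_json$seed, 23L)
})
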