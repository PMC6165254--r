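test_that("mask agreement identities hold", {
  a <- solid_mask(c(10, 10), 2:7, 2:7)
  expect_equal(mask_agreement(a, a), tibble::tibble(jsi = 1, aum = 0, avm = 0))

  b <- solid_mask(c(10, 10), 9:10, 9:10)
  expect_equal(mask_agreement(a, b), tibble::tibble(jsi = 0, aum = 1, avm = 1))

  # seg strictly contains gt with double its area
  gt <- solid_mask(c(10, 10), 1:5, 1:4)       # 20 px
  seg <- solid_mask(c(10, 10), 1:5, 1:8)      # 40 px
  expect_equal(mask_agreement(seg, gt), tibble::tibble(jsi = 0.5, aum = 0, avm = 0.5))

  expect_error(mask_agreement(a, matrix(FALSE, 10, 10)),
               class = "elastocad_invalid_input")
  expect_error(mask_agreement(a, solid_mask(c(5, 5), 1, 1)),
               class = "elastocad_shape_error")
})

test_that("mask agreement is symmetric in the expected way", {
  set.seed(61)
  for (i in 1:10) {
    a <- matrix(runif(100) < 0.4, 10, 10)
    b <- matrix(runif(100) < 0.4, 10, 10)
    if (!any(a) || !any(b)) next
    ab <- mask_agreement(a, b); ba <- mask_agreement(b, a)
    expect_equal(ab$jsi, ba$jsi)
    expect_equal(ab$aum, ba$avm)
    expect_equal(ab$avm, ba$aum)
  }
})

test_that("sensitivity and specificity reproduce hand-checked worked examples", {
  # 31 malignant, 52 benign; counts implied by the reported percentages
  r1 <- sens_spec(list(tp = 22, fn = 9, tn = 46, fp = 6))
  expect_equal(round(r1$sensitivity, 2), 70.97)
  expect_equal(round(r1$specificity, 2), 88.46)
  expect_equal(sens_spec(list(tp = 0, fn = 5, tn = 3, fp = 1))$sensitivity, 0)
  expect_error(sens_spec(list(tp = 0, fn = 0, tn = 5, fp = 0)),
               class = "elastocad_invalid_input")
})

test_that("AUC equals brute-force pair enumeration", {
  # hand-enumerable example: 9 pairs, 8.5 favourable half-counted
  s <- c(1, 1, 2, 2, 3, 3)
  l <- c("benign", "benign", "benign", "malignant", "malignant", "malignant")
  expect_equal(roc_auc(s, l), 8.5 / 9)
  expect_equal(roc_auc(s, l), oracle_auc(s, l))

  expect_equal(roc_auc(c(1, 2, 3, 4), c("benign", "benign", "malignant", "malignant")), 1)
  expect_equal(roc_auc(rep(2, 6), rep(c("benign", "malignant"), 3)), 0.5)

  set.seed(62)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    labels <- sample(c("benign", "malignant"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("benign", "malignant")
    scores <- sample(1:5, n, replace = TRUE)
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels),
                 info = paste("case", i))
    # relabeling complement
    flipped <- ifelse(labels == "benign", "malignant", "benign")
    expect_equal(roc_auc(scores, flipped), 1 - roc_auc(scores, labels))
  }
  expect_error(roc_auc(1:3, rep("benign", 3)), class = "elastocad_invalid_input")
})

test_that("AUC agrees with pROC on a random instance", {
  set.seed(63)
  scores <- c(rnorm(40, 1), rnorm(40))
  labels <- rep(c("malignant", "benign"), each = 40)
  got <- roc_auc(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c("benign", "malignant"), direction = "<", quiet = TRUE
  )))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("bootstrap AUC intervals are stratified, sane and reproducible", {
  labels <- rep(c("benign", "malignant"), each = 20)
  sep <- c(rnorm(20, 0), rnorm(20, 50))
  r <- bootstrap_auc_ci(sep, labels, n_boot = 200, seed = 9)
  expect_equal(r$ci_low, 1)
  expect_equal(r$ci_high, 1)

  r2 <- bootstrap_auc_ci(sep, labels, n_boot = 200, seed = 9)
  expect_identical(r, r2)

  set.seed(64)
  null_scores <- rnorm(1000)
  null_labels <- rep(c("benign", "malignant"), each = 500)
  rn <- bootstrap_auc_ci(null_scores, null_labels, n_boot = 2000, seed = 10)
  expect_lt(rn$ci_low, 0.5)
  expect_gt(rn$ci_high, 0.5)
  expect_true(rn$ci_low <= rn$auc && rn$auc <= rn$ci_high)
})

test_that("paired AUC-difference test behaves under null and alternative", {
  labels <- rep(c("benign", "malignant"), each = 30)
  set.seed(65)
  scores <- c(rnorm(30), rnorm(30, 1))
  same <- auc_difference_test(scores, scores, labels, n_boot = 500, seed = 1)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)

  perfect <- c(rep(0, 30), rep(1, 30))
  noise <- withr::with_seed(66, rnorm(60))
  dt <- auc_difference_test(perfect, noise, labels, n_boot = 1000, seed = 2)
  expect_gt(dt$difference, 0)       # reported as A - B
  expect_lt(dt$p_value, 0.05)

  expect_error(auc_difference_test(1:5, 1:4, labels[1:5], seed = 1),
               class = "elastocad_invalid_input")
})

test_that("kappa reproduces hand-computed contingency arithmetic", {
  # 2x2 table (25, 5; 5, 25): p_o = 50/60, p_e = 0.5 -> kappa = 2/3
  a <- rep(c("benign", "benign", "malignant", "malignant"), c(25, 5, 5, 25))
  b <- rep(c("benign", "malignant", "benign", "malignant"), c(25, 5, 5, 25))
  k <- cohens_kappa(a, b)
  expect_equal(k$kappa, 2 / 3, tolerance = 1e-12)
  expect_identical(k$band, "good")

  ident <- cohens_kappa(c("x", "y", "x", "z"), c("x", "y", "x", "z"))
  expect_equal(ident$kappa, 1)
  expect_identical(ident$band, "very_good")

  # invariance under category relabeling
  relab <- cohens_kappa(chartr("bm", "qr", substr(a, 1, 1)),
                        chartr("bm", "qr", substr(b, 1, 1)))
  expect_equal(relab$kappa, k$kappa)

  # agreement with an independent implementation
  ca <- e1071::classAgreement(table(a, b))
  expect_equal(k$kappa, ca$kappa, tolerance = 1e-12)

  # independent raters at large n give kappa ~ 0
  set.seed(67)
  x <- sample(c("benign", "malignant"), 4000, replace = TRUE)
  y <- sample(c("benign", "malignant"), 4000, replace = TRUE)
  expect_equal(cohens_kappa(x, y)$kappa, 0, tolerance = 0.05)

  expect_warning(kc <- cohens_kappa(rep("a", 5), rep("a", 5)))
  expect_equal(kc$kappa, 1)
})

test_that("kappa bands follow the conventional cut points", {
  expect_identical(kappa_band(c(0.1, 0.3, 0.5, 0.7, 0.9)),
                   c("poor", "fair", "moderate", "good", "very_good"))
  expect_identical(kappa_band(c(0.20, 0.40, 0.60, 0.80, 1.00)),
                   c("poor", "fair", "moderate", "good", "very_good"))
  expect_identical(kappa_band(-0.3), "poor")
})

test_that("ICC(2,1) matches the ANOVA oracle and behaves at the extremes", {
  m <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8), nrow = 4)
  expect_equal(icc_agreement(m), oracle_icc21(m), tolerance = 1e-12)

  # identical raters with between-lesion variance
  ident <- cbind(1:6, 1:6, 1:6)
  expect_equal(icc_agreement(ident), 1)

  # independent noise columns
  set.seed(68)
  noise <- matrix(rnorm(600), ncol = 3)
  expect_equal(icc_agreement(noise), 0, tolerance = 0.1)

  expect_error(icc_agreement(matrix(1, 4, 3)), class = "elastocad_degenerate")
  expect_error(icc_agreement(matrix(1:4, 4, 1)), class = "elastocad_invalid_input")
})

test_that("evaluate_performance bundles the metrics consistently", {
  d <- tibble::tibble(
    score = c(1, 1, 2, 2, 3, 3, 3, 1),
    truth = rep(c("benign", "malignant"), each = 4)
  )
  d$call <- binary_call(as.integer(d$score))
  ev <- evaluate_performance(d, n_boot = 200, seed = 3)
  expect_s3_class(ev, "cad_eval")
  expect_equal(ev$sensitivity, 75)
  expect_equal(ev$specificity, 100)
  expect_equal(ev$roc$auc, roc_auc(d$score, d$truth))
  td <- tidy(ev)
  expect_identical(td$value[td$metric == "tp"], 3)
  g <- glance(ev)
  expect_identical(g$n, 8L)
  p <- autoplot(ev)
  expect_s3_class(p, "ggplot")
})
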