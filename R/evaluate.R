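#' Agreement between two segmentation masks
#'
#' Compares a segmentation against a reference with the Jaccard similarity
#' index and the relative under- and over-segmentation areas:
#' \deqn{JSI = |S \cap G| / |S \cup G|,\quad
#'       AUM = |G \setminus S| / |G|,\quad
#'       AVM = |S \setminus G| / |S|}
#' where \eqn{S} is the segmented mask and \eqn{G} the reference (ground
#' truth). All three lie in \[0, 1\]; perfect overlap gives (1, 0, 0).
#'
#' @param seg,gt Logical matrices of equal shape, both nonempty.
#' @return A one-row tibble with columns `jsi`, `aum`, `avm`.
#' @export
mask_agreement <- function(seg, gt) {
  seg <- as.logical(seg); gt <- as.logical(gt)
  if (length(seg) != length(gt)) {
    abort("Masks have different shapes.", class = "elastocad_shape_error")
  }
  ns <- sum(seg); ng <- sum(gt)
  if (ns < 1L || ng < 1L) {
    abort("Both masks must be nonempty.", class = "elastocad_invalid_input")
  }
  inter <- sum(seg & gt)
  tibble(
    jsi = inter / (ns + ng - inter),
    aum = (ng - inter) / ng,
    avm = (ns - inter) / ns
  )
}

#' Confusion counts for binary calls
#'
#' Tallies true/false positives and negatives taking `"malignant"` as the
#' positive class.
#'
#' @param call Character vector of predicted calls (`"benign"`/`"malignant"`).
#' @param truth Character vector of reference labels, same length.
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(call, truth) {
  if (length(call) != length(truth)) {
    abort("`call` and `truth` must have equal length.",
          class = "elastocad_invalid_input")
  }
  tibble(
    tp = sum(call == "malignant" & truth == "malignant"),
    fp = sum(call == "malignant" & truth == "benign"),
    tn = sum(call == "benign" & truth == "benign"),
    fn = sum(call == "benign" & truth == "malignant")
  )
}

#' Sensitivity and specificity from confusion counts
#'
#' @param counts A one-row data frame or named list with `tp`, `fp`, `tn`,
#'   `fn` (e.g. from [confusion_counts()]).
#' @return A one-row tibble with `sensitivity` and `specificity`, in percent.
#' @examples
#' sens_spec(list(tp = 22, fn = 9, tn = 46, fp = 6))
#' @export
sens_spec <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (any(is.na(c(tp, fp, tn, fn))) || any(c(tp, fp, tn, fn) < 0)) {
    abort("Counts must be non-negative.", class = "elastocad_invalid_input")
  }
  if (tp + fn < 1L || tn + fp < 1L) {
    abort("Sensitivity/specificity undefined: a class has zero lesions.",
          class = "elastocad_invalid_input")
  }
  tibble(
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp)
  )
}

.check_labels <- function(labels) {
  pos <- labels == "malignant"
  if (!any(pos) || all(pos)) {
    abort("Both benign and malignant labels are required.",
          class = "elastocad_invalid_input")
  }
  pos
}

#' Area under the ROC curve
#'
#' The AUC equals the Mann-Whitney probability that a randomly chosen
#' malignant lesion outranks a randomly chosen benign one, with ties counted
#' half. Computed from midranks, which is exactly the normalized
#' Mann-Whitney U statistic.
#'
#' @param scores Numeric or ordinal scores (higher = more suspicious).
#' @param labels `"benign"`/`"malignant"` labels, same length.
#' @return The AUC, a proportion in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length.",
          class = "elastocad_invalid_input")
  }
  pos <- .check_labels(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)  # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC operating points over all score thresholds (for plotting)
roc_points <- function(scores, labels) {
  pos <- .check_labels(labels)
  cuts <- sort(unique(scores), decreasing = TRUE)
  pts <- purrr::map_dfr(cuts, function(cc) {
    tibble(fpr = mean(scores[!pos] >= cc), tpr = mean(scores[pos] >= cc))
  })
  dplyr::bind_rows(tibble(fpr = 0, tpr = 0), pts, tibble(fpr = 1, tpr = 1)) |>
    dplyr::distinct()
}

#' Bootstrap confidence interval for the AUC
#'
#' Resamples lesions with replacement within each class (stratified, so
#' every replicate keeps both classes) and reports the percentile 95%
#' interval of the replicate AUCs. Bit-reproducible for a fixed seed.
#'
#' @inheritParams roc_auc
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed; mandatory, so results are reproducible.
#' @return A `roc_summary`: list with `auc`, `ci_low`, `ci_high`, `n_boot`,
#'   `seed`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 2000L, seed) {
  if (n_boot < 100L) {
    abort("`n_boot` must be at least 100.", class = "elastocad_invalid_input")
  }
  pos <- .check_labels(labels)
  auc <- roc_auc(scores, labels)
  ip <- which(pos); ib <- which(!pos)
  boots <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      idx <- c(sample(ip, length(ip), replace = TRUE),
               sample(ib, length(ib), replace = TRUE))
      roc_auc(scores[idx], labels[idx])
    }, numeric(1))
  })
  ci <- unname(quantile(boots, c(0.025, 0.975)))
  structure(
    list(auc = auc, ci_low = ci[1], ci_high = ci[2],
         n_boot = as.integer(n_boot), seed = as.integer(seed)),
    class = "roc_summary"
  )
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("<roc_summary> AUC %.3f (95%% CI %.3f-%.3f; %d bootstrap replicates, seed %d)\n",
              x$auc, x$ci_low, x$ci_high, x$n_boot, x$seed))
  invisible(x)
}

#' Paired bootstrap test for an AUC difference
#'
#' Compares two scoring schemes evaluated on the same lesions. Lesions are
#' resampled (stratified by class) jointly for both score vectors; the
#' difference is reported as A minus B with a percentile interval and a
#' two-sided p-value from the sign proportion of the bootstrap distribution.
#'
#' @param scores_a,scores_b Paired scores on the same lesions.
#' @param labels `"benign"`/`"malignant"` labels.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return A one-row tibble: `difference`, `ci_low`, `ci_high`, `p_value`,
#'   `n_boot`, `seed`.
#' @export
auc_difference_test <- function(scores_a, scores_b, labels,
                                n_boot = 2000L, seed) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    abort("Scores and labels must be paired (equal lengths).",
          class = "elastocad_invalid_input")
  }
  pos <- .check_labels(labels)
  obs <- roc_auc(scores_a, labels) - roc_auc(scores_b, labels)
  ip <- which(pos); ib <- which(!pos)
  boots <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      idx <- c(sample(ip, length(ip), replace = TRUE),
               sample(ib, length(ib), replace = TRUE))
      roc_auc(scores_a[idx], labels[idx]) - roc_auc(scores_b[idx], labels[idx])
    }, numeric(1))
  })
  ci <- unname(quantile(boots, c(0.025, 0.975)))
  p <- min(1, 2 * min(mean(boots <= 0), mean(boots >= 0)))
  tibble(difference = obs, ci_low = ci[1], ci_high = ci[2],
         p_value = p, n_boot = as.integer(n_boot), seed = as.integer(seed))
}

#' Cohen's kappa with interpretive band
#'
#' Chance-corrected agreement between two raters on the same items,
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with the expected agreement
#' \eqn{p_e} from the product of marginal proportions. The interpretive
#' band follows the conventional cut points: up to 0.20 poor, 0.21-0.40
#' fair, 0.41-0.60 moderate, 0.61-0.80 good, 0.81-1.00 very good.
#'
#' @param ratings_a,ratings_b Paired categorical ratings (length >= 2).
#' @return A `kappa_result`: list with `kappa`, `band`, `p_o`, `p_e`, `n`.
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b) || length(ratings_a) < 2L) {
    abort("Ratings must be paired with length >= 2.",
          class = "elastocad_invalid_input")
  }
  lev <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(as.character(ratings_a), levels = lev)
  b <- factor(as.character(ratings_b), levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1) {
    warn("Both raters are constant and identical; kappa set to 1 by convention.")
    kappa <- 1
  } else {
    kappa <- (p_o - p_e) / (1 - p_e)
  }
  structure(
    list(kappa = kappa, band = kappa_band(kappa), p_o = p_o, p_e = p_e, n = n),
    class = "kappa_result"
  )
}

#' @rdname cohens_kappa
#' @param kappa A kappa value in \[-1, 1\].
#' @export
kappa_band <- function(kappa) {
  cut(kappa, breaks = c(-1, 0.20, 0.40, 0.60, 0.80, 1),
      labels = c("poor", "fair", "moderate", "good", "very_good"),
      include.lowest = TRUE) |> as.character()
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa_result> kappa %.3f (%s agreement; n = %d)\n",
              x$kappa, x$band, x$n))
  invisible(x)
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC from the
#' standard mean-squares decomposition: with row (lesion) mean square MSR,
#' column (rater) mean square MSC and residual MSE over n lesions and k
#' raters,
#' \deqn{ICC(2,1) = \frac{MSR - MSE}{MSR + (k-1) MSE + k (MSC - MSE)/n}.}
#'
#' @param ratings Numeric matrix, lesions in rows and raters in columns, no
#'   missing cells; >= 2 of each.
#' @return The ICC, a single number.
#' @export
icc_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) {
    abort("Ratings matrix has missing cells.", class = "elastocad_invalid_input")
  }
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) {
    abort("Need at least 2 lesions and 2 raters.",
          class = "elastocad_invalid_input")
  }
  if (var(as.numeric(ratings)) == 0) {
    abort("Zero total variance; ICC undefined.", class = "elastocad_degenerate")
  }
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Diagnostic performance of a set of calls and scores
#'
#' Bundles the per-cohort performance summary: confusion counts, sensitivity
#' and specificity, score-based AUC and (when a seed is given) its stratified
#' bootstrap confidence interval.
#'
#' @param data A data frame with one row per lesion.
#' @param score,call,truth Columns of `data` holding the ordinal score, the
#'   binary call and the reference label; tidy-evaluated.
#' @param n_boot Bootstrap replicates for the AUC interval.
#' @param seed Integer seed for the bootstrap; `NULL` skips the interval.
#' @return A `cad_eval` object; see [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @export
evaluate_performance <- function(data, score = score, call = call,
                                 truth = truth, n_boot = 2000L, seed = NULL) {
  sc <- dplyr::pull(data, {{ score }})
  cl <- dplyr::pull(data, {{ call }})
  tr <- dplyr::pull(data, {{ truth }})
  cc <- confusion_counts(cl, tr)
  ss <- sens_spec(cc)
  roc <- if (!is.null(seed)) {
    bootstrap_auc_ci(sc, tr, n_boot = n_boot, seed = seed)
  } else {
    structure(list(auc = roc_auc(sc, tr), ci_low = NA_real_,
                   ci_high = NA_real_, n_boot = 0L, seed = NA_integer_),
              class = "roc_summary")
  }
  structure(
    list(confusion = cc, sensitivity = ss$sensitivity,
         specificity = ss$specificity, roc = roc,
         n = length(tr), scores = sc, labels = tr),
    class = "cad_eval"
  )
}

#' @export
print.cad_eval <- function(x, ...) {
  cat(sprintf("<cad_eval> %d lesions (%d malignant / %d benign)\n",
              x$n, x$confusion$tp + x$confusion$fn,
              x$confusion$tn + x$confusion$fp))
  cat(sprintf("  sensitivity %.2f%%, specificity %.2f%%, AUC %.3f",
              x$sensitivity, x$specificity, x$roc$auc))
  if (!is.na(x$roc$ci_low)) {
    cat(sprintf(" (95%% CI %.3f-%.3f)", x$roc$ci_low, x$roc$ci_high))
  }
  cat("\n")
  invisible(x)
}
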