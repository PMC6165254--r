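#' Otsu threshold of a value distribution
#'
#' Finds the threshold that best separates a set of scalar values into two
#' classes by maximizing the between-class variance
#' \eqn{\sigma_B^2(t) = w_0(t)\,w_1(t)\,(\mu_0(t)-\mu_1(t))^2}, which is
#' equivalent to minimizing the combined within-class variance. Candidate
#' thresholds are the interior boundaries of `n_bins` equal-width bins over
#' the observed range; class weights and means are computed from the raw
#' values, so agreement with an exhaustive search over the same candidate
#' grid is exact. Ties in the maximal between-class variance resolve to the
#' lowest qualifying threshold.
#'
#' @param values Numeric vector (length >= 2) to threshold; here, the a*
#'   values of lesion pixels.
#' @param n_bins Number of equal-width histogram bins (>= 2) defining the
#'   candidate threshold grid. The default 256 mirrors the 8-bit convention.
#' @return An `otsu_result`: list with `threshold`, `inter_class_variance`,
#'   `n_foreground` (values above the threshold), `n_background`.
#' @examples
#' otsu_threshold(c(rnorm(50, 0), rnorm(50, 10)))$threshold
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    abort("`values` must be finite and non-missing.",
          class = "elastocad_invalid_input")
  }
  if (length(values) < 2L) {
    abort("Need at least 2 values to threshold.",
          class = "elastocad_invalid_input")
  }
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) {
    abort("`n_bins` must be at least 2.", class = "elastocad_invalid_input")
  }
  lo <- min(values); hi <- max(values)
  if (hi - lo <= 0) {
    abort("All values are identical; no threshold separates two classes.",
          class = "elastocad_degenerate")
  }
  cand <- seq(lo, hi, length.out = n_bins + 1L)[2:n_bins]
  s <- sort(values)
  n <- length(s)
  cs <- cumsum(s)
  # for each candidate t: lower class = values <= t
  n0 <- findInterval(cand, s)           # count of s <= t
  valid <- n0 > 0L & n0 < n
  sigma_b <- rep(-Inf, length(cand))
  if (any(valid)) {
    n0v <- n0[valid]
    mu0 <- cs[n0v] / n0v
    mu1 <- (cs[n] - cs[n0v]) / (n - n0v)
    w0 <- n0v / n
    sigma_b[valid] <- w0 * (1 - w0) * (mu0 - mu1)^2
  }
  best <- which.max(sigma_b)  # which.max takes the first (lowest) maximizer
  thr <- cand[best]
  structure(
    list(threshold = thr,
         inter_class_variance = sigma_b[best],
         n_foreground = sum(values > thr),
         n_background = sum(values <= thr)),
    class = "otsu_result"
  )
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf("<otsu_result> threshold %.4g (between-class variance %.4g); %d above / %d below\n",
              x$threshold, x$inter_class_variance, x$n_foreground, x$n_background))
  invisible(x)
}
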