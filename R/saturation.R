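#' Saturating detection model for collection effort
#'
#' The number of nonnative species detectable in a year saturates with the
#' collection effort `ef` (herbarium specimens collected that year):
#' \deqn{n(ef) = \frac{a \, ef}{1 + b \, ef}}
#' Rescaling \eqn{n} by the maximum detectable count `n_max` (the model value
#' at `ref_effort`, rounded) turns the curve into a detection probability, and
#' its complement into the probability `pu` that a species present in a given
#' year went uncollected. `fit_saturation` estimates `(a, b)` by nonlinear
#' least squares; `saturation_model` builds the same object from known
#' coefficients.
#'
#' @param ef numeric vector of yearly collection efforts (specimen counts).
#' @param n numeric vector of species detected in the corresponding years.
#' @param ref_effort effort at which `n_max` is read; default 1800.
#' @return an object of class `saturation_fit` with elements `a`, `b`, `r2`,
#'   `n_max`, `ref_effort`, and (when fitted) the `nls` fit.
#' @examples
#' m <- saturation_model(a = 0.7402232, b = 0.0031367)
#' predict(m, ef = 1800)       # ~200 species
#' detection_probability(m, 100)
#' @export
fit_saturation <- function(ef, n, ref_effort = 1800) {
  stopifnot(length(ef) == length(n))
  keep <- is.finite(ef) & is.finite(n)
  ef <- ef[keep]; n <- n[keep]
  if (length(unique(ef[ef > 0])) < 3L)
    stopf("fit_saturation: need >= 3 points with distinct positive effort")
  if (all(n == 0))
    stopf("fit_saturation: degenerate data, all species counts are zero")
  # deterministic init: a0 from the initial slope over the lowest positive
  # efforts, b0 = a0 / max(n); scaleOffset keeps the convergence criterion
  # defined on (near-)noise-free data
  pos <- which(ef > 0)
  lo <- pos[order(ef[pos])][seq_len(max(3L, length(pos) %/% 4L))]
  lo <- lo[!is.na(lo)]
  a0 <- max(sum(ef[lo] * n[lo]) / sum(ef[lo]^2), 1e-8)
  b0 <- a0 / max(n)
  dat <- data.frame(ef = ef, n = n)
  fit <- tryCatch(
    stats::nls(n ~ a * ef / (1 + b * ef), data = dat,
               start = list(a = a0, b = b0),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE,
                                            scaleOffset = 1)),
    error = function(e) stopf(
      "fit_saturation: nonlinear fit did not converge (start a=%.6g, b=%.6g): %s",
      a0, b0, conditionMessage(e)))
  cf <- stats::coef(fit)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((n - mean(n))^2)
  out <- saturation_model(cf[["a"]], cf[["b"]], ref_effort = ref_effort)
  out$r2 <- r2
  out$fit <- fit
  out$data <- dat
  out
}

#' @rdname fit_saturation
#' @param a,b positive model coefficients.
#' @export
saturation_model <- function(a, b, ref_effort = 1800) {
  stopifnot(is.numeric(a), is.numeric(b), a > 0, b > 0, ref_effort > 0)
  out <- list(a = unname(a), b = unname(b), ref_effort = ref_effort, r2 = NA_real_)
  out$n_max <- round(a * ref_effort / (1 + b * ref_effort))
  if (out$n_max <= 0) stopf("saturation_model: n_max is not positive")
  class(out) <- "saturation_fit"
  out
}

#' @rdname fit_saturation
#' @param object a `saturation_fit`.
#' @param ... unused.
#' @export
predict.saturation_fit <- function(object, ef, ...) {
  if (any(ef < 0)) stopf("saturation model: effort must be >= 0")
  object$a * ef / (1 + object$b * ef)
}

#' @rdname fit_saturation
#' @export
coef.saturation_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
print.saturation_fit <- function(x, ...) {
  cat("Saturating collection-effort model: n(ef) = a*ef / (1 + b*ef)\n")
  cat(sprintf("  a = %.7f, b = %.7f (asymptote a/b = %.1f)\n", x$a, x$b, x$a / x$b))
  cat(sprintf("  n_max = %d species at reference effort %g\n", x$n_max, x$ref_effort))
  if (is.finite(x$r2)) cat(sprintf("  R^2 = %.4f\n", x$r2))
  invisible(x)
}

#' Detection probability and probability of remaining undetected
#'
#' `detection_probability` rescales the saturation-model value by `n_max` and
#' clamps to `[0, 1]` (the raw ratio slightly exceeds 1 above the reference
#' effort); `undetected_probability` is its complement `pu = 1 - dp`.
#'
#' @param model a `saturation_fit`.
#' @param ef effort value(s), >= 0.
#' @return probabilities in `[0, 1]`.
#' @export
detection_probability <- function(model, ef) {
  stopifnot(inherits(model, "saturation_fit"))
  pmin(pmax(predict(model, ef) / model$n_max, 0), 1)
}

#' @rdname detection_probability
#' @export
undetected_probability <- function(model, ef) 1 - detection_probability(model, ef)

#' Adjusted residence time
#'
#' Corrects the residence time of a species for the chance that it went
#' uncollected in its first-record year: `art = rt + scale * pu`, where `pu`
#' is the probability of remaining undetected at that year's collection
#' effort and `scale` defaults to the conventional 100 years.
#'
#' @param rt residence time(s) in years, >= 0.
#' @param pu probability/probabilities of remaining undetected, in `[0, 1]`.
#' @param scale years added per unit of undetection probability.
#' @return adjusted residence time(s) in years.
#' @examples
#' adjust_residence_time(23, 0.25)  # 48
#' @export
adjust_residence_time <- function(rt, pu, scale = 100) {
  if (any(rt < 0)) stopf("adjust_residence_time: rt must be >= 0")
  if (!is_prob(pu)) stopf("adjust_residence_time: pu must lie in [0, 1]")
  rt + scale * pu
}

#' Per-year undetection probabilities from an effort series
#'
#' @param model a `saturation_fit`.
#' @param effort an effort series as returned by [effort_series()] (columns
#'   `year`, `ef`).
#' @return named numeric vector: `pu` keyed by year.
#' @export
pu_by_year <- function(model, effort) {
  stopifnot(is.data.frame(effort), all(c("year", "ef") %in% names(effort)))
  stats::setNames(undetected_probability(model, effort$ef), effort$year)
}
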