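#' Log-log regression of occupied localities on adjusted residence time
#'
#' Fits, by ordinary least squares, `log10(n_localities) ~ log10(art)` for
#' the species of one life-form group. The position of a species relative to
#' the pointwise confidence band of this line classifies it as occupying
#' more (`ML`) or fewer (`FL`) localities than expected from its residence
#' time alone.
#'
#' @param profiles a `species_profiles` data frame (or any data frame with
#'   columns `species`, `art`, `n_localities`).
#' @param life_form optional filter, `"herb_subshrub"` or `"tree_shrub"`.
#' @param post_lag_only if `TRUE`, fit only species with `art` above
#'   `lag_threshold` (default fits all species of the group, with the lag
#'   gate applied at classification time only).
#' @param lag_threshold years; used when `post_lag_only = TRUE`.
#' @return object of class `spread_fit`: coefficients, `r2`, two-sided
#'   slope `p_value`, `residual_sd`, sufficient statistics (`n`, `x_mean`,
#'   `s_xx`) for band computation, the underlying `lm`, and the fitting data.
#' @examples
#' pr <- data.frame(species = letters[1:6], art = c(60, 80, 120, 150, 200, 300),
#'                  n_localities = c(4, 6, 11, 15, 25, 48))
#' fit <- fit_spread(pr)
#' coef(fit)
#' confidence_band(fit, log10(100))
#' @export
fit_spread <- function(profiles, life_form = NULL, post_lag_only = FALSE,
                       lag_threshold = 54) {
  stopifnot(is.data.frame(profiles),
            all(c("species", "art", "n_localities") %in% names(profiles)))
  dat <- profiles
  if (!is.null(life_form)) dat <- dat[dat$life_form_group == life_form, , drop = FALSE]
  if (post_lag_only) dat <- dat[dat$art > lag_threshold, , drop = FALSE]
  if (nrow(dat) < 3L) stopf("fit_spread: need >= 3 species, got %d", nrow(dat))
  if (any(dat$n_localities < 1)) stopf("fit_spread: locality counts must be >= 1")
  if (any(dat$art <= 0)) stopf("fit_spread: adjusted residence times must be > 0")

  x <- log10(dat$art)
  y <- log10(dat$n_localities)
  if (stats::sd(x) == 0) stopf("fit_spread: zero variance in adjusted residence time")
  fit <- stats::lm(y ~ x)
  # noise-free input is legitimate here; silence the perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  out <- list(intercept = unname(stats::coef(fit)[1L]),
              slope = unname(stats::coef(fit)[2L]),
              r2 = sm$r.squared,
              p_value = sm$coefficients["x", "Pr(>|t|)"],
              residual_sd = sm$sigma,
              n = nrow(dat),
              x_mean = mean(x),
              s_xx = sum((x - mean(x))^2),
              life_form_group = if (is.null(life_form)) unique(dat$life_form_group) else life_form,
              lm = fit,
              data = data.frame(species = dat$species, x = x, y = y,
                                stringsAsFactors = FALSE))
  class(out) <- "spread_fit"
  out
}

#' @export
print.spread_fit <- function(x, ...) {
  cat("Spread regression: log10(localities) ~ log10(adjusted residence time)\n")
  cat(sprintf("  n = %d (%s)\n", x$n, paste(x$life_form_group, collapse = ", ")))
  cat(sprintf("  log10 N = %.4g + %.4g * log10 Rt\n", x$intercept, x$slope))
  cat(sprintf("  R^2 = %.4f, slope p = %.3g, residual sd = %.4f\n",
              x$r2, x$p_value, x$residual_sd))
  invisible(x)
}

#' @export
summary.spread_fit <- function(object, ...) summary(object$lm, ...)

#' @export
coef.spread_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @rdname fit_spread
#' @param object,x a `spread_fit`.
#' @param newdata optional data frame with an `art` column; default refits
#'   the training data.
#' @param ... unused.
#' @export
predict.spread_fit <- function(object, newdata = NULL, ...) {
  xv <- if (is.null(newdata)) object$data$x else log10(newdata$art)
  object$intercept + object$slope * xv
}

#' @export
residuals.spread_fit <- function(object, ...) {
  stats::setNames(object$data$y - predict(object), object$data$species)
}

#' Pointwise confidence band of the fitted spread line
#'
#' For the mean response at `x` (log10 years):
#' \deqn{\hat y(x) \pm t_{n-2,(1+level)/2}\; s \sqrt{1/n + (x-\bar x)^2/S_{xx}}}
#' With `type = "prediction"` the usual prediction-interval factor
#' `sqrt(1 + 1/n + ...)` is used instead.
#'
#' @param model a `spread_fit`.
#' @param x log10 adjusted residence time(s).
#' @param level confidence level in (0, 1).
#' @param type `"confidence"` (band for the mean response, the default) or
#'   `"prediction"`.
#' @return data frame with columns `x`, `fit`, `lower`, `upper`.
#' @export
confidence_band <- function(model, x, level = 0.95,
                            type = c("confidence", "prediction")) {
  stopifnot(inherits(model, "spread_fit"), level > 0, level < 1)
  type <- match.arg(type)
  fit <- model$intercept + model$slope * x
  lever <- 1 / model$n + (x - model$x_mean)^2 / model$s_xx
  if (type == "prediction") lever <- 1 + lever
  half <- stats::qt((1 + level) / 2, df = model$n - 2) *
    model$residual_sd * sqrt(lever)
  data.frame(x = x, fit = fit, lower = fit - half, upper = fit + half)
}

#' Classify species spread against the regression band
#'
#' Species with `art <= lag_threshold` are still within their lag phase
#' (`PRE_LAG`) and are not classified. Of the rest, a species above the
#' upper band limit occupies more localities than expected (`ML`), one below
#' the lower limit fewer (`FL`), and one inside the band `EXPECTED`. The
#' residual (observed minus fitted log10 localities) is stored for every
#' species, including pre-lag ones.
#'
#' @param profiles a `species_profiles` data frame (same life-form group as
#'   the model).
#' @param model a `spread_fit`.
#' @param lag_threshold lag-phase duration in years (54 for herbs and
#'   subshrubs, 300 for trees and shrubs).
#' @param level confidence level of the band.
#' @param type band type, as in [confidence_band()].
#' @return a `spread_classification` data frame: `species`, `art`,
#'   `n_localities`, `residual`, `label`; attribute `lag_threshold_used`.
#' @export
classify_spread <- function(profiles, model, lag_threshold = 54, level = 0.95,
                            type = c("confidence", "prediction")) {
  stopifnot(inherits(model, "spread_fit"), is.data.frame(profiles))
  type <- match.arg(type)
  x <- log10(profiles$art)
  y <- log10(profiles$n_localities)
  band <- confidence_band(model, x, level = level, type = type)
  residual <- y - band$fit
  label <- ifelse(profiles$art <= lag_threshold, "PRE_LAG",
                  ifelse(y > band$upper, "ML",
                         ifelse(y < band$lower, "FL", "EXPECTED")))
  out <- data.frame(species = profiles$species,
                    art = profiles$art,
                    n_localities = profiles$n_localities,
                    residual = residual,
                    label = label,
                    stringsAsFactors = FALSE)
  if ("n_relatives" %in% names(profiles)) out$n_relatives <- profiles$n_relatives
  attr(out, "lag_threshold_used") <- lag_threshold
  attr(out, "level") <- level
  attr(out, "band_type") <- type
  class(out) <- c("spread_classification", "data.frame")
  out
}

#' @export
plot.spread_fit <- function(x, classification = NULL, level = 0.95, ...) {
  dat <- x$data
  plot(dat$x, dat$y, xlab = "log10 adjusted residence time (yr)",
       ylab = "log10 localities", pch = 16,
       col = if (is.null(classification)) "grey30" else
         c(ML = "red", FL = "blue", EXPECTED = "grey50",
           PRE_LAG = "grey80")[classification$label], ...)
  xs <- seq(min(dat$x), max(dat$x), length.out = 100)
  bd <- confidence_band(x, xs, level = level)
  graphics::lines(xs, bd$fit)
  graphics::lines(xs, bd$lower, lty = 2, col = "darkgreen")
  graphics::lines(xs, bd$upper, lty = 2, col = "darkgreen")
  invisible(x)
}
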