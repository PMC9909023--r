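#' Fit a power-law species-area relationship
#'
#' Ordinary least squares of log(S) on log(A): log S = C + z log A. The
#' slope z is invariant to log base and area unit; the intercept C depends
#' on both (default base 10; the pipeline feeds areas in cm2 so C stays
#' positive). The slope p-value is the two-sided t-test with n - 2 df.
#'
#' @param points data.frame with columns `area` (> 0) and `richness` (> 0),
#'   at least 3 rows.
#' @param log_base 10 (default) or `exp(1)`.
#' @param area_scale multiplier applied to areas before fitting (e.g. 1e4
#'   for m2 -> cm2); affects only C.
#' @return a `sar_fit`: list with `z`, `C`, `r_squared`, `p_value`,
#'   `ci` (95% CI of z), `n_points`, `log_base`, `area_scale`.
#' @export
fit_sar <- function(points, log_base = 10, area_scale = 1) {
  if (nrow(points) < 3L)
    passar_error("SAR fit needs at least 3 points", "passar_too_few_points")
  if (any(points$area <= 0) || any(points$richness <= 0))
    passar_error("areas and richness must be positive", "passar_bad_points")
  la <- log(points$area * area_scale, base = log_base)
  ls <- log(points$richness, base = log_base)
  if (max(la) - min(la) < 1e-12)
    passar_error("zero variance in log(area)", "passar_degenerate_areas")
  fit <- lm(ls ~ la)
  # exact power-law input is legitimate; silence only lm's perfect-fit notice
  muffle_perfect <- function(expr) withCallingHandlers(expr,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  sm <- muffle_perfect(summary(fit))
  ci <- muffle_perfect(confint(fit, "la", level = 0.95))
  structure(list(z = unname(coef(fit)["la"]),
                 C = unname(coef(fit)["(Intercept)"]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients["la", "Pr(>|t|)"]),
                 ci = c(lower = ci[1L], upper = ci[2L]),
                 n_points = nrow(points),
                 log_base = log_base, area_scale = area_scale),
            class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf("SAR fit: z = %.4f (95%% CI %.4f..%.4f), C = %.4f, r2 = %.4f, p = %.3g (n = %d)\n",
              x$z, x$ci[1], x$ci[2], x$C, x$r_squared, x$p_value, x$n_points))
  invisible(x)
}

#' Mean SAR slope over several fits
#' @param fits non-empty list of [fit_sar()] results.
#' @return arithmetic mean of the z values.
#' @export
mean_slope <- function(fits) {
  if (length(fits) == 0L)
    passar_error("no fits supplied", "passar_bad_spec")
  mean(vapply(fits, `[[`, numeric(1), "z"))
}

#' Fit one SAR per island model
#'
#' @param models island models from [build_island_models()].
#' @param log_base,area_scale passed to [fit_sar()]; the default scale 1e4
#'   converts m2 areas to cm2.
#' @return data.frame with one row per model: `model`, `z`, `C`, `r2`, `p`,
#'   `ci_lo`, `ci_hi`.
#' @export
fit_sar_models <- function(models, log_base = 10, area_scale = 1e4) {
  pts <- group_richness_points(models)
  do.call(rbind, lapply(split(pts, pts$model), function(d) {
    f <- fit_sar(d, log_base = log_base, area_scale = area_scale)
    data.frame(model = d$model[1L], z = f$z, C = f$C, r2 = f$r_squared,
               p = f$p_value, ci_lo = unname(f$ci[1L]),
               ci_hi = unname(f$ci[2L]), row.names = NULL)
  }))
}
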