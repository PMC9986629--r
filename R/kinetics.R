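# Enzyme-characterization fits: Michaelis-Menten kinetics, first-order
# thermal-inactivation decay with half-life, and comparative bookkeeping.

#' Fit the Michaelis-Menten model
#'
#' Nonlinear least squares of `v = Vmax * S / (Km + S)` via
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]). Starting values: `Vmax0 =
#' max(v)` and `Km0` = substrate level at half-maximal velocity
#' (interpolated); parameters are bounded below by 0. Non-identifiable data
#' (e.g. velocity independent of substrate) is reported with
#' `converged = FALSE`.
#'
#' @param data data frame of the assay observations.
#' @param substrate,velocity columns holding substrate concentration
#'   (mg/mL) and initial velocity (tidy-eval; defaults to columns named
#'   `substrate` and `velocity`).
#' @return an object of class `mm_fit`: vmax, km, standard errors, residual
#'   sum of squares, `converged`, and the underlying `nls` object.
#' @export
fit_michaelis_menten <- function(data, substrate = substrate,
                                 velocity = velocity) {
  s <- rlang::eval_tidy(rlang::enquo(substrate), data)
  v <- rlang::eval_tidy(rlang::enquo(velocity), data)
  if (length(s) < 4) abort("Michaelis-Menten fit needs at least 4 points.")
  if (length(unique(s)) < 2) abort("Need at least 2 distinct substrate levels.")
  if (any(v < 0)) abort("Velocities must be non-negative.")
  vmax0 <- max(v)
  ord <- order(s)
  km0 <- tryCatch(
    approx(v[ord], s[ord], xout = vmax0 / 2, ties = mean)$y,
    error = function(e) NA_real_)
  if (!is.finite(km0) || km0 <= 0) km0 <- median(s)
  df <- tibble(s = s, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * s / (km + s), data = df,
                      start = list(vmax = vmax0, km = km0),
                      lower = c(0, 0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ptol = 1e-10, ftol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(vmax = NA_real_, km = NA_real_,
                          vmax_se = NA_real_, km_se = NA_real_,
                          rss = NA_real_, n = length(s),
                          converged = FALSE, fit = NULL, data = df),
                     class = "mm_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 2))
  identifiable <- cf[["km"]] > 1e-6 * median(s) && cf[["vmax"]] > 0
  structure(list(vmax = cf[["vmax"]], km = cf[["km"]],
                 vmax_se = se[[1]], km_se = se[[2]],
                 rss = sum(stats::residuals(fit)^2), n = length(s),
                 converged = fit$convInfo$isConv && identifiable,
                 fit = fit, data = df),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> Vmax = %.4g +- %.2g, Km = %.4g +- %.2g (n = %d, RSS = %.4g, %s)\n",
              x$vmax, x$vmax_se, x$km, x$km_se, x$n, x$rss,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(term = c("vmax", "km"),
         estimate = c(x$vmax, x$km),
         std.error = c(x$vmax_se, x$km_se))
}

#' @export
glance.mm_fit <- function(x, ...) {
  tibble(vmax = x$vmax, km = x$km, rss = x$rss, n = x$n,
         converged = x$converged)
}

#' Fit first-order thermal inactivation and half-life
#'
#' Nonlinear least squares of `A(t) = A0 * exp(-k t)` (log-linear regression
#' start), with `t_half = ln(2) / k`. Non-positive activities are dropped
#' with a warning; data showing no decay raise an error.
#'
#' @param data data frame of the inactivation time course.
#' @param time,activity columns holding incubation time (min) and residual
#'   activity (tidy-eval; defaults to columns `time` and `activity`).
#' @return an object of class `decay_fit`: a0, k (1/min), t_half (min),
#'   standard errors, residual sum of squares, `converged`.
#' @export
fit_decay <- function(data, time = time, activity = activity) {
  t <- rlang::eval_tidy(rlang::enquo(time), data)
  a <- rlang::eval_tidy(rlang::enquo(activity), data)
  if (anyDuplicated(t)) abort("Times must be distinct.")
  if (any(t < 0)) abort("Times must be non-negative.")
  keep <- a > 0
  if (!all(keep)) {
    warn(sprintf("%d non-positive activity value(s) excluded from the decay fit",
                 sum(!keep)))
  }
  t <- t[keep]; a <- a[keep]
  if (length(t) < 3) abort("Decay fit needs at least 3 usable points.")
  ll <- lm(log(a) ~ t)
  k0 <- -coef(ll)[["t"]]
  if (k0 <= 1e-8) abort("No decay detected (activity does not decrease with time).")
  df <- tibble(t = t, a = a)
  fit <- minpack.lm::nlsLM(a ~ a0 * exp(-k * t), data = df,
                           start = list(a0 = exp(coef(ll)[[1]]), k = k0),
                           lower = c(0, 0),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ptol = 1e-10, ftol = 1e-12))
  cf <- coef(fit)
  if (cf[["k"]] <= 1e-8) abort("No decay detected (fitted rate is zero).")
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 2))
  structure(list(a0 = cf[["a0"]], k = cf[["k"]],
                 t_half = log(2) / cf[["k"]],
                 a0_se = se[[1]], k_se = se[[2]],
                 rss = sum(stats::residuals(fit)^2), n = length(t),
                 converged = fit$convInfo$isConv, fit = fit, data = df),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> k = %.4g 1/min, t1/2 = %.4g min (n = %d, %s)\n",
              x$k, x$t_half, x$n,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("a0", "k", "t_half"),
         estimate = c(x$a0, x$k, x$t_half),
         std.error = c(x$a0_se, x$k_se, x$k_se * log(2) / x$k^2))
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble(a0 = x$a0, k = x$k, t_half = x$t_half, rss = x$rss, n = x$n,
         converged = x$converged)
}

#' Wild-type vs mutant comparison record
#'
#' @param wild,mutant the two values being compared.
#' @param quantity name of the quantity (e.g. `"t_half"`, `"Tm"`).
#' @return a one-row tibble: `quantity`, `wild`, `mutant`, `delta = mutant -
#'   wild`, `fold_increase = (mutant - wild) / wild` (`NA` when wild is 0).
#' @examples
#' compare(8.3, 73.4, "t_half")   # fold_increase ~ 7.8
#' compare(75.7, 77.7, "Tm")      # delta 2.0
#' @export
compare <- function(wild, mutant, quantity = "value") {
  fold <- if (wild == 0) NA_real_ else (mutant - wild) / wild
  tibble(quantity = quantity, wild = wild, mutant = mutant,
         delta = mutant - wild, fold_increase = fold)
}

#' Catalytic efficiency kcat / Km
#'
#' @param kcat turnover number (1/s).
#' @param km Michaelis constant (mg/mL); must be positive.
#' @return kcat / km (mL mg^-1 s^-1).
#' @export
catalytic_efficiency <- function(kcat, km) {
  if (any(km <= 0)) abort("Km must be positive.")
  kcat / km
}
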