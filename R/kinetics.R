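#' Michaelis-Menten rate law
#'
#' \eqn{v = V_{max} S / (K_m + S)}.
#'
#' @param S Substrate concentration(s), same units as `Km` (>= 0).
#' @param Vmax Maximum velocity (> 0), in rate units.
#' @param Km Michaelis constant (> 0).
#' @return Rate(s), vectorized over `S`.
#' @export
#' @examples
#' mm_rate(153, Vmax = 1, Km = 153)  # half saturation
mm_rate <- function(S, Vmax, Km) {
  if (any(S < 0)) stop("'S' must be >= 0")
  if (Vmax <= 0 || Km <= 0) stop("'Vmax' and 'Km' must be positive")
  Vmax * S / (Km + S)
}

#' Fit the Michaelis-Menten model to initial-rate data
#'
#' Levenberg-Marquardt nonlinear least squares with positivity enforced by
#' a log-parameterization of `Vmax` and `Km`. The catalytic constant is
#' `kcat = Vmax / [E]` with units handled via `rate_to_conc`: rates are
#' assumed to be in concentration/time units after multiplication by that
#' calibration factor (default 1, i.e. rates already in uM/s), and the
#' enzyme concentration is given in nM, so
#' `kcat (1/s) = rate_to_conc * Vmax / (enzyme_conc * 1e-3)`.
#'
#' @param S Substrate concentrations (uM), >= 3 distinct values.
#' @param rate Observed initial rates, same length.
#' @param enzyme_conc Enzyme concentration (nM); `NA` skips kcat.
#' @param start Optional `c(Vmax, Km)` start; defaults to
#'   `c(max(rate), median(S))`.
#' @param rate_to_conc Calibration factor converting rate units to uM/s.
#'   Default 1.
#' @return Object of class `mm_fit`: list with `Vmax`, `Km`, `kcat`,
#'   `kcat_over_Km`, `se` (approximate SEs of `Vmax` and `Km`),
#'   `converged`, `fitted`, `residuals` and `diagnostics`.
#' @export
fit_mm <- function(S, rate, enzyme_conc = NA_real_, start = NULL,
                   rate_to_conc = 1) {
  stopifnot(length(S) == length(rate))
  if (length(unique(S)) < 3L) stop("need >= 3 distinct substrate concentrations")
  if (any(S < 0) || any(rate < 0)) stop("concentrations and rates must be >= 0")
  failed <- function(msg) {
    structure(list(Vmax = NA_real_, Km = NA_real_, kcat = NA_real_,
                   kcat_over_Km = NA_real_,
                   se = c(Vmax = NA_real_, Km = NA_real_),
                   converged = FALSE, fitted = NULL, residuals = NULL,
                   enzyme_conc = enzyme_conc, diagnostics = msg),
              class = "mm_fit")
  }
  # degenerate data: no saturation signal to fit
  if (max(rate) <= 0 || isTRUE(all.equal(min(rate), max(rate), tolerance = 1e-12))) {
    return(failed("rates carry no concentration dependence (ND)"))
  }
  default_start <- c(max(rate), stats::median(S))
  if (is.null(start)) start <- default_start
  if (any(start <= 0)) stop("start values must be positive")
  df <- data.frame(S = S, rate = rate)
  try_fit <- function(st) {
    tryCatch(
      minpack.lm::nlsLM(rate ~ exp(lV) * S / (exp(lK) + S), data = df,
                        start = list(lV = log(st[1L]), lK = log(st[2L])),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL
    )
  }
  fit <- try_fit(start)
  # a badly scaled user start can leave the initial Jacobian singular;
  # retry from the data-driven default before reporting failure
  if (is.null(fit) && !isTRUE(all.equal(start, default_start))) {
    fit <- try_fit(default_start)
  }
  if (is.null(fit)) return(failed("nonlinear least squares did not converge"))
  co <- coef(fit)
  Vmax <- exp(co[["lV"]]); Km <- exp(co[["lK"]])
  se_log <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
  se <- c(Vmax = Vmax * se_log[[1L]], Km = Km * se_log[[2L]])  # delta method
  kcat <- if (is.na(enzyme_conc)) NA_real_ else {
    if (enzyme_conc <= 0) stop("'enzyme_conc' must be positive")
    rate_to_conc * Vmax / (enzyme_conc * 1e-3)
  }
  structure(list(
    Vmax = Vmax, Km = Km, kcat = kcat,
    kcat_over_Km = if (is.na(kcat)) NA_real_ else kcat / Km,
    se = se, converged = TRUE, fitted = fitted(fit),
    residuals = stats::residuals(fit), enzyme_conc = enzyme_conc,
    diagnostics = "ok"
  ), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<mm_fit> not converged:", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat(sprintf("<mm_fit> Vmax = %.4g  Km = %.4g", x$Vmax, x$Km))
  if (!is.na(x$kcat)) {
    cat(sprintf("  kcat = %.4g 1/s  kcat/Km = %.4g", x$kcat, x$kcat_over_Km))
  }
  cat("\n")
  invisible(x)
}

#' Catalytic efficiency kcat/Km
#'
#' @param fit A converged [fit_mm()] result with `kcat` available.
#' @return `kcat / Km` (uM^-1 s^-1), full precision (round to the table's
#'   printed precision for comparisons).
#' @export
efficiency <- function(fit) {
  stopifnot(inherits(fit, "mm_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  if (is.na(fit$kcat)) stop("kcat unavailable: no enzyme concentration supplied")
  if (fit$Km == 0) stop("Km is zero")
  fit$kcat / fit$Km
}

#' Summarize a pH-activity profile
#'
#' Normalizes activities to percent of the maximum, reports the optimum pH
#' (argmax) and the half-maximal range: the outermost measured pH values,
#' contiguous with the optimum, at which activity is >= 50% of maximum.
#'
#' @param ph Measured pH grid (>= 3 points, increasing).
#' @param activity Activities, same length, not all zero.
#' @return List with `ph`, `activity_pct`, `optimum`, `half_max_range`
#'   (length-2 numeric).
#' @export
ph_summary <- function(ph, activity) {
  stopifnot(length(ph) == length(activity))
  if (length(ph) < 3L) stop("need >= 3 pH points")
  if (is.unsorted(ph, strictly = TRUE)) stop("'ph' must be strictly increasing")
  if (all(activity == 0)) stop("all activities are zero")
  if (any(activity < 0)) stop("activities must be >= 0")
  pct <- activity / max(activity) * 100
  iopt <- which.max(pct)
  lo <- iopt
  while (lo > 1L && pct[lo - 1L] >= 50) lo <- lo - 1L
  hi <- iopt
  while (hi < length(ph) && pct[hi + 1L] >= 50) hi <- hi + 1L
  list(ph = ph, activity_pct = pct, optimum = ph[iopt],
       half_max_range = c(ph[lo], ph[hi]))
}
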