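#' Relative fluorescence change
#'
#' \code{(F - F0) / F0}, the fractional fluorescence increase over the
#' ligand-free baseline.
#'
#' @param f Fluorescence reading(s).
#' @param f0 Baseline fluorescence at zero ligand (> 0).
#' @return Dimensionless relative fluorescence.
#' @export
relative_fluorescence <- function(f, f0) {
  if (any(f0 <= 0)) stop("F0 must be positive")
  (f - f0) / f0
}

#' Fit a Hill binding curve to a titration series
#'
#' Nonlinear least squares of \code{y = A x^n / (K_D^n + x^n)} against
#' relative-fluorescence readings y at ligand concentrations x.
#' Initialization is deterministic: \code{A = max(y)}, \code{K_D} at the
#' half-maximal concentration by linear interpolation, \code{n = 1};
#' the optimizer (Levenberg--Marquardt, \code{minpack.lm::nlsLM}) runs to
#' relative tolerance 1e-8 within 500 iterations. The Hill coefficient is
#' fitted by default; \code{fix_n = TRUE} pins it at 1 for the classic
#' one-site interpretation.
#'
#' @param concentration Ligand concentrations (ascending, same units as
#'   the returned K_D; typically uM). A leading zero-concentration point
#'   is allowed.
#' @param response Relative fluorescence at each concentration.
#' @param fix_n Fix the Hill coefficient at 1.
#' @return Object of class \code{hill_fit}: \code{K_D}, \code{hill_n},
#'   \code{amplitude}, \code{residual_norm}, \code{se} (named standard
#'   errors) and the underlying \code{nls} fit.
#' @export
fit_hill <- function(concentration, response, fix_n = FALSE) {
  x <- as.numeric(concentration)
  y <- as.numeric(response)
  if (length(x) != length(y) || length(x) < 5L) {
    stop("need >= 5 (concentration, response) points")
  }
  if (any(x < 0)) stop("concentrations must be non-negative")
  if (is.unsorted(x, strictly = TRUE)) {
    stop("concentrations must be strictly increasing")
  }
  if (all(y == 0)) stop("degenerate titration: all responses are zero")
  a0 <- max(y)
  half <- a0 / 2
  k0 <- if (any(y >= half) && any(y < half)) {
    approx(y, x, xout = half, ties = "ordered")$y
  } else {
    x[which.min(abs(y - half))]
  }
  if (!is.finite(k0) || k0 <= 0) k0 <- median(x[x > 0])
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8,
                                     maxiter = 500L)
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    if (fix_n) {
      minpack.lm::nlsLM(y ~ A * x / (K + x), data = dat,
                        start = list(A = a0, K = k0),
                        lower = c(A = 0, K = 1e-12), control = ctrl)
    } else {
      minpack.lm::nlsLM(y ~ A * x^n / (K^n + x^n), data = dat,
                        start = list(A = a0, K = k0, n = 1),
                        lower = c(A = 0, K = 1e-12, n = 0.05),
                        control = ctrl)
    },
    error = function(e) stop("Hill fit failed to converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, length(est)),
                                              names(est)))
  structure(
    list(K_D = unname(est["K"]),
         hill_n = if (fix_n) 1 else unname(est["n"]),
         amplitude = unname(est["A"]),
         residual_norm = sqrt(sum(residuals(fit)^2)),
         se = se, fit = fit),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> K_D = %.4g, n = %.3g, A = %.4g (residual norm %.3g)\n",
              x$K_D, x$hill_n, x$amplitude, x$residual_norm))
  invisible(x)
}

#' Convert observed ellipticity to mean residue ellipticity
#'
#' \code{MRE = theta_mdeg / (10 * concentration * pathlength *
#' n_residues)}, in deg cm^2 dmol^-1.
#'
#' @param theta_mdeg Observed ellipticity in millidegrees.
#' @param concentration_M Protein concentration in mol/L.
#' @param pathlength_cm Cuvette pathlength in cm.
#' @param n_residues Number of residues in the chain.
#' @return Mean residue ellipticity (deg cm^2 dmol^-1).
#' @export
mre_convert <- function(theta_mdeg, concentration_M, pathlength_cm,
                        n_residues) {
  if (any(concentration_M <= 0) || any(pathlength_cm <= 0) ||
      any(n_residues <= 0)) {
    stop("concentration, pathlength and n_residues must be positive")
  }
  theta_mdeg / (10 * concentration_M * pathlength_cm * n_residues)
}

#' Thermal reversibility of the 222 nm CD signal
#'
#' Ratio of the helix-diagnostic theta-222 signal after a heat/cool cycle
#' to its pre-heating value; 1.0 means complete recovery of the native
#' spectrum.
#'
#' @param theta222_start Signal before heating (nonzero).
#' @param theta222_end Signal after cooling back.
#' @return Recovery fraction.
#' @export
thermal_recovery <- function(theta222_start, theta222_end) {
  if (any(theta222_start == 0)) stop("starting theta-222 signal is zero")
  theta222_end / theta222_start
}
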