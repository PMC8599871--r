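#' Worm-like-chain force at a given relative extension
#'
#' Evaluates the classical worm-like-chain (Marko-Siggia) interpolation
#' formula for the tension in a semiflexible polymer held at relative
#' end-to-end extension `rel_ext` = L_e / (N_b * L_0):
#'
#'   F = (kT / L_p) * ( -1/4 + 1 / (4 (1 - x)^2) + x )
#'
#' The force is zero at x = 0, strictly increasing in x, and diverges as
#' x approaches 1.
#'
#' @param rel_ext Relative extension(s), dimensionless, in \[0, 1).
#' @param phase A [phase_params()] object supplying the persistence length.
#' @param kT Thermal energy in pN nm (default 4.28).
#' @return Force(s) in pN, same length as `rel_ext`.
#' @examples
#' wlc_force(0.5, phase_params(50, 0.34))  # 0.107 pN
#' @seealso [wlc_extension()] for the numerical inverse.
#' @export
wlc_force <- function(rel_ext, phase, kT = 4.28) {
  .check_phase(phase)
  .check_kT(kT)
  bad <- !is.finite(rel_ext) | rel_ext < 0 | rel_ext >= 1
  if (any(bad)) {
    stop("relative extension must lie in [0, 1); offending value(s): ",
         paste(format(rel_ext[bad]), collapse = ", "), call. = FALSE)
  }
  (kT / phase$persistence_length) *
    (-0.25 + 1 / (4 * (1 - rel_ext)^2) + rel_ext)
}

# Solve the WLC interpolation formula for the relative extension at a given
# force: Brent bracketing on x in [0, 1 - 1e-9] followed by Newton polish.
# The left-hand side is strictly monotone, so the root is unique.
.wlc_rel_ext <- function(force, L_p, kT) {
  target <- force * L_p / kT
  g <- function(x) -0.25 + 1 / (4 * (1 - x)^2) + x - target
  upper <- 1 - 1e-9
  if (g(upper) <= 0) return(upper)
  x <- stats::uniroot(g, c(0, upper), tol = 1e-12)$root
  for (i in 1:3) {
    gp <- 1 / (2 * (1 - x)^3) + 1
    x <- x - g(x) / gp
    if (x < 0) x <- 0
    if (x > upper) x <- upper
  }
  x
}

#' Worm-like-chain extension at a given force
#'
#' Numerical inverse of [wlc_force()]: returns the equilibrium end-to-end
#' extension L_e = N_b * L_0 * x, where x solves the WLC interpolation
#' formula at the supplied tension.  The root is found by Brent bracketing on
#' x in \[0, 1 - 1e-9\] (the monotonicity of the formula guarantees
#' convergence) and polished with Newton steps, so the round trip
#' `wlc_force(x)` reproduces the input force to better than 1e-10 relative.
#'
#' @param force Applied force(s) in pN; must be positive (the model is used
#'   only under tension).
#' @param phase A [phase_params()] object.
#' @param tether A [tether_spec()] giving the number of base pairs.
#' @param kT Thermal energy in pN nm (default 4.28).
#' @return Extension(s) in nm.
#' @examples
#' wlc_extension(1.1, phase_params(50, 0.34), tether_spec(4642))
#' @export
wlc_extension <- function(force, phase, tether, kT = 4.28) {
  .check_phase(phase)
  .check_tether(tether)
  .check_kT(kT)
  bad <- !is.finite(force) | force <= 0
  if (any(bad)) {
    stop("`force` must be positive (pN); offending value(s): ",
         paste(format(force[bad]), collapse = ", "), call. = FALSE)
  }
  x <- vapply(force, .wlc_rel_ext, numeric(1),
              L_p = phase$persistence_length, kT = kT)
  tether$n_bp * phase$rise_per_bp * x
}

#' Convert imposed turns to supercoiling density
#'
#' The supercoiling density is the number of imposed turns normalised by the
#' natural helical turns of the relaxed tether: sigma = n_t / (N_b / 10.4).
#'
#' @param n_t Imposed turns (signed; negative = unwinding).
#' @param tether A [tether_spec()].
#' @return Supercoiling density (dimensionless), sign preserved.
#' @examples
#' sigma_from_turns(-800, tether_spec(4642))  # about -1.79
#' @export
sigma_from_turns <- function(n_t, tether) {
  .check_tether(tether)
  n_t * tether$bp_per_turn / tether$n_bp
}

#' Convert supercoiling density to imposed turns
#'
#' Exact inverse of [sigma_from_turns()]: n_t = sigma * (N_b / 10.4).
#'
#' @param sigma Supercoiling density (dimensionless).
#' @param tether A [tether_spec()].
#' @return Turns (real-valued).
#' @examples
#' turns_from_sigma(-1.8, tether_spec(4642))  # about -803.4
#' @export
turns_from_sigma <- function(sigma, tether) {
  .check_tether(tether)
  sigma * tether$n_bp / tether$bp_per_turn
}

#' Fit the worm-like chain to a force-extension curve
#'
#' Least-squares estimation of the contour length L_C and persistence length
#' L_p from a table of (force, extension) measurements at zero imposed turns,
#' the standard characterisation of a magnetic-tweezers tether.  The fit is
#' performed in extension space - for each trial (L_C, L_p) the WLC relation
#' is inverted per point and the squared extension residuals are minimised by
#' Levenberg-Marquardt - matching how tweezers data are collected (extension
#' is the measured, noisy quantity).
#'
#' @param force Applied forces in pN.  At least 4 distinct values spanning at
#'   least a factor of 3 are required.
#' @param extension Measured extensions in nm, same length as `force`.
#' @param kT Thermal energy in pN nm (default 4.28).
#' @param start Optional numeric vector `c(L_C, L_p)` of starting values;
#'   defaults to `c(max(extension) / 0.95, 50)`.
#' @return An object of class `"wlc_fit"` with components `coefficients`
#'   (named `contour_length`, `persistence_length`, in nm), `stderr`
#'   (standard errors from the Jacobian), `residual_norm` (nm), `fitted`,
#'   `residuals`, `data`, and `kT`.
#' @examples
#' teth <- tether_spec(6258)
#' B <- phase_params(48.2, 0.34)
#' f <- c(0.25, 0.5, 1, 2, 4, 8)
#' e <- wlc_extension(f, B, teth)
#' fit <- fit_wlc(f, e)
#' coef(fit)
#' @export
fit_wlc <- function(force, extension, kT = 4.28, start = NULL) {
  .check_kT(kT)
  if (length(force) != length(extension)) {
    stop("`force` and `extension` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(force)) || any(force <= 0)) {
    stop("all forces must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(extension)) || any(extension < 0)) {
    stop("all extensions must be finite and non-negative", call. = FALSE)
  }
  if (length(unique(force)) < 4L) {
    stop("need at least 4 distinct force points to fit the WLC (got ",
         length(unique(force)), ")", call. = FALSE)
  }
  if (max(force) / min(force) < 3) {
    stop("forces must span at least a factor of 3 (span: ",
         format(max(force) / min(force), digits = 3), ")", call. = FALSE)
  }
  if (is.null(start)) start <- c(max(extension) / 0.95, 50)
  start <- as.numeric(start)
  resid_fun <- function(par) {
    x <- vapply(force, .wlc_rel_ext, numeric(1), L_p = par[2], kT = kT)
    extension - par[1] * x
  }
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fun,
    lower = c(1e-6, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  if (!(fit$info %in% 1:4)) {
    stop("WLC fit did not converge (", fit$message, "); best-so-far: L_C = ",
         format(fit$par[1]), " nm, L_p = ", format(fit$par[2]), " nm",
         call. = FALSE)
  }
  n <- length(force)
  dof <- n - 2L
  sigma2 <- fit$deviance / max(dof, 1L)
  covmat <- tryCatch(solve(fit$hessian) * sigma2,
                     error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(covmat), 0))
  res <- resid_fun(fit$par)
  est <- c(contour_length = fit$par[1], persistence_length = fit$par[2])
  structure(list(coefficients = est,
                 stderr = stats::setNames(se, names(est)),
                 residual_norm = sqrt(fit$deviance),
                 fitted = extension - res,
                 residuals = res,
                 data = data.frame(force_pN = force, extension_nm = extension),
                 kT = kT,
                 info = fit$info,
                 niter = fit$niter),
            class = "wlc_fit")
}

#' @export
print.wlc_fit <- function(x, ...) {
  cat("Worm-like-chain fit (extension vs force)\n")
  cat(sprintf("  contour length     L_C = %.6g nm (se %.3g)\n",
              x$coefficients[1], x$stderr[1]))
  cat(sprintf("  persistence length L_p = %.6g nm (se %.3g)\n",
              x$coefficients[2], x$stderr[2]))
  cat(sprintf("  residual norm: %.4g nm over %d points\n",
              x$residual_norm, nrow(x$data)))
  invisible(x)
}

#' @export
coef.wlc_fit <- function(object, ...) object$coefficients

#' @export
summary.wlc_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$stderr)
  structure(list(coefficients = tab,
                 residual_norm = object$residual_norm,
                 n = nrow(object$data), kT = object$kT),
            class = "summary.wlc_fit")
}

#' @export
print.summary.wlc_fit <- function(x, ...) {
  cat("Worm-like-chain fit summary\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("kT = %g pN nm; residual norm %.4g nm over %d points\n",
              x$kT, x$residual_norm, x$n))
  invisible(x)
}

#' @export
residuals.wlc_fit <- function(object, ...) object$residuals

#' Predicted WLC extensions from a fitted model
#'
#' @param object A `"wlc_fit"` object.
#' @param newdata Optional data frame with a `force_pN` column (or a numeric
#'   vector of forces); defaults to the fitted data.
#' @param ... Unused.
#' @return Predicted extensions in nm.
#' @export
predict.wlc_fit <- function(object, newdata = NULL, ...) {
  f <- if (is.null(newdata)) {
    object$data$force_pN
  } else if (is.data.frame(newdata)) {
    newdata$force_pN
  } else {
    as.numeric(newdata)
  }
  if (is.null(f)) stop("`newdata` must supply a `force_pN` column",
                       call. = FALSE)
  x <- vapply(f, .wlc_rel_ext, numeric(1),
              L_p = object$coefficients[["persistence_length"]],
              kT = object$kT)
  object$coefficients[["contour_length"]] * x
}

#' @export
plot.wlc_fit <- function(x, ...) {
  d <- x$data[order(x$data$force_pN), ]
  graphics::plot(d$force_pN, d$extension_nm, log = "x",
                 xlab = "force (pN)", ylab = "extension (nm)",
                 main = "WLC force-extension fit", ...)
  fgrid <- exp(seq(log(min(d$force_pN)), log(max(d$force_pN)),
                   length.out = 200))
  graphics::lines(fgrid, predict(x, fgrid), col = "firebrick")
  invisible(x)
}
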