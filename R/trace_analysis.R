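# Exact least-squares SSE of a straight-line fit on index range [a, b]
# (vectorised over candidate ranges) from padded prefix sums.
.seg_sse <- function(a, b, CX, CY, CXX, CXY, CYY) {
  n <- b - a + 1
  sx <- CX[b + 1] - CX[a]
  sy <- CY[b + 1] - CY[a]
  sxx <- CXX[b + 1] - CXX[a]
  sxy <- CXY[b + 1] - CXY[a]
  syy <- CYY[b + 1] - CYY[a]
  sxx_c <- sxx - sx * sx / n
  sxy_c <- sxy - sx * sy / n
  syy_c <- syy - sy * sy / n
  sse <- syy_c - ifelse(sxx_c > 0, sxy_c * sxy_c / sxx_c, 0)
  pmax(sse, 0)
}

# Ordinary least-squares line fit on a point subset; returns slope, its
# standard error, and bookkeeping for a SlopeEstimate row.
.line_fit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  se <- if (n > 2) sqrt(sum(res^2) / (n - 2) / sxx) else NA_real_
  list(slope = slope, intercept = intercept, stderr = se,
       sse = sum(res^2), n = n)
}

#' Segment an extension-versus-turns trace into three linear regimes
#'
#' Fits the canonical three-regime structure of a twist trace - L
#' plectonemic at the most negative turns, mixed BL in between, B (or B
#' plectonemic) at the least negative turns - by exhaustive search over
#' ordered breakpoint pairs on the observed turn values.  For every
#' candidate pair three independent least-squares lines are fitted (via
#' exact prefix-sum algebra, so the search over all O(n^2) candidates is
#' cheap) and the global sum-of-squared-errors minimiser is returned.  Ties
#' are broken in favour of the candidate with the longest middle (BL)
#' segment, then the smaller first breakpoint.
#'
#' Final per-segment slopes are re-fitted after excluding the innermost
#' `trim_frac` of points adjacent to each breakpoint, which reduces the bias
#' from junction curvature in real (noisy) traces; the SSE search itself
#' uses all points.
#'
#' @param trace A data frame for a single trace with columns `n_turns`,
#'   `extension_nm` and (optionally) `force_pN`, `trace_id`.
#' @param window Optional length-2 turn range restricting the fit.
#' @param min_seg Minimum points per provisional segment (default 4);
#'   candidates violating it are skipped.
#' @param trim_frac Fraction of each segment's points excluded next to each
#'   breakpoint when fitting the reported slopes (default 0.1).
#' @param grid_stride Evaluate only every `grid_stride`-th breakpoint
#'   candidate (default 1, the exhaustive search; coarser grids can only
#'   raise the attained SSE).
#' @return An object of class `"bl_segmentation"`: `breakpoints` (named turn
#'   values `L_BL`, `BL_B`), `sse`, `slopes` (one row per regime with
#'   `regime`, `slope`, `stderr`, `force`, `n_points`, `turn_min`,
#'   `turn_max`), and `single_regime_suspected`.
#' @examples
#' cfg <- bl_config(phase_L = phase_params(3.8, 0.34 * 1.4))
#' tr <- gen_twist_trace(2.3, c(-880, 60), cfg, noise_sd = 0, by = 5)
#' segment_trace(tr)
#' @export
segment_trace <- function(trace, window = NULL, min_seg = 4,
                          trim_frac = 0.1, grid_stride = 1) {
  if (!is.data.frame(trace) ||
      !all(c("n_turns", "extension_nm") %in% names(trace))) {
    stop("`trace` must be a data frame with columns n_turns, extension_nm",
         call. = FALSE)
  }
  if ("trace_id" %in% names(trace) &&
      length(unique(trace$trace_id)) > 1L) {
    stop("`trace` must contain a single trace; got ",
         length(unique(trace$trace_id)), " trace_ids", call. = FALSE)
  }
  if (!is.null(window)) {
    keep <- trace$n_turns >= min(window) & trace$n_turns <= max(window)
    trace <- trace[keep, , drop = FALSE]
  }
  ord <- order(trace$n_turns)
  x <- as.numeric(trace$n_turns[ord])
  y <- as.numeric(trace$extension_nm[ord])
  n <- length(x)
  if (n < 12L) {
    stop("segmentation needs at least 12 points spanning the window (got ",
         n, ")", call. = FALSE)
  }
  if (n < 3L * min_seg) {
    stop("segmentation error: no candidate breakpoint pair leaves ",
         min_seg, " points per segment (only ", n, " points)", call. = FALSE)
  }
  CX <- c(0, cumsum(x)); CY <- c(0, cumsum(y))
  CXX <- c(0, cumsum(x * x)); CXY <- c(0, cumsum(x * y))
  CYY <- c(0, cumsum(y * y))
  i_vals <- seq.int(min_seg, n - 2L * min_seg, by = grid_stride)
  cand_i <- list(); cand_j <- list()
  for (k in seq_along(i_vals)) {
    jk <- seq.int(i_vals[k] + min_seg, n - min_seg, by = grid_stride)
    cand_i[[k]] <- rep.int(i_vals[k], length(jk))
    cand_j[[k]] <- jk
  }
  I <- unlist(cand_i); J <- unlist(cand_j)
  if (length(I) == 0L) {
    stop("segmentation error: empty breakpoint candidate set", call. = FALSE)
  }
  sse_tot <- .seg_sse(1L, I, CX, CY, CXX, CXY, CYY) +
    .seg_sse(I + 1L, J, CX, CY, CXX, CXY, CYY) +
    .seg_sse(J + 1L, n, CX, CY, CXX, CXY, CYY)
  sse_min <- min(sse_tot)
  tol <- 1e-9 * (1 + sse_min)
  tied <- which(sse_tot <= sse_min + tol)
  mid_len <- J[tied] - I[tied]
  tied <- tied[mid_len == max(mid_len)]
  best <- tied[which.min(x[I[tied]])]
  ib <- I[best]; jb <- J[best]

  # single-regime diagnostic: three segments barely beat one line
  sse_one <- .seg_sse(1L, n, CX, CY, CXX, CXY, CYY)
  single <- (sse_one - sse_min) <= 0.01 * sse_one

  force <- if ("force_pN" %in% names(trace)) trace$force_pN[1] else NA_real_
  seg_idx <- list(L = seq_len(ib),
                  BL = seq.int(ib + 1L, jb),
                  B = seq.int(jb + 1L, n))
  rows <- lapply(names(seg_idx), function(reg) {
    idx <- seg_idx[[reg]]
    k <- floor(trim_frac * length(idx))
    # trim only the end(s) that touch a breakpoint, keep >= 3 points
    while (k > 0 && length(idx) - k * (1 + (reg == "BL")) < 3) k <- k - 1
    use <- switch(reg,
                  L = idx[seq_len(length(idx) - k)],
                  BL = idx[seq.int(1L + k, length(idx) - k)],
                  B = idx[seq.int(1L + k, length(idx))])
    fit <- .line_fit(x[use], y[use])
    data.frame(regime = reg, slope = fit$slope, stderr = fit$stderr,
               force = force, n_points = fit$n,
               turn_min = min(x[use]), turn_max = max(x[use]),
               stringsAsFactors = FALSE)
  })
  structure(list(
    breakpoints = c(L_BL = (x[ib] + x[ib + 1]) / 2,
                    BL_B = (x[jb] + x[jb + 1]) / 2),
    sse = sse_min,
    slopes = do.call(rbind, rows),
    single_regime_suspected = single,
    n_points = n),
    class = "bl_segmentation")
}

#' @export
print.bl_segmentation <- function(x, ...) {
  cat(sprintf("Three-regime segmentation (%d points, SSE %.4g nm^2)\n",
              x$n_points, x$sse))
  cat(sprintf("  breakpoints: L|BL at %.1f turns, BL|B at %.1f turns\n",
              x$breakpoints[["L_BL"]], x$breakpoints[["BL_B"]]))
  print(x$slopes, row.names = FALSE)
  if (isTRUE(x$single_regime_suspected)) {
    cat("  note: single-regime suspected (3-segment fit barely improves on a line)\n")
  }
  invisible(x)
}

#' Per-force regime slopes across a collection of traces
#'
#' Applies [segment_trace()] to every trace in a stacked trace table (or
#' fits a single line inside a fixed turn `window` when one is supplied) and
#' collects the slope of the requested regime, one row per trace.  Traces in
#' which the regime cannot be estimated are skipped with a warning, not an
#' error.  B-regime slopes are additionally reported as absolute values
#' (`abs_slope`), the convention for plectonemic slope-versus-force plots.
#'
#' @param traces A data frame of stacked traces (columns `trace_id`,
#'   `force_pN`, `n_turns`, `extension_nm`).
#' @param regime One of `"BL"`, `"B"`, `"L"`.
#' @param window Optional length-2 turn range; when given, a single line is
#'   fitted to the points inside it (no segmentation) and labelled with
#'   `regime`.
#' @param ... Passed on to [segment_trace()].
#' @return A data frame with columns `trace_id`, `force`, `regime`, `slope`,
#'   `abs_slope`, `stderr`, `n_points`, `turn_min`, `turn_max`.
#' @export
slope_vs_force <- function(traces, regime = c("BL", "B", "L"),
                           window = NULL, ...) {
  regime <- match.arg(regime)
  need <- c("trace_id", "force_pN", "n_turns", "extension_nm")
  if (!is.data.frame(traces) || !all(need %in% names(traces))) {
    stop("`traces` must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (id in unique(traces$trace_id)) {
    tr <- traces[traces$trace_id == id, , drop = FALSE]
    row <- NULL
    if (!is.null(window)) {
      keep <- tr$n_turns >= min(window) & tr$n_turns <= max(window)
      if (sum(keep) >= 3) {
        fit <- .line_fit(as.numeric(tr$n_turns[keep]),
                         as.numeric(tr$extension_nm[keep]))
        row <- data.frame(trace_id = id, force = tr$force_pN[1],
                          regime = regime, slope = fit$slope,
                          stderr = fit$stderr, n_points = fit$n,
                          turn_min = min(tr$n_turns[keep]),
                          turn_max = max(tr$n_turns[keep]),
                          stringsAsFactors = FALSE)
      }
    } else {
      seg <- tryCatch(segment_trace(tr, ...), error = function(e) NULL)
      if (!is.null(seg)) {
        r <- seg$slopes[seg$slopes$regime == regime, , drop = FALSE]
        if (nrow(r) == 1L) {
          row <- data.frame(trace_id = id, force = r$force, regime = regime,
                            slope = r$slope, stderr = r$stderr,
                            n_points = r$n_points, turn_min = r$turn_min,
                            turn_max = r$turn_max, stringsAsFactors = FALSE)
        }
      }
    }
    if (is.null(row)) {
      warning("trace ", id, ": ", regime,
              " regime could not be estimated; trace skipped", call. = FALSE)
    } else {
      out[[length(out) + 1L]] <- row
    }
  }
  if (length(out) == 0L) {
    return(data.frame(trace_id = character(), force = numeric(),
                      regime = character(), slope = numeric(),
                      abs_slope = numeric(), stderr = numeric(),
                      n_points = integer(), turn_min = numeric(),
                      turn_max = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$abs_slope <- abs(res$slope)
  res[, c("trace_id", "force", "regime", "slope", "abs_slope", "stderr",
          "n_points", "turn_min", "turn_max")]
}

# interpolate the zero crossing of mean slope vs force; NA when no crossing
.interp_crossing <- function(force, slope) {
  o <- order(force)
  f <- force[o]; s <- slope[o]
  for (k in seq_len(length(f) - 1)) {
    if (s[k] == 0) return(f[k])
    if (s[k] > 0 && s[k + 1] <= 0) {
      return(f[k] + s[k] * (f[k + 1] - f[k]) / (s[k] - s[k + 1]))
    }
  }
  if (s[length(s)] == 0) return(f[length(f)])
  NA_real_
}

#' Estimate the inversion force from BL-regime slopes
#'
#' The inversion force F* is the tension at which the BL slope of extension
#' versus turns crosses zero.  Slopes are averaged per force, and F* is
#' obtained by linear interpolation of mean slope versus force across the
#' sign change (positive below, negative above).  The confidence interval is
#' computed by resampling whole traces with replacement within each force
#' (respecting within-trace correlation) and taking percentiles of the
#' re-interpolated crossing.
#'
#' @param slopes A data frame of BL-regime slope estimates (from
#'   [slope_vs_force()]) with columns `force`, `slope` and, for the
#'   bootstrap, `trace_id`.
#' @param n_boot Number of bootstrap replicates (default 1999; 0 skips the
#'   bootstrap and returns the point estimate for both CI bounds).
#' @param seed Optional integer seed for the bootstrap.
#' @param level Confidence level (default 0.95).
#' @return An object of class `"fstar_estimate"`: `f_star`, `ci_low`,
#'   `ci_high` (pN), `method`, `n_boot`.
#' @export
estimate_f_star <- function(slopes, n_boot = 1999, seed = NULL,
                            level = 0.95) {
  if (!is.data.frame(slopes) ||
      !all(c("force", "slope") %in% names(slopes))) {
    stop("`slopes` must be a data frame with columns force, slope",
         call. = FALSE)
  }
  if (nrow(slopes) < 2L || length(unique(slopes$force)) < 2L) {
    stop("need BL slopes at >= 2 distinct forces", call. = FALSE)
  }
  mean_by_force <- tapply(slopes$slope, slopes$force, mean)
  f <- as.numeric(names(mean_by_force))
  s <- as.numeric(mean_by_force)
  if (all(s > 0) || all(s < 0)) {
    stop("no sign change in BL slopes across forces (slope range [",
         format(min(s), digits = 4), ", ", format(max(s), digits = 4),
         "] nm/turn); the inversion force is not bracketed", call. = FALSE)
  }
  f_star <- .interp_crossing(f, s)
  if (is.na(f_star)) {
    stop("no downward zero crossing of BL slope versus force found",
         call. = FALSE)
  }
  ci <- c(f_star, f_star)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    by_force <- split(slopes$slope, slopes$force)
    boots <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      sb <- vapply(by_force, function(v) {
        mean(v[sample.int(length(v), replace = TRUE)])
      }, numeric(1))
      boots[b] <- .interp_crossing(f, as.numeric(sb))
    }
    boots <- boots[!is.na(boots)]
    if (length(boots) >= 10) {
      alpha <- (1 - level) / 2
      ci <- as.numeric(stats::quantile(boots, c(alpha, 1 - alpha)))
    }
  }
  structure(list(f_star = f_star,
                 ci_low = min(ci[1], f_star), ci_high = max(ci[2], f_star),
                 method = sprintf(
                   "slope-vs-force zero-crossing interpolation; trace bootstrap (%d replicates)",
                   n_boot),
                 n_boot = n_boot, forces = f, mean_slopes = s),
            class = "fstar_estimate")
}

#' @export
print.fstar_estimate <- function(x, ...) {
  cat(sprintf("Inversion force estimate: F* = %.4g pN [%.4g, %.4g]\n",
              x$f_star, x$ci_low, x$ci_high))
  cat("  method:", x$method, "\n")
  invisible(x)
}

#' Fit the two-phase B-to-L transition model to twist traces
#'
#' The umbrella estimator of the package: from a collection of
#' extension-versus-turns traces at several forces it (i) extracts the
#' BL-regime slope of every trace (by three-regime segmentation, or a fixed
#' turn window if supplied), (ii) locates the inversion force F* where the
#' slope crosses zero, with a trace-level bootstrap confidence interval, and
#' (iii) inverts the two-phase worm-like-chain balance at F*, at a fixed
#' contour ratio, for the persistence length of the L-form.
#'
#' @param traces Stacked trace data frame (columns `trace_id`, `force_pN`,
#'   `n_turns`, `extension_nm`).
#' @param phase_B B-form mechanical parameters (default
#'   `phase_params(50, 0.34)`).
#' @param tether A [tether_spec()] (default 4642 bp); used by the regime
#'   bookkeeping and the predict/simulate methods.
#' @param kT Thermal energy in pN nm (default 4.28).
#' @param ratio_L0 Contour ratio L_0L / L_0B fixed during the inversion
#'   (default 1.4, the backbone-conservation value).
#' @param sigma_max,n_b_max Topology thresholds, as in [bl_config()].
#' @param window Optional fixed turn window for the BL slope fits; `NULL`
#'   (default) segments each trace.
#' @param n_boot Bootstrap replicates for the F* confidence interval
#'   (default 1999; 0 to skip).
#' @param seed Optional seed for the bootstrap.
#' @param ... Passed on to [segment_trace()].
#' @return An object of class `"bl_fit"` with components `slopes`,
#'   `fstar` (an `"fstar_estimate"`), `lpl` (nm), `lpl_ci`, `ratio_L0`, and
#'   `config` (a [bl_config()] with the inferred L phase), supporting
#'   `print`, `summary`, `coef`, `predict`, `plot`, `residuals` and
#'   `simulate` methods.
#' @examples
#' cfg <- bl_config(phase_L = phase_params(3.8, 0.34 * 1.4))
#' traces <- gen_trace_family(seq(1, 4, by = 0.5), reps = 2, config = cfg,
#'                            noise_sd = 0, seed = 1, by = 10)
#' fit <- fit_bl_transition(traces, n_boot = 0)
#' coef(fit)
#' @export
fit_bl_transition <- function(traces, phase_B = phase_params(50, 0.34),
                              tether = tether_spec(4642), kT = 4.28,
                              ratio_L0 = 1.4, sigma_max = -1.8, n_b_max = 0,
                              window = NULL, n_boot = 1999, seed = NULL,
                              ...) {
  slopes <- slope_vs_force(traces, regime = "BL", window = window, ...)
  if (nrow(slopes) == 0L) {
    stop("no usable BL slopes could be extracted from `traces`",
         call. = FALSE)
  }
  fstar <- estimate_f_star(slopes, n_boot = n_boot, seed = seed)
  ref_cfg <- bl_config(phase_B = phase_B,
                       phase_L = phase_params(1, ratio_L0 *
                                                phase_B$rise_per_bp),
                       tether = tether, kT = kT, sigma_max = sigma_max,
                       n_b_max = n_b_max)
  lpl <- lpl_from_inversion(fstar$f_star, ratio_L0, ref_cfg)
  # F* -> L_pL is monotone decreasing, so CI bounds swap
  lpl_ci <- tryCatch(
    sort(c(lpl_from_inversion(fstar$ci_high, ratio_L0, ref_cfg),
           lpl_from_inversion(fstar$ci_low, ratio_L0, ref_cfg))),
    error = function(e) c(NA_real_, NA_real_))
  config <- bl_config(phase_B = phase_B,
                      phase_L = phase_params(lpl,
                                             ratio_L0 * phase_B$rise_per_bp),
                      tether = tether, kT = kT, sigma_max = sigma_max,
                      n_b_max = n_b_max)
  structure(list(call = match.call(), slopes = slopes, fstar = fstar,
                 lpl = lpl, lpl_ci = lpl_ci, ratio_L0 = ratio_L0,
                 config = config, window = window),
            class = "bl_fit")
}

#' @export
print.bl_fit <- function(x, ...) {
  cat("Two-phase B-to-L transition fit\n")
  cat(sprintf("  inversion force F*      = %.4g pN [%.4g, %.4g]\n",
              x$fstar$f_star, x$fstar$ci_low, x$fstar$ci_high))
  cat(sprintf("  L-form persistence L_pL = %.4g nm [%.4g, %.4g]  (ratio L_0L/L_0B fixed at %g)\n",
              x$lpl, x$lpl_ci[1], x$lpl_ci[2], x$ratio_L0))
  cat(sprintf("  %d BL slopes across %d forces\n",
              nrow(x$slopes), length(unique(x$slopes$force))))
  invisible(x)
}

#' @export
coef.bl_fit <- function(object, ...) {
  c(f_star = object$fstar$f_star, L_pL = object$lpl)
}

#' @export
summary.bl_fit <- function(object, ...) {
  agg <- stats::aggregate(slope ~ force, data = object$slopes,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  tab <- data.frame(force = agg$force,
                    mean_slope = agg$slope[, "mean"],
                    sd_slope = agg$slope[, "sd"],
                    n_traces = agg$slope[, "n"])
  structure(list(fit = object, slope_table = tab), class = "summary.bl_fit")
}

#' @export
print.summary.bl_fit <- function(x, ...) {
  print(x$fit)
  cat("\nMean BL slope by force (nm/turn):\n")
  print(x$slope_table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predicted mixed-phase extensions from a fitted B-to-L model
#'
#' @param object A `"bl_fit"` object.
#' @param newdata Data frame with columns `force_pN` and `n_turns`.
#' @param ... Unused.
#' @return Predicted extensions in nm.
#' @export
predict.bl_fit <- function(object, newdata, ...) {
  if (missing(newdata) || !is.data.frame(newdata) ||
      !all(c("force_pN", "n_turns") %in% names(newdata))) {
    stop("`newdata` must be a data frame with columns force_pN, n_turns",
         call. = FALSE)
  }
  out <- numeric(nrow(newdata))
  for (f in unique(newdata$force_pN)) {
    idx <- newdata$force_pN == f
    out[idx] <- mixed_extension(f, newdata$n_turns[idx], object$config)
  }
  out
}

#' @export
residuals.bl_fit <- function(object, ...) {
  object$slopes$slope - bl_slope(object$slopes$force, object$config)
}

#' @export
plot.bl_fit <- function(x, ...) {
  agg <- stats::aggregate(slope ~ force, data = x$slopes, FUN = mean)
  graphics::plot(agg$force, agg$slope, pch = 16,
                 xlab = "force (pN)", ylab = "BL slope (nm/turn)",
                 main = "BL slope vs force", ...)
  fgrid <- seq(min(agg$force), max(agg$force), length.out = 100)
  graphics::lines(fgrid, bl_slope(fgrid, x$config), col = "grey50")
  graphics::abline(h = 0, lty = 2)
  graphics::points(x$fstar$f_star, 0, pch = 8, cex = 1.6, col = "firebrick")
  invisible(x)
}

#' Simulate trace families from a fitted B-to-L model
#'
#' @param object A `"bl_fit"` object.
#' @param nsim Number of simulated families (default 1).
#' @param seed Optional integer seed.
#' @param forces Forces at which to simulate (default: the fitted forces).
#' @param reps Traces per force (default 3).
#' @param n_t_range Turn range (default `c(-880, 60)`).
#' @param noise_sd Axial noise sd in nm (default 10).
#' @param by Turn step (default 1).
#' @param ... Unused.
#' @return A list of `nsim` stacked trace data frames.
#' @export
simulate.bl_fit <- function(object, nsim = 1, seed = NULL,
                            forces = NULL, reps = 3,
                            n_t_range = c(-880, 60), noise_sd = 10, by = 1,
                            ...) {
  if (is.null(forces)) forces <- sort(unique(object$slopes$force))
  if (is.null(seed)) seed <- 1L
  lapply(seq_len(nsim), function(k) {
    gen_trace_family(forces, reps = reps, n_t_range = n_t_range,
                     config = object$config, noise_sd = noise_sd,
                     seed = seed + k - 1L, by = by)
  })
}
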