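test_that("segmentation of a noise-free three-regime trace recovers the true breakpoints", {
  cfg <- wt_config()
  n_t_max <- turns_from_sigma(cfg$sigma_max, cfg$tether)
  tr <- gen_twist_trace(2.3, c(-880, 60), cfg, noise_sd = 0, by = 1)
  seg <- segment_trace(tr)
  expect_lt(abs(seg$breakpoints[["L_BL"]] - n_t_max), 2)
  expect_lt(abs(seg$breakpoints[["BL_B"]] - cfg$n_b_max), 2)
  expect_false(seg$single_regime_suspected)
  bl <- seg$slopes[seg$slopes$regime == "BL", ]
  expect_equal(bl$slope, bl_slope(2.3, cfg), tolerance = 1e-6)
  expect_true(all(seg$slopes$n_points >= 3))
  expect_true(all(seg$slopes$turn_min >= min(tr$n_turns) &
                    seg$slopes$turn_max <= max(tr$n_turns)))
})

test_that("BL slopes from noisy traces agree with the model within uncertainty", {
  cfg <- wt_config()
  for (f in c(1.2, 3.1)) {
    tr <- gen_twist_trace(f, c(-880, 60), cfg, noise_sd = 10, seed = 101,
                          by = 2)
    seg <- segment_trace(tr)
    bl <- seg$slopes[seg$slopes$regime == "BL", ]
    expect_lt(abs(bl$slope - bl_slope(f, cfg)), 2 * bl$stderr + 1e-12)
  }
})

test_that("a purely linear trace is flagged as single-regime", {
  x <- seq(-400, -100, by = 10)
  tr <- data.frame(trace_id = "lin", dna_label = "WT", force_pN = 2,
                   n_turns = x, extension_nm = 1000 + 0.5 * x, clipped = 0)
  seg <- segment_trace(tr)
  expect_true(seg$single_regime_suspected)
  # tie-break: middle segment as long as the candidate grid allows
  expect_equal(unname(diff(seg$breakpoints)),
               max(x) - min(x) - 2 * 4 * 10 + 10, tolerance = 11)
})

test_that("segmentation SSE never improves when the candidate grid is coarsened", {
  cfg <- wt_config()
  tr <- gen_twist_trace(2.0, c(-880, 60), cfg, noise_sd = 10, seed = 21,
                        by = 4)
  full <- segment_trace(tr)
  for (stride in c(2, 5)) {
    coarse <- segment_trace(tr, grid_stride = stride)
    expect_gte(coarse$sse, full$sse - 1e-9)
  }
})

test_that("slope_vs_force collects per-force regime slopes and skips empty regimes", {
  cfg <- wt_config()
  forces <- c(1.5, 2.5, 3.5)
  traces <- do.call(rbind, lapply(forces, function(f) {
    gen_twist_trace(f, c(-880, 60), cfg, noise_sd = 0, by = 4,
                    trace_id = sprintf("F%g", f))
  }))
  sl <- slope_vs_force(traces, "BL")
  expect_equal(nrow(sl), 3)
  expect_equal(sl$slope, bl_slope(forces, cfg), tolerance = 1e-6)
  # fixed window route matches the model exactly on noise-free data
  slw <- slope_vs_force(traces, "BL", window = c(-700, -100))
  expect_equal(slw$slope, bl_slope(forces, cfg), tolerance = 1e-8)
  # B slopes are reported as magnitudes too
  sb <- slope_vs_force(traces, "B")
  expect_true(all(sb$abs_slope >= 0))
  expect_equal(sb$abs_slope, abs(sb$slope), tolerance = 1e-12)
  # a trace with no fittable window in the regime is skipped with a warning
  short <- traces[traces$trace_id == "F1.5" & traces$n_turns > -50, ]
  expect_warning(out <- slope_vs_force(short, "BL", window = c(-700, -600)),
                 "skipped")
  expect_equal(nrow(out), 0)
})

test_that("the inversion force is recovered from noise-free slope-vs-force families", {
  forces <- seq(1, 4, by = 0.25)
  for (cfg in list(wt_config(), dap_config())) {
    traces <- do.call(rbind, lapply(forces, function(f) {
      gen_twist_trace(f, c(-700, -100), cfg, noise_sd = 0, by = 5,
                      trace_id = sprintf("F%g", f))
    }))
    sl <- slope_vs_force(traces, "BL", window = c(-700, -100))
    fs <- estimate_f_star(sl, n_boot = 0)
    truth <- inversion_force(cfg)$f_star
    expect_lt(abs(fs$f_star - truth), 0.25)  # within one force-grid step
  }
  # all-positive slopes cannot bracket a crossing
  pos <- data.frame(trace_id = "a", force = c(1, 2, 3),
                    slope = c(0.3, 0.2, 0.1))
  expect_error(estimate_f_star(pos), "no sign change")
})

test_that("the bootstrap CI brackets the point estimate and is seed-stable", {
  cfg <- wt_config()
  traces <- gen_trace_family(seq(1, 4, length.out = 7), reps = 3,
                             config = cfg, noise_sd = 10, seed = 9, by = 4)
  sl <- slope_vs_force(traces, "BL")
  a <- estimate_f_star(sl, n_boot = 199, seed = 1)
  b <- estimate_f_star(sl, n_boot = 199, seed = 1)
  expect_identical(a$f_star, b$f_star)
  expect_identical(c(a$ci_low, a$ci_high), c(b$ci_low, b$ci_high))
  expect_lte(a$ci_low, a$f_star)
  expect_gte(a$ci_high, a$f_star)
})

test_that("fit_bl_transition recovers generating parameters and supports the model methods", {
  cfg <- wt_config()
  traces <- gen_trace_family(seq(1, 4, length.out = 9), reps = 3,
                             config = cfg, noise_sd = 10, seed = 4, by = 4)
  fit <- fit_bl_transition(traces, n_boot = 199, seed = 4)
  expect_s3_class(fit, "bl_fit")
  expect_lt(abs(fit$lpl - 3.8) / 3.8, 0.1)
  cf <- coef(fit)
  expect_named(cf, c("f_star", "L_pL"))
  expect_output(print(fit), "inversion force")
  expect_output(print(summary(fit)), "Mean BL slope")
  # predict reproduces the mixed-phase model under the fitted parameters
  nd <- data.frame(force_pN = 2.3, n_turns = c(-600, -300))
  expect_equal(predict(fit, nd),
               mixed_extension(2.3, c(-600, -300), fit$config),
               tolerance = 1e-12)
  # residuals against the fitted slope curve are centred near zero
  expect_lt(abs(mean(residuals(fit))), 0.05)
  # simulate returns trace families in the canonical schema
  sim <- simulate(fit, nsim = 2, seed = 7, by = 20, reps = 1)
  expect_length(sim, 2)
  expect_true(all(c("trace_id", "n_turns", "extension_nm") %in%
                    names(sim[[1]])))
  # plot method draws without error
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
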