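# Stable 32-bit hash of an R object (for config provenance headers).
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.trace_cols <- c("trace_id", "dna_label", "force_pN", "n_turns",
                 "extension_nm", "clipped")
.trace_numeric <- c("force_pN", "n_turns", "extension_nm", "clipped")

#' Read twist traces from CSV
#'
#' Reads a trace table in the package CSV schema (`trace_id, dna_label,
#' force_pN, n_turns, extension_nm, clipped`; `#`-prefixed header comment
#' lines are skipped).  Unknown extra columns are dropped with a warning;
#' a missing required column is an error naming it; a non-numeric cell in a
#' numeric column is a parse error reporting the file line number.
#'
#' @param path Path to a CSV file written by [write_traces()] (or any file
#'   matching the schema).
#' @return A data frame of traces, row order preserved.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", raw)
  body <- raw[!is_comment]
  body_lines <- which(!is_comment)   # original line numbers
  if (length(body) == 0L || all(!nzchar(trimws(body)))) {
    warning("empty trace file: ", path, call. = FALSE)
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(.trace_cols)), .trace_cols))
    for (cc in .trace_numeric) out[[cc]] <- numeric(0)
    return(out)
  }
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(setdiff(.trace_cols, "clipped"), names(df))
  if (length(missing_cols) > 0L) {
    stop("trace file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extras <- setdiff(names(df), .trace_cols)
  if (length(extras) > 0L) {
    warning("ignoring unknown column(s) in ", path, ": ",
            paste(extras, collapse = ", "), call. = FALSE)
    df <- df[, setdiff(names(df), extras), drop = FALSE]
  }
  if (!"clipped" %in% names(df)) df$clipped <- "0"
  if (nrow(df) == 0L) {
    warning("empty trace file: ", path, call. = FALSE)
  }
  for (cc in .trace_numeric) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- is.na(v) & !is.na(df[[cc]]) & nzchar(df[[cc]])
    if (any(bad)) {
      # +1: data row r sits after the header line within the body
      line_no <- body_lines[which(bad)[1] + 1L]
      stop("non-numeric value ", dQuote(df[[cc]][which(bad)[1]]),
           " in column ", cc, " at line ", line_no, " of ", path,
           call. = FALSE)
    }
    df[[cc]] <- v
  }
  df[, .trace_cols]
}

#' Write twist traces to CSV
#'
#' Writes the trace table in the package CSV schema with a `#` comment
#' header recording the config hash and seed, so every artifact carries its
#' provenance.  [read_traces()] round-trips the result.
#'
#' @param traces A trace data frame (as produced by [gen_twist_trace()] or
#'   [gen_trace_family()]).
#' @param path Output path.
#' @param config Optional object whose hash is recorded in the header.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, config = NULL, seed = NULL) {
  need <- setdiff(.trace_cols, "clipped")
  if (!is.data.frame(traces) || !all(need %in% names(traces))) {
    stop("`traces` must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"clipped" %in% names(traces)) traces$clipped <- 0L
  hdr <- sprintf("# bldna traces; config_hash=%s; seed=%s",
                 if (is.null(config)) "none" else config_hash(config),
                 if (is.null(seed)) "none" else format(seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(traces[, .trace_cols], con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a full pipeline run configuration
#'
#' Bundles everything a reproducible simulation-plus-analysis run needs:
#' the two-phase model, the plectoneme surrogate, the noise level, the
#' simulated experiment design (forces, repeats, turn range) and the seed.
#'
#' @param model A [bl_config()].
#' @param plectoneme A [plectoneme_params()].
#' @param noise_sd Axial noise sd in nm (default 10).
#' @param forces Forces of the simulated family in pN.
#' @param reps Traces per force (default 3).
#' @param n_t_range Turn range per trace (default `c(-880, 60)`).
#' @param by Turn step (default 4).
#' @param ratio_L0 Contour ratio used by the `infer-lpl` stage (default 1.4).
#' @param seed Integer seed (default 1).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(model = bl_config(phase_L = phase_params(3.8,
                                                                0.34 * 1.4)),
                       plectoneme = plectoneme_params(),
                       noise_sd = 10,
                       forces = seq(1, 4, by = 0.375),
                       reps = 3, n_t_range = c(-880, 60), by = 4,
                       ratio_L0 = 1.4, seed = 1) {
  .check_config(model, "model")
  structure(list(model = model, plectoneme = plectoneme,
                 noise_sd = noise_sd, forces = forces, reps = reps,
                 n_t_range = n_t_range, by = by, ratio_L0 = ratio_L0,
                 seed = as.integer(seed)),
            class = "run_config")
}

.pipeline_stages <- c("simulate", "segment", "slopes", "fstar", "infer-lpl")

#' Run the simulation-and-analysis pipeline
#'
#' Executes a valid prefix of the stage sequence
#' `simulate -> segment -> slopes -> fstar -> infer-lpl`, writing one CSV
#' artifact per stage plus a JSON summary into `out_dir`.  Every artifact
#' carries a comment header with the config hash and seed; given the same
#' configuration and seed the outputs are byte-identical, so reruns are
#' idempotent.
#'
#' @param config A [run_config()].
#' @param stages Character vector of stages to run; must be a prefix of the
#'   canonical order (default: all stages).
#' @param out_dir Output directory (created if needed).
#' @param verbose Emit one log line per stage to stderr (default TRUE).
#' @return Invisibly, a list with the artifact `paths` and the `summary`
#'   list (which contains `f_star`, its CI, and `lpl_estimate` when those
#'   stages ran).
#' @export
run_pipeline <- function(config, stages = .pipeline_stages,
                         out_dir = ".", verbose = TRUE) {
  if (!inherits(config, "run_config")) {
    stop("`config` must be created with run_config()", call. = FALSE)
  }
  if (length(stages) == 0L ||
      !identical(stages, .pipeline_stages[seq_along(stages)])) {
    stop("`stages` must be a non-empty prefix of: ",
         paste(.pipeline_stages, collapse = " -> "), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_line <- function(...) {
    if (verbose) message(sprintf("[bldna seed=%d hash=%s] ",
                                 config$seed, hash), ...)
  }
  paths <- list()
  summary <- list(seed = config$seed, config_hash = hash,
                  stages = stages)
  log_line("run start; stages: ", paste(stages, collapse = ", "))

  traces <- gen_trace_family(config$forces, reps = config$reps,
                             n_t_range = config$n_t_range,
                             config = config$model,
                             plect = config$plectoneme,
                             noise_sd = config$noise_sd,
                             seed = config$seed, by = config$by)
  paths$traces <- file.path(out_dir, "traces.csv")
  write_traces(traces, paths$traces, config = config, seed = config$seed)
  log_line("simulate: ", nrow(traces), " points, ",
           length(unique(traces$trace_id)), " traces")

  seg_tab <- NULL
  if ("segment" %in% stages) {
    rows <- list()
    for (id in unique(traces$trace_id)) {
      tr <- traces[traces$trace_id == id, , drop = FALSE]
      seg <- segment_trace(tr)
      rows[[id]] <- data.frame(trace_id = id,
                               force_pN = tr$force_pN[1],
                               bp_L_BL = seg$breakpoints[["L_BL"]],
                               bp_BL_B = seg$breakpoints[["BL_B"]],
                               sse = seg$sse,
                               single_regime = as.integer(
                                 seg$single_regime_suspected),
                               stringsAsFactors = FALSE)
    }
    seg_tab <- do.call(rbind, rows)
    paths$segments <- file.path(out_dir, "segments.csv")
    .write_csv_with_header(seg_tab, paths$segments, hash, config$seed)
    log_line("segment: ", nrow(seg_tab), " traces segmented")
  }

  slopes <- NULL
  if ("slopes" %in% stages) {
    slopes <- slope_vs_force(traces, regime = "BL")
    paths$slopes <- file.path(out_dir, "slopes.csv")
    .write_csv_with_header(slopes, paths$slopes, hash, config$seed)
    log_line("slopes: ", nrow(slopes), " BL slopes")
  }

  if ("fstar" %in% stages) {
    fs <- estimate_f_star(slopes, seed = config$seed)
    summary$f_star <- fs$f_star
    summary$f_star_ci <- c(fs$ci_low, fs$ci_high)
    log_line(sprintf("fstar: F* = %.4g pN", fs$f_star))
    if ("infer-lpl" %in% stages) {
      summary$lpl_estimate <- lpl_from_inversion(fs$f_star, config$ratio_L0,
                                                 config$model)
      summary$lpl_ci <- tryCatch(
        sort(c(lpl_from_inversion(fs$ci_high, config$ratio_L0,
                                  config$model),
               lpl_from_inversion(fs$ci_low, config$ratio_L0,
                                  config$model))),
        error = function(e) c(NA_real_, NA_real_))
      summary$ratio_L0 <- config$ratio_L0
      log_line(sprintf("infer-lpl: L_pL = %.4g nm", summary$lpl_estimate))
    }
  }

  paths$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, summary = summary))
}

.write_csv_with_header <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bldna; config_hash=%s; seed=%s", hash, seed), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write a run configuration as JSON
#'
#' Flat JSON serialisation of a [run_config()] so a run is reproducible from
#' a config file plus a seed.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_run_config()` returns a `"run_config"`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  if (!inherits(config, "run_config")) {
    stop("`config` must be created with run_config()", call. = FALSE)
  }
  flat <- list(
    phase_B_Lp = config$model$phase_B$persistence_length,
    phase_B_rise = config$model$phase_B$rise_per_bp,
    phase_L_Lp = config$model$phase_L$persistence_length,
    phase_L_rise = config$model$phase_L$rise_per_bp,
    n_bp = config$model$tether$n_bp,
    bp_per_turn = config$model$tether$bp_per_turn,
    kT = config$model$kT,
    sigma_max = config$model$sigma_max,
    n_b_max = config$model$n_b_max,
    ionic_strength = config$plectoneme$ionic_strength,
    efficiency = config$plectoneme$efficiency,
    noise_sd = config$noise_sd,
    forces = config$forces,
    reps = config$reps,
    n_t_range = config$n_t_range,
    by = config$by,
    ratio_L0 = config$ratio_L0,
    seed = config$seed)
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(
    model = bl_config(
      phase_B = phase_params(x$phase_B_Lp, x$phase_B_rise),
      phase_L = phase_params(x$phase_L_Lp, x$phase_L_rise),
      tether = tether_spec(x$n_bp, x$bp_per_turn),
      kT = x$kT, sigma_max = x$sigma_max, n_b_max = x$n_b_max),
    plectoneme = plectoneme_params(x$ionic_strength, x$efficiency),
    noise_sd = x$noise_sd, forces = x$forces, reps = x$reps,
    n_t_range = x$n_t_range, by = x$by, ratio_L0 = x$ratio_L0,
    seed = x$seed)
}
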