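#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end analysis in one flat list, with
#' the defaults used throughout: order-15 median filter, stopping ratio
#' 0.995, 0.75 Hz level merge, 3 s histogram bins, 10 s H threshold,
#' N_tot = 11. The config round-trips losslessly through YAML or JSON, and
#' every pipeline run writes the fully resolved config (plus a content
#' hash) next to its results.
#'
#' @param params A [rate_params()] for the simulation block (ignored when
#'   analysing external traces).
#' @param n_motors Motors to simulate (when no input traces are given).
#' @param duration,initial_N,speed_per_unit,noise_sd,frame_rate See
#'   [sim_config()].
#' @param scheme Simulation scheme.
#' @param filter_order,stop_ratio,n_random,min_seg,merge_threshold,zero_tol
#'   Step-fitting parameters; see [fit_trace()].
#' @param h_max H-excursion threshold (s); see [identify_h_states()].
#' @param hist_bin Dwell histogram bin (s).
#' @param n_boot Bootstrap resamples for dwell statistics.
#' @param N_tot Total binding sites.
#' @param use_true_N If TRUE and the input is simulated, analyse the
#'   ground-truth N(t) from the trajectories instead of step-fitting the
#'   noisy traces (useful to separate model error from detection error).
#' @param seed Master seed.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(params = NULL, n_motors = 58L, duration = 360,
                            initial_N = 0L, speed_per_unit = 1.0,
                            noise_sd = 0.4, frame_rate = 100,
                            scheme = "four_state",
                            filter_order = 15L, stop_ratio = 0.995,
                            n_random = 100L, min_seg = 2L,
                            merge_threshold = 0.75, zero_tol = 0.5,
                            h_max = 10, hist_bin = 3, n_boot = 1000L,
                            N_tot = 11L, use_true_N = FALSE, seed = 1L) {
  structure(list(params = params, n_motors = as.integer(n_motors),
                 duration = duration, initial_N = as.integer(initial_N),
                 speed_per_unit = speed_per_unit, noise_sd = noise_sd,
                 frame_rate = frame_rate, scheme = scheme,
                 filter_order = as.integer(filter_order),
                 stop_ratio = stop_ratio, n_random = as.integer(n_random),
                 min_seg = as.integer(min_seg),
                 merge_threshold = merge_threshold, zero_tol = zero_tol,
                 h_max = h_max, hist_bin = hist_bin,
                 n_boot = as.integer(n_boot), N_tot = as.integer(N_tot),
                 use_true_N = isTRUE(use_true_N), seed = as.integer(seed)),
            class = "pipeline_config")
}

config_to_list <- function(config) {
  out <- unclass(config)
  if (inherits(out$params, "rate_params")) {
    p <- unclass(out$params)
    if (inherits(p$on_rate_mod, "on_rate_model")) {
      p$on_rate_mod <- unclass(p$on_rate_mod)
    }
    out$params <- p
  }
  out
}

list_to_config <- function(x) {
  if (!is.null(x$params)) {
    p <- x$params
    mod <- p$on_rate_mod
    if (is.list(mod)) {
      mod <- on_rate_model(mod$k_on0, mod$A, mod$B, mod$C)
    }
    x$params <- rate_params(k_on0 = p$k_on0, on_rate_mod = mod,
                            k_off_l = p$k_off_l, k_off_t = p$k_off_t,
                            k_t = p$k_t, k_l = p$k_l, k_h = p$k_h,
                            k_mh = p$k_mh, N_tot = p$N_tot)
  }
  do.call(pipeline_config, x[setdiff(names(x), "hash")])
}

#' Read / write a pipeline config (YAML or JSON by extension)
#' @param config A `"pipeline_config"`.
#' @param path File path ending in .yaml/.yml or .json.
#' @return `read_pipeline_config()` returns the config; the writer returns
#'   the path invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  x <- config_to_list(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  list_to_config(x)
}

# FNV-1a over the serialized config text: a content hash to stamp outputs
# with (no cryptographic intent).
config_hash <- function(config) {
  bytes <- utf8ToInt(jsonlite::toJSON(config_to_list(config),
                                      auto_unbox = TRUE, digits = NA,
                                      null = "null"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write / read a speed trace as two-column delimited text
#'
#' Column names are fixed (time_s, speed_hz); a JSON sidecar `<path>.json`
#' carries the simulation config and seed when the trace is synthetic.
#'
#' @param trace A `"speed_trace"` or data.frame (time_s, speed_hz).
#' @param path Output path (tab-separated text).
#' @param sidecar Write the JSON sidecar when the trace has a config.
#' @return The path (writer, invisibly) or the trace (reader).
#' @export
write_speed_trace <- function(trace, path, sidecar = TRUE) {
  utils::write.table(trace[, c("time_s", "speed_hz")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cfg <- attr(trace, "config")
  if (sidecar && !is.null(cfg)) {
    meta <- list(seed = cfg$seed, frame_rate = cfg$frame_rate,
                 duration = cfg$duration, scheme = cfg$scheme,
                 speed_per_unit = cfg$speed_per_unit,
                 noise_sd = cfg$noise_sd,
                 motor_id = attr(trace, "motor_id"))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_speed_trace
#' @export
read_speed_trace <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("time_s", "speed_hz") %in% names(df)))
  structure(df, class = c("speed_trace", "data.frame"))
}

#' Write a trajectory event list as delimited text
#' @param traj A `"trajectory"`.
#' @param path Output path (tab-separated: time_s, unit, from, to).
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(traj$events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Select traces suitable for remodeling analysis
#'
#' Keeps only records whose mean speed in the final `window` seconds of the
#' low-load (pre-step) phase is below `max_speed_hz` (default 1 Hz), so
#' that at most one stator unit is bound when the high-load phase begins.
#' Traces without a load-step annotation are skipped with a warning.
#'
#' @param traces List of speed traces (data.frames with time_s, speed_hz).
#' @param load_step_s Numeric vector (or single value) giving the load-step
#'   time of each trace (s); NA marks a missing annotation.
#' @param window Averaging window before the load step (s), default 5.
#' @param max_speed_hz Selection threshold (Hz), default 1.
#' @return A list with `kept` (the selected traces), `kept_idx`, and
#'   `pre_step_speed` for every input trace.
#' @export
select_traces <- function(traces, load_step_s, window = 5,
                          max_speed_hz = 1) {
  load_step_s <- rep_len(load_step_s, length(traces))
  pre <- vapply(seq_along(traces), function(i) {
    ls <- load_step_s[i]
    if (is.na(ls)) return(NA_real_)
    tr <- traces[[i]]
    sel <- tr$time_s >= ls - window & tr$time_s < ls
    if (!any(sel)) return(NA_real_)
    mean(abs(tr$speed_hz[sel]))
  }, numeric(1))
  if (anyNA(pre)) {
    warning(sprintf("%d trace(s) without usable load-step annotation skipped",
                    sum(is.na(pre))))
  }
  keep <- which(!is.na(pre) & pre < max_speed_hz)
  list(kept = traces[keep], kept_idx = keep, pre_step_speed = pre)
}

#' Run the full stator-remodeling analysis pipeline
#'
#' simulate (or ingest) -> step-fit -> level merge and stator assignment ->
#' dwell extraction -> H-state cleaning -> per-N dwell statistics ->
#' bound-state and on-rate fits. Deterministic given the config seed; the
#' returned report carries per-stage counts and, when `out_dir` is given,
#' is also written to disk (dwell table and statistics as TSV, fits and H
#' summary as JSON, resolved config with its hash).
#'
#' @param config A `"pipeline_config"`.
#' @param traces Optional list of speed traces to analyse instead of
#'   simulating (each a data.frame time_s, speed_hz).
#' @param out_dir Optional output directory.
#' @return A `"pipeline_report"` list: `config`, `hash`, per-stage `counts`,
#'   `dwells` (cleaned table), `h_summary`, `stats`, `on_rates`, `fit`
#'   (NULL when too few levels), `on_rate_fit`, `histogram`.
#' @export
run_pipeline <- function(config, traces = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  counts <- list()
  trajs <- NULL
  if (is.null(traces)) {
    if (is.null(config$params)) stop("config$params needed to simulate")
    sc <- sim_config(config$params, duration = config$duration,
                     initial_N = config$initial_N,
                     speed_per_unit = config$speed_per_unit,
                     noise_sd = config$noise_sd,
                     frame_rate = config$frame_rate, seed = config$seed,
                     scheme = config$scheme)
    trajs <- simulate_ensemble(sc, config$n_motors)
    counts$simulated <- length(trajs)
    if (!config$use_true_N) {
      traces <- lapply(trajs, trajectory_to_speed)
    }
  }
  dwell_tabs <- list()
  if (!is.null(trajs) && config$use_true_N) {
    for (i in seq_along(trajs)) {
      Nt <- trajectory_N_of_t(trajs[[i]])
      dwell_tabs[[i]] <- extract_dwells(Nt, record_end_s = config$duration,
                                        motor_id = trajs[[i]]$motor_id)
    }
    counts$step_fitted <- 0L
  } else {
    n_failed <- 0L
    for (i in seq_along(traces)) {
      ft <- fit_trace(traces[[i]], filter_order = config$filter_order,
                      stop_ratio = config$stop_ratio,
                      n_random = config$n_random,
                      seed = derive_seed(config$seed, 500000L + i),
                      min_seg = config$min_seg,
                      merge_threshold = config$merge_threshold,
                      zero_tol = config$zero_tol)
      tab <- tryCatch(
        extract_dwells(ft$N_table, record_end_s = ft$record_end_s,
                       motor_id = i),
        error = function(e) {
          # a multi-unit fitted jump: two events inside the detector's
          # resolution; the trace cannot be dwell-decomposed reliably
          warning(sprintf("trace %d skipped: %s", i, conditionMessage(e)),
                  call. = FALSE)
          NULL
        })
      if (is.null(tab)) n_failed <- n_failed + 1L
      else dwell_tabs[[length(dwell_tabs) + 1L]] <- tab
    }
    counts$step_fitted <- length(traces) - n_failed
    counts$step_fit_skipped <- n_failed
  }
  dwells_raw <- bind_dwells(dwell_tabs)
  counts$dwells_raw <- nrow(dwells_raw)
  hc <- identify_h_states(dwells_raw, h_max = config$h_max)
  counts$h_episodes <- hc$summary$N_H
  counts$dwells_clean <- nrow(hc$cleaned)
  stats <- dwell_statistics(hc$cleaned, n_boot = config$n_boot,
                            seed = derive_seed(config$seed, 900001L),
                            N_tot = config$N_tot)
  on_rates <- empirical_on_rates(stats)
  # the dwell table is in hand, so use the likelihood objective, which
  # resolves the (c, sigma+) ridge that the moment triples leave flat
  fit <- tryCatch(
    fit_bound_state_model(stats, table = hc$cleaned,
                          objective = "likelihood",
                          seed = derive_seed(config$seed, 900002L)),
    error = function(e) NULL)
  ok <- is.finite(on_rates$k_on) & is.finite(on_rates$k_on_se) &
    on_rates$k_on_se > 0
  on_fit <- if (sum(ok) >= 4L) {
    tryCatch(fit_on_rate_model(on_rates$N[ok], on_rates$k_on[ok],
                               on_rates$k_on_se[ok],
                               seed = derive_seed(config$seed, 900003L)),
             error = function(e) NULL)
  } else NULL
  report <- structure(list(config = config, hash = config_hash(config),
                           counts = counts, dwells = hc$cleaned,
                           h_summary = hc$summary, stats = stats,
                           on_rates = on_rates, fit = fit,
                           on_rate_fit = on_fit,
                           histogram = dwell_histogram(hc$cleaned,
                                                       config$hist_bin)),
                      class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report [%s]: %d dwells (%d H episodes spliced)\n",
              x$hash, nrow(x$dwells), x$h_summary$N_H))
  print(x$stats)
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(hash = report$hash, seed = report$config$seed)
  cfgl <- config_to_list(report$config)
  cfgl$hash <- report$hash
  jsonlite::write_json(cfgl, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  utils::write.table(as.data.frame(report$dwells),
                     file.path(out_dir, "dwells.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$stats$per_N,
                     file.path(out_dir, "dwell_stats.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$histogram,
                     file.path(out_dir, "dwell_histogram.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(unclass(report$h_summary), stamp),
                       file.path(out_dir, "h_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$fit)) {
    f <- report$fit
    jsonlite::write_json(
      c(list(c = f$c, sigma_plus = f$sigma_plus,
             sigma_minus = f$sigma_minus,
             sigma_minus_is_upper_bound = f$sigma_minus_is_upper_bound,
             k_off_l = f$k_off_l, k_t = f$k_t, k_l = f$k_l,
             objective = f$objective, age_policy = f$age_policy,
             fit_seed = f$seed), stamp),
      file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(f$comparison,
                       file.path(out_dir, "model_vs_data.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$on_rate_fit)) {
    m <- report$on_rate_fit$model
    jsonlite::write_json(
      c(list(k_on0 = m$k_on0, A = m$A, B = m$B, C = m$C,
             objective = report$on_rate_fit$objective), stamp),
      file.path(out_dir, "on_rate_fit.json"), auto_unbox = TRUE,
      digits = NA)
  }
  invisible(out_dir)
}
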