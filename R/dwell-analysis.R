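#' Extract dwell records from a stepwise stator-count series
#'
#' A dwell is a maximal interval of constant N. Its end type is '+' when
#' the next transition increases N, '-' when it decreases, and "censored"
#' for the final interval of the record, whose true duration is unknown.
#' Transitions must change N by exactly one unit; larger jumps indicate an
#' upstream step-fit failure and raise an error naming the offenders.
#'
#' @param N_table A data.frame (time_s, N) of transition times: row i means
#'   N holds from time_s\[i\] until time_s\[i+1\] (or `record_end_s`).
#' @param record_end_s End of the record (s); defaults to the last
#'   transition time (making the final dwell zero-length and dropped).
#' @param motor_id Identifier copied into the output rows.
#' @return A `"dwell_table"` data.frame with columns motor, N, tau (s),
#'   end ('+', '-', 'censored'), entry ('+', '-', 'start': how the dwell
#'   was entered), start (s).
#' @export
extract_dwells <- function(N_table, record_end_s = NULL, motor_id = 1L) {
  stopifnot(all(c("time_s", "N") %in% names(N_table)))
  tt <- N_table$time_s
  NN <- as.integer(N_table$N)
  if (is.unsorted(tt, strictly = TRUE)) stop("time_s must be increasing")
  dN <- diff(NN)
  bad <- which(abs(dN) > 1L)
  if (length(bad)) {
    stop(sprintf("non-unit N transitions at t = %s (|dN| = %s)",
                 paste(signif(tt[bad + 1L], 6), collapse = ", "),
                 paste(abs(dN[bad]), collapse = ", ")))
  }
  if (is.null(record_end_s)) record_end_s <- tt[length(tt)]
  ends <- c(ifelse(dN > 0L, "+", "-"), "censored")
  entry <- c("start", ends[-length(ends)])
  tau <- c(diff(tt), record_end_s - tt[length(tt)])
  keep <- tau > 0
  structure(data.frame(motor = motor_id, N = NN[keep], tau = tau[keep],
                       end = ends[keep], entry = entry[keep],
                       start = tt[keep], stringsAsFactors = FALSE),
            class = c("dwell_table", "data.frame"))
}

#' Bind dwell tables from several motors
#' @param ... `"dwell_table"` objects (or one list of them).
#' @return A combined `"dwell_table"`.
#' @export
bind_dwells <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && !inherits(tabs[[1]], "data.frame")) {
    tabs <- tabs[[1]]
  }
  if (!length(tabs)) {
    out <- data.frame(motor = integer(0), N = integer(0), tau = numeric(0),
                      end = character(0), entry = character(0),
                      start = numeric(0))
  } else {
    out <- do.call(rbind, lapply(tabs, as.data.frame))
  }
  rownames(out) <- NULL
  structure(out, class = c("dwell_table", "data.frame"))
}

#' Identify hidden-state (H) episodes and clean the dwell table
#'
#' A transiently unbound unit produces a characteristic down-up excursion:
#' a short dwell at N - 1 sandwiched between two dwells at N. Any such
#' single-unit excursion shorter than `h_max` is classified as one H
#' episode of the N-stator state, and the three rows are spliced into a
#' single N-dwell (durations summed), so total observation time is
#' conserved. Scanning repeats until no pattern remains, so nested
#' excursions collapse correctly. Multi-unit excursions are never touched.
#'
#' The H-state rates follow from the episode bookkeeping:
#' k_h = N_H / T_tot, where T_tot = sum(N_i tau_i) over the cleaned table
#' is the total bound-unit exposure (each dwell weighted by how many units
#' were bound and therefore at risk of detaching), and k_mh = 1 / tau_H
#' with tau_H the mean H-episode duration.
#'
#' @param table A `"dwell_table"` (one or several motors).
#' @param h_max Maximum duration of an H excursion (s), default 10 — a few
#'   multiples of the expected H lifetime.
#' @return A list with `summary` (class `"h_state_summary"`: N_H, tau_H,
#'   T_tot, k_h, k_mh) and `cleaned` (the spliced `"dwell_table"`).
#' @export
identify_h_states <- function(table, h_max = 10) {
  stopifnot(inherits(table, "dwell_table"))
  if (h_max <= 0) stop("h_max must be > 0")
  h_taus <- numeric(0)
  clean1 <- function(tb) {
    repeat {
      n <- nrow(tb)
      if (n < 3L) return(tb)
      i <- 2L
      spliced <- FALSE
      while (i < n) {
        if (tb$N[i] == tb$N[i - 1L] - 1L && tb$N[i + 1L] == tb$N[i - 1L] &&
            tb$tau[i] < h_max && tb$end[i] != "censored" &&
            tb$end[i - 1L] != "censored") {
          h_taus[[length(h_taus) + 1L]] <<- tb$tau[i]
          tb$tau[i - 1L] <- tb$tau[i - 1L] + tb$tau[i] + tb$tau[i + 1L]
          tb$end[i - 1L] <- tb$end[i + 1L]
          tb <- tb[-c(i, i + 1L), , drop = FALSE]
          n <- nrow(tb)
          spliced <- TRUE
        } else i <- i + 1L
      }
      if (!spliced) return(tb)
    }
  }
  parts <- lapply(split(as.data.frame(table), table$motor), clean1)
  cleaned <- if (length(parts)) do.call(rbind, parts)
             else as.data.frame(table)
  rownames(cleaned) <- NULL
  cleaned <- structure(cleaned, class = c("dwell_table", "data.frame"))
  N_H <- length(h_taus)
  T_tot <- sum(cleaned$N * cleaned$tau)
  tau_H <- if (N_H) mean(h_taus) else NA_real_
  structure(list(
    summary = structure(list(N_H = N_H, tau_H = tau_H, T_tot = T_tot,
                             k_h = if (T_tot > 0) N_H / T_tot else NA_real_,
                             k_mh = if (N_H) 1 / tau_H else NA_real_,
                             h_max = h_max),
                        class = "h_state_summary"),
    cleaned = cleaned), class = "h_clean_result")
}

#' @export
print.h_state_summary <- function(x, ...) {
  cat(sprintf(
    "H states: N_H = %d episodes, tau_H = %.3g s, T_tot = %.6g unit-s\n",
    x$N_H, x$tau_H, x$T_tot))
  cat(sprintf("  k_h = %.3g s^-1, k_-h = %.3g s^-1 (threshold %.3g s)\n",
              x$k_h, x$k_mh, x$h_max))
  invisible(x)
}

#' H-rate estimators from episode counts
#'
#' k_h = N_H / T_tot and k_minus_h = 1 / tau_H, for use when the episode
#' bookkeeping comes from elsewhere (e.g. published counts).
#'
#' @param N_H Number of H episodes.
#' @param T_tot Total bound-unit exposure sum(N_i tau_i) (unit-seconds).
#' @param tau_H Mean H-episode duration (s).
#' @return A list with `k_h` and `k_mh` (s^-1).
#' @export
h_rate_estimators <- function(N_H, T_tot, tau_H) {
  if (T_tot <= 0 || tau_H <= 0) stop("T_tot and tau_H must be > 0")
  list(k_h = N_H / T_tot, k_mh = 1 / tau_H)
}

#' Per-N dwell statistics with bootstrap errors
#'
#' For each stator count N, from the uncensored dwells: the number of
#' dwells, the fraction f_plus ending in a binding event, the mean dwell
#' time, and the normalised variance V = var(tau) / mean(tau)^2. Standard
#' errors come from a seeded nonparametric bootstrap over dwells (pooled
#' across motors). Derived rates: k_plus = f_plus / mean_tau and
#' k_on = k_plus / (N_tot - N). Censored dwells are excluded from all
#' estimates; their count is reported. Levels with fewer than 2 uncensored
#' dwells get NA statistics rather than fabricated values.
#'
#' @param table A cleaned `"dwell_table"` (H episodes spliced out).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @param N_tot Total binding sites (for k_on).
#' @return A `"dwell_stats"`: data.frame `per_N` with columns N, n_dwells,
#'   n_censored, f_plus, mean_tau, V, k_plus, k_on and their `_se`
#'   companions; plus `V_mean`, `V_sd` (across-N mean and SD of V) and
#'   `n_censored_total`.
#' @export
dwell_statistics <- function(table, n_boot = 1000L, seed = 1L, N_tot = 11L) {
  stopifnot(inherits(table, "dwell_table"))
  set.seed(seed)
  obs <- table[table$end != "censored", , drop = FALSE]
  cens <- table[table$end == "censored", , drop = FALSE]
  Ns <- sort(unique(table$N))
  if (!length(Ns)) {
    empty <- data.frame(N = integer(0), n_dwells = integer(0),
                        n_censored = integer(0), f_plus = numeric(0),
                        mean_tau = numeric(0), V = numeric(0),
                        f_plus_se = numeric(0), mean_tau_se = numeric(0),
                        V_se = numeric(0), k_plus = numeric(0),
                        k_on = numeric(0), k_plus_se = numeric(0),
                        k_on_se = numeric(0))
    return(structure(list(per_N = empty, V_mean = NA_real_, V_sd = NA_real_,
                          n_censored_total = 0L, N_tot = N_tot,
                          n_boot = n_boot, seed = seed),
                     class = "dwell_stats"))
  }
  one <- function(tau, plus) {
    m <- mean(tau)
    c(f_plus = mean(plus), mean_tau = m,
      V = if (length(tau) > 1L) stats::var(tau) / m^2 else NA_real_)
  }
  rows <- lapply(Ns, function(Nv) {
    d <- obs[obs$N == Nv, , drop = FALSE]
    nc <- sum(cens$N == Nv)
    if (nrow(d) < 2L) {
      return(data.frame(N = Nv, n_dwells = nrow(d), n_censored = nc,
                        f_plus = NA_real_, mean_tau = NA_real_, V = NA_real_,
                        f_plus_se = NA_real_, mean_tau_se = NA_real_,
                        V_se = NA_real_, k_plus = NA_real_, k_on = NA_real_,
                        k_plus_se = NA_real_, k_on_se = NA_real_))
    }
    plus <- d$end == "+"
    est <- one(d$tau, plus)
    boot <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(d), replace = TRUE)
      e <- one(d$tau[idx], plus[idx])
      c(e, k_plus = unname(e["f_plus"] / e["mean_tau"]))
    }, numeric(4))
    se <- apply(boot, 1, stats::sd, na.rm = TRUE)
    k_plus <- unname(est["f_plus"] / est["mean_tau"])
    sites <- N_tot - Nv
    data.frame(N = Nv, n_dwells = nrow(d), n_censored = nc,
               f_plus = unname(est["f_plus"]),
               mean_tau = unname(est["mean_tau"]), V = unname(est["V"]),
               f_plus_se = se[1], mean_tau_se = se[2], V_se = se[3],
               k_plus = k_plus,
               k_on = if (sites > 0) k_plus / sites else NA_real_,
               k_plus_se = se[4],
               k_on_se = if (sites > 0) se[4] / sites else NA_real_)
  })
  per_N <- do.call(rbind, rows)
  rownames(per_N) <- NULL
  V_ok <- per_N$V[!is.na(per_N$V)]
  structure(list(per_N = per_N,
                 V_mean = if (length(V_ok)) mean(V_ok) else NA_real_,
                 V_sd = if (length(V_ok) > 1L) stats::sd(V_ok) else NA_real_,
                 n_censored_total = nrow(cens),
                 N_tot = N_tot, n_boot = n_boot, seed = seed),
            class = "dwell_stats")
}

#' @export
print.dwell_stats <- function(x, ...) {
  cat(sprintf(
    "Dwell statistics over %d levels (%d censored dwells excluded)\n",
    nrow(x$per_N), x$n_censored_total))
  print(x$per_N[, c("N", "n_dwells", "f_plus", "mean_tau", "V",
                    "k_plus", "k_on")], digits = 3, row.names = FALSE)
  cat(sprintf("Across-N V: mean = %.3g, SD = %.3g\n", x$V_mean, x$V_sd))
  invisible(x)
}

#' Empirical on rates per stator count
#'
#' k_plus(N) = f_plus(N) / mean_tau(N) — a direct consequence of the
#' first-passage identity f_plus = k_plus * mean(tau) — and the per-site
#' rate k_on(N) = k_plus(N) / (N_tot - N), undefined at a full motor.
#'
#' @param stats A `"dwell_stats"`.
#' @param N_tot Total binding sites (defaults to the value in `stats`).
#' @return A data.frame (N, k_plus, k_plus_se, k_on, k_on_se).
#' @export
empirical_on_rates <- function(stats, N_tot = stats$N_tot) {
  stopifnot(inherits(stats, "dwell_stats"))
  d <- stats$per_N
  sites <- N_tot - d$N
  data.frame(N = d$N, k_plus = d$k_plus, k_plus_se = d$k_plus_se,
             k_on = ifelse(sites > 0, d$k_plus / sites, NA_real_),
             k_on_se = ifelse(sites > 0, d$k_plus_se / sites, NA_real_))
}

#' Dwell-time histogram
#'
#' Fixed-width binning of the uncensored dwell durations, pooled over N
#' by default or split per N. Default bin width 3 s.
#'
#' @param table A `"dwell_table"`.
#' @param bin Bin width (s), > 0.
#' @param per_N If TRUE, return one histogram per stator count.
#' @return A data.frame (bin_left, count, density), or a list of them
#'   named by N when `per_N` is TRUE. Density integrates to 1.
#' @export
dwell_histogram <- function(table, bin = 3, per_N = FALSE) {
  stopifnot(inherits(table, "dwell_table"))
  if (bin <= 0) stop("bin must be > 0")
  obs <- table[table$end != "censored", , drop = FALSE]
  hist1 <- function(tau) {
    if (!length(tau)) {
      return(data.frame(bin_left = numeric(0), count = integer(0),
                        density = numeric(0)))
    }
    br <- seq(0, (floor(max(tau) / bin) + 1) * bin, by = bin)
    ct <- tabulate(findInterval(tau, br, left.open = TRUE,
                                rightmost.closed = TRUE),
                   nbins = length(br) - 1L)
    data.frame(bin_left = br[-length(br)], count = ct,
               density = ct / (sum(ct) * bin))
  }
  if (!per_N) return(hist1(obs$tau))
  lapply(split(obs$tau, obs$N), hist1)
}
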