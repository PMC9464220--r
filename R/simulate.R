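#' Simulation configuration for synthetic single-motor records
#'
#' Describes one simulated electrorotation-style experiment: after a sudden
#' load increase at t = 0 the motor starts near N = 0 bound units and
#' recruits stator units over a 6-minute recording. Speed is linear in the
#' number of force-generating (L or T) units, about 1 Hz per unit under
#' high load, corrupted by per-frame Gaussian measurement noise.
#'
#' @param params A [rate_params()].
#' @param duration Record length (s), default 360.
#' @param initial_N Bound units at t = 0, default 0.
#' @param speed_per_unit Speed increment per bound unit (Hz), default 1.
#' @param noise_sd Per-frame measurement noise SD (Hz), default 0.4 —
#'   small enough that 1 Hz levels separate cleanly after the order-15
#'   median filter used upstream of step fitting.
#' @param frame_rate Sampling rate (frames/s), default 100.
#' @param seed Integer seed; every simulation is reproducible given
#'   (seed, config).
#' @param scheme `"four_state"` (D/L/T/H) or `"two_state"` (D/bound, using
#'   `k_off_l` as the single off rate).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(params, duration = 360, initial_N = 0L,
                       speed_per_unit = 1.0, noise_sd = 0.4,
                       frame_rate = 100, seed = 1L,
                       scheme = c("four_state", "two_state")) {
  stopifnot(inherits(params, "rate_params"))
  scheme <- match.arg(scheme)
  if (duration <= 0) stop("duration must be > 0")
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  if (speed_per_unit <= 0) stop("speed_per_unit must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  initial_N <- as.integer(initial_N)
  if (initial_N < 0 || initial_N > params$N_tot) {
    stop("initial_N must be in [0, N_tot]")
  }
  structure(list(params = params, duration = duration,
                 initial_N = initial_N, speed_per_unit = speed_per_unit,
                 noise_sd = noise_sd, frame_rate = frame_rate,
                 seed = as.integer(seed), scheme = scheme),
            class = "sim_config")
}

new_trajectory <- function(events, states, config, motor_id = 1L) {
  structure(list(events = events, final_states = states,
                 config = config, motor_id = motor_id),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Simulated motor trajectory: %d events over %g s (scheme %s)\n",
              nrow(x$events), x$config$duration, x$config$scheme))
  invisible(x)
}

#' Simulate one motor with the four-state (D/L/T/H) scheme
#'
#' Exact event-driven (Gillespie) simulation of N_tot stator units. At any
#' instant the complex-level hazard of a binding event (D -> L) is
#' (number of D units) * k_on(N) with N the current bound (L + T) count;
#' each L unit independently risks L -> D (k_off_l), L -> T (k_t) and
#' L -> H (k_h); each T unit T -> L (k_l), T -> D (k_off_t) and T -> H
#' (k_h); each H unit returns to the bound state it left at rate k_mh.
#' All hazards are re-evaluated after every event, so the N-dependence of
#' the on rate is honoured exactly.
#'
#' `initial_N` units start in the loose state with age 0 at t = 0.
#'
#' @param config A [sim_config()] with `scheme = "four_state"`.
#' @return A `"trajectory"`: `events` is a data.frame
#'   (time_s, unit, from, to), plus the final per-unit states.
#' @export
simulate_motor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$scheme != "four_state") {
    stop("simulate_motor requires scheme = \"four_state\"")
  }
  p <- config$params
  set.seed(config$seed)
  n_units <- p$N_tot
  state <- rep("D", n_units)
  if (config$initial_N > 0) state[seq_len(config$initial_N)] <- "L"
  h_prev <- rep(NA_character_, n_units)   # bound state a unit left for H
  t <- 0
  ev_time <- numeric(0); ev_unit <- integer(0)
  ev_from <- character(0); ev_to <- character(0)
  push <- function(unit, from, to) {
    ev_time[[length(ev_time) + 1L]] <<- t
    ev_unit[[length(ev_unit) + 1L]] <<- unit
    ev_from[[length(ev_from) + 1L]] <<- from
    ev_to[[length(ev_to) + 1L]] <<- to
  }
  repeat {
    iD <- which(state == "D"); iL <- which(state == "L")
    iT <- which(state == "T"); iH <- which(state == "H")
    N <- length(iL) + length(iT)
    haz <- c(on    = length(iD) * on_rate(N, p),
             l_off = length(iL) * p$k_off_l,
             l_t   = length(iL) * p$k_t,
             l_h   = length(iL) * p$k_h,
             t_l   = length(iT) * p$k_l,
             t_off = length(iT) * p$k_off_t,
             t_h   = length(iT) * p$k_h,
             h_b   = length(iH) * p$k_mh)
    A <- sum(haz)
    if (A <= 0) break
    t <- t + stats::rexp(1, A)
    if (t > config$duration) break
    ev <- sample.int(8L, 1L, prob = haz)
    pick <- function(idx) if (length(idx) == 1L) idx else sample(idx, 1L)
    switch(ev,
      { u <- pick(iD); state[u] <- "L"; push(u, "D", "L") },                 # D -> L
      { u <- pick(iL); state[u] <- "D"; push(u, "L", "D") },                 # L -> D
      { u <- pick(iL); state[u] <- "T"; push(u, "L", "T") },                 # L -> T
      { u <- pick(iL); state[u] <- "H"; h_prev[u] <- "L"; push(u, "L", "H") },
      { u <- pick(iT); state[u] <- "L"; push(u, "T", "L") },                 # T -> L
      { u <- pick(iT); state[u] <- "D"; push(u, "T", "D") },                 # T -> D
      { u <- pick(iT); state[u] <- "H"; h_prev[u] <- "T"; push(u, "T", "H") },
      { u <- pick(iH); state[u] <- h_prev[u]; push(u, "H", h_prev[u]) }      # H -> back
    )
  }
  new_trajectory(
    data.frame(time_s = ev_time, unit = ev_unit,
               from = ev_from, to = ev_to, stringsAsFactors = FALSE),
    state, config)
}

#' Simulate one motor with the plain two-state (bound/unbound) scheme
#'
#' Reference scenario: units toggle between D and a single bound state with
#' per-site on rate k_on(N) and per-unit off rate `k_off_l`. At fixed N the
#' dwell time is exponential with rate k_plus(N) + N k_off — a single
#' timescale, so V = 1 and no long dwell-time tail.
#'
#' @param config A [sim_config()] with `scheme = "two_state"`.
#' @return A `"trajectory"` with states "D"/"L".
#' @export
simulate_two_state <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$scheme != "two_state") {
    stop("simulate_two_state requires scheme = \"two_state\"")
  }
  p <- config$params
  set.seed(config$seed)
  n_units <- p$N_tot
  state <- rep("D", n_units)
  if (config$initial_N > 0) state[seq_len(config$initial_N)] <- "L"
  t <- 0
  ev_time <- numeric(0); ev_unit <- integer(0)
  ev_from <- character(0); ev_to <- character(0)
  repeat {
    iD <- which(state == "D"); iB <- which(state == "L")
    N <- length(iB)
    haz <- c(length(iD) * on_rate(N, p), N * p$k_off_l)
    A <- sum(haz)
    if (A <= 0) break
    t <- t + stats::rexp(1, A)
    if (t > config$duration) break
    if (stats::runif(1) * A < haz[1]) {
      u <- if (length(iD) == 1L) iD else sample(iD, 1L)
      state[u] <- "L"
      from <- "D"; to <- "L"
    } else {
      u <- if (length(iB) == 1L) iB else sample(iB, 1L)
      state[u] <- "D"
      from <- "L"; to <- "D"
    }
    k <- length(ev_time) + 1L
    ev_time[[k]] <- t; ev_unit[[k]] <- u
    ev_from[[k]] <- from; ev_to[[k]] <- to
  }
  new_trajectory(
    data.frame(time_s = ev_time, unit = ev_unit,
               from = ev_from, to = ev_to, stringsAsFactors = FALSE),
    state, config)
}

#' Piecewise-constant bound-unit count N(t) of a trajectory
#'
#' Bound means force-generating (L or T); a unit in the hidden state does
#' not count, so an H episode shows up as a transient one-unit dip — this
#' is the observable the speed trace reports. With `count_h = TRUE` a unit
#' in H still counts as bound, which is the ground-truth H-cleaned series:
#' exactly what threshold-based H splicing tries to reconstruct from the
#' observable alone.
#'
#' @param traj A `"trajectory"`.
#' @param count_h Count H-state units as bound (ground-truth H cleaning).
#' @return A data.frame (time_s, N): N on \[time_s\[i\], time_s\[i+1\]),
#'   starting at t = 0 and ending with the value held until the record end.
#' @export
trajectory_N_of_t <- function(traj, count_h = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  bound <- if (count_h) c(D = 0L, L = 1L, T = 1L, H = 1L)
           else c(D = 0L, L = 1L, T = 1L, H = 0L)
  ev <- traj$events
  dN <- if (nrow(ev)) bound[ev$to] - bound[ev$from] else integer(0)
  N0 <- traj$config$initial_N
  keep <- dN != 0L
  data.frame(time_s = c(0, ev$time_s[keep]),
             N = as.integer(N0 + cumsum(c(0L, dN[keep]))))
}

#' Convert a trajectory to a noisy sampled speed trace
#'
#' speed(t) = speed_per_unit * N_bound(t) + Gaussian noise per frame, on a
#' uniform grid at the configured frame rate. Noise is drawn from the
#' trajectory's seed offset by one stream so trajectory and noise are
#' independently reproducible.
#'
#' @param traj A `"trajectory"`.
#' @param config Optional [sim_config()] override; defaults to the one the
#'   trajectory was simulated with.
#' @return A `"speed_trace"`: data.frame (time_s, speed_hz) with the config
#'   attached as an attribute.
#' @export
trajectory_to_speed <- function(traj, config = traj$config) {
  stopifnot(inherits(traj, "trajectory"))
  n <- round(config$duration * config$frame_rate)
  tt <- (seq_len(n) - 1) / config$frame_rate
  Nt <- trajectory_N_of_t(traj)
  idx <- findInterval(tt, Nt$time_s)
  speed <- config$speed_per_unit * Nt$N[idx]
  if (config$noise_sd > 0) {
    set.seed(derive_seed(config$seed, 999983L))
    speed <- speed + stats::rnorm(n, 0, config$noise_sd)
  }
  structure(data.frame(time_s = tt, speed_hz = speed),
            config = config, motor_id = traj$motor_id,
            class = c("speed_trace", "data.frame"))
}

#' Ground-truth hidden-state episodes of simulated trajectories
#'
#' Reads the H episodes straight from the event bookkeeping of one or more
#' trajectories: every X -> H excursion with its duration (episodes still
#' open at the record end are truncated there). Returns the same summary
#' as the threshold detector in [identify_h_states()], so detector output
#' can be benchmarked against truth.
#'
#' @param trajs A `"trajectory"` or list of them.
#' @param T_tot Bound-unit exposure sum(N tau) to use for the k_h
#'   estimator; when NULL it is computed from the H-cleaned (`count_h`)
#'   series of the trajectories.
#' @return An `"h_state_summary"` (N_H, tau_H, T_tot, k_h, k_mh).
#' @export
true_h_summary <- function(trajs, T_tot = NULL) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  durs <- unlist(lapply(trajs, function(tr) {
    ev <- tr$events
    starts <- ev$time_s[ev$to == "H"]
    ends <- ev$time_s[ev$from == "H"]
    if (length(ends) < length(starts)) {
      ends <- c(ends, tr$config$duration)
    }
    ends - starts
  }))
  if (is.null(T_tot)) {
    T_tot <- sum(vapply(trajs, function(tr) {
      Nt <- trajectory_N_of_t(tr, count_h = TRUE)
      bounds <- c(Nt$time_s, tr$config$duration)
      sum(Nt$N * diff(bounds))
    }, numeric(1)))
  }
  N_H <- length(durs)
  tau_H <- if (N_H) mean(durs) else NA_real_
  structure(list(N_H = N_H, tau_H = tau_H, T_tot = T_tot,
                 k_h = if (T_tot > 0) N_H / T_tot else NA_real_,
                 k_mh = if (N_H) 1 / tau_H else NA_real_,
                 h_max = NA_real_),
            class = "h_state_summary")
}

derive_seed <- function(master, i) {
  as.integer((as.double(master) %% 2147483647 * 48271 + i * 16807) %%
               2147483647)
}

#' Simulate an ensemble of independent motors
#'
#' Emulates a multi-motor electrorotation dataset (the reference experiment
#' pooled 58 motors). Per-motor seeds are derived deterministically from
#' the master seed and the motor index, so the ensemble is reproducible
#' and order-independent.
#'
#' @param config A [sim_config()]; its `seed` is the master seed.
#' @param n_motors Number of motors (>= 1).
#' @return A list of `"trajectory"` objects with `motor_id` set to 1..n.
#' @export
simulate_ensemble <- function(config, n_motors) {
  stopifnot(inherits(config, "sim_config"), n_motors >= 1)
  simulate1 <- if (config$scheme == "four_state") simulate_motor
               else simulate_two_state
  lapply(seq_len(n_motors), function(i) {
    ci <- config
    ci$seed <- derive_seed(config$seed, i)
    traj <- simulate1(ci)
    traj$motor_id <- i
    traj
  })
}
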