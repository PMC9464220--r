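# Shared fixtures: the high-load reference rate set and small builders.

ref_params <- function(...) reference_rate_params(...)

# Constant-on-rate variant of the reference set (overrides allowed).
const_params <- function(k_on0 = 0.0037, k_off_l = 0.057, k_t = 0.13,
                         k_l = 0.0017, k_h = 0, k_mh = 0, N_tot = 11L) {
  rate_params(k_on0 = k_on0, k_off_l = k_off_l, k_t = k_t, k_l = k_l,
              k_h = k_h, k_mh = k_mh, N_tot = N_tot)
}

# Independent quadratic-root oracle for the bound-state eigenvalues:
# roots of x^2 - (k_l + k_t + k_off_l) x + k_l k_off_l via polyroot().
eigen_oracle <- function(k_l, k_t, k_off_l) {
  r <- sort(Re(polyroot(c(k_l * k_off_l, -(k_l + k_t + k_off_l), 1))))
  sp <- r[2]; sm <- r[1]
  list(sigma_plus = sp, sigma_minus = sm,
       c = (sp - k_l - k_t) / (sp - sm))
}

# Draw a random valid rate set for property-style loops.
random_params <- function() {
  rate_params(k_on0 = stats::runif(1, 1e-4, 0.05),
              k_off_l = stats::runif(1, 0.01, 0.5),
              k_t = stats::runif(1, 0, 0.5),
              k_l = stats::runif(1, 1e-4, 0.2),
              N_tot = sample(2:11, 1))
}

# Dwell table built directly from vectors (test fixture helper).
make_dwell_table <- function(N, tau, end, motor = 1L,
                             entry = c("start", utils::head(end, -1))) {
  structure(data.frame(motor = rep(motor, length.out = length(tau)),
                       N = as.integer(N), tau = tau,
                       end = end, entry = entry,
                       start = if (length(tau))
                         cumsum(c(0, utils::head(tau, -1))) else numeric(0),
                       stringsAsFactors = FALSE),
            class = c("dwell_table", "data.frame"))
}

# Ground-truth-cleaned dwell table of a simulated ensemble.
ensemble_dwells <- function(trajs, duration) {
  bind_dwells(lapply(trajs, function(tr) {
    extract_dwells(trajectory_N_of_t(tr, count_h = TRUE),
                   record_end_s = duration, motor_id = tr$motor_id)
  }))
}

# Observable (H dips included) dwell table, as a step-fitted trace sees it.
ensemble_dwells_observable <- function(trajs, duration) {
  bind_dwells(lapply(trajs, function(tr) {
    extract_dwells(trajectory_N_of_t(tr),
                   record_end_s = duration, motor_id = tr$motor_id)
  }))
}
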