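#' Kinetic rate parameters of the four-state stator model
#'
#' Bundles the rate constants of the D-L-T-H scheme for stator-unit turnover
#' in the flagellar motor: a diffusive unbound state (D), a loosely bound
#' state (L) with a high off rate, a tightly bound state (T) with a low
#' (by default zero) off rate, and a short-lived "hidden" unbound state (H)
#' in which a unit transiently disengages from the rotor while staying
#' assembled in the motor. All rates are in s^-1.
#'
#' Allowed transitions: D -> L at rate `k_on(N)` per empty site (see
#' `on_rate_mod`), L -> D at `k_off_l`, L <-> T at `k_t` / `k_l`,
#' T -> D at `k_off_t` (default 0), and L/T <-> H at `k_h` / `k_mh`.
#' The H-state rates only matter for simulation and the H-rate estimators;
#' the analytic dwell model excludes H, which is separated out by a
#' timescale threshold before analysis.
#'
#' @param k_on0 On rate per empty site at N = 0 (s^-1).
#' @param on_rate_mod Either the string `"constant"` (k_on independent of N)
#'   or an [on_rate_model()] giving k_on(N) = k_on0 f1(N) f2(N).
#' @param k_off_l Off rate from the loosely bound state (s^-1).
#' @param k_off_t Off rate from the tightly bound state (s^-1); default 0.
#' @param k_t L -> T transition rate (s^-1).
#' @param k_l T -> L transition rate (s^-1).
#' @param k_h Bound -> H detachment rate per unit (s^-1).
#' @param k_mh H -> bound reattachment rate (s^-1).
#' @param N_tot Total number of stator binding sites (default 11).
#' @return An object of class `"rate_params"`.
#' @examples
#' p <- rate_params(k_on0 = 0.0037, k_off_l = 0.057, k_t = 0.13, k_l = 0.0017)
#' eigen_rates(p)
#' @export
rate_params <- function(k_on0, on_rate_mod = "constant", k_off_l,
                        k_off_t = 0, k_t = 0, k_l = 0,
                        k_h = 0, k_mh = 0, N_tot = 11L) {
  rates <- c(k_on0 = k_on0, k_off_l = k_off_l, k_off_t = k_off_t,
             k_t = k_t, k_l = k_l, k_h = k_h, k_mh = k_mh)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rates must be finite and >= 0")
  }
  if (k_off_t > k_off_l) {
    stop("k_off_t must not exceed k_off_l (tight state is more stable)")
  }
  N_tot <- as.integer(N_tot)
  if (is.na(N_tot) || N_tot < 1L) stop("N_tot must be >= 1")
  if (!identical(on_rate_mod, "constant") &&
      !inherits(on_rate_mod, "on_rate_model")) {
    stop("on_rate_mod must be \"constant\" or an on_rate_model object")
  }
  structure(list(k_on0 = k_on0, on_rate_mod = on_rate_mod,
                 k_off_l = k_off_l, k_off_t = k_off_t,
                 k_t = k_t, k_l = k_l, k_h = k_h, k_mh = k_mh,
                 N_tot = N_tot),
            class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Four-state stator kinetic rates (s^-1):\n")
  cat(sprintf("  k_on(0) = %g (%s), k_off,l = %g, k_off,t = %g\n",
              x$k_on0,
              if (identical(x$on_rate_mod, "constant")) "constant in N"
              else "N-dependent",
              x$k_off_l, x$k_off_t))
  cat(sprintf("  k_t = %g, k_l = %g, k_h = %g, k_-h = %g, N_tot = %d\n",
              x$k_t, x$k_l, x$k_h, x$k_mh, x$N_tot))
  invisible(x)
}

#' Phenomenological N-dependent on-rate model
#'
#' k_on(N) = k_on0 * f1(N) * f2(N), with f1(N) = 1 + A (1 - exp(-B N)) a
#' saturating enhancement (faster rotation increases collision rate and
#' strength) and f2(N) = 1 - exp(-C / N) a decreasing factor (faster rotation
#' shortens the contact time available for binding). Both factors equal 1 at
#' N = 0, so k_on0 is the nucleation rate.
#'
#' @param k_on0 On rate at N = 0 (s^-1).
#' @param A Dimensionless amplitude of the enhancement, >= 0.
#' @param B Rate of saturation of f1, per unit, > 0.
#' @param C Scale of the contact-time reduction, in units, > 0.
#' @return An object of class `"on_rate_model"`.
#' @examples
#' m <- on_rate_model(k_on0 = 0.0037, A = 0.23, B = 1.8, C = 3.8)
#' on_rate(0:8, m)
#' @export
on_rate_model <- function(k_on0, A, B, C) {
  if (!is.finite(k_on0) || k_on0 < 0) stop("k_on0 must be >= 0")
  if (!is.finite(A) || A < 0) stop("A must be >= 0")
  if (!is.finite(B) || B <= 0) stop("B must be > 0")
  if (!is.finite(C) || C <= 0) stop("C must be > 0")
  structure(list(k_on0 = k_on0, A = A, B = B, C = C),
            class = "on_rate_model")
}

#' @export
print.on_rate_model <- function(x, ...) {
  cat(sprintf(
    "On-rate model k_on(N) = k_on0 f1 f2: k_on0 = %g s^-1, A = %g, B = %g, C = %g\n",
    x$k_on0, x$A, x$B, x$C))
  invisible(x)
}

#' Per-site on rate at stator count N
#'
#' For a `"constant"` model this is `k_on0` for every N. For an
#' [on_rate_model()] it is k_on0 f1(N) f2(N); f2(0) is defined by its
#' continuous limit, 1 (exp(-C/N) -> 0 as N -> 0+), handled as an explicit
#' special case.
#'
#' @param N Number of bound stator units (vectorised, integer >= 0).
#' @param model An [on_rate_model()], or a [rate_params()] whose
#'   `on_rate_mod` is used.
#' @return On rate per empty site (s^-1), same length as `N`.
#' @export
on_rate <- function(N, model) {
  if (any(N < 0)) stop("N must be >= 0")
  if (inherits(model, "rate_params")) {
    if (identical(model$on_rate_mod, "constant")) {
      return(rep_len(model$k_on0, length(N)))
    }
    model <- model$on_rate_mod
  }
  if (!inherits(model, "on_rate_model")) stop("not an on-rate model")
  f1 <- 1 + model$A * (1 - exp(-model$B * N))
  f2 <- ifelse(N == 0, 1, 1 - exp(-model$C / pmax(N, 1e-300)))
  model$k_on0 * f1 * f2
}

#' Total on rate of the motor complex at stator count N
#'
#' k_plus(N) = (N_tot - N) k_on(N): the hazard of the next binding event,
#' proportional to the number of empty sites. Zero when the motor is full.
#'
#' @param N Number of bound units (vectorised).
#' @param params A [rate_params()].
#' @return Total on rate k_plus (s^-1).
#' @export
total_on_rate <- function(N, params) {
  stopifnot(inherits(params, "rate_params"))
  if (any(N < 0 | N > params$N_tot)) stop("N must be in [0, N_tot]")
  (params$N_tot - N) * on_rate(N, params)
}

#' Equilibrium tight-state occupancy and effective off rate
#'
#' For a bound unit at equilibrium between the L and T states, the
#' probability of being tightly bound is P_t = k_t / (k_t + k_l), and the
#' observed (state-averaged) off rate is
#' k_off_eff = P_t k_off,t + (1 - P_t) k_off,l. Because torque shifts the
#' L/T balance (k_t/k_l grows with torque), a loaded motor has a much
#' smaller effective off rate than an unloaded one — the catch-bond-like
#' mechanism behind mechano-adaptation.
#'
#' @param params A [rate_params()] with k_t + k_l > 0.
#' @return A list with `P_t` and `k_off_eff` (class `"bound_state_summary"`).
#' @export
equilibrium_tight_fraction <- function(params) {
  stopifnot(inherits(params, "rate_params"))
  if (params$k_t + params$k_l <= 0) {
    stop("k_t + k_l must be > 0 to define the L/T equilibrium")
  }
  P_t <- params$k_t / (params$k_t + params$k_l)
  k_off_eff <- P_t * params$k_off_t + (1 - P_t) * params$k_off_l
  structure(list(P_t = P_t, k_off_eff = k_off_eff),
            class = "bound_state_summary")
}

#' @export
print.bound_state_summary <- function(x, ...) {
  cat(sprintf("P_t = %.4g, effective off rate = %.4g s^-1\n",
              x$P_t, x$k_off_eff))
  invisible(x)
}
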