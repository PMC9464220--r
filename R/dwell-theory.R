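#' @name dwell_theory
#' @title First-passage-time dwell statistics of the N-stator state
#'
#' @description
#' When the motor reaches a state with N bound units at t = 0, the dwell in
#' that state ends with either a binding ('+') or an unbinding ('-') event,
#' whichever comes first. The on process is Markovian with total rate
#' k_plus(N) = (N_tot - N) k_on(N); the off process is the superposition of
#' the N per-unit off hazards, each of which depends on how long ago that
#' unit bound (its "age"), because a freshly bound unit still sits in the
#' high-off-rate loose state while an old unit has equilibrated into the
#' tight state. The motor-level survival probability factorises as
#' \deqn{S(t \mid N) = e^{-k_+ t} \prod_{i=1}^{N} S_i(a_i + t) / S_i(a_i),}
#' a product of two-mode exponential mixtures. Expanding the product gives
#' S as an exact finite sum of N + 1 exponentials with decay rates
#' k_plus + j sigma+ + (N - j) sigma- (j = 0..N), from which dwell-time
#' densities, splitting fractions and moments follow in closed form.
#'
#' Unit-age policies, for when exact ages are not tracked:
#' * `"fresh_equilibrated"` (default for dwells entered by a binding event):
#'   one unit has age 0, the other N - 1 are equilibrated (age Inf, pure
#'   slow-mode survival).
#' * `"all_equilibrated"`: every unit decays at the slow rate sigma-
#'   (dwells entered from above).
#' * `"tracked"`: explicit `ages` supplied by the caller.
NULL

resolve_ages <- function(N, ages = NULL,
                         age_policy = c("fresh_equilibrated",
                                        "all_equilibrated", "tracked")) {
  age_policy <- match.arg(age_policy)
  if (!is.null(ages)) {
    if (length(ages) != N) {
      stop(sprintf("ages has length %d but N = %d", length(ages), N))
    }
    if (any(ages < 0)) stop("ages must be >= 0")
    return(as.numeric(ages))
  }
  if (age_policy == "tracked") {
    stop("age_policy \"tracked\" requires explicit ages")
  }
  if (N == 0) return(numeric(0))
  if (age_policy == "fresh_equilibrated") c(0, rep(Inf, N - 1))
  else rep(Inf, N)
}

# Exact exponential-sum expansion of S(t | N).
# Each bound unit contributes a conditional survival factor
#   S_i(a + t)/S_i(a) = w e^{-sigma+ t} + (1 - w) e^{-sigma- t},
#   w = c e^{-sigma+ a} / S_i(a),
# (w = 0 for an equilibrated unit, a = Inf). The product over units is
# expanded by convolution into coefficients coef[j + 1] on the rate
# rate[j + 1] = k_plus + j sigma+ + (N - j) sigma-.
survival_expansion <- function(N, eig, k_plus, ages = NULL,
                               age_policy = "fresh_equilibrated") {
  eig <- as_eigen(eig)
  if (!is.finite(k_plus) || k_plus < 0) stop("k_plus must be >= 0")
  ages <- resolve_ages(N, ages, age_policy)
  coef <- 1
  if (N > 0) {
    # w = c e^{-dsigma a} / (c e^{-dsigma a} + 1 - c), written to stay
    # stable for large ages where e^{-sigma a} underflows
    ed <- exp(-eig$delta_sigma * pmin(ages, .Machine$double.xmax))
    w <- eig$c * ed / (eig$c * ed + 1 - eig$c)
    w[!is.finite(ages)] <-
      if (eig$delta_sigma > 0 && eig$c < 1) 0 else eig$c
    for (wi in w) {
      coef <- c(coef * (1 - wi), 0) + c(0, coef * wi)
    }
  }
  j <- seq_len(N + 1) - 1
  list(coef = coef,
       rate = k_plus + j * eig$sigma_plus + (N - j) * eig$sigma_minus,
       k_plus = k_plus, eig = eig, N = N)
}

#' Motor-level survival probability S(t | N)
#'
#' Probability that a motor that reached N bound units at t = 0 is still at
#' N at time t, given the ages of its bound units.
#'
#' @param t Times since the N-state was entered (s); vectorised.
#' @param N Number of bound units.
#' @param params A [rate_params()]; supplies k_plus(N) and the eigenmodes.
#' @param ages Optional numeric vector of unit ages (s), length N; Inf
#'   denotes an equilibrated unit.
#' @param age_policy Age policy used when `ages` is NULL; see
#'   [dwell_theory].
#' @param k_plus Optional override of the total on rate (s^-1); defaults to
#'   `total_on_rate(N, params)`.
#' @return Survival probabilities, same length as `t`.
#' @export
motor_survival <- function(t, N, params, ages = NULL,
                           age_policy = "fresh_equilibrated",
                           k_plus = NULL) {
  if (any(t < 0)) stop("t must be >= 0")
  if (is.null(k_plus)) k_plus <- total_on_rate(N, params)
  ex <- survival_expansion(N, params, ages = ages, age_policy = age_policy,
                           k_plus = k_plus)
  drop(exp(-outer(t, ex$rate)) %*% ex$coef)
}

#' Dwell-time densities P_plus(tau | N) and P_minus(tau | N)
#'
#' The joint densities of (dwell time, end type): P_plus = k_plus S(tau | N)
#' for dwells ending in a binding event and P_minus = k_minus(tau | N)
#' S(tau | N) for dwells ending in an unbinding, with
#' P_plus + P_minus = -dS/dt. Both are evaluated analytically from the
#' exponential-sum expansion of S.
#'
#' @param tau_grid Times at which to evaluate the densities (s), non-empty.
#' @inheritParams motor_survival
#' @return A data.frame with columns `tau`, `P_plus`, `P_minus`, `S`.
#' @export
dwell_distributions <- function(N, params, tau_grid, ages = NULL,
                                age_policy = "fresh_equilibrated",
                                k_plus = NULL) {
  if (length(tau_grid) == 0) stop("tau_grid must be non-empty")
  if (any(tau_grid < 0)) stop("tau_grid must be >= 0")
  if (is.null(k_plus)) k_plus <- total_on_rate(N, params)
  ex <- survival_expansion(N, params, ages = ages, age_policy = age_policy,
                           k_plus = k_plus)
  E <- exp(-outer(tau_grid, ex$rate))
  S <- drop(E %*% ex$coef)
  P_tot <- drop(E %*% (ex$coef * ex$rate))   # -dS/dt
  P_plus <- ex$k_plus * S
  data.frame(tau = tau_grid, P_plus = P_plus,
             P_minus = pmax(P_tot - P_plus, 0), S = S)
}

#' Closed-form dwell-time moments and splitting fractions
#'
#' From the exponential-sum expansion of S(t | N) (coefficients C_j, rates
#' r_j): the splitting fraction f_plus = k_plus * sum(C_j / r_j), the mean
#' dwell time `mean_tau` = sum(C_j / r_j), the second moment
#' 2 sum(C_j / r_j^2), and the normalised variance V = var(tau)/mean(tau)^2.
#' V = 1 signals a single (exponential) timescale; V > 1 betrays hidden
#' internal states. The identity f_plus = k_plus * mean_tau holds exactly.
#'
#' @param params A [rate_params()], or an [eigen_decomp()] (then `k_plus`
#'   must be given explicitly).
#' @inheritParams motor_survival
#' @return A list with `f_plus`, `f_minus`, `mean_tau` (s), `V`.
#' @examples
#' p <- rate_params(k_on0 = 0.0037, k_off_l = 0.057, k_t = 0.13, k_l = 0.0017)
#' dwell_moments(3, p)
#' @export
dwell_moments <- function(N, params, ages = NULL,
                          age_policy = "fresh_equilibrated",
                          k_plus = NULL) {
  if (is.null(k_plus)) {
    if (!inherits(params, "rate_params")) {
      stop("k_plus must be supplied when params is an eigen_decomp")
    }
    k_plus <- total_on_rate(N, params)
  }
  ex <- survival_expansion(N, params, ages = ages, age_policy = age_policy,
                           k_plus = k_plus)
  live <- ex$coef != 0
  if (any(live & ex$rate <= 0)) {
    stop("dwell-time moments diverge: a surviving mode has zero total exit rate")
  }
  m1 <- sum(ex$coef[live] / ex$rate[live])
  m2 <- 2 * sum(ex$coef[live] / ex$rate[live]^2)
  list(f_plus = ex$k_plus * m1,
       f_minus = 1 - ex$k_plus * m1,
       mean_tau = m1,
       V = (m2 - m1^2) / m1^2)
}
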