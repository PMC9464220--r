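#' Eigen-decomposition of the two-bound-state sub-chain
#'
#' A stator unit bound to the rotor hops between the loose (L) and tight (T)
#' states and can unbind only from L (with `k_off_t = 0`). The transition
#' rate matrix of this two-state sub-chain has eigenvalues
#' \deqn{\sigma_{\pm} = \tfrac12\left[(k_l + k_t + k_{off,l}) \pm
#'   \sqrt{(k_l + k_t + k_{off,l})^2 - 4 k_l k_{off,l}}\right],}
#' which set the fast and slow decay modes of the per-unit survival
#' probability, with mixing weight
#' \deqn{c = (\sigma_+ - k_l - k_t) / (\sigma_+ - \sigma_-).}
#' By Vieta's formulas, \eqn{\sigma_+ + \sigma_- = k_l + k_t + k_{off,l}} and
#' \eqn{\sigma_+ \sigma_- = k_l k_{off,l}} exactly. The slow eigenvalue
#' \eqn{\sigma_-} is the equilibrium (long-time) effective off rate; the gap
#' \eqn{\Delta\sigma = \sigma_+ - \sigma_-} sets the equilibration timescale
#' \eqn{\tau_e = 1/\Delta\sigma} of a freshly bound unit.
#'
#' @param params A [rate_params()] (only `k_l`, `k_t`, `k_off_l` are used);
#'   requires k_l + k_t + k_off_l > 0.
#' @return An object of class `"eigen_decomp"` with fields `sigma_plus`,
#'   `sigma_minus`, `c`, `delta_sigma`, `tau_e`.
#' @seealso [eigen_decomp()] to build one directly from fitted
#'   (c, sigma_plus, sigma_minus).
#' @examples
#' eigen_rates(rate_params(k_on0 = 0.0037, k_off_l = 0.057,
#'                         k_t = 0.13, k_l = 0.0017))
#' @export
eigen_rates <- function(params) {
  stopifnot(inherits(params, "rate_params"))
  s <- params$k_l + params$k_t + params$k_off_l
  if (s <= 0) stop("k_l + k_t + k_off_l must be > 0")
  p <- params$k_l * params$k_off_l
  disc <- s^2 - 4 * p   # always >= (k_l - k_off_l)^2 + ... >= 0
  root <- sqrt(max(disc, 0))
  sigma_plus <- (s + root) / 2
  # computed via the product identity to avoid cancellation when p << s^2
  sigma_minus <- if (sigma_plus > 0) p / sigma_plus else 0
  d <- sigma_plus - sigma_minus
  cc <- if (d > 0) (sigma_plus - params$k_l - params$k_t) / d else 1
  eigen_decomp(c = cc, sigma_plus = sigma_plus, sigma_minus = sigma_minus)
}

#' Construct an eigen-decomposition from (c, sigma_plus, sigma_minus)
#'
#' Used when the eigen-parameters come from a fit rather than from
#' microscopic rates.
#'
#' @param c Weight of the fast mode in the per-unit survival, in \[0, 1\].
#' @param sigma_plus Fast eigenvalue (s^-1).
#' @param sigma_minus Slow eigenvalue (s^-1), <= sigma_plus.
#' @return An object of class `"eigen_decomp"`.
#' @export
eigen_decomp <- function(c, sigma_plus, sigma_minus) {
  if (!is.finite(c) || c < -1e-12 || c > 1 + 1e-12) {
    stop("c must lie in [0, 1]")
  }
  c <- min(max(c, 0), 1)
  if (sigma_minus < 0 || sigma_plus < sigma_minus) {
    stop("need sigma_plus >= sigma_minus >= 0")
  }
  d <- sigma_plus - sigma_minus
  structure(list(sigma_plus = sigma_plus, sigma_minus = sigma_minus,
                 c = c, delta_sigma = d,
                 tau_e = if (d > 0) 1 / d else Inf),
            class = "eigen_decomp")
}

#' @export
print.eigen_decomp <- function(x, ...) {
  cat(sprintf(
    "Bound-state eigenmodes: sigma+ = %.4g, sigma- = %.4g s^-1, c = %.3g (tau_e = %.4g s)\n",
    x$sigma_plus, x$sigma_minus, x$c, x$tau_e))
  invisible(x)
}

as_eigen <- function(x) {
  if (inherits(x, "eigen_decomp")) x
  else if (inherits(x, "rate_params")) eigen_rates(x)
  else stop("expected an eigen_decomp or rate_params object")
}

#' Survival probability of a single bound stator unit
#'
#' S_i(a) = c exp(-sigma+ a) + (1 - c) exp(-sigma- a): the probability that a
#' unit that entered the loose state an interval `age` ago is still bound
#' (in L or T). The two exponentials reflect the fast relaxation into the
#' L/T equilibrium and the slow equilibrium unbinding.
#'
#' @param age Time since the unit bound (s); vectorised, >= 0 (Inf allowed).
#' @param eig An `"eigen_decomp"` (or [rate_params()], decomposed on the fly).
#' @return Survival probability in \[0, 1\].
#' @export
unit_survival <- function(age, eig) {
  eig <- as_eigen(eig)
  if (any(age < 0)) stop("age must be >= 0")
  # exp(-sigma * Inf) -> 0 even when sigma == 0 would give NaN; ages of Inf
  # denote the slow-mode (equilibrated-unit) limit, handled by the callers.
  f <- eig$c * exp(-eig$sigma_plus * age)
  s <- (1 - eig$c) * exp(-eig$sigma_minus * age)
  f[!is.finite(age) & eig$sigma_plus == 0] <- eig$c
  s[!is.finite(age) & eig$sigma_minus == 0] <- 1 - eig$c
  f + s
}

#' Instantaneous off rate of a single bound stator unit
#'
#' The hazard of unbinding for a unit of a given age,
#' \deqn{k_{-,i}(a) = -\frac{d \log S_i}{da} =
#'   \frac{c\,\sigma_+ e^{-\Delta\sigma a} + (1-c)\,\sigma_-}
#'        {c\, e^{-\Delta\sigma a} + (1-c)}.}
#' It starts at the bare loose-state off rate k_off,l at age 0 and decays
#' monotonically to the equilibrium value sigma- on the timescale
#' tau_e = 1/(sigma+ - sigma-), the memory effect that makes the motor-level
#' off process non-Markovian.
#'
#' @inheritParams unit_survival
#' @return Off rate (s^-1), in \[sigma-, k_off,l\].
#' @export
unit_off_rate <- function(age, eig) {
  eig <- as_eigen(eig)
  if (any(age < 0)) stop("age must be >= 0")
  w <- eig$c * exp(-eig$delta_sigma * age)
  w[!is.finite(age)] <- if (eig$delta_sigma == 0) eig$c else 0
  (w * eig$sigma_plus + (1 - eig$c) * eig$sigma_minus) / (w + (1 - eig$c))
}
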