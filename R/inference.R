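#' Microscopic rates from fitted eigen-parameters
#'
#' Inverts the eigen-decomposition of the two-bound-state sub-chain. In the
#' high-load regime sigma+ >> sigma- the relations simplify to the
#' `"approx"` form used for reporting:
#' k_off,l = c sigma+, k_t = (1 - c) sigma+, k_l = sigma- / c.
#' The `"exact"` inversion uses the Vieta identities without approximation:
#' k_off,l = c sigma+ + (1 - c) sigma-, k_l = sigma+ sigma- / k_off,l,
#' k_t = (sigma+ + sigma-) - k_off,l - k_l, and round-trips through
#' [eigen_rates()] to machine precision.
#'
#' @param c Fast-mode weight, in (0, 1\].
#' @param sigma_plus Fast eigenvalue (s^-1).
#' @param sigma_minus Slow eigenvalue (s^-1); when only an upper bound for
#'   sigma- is known, the returned k_l is the corresponding upper bound.
#' @param method `"approx"` (high-load relations, the reporting convention)
#'   or `"exact"`.
#' @return A list with `k_off_l`, `k_t`, `k_l` (s^-1) and `method`.
#' @examples
#' derive_microscopic_rates(c = 0.30, sigma_plus = 0.19,
#'                          sigma_minus = 0.0005)
#' @export
derive_microscopic_rates <- function(c, sigma_plus, sigma_minus,
                                     method = c("approx", "exact")) {
  method <- match.arg(method)
  if (c <= 0) stop("c = 0: k_l is undefined (no fast-mode weight)")
  if (c > 1 || sigma_plus < sigma_minus || sigma_minus < 0) {
    stop("need 0 < c <= 1 and sigma_plus >= sigma_minus >= 0")
  }
  if (method == "approx") {
    list(k_off_l = c * sigma_plus,
         k_t = (1 - c) * sigma_plus,
         k_l = sigma_minus / c,
         method = method)
  } else {
    k_off_l <- c * sigma_plus + (1 - c) * sigma_minus
    k_l <- sigma_plus * sigma_minus / k_off_l
    list(k_off_l = k_off_l,
         k_t = (sigma_plus + sigma_minus) - k_off_l - k_l,
         k_l = k_l,
         method = method)
  }
}

# Negative log-likelihood of a cleaned dwell table under eigen-parameters
# eig and plug-in k_plus per N. Each dwell's unit-age composition follows
# its entry type: entered by a binding event -> one fresh + N-1
# equilibrated units; entered from above or at the record start -> all
# equilibrated. Censored dwells contribute their survival probability, so
# record-end truncation is handled exactly rather than by exclusion.
dwell_neg_loglik <- function(table, eig, k_plus_by_N) {
  nll <- 0
  grp <- interaction(table$N, table$entry == "+", drop = TRUE)
  for (g in split(seq_len(nrow(table)), grp)) {
    N <- table$N[g[1]]
    kp <- k_plus_by_N[[as.character(N)]]
    if (is.null(kp) || !is.finite(kp)) next
    pol <- if (table$entry[g[1]] == "+" && N > 0) "fresh_equilibrated"
           else "all_equilibrated"
    ex <- survival_expansion(N, eig, k_plus = kp, age_policy = pol)
    tau <- table$tau[g]
    E <- exp(-outer(tau, ex$rate))
    S <- pmax(drop(E %*% ex$coef), 1e-300)
    end <- table$end[g]
    ll <- numeric(length(g))
    isp <- end == "+"
    ism <- end == "-"
    isc <- end == "censored"
    if (any(isp)) ll[isp] <- log(kp) + log(S[isp])
    if (any(ism)) {
      # P_minus(tau) = sum_j C_j (r_j - k_plus) e^{-r_j tau}
      dens <- drop(E[ism, , drop = FALSE] %*% (ex$coef * (ex$rate - kp)))
      ll[ism] <- log(pmax(dens, 1e-300))
    }
    if (any(isc)) ll[isc] <- log(S[isc])
    nll <- nll - sum(ll)
  }
  nll
}

# Model (mean_tau, f_plus, V) per N for eigen-parameters th and plug-in
# k_plus(N), under an age policy.
model_statistics <- function(eig, N, k_plus,
                             age_policy = "fresh_equilibrated") {
  out <- lapply(seq_along(N), function(i) {
    m <- dwell_moments(N[i], eig, k_plus = k_plus[i],
                       age_policy = age_policy)
    c(mean_tau = m$mean_tau, f_plus = m$f_plus, V = m$V)
  })
  as.data.frame(do.call(rbind, out))
}

#' Fit the bound-state eigen-parameters to per-N dwell statistics
#'
#' Two objectives are available. `objective = "moments"` is weighted least
#' squares over the per-N triples (mean_tau, f_plus, V) between the data
#' and the first-passage-time model, with weights equal to the inverse
#' bootstrap variances — the estimator that mirrors the headline
#' model-vs-data comparison. `objective = "likelihood"` (requires the
#' cleaned dwell `table`) maximises the per-dwell log-likelihood of
#' (tau, end type) with entry-type-aware unit ages and exact censoring
#' terms; because it sees the full distribution shape rather than three
#' moments, it resolves the (c, sigma+) trade-off that the moment triples
#' leave nearly flat, and is the recommended mode for parameter recovery.
#' In both modes the total on rate k_plus(N) is plugged in from the
#' empirical estimate f_plus / mean_tau, decoupling the on- and
#' off-process parameters (the identity f_plus = k_plus mean_tau would
#' make a joint fit degenerate). Free parameters: c (logit scale), sigma+
#' (log scale) and sigma- (log scale, lower bound 1e-6 s^-1). Optimisation
#' is Nelder-Mead from `n_starts` seeded random starting points.
#'
#' When the profile of the objective in sigma- is flat (within 2%) all the
#' way down to the lower bound, sigma- is reported as an upper bound
#' (`sigma_minus_is_upper_bound = TRUE`): the data then only constrain how
#' large the slow off rate can be.
#'
#' Both eigenvalues are constrained to a physically meaningful box:
#' sigma+ in \[`sigma_plus_range`\] (default 0.001–5 s^-1; faster
#' relaxation would be invisible at typical frame rates, slower would not
#' relax within a record) and sigma- in
#' \[`sigma_minus_lower`, `sigma_minus_upper`\].
#'
#' @param stats A `"dwell_stats"` with statistics for at least 3 levels.
#' @param table The cleaned `"dwell_table"` behind `stats`; required for
#'   `objective = "likelihood"`.
#' @param objective `"moments"` (default) or `"likelihood"`.
#' @param age_policy Age policy for the moments-mode model predictions
#'   (see [dwell_theory]); the likelihood mode sets ages per dwell from
#'   its entry type.
#' @param seed Seed for the multi-start draws.
#' @param n_starts Number of random restarts (>= 1; default 20).
#' @param sigma_minus_lower Lower bound for sigma- (s^-1).
#' @param sigma_minus_upper Upper bound for sigma- (s^-1).
#' @param sigma_plus_range Length-2 numeric bounds for sigma+ (s^-1).
#' @return A `"stator_fit"`: c, sigma_plus, sigma_minus,
#'   sigma_minus_is_upper_bound, derived microscopic rates, objective
#'   value, per-N model-vs-data table, age policy, seed.
#' @export
fit_bound_state_model <- function(stats, table = NULL,
                                  objective = c("moments", "likelihood"),
                                  age_policy = "fresh_equilibrated",
                                  seed = 1L, n_starts = 20L,
                                  sigma_minus_lower = 1e-6,
                                  sigma_minus_upper = 0.02,
                                  sigma_plus_range = c(1e-3, 5)) {
  stopifnot(inherits(stats, "dwell_stats"))
  objective_kind <- match.arg(objective)
  d <- stats$per_N
  d <- d[stats::complete.cases(d[, c("mean_tau", "f_plus", "V",
                                     "mean_tau_se", "f_plus_se", "V_se")]), ]
  d <- d[d$mean_tau_se > 0 & d$V_se > 0, , drop = FALSE]
  if (nrow(d) < 3L) stop("need dwell statistics for at least 3 levels of N")
  k_plus <- d$f_plus / d$mean_tau
  if (objective_kind == "likelihood") {
    if (is.null(table) || !inherits(table, "dwell_table")) {
      stop("objective = \"likelihood\" needs the cleaned dwell table")
    }
    k_plus_by_N <- stats::setNames(as.list(k_plus), d$N)
    table <- table[table$N %in% d$N, , drop = FALSE]
  }
  w_tau <- 1 / d$mean_tau_se^2
  w_f <- 1 / pmax(d$f_plus_se, 1e-3)^2
  w_V <- 1 / d$V_se^2
  objective <- function(th) {
    cc <- stats::plogis(th[1])
    sp <- exp(th[2])
    sm <- exp(th[3])
    if (sm >= sp || sp < sigma_plus_range[1] || sp > sigma_plus_range[2] ||
        sm < sigma_minus_lower / 2 || sm > sigma_minus_upper) {
      return(1e12)
    }
    eig <- tryCatch(eigen_decomp(cc, sp, sm), error = function(e) NULL)
    if (is.null(eig)) return(1e12)
    if (objective_kind == "likelihood") {
      v <- tryCatch(dwell_neg_loglik(table, eig, k_plus_by_N),
                    error = function(e) NULL)
      if (is.null(v) || !is.finite(v)) return(1e12)
      return(v)
    }
    pred <- tryCatch(model_statistics(eig, d$N, k_plus, age_policy),
                     error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(unlist(pred)))) return(1e12)
    sum(w_tau * (pred$mean_tau - d$mean_tau)^2) +
      sum(w_f * (pred$f_plus - d$f_plus)^2) +
      sum(w_V * (pred$V - d$V)^2)
  }
  set.seed(seed)
  starts <- cbind(stats::qlogis(stats::runif(n_starts, 0.05, 0.95)),
                  stats::runif(n_starts, log(0.02), log(1)),
                  stats::runif(n_starts, log(sigma_minus_lower),
                               log(sigma_minus_upper)))
  best <- NULL
  for (s in seq_len(n_starts)) {
    o <- tryCatch(
      stats::optim(starts[s, ], objective, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best) || best$value >= 1e12) {
    stop("bound-state fit failed to converge from any starting point")
  }
  cc <- stats::plogis(best$par[1])
  sp <- exp(best$par[2])
  sm <- max(exp(best$par[3]), sigma_minus_lower)
  # profile sigma- down to the bound: flat profile => only an upper bound
  prof <- vapply(exp(seq(log(sigma_minus_lower), log(sm), length.out = 8)),
                 function(smv) objective(c(best$par[1], best$par[2],
                                           log(smv))),
                 numeric(1))
  upper_bound <- all(prof <= best$value * 1.02 + 1e-12)
  rates <- derive_microscopic_rates(cc, sp, sm)
  eig <- eigen_decomp(cc, sp, sm)
  pred <- model_statistics(eig, d$N, k_plus, age_policy)
  structure(list(c = cc, sigma_plus = sp, sigma_minus = sm,
                 sigma_minus_is_upper_bound = upper_bound,
                 k_off_l = rates$k_off_l, k_t = rates$k_t, k_l = rates$k_l,
                 objective = best$value, objective_kind = objective_kind,
                 comparison = data.frame(N = d$N, k_plus = k_plus,
                                         data_mean_tau = d$mean_tau,
                                         model_mean_tau = pred$mean_tau,
                                         data_f_plus = d$f_plus,
                                         model_f_plus = pred$f_plus,
                                         data_V = d$V, model_V = pred$V),
                 age_policy = age_policy, seed = seed,
                 n_starts = n_starts),
            class = "stator_fit")
}

#' @export
print.stator_fit <- function(x, ...) {
  cat(sprintf("Bound-state fit: c = %.3g, sigma+ = %.3g s^-1, sigma- %s %.3g s^-1\n",
              x$c, x$sigma_plus,
              if (x$sigma_minus_is_upper_bound) "<=" else "=",
              x$sigma_minus))
  cat(sprintf("  derived: k_off,l = %.3g, k_t = %.3g, k_l %s %.3g s^-1\n",
              x$k_off_l, x$k_t,
              if (x$sigma_minus_is_upper_bound) "<=" else "=", x$k_l))
  cat(sprintf("  objective = %.4g (%s ages, %d restarts)\n",
              x$objective, x$age_policy, x$n_starts))
  invisible(x)
}

#' Fit the phenomenological on-rate curve k_on(N)
#'
#' Weighted least squares for (k_on0, A, B, C) of
#' k_on(N) = k_on0 (1 + A (1 - exp(-B N))) (1 - exp(-C / N)), by
#' multi-start Nelder-Mead on log/positivity-transformed parameters.
#' Flat data drive A toward 0 with large C (degenerate but valid).
#'
#' @param N Stator counts with on-rate estimates (>= 4 values).
#' @param k_on Estimated per-site on rates (s^-1).
#' @param se Standard errors (weights 1/se^2); default equal weights.
#' @param seed Seed for the restarts.
#' @param n_starts Number of restarts.
#' @return A list with `model` (an [on_rate_model()]), `objective`,
#'   `fitted` and `residuals`.
#' @export
fit_on_rate_model <- function(N, k_on, se = NULL, seed = 1L,
                              n_starts = 20L) {
  ok <- is.finite(k_on) & (if (is.null(se)) TRUE else is.finite(se) & se > 0)
  N <- N[ok]; k_on <- k_on[ok]
  w <- if (is.null(se)) rep(1, length(N)) else 1 / se[ok]^2
  if (length(N) < 4L) stop("need on-rate estimates for at least 4 levels of N")
  objective <- function(th) {
    m <- list(k_on0 = exp(th[1]), A = exp(th[2]), B = exp(th[3]),
              C = exp(th[4]))
    pred <- m$k_on0 * (1 + m$A * (1 - exp(-m$B * N))) *
      ifelse(N == 0, 1, 1 - exp(-m$C / pmax(N, 1e-300)))
    sum(w * (pred - k_on)^2)
  }
  set.seed(seed)
  k0 <- max(mean(k_on), 1e-8)
  starts <- cbind(log(k0) + stats::rnorm(n_starts, 0, 0.5),
                  log(stats::runif(n_starts, 0.01, 2)),
                  log(stats::runif(n_starts, 0.2, 5)),
                  log(stats::runif(n_starts, 0.5, 20)))
  best <- NULL
  for (s in seq_len(n_starts)) {
    o <- tryCatch(
      stats::optim(starts[s, ], objective, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("on-rate fit failed to converge")
  model <- on_rate_model(k_on0 = exp(best$par[1]), A = exp(best$par[2]),
                         B = exp(best$par[3]), C = exp(best$par[4]))
  fitted <- on_rate(N, model)
  list(model = model, objective = best$value, fitted = fitted,
       residuals = k_on - fitted, N = N, seed = seed)
}

#' Model dwell-statistic curves for a fitted model
#'
#' Forward evaluation of the first-passage-time model at the fitted
#' eigen-parameters: (mean_tau, f_plus, V) for each requested N, plus the
#' across-N mean and SD of V — the model-side band drawn against the data.
#'
#' @param fit A `"stator_fit"`.
#' @param N Stator counts to evaluate (default the fitted range).
#' @param k_plus Total on rates per N; default the plug-in values stored in
#'   the fit (N must then match the fitted levels).
#' @return A list with `curves` (data.frame N, mean_tau, f_plus, V),
#'   `V_mean`, `V_sd`.
#' @export
predict_statistics <- function(fit, N = fit$comparison$N, k_plus = NULL) {
  stopifnot(inherits(fit, "stator_fit"))
  if (is.null(k_plus)) {
    idx <- match(N, fit$comparison$N)
    if (any(is.na(idx))) {
      stop("k_plus must be supplied for N outside the fitted levels")
    }
    k_plus <- fit$comparison$k_plus[idx]
  }
  eig <- eigen_decomp(fit$c, fit$sigma_plus, fit$sigma_minus)
  pred <- model_statistics(eig, N, k_plus, fit$age_policy)
  curves <- cbind(N = N, pred)
  list(curves = curves, V_mean = mean(pred$V), V_sd = stats::sd(pred$V))
}
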