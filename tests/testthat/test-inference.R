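test_that("microscopic rates follow from the fitted eigen-parameters", {
  r <- derive_microscopic_rates(c = 0.30, sigma_plus = 0.19,
                                sigma_minus = 0.0005)
  expect_equal(r$k_off_l, 0.3 * 0.19)
  expect_equal(signif(r$k_off_l, 2), 0.057)
  expect_equal(r$k_t, 0.7 * 0.19)
  expect_equal(signif(r$k_t, 2), 0.13)
  expect_equal(r$k_l, 0.0005 / 0.3)
  expect_lte(signif(r$k_l, 2), 0.0017)
  expect_error(derive_microscopic_rates(0, 0.19, 0.0005), "undefined")
})

test_that("the exact inversion round-trips through eigen_rates", {
  set.seed(8)
  for (i in 1:25) {
    p <- random_params()
    e <- eigen_rates(p)
    r <- derive_microscopic_rates(e$c, e$sigma_plus, e$sigma_minus,
                                  method = "exact")
    expect_equal(r$k_off_l, p$k_off_l, tolerance = 1e-8)
    expect_equal(r$k_t, p$k_t, tolerance = 1e-7)
    expect_equal(r$k_l, p$k_l, tolerance = 1e-8)
  }
  # the high-load approximation round-trips within its own error
  r <- derive_microscopic_rates(0.30, 0.19, 0.0005)
  e2 <- eigen_rates(rate_params(k_on0 = 0.0037, k_off_l = r$k_off_l,
                                k_t = r$k_t, k_l = r$k_l))
  expect_equal(e2$sigma_plus, 0.19, tolerance = 0.01)
  expect_equal(e2$c, 0.30, tolerance = 0.02)
})

test_that("the moments fit is a fixed point of the forward map", {
  # statistics generated exactly by the model, tiny errors: the fit must
  # return the generating parameters
  cc <- 0.30; sp <- 0.19; sm <- 5e-4
  eig <- eigen_decomp(cc, sp, sm)
  Ns <- 0:8
  kp <- total_on_rate(Ns, reference_rate_params())
  rows <- lapply(seq_along(Ns), function(i) {
    m <- dwell_moments(Ns[i], eig, k_plus = kp[i])
    data.frame(N = Ns[i], n_dwells = 1000L, n_censored = 0L,
               f_plus = m$f_plus, mean_tau = m$mean_tau, V = m$V,
               f_plus_se = 0.01, mean_tau_se = m$mean_tau * 0.01,
               V_se = 0.01, k_plus = kp[i], k_on = NA_real_,
               k_plus_se = 1e-4, k_on_se = NA_real_)
  })
  st <- structure(list(per_N = do.call(rbind, rows), V_mean = NA,
                       V_sd = NA, n_censored_total = 0L, N_tot = 11L,
                       n_boot = 0L, seed = 1L),
                  class = "dwell_stats")
  fit <- fit_bound_state_model(st, seed = 5, n_starts = 40L)
  expect_equal(fit$c, cc, tolerance = 0.01)
  expect_equal(fit$sigma_plus, sp, tolerance = 0.01)
  expect_equal(fit$sigma_minus, sm, tolerance = 0.2)
  expect_equal(fit$k_off_l, 0.057, tolerance = 0.02)
})

test_that("single-bound-state data drive the fit to the V = 1 degeneracy", {
  # dwells truly exponential: model V(N) at the fit should be ~1 and the
  # fitted fast-mode weight should carry (almost) no excess variance
  p <- rate_params(k_on0 = 0.005, k_off_l = 0.03, N_tot = 11L)
  trajs <- simulate_ensemble(sim_config(p, scheme = "two_state",
                                        duration = 1500, seed = 19), 80)
  tab <- ensemble_dwells(trajs, 1500)
  st <- dwell_statistics(tab, n_boot = 100, seed = 3)
  fit <- fit_bound_state_model(st, table = tab, objective = "likelihood",
                               seed = 6)
  pred <- predict_statistics(fit)
  expect_lt(abs(pred$V_mean - 1), 0.25)
})

test_that("likelihood fitting recovers the generating eigen-parameters", {
  p <- ref_params()
  fits <- lapply(1:3, function(s) {
    trajs <- simulate_ensemble(sim_config(p, seed = s + 300), 58)
    tab <- ensemble_dwells(trajs, 360)
    st <- dwell_statistics(tab, n_boot = 100, seed = 2)
    fit_bound_state_model(st, table = tab, objective = "likelihood",
                          seed = s, n_starts = 12L)
  })
  e_true <- eigen_rates(p)
  errs_c <- vapply(fits, function(f) abs(f$c - e_true$c), numeric(1))
  errs_s <- vapply(fits, function(f) abs(f$sigma_plus - e_true$sigma_plus),
                   numeric(1))
  expect_lt(stats::median(errs_c), 0.11)
  expect_lt(stats::median(errs_s), 0.1)
})

test_that("the on-rate curve fit is exact on noiseless data and flat when flat", {
  truth <- on_rate_model(k_on0 = 0.0037, A = 0.23, B = 1.8, C = 3.8)
  N <- 0:8
  fit <- fit_on_rate_model(N, on_rate(N, truth), seed = 2, n_starts = 30L)
  expect_lt(max(abs(fit$fitted - on_rate(N, truth)) / on_rate(N, truth)),
            0.01)
  expect_equal(fit$model$k_on0, 0.0037, tolerance = 0.01)
  # flat data: fitted curve flat (A ~ 0 / C large degeneracy is fine)
  flat <- fit_on_rate_model(N, rep(0.005, 9), seed = 2)
  expect_lt(max(abs(flat$fitted - 0.005)) / 0.005, 0.02)
  expect_error(fit_on_rate_model(0:2, rep(0.005, 3)), "at least 4")
})

test_that("noisy on-rate data stay within a pointwise band of the truth", {
  truth <- on_rate_model(k_on0 = 0.0037, A = 0.23, B = 1.8, C = 3.8)
  N <- 0:8
  k_true <- on_rate(N, truth)
  set.seed(60)
  hits <- 0L; total <- 0L
  for (rep in 1:10) {
    obs <- k_true * (1 + rnorm(9, 0, 0.1))
    fit <- fit_on_rate_model(N, obs, se = k_true * 0.1, seed = rep,
                             n_starts = 15L)
    hits <- hits + sum(abs(fit$fitted - k_true) <= 2 * k_true * 0.1)
    total <- total + 9L
  }
  expect_gte(hits / total, 0.9)
})

test_that("model curves report the across-N V band", {
  # single bound state: V identically 1
  tab <- make_dwell_table(N = rep(c(1L, 2L, 3L), each = 4),
                          tau = rep(c(10, 12, 9, 11), 3),
                          end = rep(c("+", "-", "+", "-"), 3))
  st <- dwell_statistics(tab, n_boot = 50, seed = 1)
  fit0 <- structure(list(c = 1, sigma_plus = 0.05, sigma_minus = 0.05,
                         sigma_minus_is_upper_bound = FALSE,
                         comparison = data.frame(N = 1:3,
                                                 k_plus = rep(0.02, 3)),
                         age_policy = "fresh_equilibrated"),
                    class = "stator_fit")
  pred <- predict_statistics(fit0)
  expect_equal(pred$curves$V, rep(1, 3), tolerance = 1e-9)
  # the reference parameters give V well above 1 across N
  e <- eigen_rates(ref_params())
  fit1 <- structure(list(c = e$c, sigma_plus = e$sigma_plus,
                         sigma_minus = e$sigma_minus,
                         sigma_minus_is_upper_bound = FALSE,
                         comparison = data.frame(
                           N = 0:8,
                           k_plus = total_on_rate(0:8, ref_params())),
                         age_policy = "fresh_equilibrated"),
                    class = "stator_fit")
  pred1 <- predict_statistics(fit1)
  expect_gt(pred1$V_mean, 1.3)
  expect_lt(pred1$V_mean, 2.2)
})
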