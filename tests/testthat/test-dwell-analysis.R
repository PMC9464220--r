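test_that("dwell extraction follows the definition, censoring the last interval", {
  Nt <- data.frame(time_s = c(0, 30, 90), N = c(0L, 1L, 2L))
  tab <- extract_dwells(Nt, record_end_s = 150)
  expect_equal(tab$N, c(0L, 1L, 2L))
  expect_equal(tab$tau, c(30, 60, 60))
  expect_equal(tab$end, c("+", "+", "censored"))
  expect_equal(tab$entry, c("start", "+", "+"))
  # a single constant record is one censored dwell
  one <- extract_dwells(data.frame(time_s = 0, N = 3L), record_end_s = 100)
  expect_equal(nrow(one), 1L)
  expect_equal(one$end, "censored")
  # non-unit jumps flag an upstream step-fit failure
  expect_error(extract_dwells(data.frame(time_s = c(0, 10), N = c(0L, 2L))),
               "non-unit")
})

test_that("dwell counts agree with the simulator's event bookkeeping", {
  p <- ref_params()
  trajs <- simulate_ensemble(sim_config(p, seed = 31), 20)
  for (tr in trajs[1:5]) {
    Nt <- trajectory_N_of_t(tr)
    tab <- extract_dwells(Nt, record_end_s = 360, motor_id = tr$motor_id)
    expect_equal(nrow(tab), nrow(Nt))
    expect_equal(sum(tab$tau), 360)
  }
})

test_that("H excursions are spliced, conserving total observation time", {
  tab <- make_dwell_table(N = c(0L, 1L, 2L, 1L, 2L, 3L),
                          tau = c(20, 40, 15, 3, 50, 30),
                          end = c("+", "+", "-", "+", "+", "censored"))
  hc <- identify_h_states(tab, h_max = 10)
  expect_equal(hc$summary$N_H, 1L)
  expect_equal(hc$summary$tau_H, 3)
  cl <- hc$cleaned
  expect_equal(nrow(cl), 4L)
  expect_equal(cl$N, c(0L, 1L, 2L, 3L))
  expect_equal(cl$tau[3], 15 + 3 + 50)   # the spliced N = 2 dwell
  expect_equal(sum(cl$tau), sum(tab$tau))
  expect_equal(hc$summary$T_tot, sum(cl$N * cl$tau))
  expect_equal(hc$summary$k_mh, 1 / 3)
  # no pattern: table unchanged, summary empty
  hc2 <- identify_h_states(tab[1:2, ], h_max = 10)
  expect_equal(hc2$summary$N_H, 0L)
  expect_equal(nrow(hc2$cleaned), 2L)
  expect_error(identify_h_states(tab, h_max = 0), "h_max")
})

test_that("published-scale episode counts give the expected H rates", {
  est <- h_rate_estimators(N_H = 43, T_tot = 136620, tau_H = 4.1)
  expect_equal(est$k_h, 43 / 136620)
  expect_equal(est$k_h, 0.0003, tolerance = 0.05)
  expect_equal(est$k_mh, 1 / 4.1)
  expect_equal(est$k_mh, 0.24, tolerance = 0.02)
})

test_that("threshold H detection finds the true episodes in simulated data", {
  p <- ref_params()
  trajs <- simulate_ensemble(sim_config(p, seed = 23), 150)
  tab_obs <- ensemble_dwells_observable(trajs, 360)
  hc <- identify_h_states(tab_obs, h_max = 10)
  truth <- true_h_summary(trajs)
  # recall: nearly every true H episode is a short down-up excursion
  expect_gte(hc$summary$N_H, 0.9 * truth$N_H)
  # recovered reattachment rate is near the true one (false splices are
  # slower excursions, so the detector's tau_H is biased upward a little)
  expect_lt(abs(hc$summary$k_mh - p$k_mh), 0.12)
  expect_lt(hc$summary$k_h, 5 * p$k_h)
  expect_gt(hc$summary$k_h, p$k_h / 2)
})

test_that("per-N statistics handle degenerate and textbook cases", {
  tab <- make_dwell_table(N = rep(1L, 6), tau = rep(10, 6),
                          end = rep("+", 6),
                          entry = rep("+", 6))
  st <- dwell_statistics(tab, n_boot = 50, seed = 1)
  expect_equal(st$per_N$f_plus, 1)
  expect_equal(st$per_N$mean_tau, 10)
  expect_equal(st$per_N$V, 0)
  expect_equal(st$per_N$k_plus, 0.1)
  expect_equal(st$per_N$k_on, 0.1 / 10)
  # a level with fewer than 2 dwells is flagged, not fabricated
  tab2 <- make_dwell_table(N = c(1L, 2L, 1L), tau = c(5, 7, 9),
                           end = c("+", "-", "censored"))
  st2 <- dwell_statistics(tab2, n_boot = 50, seed = 1)
  expect_true(is.na(st2$per_N$V[st2$per_N$N == 2]))
  # i.i.d. exponential dwells drive V to 1
  set.seed(99)
  n <- 1e4
  tab3 <- make_dwell_table(N = rep(3L, n), tau = rexp(n, 0.1),
                           end = sample(c("+", "-"), n, replace = TRUE),
                           entry = rep("+", n))
  st3 <- dwell_statistics(tab3, n_boot = 50, seed = 2)
  expect_equal(st3$per_N$V, 1, tolerance = 0.1)
})

test_that("empirical on rates follow the first-passage identity", {
  tab <- make_dwell_table(N = rep(0L, 4), tau = rep(100, 4),
                          end = rep("+", 4), entry = rep("start", 4))
  st <- dwell_statistics(tab, n_boot = 20, seed = 1)
  on <- empirical_on_rates(st)
  expect_equal(on$k_plus, 0.01)
  expect_equal(on$k_on, 0.01 / 11)
  expect_equal(on$k_on, 9.09e-4, tolerance = 1e-3)
  # f_plus = 0 gives a zero on rate
  tabm <- make_dwell_table(N = rep(2L, 5), tau = 1:5,
                           end = rep("-", 5), entry = rep("-", 5))
  stm <- dwell_statistics(tabm, n_boot = 20, seed = 1)
  expect_equal(empirical_on_rates(stm)$k_plus, 0)
})

test_that("a constant per-site on rate is recovered flat across N", {
  p <- rate_params(k_on0 = 0.005, k_off_l = 0.02, N_tot = 11L)
  trajs <- simulate_ensemble(sim_config(p, scheme = "two_state",
                                        duration = 2000, seed = 41), 60)
  tab <- ensemble_dwells(trajs, 2000)
  st <- dwell_statistics(tab, n_boot = 200, seed = 3)
  on <- empirical_on_rates(st)
  ok <- !is.na(on$k_on) & !is.na(on$k_on_se) & st$per_N$n_dwells >= 50
  expect_gte(sum(ok), 4)
  covered <- abs(on$k_on[ok] - 0.005) <= 3 * on$k_on_se[ok]
  expect_gte(mean(covered), 0.75)
})

test_that("histograms bin at 3 s, conserve counts and show the four-state tail", {
  empty <- dwell_histogram(make_dwell_table(integer(0), numeric(0),
                                            character(0),
                                            entry = character(0)))
  expect_equal(nrow(empty), 0)
  tab <- make_dwell_table(N = rep(1L, 5), tau = c(0.5, 2, 4, 7.5, 100),
                          end = c(rep("+", 4), "censored"))
  h <- dwell_histogram(tab)
  expect_equal(sum(h$count), 4)   # censored dwell excluded
  expect_equal(h$bin_left[1:3], c(0, 3, 6))
  expect_equal(sum(h$density) * 3, 1)
  # the multi-state model has more mass beyond 50 s than fast two-state
  p4 <- ref_params()
  p2 <- rate_params(k_on0 = 0.0037, k_off_l = 0.05, N_tot = 11L)
  t4 <- ensemble_dwells(simulate_ensemble(sim_config(p4, seed = 2), 80), 360)
  t2 <- ensemble_dwells(simulate_ensemble(sim_config(p2,
                                                     scheme = "two_state",
                                                     seed = 2), 80), 360)
  tail4 <- mean(t4$tau[t4$end != "censored"] > 50)
  tail2 <- mean(t2$tau[t2$end != "censored"] > 50)
  expect_gt(tail4, tail2)
})

test_that("H-rate estimators tighten as the ensemble grows", {
  p <- ref_params()
  errs <- vapply(c(40, 120, 360), function(n) {
    trajs <- simulate_ensemble(sim_config(p, seed = 77), n)
    abs(true_h_summary(trajs)$k_mh - p$k_mh)
  }, numeric(1))
  expect_lt(errs[3], errs[1] + 0.02)
  expect_lt(errs[3], 0.05)
})
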