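# Brute-force two-segment residual scan, the oracle for best_changepoint.
brute_changepoint <- function(x, min_seg = 2L) {
  n <- length(x)
  best <- NULL
  for (l in seq.int(min_seg, n - min_seg)) {
    d <- sum((x[1:l] - mean(x[1:l]))^2) +
      sum((x[(l + 1):n] - mean(x[(l + 1):n]))^2)
    if (is.null(best) || d < best$delta - 1e-12) best <- list(l = l, delta = d)
  }
  best
}

test_that("median filter preserves constants, kills spikes, reduces variance", {
  expect_equal(median_filter(rep(2, 50)), rep(2, 50))
  x <- rep(1, 60); x[30] <- 25
  expect_equal(median_filter(x, 15), rep(1, 60))
  expect_error(median_filter(x, 4), "odd")
  set.seed(1)
  y <- rnorm(5000, 3, 0.4)
  expect_lt(var(median_filter(y, 15)), var(y) / 2)
  expect_length(median_filter(y, 15), 5000)
})

test_that("best_changepoint agrees with the brute-force oracle", {
  b <- best_changepoint(c(0, 0, 0, 5, 5, 5))
  expect_equal(b$l, 3)
  expect_equal(b$delta, 0)
  set.seed(7)
  for (i in 1:30) {
    n <- sample(6:80, 1)
    x <- round(rnorm(n), 2)   # rounding provokes exact ties
    got <- best_changepoint(x)
    want <- brute_changepoint(x)
    expect_equal(got$delta, want$delta, tolerance = 1e-9)
    expect_equal(got$l, want$l)
  }
  # perfectly linear ramp: symmetry puts the best split at the midpoint
  r <- best_changepoint(as.numeric(1:100))
  expect_equal(r$l, 50)
  # constant segment: all splits tie, smallest admissible index returned
  cst <- best_changepoint(rep(1, 20))
  expect_equal(cst$l, 2)
  expect_null(best_changepoint(c(1, 2, 3)))
})

test_that("noise-free staircases are recovered exactly with zero residual", {
  lv <- c(0, 1, 2, 1, 3, 4)
  x <- rep(lv, times = c(300, 200, 400, 150, 250, 300))
  fit <- fit_steps(x, seed = 2)
  expect_equal(fit$residual, 0)
  expect_equal(length(fit$level_values), 6)
  expect_equal(fit$level_values, lv)
  expect_equal(fit$changepoints, cumsum(c(300, 200, 400, 150, 250)))
})

test_that("white noise produces few or no change points", {
  set.seed(15)
  for (s in 1:5) {
    x <- rnorm(3000)
    fit <- fit_steps(x, seed = s)
    expect_lte(length(fit$changepoints), 5)
  }
})

test_that("the stored residual equals the from-scratch partition sum", {
  set.seed(3)
  x <- rep(c(0, 2, 5, 3), each = 500) + rnorm(2000, 0, 0.4)
  fit <- fit_steps(x, seed = 4)
  lo <- c(1L, fit$changepoints + 1L)
  hi <- c(fit$changepoints, length(x))
  manual <- sum(vapply(seq_along(lo), function(k) {
    seg <- x[lo[k]:hi[k]]
    sum((seg - mean(seg))^2)
  }, numeric(1)))
  expect_equal(fit$residual, manual, tolerance = 1e-9)
  # residual never increases as more change points are allowed
  fit_loose <- fit_steps(x, stop_ratio = 0.9999, seed = 4)
  expect_gte(length(fit_loose$changepoints), length(fit$changepoints))
  expect_lte(fit_loose$residual, fit$residual + 1e-9)
})

test_that("near-identical levels merge by duration-weighted average", {
  fit <- structure(list(changepoints = c(100L, 400L),
                        level_values = c(5.0, 5.5, 9.0),
                        seg_lengths = c(100L, 300L, 100L),
                        residual = 0, n_iterations = 2L, n = 500L),
                   class = "step_fit")
  m <- merge_levels(fit)
  expect_equal(m$merged_levels, c((5.0 * 100 + 5.5 * 300) / 400, 9.0))
  expect_equal(m$merged_levels[1], 5.375)
  # well-separated levels untouched
  fit2 <- structure(list(changepoints = c(10L, 20L),
                         level_values = c(0.1, 1.2, 2.1),
                         seg_lengths = c(10L, 10L, 10L),
                         residual = 0, n_iterations = 2L, n = 30L),
                    class = "step_fit")
  m2 <- merge_levels(fit2)
  expect_equal(m2$merged_levels, c(0.1, 1.2, 2.1))
  # idempotence: re-merging the merged levels changes nothing
  fit3 <- structure(list(changepoints = c(400L),
                         level_values = m$merged_levels,
                         seg_lengths = m$merged_weights,
                         residual = 0, n_iterations = 1L, n = 500L),
                    class = "step_fit")
  expect_equal(merge_levels(fit3)$merged_levels, m$merged_levels)
})

test_that("stator numbers count up from the near-zero level", {
  fit <- structure(list(changepoints = c(50L, 100L),
                        level_values = c(0.05, 1.0, 2.1),
                        seg_lengths = c(50L, 50L, 50L),
                        residual = 0, n_iterations = 2L, n = 150L),
                   class = "step_fit")
  asg <- assign_stator_numbers(merge_levels(fit))
  expect_equal(unname(asg$level_to_N), c(0L, 1L, 2L))
  expect_equal(asg$offset_applied, 0L)
  expect_equal(asg$N_of_t, rep(c(0L, 1L, 2L), each = 50))
  # no zero level observed: offset by the median spacing rule
  fit2 <- structure(list(changepoints = c(50L),
                         level_values = c(0.9, 1.95),
                         seg_lengths = c(50L, 50L),
                         residual = 0, n_iterations = 1L, n = 100L),
                    class = "step_fit")
  asg2 <- assign_stator_numbers(merge_levels(fit2))
  expect_equal(asg2$offset_applied, 1L)
  expect_equal(unname(asg2$level_to_N), c(1L, 2L))
})

test_that("the full pipeline is the identity on noise-free synthetic traces", {
  p <- ref_params()
  for (s in c(7, 21)) {
    cfg <- sim_config(p, seed = s, noise_sd = 0)
    tr <- simulate_motor(cfg)
    sp <- trajectory_to_speed(tr)
    ft <- fit_trace(sp, filter_order = 1L)
    Nt <- trajectory_N_of_t(tr)
    # frame-quantised ground truth N at each sample instant
    idx <- findInterval(sp$time_s, Nt$time_s)
    expect_equal(ft$assignment$N_of_t, Nt$N[idx])
  }
})

test_that("noisy traces recover transitions bracketed by long dwells", {
  p <- ref_params()
  n_found <- 0L; n_true <- 0L
  for (s in c(5, 9, 13, 27, 31, 44)) {
    cfg <- sim_config(p, seed = s, noise_sd = 0.4)
    tr <- simulate_motor(cfg)
    sp <- trajectory_to_speed(tr)
    ft <- fit_trace(sp)
    Nt <- trajectory_N_of_t(tr)
    durs <- diff(c(Nt$time_s, 360))
    # transitions with > 5 s of data on both sides
    well_sep <- which(durs[-length(durs)] > 5 & durs[-1] > 5)
    for (w in well_sep) {
      t_true <- Nt$time_s[w + 1]
      n_true <- n_true + 1L
      if (any(abs(ft$N_table$time_s - t_true) <= 1)) {
        n_found <- n_found + 1L
      }
    }
  }
  expect_gte(n_true, 30L)
  expect_gte(n_found / n_true, 0.95)
})
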