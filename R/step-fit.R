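#' Running median filter for speed traces
#'
#' Order-15 median filtering is the standard pre-processing step for
#' tethered-cell speed records: it suppresses per-frame tracking noise and
#' single-frame spikes while preserving the step edges that carry the
#' stator-number signal. Edges are handled by shrinking the window
#' (Tukey's endrule), so the output has the same length as the input.
#'
#' @param speed Numeric series (Hz).
#' @param order Window width, odd, >= 1; default 15 frames.
#' @return Filtered series of the same length.
#' @export
median_filter <- function(speed, order = 15L) {
  order <- as.integer(order)
  if (is.na(order) || order < 1L || order %% 2L == 0L) {
    stop("order must be an odd integer >= 1")
  }
  if (order == 1L || length(speed) < 2L) return(as.numeric(speed))
  as.numeric(stats::runmed(speed, k = min(order, length(speed) -
                                            (length(speed) + 1) %% 2),
                           endrule = "median"))
}

# Cumulative sums for O(1) segment residuals: sum of squared deviations
# from the mean of x[i..j] (vectorised over i, j).
make_ss <- function(x) {
  s1 <- c(0, cumsum(x))
  s2 <- c(0, cumsum(x^2))
  function(i, j) {
    n <- j - i + 1
    pmax(s2[j + 1] - s2[i] - (s1[j + 1] - s1[i])^2 / n, 0)
  }
}

#' Best single change point of a segment
#'
#' Exhaustively scans every admissible split of `x` into a left part
#' x\[1..l\] and a right part x\[(l+1)..n\] and returns the l minimising the
#' total sum of squared deviations of each part from its own mean (the
#' two-segment residual). Ties are broken by the smallest l, so the result
#' is deterministic.
#'
#' @param x Numeric segment.
#' @param min_seg Minimum samples per part (default 2, so no single-point
#'   levels are created).
#' @return A list with `l` (last index of the left part), `delta` (the
#'   two-segment residual), `delta0` (the unsplit residual); or NULL when
#'   the segment is too short to split.
#' @export
best_changepoint <- function(x, min_seg = 2L) {
  n <- length(x)
  if (n < 2L * min_seg) return(NULL)
  ss <- make_ss(x)
  ls <- seq.int(min_seg, n - min_seg)
  d <- ss(rep.int(1L, length(ls)), ls) + ss(ls + 1L, rep.int(n, length(ls)))
  b <- which.min(d)   # which.min takes the first minimum: smallest l on ties
  list(l = ls[b], delta = d[b], delta0 = unname(ss(1L, n)))
}

# Total residual (Eq.-9-style sum over segments) of a partition of x given
# internal boundaries cp (sorted last-indices of all segments but the last).
partition_residual <- function(ss, n, cp) {
  lo <- c(1L, cp + 1L)
  hi <- c(cp, n)
  sum(ss(lo, hi))
}

# Residual reduction achieved by inserting cut t into the partition cp
# (vectorised over t): the cut splits only its containing segment.
insertion_reduction <- function(ss, n, cp, t) {
  lo <- c(1L, cp + 1L)
  hi <- c(cp, n)
  k <- findInterval(t, lo)
  red <- ss(lo[k], hi[k]) - ss(lo[k], t) - ss(t + 1L, hi[k])
  red[t >= hi[k] | t < lo[k]] <- 0   # cut on an existing boundary
  red
}

# Best split of x[lo..hi] using the trace-wide ss function; returns the
# absolute split index and the residual reduction (NULL if unsplittable).
best_split_global <- function(ss, lo, hi, min_seg) {
  len <- hi - lo + 1L
  if (len < 2L * min_seg) return(NULL)
  ls <- seq.int(lo + min_seg - 1L, hi - min_seg)
  d <- ss(rep.int(lo, length(ls)), ls) + ss(ls + 1L, rep.int(hi, length(ls)))
  b <- which.min(d)
  list(l = ls[b], red = unname(ss(lo, hi)) - d[b])
}

#' Fit a step function to a speed trace by recursive change-point insertion
#'
#' Greedy residual-minimising partition with a randomised stopping rule.
#' Starting from a single segment, each iteration inserts the change point
#' that most reduces the total residual Delta (the sum over segments of
#' squared deviations from the segment mean). Over-fitting is controlled by
#' comparing against chance: for each candidate insertion the fitted
#' residual Delta_min is divided by the mean residual Delta_tilde obtained
#' when the additional step is instead placed at `n_random` uniformly
#' random instants, the already-fitted steps kept; once
#' Delta_min / Delta_tilde > `stop_ratio` (default 0.995, i.e. the
#' computed step improves the fit by less than 0.5% over a randomly
#' placed one) the candidate is rejected and fitting stops. Randomising
#' only the new step is what makes the rule terminate at the true number
#' of steps: a reference partition that never contains the already-found
#' steps would keep the full staircase structure in Delta_tilde, and the
#' ratio would stay far below 1 long after the real steps were exhausted.
#'
#' @param speed Numeric series (Hz), length >= 2. Typically already
#'   median-filtered; [fit_steps()] does not filter.
#' @param stop_ratio Stopping threshold for Delta_min / Delta_tilde.
#' @param n_random Number of random partitions behind Delta_tilde.
#' @param seed Integer seed for the random partitions.
#' @param min_seg Minimum segment length in frames.
#' @return A `"step_fit"`: `changepoints` (last index of each segment except
#'   the final one), `level_values` (segment means, Hz), `seg_lengths`
#'   (frames), `residual` (Delta, Hz^2), `n_iterations`.
#' @export
fit_steps <- function(speed, stop_ratio = 0.995, n_random = 100L,
                      seed = 1L, min_seg = 2L) {
  x <- as.numeric(speed)
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  ss <- make_ss(x)
  set.seed(seed)
  cp <- integer(0)
  delta0 <- unname(ss(1L, n))
  delta <- delta0
  admissible <- seq.int(min_seg, n - min_seg)
  # cached per-segment best splits, keyed by segment start
  segs <- list(`1` = c(lo = 1L, hi = n, l = NA, red = NA))
  segs[["1"]][c("l", "red")] <- {
    b <- best_split_global(ss, 1L, n, min_seg)
    if (is.null(b)) c(NA, -Inf) else c(b$l, b$red)
  }
  repeat {
    reds <- vapply(segs, function(s) s[["red"]], numeric(1))
    k <- which.max(reds)
    if (!is.finite(reds[k]) || reds[k] <= 0) break
    s <- segs[[k]]
    cand <- sort(c(cp, as.integer(s[["l"]])))
    delta_min <- delta - reds[k]
    # chance reference: the additional step placed uniformly at random
    # instead of at the computed optimum, existing steps kept
    if (length(admissible) >= 1L) {
      rt <- sample(admissible, n_random, replace = TRUE)
      delta_tilde <- delta - mean(insertion_reduction(ss, n, cp, rt))
      if (delta_tilde <= 0 || delta_min / delta_tilde > stop_ratio) break
    }
    cp <- cand
    delta <- delta_min
    # replace the split segment by its two children in the cache
    for (child in list(c(s[["lo"]], s[["l"]]), c(s[["l"]] + 1L, s[["hi"]]))) {
      b <- best_split_global(ss, as.integer(child[1]), as.integer(child[2]),
                             min_seg)
      segs[[as.character(child[1])]] <-
        c(lo = as.integer(child[1]), hi = as.integer(child[2]),
          l = if (is.null(b)) NA else b$l,
          red = if (is.null(b)) -Inf else b$red)
    }
    if (delta <= 1e-12 * delta0) break  # perfect fit
  }
  lo <- c(1L, cp + 1L)
  hi <- c(cp, n)
  levels <- vapply(seq_along(lo),
                   function(k) mean(x[lo[k]:hi[k]]), numeric(1))
  structure(list(changepoints = cp, level_values = levels,
                 seg_lengths = hi - lo + 1L,
                 residual = partition_residual(ss, n, cp),
                 n_iterations = length(cp), n = n,
                 stop_ratio = stop_ratio, seed = seed),
            class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("Step fit: %d segments (%d change points), residual = %.4g\n",
              length(x$level_values), length(x$changepoints), x$residual))
  invisible(x)
}

#' Merge nearly-equal fitted levels
#'
#' Distinct fitted segments often share a stator number. Levels are sorted
#' ascending and, while any two consecutive level values differ by less
#' than `threshold` (default 0.75 Hz, under a 1 Hz-per-unit spacing), the
#' closest pair is replaced by its duration-weighted average. The result is
#' a fixed point: merging twice changes nothing.
#'
#' @param fit A `"step_fit"`.
#' @param threshold Minimum gap between distinct levels (Hz).
#' @return A `"level_assignment"`: `merged_levels` (ascending, Hz),
#'   `merged_weights` (frames), and `segment_group` mapping each fitted
#'   segment to its merged level.
#' @export
merge_levels <- function(fit, threshold = 0.75) {
  stopifnot(inherits(fit, "step_fit"))
  ord <- order(fit$level_values)
  vals <- fit$level_values[ord]
  wts <- as.numeric(fit$seg_lengths[ord])
  group <- as.list(ord)   # fitted-segment indices behind each merged level
  while (length(vals) > 1L) {
    gaps <- diff(vals)
    g <- which.min(gaps)
    if (gaps[g] >= threshold) break
    w <- wts[g] + wts[g + 1L]
    vals[g] <- (vals[g] * wts[g] + vals[g + 1L] * wts[g + 1L]) / w
    wts[g] <- w
    group[[g]] <- c(group[[g]], group[[g + 1L]])
    vals <- vals[-(g + 1L)]; wts <- wts[-(g + 1L)]; group <- group[-(g + 1L)]
  }
  segment_group <- integer(length(fit$level_values))
  for (m in seq_along(group)) segment_group[group[[m]]] <- m
  structure(list(merged_levels = vals, merged_weights = wts,
                 segment_group = segment_group, fit = fit),
            class = "level_assignment")
}

#' @export
print.level_assignment <- function(x, ...) {
  cat("Merged speed levels (Hz):",
      paste(sprintf("%.3g", x$merged_levels), collapse = ", "), "\n")
  invisible(x)
}

#' Assign stator numbers to merged levels
#'
#' Levels are numbered consecutively from the bottom: the lowest merged
#' level gets N = 0 when it lies within `zero_tol` of 0 Hz, and each
#' subsequent level adds one unit. When no near-zero level was observed
#' (the motor never emptied during the record) the numbering is offset by
#' round(lowest level / median level spacing) and the result is flagged.
#'
#' @param levels A `"level_assignment"`.
#' @param zero_tol Tolerance for calling the lowest level "zero" (Hz).
#' @return A `"stator_series"`: `N_of_t` (integer per frame),
#'   `level_to_N`, `offset_applied`, and a per-segment step table
#'   (start_idx, end_idx, level_hz, N).
#' @export
assign_stator_numbers <- function(levels, zero_tol = 0.5) {
  stopifnot(inherits(levels, "level_assignment"))
  fit <- levels$fit
  vals <- levels$merged_levels
  offset <- 0L
  if (vals[1] > zero_tol) {
    spacing <- if (length(vals) > 1L) stats::median(diff(vals)) else vals[1]
    offset <- as.integer(round(vals[1] / spacing))
  }
  level_to_N <- offset + seq_along(vals) - 1L
  seg_N <- level_to_N[levels$segment_group]
  lo <- c(1L, fit$changepoints + 1L)
  hi <- c(fit$changepoints, fit$n)
  N_of_t <- integer(fit$n)
  for (k in seq_along(lo)) N_of_t[lo[k]:hi[k]] <- seg_N[k]
  structure(list(N_of_t = N_of_t,
                 level_to_N = stats::setNames(level_to_N,
                                              sprintf("%.6g", vals)),
                 offset_applied = offset,
                 steps = data.frame(start_idx = lo, end_idx = hi,
                                    level_hz = vals[levels$segment_group],
                                    N = seg_N)),
            class = "stator_series")
}

#' @export
print.stator_series <- function(x, ...) {
  cat(sprintf("Stator-number series: %d segments, N in [%d, %d]%s\n",
              nrow(x$steps), min(x$steps$N), max(x$steps$N),
              if (x$offset_applied > 0)
                sprintf(" (offset +%d: no zero level observed)",
                        x$offset_applied) else ""))
  invisible(x)
}

#' Full step-fitting pipeline for one speed trace
#'
#' Absolute value, median filter, step fit, level merge and stator-number
#' assignment in one call. Returns the stator series together with the
#' intermediate fit objects and a per-dwell-ready N(t) table.
#'
#' @param trace A `"speed_trace"` or data.frame with columns time_s,
#'   speed_hz.
#' @param filter_order Median filter order (frames).
#' @param stop_ratio,n_random,seed,min_seg Passed to [fit_steps()].
#' @param merge_threshold Passed to [merge_levels()] (Hz).
#' @param zero_tol Passed to [assign_stator_numbers()] (Hz).
#' @return A list with `assignment` (`"stator_series"`), `fit`, `levels`,
#'   and `N_table` (time_s, N) of the fitted stepwise count.
#' @export
fit_trace <- function(trace, filter_order = 15L, stop_ratio = 0.995,
                      n_random = 100L, seed = 1L, min_seg = 2L,
                      merge_threshold = 0.75, zero_tol = 0.5) {
  stopifnot(all(c("time_s", "speed_hz") %in% names(trace)))
  # filter before rectifying: the median commutes with the sign flip for a
  # consistently counter-clockwise motor, while |noise| around a 0 Hz
  # level would bias the empty-motor level upward by E|noise| ~ 0.3 Hz
  # and can push the 0-1 gap under the merge threshold
  x <- abs(median_filter(trace$speed_hz, filter_order))
  fit <- fit_steps(x, stop_ratio = stop_ratio, n_random = n_random,
                   seed = seed, min_seg = min_seg)
  lv <- merge_levels(fit, merge_threshold)
  asg <- assign_stator_numbers(lv, zero_tol)
  N_table <- data.frame(time_s = trace$time_s[asg$steps$start_idx],
                        N = asg$steps$N)
  # consecutive segments can share an N after merging; keep true changes only
  keep <- c(TRUE, diff(N_table$N) != 0L)
  end_time <- trace$time_s[length(trace$time_s)] +
    (trace$time_s[2] - trace$time_s[1])
  list(assignment = asg, fit = fit, levels = lv,
       N_table = N_table[keep, , drop = FALSE],
       record_end_s = end_time)
}
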