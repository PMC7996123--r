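# Result-generation procedures: steady-state detection, minimum
# sufficient HC capacity (MSHC) search, policy comparison table,
# sensitivity sweeps, analytic steady-state oracle, FIT score.

#' Detect the steady state of a series
#'
#' A series is considered steady from the first period after which its
#' per-period change never again exceeds `tolerance` through the end of
#' the horizon.  At least `window` quiet periods must follow, so a series
#' still moving at the end (e.g. strictly increasing) has no steady
#' state.  The steady value is reported rounded to 2 decimals.
#'
#' @param series Finite numeric series (element 1 is period 0).
#' @param tolerance Maximum per-period absolute change counted as "no
#'   change" (default 0.001 HP pc units per period).
#' @param window Minimum number of quiet periods required after the
#'   detected time.
#' @return List with `time` (period index) and `value` (series value at
#'   that period, rounded to 2 decimals), or `NULL` if the series never
#'   steadies within the horizon.
#' @export
#' @examples
#' detect_steady(rep(5, 10))$time  # 0
detect_steady <- function(series, tolerance = 0.001, window = 3) {
  stopifnot(all(is.finite(series)))
  n <- length(series)
  if (n <= window) return(NULL)
  d <- abs(diff(series))  # d[u] = change into period u (u = 1..n-1)
  loud <- which(d > tolerance)
  # steady from the first period whose change from its predecessor is
  # negligible, i.e. one past the last loud change
  time <- if (length(loud)) loud[length(loud)] + 1L else 0L
  if ((n - 1L) - time < window) return(NULL)
  list(time = time, value = round(series[time + 1L], 2))
}

# Shared summary of a run at a given policy/capacity: end populations,
# steady HP pc values, and the time of steady HP.  The immigrant group
# settles after the natives while it persists, so its steadying time is
# reported; once it is (effectively) gone the natives' time is.
.policy_summary <- function(trace) {
  endrow <- trace[nrow(trace), ]
  st_i <- detect_steady(trace$di_hppc_s)
  st_n <- detect_steady(trace$dn_hppc_s)
  immigrants_persist <- round(endrow$di_pop_s) > 0
  st_t <- if (immigrants_persist) st_i else st_n
  list(
    di_pop_t60 = endrow$di_pop_s,
    dn_pop_t60 = endrow$dn_pop_s,
    di_steady_hp = if (is.null(st_i)) NA_real_ else st_i$value,
    dn_steady_hp = if (is.null(st_n)) NA_real_ else st_n$value,
    steady_time = if (is.null(st_t)) NA_integer_ else st_t$time
  )
}

# Is a capacity sufficient: total HC need for provision never exceeds it
# over t = 1..endtime.
.capacity_sufficient <- function(barrier, quality, spillover, capacity,
                                 endtime, seed) {
  s <- policy_storyline(barrier, quality, spillover, capacity,
                        endtime = endtime, seed = seed)
  tr <- run_simulation(s)
  tnfp <- tr$d_tnhcfp_a[tr$t >= 1]
  all(tnfp <= capacity)
}

#' Minimum sufficient HC capacity for a policy
#'
#' Finds the smallest integer HC capacity for which the total HC need for
#' provision (TNFP) never exceeds the capacity over periods 1 to the end
#' time, under an S2-style storyline with the given immigrant HC barrier
#' and quality.  Integer bisection; by minimality, capacity `mshc - 1`
#' leaves at least one shortage period.
#'
#' @param barrier Immigrant HC barrier in `[0, 1]`.
#' @param quality Immigrant HC quality in `[0, 1]`.
#' @param spillover Symmetric HP pc spillover share (default 0.02).
#' @param lower,upper Capacity search bounds; the upper bound is widened
#'   (doubling, up to `max_upper`) if infeasible.
#' @param max_upper Hard cap on the search; an explicit error is raised
#'   if even this capacity is insufficient.
#' @param endtime,seed Passed to the storyline.
#' @return List of class `mshc_result`: `barrier`, `quality`, `mshc`, and
#'   the summary of the run at that capacity (`di_pop_t60`, `dn_pop_t60`,
#'   `di_steady_hp`, `dn_steady_hp`, `steady_time`).
#' @export
find_mshc <- function(barrier, quality, spillover = 0.02,
                      lower = 0, upper = 16384, max_upper = 2^20,
                      endtime = 60L, seed = 1L) {
  feas <- function(cap) .capacity_sufficient(barrier, quality, spillover,
                                             cap, endtime, seed)
  while (!feas(upper)) {
    if (upper >= max_upper) {
      stop(sprintf("find_mshc: capacity %d is still insufficient", upper))
    }
    upper <- min(upper * 2, max_upper)
  }
  lo <- as.integer(lower) - 1L  # infeasible (or below any capacity)
  hi <- as.integer(upper)      # feasible
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (feas(mid)) hi <- mid else lo <- mid
  }
  s <- policy_storyline(barrier, quality, spillover, hi,
                        endtime = endtime, seed = seed)
  tr <- run_simulation(s)
  res <- c(list(barrier = barrier, quality = quality, mshc = hi),
           .policy_summary(tr))
  structure(res, class = "mshc_result")
}

#' @export
print.mshc_result <- function(x, ...) {
  cat(sprintf("<mshc_result> b=%g, q=%g: MSHC %d\n", x$barrier, x$quality,
              x$mshc))
  cat(sprintf("  t-60 populations: immigrants %.0f, natives %.0f\n",
              x$di_pop_t60, x$dn_pop_t60))
  cat(sprintf("  steady HP pc: immigrants %.2f, natives %.2f (by t %d)\n",
              x$di_steady_hp, x$dn_steady_hp, x$steady_time))
  invisible(x)
}

#' Policy comparison table
#'
#' Runs [find_mshc()] for each `(barrier, quality)` policy and assembles
#' one row per policy: MSHC, end populations (rounded to integers for
#' display), steady HP pc values, and time of steady HP.
#'
#' @param policies Data frame with columns `barrier` and `quality`.
#' @param ... Passed to [find_mshc()].
#' @return Data frame, one row per policy.
#' @export
#' @examples
#' \donttest{
#' policy_table(data.frame(barrier = c(0.25, 0), quality = c(0.75, 1)))
#' }
policy_table <- function(policies, ...) {
  stopifnot(is.data.frame(policies),
            all(c("barrier", "quality") %in% names(policies)))
  rows <- lapply(seq_len(nrow(policies)), function(i) {
    r <- find_mshc(policies$barrier[i], policies$quality[i], ...)
    data.frame(barrier = r$barrier, quality = r$quality, mshc = r$mshc,
               di_pop_t60 = round(r$di_pop_t60),
               dn_pop_t60 = round(r$dn_pop_t60),
               di_steady_hp = r$di_steady_hp,
               dn_steady_hp = r$dn_steady_hp,
               steady_time = r$steady_time)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Sweep one storyline input over a list of values
#'
#' Runs independent simulations sharing the seed, one per value of the
#' swept input.  The parameter path addresses a field of the storyline,
#' e.g. `"parameters.dn_dihppc_p"` or `"scenarios.di_hcb_x"` (a scenario
#' path sets the whole series to the value).
#'
#' @param s A [storyline()].
#' @param path Character path of the form `"parameters.<name>"` or
#'   `"scenarios.<name>"`.
#' @param values Numeric vector of values to sweep.
#' @return Named list of `simulation_trace` objects, keyed by value.
#' @export
parameter_sweep <- function(s, path, values) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[1] %in% c("parameters", "scenarios")) {
    stop("parameter_sweep: 'path' must be 'parameters.<name>' or 'scenarios.<name>'")
  }
  field <- parts[2]
  if (is.null(s[[parts[1]]][[field]])) {
    stop(sprintf("parameter_sweep: unknown path '%s'", path))
  }
  traces <- lapply(values, function(v) {
    sv <- s
    if (parts[1] == "parameters") {
      sv$parameters[[field]] <- v
    } else {
      sv$scenarios[[field]] <- v
    }
    run_simulation(sv)
  })
  names(traces) <- as.character(values)
  traces
}

#' Analytic steady-state HP pc under sufficient capacity
#'
#' With capacity always sufficient, provision equals need and each
#' group's HP pc flow vanishes where
#' `q(1-b) * (h_i - threshold) = (w + tne) + s * h_n` (immigrants) and
#' `1 * (h_n - threshold) = (w + tne) + s * h_i` (natives, full access
#' and perfect quality).  Solves this 2-by-2 linear system.
#'
#' @param barrier Immigrant HC barrier `b` in `[0, 1)`.
#' @param quality Immigrant HC quality `q` in `(0, 1]`; requires
#'   `q * (1 - b) > 0` (else no finite steady state exists).
#' @param spillover Symmetric HP pc spillover share `s`.
#' @param wear Wear & tear per period (default 2).
#' @param tne TNE impact on the HP pc flows (default -1).
#' @param threshold HP pc threshold for HC need (default 48).
#' @return List with `di_steady_hp` and `dn_steady_hp`.
#' @export
#' @examples
#' steady_hp_oracle(0, 1, 0)        # both 49
#' steady_hp_oracle(0.25, 0.75, 0.02)
steady_hp_oracle <- function(barrier, quality, spillover,
                             wear = 2, tne = -1, threshold = 48) {
  a <- quality * (1 - barrier)
  if (a <= 0) {
    stop("steady_hp_oracle: q * (1 - b) = 0 admits no finite steady state")
  }
  base <- wear + tne
  # a * (h_i - th) - s * h_n = base ;  -s * h_i + (h_n - th) = base
  A <- rbind(c(a, -spillover), c(-spillover, 1))
  rhs <- c(base + a * threshold, base + threshold)
  h <- solve(A, rhs)
  list(di_steady_hp = h[1], dn_steady_hp = h[2])
}

#' Sum-of-squares fit between a simulated and an observed series
#'
#' @param simulated,observed Equal-length numeric series.
#' @return `sum((simulated - observed)^2)`.
#' @export
#' @examples
#' fit_score(c(1, 2), c(0, 0))  # 5
fit_score <- function(simulated, observed) {
  if (length(simulated) != length(observed)) {
    stop("fit_score: series lengths differ")
  }
  sum((simulated - observed)^2)
}
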