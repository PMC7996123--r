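# Simulation loop: advance the nine stocks period by period, recording
# every auxiliary and flow, until the end time.

# Compute all auxiliaries and flows for one period from current stocks.
compute_period <- function(t, stocks, lag, s, stream) {
  scen <- as.list(s$scenarios[t + 1L, ])
  ov <- s$controllers == "override"
  oc <- conflict_step("origin", stocks,
                      list(cr = lag[["o_cr_a"]], ci = lag[["o_ci_a"]]),
                      scen, s$bank, ov[["o_ci_a"]], stream)
  dc <- conflict_step("destination", stocks,
                      list(cr = lag[["d_cr_a"]], ci = lag[["d_ci_a"]]),
                      scen, s$bank, ov[["d_ci_a"]], stream)
  mig <- migration_step(stocks, oc$intensity, dc$intensity, scen, s$bank,
                        c(od_nm_a = unname(ov[["od_nm_a"]]),
                          od_imhppc_a = unname(ov[["od_imhppc_a"]])))
  of <- origin_flows(stocks, oc$intensity, mig, scen, s$parameters,
                     s$bank, stream)
  df <- destination_flows(stocks, dc$intensity, mig, scen, s$parameters,
                          s$bank, stream)
  rec <- c(list(t = t,
                o_cr_a = oc$risk, o_ci_a = oc$intensity,
                d_cr_a = dc$risk, d_ci_a = dc$intensity),
           mig, of, df, as.list(stocks))
  bad <- names(rec)[!vapply(rec, function(v) all(is.finite(v)), logical(1))]
  if (length(bad)) {
    stop(sprintf("non-finite value(s) at period %d: %s",
                 t, paste(bad, collapse = ", ")))
  }
  rec
}

#' Advance a simulation by one period
#'
#' Computes every auxiliary and flow for period `t` from the current
#' stocks, then returns the stocks for `t + 1` (stock + flow, floored at
#' 0).  A group whose population hits 0 has its HP pc stock set to 0 by
#' the zero-population per-capita rule.  Clamp events are returned so the
#' engine can log them.
#'
#' @param t Period index.
#' @param stocks Named numeric vector of the nine stocks at `t`.
#' @param lag Named vector of the prior period's conflict risk/intensity
#'   per site (`o_cr_a`, `o_ci_a`, `d_cr_a`, `d_ci_a`).
#' @param s A [storyline()].
#' @param stream A [random_stream()].
#' @return List with `record` (all auxiliaries/flows/stocks of period
#'   `t`), `stocks` (at `t + 1`), `lag` (for `t + 1`), and `clamps`
#'   (data frame of clamp events, possibly empty).
#' @export
simulate_step <- function(t, stocks, lag, s, stream) {
  rec <- compute_period(t, stocks, lag, s, stream)
  flows <- c(o_pop_s = rec$o_pop_f, o_hppc_s = rec$o_hppc_f,
             o_ep_s = rec$o_ep_f,
             di_pop_s = rec$di_pop_f, di_hppc_s = rec$di_hppc_f,
             di_ep_s = rec$di_ep_f,
             dn_pop_s = rec$dn_pop_f, dn_hppc_s = rec$dn_hppc_f,
             dn_ep_s = rec$dn_ep_f)
  raw <- stocks[.stock_names] + flows[.stock_names]
  clamps <- data.frame(t = integer(0), variable = character(0),
                       raw = numeric(0))
  nxt <- raw
  for (nm in .stock_names) {
    if (raw[[nm]] < 0) {
      nxt[[nm]] <- 0
      clamps <- rbind(clamps,
                      data.frame(t = t + 1L, variable = nm, raw = raw[[nm]]))
    }
  }
  # zero-population rule: per-capita stocks of an empty group are 0
  for (grp in c("o", "di", "dn")) {
    pop <- nxt[[paste0(grp, "_pop_s")]]
    hp <- paste0(grp, "_hppc_s")
    if (pop == 0 && nxt[[hp]] != 0) {
      clamps <- rbind(clamps,
                      data.frame(t = t + 1L, variable = hp, raw = nxt[[hp]]))
      nxt[[hp]] <- 0
    }
  }
  list(record = rec, stocks = nxt,
       lag = c(o_cr_a = rec$o_cr_a, o_ci_a = rec$o_ci_a,
               d_cr_a = rec$d_cr_a, d_ci_a = rec$d_ci_a),
       clamps = clamps)
}

#' Run a storyline to its end time
#'
#' Validates the storyline, then iterates [simulate_step()] for
#' `t = 0, ..., endtime_p`, recording every auxiliary, flow, and stock.
#' Flows and auxiliaries are also computed at the final period (stocks
#' are no longer updated).  Deterministic given the seed.
#'
#' @param s A [storyline()].
#' @param seed Optional seed overriding the storyline's.
#' @return A `simulation_trace`: a data frame with one row per period and
#'   one column per variable, with attributes `storyline`, `seed`, and
#'   `clamp_events` (data frame of stock floors and per-capita zeroings).
#' @export
#' @examples
#' tr <- run_simulation(build_storyline("S1"))
#' tr$di_hppc_s[tr$t == 10]  # 49
run_simulation <- function(s, seed = NULL) {
  validate_storyline(s)
  if (is.null(seed)) seed <- s$seed
  stream <- random_stream(seed)
  endtime <- s$parameters$endtime_p
  stocks <- s$init[.stock_names]
  lag <- s$init_lag
  rows <- vector("list", endtime + 1L)
  clamp_log <- list()
  for (t in 0:endtime) {
    step <- simulate_step(t, stocks, lag, s, stream)
    rows[[t + 1L]] <- step$record
    if (t < endtime) {
      stocks <- step$stocks
      lag <- step$lag
      if (nrow(step$clamps)) clamp_log[[length(clamp_log) + 1L]] <- step$clamps
    }
  }
  trace <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  rownames(trace) <- NULL
  attr(trace, "storyline") <- s
  attr(trace, "seed") <- seed
  attr(trace, "clamp_events") <- if (length(clamp_log)) {
    do.call(rbind, clamp_log)
  } else {
    data.frame(t = integer(0), variable = character(0), raw = numeric(0))
  }
  class(trace) <- c("simulation_trace", "data.frame")
  trace
}

#' Write a simulation trace to CSV
#'
#' One row per period, one column per stock/flow/auxiliary, header names
#' matching the model's symbol names (`o_pop_s`, `di_hppc_f`, ...).
#'
#' @param trace A `simulation_trace` from [run_simulation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @export
`[.simulation_trace` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.simulation_trace <- function(x, ...) {
  s <- attr(x, "storyline")
  if (is.null(s)) return(print.data.frame(x, ...))
  cat(sprintf("<simulation_trace> %d periods of storyline '%s' (seed %d)\n",
              nrow(x) - 1L, s$name, attr(x, "seed")))
  last <- x[nrow(x), c("t", "di_pop_s", "dn_pop_s", "di_hppc_s", "dn_hppc_s")]
  cat(sprintf("  at t %d: immigrants %.1f (HP pc %.2f), natives %.1f (HP pc %.2f)\n",
              last$t, last$di_pop_s, last$di_hppc_s,
              last$dn_pop_s, last$dn_hppc_s))
  nc <- nrow(attr(x, "clamp_events"))
  if (nc) cat(sprintf("  %d clamp event(s) logged\n", nc))
  invisible(x)
}
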