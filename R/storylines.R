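# Reference storylines S1-S4 and their sensitivity variants; config I/O.

# Arrival series: 10/period in the first three periods, 100 in the
# fourth, rising by 25/period through the eighth, then 0.  Arrival HP
# pc: 48 in the first three periods, 55 in the next five, then 0.  The
# first arrival period is simulation period t = 0 (the walk-through's
# flows begin at t 0; this indexing reproduces the reported first
# shortage and extinction periods).
.arrival_series <- function(endtime) {
  nm <- numeric(endtime + 1L)
  hp <- numeric(endtime + 1L)
  k <- seq_len(min(8L, endtime + 1L))
  nm[k] <- c(10, 10, 10, 100, 125, 150, 175, 200)[k]
  hp[k] <- c(48, 48, 48, 55, 55, 55, 55, 55)[k]
  list(od_nm_x = nm, od_imhppc_x = hp)
}

#' Build a reference storyline
#'
#' Regenerates the four reference storylines and their sensitivity
#' variants.
#'
#' * **S1** — baseline: perfect HC/ES quality, no barriers, HC/ES
#'   capacities 4200, no arrivals, no spillovers, no conflict or EICC.
#'   Initial stocks: 100 immigrants, 2000 natives, HP pc 48, EP 47.
#'   Thresholds 48 (HC/ES need) and 50 (death); wear & tear 2/period;
#'   net birth rate 0.001/period; HP pc TNE impact -1/period.
#' * **S2** — S1 plus climate-migrant arrivals (10, 10, 10, 100, 125,
#'   150, 175, 200 in periods 1-8, arrival HP pc 48/48/48/55/55/55/55/55)
#'   and symmetric HP pc spillovers (default 1%).
#' * **S3** — S2 with 2% spillovers and an HC access barrier for
#'   immigrants (default 0.25).
#' * **S4** — S2 with 2% spillovers and reduced HC quality for immigrants
#'   (default 0.5).
#'
#' Arrivals, arrival HP pc, and both conflict intensities are overridden
#' by their scenario series in every reference storyline.  Origin-site
#' inputs mirror the S1 destination values.
#'
#' @param base `"S1"`, `"S2"`, `"S3"`, or `"S4"`.
#' @param spillover Symmetric HP pc spillover share (defaults: 0 for S1,
#'   0.01 for S2, 0.02 for S3/S4).
#' @param barrier HC barrier facing immigrants (S3; ignored by S1/S2).
#' @param quality HC quality provided to immigrants (S4).
#' @param hc_capacity Destination HC capacity (default 4200).
#' @param endtime Simulation horizon in periods.
#' @param seed Integer seed stored in the storyline.
#' @return A [storyline()].
#' @export
#' @examples
#' s3 <- build_storyline("S3", barrier = 0.25)
#' run_simulation(s3)
build_storyline <- function(base = c("S1", "S2", "S3", "S4"),
                            spillover = NULL, barrier = NULL, quality = NULL,
                            hc_capacity = 4200, endtime = 60L, seed = 1L) {
  base <- match.arg(base)
  if (base == "S1" &&
      (!is.null(barrier) || !is.null(quality) ||
       (!is.null(spillover) && spillover != 0))) {
    stop("build_storyline: S1 forbids arrivals, spillovers, barriers, and quality variants")
  }
  if (base %in% c("S1", "S2") && (!is.null(barrier) || !is.null(quality))) {
    stop("build_storyline: barriers/quality variants belong to S3/S4")
  }
  spill <- if (!is.null(spillover)) spillover else
    switch(base, S1 = 0, S2 = 0.01, S3 = 0.02, S4 = 0.02)
  b <- if (base == "S3") (if (is.null(barrier)) 0.25 else barrier) else 0
  q <- if (base == "S4") (if (is.null(quality)) 0.5 else quality) else 1

  params <- default_parameters(endtime_p = as.integer(endtime),
                               dn_dihppc_p = spill, di_dnhppc_p = spill)
  arr <- if (base == "S1") {
    list(od_nm_x = 0, od_imhppc_x = 0)
  } else {
    .arrival_series(endtime)
  }
  scen <- scenario_table(
    endtime,
    # destination services
    d_hcc_x = hc_capacity, d_esc_x = 4200,
    di_hcq_x = q, dn_hcq_x = 1, di_esq_x = 1, dn_esq_x = 1,
    di_hcb_x = b, dn_hcb_x = 0, di_esb_x = 0, dn_esb_x = 0,
    # origin services mirror the destination baseline
    o_hcc_x = 4200, o_esc_x = 4200, o_hcq_x = 1, o_esq_x = 1,
    o_hcb_x = 0, o_esb_x = 0,
    # pro-health TNE impact on every HP pc flow
    o_hppc_tx = -1, di_hppcf_tx = -1, dn_hppcf_tx = -1,
    # overridden series: arrivals, arrival HP pc, conflict intensities
    od_nm_x = arr$od_nm_x, od_imhppc_x = arr$od_imhppc_x,
    o_ci_x = 0, d_ci_x = 0
  )
  storyline(
    parameters = params, scenarios = scen,
    init = c(o_pop_s = 2000, o_hppc_s = 48, o_ep_s = 47,
             di_pop_s = 100, di_hppc_s = 48, di_ep_s = 47,
             dn_pop_s = 2000, dn_hppc_s = 48, dn_ep_s = 47),
    seed = seed,
    name = sprintf("%s (spill=%g, b=%g, q=%g, hcc=%g)",
                   base, spill, b, q, hc_capacity)
  )
}

#' Build a policy variant for capacity analysis
#'
#' An S2-style storyline (arrivals as in S2, 2% spillovers by default)
#' with an arbitrary immigrant HC barrier `b`, immigrant HC quality `q`,
#' and HC capacity — the input bundle over which the minimum sufficient
#' HC capacity is searched.
#'
#' @param barrier Immigrant HC barrier in `[0, 1]`.
#' @param quality Immigrant HC quality in `[0, 1]`.
#' @param spillover Symmetric HP pc spillover share.
#' @param hc_capacity Destination HC capacity.
#' @param endtime,seed Passed through.
#' @return A [storyline()].
#' @export
policy_storyline <- function(barrier = 0, quality = 1, spillover = 0.02,
                             hc_capacity = 4200, endtime = 60L, seed = 1L) {
  s <- build_storyline("S2", spillover = spillover,
                       hc_capacity = hc_capacity,
                       endtime = endtime, seed = seed)
  s$scenarios$di_hcb_x <- barrier
  s$scenarios$di_hcq_x <- quality
  s$name <- sprintf("policy (b=%g, q=%g, spill=%g, hcc=%g)",
                    barrier, quality, spillover, hc_capacity)
  validate_storyline(s)
  s
}

#' Save and load storyline configurations
#'
#' `save_storyline()` writes a directory holding `storyline.json`
#' (parameters, controllers, initial stocks, lagged values, seed, name,
#' function bank) and `scenarios.csv` (one column per exogenous series,
#' one row per period).  `load_storyline()` reads it back; the round trip
#' is exact.
#'
#' @param s A [storyline()].
#' @param dir Directory path (created if missing).
#' @return `save_storyline()` returns `dir` invisibly; `load_storyline()`
#'   returns the storyline.
#' @export
save_storyline <- function(s, dir) {
  validate_storyline(s)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  header <- list(
    name = s$name, seed = s$seed,
    parameters = s$parameters,
    controllers = as.list(s$controllers),
    init = as.list(s$init),
    init_lag = as.list(s$init_lag),
    bank = .bank_to_list(s$bank),
    scenarios_file = "scenarios.csv"
  )
  jsonlite::write_json(header, file.path(dir, "storyline.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(format(s$scenarios, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   file.path(dir, "scenarios.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname save_storyline
#' @export
load_storyline <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "storyline.json"))
  scen <- utils::read.csv(file.path(dir, header$scenarios_file))
  params <- as.list(header$parameters)
  params$endtime_p <- as.integer(params$endtime_p)
  storyline(
    parameters = params,
    scenarios = scen,
    controllers = unlist(header$controllers),
    init = unlist(header$init),
    init_lag = unlist(header$init_lag),
    bank = .bank_from_list(header$bank),
    seed = header$seed,
    name = header$name
  )
}

.bank_to_list <- function(bank) {
  list(R = lapply(bank$R, unclass), RF = lapply(bank$RF, unclass))
}

.bank_from_list <- function(lst) {
  bank <- list(
    R = lapply(lst$R, function(f) {
      do.call(rise_fn, as.list(f))
    }),
    RF = lapply(lst$RF, function(f) {
      do.call(risefall_fn, as.list(f)[c("p1", "pm", "p2", "fm", "fall_slope")])
    })
  )
  structure(bank, class = "function_bank")
}
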