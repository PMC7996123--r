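# Model state: stocks, parameters, scenario series, controllers, clamping.

# Names of the nine stocks, in the order they are updated each period.
.stock_names <- c("o_pop_s", "o_hppc_s", "o_ep_s",
                  "di_pop_s", "di_hppc_s", "di_ep_s",
                  "dn_pop_s", "dn_hppc_s", "dn_ep_s")

# Scenario columns bounded to [0, 1].
.unit_scenarios <- c("o_hcb_x", "o_esb_x", "di_hcb_x", "dn_hcb_x",
                     "di_esb_x", "dn_esb_x",
                     "o_hcq_x", "o_esq_x", "di_hcq_x", "dn_hcq_x",
                     "di_esq_x", "dn_esq_x",
                     "di_hccsha_x", "dn_hccsha_x",
                     "di_escsha_x", "dn_escsha_x")

# Scenario columns that must be >= 0.
.nonneg_scenarios <- c("o_eicc_x", "d_eicc_x", "o_hcc_x", "o_esc_x",
                       "d_hcc_x", "d_esc_x", "od_nmhppc_x",
                       "o_ci_x", "d_ci_x", "od_nm_x", "od_imhppc_x")

# Unbounded TNE effect series.
.tne_scenarios <- c("o_cr_tx", "o_ci_tx", "d_cr_tx", "d_ci_tx",
                    "o_nm_tx", "d_nm_tx", "od_nm_tx",
                    "o_hppc_tx", "di_hppcf_tx", "dn_hppcf_tx",
                    "o_ep_tx", "di_ep_tx", "dn_ep_tx",
                    "o_popgr_tx", "di_popgr_tx", "dn_popgr_tx")

.scenario_names <- c(.unit_scenarios, .nonneg_scenarios,
                     c("d_divhcc_x", "d_divesc_x"), .tne_scenarios)

# Controllable auxiliaries and the scenario series that overrides each.
.controllables <- c(od_nm_a = "od_nm_x", od_imhppc_a = "od_imhppc_x",
                    o_ci_a = "o_ci_x", d_ci_a = "d_ci_x")

#' Clamp a computed value to the range its kind allows
#'
#' Conflict risks, service qualities, and access barriers live in
#' `[0, 1]`; stocks (populations, HP pc, EP) are floored at 0.  Values
#' already inside the range pass through unchanged.
#'
#' @param raw Finite numeric value.
#' @param kind One of `"risk"`, `"quality"`, `"barrier"`, `"stock"`.
#' @param context Optional string naming the period/variable for error
#'   messages.
#' @return The clamped value.
#' @export
#' @examples
#' clamp_state(1.2, "risk")   # 1
#' clamp_state(-3.2, "stock") # 0
clamp_state <- function(raw, kind = c("risk", "quality", "barrier", "stock"),
                        context = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(raw)) {
    stop(sprintf("non-finite %s value%s", kind,
                 if (is.null(context)) "" else paste0(" at ", context)))
  }
  if (kind == "stock") max(raw, 0) else min(max(raw, 0), 1)
}

#' Per-capita division with the zero-population rule
#'
#' Divides a group total by its population; a population of exactly 0
#' yields 0 rather than a division error, matching the model's rule that
#' every per-capita quantity of an empty group is 0.
#'
#' @param total Numeric total.
#' @param pop Population, `>= 0`.
#' @return `total / pop`, or 0 when `pop == 0`.
#' @export
per_capita <- function(total, pop) {
  if (pop < 0) stop("per_capita: 'pop' must be >= 0")
  if (pop == 0) 0 else total / pop
}

#' Default model parameters
#'
#' Returns the baseline parameter set shared by all reference storylines:
#' HC/ES need thresholds 48, HP pc wear & tear 2 per period, self-healing
#' 0, HP chance variance 0, net birth rates 0.001 per period for every
#' group, zero EP creation/decay, zero spillover shares, and a 60-period
#' horizon.
#'
#' @param ... Named parameter overrides.
#' @return Named list of parameters.
#' @export
default_parameters <- function(...) {
  p <- list(
    hchppc_p = 48,       # HP pc threshold for HC need
    esep_p = 48,         # EP threshold for ES need
    wthppc_p = 2,        # HP pc natural wear & tear per period
    shhppc_p = 0,        # HP pc self-healing per period
    vhppc_p = 0,         # variance of the HP pc impact of chance
    o_netbr_p = 0.001, di_netbr_p = 0.001, dn_netbr_p = 0.001,
    o_ieppc_p = 0, d_ieppc_p = 0,    # EP created per person-period
    o_decrep_p = 0, d_decrep_p = 0,  # EP decay rates
    dn_dihppc_p = 0,     # share of immigrant HP pc spilling onto natives
    di_dnhppc_p = 0,     # share of native HP pc spilling onto immigrants
    dn_diep_p = 0, di_dnep_p = 0,    # EP spillover shares
    endtime_p = 60L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) {
    stop("default_parameters: unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  }
  p[names(dots)] <- dots
  p
}

#' Constant scenario table
#'
#' Builds the scenario data frame (one row per period `t = 0..endtime`)
#' with every exogenous series constant at the values given; unspecified
#' series default to 0 except capacity-split modes (1) and the emigrant
#' selection ratio `od_nmhppc_x` (1).
#'
#' @param endtime Number of periods; the table has `endtime + 1` rows.
#' @param ... Named series values: a scalar (recycled) or a vector of
#'   length `endtime + 1`.
#' @return A data frame with column `t` plus one column per exogenous
#'   variable.
#' @export
scenario_table <- function(endtime = 60L, ...) {
  n <- endtime + 1L
  scen <- data.frame(t = 0:endtime)
  for (nm in .scenario_names) scen[[nm]] <- 0
  scen$d_divhcc_x <- 1
  scen$d_divesc_x <- 1
  scen$od_nmhppc_x <- 1
  dots <- list(...)
  unknown <- setdiff(names(dots), .scenario_names)
  if (length(unknown)) {
    stop("scenario_table: unknown scenario series: ",
         paste(unknown, collapse = ", "))
  }
  for (nm in names(dots)) {
    v <- dots[[nm]]
    if (!length(v) %in% c(1L, n)) {
      stop(sprintf("scenario_table: series '%s' must have length 1 or %d", nm, n))
    }
    scen[[nm]] <- rep(v, length.out = n)
  }
  scen
}

#' Assemble a storyline
#'
#' A storyline bundles everything one simulation needs: parameters,
#' scenario series, controller flags, initial stocks, initial lagged
#' conflict values, the response-function bank, and a seed.
#'
#' @param parameters From [default_parameters()].
#' @param scenarios From [scenario_table()].
#' @param controllers Named character vector over the controllable
#'   auxiliaries (`od_nm_a`, `od_imhppc_a`, `o_ci_a`, `d_ci_a`), each
#'   `"compute"` or `"override"`.  Overridden variables follow their
#'   scenario series instead of their equations.
#' @param init Named numeric vector of the nine initial stocks.
#' @param init_lag Named numeric vector of prior-period conflict values
#'   (`o_cr_a`, `o_ci_a`, `d_cr_a`, `d_ci_a`) used at `t = 0`.
#' @param bank A [function_bank()].
#' @param seed Integer seed.
#' @param name Optional label.
#' @return An object of class `storyline`.
#' @export
storyline <- function(parameters = default_parameters(),
                      scenarios = scenario_table(parameters$endtime_p),
                      controllers = c(od_nm_a = "override",
                                      od_imhppc_a = "override",
                                      o_ci_a = "override",
                                      d_ci_a = "override"),
                      init,
                      init_lag = c(o_cr_a = 0, o_ci_a = 0,
                                   d_cr_a = 0, d_ci_a = 0),
                      bank = function_bank(),
                      seed = 1L,
                      name = "custom") {
  s <- structure(list(parameters = parameters, scenarios = scenarios,
                      controllers = controllers, init = init,
                      init_lag = init_lag, bank = bank,
                      seed = as.integer(seed), name = name),
                 class = "storyline")
  validate_storyline(s)
  s
}

#' Validate a storyline
#'
#' Checks scenario lengths, range bounds on barriers/qualities/shares,
#' non-negativity of capacities and stocks, controller flags, and
#' parameter ranges.  Errors name the offending field.
#'
#' @param s A [storyline()].
#' @return `s`, invisibly, if valid.
#' @export
validate_storyline <- function(s) {
  stopifnot(inherits(s, "storyline"))
  p <- s$parameters
  if (!is.numeric(p$endtime_p) || p$endtime_p < 1 ||
      p$endtime_p != round(p$endtime_p)) {
    stop("storyline: 'endtime_p' must be a positive integer")
  }
  n <- p$endtime_p + 1
  if (nrow(s$scenarios) != n) {
    stop(sprintf("storyline: scenario table has %d rows, expected %d (endtime_p + 1)",
                 nrow(s$scenarios), n))
  }
  missing_cols <- setdiff(.scenario_names, names(s$scenarios))
  if (length(missing_cols)) {
    stop("storyline: missing scenario series: ",
         paste(missing_cols, collapse = ", "))
  }
  for (nm in .unit_scenarios) {
    v <- s$scenarios[[nm]]
    if (any(v < 0 | v > 1)) {
      stop(sprintf("storyline: scenario '%s' must lie in [0, 1]", nm))
    }
  }
  for (nm in .nonneg_scenarios) {
    if (any(s$scenarios[[nm]] < 0)) {
      stop(sprintf("storyline: scenario '%s' must be >= 0", nm))
    }
  }
  for (nm in c("d_divhcc_x", "d_divesc_x")) {
    if (!all(s$scenarios[[nm]] %in% c(1, 2))) {
      stop(sprintf("storyline: scenario '%s' must be 1 or 2", nm))
    }
  }
  for (nm in c("hchppc_p", "esep_p", "wthppc_p", "shhppc_p", "vhppc_p")) {
    if (p[[nm]] < 0) stop(sprintf("storyline: parameter '%s' must be >= 0", nm))
  }
  for (nm in c("dn_dihppc_p", "di_dnhppc_p", "dn_diep_p", "di_dnep_p",
               "o_decrep_p", "d_decrep_p")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop(sprintf("storyline: parameter '%s' must lie in [0, 1]", nm))
    }
  }
  if (!setequal(names(s$init), .stock_names) || any(s$init < 0)) {
    stop("storyline: 'init' must name all nine stocks with values >= 0")
  }
  if (!all(names(.controllables) %in% names(s$controllers)) ||
      !all(s$controllers %in% c("compute", "override"))) {
    stop("storyline: controllers must flag each of ",
         paste(names(.controllables), collapse = ", "),
         " as 'compute' or 'override'")
  }
  if (!all(c("o_cr_a", "o_ci_a", "d_cr_a", "d_ci_a") %in% names(s$init_lag))) {
    stop("storyline: 'init_lag' must name o_cr_a, o_ci_a, d_cr_a, d_ci_a")
  }
  invisible(s)
}

#' @export
print.storyline <- function(x, ...) {
  cat(sprintf("<storyline '%s'>: %d periods, seed %d\n",
              x$name, x$parameters$endtime_p, x$seed))
  cat("  initial stocks:",
      paste(sprintf("%s=%g", names(x$init), x$init), collapse = ", "), "\n")
  ov <- names(x$controllers)[x$controllers == "override"]
  cat("  overridden:", if (length(ov)) paste(ov, collapse = ", ") else "none", "\n")
  invisible(x)
}
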