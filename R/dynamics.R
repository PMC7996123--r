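# Pure per-period computations: conflict, migration, service provision,
# and the HP pc / EP / population flow blocks.

#' Conflict risk and intensity for one site
#'
#' Computes the site's conflict risk as a sum of rise/rise-fall responses
#' to population, lagged risk and intensity, EICC, HP pc, and a TNE term,
#' clamps it to `[0, 1]`, draws a uniform threshold, and sets the
#' intensity from the intensity equation when the risk tops the draw
#' (else 0).  When the site's intensity controller is overridden the
#' intensity follows its scenario series and no draw is consumed.
#'
#' @param site `"origin"` or `"destination"`.
#' @param stocks Named vector of current stocks.
#' @param lag Named list/vector with the prior period's `cr` and `ci` for
#'   this site.
#' @param scen Scenario row (list) for the period.
#' @param bank A [function_bank()].
#' @param override Logical; is the intensity controller set to override?
#' @param stream A [random_stream()].
#' @return List with `risk`, `intensity`, and `draw` (NA when overridden).
#' @export
conflict_step <- function(site = c("origin", "destination"),
                          stocks, lag, scen, bank, override, stream) {
  site <- match.arg(site)
  if (site == "origin") {
    risk <- Rb(bank, 1, stocks[["o_pop_s"]]) +
      Rb(bank, 2, lag$cr) +
      RFb(bank, 1, scen$o_eicc_x) +
      RFb(bank, 2, lag$ci) +
      RFb(bank, 3, stocks[["o_hppc_s"]]) +
      scen$o_cr_tx
  } else {
    risk <- Rb(bank, 4, stocks[["di_pop_s"]]) +
      Rb(bank, 5, stocks[["dn_pop_s"]]) +
      Rb(bank, 6, lag$cr) +
      RFb(bank, 7, scen$d_eicc_x) +
      RFb(bank, 8, lag$ci) +
      RFb(bank, 9, stocks[["di_hppc_s"]]) +
      RFb(bank, 10, stocks[["dn_hppc_s"]]) +
      scen$d_cr_tx
  }
  risk <- clamp_state(risk, "risk", context = paste(site, "conflict risk"))
  if (override) {
    ci <- if (site == "origin") scen$o_ci_x else scen$d_ci_x
    return(list(risk = risk, intensity = max(ci, 0), draw = NA_real_))
  }
  sub <- if (site == "origin") "origin_conflict" else "destination_conflict"
  u <- draw_uniform(stream, sub)
  if (risk <= u) {
    return(list(risk = risk, intensity = 0, draw = u))
  }
  if (site == "origin") {
    ci <- Rb(bank, 3, stocks[["o_pop_s"]]) +
      RFb(bank, 4, scen$o_eicc_x) +
      RFb(bank, 5, lag$ci) +
      RFb(bank, 6, stocks[["o_hppc_s"]]) +
      scen$o_ci_tx
  } else {
    ci <- Rb(bank, 7, stocks[["di_pop_s"]]) +
      Rb(bank, 8, stocks[["dn_pop_s"]]) +
      RFb(bank, 11, scen$d_eicc_x) +
      RFb(bank, 12, lag$ci) +
      RFb(bank, 13, stocks[["di_hppc_s"]]) +
      RFb(bank, 14, stocks[["dn_hppc_s"]]) +
      scen$d_ci_tx
  }
  list(risk = risk, intensity = max(ci, 0), draw = u)
}

#' Migration: number of movers and their HP pc on arrival
#'
#' The mover count sums an origin push effect, a destination pull effect,
#' and an OD-pair TNE term, floored at 0 and capped at the origin
#' population.  Arrival HP pc is the origin HP pc stock scaled by the
#' emigrant selection ratio.  Overridden controllers take both values
#' from their scenario series (the mover cap still applies).
#'
#' @inheritParams conflict_step
#' @param o_ci,d_ci This period's conflict intensities.
#' @param override Named logical vector with elements `od_nm_a` and
#'   `od_imhppc_a`.
#' @return List with `o_nm_a`, `d_nm_a`, `od_nm_a`, `od_imhppc_a`.
#' @export
migration_step <- function(stocks, o_ci, d_ci, scen, bank, override) {
  if (scen$od_nmhppc_x < 0) {
    stop("migration_step: selection ratio 'od_nmhppc_x' must be >= 0")
  }
  o_nm <- Rb(bank, 9, stocks[["o_pop_s"]]) +
    RFb(bank, 15, stocks[["o_hppc_s"]]) +
    RFb(bank, 16, stocks[["o_ep_s"]]) +
    RFb(bank, 17, o_ci) +
    RFb(bank, 18, scen$o_eicc_x) +
    scen$o_nm_tx
  d_nm <- Rb(bank, 10, stocks[["di_pop_s"]]) +
    Rb(bank, 11, stocks[["dn_pop_s"]]) -
    Rb(bank, 12, stocks[["di_hppc_s"]]) -
    Rb(bank, 13, stocks[["dn_hppc_s"]]) -
    Rb(bank, 14, stocks[["di_ep_s"]]) -
    Rb(bank, 15, stocks[["dn_ep_s"]]) -
    Rb(bank, 16, d_ci) -
    Rb(bank, 17, scen$d_eicc_x) +
    scen$d_nm_tx
  od_nm <- if (override[["od_nm_a"]]) {
    scen$od_nm_x
  } else {
    o_nm + d_nm + scen$od_nm_tx
  }
  od_nm <- min(max(od_nm, 0), stocks[["o_pop_s"]])
  imhppc <- if (override[["od_imhppc_a"]]) {
    scen$od_imhppc_x
  } else {
    stocks[["o_hppc_s"]] * scen$od_nmhppc_x
  }
  list(o_nm_a = o_nm, d_nm_a = d_nm, od_nm_a = od_nm,
       od_imhppc_a = max(imhppc, 0))
}

#' Effective service quality and capacity under conflict and EICC damage
#'
#' Base quality/capacity follow their scenario series; each is reduced by
#' rise-function damage responses to conflict intensity and EICC.
#' Quality is clamped to `[0, 1]` and capacity floored at 0.
#'
#' @param base_quality Scenario quality in `[0, 1]`.
#' @param base_capacity Scenario capacity `>= 0`.
#' @param ci,eicc Conflict intensity and EICC intensity.
#' @param q_fns,c_fns Length-2 lists of [rise_fn()]s: damage responses of
#'   quality and capacity to `ci` and `eicc`, in that order.
#' @return List with `quality` and `capacity`.
#' @export
effective_service <- function(base_quality, base_capacity, ci, eicc,
                              q_fns, c_fns) {
  q <- base_quality - eval_rise(q_fns[[1]], ci) - eval_rise(q_fns[[2]], eicc)
  cap <- base_capacity - eval_rise(c_fns[[1]], ci) - eval_rise(c_fns[[2]], eicc)
  list(quality = clamp_state(q, "quality"),
       capacity = clamp_state(cap, "stock"))
}

#' Need for provision of a service
#'
#' The per-capita need is the excess of the problem stock over the need
#' threshold; barriers block a fraction of it.  HC need (and destination
#' ES need) scales with the group population; the origin's ES need is
#' population-free.
#'
#' @param stock Problem stock (HP pc or EP).
#' @param threshold Need threshold.
#' @param barrier Access barrier in `[0, 1]`.
#' @param pop Group population, or `NULL` for a population-free need.
#' @return Need for provision, `>= 0`.
#' @export
need_for_provision <- function(stock, threshold, barrier, pop = NULL) {
  if (barrier < 0 || barrier > 1) {
    stop("need_for_provision: 'barrier' must lie in [0, 1]")
  }
  need <- max(stock - threshold, 0) * (1 - barrier)
  if (is.null(pop)) need else need * pop
}

#' Divide a service capacity among groups
#'
#' With sufficient capacity every group receives its need.  Under
#' shortage, mode 1 divides the capacity by the groups' shares of the
#' total need; mode 2 hands out fixed scenario shares, with each group's
#' provision capped at its need so provision never exceeds what is
#' needed.
#'
#' @param needs Numeric vector of group needs for provision, `>= 0`.
#' @param capacity Available capacity, `>= 0`.
#' @param mode 1 (proportional shares) or 2 (fixed shares).
#' @param shares Fixed shares in `[0, 1]` (mode 2 only).
#' @return Numeric vector of provisions (group totals).
#' @export
#' @examples
#' allocate_capacity(c(100, 300), 500)            # c(100, 300)
#' allocate_capacity(c(100, 300), 200)            # c(50, 150)
#' allocate_capacity(c(100, 300), 200, 2, c(0.3, 0.7))  # c(60, 140)
allocate_capacity <- function(needs, capacity, mode = 1, shares = NULL) {
  stopifnot(all(needs >= 0), capacity >= 0)
  total <- sum(needs)
  if (total <= capacity) return(needs)
  if (mode == 1) {
    capacity * needs / total
  } else if (mode == 2) {
    if (is.null(shares) || length(shares) != length(needs)) {
      stop("allocate_capacity: mode 2 requires one fixed share per group")
    }
    if (any(shares < 0 | shares > 1)) {
      stop("allocate_capacity: shares must lie in [0, 1]")
    }
    pmin(capacity * shares, needs)
  } else {
    stop("allocate_capacity: 'mode' must be 1 or 2")
  }
}

#' HP pc mixing adjustment for departures and arrivals
#'
#' Emigration raises the origin's HP pc when the movers are healthier
#' than the pool they leave (`departure`); arrivals lower the immigrant
#' group's HP pc when they are healthier than the residents they join
#' (`arrival`).
#'
#' @param movers Number of movers, `>= 0`.
#' @param pool_pop Population of the pool (origin residents for
#'   departures, resident immigrants for arrivals).
#' @param pool_hppc HP pc stock of the pool.
#' @param mover_hppc HP pc of the movers.
#' @param direction `"departure"` or `"arrival"`.
#' @return The HP pc flow term.  A zero post-move pool yields 0 under the
#'   zero-population rule.
#' @export
mixing_adjustment <- function(movers, pool_pop, pool_hppc, mover_hppc,
                              direction = c("departure", "arrival")) {
  direction <- match.arg(direction)
  stopifnot(movers >= 0, pool_pop >= 0)
  if (direction == "departure") {
    movers <- min(movers, pool_pop)
    denom <- pool_pop - movers
    if (denom == 0) return(0)
    movers / denom * (pool_hppc - mover_hppc)
  } else {
    denom <- pool_pop + movers
    if (denom == 0) return(0)
    movers / denom * (mover_hppc - pool_hppc)
  }
}

#' Origin-site auxiliaries and flows for one period
#'
#' Computes the origin's HC and ES blocks (need, effective quality and
#' capacity, provision) and the HP pc, EP, and population flows.
#'
#' @param stocks Named vector of current stocks.
#' @param o_ci Origin conflict intensity for the period.
#' @param mig Result of [migration_step()].
#' @param scen Scenario row (list) for the period.
#' @param params Parameter list (see [default_parameters()]).
#' @param bank A [function_bank()].
#' @param stream A [random_stream()].
#' @return Named list of origin auxiliaries and flows.
#' @export
origin_flows <- function(stocks, o_ci, mig, scen, params, bank, stream) {
  o_pop <- stocks[["o_pop_s"]]
  o_hppc <- stocks[["o_hppc_s"]]
  o_ep <- stocks[["o_ep_s"]]

  # HC block
  o_tnhcfp <- need_for_provision(o_hppc, params$hchppc_p, scen$o_hcb_x, o_pop)
  hc <- effective_service(scen$o_hcq_x, scen$o_hcc_x, o_ci, scen$o_eicc_x,
                          list(bank$R[[18]], bank$R[[19]]),
                          list(bank$R[[20]], bank$R[[21]]))
  o_phchppc <- per_capita(min(o_tnhcfp, hc$capacity), o_pop) * hc$quality
  o_emhppc <- mixing_adjustment(mig$od_nm_a, o_pop, o_hppc,
                                mig$od_imhppc_a, "departure")
  o_hppc_f <- params$wthppc_p +
    Rb(bank, 22, o_ep) + Rb(bank, 23, o_ci) + Rb(bank, 24, scen$o_eicc_x) +
    o_emhppc +
    draw_normal(stream, "origin_hp_chance", params$vhppc_p) -
    params$shhppc_p - o_phchppc + scen$o_hppc_tx

  # ES block (origin ES need is population-free)
  o_tnesfp <- need_for_provision(o_ep, params$esep_p, scen$o_esb_x)
  es <- effective_service(scen$o_esq_x, scen$o_esc_x, o_ci, scen$o_eicc_x,
                          list(bank$R[[25]], bank$R[[26]]),
                          list(bank$R[[27]], bank$R[[28]]))
  o_tpesep <- min(o_tnesfp, es$capacity) * es$quality
  o_ep_f <- params$o_ieppc_p * (o_pop - mig$od_nm_a) +
    RFb(bank, 19, o_ci) + RFb(bank, 20, scen$o_eicc_x) -
    o_tpesep - params$o_decrep_p * o_ep + scen$o_ep_tx

  # population flow
  o_pop_f <- o_pop * (params$o_netbr_p - Rb(bank, 29, o_hppc) +
                        scen$o_popgr_tx) - mig$od_nm_a

  list(o_tnhcfp_a = o_tnhcfp, o_hcq_a = hc$quality, o_hcc_a = hc$capacity,
       o_phchppc_a = o_phchppc, o_emhppc_a = o_emhppc,
       o_tnesfp_a = o_tnesfp, o_esq_a = es$quality, o_esc_a = es$capacity,
       o_tpesep_a = o_tpesep,
       o_hppc_f = o_hppc_f, o_ep_f = o_ep_f, o_pop_f = o_pop_f)
}

#' Destination-site auxiliaries and flows for one period
#'
#' Computes the destination HC block (per-group need, effective quality,
#' site capacity, allocation under shortage), the ES block, the arrival
#' mixing and spillover terms, and the HP pc, EP, and population flows of
#' both groups.
#'
#' @inheritParams origin_flows
#' @param d_ci Destination conflict intensity for the period.
#' @return Named list of destination auxiliaries and flows.
#' @export
destination_flows <- function(stocks, d_ci, mig, scen, params, bank, stream) {
  di_pop <- stocks[["di_pop_s"]]; dn_pop <- stocks[["dn_pop_s"]]
  di_hppc <- stocks[["di_hppc_s"]]; dn_hppc <- stocks[["dn_hppc_s"]]
  di_ep <- stocks[["di_ep_s"]]; dn_ep <- stocks[["dn_ep_s"]]

  # HC block
  di_tnhcfp <- need_for_provision(di_hppc, params$hchppc_p, scen$di_hcb_x, di_pop)
  dn_tnhcfp <- need_for_provision(dn_hppc, params$hchppc_p, scen$dn_hcb_x, dn_pop)
  d_tnhcfp <- di_tnhcfp + dn_tnhcfp
  di_hcq <- clamp_state(scen$di_hcq_x - Rb(bank, 30, d_ci) -
                          Rb(bank, 31, scen$d_eicc_x), "quality")
  dn_hcq <- clamp_state(scen$dn_hcq_x - Rb(bank, 32, d_ci) -
                          Rb(bank, 33, scen$d_eicc_x), "quality")
  d_hcc <- clamp_state(scen$d_hcc_x - Rb(bank, 34, d_ci) -
                         Rb(bank, 35, scen$d_eicc_x), "stock")
  hc_prov <- allocate_capacity(c(di_tnhcfp, dn_tnhcfp), d_hcc,
                               mode = scen$d_divhcc_x,
                               shares = c(scen$di_hccsha_x, scen$dn_hccsha_x))
  di_phcpc <- per_capita(hc_prov[1], di_pop)
  dn_phcpc <- per_capita(hc_prov[2], dn_pop)
  di_phchppc <- di_phcpc * di_hcq
  dn_phchppc <- dn_phcpc * dn_hcq

  # arrival mixing and HP pc flows
  di_imhppc <- mixing_adjustment(mig$od_nm_a, di_pop, di_hppc,
                                 mig$od_imhppc_a, "arrival")
  di_hppc_f <- params$wthppc_p - params$shhppc_p +
    Rb(bank, 36, di_ep) + Rb(bank, 37, scen$d_eicc_x) + Rb(bank, 38, d_ci) +
    draw_normal(stream, "immigrant_hp_chance", params$vhppc_p) +
    params$di_dnhppc_p * dn_hppc - di_phchppc + di_imhppc + scen$di_hppcf_tx
  dn_hppc_f <- params$wthppc_p - params$shhppc_p +
    Rb(bank, 39, dn_ep) + Rb(bank, 40, scen$d_eicc_x) + Rb(bank, 41, d_ci) +
    draw_normal(stream, "native_hp_chance", params$vhppc_p) +
    params$dn_dihppc_p * di_hppc - dn_phchppc + scen$dn_hppcf_tx

  # ES block
  di_tnesfp <- need_for_provision(di_ep, params$esep_p, scen$di_esb_x, di_pop)
  dn_tnesfp <- need_for_provision(dn_ep, params$esep_p, scen$dn_esb_x, dn_pop)
  d_tnesfp <- di_tnesfp + dn_tnesfp
  di_esq <- clamp_state(scen$di_esq_x - Rb(bank, 42, d_ci) -
                          Rb(bank, 43, scen$d_eicc_x), "quality")
  dn_esq <- clamp_state(scen$dn_esq_x - Rb(bank, 44, d_ci) -
                          Rb(bank, 45, scen$d_eicc_x), "quality")
  d_esc <- clamp_state(scen$d_esc_x - Rb(bank, 46, d_ci) -
                         Rb(bank, 47, scen$d_eicc_x), "stock")
  es_prov <- allocate_capacity(c(di_tnesfp, dn_tnesfp), d_esc,
                               mode = scen$d_divesc_x,
                               shares = c(scen$di_escsha_x, scen$dn_escsha_x))
  di_pesep <- es_prov[1] * di_esq
  dn_pesep <- es_prov[2] * dn_esq
  di_ep_f <- params$d_ieppc_p * (di_pop + mig$od_nm_a) +
    params$di_dnep_p * dn_ep - params$dn_diep_p * di_ep +
    RFb(bank, 21, d_ci) + RFb(bank, 22, scen$d_eicc_x) -
    di_pesep - params$d_decrep_p * di_ep + scen$di_ep_tx
  dn_ep_f <- params$d_ieppc_p * dn_pop +
    params$dn_diep_p * di_ep - params$di_dnep_p * dn_ep +
    RFb(bank, 23, d_ci) + RFb(bank, 24, scen$d_eicc_x) -
    dn_pesep - params$d_decrep_p * dn_ep + scen$dn_ep_tx

  # population flows (arrivals join the immigrants within the period)
  di_pop_f <- di_pop * (params$di_netbr_p - Rb(bank, 48, di_hppc) +
                          scen$di_popgr_tx) + mig$od_nm_a
  dn_pop_f <- dn_pop * (params$dn_netbr_p - Rb(bank, 49, dn_hppc) +
                          scen$dn_popgr_tx)

  list(di_tnhcfp_a = di_tnhcfp, dn_tnhcfp_a = dn_tnhcfp,
       d_tnhcfp_a = d_tnhcfp,
       di_hcq_a = di_hcq, dn_hcq_a = dn_hcq, d_hcc_a = d_hcc,
       di_phcpc_a = di_phcpc, dn_phcpc_a = dn_phcpc,
       di_phchppc_a = di_phchppc, dn_phchppc_a = dn_phchppc,
       di_imhppc_a = di_imhppc,
       di_tnesfp_a = di_tnesfp, dn_tnesfp_a = dn_tnesfp,
       d_tnesfp_a = d_tnesfp,
       di_esq_a = di_esq, dn_esq_a = dn_esq, d_esc_a = d_esc,
       di_tpes_a = es_prov[1], dn_tpes_a = es_prov[2],
       di_pesep_a = di_pesep, dn_pesep_a = dn_pesep,
       di_hppc_f = di_hppc_f, dn_hppc_f = dn_hppc_f,
       di_ep_f = di_ep_f, dn_ep_f = dn_ep_f,
       di_pop_f = di_pop_f, dn_pop_f = dn_pop_f)
}
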