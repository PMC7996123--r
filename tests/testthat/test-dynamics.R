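# Helpers shared by the dynamics tests: a one-row scenario and zero bank.
scen_row <- function(...) {
  as.list(scenario_table(0, ...)[1, ])
}
zero_stocks <- c(o_pop_s = 0, o_hppc_s = 0, o_ep_s = 0,
                 di_pop_s = 0, di_hppc_s = 0, di_ep_s = 0,
                 dn_pop_s = 0, dn_hppc_s = 0, dn_ep_s = 0)

test_that("need for provision scales with excess, barrier, and population", {
  expect_equal(need_for_provision(49, 48, 0, 2002), 2002)
  expect_equal(need_for_provision(48, 48, 0, 1000), 0)
  expect_equal(need_for_provision(50, 48, 0.25, 100), 150)
  expect_equal(need_for_provision(50, 48, 0.3), 1.4)  # population-free
  expect_error(need_for_provision(50, 48, 1.2, 10), "barrier")
})

test_that("capacity allocation serves needs, shares shortage, and conserves", {
  expect_equal(allocate_capacity(c(100, 300), 500), c(100, 300))
  expect_equal(allocate_capacity(c(100, 300), 200, mode = 1), c(50, 150))
  expect_equal(allocate_capacity(c(100, 300), 200, mode = 2,
                                 shares = c(0.3, 0.7)), c(60, 140))
  expect_error(allocate_capacity(c(1, 2), 1, mode = 2), "share")

  # conservation property: sum(provided) == min(total need, capacity)
  set.seed(5)
  for (i in 1:50) {
    needs <- runif(2, 0, 1000)
    cap <- runif(1, 0, 1500)
    prov <- allocate_capacity(needs, cap, mode = 1)
    expect_equal(sum(prov), min(sum(needs), cap))
    expect_true(all(prov <= needs + 1e-12))
  }
})

test_that("mixing adjustments move HP pc toward the movers' level", {
  expect_equal(mixing_adjustment(100, 100, 49, 55, "arrival"), 3)
  expect_equal(mixing_adjustment(100, 1000, 50, 40, "departure"), 100 / 900 * 10)
  expect_equal(mixing_adjustment(50, 200, 47, 47, "arrival"), 0)
  expect_equal(mixing_adjustment(50, 200, 47, 47, "departure"), 0)
  # zero post-move pools fall back to 0
  expect_equal(mixing_adjustment(10, 10, 50, 40, "departure"), 0)
  expect_equal(mixing_adjustment(0, 0, 0, 0, "arrival"), 0)
})

test_that("effective service subtracts damage and clamps", {
  bank <- function_bank(overrides = list(
    R1 = rise_fn("linear", p = 0, s = 0.1),
    R2 = rise_fn("linear", p = 0, s = 0)
  ))
  out <- effective_service(0.75, 4200, 1, 0,
                           q_fns = list(bank$R[[1]], bank$R[[2]]),
                           c_fns = list(bank$R[[2]], bank$R[[2]]))
  expect_equal(out$quality, 0.65)
  expect_equal(out$capacity, 4200)

  out2 <- effective_service(0.5, 100, 10, 0,
                            q_fns = list(bank$R[[1]], bank$R[[2]]),
                            c_fns = list(rise_fn("linear", s = 50), bank$R[[2]]))
  expect_equal(out2$quality, 0)    # damage exceeds base quality
  expect_equal(out2$capacity, 0)   # capacity floored
})

test_that("conflict risk is clamped and overridden intensity skips the draw", {
  stream <- random_stream(1)
  scen <- scen_row(o_cr_tx = 2.0, o_ci_x = 0)
  out <- conflict_step("origin", zero_stocks, list(cr = 0, ci = 0),
                       scen, function_bank(), override = TRUE, stream)
  expect_equal(out$risk, 1)        # TNE risk 2.0 clamped
  expect_equal(out$intensity, 0)   # overridden by the zero scenario
  expect_true(is.na(out$draw))

  # zero functions and zero TNE: risk 0 never tops the uniform draw
  out2 <- conflict_step("destination", zero_stocks, list(cr = 0, ci = 0),
                        scen_row(), function_bank(), override = FALSE, stream)
  expect_equal(out2$risk, 0)
  expect_equal(out2$intensity, 0)
  expect_false(is.na(out2$draw))
})

test_that("migration caps movers at the origin population and scales arrival HP", {
  stocks <- zero_stocks
  stocks[["o_pop_s"]] <- 120
  stocks[["o_hppc_s"]] <- 40
  # computed arrival HP pc follows the selection ratio
  out <- migration_step(stocks, 0, 0, scen_row(od_nmhppc_x = 0.9),
                        function_bank(),
                        c(od_nm_a = FALSE, od_imhppc_a = FALSE))
  expect_equal(out$od_imhppc_a, 36)
  expect_equal(out$od_nm_a, 0)  # all functions and TNE zero

  # overridden arrivals follow the scenario but never exceed the population
  out2 <- migration_step(stocks, 0, 0,
                         scen_row(od_nm_x = 500, od_imhppc_x = 55),
                         function_bank(),
                         c(od_nm_a = TRUE, od_imhppc_a = TRUE))
  expect_equal(out2$od_nm_a, 120)
  expect_equal(out2$od_imhppc_a, 55)
})

test_that("origin flows reproduce the baseline hand computation", {
  s1 <- build_storyline("S1")
  stream <- random_stream(1)
  scen <- as.list(s1$scenarios[1, ])
  mig <- list(od_nm_a = 0, od_imhppc_a = 0)
  of <- origin_flows(s1$init, 0, mig, scen, s1$parameters, s1$bank, stream)
  expect_equal(of$o_hppc_f, 1)   # wear 2 + TNE -1, nothing else
  expect_equal(of$o_ep_f, 0)
  expect_equal(of$o_pop_f, 2)    # 2000 * 0.001

  # with population 1000 and HP pc 53 the death response dominates
  stocks <- s1$init
  stocks[["o_pop_s"]] <- 1000
  stocks[["o_hppc_s"]] <- 53
  of2 <- origin_flows(stocks, 0, mig, scen, s1$parameters, s1$bank, stream)
  expect_equal(of2$o_pop_f, 1000 * (0.001 - 0.001 * (exp(3) - 1)))
})

test_that("destination flows give the baseline period-0 values", {
  s1 <- build_storyline("S1")
  stream <- random_stream(1)
  scen <- as.list(s1$scenarios[1, ])
  mig <- list(od_nm_a = 0, od_imhppc_a = 0)
  df <- destination_flows(s1$init, 0, mig, scen, s1$parameters, s1$bank, stream)
  expect_equal(df$di_pop_f, 0.1)
  expect_equal(df$dn_pop_f, 2)
  expect_equal(df$di_hppc_f, 1)
  expect_equal(df$dn_hppc_f, 1)
  expect_equal(df$di_ep_f, 0)
  expect_equal(df$dn_ep_f, 0)
  expect_equal(df$d_tnhcfp_a, 0)  # stocks at the need threshold
})
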