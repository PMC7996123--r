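test_that("steady-state detection finds settled values and skips moving series", {
  expect_equal(detect_steady(rep(5, 10)), list(time = 0L, value = 5))
  expect_null(detect_steady(1:20))
  expect_null(detect_steady(c(1, 1, 1)))  # too short to confirm

  # settles after an initial transient
  x <- c(10, 7, 5.5, 5.05, 5.005, rep(5, 6))
  st <- detect_steady(x)
  expect_equal(st$value, 5)
  expect_gt(st$time, 3)

  tr3 <- run_simulation(build_storyline("S3", barrier = 0.25))
  expect_equal(detect_steady(tr3$dn_hppc_s)$value, 50.01)
  expect_equal(detect_steady(tr3$di_hppc_s)$value, 50.67)
})

test_that("the analytic steady state solves the provision balance", {
  expect_equal(steady_hp_oracle(0, 1, 0),
               list(di_steady_hp = 49, dn_steady_hp = 49))
  o <- steady_hp_oracle(0.25, 0.75, 0.02)
  expect_equal(o$di_steady_hp, 51.557, tolerance = 1e-3)
  expect_equal(o$dn_steady_hp, 50.031, tolerance = 1e-3)
  expect_error(steady_hp_oracle(0.5, 0, 0.02), "no finite steady state")
  expect_error(steady_hp_oracle(1, 1, 0.02), "no finite steady state")

  # brute-force check: iterate the balance map to its fixed point
  fix <- function(b, q, s) {
    h <- c(48, 48)
    for (i in 1:5000) {
      h <- c(48 + (1 + s * h[2]) / (q * (1 - b)), 48 + (1 + s * h[1]))
    }
    h
  }
  for (pars in list(c(0.25, 0.75, 0.02), c(0, 1, 0.02), c(0.5, 0.5, 0))) {
    o <- steady_hp_oracle(pars[1], pars[2], pars[3])
    f <- fix(pars[1], pars[2], pars[3])
    expect_equal(c(o$di_steady_hp, o$dn_steady_hp), f, tolerance = 1e-9)
  }
})

test_that("simulated steady HP matches the analytic oracle under ample capacity", {
  # generous capacity: provision always equals need
  for (pars in list(c(0, 1, 0.02), c(0.25, 0.75, 0.02), c(0.25, 0.5, 0.02))) {
    s <- policy_storyline(pars[1], pars[2], pars[3], hc_capacity = 50000)
    tr <- run_simulation(s)
    o <- steady_hp_oracle(pars[1], pars[2], pars[3])
    expect_equal(tr$di_hppc_s[61], o$di_steady_hp, tolerance = 0.1)
    expect_equal(tr$dn_hppc_s[61], o$dn_steady_hp, tolerance = 0.1)
  }
})

test_that("the fit score is the sum of squared deviations", {
  expect_equal(fit_score(1:5, 1:5), 0)
  expect_equal(fit_score(c(1, 2), c(0, 0)), 5)
  expect_error(fit_score(1:3, 1:4), "length")
  # adding a constant c to one of two equal series of length T gives T * c^2
  y <- rnorm(7)
  expect_equal(fit_score(y + 0.3, y), 7 * 0.09)
})

test_that("parameter sweeps run independent seeded variants", {
  s2 <- build_storyline("S2")
  sweep <- parameter_sweep(s2, "parameters.dn_dihppc_p", c(0, 0.01))
  expect_named(sweep, c("0", "0.01"))

  # single-value sweep equals a direct run
  one <- parameter_sweep(s2, "scenarios.di_hcb_x", 0.25)
  direct <- run_simulation(build_storyline("S3", barrier = 0.25,
                                           spillover = 0.01))
  expect_equal(one[["0.25"]]$di_pop_s, direct$di_pop_s)

  expect_error(parameter_sweep(s2, "parameters.nope", 1), "unknown path")
  expect_error(parameter_sweep(s2, "bad", 1), "path")
})

test_that("spillover sweep: the zero case leaves natives on the baseline path", {
  # with both spillover shares zero the native columns must match the
  # baseline exactly: nothing couples the natives to the arrival wave
  # (under the baseline capacity the zero-spillover wave never produces a
  # shortage, so the natives' provision is untouched too)
  s2 <- build_storyline("S2")
  tr0i <- run_simulation({
    s <- s2; s$parameters$dn_dihppc_p <- 0; s$parameters$di_dnhppc_p <- 0; s
  })
  tr1 <- run_simulation(build_storyline("S1"))
  for (nm in c("dn_pop_s", "dn_hppc_s", "dn_ep_s", "dn_hppc_f", "dn_pop_f")) {
    expect_equal(tr0i[[nm]], tr1[[nm]], label = nm)
  }
})

test_that("minimum sufficient capacity is minimal and reports the run summary", {
  res <- find_mshc(0, 1, spillover = 0.02)
  expect_s3_class(res, "mshc_result")
  # sufficient at the reported capacity, insufficient one unit below
  s_ok <- policy_storyline(0, 1, 0.02, res$mshc)
  s_lo <- policy_storyline(0, 1, 0.02, res$mshc - 1)
  tr_ok <- run_simulation(s_ok)
  tr_lo <- run_simulation(s_lo)
  expect_true(all(tr_ok$d_tnhcfp_a[-1] <= res$mshc))
  expect_true(any(tr_lo$d_tnhcfp_a[-1] > res$mshc - 1))
  expect_equal(res$di_pop_t60, tr_ok$di_pop_s[61])
})

test_that("shortage splits favour barriers over quality at equal healing power", {
  # with immigrant need m and native need n, the immigrant capacity share
  # under [b=0, q=0.75] is 0.75m/(m+n) < 0.75m/(0.75m+n) under [b=0.25, q=1]
  for (i in 1:20) {
    m <- runif(1, 1, 5000); n <- runif(1, 1, 5000)
    expect_lt(0.75 * m / (m + n), 0.75 * m / (0.75 * m + n))
  }
  # in full runs the immigrants' HP pc climbs sooner and higher under
  # [b=0, q=0.75]: the trajectory dominates through its peak, which is both
  # earlier and larger (the curves cross later, during recovery, as the
  # sicker group also shrinks faster)
  tr_q <- run_simulation(policy_storyline(0, 0.75, 0.02, 4200))
  tr_b <- run_simulation(policy_storyline(0.25, 1, 0.02, 4200))
  peak_q <- which.max(tr_q$di_hppc_s)
  peak_b <- which.max(tr_b$di_hppc_s)
  expect_lt(peak_q, peak_b)
  expect_gt(max(tr_q$di_hppc_s), max(tr_b$di_hppc_s))
  expect_true(all(tr_q$di_hppc_s[1:peak_q] >= tr_b$di_hppc_s[1:peak_q] - 1e-9))
  # provision impact per unit of need is identical (q(1-b) = 0.75), so the
  # difference comes from the shortage split alone
})

test_that("raising the immigrant barrier weakly raises immigrant HP pc", {
  # ample capacity so the shortage split does not confound the comparison
  trs <- lapply(c(0, 0.1, 0.25), function(b) {
    run_simulation(policy_storyline(b, 1, 0.02, hc_capacity = 50000))
  })
  expect_true(all(trs[[2]]$di_hppc_s - trs[[1]]$di_hppc_s >= -1e-9))
  expect_true(all(trs[[3]]$di_hppc_s - trs[[2]]$di_hppc_s >= -1e-9))
  # and lowering quality likewise
  trq <- run_simulation(policy_storyline(0, 0.75, 0.02, hc_capacity = 50000))
  expect_true(all(trq$di_hppc_s - trs[[1]]$di_hppc_s >= -1e-9))
})
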