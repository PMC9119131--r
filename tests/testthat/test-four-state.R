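test_that("apo limit splits the protein by the conformational equilibrium", {
  m <- four_state_model(keq_apo = 1, kd_wt = 684, kd_slip = Inf)
  st <- solve_four_state(m, p_total = 200, l_total = 0)
  expect_equal(st$c_wt_unbound, 100)
  expect_equal(st$c_slip_unbound, 100)
  expect_equal(st$c_wt_bound, 0)
  expect_equal(st$c_slip_bound, 0)
  expect_equal(st$c_ligand_free, 0)

  m3 <- four_state_model(keq_apo = 3, kd_wt = 100)
  st3 <- solve_four_state(m3, 100, 0)
  expect_equal(st3$c_wt_unbound, 75)
  expect_equal(st3$c_slip_unbound, 25)
})

test_that("solved titration point matches the closed-form free-ligand root", {
  # keq=1, kd_wt=684, slip non-binding, p=200, l=1000: the ligand balance
  # reduces to the quadratic Lf^2 + 568 Lf - 1368000 = 0
  lf <- (-568 + sqrt(568^2 + 4 * 1368000)) / 2
  m <- four_state_model(1, 684, Inf)
  st <- solve_four_state(m, 200, 1000)
  expect_equal(st$c_ligand_free, lf, tolerance = 1e-9)
  expect_equal(st$c_wt_unbound, 200 / (2 + lf / 684), tolerance = 1e-9)
  expect_equal(st$c_wt_bound, 200 / (2 + lf / 684) * lf / 684,
               tolerance = 1e-9)
  # frozen values from the quadratic
  expect_equal(st$c_wt_unbound, 59.80063, tolerance = 1e-6)
  expect_equal(st$c_wt_bound, 80.39874, tolerance = 1e-6)
  expect_equal(st$c_ligand_free, 919.60126, tolerance = 1e-6)
  # both mass balances to 1e-9 relative
  expect_lt(abs(st$c_wt_unbound + st$c_wt_bound + st$c_slip_unbound +
                  st$c_slip_bound - 200), 1e-9 * 200)
  expect_lt(abs(st$c_ligand_free + st$c_wt_bound + st$c_slip_bound - 1000),
            1e-9 * 1000)
})

test_that("equal affinities cannot shift the conformational ratio", {
  for (k in c(0.5, 1, 4)) {
    m <- four_state_model(keq_apo = k, kd_wt = 250, kd_slip = 250)
    for (l in c(0, 50, 400, 3000)) {
      st <- solve_four_state(m, 120, l)
      frac_wt <- (st$c_wt_unbound + st$c_wt_bound) / 120
      expect_equal(frac_wt, k / (1 + k), tolerance = 1e-9)
    }
  }
})

test_that("solver agrees with the independent bisection oracle", {
  withr::local_seed(421)
  for (i in 1:200) {
    inst <- random_instance()
    m <- four_state_model(inst$keq_apo, inst$kd_wt, inst$kd_slip)
    st <- solve_four_state(m, inst$p_total, inst$l_total)
    or <- oracle_solve(inst$keq_apo, inst$kd_wt, inst$kd_slip,
                       inst$p_total, inst$l_total)
    expect_equal(st$c_wt_unbound, or$wt_u, tolerance = 1e-6)
    expect_equal(st$c_wt_bound, or$wt_b, tolerance = 1e-6)
    expect_equal(st$c_slip_unbound, or$slip_u, tolerance = 1e-6)
    expect_equal(st$c_slip_bound, or$slip_b, tolerance = 1e-6)
  }
})

test_that("mass balances are conserved across random valid models", {
  withr::local_seed(1187)
  for (i in 1:200) {
    inst <- random_instance()
    m <- four_state_model(inst$keq_apo, inst$kd_wt, inst$kd_slip)
    st <- solve_four_state(m, inst$p_total, inst$l_total)
    expect_true(all(unlist(st[1:5]) >= 0))
    expect_lt(abs(st$c_wt_unbound + st$c_wt_bound + st$c_slip_unbound +
                    st$c_slip_bound - inst$p_total),
              1e-9 * max(inst$p_total, 1))
    expect_lt(abs(st$c_ligand_free + st$c_wt_bound + st$c_slip_bound -
                    inst$l_total), 1e-9 * max(inst$l_total, 1))
    # equilibrium relations hold at the solution
    expect_equal(st$c_wt_unbound / st$c_slip_unbound, inst$keq_apo,
                 tolerance = 1e-8)
    expect_equal(st$c_wt_bound,
                 st$c_wt_unbound * st$c_ligand_free / inst$kd_wt,
                 tolerance = 1e-8)
  }
})

test_that("bound-state equilibrium constant closes the thermodynamic cycle", {
  expect_equal(keq_bound(four_state_model(1, 684, 9000)), 9000 / 684)
  expect_equal(keq_bound(four_state_model(1, 684, 9000)), 13.1579,
               tolerance = 1e-4)
  expect_equal(keq_bound(four_state_model(1, 500, 500)), 1)
  expect_equal(keq_bound(four_state_model(0.5, 100, 400)), 2)
  # cycle closure: keq_bound * kd_wt / kd_slip == keq_apo exactly
  withr::local_seed(7)
  for (i in 1:50) {
    ka <- exp(runif(1, -2, 2))
    kw <- 10^runif(1, 0, 4)
    ks <- 10^runif(1, 0, 4)
    expect_equal(keq_bound(four_state_model(ka, kw, ks)) * kw / ks, ka,
                 tolerance = 1e-14)
  }
  expect_warning(kb <- keq_bound(four_state_model(1, 684, Inf)),
                 "non-binding")
  expect_identical(kb, Inf)
})

test_that("shift curve starts at the apo ratio and rises to the bound limit", {
  m <- four_state_model(1, 684, Inf)
  curve <- predict_shift_curve(m, 200, c(0, 25, 100, 1000))
  expect_equal(curve$percent_wt[1], 50)
  expect_equal(curve$percent_slip[1], 50)
  expect_equal(curve$percent_wt[curve$l_total == 1000], 70.0997,
               tolerance = 1e-5)
  expect_equal(curve$percent_wt + curve$percent_slip, rep(100, 4))

  # large-ligand limit approaches the bound-state equilibrium ratio
  m2 <- four_state_model(0.8, 100, 2000)
  lim <- predict_shift_curve(m2, 50, 1e9)
  kb <- keq_bound(m2)
  expect_equal(lim$percent_wt, 100 * kb / (1 + kb), tolerance = 1e-4)
})

test_that("fraction WT is monotone in ligand iff the WT affinity is higher", {
  withr::local_seed(99)
  grid <- c(0, 10, 50, 100, 500, 1000, 5000)
  for (i in 1:40) {
    ka <- exp(runif(1, -1.5, 1.5))
    kw <- 10^runif(1, 1, 3.5)
    ks <- 10^runif(1, 1, 3.5)
    p <- runif(1, 20, 300)
    curve <- predict_shift_curve(four_state_model(ka, kw, ks), p, grid)
    d <- diff(curve$percent_wt)
    if (kw < ks) {
      expect_true(all(d >= -1e-9))
    } else if (kw > ks) {
      expect_true(all(d <= 1e-9))
    }
  }
})

test_that("invalid model parameters and inputs are rejected", {
  expect_error(four_state_model(-1, 684), "keq_apo")
  expect_error(four_state_model(1, 0), "kd_wt")
  expect_error(four_state_model(1, 684, -5), "kd_slip")
  expect_error(four_state_model(1, 684, "sometimes"), "non-binding")
  m <- four_state_model(1, 684, "non-binding")
  expect_identical(m$kd_slip, Inf)
  expect_error(solve_four_state(m, -1, 0), "p_total")
  expect_error(solve_four_state(m, 100, -2), "l_total")
  expect_error(predict_shift_curve(m, 100, c(0, -5)), "ligand_grid")
})
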