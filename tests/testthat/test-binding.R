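titration_table <- function(ratios_wt, ratios_slip, cl) {
  # two unperturbed residue pairs per point; volumes = ratio x base volume
  purrr::map2(seq_along(cl), cl, function(i, l) {
    tibble::tibble(
      condition_id = sprintf("L%g", l), covariate = l,
      peak_id = c("p1.WT", "p2.WT", "p1.SLIP", "p2.SLIP"),
      conformer = rep(c("WT", "SLIP"), each = 2),
      volume = c(ratios_wt[i] * c(2, 3), ratios_slip[i] * c(1.5, 4)),
      unperturbed = TRUE
    )
  }) |> dplyr::bind_rows()
}

test_that("volumes identical to the reference give zero bound WT", {
  cl <- c(0, 100, 500)
  tab <- titration_table(rep(1, 3), rep(1, 3), cl)
  series <- titration_series(tab, c_wt_0 = 100, c_slip_0 = 100)
  pts <- bound_wt_series(series)
  expect_equal(pts$c_wt_bound, rep(0, 3))
  expect_error(fit_isotherm(pts$l_total, pts$c_wt_bound), "no binding")
})

test_that("volume accounting substitutes directly into the inversion", {
  # V_WT/V_WT,0 = 1.0, V_SLIP/V_SLIP,0 = 0.6, 100 µM pools, Keq_apo = 1
  tab <- titration_table(c(1, 1), c(1, 0.6), c(0, 200))
  series <- titration_series(tab, c_wt_0 = 100, c_slip_0 = 100,
                             keq_apo = 1)
  pts <- bound_wt_series(series)
  expect_equal(pts$c_wt_total, c(100, 100))
  expect_equal(pts$c_slip, c(100, 60))
  expect_equal(pts$c_wt_bound, c(0, 40))
})

test_that("the inversion generalises to apo ratios away from 50:50", {
  # keq_apo = 2: C_WT,B = C_WT,T - 2 * C_SLIP
  tab <- titration_table(c(1, 1.2), c(1, 0.7), c(0, 300))
  series <- titration_series(tab, c_wt_0 = 120, c_slip_0 = 60,
                             keq_apo = 2)
  pts <- bound_wt_series(series)
  expect_equal(pts$c_wt_bound[2], 1.2 * 120 - 2 * 0.7 * 60)
})

test_that("negative bound concentrations are clipped and flagged", {
  tab <- titration_table(c(1, 0.9), c(1, 1.0), c(0, 50))
  series <- titration_series(tab, c_wt_0 = 100, c_slip_0 = 100)
  expect_warning(pts <- bound_wt_series(series), "clipped")
  expect_equal(pts$c_wt_bound[2], 0)
  expect_true(pts$clipped[2])
  expect_false(pts$clipped[1])
})

test_that("per-peak response factors cancel in the volume ratios", {
  cfg1 <- synthetic_config(noise_cv = 0, n_peaks_per_conformer = 3,
                           response_factors = c(1, 1, 1))
  cfg2 <- synthetic_config(noise_cv = 0, n_peaks_per_conformer = 3,
                           response_factors = c(0.2, 3.7, 1.4, 9.1, 0.05,
                                                2.2))
  p1 <- bound_wt_series(generate_titration(cfg1))
  p2 <- bound_wt_series(generate_titration(cfg2))
  expect_equal(p2$c_wt_bound, p1$c_wt_bound, tolerance = 1e-12)
  expect_equal(p2$c_slip, p1$c_slip, tolerance = 1e-12)
})

test_that("zero-noise inversion returns the generator's bound WT exactly", {
  cfg <- synthetic_config(noise_cv = 0)
  series <- generate_titration(cfg)
  pts <- bound_wt_series(series)
  expect_equal(pts$c_wt_bound, series$truth$c_wt_bound, tolerance = 1e-9)
  expect_equal(pts$c_wt_total,
               series$truth$c_wt_unbound + series$truth$c_wt_bound,
               tolerance = 1e-9)
})

test_that("isotherm fit recovers exact single-site data", {
  cl <- c(0, 25, 50, 100, 200, 500, 1000)
  fit <- fit_isotherm(cl, 100 * cl / (500 + cl))
  expect_equal(fit$kd, 500, tolerance = 1e-6)
  expect_equal(fit$bmax, 100, tolerance = 1e-6)
  expect_equal(predict(fit, 0), 0)
  td <- tidy(fit)
  expect_equal(td$estimate, c(fit$kd, fit$bmax))
})

test_that("isotherm forward prediction matches hand arithmetic", {
  # Bmax = 111, Kd = 684 at CL = 1000: 111*1000/1684
  fit <- structure(list(kd = 684, bmax = 111), class = "binding_fit")
  expect_equal(predict(fit, 1000), 111 * 1000 / 1684)
  expect_equal(predict(fit, 1000), 65.9, tolerance = 1e-3)
  expect_equal(predict(fit, 0), 0)
})

test_that("isotherm fit rejects unusable inputs", {
  expect_error(fit_isotherm(c(0, 10), c(0, 1)), ">= 3")
  expect_error(fit_isotherm(c(10, 20, 30), c(1, 2, 3)), "zero-ligand")
  expect_error(fit_isotherm(c(0, 10, 20), c(0, -1, 2)), ">= 0")
})

test_that("end-to-end titration fit recovers generator truth at zero noise", {
  # WT-selective ligand, 50:50 apo equilibrium, amide-detected grid
  cfg <- synthetic_config(model = four_state_model(1, 684, Inf),
                          p_total = 200,
                          ligand_grid = c(0, 25, 50, 100, 200, 500, 1000),
                          noise_cv = 0)
  fit <- titration_fit(generate_titration(cfg))
  expect_equal(fit$kd, 684, tolerance = 1e-6)
  expect_equal(fit$bmax, 100, tolerance = 1e-6)  # apo WT pool
  # apparent parameters obey the linkage relations
  expect_equal(fit$apparent$kd, 684 * 2, tolerance = 1e-6)
  expect_equal(fit$apparent$bmax, 200, tolerance = 1e-6)
})

test_that("methyl-detected fits recover the same model on their own grids", {
  # single residue pair, methyl-style observables, two ligand series
  for (case in list(list(kd = 414, grid = c(0, 500, 1000, 2000, 3000, 4000)),
                    list(kd = 1947,
                         grid = c(0, 500, 1000, 2500, 5000, 10000)))) {
    cfg <- synthetic_config(model = four_state_model(1, case$kd, Inf),
                            p_total = 250, ligand_grid = case$grid,
                            n_peaks_per_conformer = 1, noise_cv = 0)
    fit <- methyl_titration_fit(generate_titration(cfg))
    expect_equal(fit$kd, case$kd, tolerance = 1e-6)
    expect_equal(fit$bmax, 125, tolerance = 1e-6)
    expect_identical(fit$observable, "methyl")
  }
  # observable-independence: amide and methyl pipelines agree
  cfg_a <- synthetic_config(noise_cv = 0, n_peaks_per_conformer = 5)
  cfg_m <- synthetic_config(noise_cv = 0, n_peaks_per_conformer = 1)
  fa <- titration_fit(generate_titration(cfg_a))
  fm <- methyl_titration_fit(generate_titration(cfg_m))
  expect_equal(fa$kd, fm$kd, tolerance = 1e-9)
})

test_that("invisible-state lower bound inverts the isotherm", {
  expect_equal(lower_bound_kd(1000, 0.10), 9000)
  expect_equal(lower_bound_kd(750, 0.5), 750)  # half-saturation
  expect_lt(lower_bound_kd(1000, 0.999), 2)    # f -> 1: no information
  # monotone decreasing in f, linear in cl_max
  f <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(lower_bound_kd(1000, f)) < 0))
  expect_equal(lower_bound_kd(c(1, 2, 5) * 1000, 0.2),
               c(1, 2, 5) * lower_bound_kd(1000, 0.2))
  expect_error(lower_bound_kd(1000, 0), "between 0 and 1")
  expect_error(lower_bound_kd(1000, 1), "between 0 and 1")
  expect_error(lower_bound_kd(-5, 0.1), "cl_max")
})

test_that("titration series constructor enforces the reference point", {
  tab <- titration_table(c(1, 0.9), c(1, 0.8), c(100, 500))
  expect_error(titration_series(tab, p_total = 200), "zero-ligand")
  tab0 <- titration_table(c(1, 0.9), c(1, 0.8), c(0, 500))
  expect_error(titration_series(tab0), "p_total")
  series <- titration_series(tab0, p_total = 200)
  expect_equal(series$c_wt_0 + series$c_slip_0, 200)
})

test_that("ML titration fit recovers kd and flags degenerate input", {
  cfg <- synthetic_config(noise_cv = 0, n_peaks_per_conformer = 2,
                          response_factors = c(0.8, 1.7))
  series <- generate_titration(cfg)
  fit <- fit_titration_ml(series)
  expect_equal(fit$kd, 684, tolerance = 1e-4)
  expect_s3_class(tidy(fit), "tbl_df")

  bad <- series
  bad$table$volume[1] <- 0
  expect_error(fit_titration_ml(bad), "positive")
})
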