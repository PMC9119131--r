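#' Configuration for synthetic peak-volume data
#'
#' Defines the ground truth from which synthetic slow-exchange peak-volume
#' tables are generated, so every pipeline stage can be validated by
#' parameter recovery. Defaults describe a protein with a 50:50 apo
#' equilibrium at 298 K whose SLIP-to-WT conversion has an enthalpy of
#' 6.8 kcal mol^-1 and entropy of 23.9 cal mol^-1 K^-1, titrated with a
#' WT-selective ligand (Kd 684 µM, SLIP non-binding) at 200 µM total
#' protein — the regime the package's worked examples explore.
#'
#' @param delta_h Conversion enthalpy, kcal mol^-1.
#' @param delta_s Conversion entropy, cal mol^-1 K^-1.
#' @param plateau_above Temperature (K) above which the apparent
#'   equilibrium is held constant, emulating the aggregation-limited
#'   plateau seen above ~303 K; `NULL` (default) disables the plateau.
#' @param model A [four_state_model()] used for titrations.
#' @param p_total Total protein concentration, µM.
#' @param temperature_grid Temperatures (K) for equilibrium series.
#' @param ligand_grid Total ligand concentrations (µM) for titrations;
#'   must include 0 (the reference point).
#' @param n_peaks_per_conformer Number of resolved peaks per conformer
#'   (peaks come in residue pairs: one WT and one SLIP peak per residue).
#' @param response_factors Positive per-residue response factors, one per
#'   residue pair, shared by the WT and SLIP peak of that pair (length
#'   `n_peaks_per_conformer`; default all 1). A length
#'   `2 * n_peaks_per_conformer` vector assigns independent per-peak
#'   factors (WT peaks first), which deliberately breaks the pair-sharing
#'   and biases raw population ratios — useful for probing robustness.
#' @param noise_cv Coefficient of variation of multiplicative volume
#'   noise (0 = noiseless).
#' @param noise_model `"lognormal"` (default; volumes stay positive, mean
#'   preserved) or `"additive"` (Gaussian, truncated at zero).
#' @param bound_attenuation Fraction of the bound-WT population visible in
#'   unperturbed WT peak volumes (default 1: unperturbed peaks report the
#'   full conformer total, the premise of the volume-accounting
#'   inversion). Values < 1 emulate broadening of the bound state and
#'   violate that premise on purpose.
#' @param seed Integer seed; identical seed and config give identical
#'   tables. `NULL` uses (and advances) the session RNG.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(delta_h = 6.8,
                             delta_s = 23.9,
                             plateau_above = NULL,
                             model = four_state_model(1, 684, Inf),
                             p_total = 200,
                             temperature_grid = seq(278, 303, by = 5),
                             ligand_grid = c(0, 25, 50, 100, 200, 500, 1000),
                             n_peaks_per_conformer = 5L,
                             response_factors = NULL,
                             noise_cv = 0,
                             noise_model = c("lognormal", "additive"),
                             bound_attenuation = 1,
                             seed = NULL) {
  noise_model <- match.arg(noise_model)
  n <- as.integer(n_peaks_per_conformer)
  if (n < 1L) stop("n_peaks_per_conformer must be >= 1", call. = FALSE)
  if (is.null(response_factors)) response_factors <- rep(1, n)
  if (!length(response_factors) %in% c(n, 2L * n)) {
    stop("response_factors must have length n_peaks_per_conformer (shared ",
         "within residue pairs) or twice that (independent per peak)",
         call. = FALSE)
  }
  if (any(response_factors <= 0)) {
    stop("response factors must be positive", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (bound_attenuation < 0 || bound_attenuation > 1) {
    stop("bound_attenuation must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(inherits(model, "four_state_model"), p_total > 0)
  structure(
    list(delta_h = delta_h, delta_s = delta_s, plateau_above = plateau_above,
         model = model, p_total = p_total,
         temperature_grid = temperature_grid, ligand_grid = ligand_grid,
         n_peaks_per_conformer = n,
         response_factors = as.numeric(response_factors),
         noise_cv = noise_cv, noise_model = noise_model,
         bound_attenuation = bound_attenuation,
         seed = seed),
    class = "synthetic_config"
  )
}

# per-peak response factors as (WT vector, SLIP vector)
split_response_factors <- function(config) {
  n <- config$n_peaks_per_conformer
  rf <- config$response_factors
  if (length(rf) == n) list(wt = rf, slip = rf)
  else list(wt = rf[seq_len(n)], slip = rf[n + seq_len(n)])
}

noise_factors <- function(n, cv, model) {
  if (cv == 0) return(rep(1, n))
  if (model == "lognormal") {
    s2 <- log(1 + cv^2)
    stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
  } else {
    pmax(1 + stats::rnorm(n, sd = cv), 1e-12)
  }
}

# run code under a seed without disturbing the session RNG stream
with_config_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Equilibrium constant on a temperature grid from van't Hoff parameters
#'
#' `Keq(T) = exp(dS/R - dH/(R*T))` with the kcal/cal unit bridge applied;
#' above `plateau_above` the value is held at `Keq(plateau_above)`.
#'
#' @param temperature Temperatures, K.
#' @inheritParams synthetic_config
#' @return Numeric vector of equilibrium constants.
#' @export
keq_of_temperature <- function(temperature, delta_h, delta_s,
                               plateau_above = NULL) {
  t_eff <- temperature
  if (!is.null(plateau_above)) t_eff <- pmin(temperature, plateau_above)
  exp(delta_s / 1000 / R_KCAL - delta_h / (R_KCAL * t_eff))
}

#' Generate a synthetic temperature-series peak-volume table
#'
#' For each temperature the conformer populations follow the van't Hoff
#' equilibrium constant (optionally plateaued above `plateau_above`), and
#' each peak's volume is population x response factor x multiplicative
#' noise. Peaks are emitted as residue pairs (`p1.WT`/`p1.SLIP`, ...), so
#' [percent_populations()] quantifies them pairwise.
#'
#' @param config A [synthetic_config()].
#' @return A peak-volume tibble in the standard dialect (see
#'   [read_peak_table()]), with attribute `truth`: a tibble of the
#'   generator's per-temperature `keq` and `percent_wt`.
#' @export
generate_equilibrium_series <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  tt <- config$temperature_grid
  if (length(tt) == 0L) stop("temperature_grid is empty", call. = FALSE)
  keq <- keq_of_temperature(tt, config$delta_h, config$delta_s,
                            config$plateau_above)
  truth <- tibble::tibble(temperature = tt, keq = keq,
                          percent_wt = 100 * keq / (1 + keq))
  rf <- split_response_factors(config)
  n <- config$n_peaks_per_conformer
  tab <- with_config_seed(config$seed, {
    purrr::map2(tt, keq, function(t1, k1) {
      pw <- k1 / (1 + k1)
      ps <- 1 / (1 + k1)
      tibble::tibble(
        condition_id = rep(sprintf("T%g", t1), 2L * n),
        covariate = t1,
        peak_id = c(sprintf("p%d.WT", seq_len(n)),
                    sprintf("p%d.SLIP", seq_len(n))),
        conformer = rep(c("WT", "SLIP"), each = n),
        volume = c(pw * rf$wt, ps * rf$slip) *
          noise_factors(2L * n, config$noise_cv, config$noise_model),
        volume_sd = NA_real_,
        unperturbed = TRUE
      )
    }) |>
      dplyr::bind_rows()
  })
  attr(tab, "truth") <- truth
  tab
}

#' Generate a synthetic ligand-titration series
#'
#' For each total ligand concentration the four-state equilibria are
#' solved exactly; unperturbed WT peaks report the total WT population
#' (unbound plus `bound_attenuation` x bound) and SLIP peaks the total
#' SLIP population, each times the peak's response factor and noise. The
#' default `bound_attenuation = 1` reproduces the premise of the
#' volume-accounting inversion, which therefore recovers the generator's
#' bound-WT concentrations exactly at zero noise.
#'
#' @param config A [synthetic_config()]; `ligand_grid` must include 0.
#' @return A [titration_series()] whose `truth` element is the tibble of
#'   solved per-point species concentrations.
#' @export
generate_titration <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lg <- config$ligand_grid
  if (length(lg) == 0L || !0 %in% lg) {
    stop("ligand_grid must be non-empty and include 0 ",
         "(the zero-ligand reference point)", call. = FALSE)
  }
  lg <- sort(unique(lg))
  states <- purrr::map(lg, function(l) {
    solve_four_state(config$model, config$p_total, l)
  }) |>
    dplyr::bind_rows()
  rf <- split_response_factors(config)
  n <- config$n_peaks_per_conformer
  tab <- with_config_seed(config$seed, {
    purrr::pmap(states, function(c_wt_unbound, c_wt_bound, c_slip_unbound,
                                 c_slip_bound, c_ligand_free, p_total,
                                 l_total) {
      obs_wt <- c_wt_unbound + config$bound_attenuation * c_wt_bound
      obs_slip <- c_slip_unbound + c_slip_bound
      tibble::tibble(
        condition_id = rep(sprintf("L%g", l_total), 2L * n),
        covariate = l_total,
        peak_id = c(sprintf("p%d.WT", seq_len(n)),
                    sprintf("p%d.SLIP", seq_len(n))),
        conformer = rep(c("WT", "SLIP"), each = n),
        volume = c(obs_wt * rf$wt, obs_slip * rf$slip) *
          noise_factors(2L * n, config$noise_cv, config$noise_model),
        volume_sd = NA_real_,
        unperturbed = TRUE
      )
    }) |>
      dplyr::bind_rows()
  })
  keq <- config$model$keq_apo
  series <- titration_series(
    tab,
    c_wt_0 = config$p_total * keq / (1 + keq),
    c_slip_0 = config$p_total / (1 + keq),
    p_total = config$p_total,
    keq_apo = keq
  )
  series$truth <- states
  series
}
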