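#' Gas constant in kcal mol^-1 K^-1
#'
#' The value used throughout for bridging `ln Keq` and free energies.
#' @export
R_KCAL <- 1.98720425e-3

#' Van't Hoff fit of a temperature-dependent conformational equilibrium
#'
#' Ordinary least squares of `ln Keq` on `1/T`:
#' `ln Keq = -dH/(R*T) + dS/R`, so the slope is `-dH/R` and the intercept
#' `dS/R`. The equilibrium-constant direction is fixed as the SLIP-to-WT
#' conversion, `Keq = [WT]/[SLIP]`; a positive enthalpy means the
#' conversion towards WT is endothermic.
#'
#' @param measurements A tibble of equilibrium measurements with columns
#'   `covariate` (temperature, K) and `keq` (or `percent_wt` from which
#'   `keq` is derived), e.g. the output of [percent_populations()] on a
#'   temperature series. An optional `sd_percent` column supplies weights
#'   when `weighted = TRUE`.
#' @param region Temperatures (K) to include in the fit; default all.
#'   See [select_linear_region()]. At least 3 distinct temperatures are
#'   required.
#' @param weighted Use inverse-variance weights propagated from
#'   `sd_percent`? Default `FALSE` (unweighted linear fit).
#' @return An object of class `thermo_fit`: a list with elements
#'   `delta_h` (kcal mol^-1), `delta_s` (cal mol^-1 K^-1), `se_delta_h`,
#'   `se_delta_s`, `r_squared`, `region` (temperatures used), `fit` (the
#'   underlying `lm`), and `data` (the points fitted). Supports [tidy()],
#'   [glance()], [delta_g()] and [ggplot2::autoplot()].
#' @examples
#' tt <- seq(278, 303, by = 5)
#' keq <- exp(23.9e-3 / R_KCAL - 6.8 / (R_KCAL * tt))
#' fit <- vant_hoff_fit(tibble::tibble(covariate = tt, keq = keq))
#' tidy(fit)
#' delta_g(fit, 298)
#' @export
vant_hoff_fit <- function(measurements, region = NULL, weighted = FALSE) {
  m <- tibble::as_tibble(measurements)
  if (!"covariate" %in% names(m)) {
    stop("measurements must have a 'covariate' column (temperature, K)",
         call. = FALSE)
  }
  if (!"keq" %in% names(m)) {
    if ("percent_wt" %in% names(m)) {
      m$keq <- keq_from_percent(m$percent_wt)
    } else {
      stop("measurements must have a 'keq' or 'percent_wt' column",
           call. = FALSE)
    }
  }
  if (!is.null(region)) {
    m <- m[m$covariate %in% region, , drop = FALSE]
  }
  bad <- !is.finite(m$keq) | m$keq <= 0
  if (any(bad)) {
    lab <- if ("condition_id" %in% names(m)) m$condition_id[bad] else
      paste0("T=", m$covariate[bad], " K")
    stop("non-positive or non-finite Keq at: ",
         paste(lab, collapse = ", "), call. = FALSE)
  }
  if (length(unique(m$covariate)) < 3L) {
    stop("van't Hoff fit needs >= 3 distinct temperatures; got ",
         length(unique(m$covariate)), call. = FALSE)
  }
  dat <- tibble::tibble(
    temperature = m$covariate,
    inv_t = 1 / m$covariate,
    ln_keq = log(m$keq)
  )
  w <- NULL
  if (weighted) {
    if (!"sd_percent" %in% names(m) || anyNA(m$sd_percent)) {
      stop("weighted fit requires sd_percent for every point", call. = FALSE)
    }
    # sd(ln Keq) = sd(p) * 100 / (p * (100 - p)) by the delta method
    p <- percent_from_keq(m$keq)
    sd_ln <- m$sd_percent * 100 / (p * (100 - p))
    w <- 1 / sd_ln^2
  }
  fit <- if (is.null(w)) stats::lm(ln_keq ~ inv_t, data = dat) else
    stats::lm(ln_keq ~ inv_t, data = dat, weights = w)
  cf <- summary(fit)$coefficients
  structure(
    list(
      delta_h = -cf["inv_t", "Estimate"] * R_KCAL,
      delta_s = cf["(Intercept)", "Estimate"] * R_KCAL * 1000,
      se_delta_h = cf["inv_t", "Std. Error"] * R_KCAL,
      se_delta_s = cf["(Intercept)", "Std. Error"] * R_KCAL * 1000,
      r_squared = summary(fit)$r.squared,
      region = sort(unique(dat$temperature)),
      fit = fit,
      data = dat,
      weighted = weighted
    ),
    class = "thermo_fit"
  )
}

#' Select the linear van't Hoff region of a temperature series
#'
#' Fold-switching equilibria are often linear in the van't Hoff sense only
#' over part of the measured range; here, above ~303 K the apparent
#' equilibrium plateaus (attributable to aggregation during
#' interconversion) and those points must be excluded. Two modes:
#'
#' * fixed cutoff (default): all temperatures `<= max_temperature`
#'   (default 303 K);
#' * `max_temperature = "auto"`: among contiguous low-temperature windows
#'   with at least `min_points` points, return the one maximising the
#'   `r_squared` of the van't Hoff line.
#'
#' @param measurements As in [vant_hoff_fit()].
#' @param min_points Minimum number of temperatures in a window (>= 3).
#' @param max_temperature Numeric cutoff in K, or `"auto"`.
#' @return A sorted numeric vector of temperatures (K).
#' @export
select_linear_region <- function(measurements, min_points = 3L,
                                 max_temperature = 303) {
  m <- tibble::as_tibble(measurements)
  stopifnot("covariate" %in% names(m))
  if (min_points < 3L) stop("min_points must be >= 3", call. = FALSE)
  temps <- sort(unique(m$covariate))
  if (identical(max_temperature, "auto")) {
    if (length(temps) < min_points) {
      stop("fewer than min_points distinct temperatures available",
           call. = FALSE)
    }
    best <- NULL
    best_r2 <- -Inf
    for (k in seq(min_points, length(temps))) {
      win <- temps[seq_len(k)]
      r2 <- vant_hoff_fit(m, region = win)$r_squared
      # near-ties resolved towards the larger window, so perfectly linear
      # data return the full range
      if (r2 >= best_r2 - 1e-9) {
        best_r2 <- max(best_r2, r2)
        best <- win
      }
    }
    return(best)
  }
  sel <- temps[temps <= max_temperature]
  if (length(sel) < min_points) {
    stop(sprintf(
      "only %d temperature(s) at or below %g K; need >= %d",
      length(sel), max_temperature, min_points), call. = FALSE)
  }
  sel
}

#' Free energy of the conformational conversion at a temperature
#'
#' `dG(T) = dH - T * dS`, with the enthalpy in kcal mol^-1 and the entropy
#' in cal mol^-1 K^-1 (the conventional reporting units); the factor of
#' 1000 bridging them is applied internally. A negative value means the
#' WT conformer is favoured at that temperature.
#'
#' @param fit A `thermo_fit` object, or a list/tibble with elements
#'   `delta_h` (kcal mol^-1) and `delta_s` (cal mol^-1 K^-1).
#' @param temperature Temperature in K (> 0); default 298 K.
#' @return Free energy in kcal mol^-1, vectorised over `temperature`.
#' @examples
#' delta_g(list(delta_h = 6.8, delta_s = 23.9), 298)  # about -0.32
#' @export
delta_g <- function(fit, temperature = 298) {
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("temperature must be positive (K)", call. = FALSE)
  }
  dh <- fit$delta_h
  ds <- fit$delta_s
  stopifnot(is.numeric(dh), is.numeric(ds))
  dh - temperature * ds / 1000
}

#' @export
print.thermo_fit <- function(x, ...) {
  cat("Van't Hoff fit (SLIP -> WT conversion, Keq = [WT]/[SLIP])\n")
  cat(sprintf("  dH: %8.3f +/- %.3f kcal mol^-1\n", x$delta_h, x$se_delta_h))
  cat(sprintf("  dS: %8.3f +/- %.3f cal mol^-1 K^-1\n",
              x$delta_s, x$se_delta_s))
  cat(sprintf("  dG(298 K): %.3f kcal mol^-1\n", delta_g(x, 298)))
  cat(sprintf("  r^2 = %.5f over %d temperatures (%g-%g K)%s\n",
              x$r_squared, length(x$region), min(x$region), max(x$region),
              if (isTRUE(x$weighted)) ", weighted" else ""))
  invisible(x)
}

#' @importFrom broom tidy
#' @export
broom::tidy

#' @importFrom broom glance
#' @export
broom::glance

#' @exportS3Method broom::tidy
tidy.thermo_fit <- function(x, ...) {
  tibble::tibble(
    term = c("delta_h", "delta_s"),
    estimate = c(x$delta_h, x$delta_s),
    std.error = c(x$se_delta_h, x$se_delta_s),
    unit = c("kcal mol^-1", "cal mol^-1 K^-1")
  )
}

#' @exportS3Method broom::glance
glance.thermo_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    delta_g_298 = delta_g(x, 298),
    nobs = nrow(x$data),
    t_min = min(x$region),
    t_max = max(x$region)
  )
}
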