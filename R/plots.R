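#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

save_plot <- function(p, path, width = 5, height = 4) {
  grDevices::pdf(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}

#' Plot conformer populations against the condition covariate
#'
#' @param object An `equilibrium_measurement` tibble from
#'   [percent_populations()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.equilibrium_measurement <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("percent_wt", "percent_slip"),
    names_to = "conformer", values_to = "percent",
    names_prefix = "percent_"
  ) |>
    dplyr::mutate(conformer = toupper(.data$conformer))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$covariate, y = .data$percent,
                               colour = .data$conformer)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "condition covariate (K or µM)",
                  y = "population (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Van't Hoff plot with the fitted line
#'
#' `ln Keq` against `1/T` with the fitted line over the fitted region.
#'
#' @param object A `thermo_fit` from [vant_hoff_fit()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.thermo_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble::tibble(inv_t = seq(min(dat$inv_t), max(dat$inv_t),
                                     length.out = 50))
  grid$ln_keq <- stats::predict(object$fit, newdata = grid)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$inv_t, y = .data$ln_keq)) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(1 / T ~ (K^-1)), y = expression(ln ~ K[eq]),
      subtitle = sprintf(
        "ΔH = %.2f kcal/mol, ΔS = %.1f cal/mol/K, r² = %.4f",
        object$delta_h, object$delta_s, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Binding isotherm with the fitted curve
#'
#' Bound-WT concentration against total ligand with the fitted
#' single-site isotherm.
#'
#' @param object A `binding_fit` from [fit_isotherm()] or
#'   [titration_fit()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.binding_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble::tibble(cl = seq(0, max(dat$cl), length.out = 100))
  grid$cwt_b <- predict(object, grid$cl)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cl, y = .data$cwt_b)) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(C[L] ~ (mu * M)),
      y = expression(C[WT * ",B"] ~ (mu * M)),
      subtitle = sprintf("Kd = %.1f ± %.1f µM, Bmax = %.1f ± %.1f µM",
                         object$kd, object$se_kd, object$bmax, object$se_bmax)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a predicted ligand-driven population shift
#'
#' @param curve Output of [predict_shift_curve()].
#' @return A ggplot.
#' @export
plot_shift_curve <- function(curve) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(curve),
    cols = c("percent_wt", "percent_slip"),
    names_to = "conformer", values_to = "percent",
    names_prefix = "percent_"
  ) |>
    dplyr::mutate(conformer = toupper(.data$conformer))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$l_total, y = .data$percent,
                               colour = .data$conformer)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(L[total] ~ (mu * M)),
                  y = "population (%)", colour = NULL) +
    ggplot2::theme_minimal()
}
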