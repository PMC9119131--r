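#' Titration series container
#'
#' Bundles a ligand-titration peak-volume table with its zero-ligand
#' reference concentrations for the volume-accounting analysis. The table
#' must contain a zero-ligand point (`covariate == 0`), which defines the
#' reference volumes and, unless overridden, the apo conformational
#' equilibrium constant.
#'
#' @param table Peak-volume table with `covariate` = total ligand
#'   concentration (µM) per condition.
#' @param c_wt_0,c_slip_0 Zero-ligand conformer concentrations (µM). If
#'   omitted, both are derived from `p_total` and the apo populations
#'   quantified from the zero-ligand point.
#' @param p_total Total protein concentration (µM); required when
#'   `c_wt_0`/`c_slip_0` are omitted.
#' @param keq_apo Apo equilibrium constant \[WT\]/\[SLIP\]; default measured
#'   from the zero-ligand point (`c_wt_0 / c_slip_0`).
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(table, c_wt_0 = NULL, c_slip_0 = NULL,
                             p_total = NULL, keq_apo = NULL) {
  table <- validate_peak_table(table)
  cl <- sort(unique(table$covariate))
  if (!0 %in% cl) {
    stop("titration table has no zero-ligand reference point ",
         "(no condition with covariate == 0)", call. = FALSE)
  }
  if (is.null(c_wt_0) || is.null(c_slip_0)) {
    if (is.null(p_total)) {
      stop("supply either c_wt_0 and c_slip_0, or p_total (µM)",
           call. = FALSE)
    }
    apo_cond <- unique(table$condition_id[table$covariate == 0])
    apo <- percent_populations(table, condition_id = apo_cond)
    c_wt_0 <- p_total * apo$percent_wt[1] / 100
    c_slip_0 <- p_total * apo$percent_slip[1] / 100
  }
  if (is.null(keq_apo)) keq_apo <- c_wt_0 / c_slip_0
  stopifnot(c_wt_0 > 0, c_slip_0 > 0, keq_apo > 0)
  structure(
    list(table = table, c_wt_0 = c_wt_0, c_slip_0 = c_slip_0,
         keq_apo = keq_apo,
         p_total = if (is.null(p_total)) c_wt_0 + c_slip_0 else p_total),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cl <- sort(unique(x$table$covariate))
  cat(sprintf(paste0("Slow-exchange ligand titration: %d points ",
                     "(CL %g-%g µM), p_total = %g µM\n"),
              length(cl), min(cl), max(cl), x$p_total))
  cat(sprintf("  zero-ligand pools: WT %g µM, SLIP %g µM (Keq_apo = %g)\n",
              x$c_wt_0, x$c_slip_0, x$keq_apo))
  invisible(x)
}

#' Ligand-bound WT concentration along a titration
#'
#' The volume-accounting inversion for a conformational-selection
#' titration in slow exchange. At each ligand concentration, unperturbed
#' peaks scale the zero-ligand conformer pools to the current total WT
#' concentration `C_WT,T` and SLIP concentration `C_SLIP`
#' (see [scale_concentrations()]). Assuming the SLIP conformer remains in
#' its apo equilibrium with the *unbound* WT conformer
#' (`C_WT,U = keq_apo * C_SLIP`), the ligand-bound WT concentration is
#'
#' `C_WT,B = C_WT,T - keq_apo * C_SLIP`.
#'
#' With a 50:50 apo equilibrium (`keq_apo = 1`) this reduces to the simple
#' difference of the two conformer concentrations. Negative values, which
#' arise from volume noise at low ligand, are clipped to zero and flagged
#' with a warning (the grid point is kept so the isotherm fit sees the
#' full ligand grid).
#'
#' @param series A [titration_series()].
#' @return A tibble with one row per titration point: `l_total`,
#'   `c_wt_total`, `c_slip`, `c_wt_bound`, `clipped`.
#' @export
bound_wt_series <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  tb <- series$table
  ref_cond <- unique(tb$condition_id[tb$covariate == 0])
  if (length(ref_cond) != 1L) {
    stop("expected exactly one zero-ligand condition, found ",
         length(ref_cond), call. = FALSE)
  }
  reference <- tb[tb$condition_id == ref_cond, , drop = FALSE]
  conds <- tb |>
    dplyr::distinct(.data$condition_id, .data$covariate) |>
    dplyr::arrange(.data$covariate)
  rows <- purrr::pmap(conds, function(condition_id, covariate) {
    vols <- tb[tb$condition_id == condition_id, , drop = FALSE]
    sc <- scale_concentrations(vols, reference,
                               c_wt_0 = series$c_wt_0,
                               c_slip_0 = series$c_slip_0)
    cwtb <- sc$c_wt_total - series$keq_apo * sc$c_slip
    tibble::tibble(
      condition_id = condition_id,
      l_total = covariate,
      c_wt_total = sc$c_wt_total,
      c_slip = sc$c_slip,
      c_wt_bound = max(0, cwtb),
      clipped = cwtb < 0
    )
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$clipped)) {
    warning(sprintf(
      "negative bound-WT concentration clipped to 0 at CL = %s µM",
      paste(out$l_total[out$clipped], collapse = ", ")), call. = FALSE)
  }
  out
}

#' Fit a single-site binding isotherm
#'
#' Nonlinear least squares of the 1:1 isotherm
#' `C_WT,B = Bmax * CL / (Kd + CL)` against per-point bound-WT
#' concentrations, with positivity bounds (Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]). Note `CL` here is the *total* ligand
#' concentration, as in the classical weak-binding titration analysis
#' where ligand is in excess of bound protein.
#'
#' Starting values: `Kd = median(CL > 0)`, `Bmax = 1.2 * max(C_WT,B)`;
#' bounds `Kd` in (0, 1e6] µM, `Bmax` in (0, `p_total`] µM.
#'
#' @param cl Total ligand concentrations (µM), including 0.
#' @param cwt_b Bound-WT concentrations (µM, >= 0), same length.
#' @param p_total Upper bound for `Bmax` (µM); default `Inf` (no protein
#'   cap). A fitted `Bmax` above the nominal binding-competent pool is
#'   reported with a warning, not an error.
#' @param nominal_pool Optional nominal binding-competent conformer pool
#'   (µM) used only for the sanity warning.
#' @return An object of class `binding_fit`: list with `kd`, `bmax`,
#'   `se_kd`, `se_bmax` (µM), `residuals`, `data`, `fit`. Supports
#'   [tidy()], [glance()], [predict()] and [ggplot2::autoplot()].
#' @examples
#' cl <- c(0, 25, 50, 100, 200, 500, 1000)
#' fit_isotherm(cl, 100 * cl / (500 + cl))
#' @export
fit_isotherm <- function(cl, cwt_b, p_total = Inf, nominal_pool = NULL) {
  stopifnot(length(cl) == length(cwt_b))
  if (length(cl) < 3L) {
    stop("isotherm fit needs >= 3 titration points", call. = FALSE)
  }
  if (!any(cl == 0)) {
    stop("isotherm fit requires the zero-ligand point (CL = 0)",
         call. = FALSE)
  }
  if (any(cwt_b < 0)) stop("bound-WT concentrations must be >= 0",
                           call. = FALSE)
  if (all(cwt_b == 0)) {
    stop("no binding signal: bound-WT concentration is zero at every point",
         call. = FALSE)
  }
  dat <- tibble::tibble(cl = as.numeric(cl), cwt_b = as.numeric(cwt_b))
  start <- list(kd = stats::median(dat$cl[dat$cl > 0]),
                bmax = 1.2 * max(dat$cwt_b))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      cwt_b ~ bmax * cl / (kd + cl),
      data = dat, start = start,
      lower = c(kd = 1e-12, bmax = 1e-12),
      upper = c(kd = 1e6, bmax = if (is.finite(p_total)) p_total else Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) {
      stop(sprintf(
        "isotherm fit failed (start: Kd=%g, Bmax=%g): %s",
        start$kd, start$bmax, conditionMessage(e)), call. = FALSE)
    }
  )
  cf <- summary(fit)$coefficients
  out <- structure(
    list(
      kd = cf["kd", "Estimate"],
      bmax = cf["bmax", "Estimate"],
      se_kd = cf["kd", "Std. Error"],
      se_bmax = cf["bmax", "Std. Error"],
      residuals = as.numeric(stats::residuals(fit)),
      data = dat,
      fit = fit
    ),
    class = "binding_fit"
  )
  if (!is.null(nominal_pool) && out$bmax > nominal_pool) {
    warning(sprintf(
      "fitted Bmax (%.3g µM) exceeds the nominal binding-competent pool (%.3g µM)",
      out$bmax, nominal_pool), call. = FALSE)
  }
  out
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Single-site isotherm fit: C_WT,B = Bmax * CL / (Kd + CL)\n")
  cat(sprintf("  Kd   = %8.3f +/- %.3f µM\n", x$kd, x$se_kd))
  cat(sprintf("  Bmax = %8.3f +/- %.3f µM\n", x$bmax, x$se_bmax))
  cat(sprintf("  %d points, residual sd %.3g µM\n",
              nrow(x$data), stats::sd(x$residuals)))
  invisible(x)
}

#' @exportS3Method broom::tidy
tidy.binding_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kd", "bmax"),
    estimate = c(x$kd, x$bmax),
    std.error = c(x$se_kd, x$se_bmax),
    unit = "µM"
  )
}

#' @exportS3Method broom::glance
glance.binding_fit <- function(x, ...) {
  tibble::tibble(
    sigma = stats::sd(x$residuals),
    nobs = nrow(x$data),
    cl_max = max(x$data$cl),
    isConv = x$fit$convInfo$isConv %||% TRUE
  )
}

#' @export
predict.binding_fit <- function(object, cl = NULL, ...) {
  if (is.null(cl)) cl <- object$data$cl
  object$bmax * cl / (object$kd + cl)
}

#' Fit a titration end-to-end: volume accounting plus isotherm
#'
#' Runs [bound_wt_series()] on a [titration_series()], extracts the free
#' ligand concentration at each point (`CL_free = L_total - C_WT,B`,
#' exact when the other conformer is non-binding), and fits the
#' single-site isotherm against it with [fit_isotherm()].
#'
#' Under conformational selection with a non-binding SLIP state, the
#' bound-WT concentration versus *free* ligand is exactly a single-site
#' isotherm — but with apparent parameters set by thermodynamic linkage:
#' `Kd_app = kd_wt * (1 + Keq) / Keq` and `Bmax_app = p_total` (at
#' saturation the entire protein pool converts to bound WT). By default
#' (`intrinsic = TRUE`) the reported parameters are converted back
#' through the linkage factor `Keq / (1 + Keq)`: `kd` is then the
#' conformer-intrinsic dissociation constant for the WT state and `bmax`
#' the apo WT pool (the maximal binding expected over an experimentally
#' accessible ligand range). With `intrinsic = FALSE` the apparent
#' parameters are reported as fitted. Either way the unconverted apparent
#' fit is kept in the `apparent` element.
#'
#' [methyl_titration_fit()] is the identically parameterised entry point
#' for methyl-detected titrations (e.g. a pair of well-resolved upfield
#' methyl peaks monitored instead of amides when amide peaks broaden);
#' the model makes no distinction between the observables, so amide- and
#' methyl-derived fits are reported separately but computed by the same
#' machinery.
#'
#' @param series A [titration_series()].
#' @param intrinsic Report conformer-intrinsic `kd` and apo-WT-pool
#'   `bmax` via the linkage conversion (default), or raw apparent
#'   parameters.
#' @param ... Passed to [fit_isotherm()].
#' @return A `binding_fit` whose `points` element holds the per-point
#'   volume-accounting intermediates and whose `apparent` element holds
#'   the unconverted (apparent-parameter) fit.
#' @export
titration_fit <- function(series, intrinsic = TRUE, ...) {
  pts <- bound_wt_series(series)
  cl_free <- pmax(0, pts$l_total - pts$c_wt_bound)
  # physical bound: protein-bound ligand cannot exceed the protein total,
  # so the apparent Bmax is constrained to (0, p_total]
  fit <- fit_isotherm(cl_free, pts$c_wt_bound,
                      p_total = series$p_total, ...)
  fit$points <- pts
  if (intrinsic) {
    link <- series$keq_apo / (1 + series$keq_apo)
    app <- fit[c("kd", "bmax", "se_kd", "se_bmax")]
    fit$apparent <- app
    fit$kd <- app$kd * link
    fit$bmax <- app$bmax * link
    fit$se_kd <- app$se_kd * link
    fit$se_bmax <- app$se_bmax * link
  }
  fit
}

#' @rdname titration_fit
#' @export
methyl_titration_fit <- function(series, ...) {
  fit <- titration_fit(series, ...)
  fit$observable <- "methyl"
  fit
}

#' Lower bound on the dissociation constant of an invisible bound state
#'
#' When a bound state is too weakly populated (or too broadened) to
#' observe, its affinity can still be bounded: if at the highest ligand
#' concentration `cl_max` the invisible bound state occupies at most a
#' fraction `f` of its conformer pool, then by the single-site isotherm
#' `f = cl_max / (kd + cl_max)`, so the true dissociation constant
#' satisfies `kd >= cl_max * (1 - f) / f`.
#'
#' @param cl_max Highest ligand concentration in the titration (µM, > 0).
#' @param max_bound_fraction Maximal undetected bound fraction `f`,
#'   strictly between 0 and 1 (default 0.10).
#' @return Lower bound on the dissociation constant, in µM.
#' @examples
#' lower_bound_kd(1000, 0.10)  # 9000 µM = 9 mM
#' @export
lower_bound_kd <- function(cl_max, max_bound_fraction = 0.10) {
  if (!is.numeric(cl_max) || any(cl_max <= 0)) {
    stop("cl_max must be positive (µM)", call. = FALSE)
  }
  f <- max_bound_fraction
  if (!is.numeric(f) || any(f <= 0) || any(f >= 1)) {
    stop("max_bound_fraction must lie strictly between 0 and 1",
         call. = FALSE)
  }
  cl_max * (1 - f) / f
}
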