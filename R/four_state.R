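#' Four-state conformational-selection binding model
#'
#' Constructs the thermodynamic model underlying conformational-selection
#' ligand binding to a protein that interconverts between two folded states,
#' here labelled WT (original strand register) and SLIP (slipped register).
#' The four states are WT-unbound, WT-bound, SLIP-unbound and SLIP-bound,
#' connected in a thermodynamic cycle: the apo conformational equilibrium
#' constant `keq_apo = [WT_unbound]/[SLIP_unbound]`, and conformer-specific
#' 1:1 dissociation constants `kd_wt` and `kd_slip`.
#'
#' A conformer that binds ligand only negligibly is declared non-binding by
#' setting its dissociation constant to `Inf` (the strings `"non-binding"`,
#' `"nonbinding"`, or `NA` are also accepted and normalised to `Inf`).
#' `Inf` is an exact sentinel in IEEE arithmetic — `x / Inf` is exactly 0 —
#' so the solver needs no special-casing.
#'
#' All concentrations in this package are in µM.
#'
#' @param keq_apo Apo equilibrium constant \[WT\]/\[SLIP\] (dimensionless, > 0).
#' @param kd_wt Dissociation constant of the ligand for the WT conformer (µM).
#' @param kd_slip Dissociation constant for the SLIP conformer (µM), or
#'   `Inf` / `"non-binding"` / `NA` for a conformer that does not bind.
#' @return An object of class `four_state_model`.
#' @examples
#' m <- four_state_model(keq_apo = 1, kd_wt = 684, kd_slip = "non-binding")
#' solve_four_state(m, p_total = 200, l_total = 1000)
#' @export
four_state_model <- function(keq_apo, kd_wt, kd_slip = Inf) {
  if (is.character(kd_slip)) {
    if (!tolower(kd_slip) %in% c("non-binding", "nonbinding", "inf")) {
      stop("kd_slip must be numeric, Inf, NA, or the string \"non-binding\"",
           call. = FALSE)
    }
    kd_slip <- Inf
  }
  if (length(kd_slip) == 1L && is.na(kd_slip)) kd_slip <- Inf
  stopifnot(is.numeric(keq_apo), length(keq_apo) == 1L,
            is.numeric(kd_wt), length(kd_wt) == 1L,
            is.numeric(kd_slip), length(kd_slip) == 1L)
  if (!is.finite(keq_apo) || keq_apo <= 0) {
    stop("keq_apo must be a finite positive number", call. = FALSE)
  }
  if (!is.finite(kd_wt) || kd_wt <= 0) {
    stop("kd_wt must be a finite positive number (µM)", call. = FALSE)
  }
  if (kd_slip <= 0) stop("kd_slip must be positive (µM) or Inf", call. = FALSE)
  structure(
    list(keq_apo = as.numeric(keq_apo),
         kd_wt = as.numeric(kd_wt),
         kd_slip = as.numeric(kd_slip)),
    class = "four_state_model"
  )
}

#' @export
print.four_state_model <- function(x, ...) {
  cat("Four-state conformational-selection model\n")
  cat(sprintf("  Keq (apo, [WT]/[SLIP]): %g\n", x$keq_apo))
  cat(sprintf("  Kd (WT conformer):      %g µM\n", x$kd_wt))
  cat(sprintf("  Kd (SLIP conformer):    %s\n",
              if (is.finite(x$kd_slip)) sprintf("%g µM", x$kd_slip)
              else "non-binding"))
  kb <- x$keq_apo * x$kd_slip / x$kd_wt
  cat(sprintf("  Keq (bound):            %s\n",
              if (is.finite(kb)) sprintf("%g", kb) else "infinite"))
  invisible(x)
}

#' Equilibrium constant between the two ligand-bound states
#'
#' Closes the thermodynamic cycle: the equilibrium constant between the
#' WT-bound and SLIP-bound states is
#' `keq_bound = keq_apo * kd_slip / kd_wt`. Preferential binding to the WT
#' conformer (`kd_wt < kd_slip`) makes the bound equilibrium more
#' WT-favoured than the apo one.
#'
#' @param model A [four_state_model()].
#' @return The bound-state equilibrium constant (dimensionless). When the
#'   SLIP conformer is non-binding the constant is formally infinite; `Inf`
#'   is returned with a warning.
#' @examples
#' keq_bound(four_state_model(1, kd_wt = 684, kd_slip = 9000)) # ~13.2
#' @export
keq_bound <- function(model) {
  stopifnot(inherits(model, "four_state_model"))
  if (!is.finite(model$kd_slip)) {
    warning("SLIP conformer is non-binding: bound-state equilibrium ",
            "constant is infinite", call. = FALSE)
    return(Inf)
  }
  model$keq_apo * model$kd_slip / model$kd_wt
}

#' Solve the coupled conformational and binding equilibria
#'
#' Given total protein and total ligand, finds the unique set of species
#' concentrations satisfying both mass balances and all equilibrium
#' relations of the four-state cycle. With free-ligand concentration `L`,
#' every protein species is proportional to the unbound SLIP concentration
#' `s`:
#' `WT_u = Keq * s`, `WT_b = Keq * s * L / kd_wt`, `SLIP_b = s * L / kd_slip`,
#' so protein mass balance yields `s` in closed form for any `L`, and the
#' ligand mass balance becomes a strictly increasing scalar function of `L`
#' with a guaranteed sign change on `[0, l_total]`. The solver is 1-D
#' root-finding on `L` ([stats::uniroot()]) followed by back-substitution;
#' it is deterministic and unconditionally convergent.
#'
#' @param model A [four_state_model()].
#' @param p_total Total protein concentration (µM, >= 0).
#' @param l_total Total ligand concentration (µM, >= 0).
#' @param rel_tol Relative tolerance on the mass-balance residuals
#'   (dimensionless; default 1e-10).
#' @return A one-row tibble of class `conformer_state` with columns
#'   `c_wt_unbound`, `c_wt_bound`, `c_slip_unbound`, `c_slip_bound`,
#'   `c_ligand_free` (µM) plus the inputs `p_total` and `l_total`.
#' @examples
#' m <- four_state_model(1, 684, Inf)
#' solve_four_state(m, p_total = 200, l_total = 1000)
#' @export
solve_four_state <- function(model, p_total, l_total, rel_tol = 1e-10) {
  stopifnot(inherits(model, "four_state_model"))
  if (!is.numeric(p_total) || length(p_total) != 1L || is.na(p_total) ||
      p_total < 0) {
    stop("p_total must be a single non-negative concentration (µM)",
         call. = FALSE)
  }
  if (!is.numeric(l_total) || length(l_total) != 1L || is.na(l_total) ||
      l_total < 0) {
    stop("l_total must be a single non-negative concentration (µM)",
         call. = FALSE)
  }
  keq <- model$keq_apo
  kdw <- model$kd_wt
  kds <- model$kd_slip

  # unbound SLIP for a given free-ligand concentration (protein balance)
  slip_u_of <- function(l_free) {
    p_total / (1 + keq + keq * l_free / kdw + l_free / kds)
  }
  # ligand bound to protein at a given free-ligand concentration
  bound_of <- function(l_free) {
    slip_u_of(l_free) * (keq * l_free / kdw + l_free / kds)
  }

  if (l_total == 0 || p_total == 0) {
    l_free <- l_total
  } else {
    f <- function(l_free) l_free + bound_of(l_free) - l_total
    # f(0) = -l_total < 0, f(l_total) >= 0: bracketed, strictly increasing
    sol <- tryCatch(
      stats::uniroot(f, lower = 0, upper = l_total,
                     tol = max(.Machine$double.eps^0.9,
                               rel_tol * l_total / 100),
                     maxiter = 10000L),
      error = function(e) {
        stop(sprintf(paste0("four-state solver failed for keq_apo=%g, ",
                            "kd_wt=%g, kd_slip=%g, p_total=%g, l_total=%g: %s"),
                     keq, kdw, kds, p_total, l_total, conditionMessage(e)),
             call. = FALSE)
      }
    )
    l_free <- sol$root
    # one Newton polish: f is smooth and strictly increasing
    fp <- function(l) (f(l + 1e-8 * max(1, l)) - f(l)) / (1e-8 * max(1, l))
    l_free <- max(0, min(l_total, l_free - f(l_free) / fp(l_free)))
  }

  s_u <- slip_u_of(l_free)
  out <- tibble::tibble(
    c_wt_unbound = keq * s_u,
    c_wt_bound = keq * s_u * l_free / kdw,
    c_slip_unbound = s_u,
    c_slip_bound = s_u * l_free / kds,
    c_ligand_free = l_free,
    p_total = p_total,
    l_total = l_total
  )
  res_p <- abs(out$c_wt_unbound + out$c_wt_bound + out$c_slip_unbound +
                 out$c_slip_bound - p_total)
  res_l <- abs(out$c_ligand_free + out$c_wt_bound + out$c_slip_bound - l_total)
  if (res_p > rel_tol * max(p_total, 1) || res_l > rel_tol * max(l_total, 1)) {
    stop(sprintf(paste0("four-state solver did not reach tolerance for ",
                        "keq_apo=%g, kd_wt=%g, kd_slip=%g, p_total=%g, ",
                        "l_total=%g (residuals %.3g, %.3g)"),
                 keq, kdw, kds, p_total, l_total, res_p, res_l),
         call. = FALSE)
  }
  class(out) <- c("conformer_state", class(out))
  out
}

#' Predicted conformer-population shift along a ligand titration
#'
#' Forward model of the ligand-driven population shift: solves the
#' four-state equilibria on a grid of total ligand concentrations and
#' reports the percentage of protein in each conformation (bound plus
#' unbound). When the ligand prefers the WT conformer (`kd_wt < kd_slip`)
#' the WT percentage rises monotonically from the apo value
#' `100 * keq_apo / (1 + keq_apo)` towards the bound-state limit set by
#' [keq_bound()].
#'
#' @param model A [four_state_model()].
#' @param p_total Total protein concentration (µM).
#' @param ligand_grid Vector of total ligand concentrations (µM, >= 0).
#' @param rel_tol Passed to [solve_four_state()].
#' @return A tibble with columns `l_total`, `percent_wt`, `percent_slip`
#'   and the solved species concentrations for each grid point.
#' @examples
#' m <- four_state_model(1, 684, Inf)
#' predict_shift_curve(m, 200, c(0, 100, 500, 1000))
#' @export
predict_shift_curve <- function(model, p_total, ligand_grid, rel_tol = 1e-10) {
  stopifnot(inherits(model, "four_state_model"))
  if (any(!is.finite(ligand_grid)) || any(ligand_grid < 0)) {
    stop("ligand_grid values must be finite and >= 0 (µM)", call. = FALSE)
  }
  if (p_total <= 0) stop("p_total must be positive (µM)", call. = FALSE)
  states <- purrr::map(ligand_grid, function(l) {
    solve_four_state(model, p_total, l, rel_tol = rel_tol)
  })
  dplyr::bind_rows(states) |>
    dplyr::mutate(
      percent_wt = 100 * (.data$c_wt_unbound + .data$c_wt_bound) / p_total,
      percent_slip = 100 * (.data$c_slip_unbound + .data$c_slip_bound) /
        p_total
    ) |>
    dplyr::select("l_total", "percent_wt", "percent_slip",
                  dplyr::everything(), -"p_total") |>
    dplyr::mutate(p_total = p_total)
}
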