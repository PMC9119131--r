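# Independent brute-force oracle for the coupled-equilibrium solver.
#
# Deliberately different from the package path: plain interval bisection
# (no uniroot, no Newton polish) on the free-ligand concentration, with the
# species expressed through per-conformer bound fractions rather than the
# unbound-SLIP parameterisation used by the solver.
oracle_solve <- function(keq_apo, kd_wt, kd_slip, p_total, l_total,
                         iters = 200L) {
  species_at <- function(l_free) {
    # conformer totals W, S from the conformational constraint on the
    # unbound species and protein mass balance
    theta_w <- l_free / (kd_wt + l_free)           # bound fraction of WT
    theta_s <- if (is.finite(kd_slip)) l_free / (kd_slip + l_free) else 0
    # WT_u = keq * SLIP_u  =>  W (1 - theta_w) = keq * S (1 - theta_s)
    # with W + S = p_total
    ratio_ws <- keq_apo * (1 - theta_s) / (1 - theta_w)
    s_tot <- p_total / (1 + ratio_ws)
    w_tot <- p_total - s_tot
    list(
      wt_u = w_tot * (1 - theta_w), wt_b = w_tot * theta_w,
      slip_u = s_tot * (1 - theta_s), slip_b = s_tot * theta_s,
      l_free = l_free
    )
  }
  bound_lig <- function(l_free) {
    sp <- species_at(l_free)
    sp$wt_b + sp$slip_b
  }
  lo <- 0
  hi <- l_total
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (mid + bound_lig(mid) < l_total) lo <- mid else hi <- mid
  }
  species_at((lo + hi) / 2)
}

# random valid four-state instance for property tests
random_instance <- function() {
  list(
    keq_apo = exp(stats::runif(1, -2, 2)),
    kd_wt = 10^stats::runif(1, 0, 4),
    kd_slip = if (stats::runif(1) < 0.3) Inf else 10^stats::runif(1, 0, 4),
    p_total = stats::runif(1, 10, 500),
    l_total = stats::runif(1, 0, 5000)
  )
}
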