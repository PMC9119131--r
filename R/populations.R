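#' Conformer populations from slow-exchange peak volumes
#'
#' In slow exchange each conformer gives its own resolvable peaks, and the
#' relative volumes of well-dispersed peaks from the two conformations
#' report their relative populations directly. This function converts a
#' conformer-labelled peak-volume table into percent populations and the
#' equilibrium constant `Keq = [WT]/[SLIP]` for one condition (or all
#' conditions at once).
#'
#' Peak pairing: when a WT peak and a SLIP peak share a residue tag — the
#' `peak_id` with any trailing/leading conformer label (`wt`, `slip`,
#' case-insensitive, separated by `.`, `_`, `-` or `:`) stripped — they are
#' treated as a pair and the percentage is computed per pair, then averaged
#' across pairs; `sd_percent` is the standard deviation across pairs.
#' When no pairing is possible the volumes are summed per conformer and
#' `sd_percent` is a leave-one-peak-out jackknife standard error.
#'
#' @param table A peak-volume table (see [read_peak_table()]): columns
#'   `condition_id`, `covariate`, `peak_id`, `conformer` (`"WT"`/`"SLIP"`),
#'   `volume`, and optionally `volume_sd`, `unperturbed`.
#' @param condition_id Condition(s) to quantify; default all conditions in
#'   the table.
#' @return A tibble of class `equilibrium_measurement` with one row per
#'   condition: `condition_id`, `covariate`, `percent_wt`, `percent_slip`,
#'   `keq`, `sd_percent`, `n_peaks_wt`, `n_peaks_slip`, `paired`.
#' @examples
#' tbl <- tibble::tibble(
#'   condition_id = "apo", covariate = 298,
#'   peak_id = c("G401.wt", "G401.slip", "L408.wt", "L408.slip"),
#'   conformer = c("WT", "SLIP", "WT", "SLIP"),
#'   volume = c(1, 1, 1.1, 1.1)
#' )
#' percent_populations(tbl)
#' @export
percent_populations <- function(table, condition_id = NULL) {
  table <- validate_peak_table(table)
  if (!is.null(condition_id)) {
    missing_ids <- setdiff(condition_id, unique(table$condition_id))
    if (length(missing_ids) > 0L) {
      stop("condition(s) not found in table: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    table <- dplyr::filter(table, .data$condition_id %in% !!condition_id)
  }
  out <- table |>
    dplyr::group_by(.data$condition_id) |>
    dplyr::group_modify(~ quantify_one_condition(.x, .y$condition_id)) |>
    dplyr::ungroup()
  class(out) <- c("equilibrium_measurement", class(out))
  out
}

# residue tag = peak_id with a conformer label affix removed
residue_tag <- function(peak_id) {
  tag <- gsub("(?i)([._:-]?(wt|slip)[._:-]?)", "", peak_id, perl = TRUE)
  tag
}

quantify_one_condition <- function(rows, cond) {
  wt <- rows[rows$conformer == "WT", , drop = FALSE]
  slip <- rows[rows$conformer == "SLIP", , drop = FALSE]
  if (nrow(wt) == 0L || nrow(slip) == 0L) {
    missing <- if (nrow(wt) == 0L) "WT" else "SLIP"
    stop(sprintf("condition '%s' has no %s-labelled peaks", cond, missing),
         call. = FALSE)
  }
  if (sum(rows$volume) == 0) {
    stop(sprintf("condition '%s' has all-zero volumes; populations undefined",
                 cond), call. = FALSE)
  }
  wt$tag <- residue_tag(wt$peak_id)
  slip$tag <- residue_tag(slip$peak_id)
  shared <- intersect(wt$tag, slip$tag)
  # drop tags that are ambiguous (duplicated within a conformer)
  shared <- shared[!(shared %in% wt$tag[duplicated(wt$tag)]) &
                     !(shared %in% slip$tag[duplicated(slip$tag)])]
  if (length(shared) > 0L) {
    vw <- wt$volume[match(shared, wt$tag)]
    vs <- slip$volume[match(shared, slip$tag)]
    ok <- (vw + vs) > 0
    pcts <- 100 * vw[ok] / (vw[ok] + vs[ok])
    pw <- mean(pcts)
    sdp <- if (length(pcts) > 1L) stats::sd(pcts) else NA_real_
    paired <- TRUE
  } else {
    pw <- 100 * sum(wt$volume) / (sum(wt$volume) + sum(slip$volume))
    # jackknife over peaks
    n <- nrow(rows)
    if (n > 2L) {
      loo <- vapply(seq_len(n), function(i) {
        r <- rows[-i, , drop = FALSE]
        sw <- sum(r$volume[r$conformer == "WT"])
        ss <- sum(r$volume[r$conformer == "SLIP"])
        if (sw + ss == 0) return(NA_real_)
        100 * sw / (sw + ss)
      }, numeric(1))
      loo <- loo[is.finite(loo)]
      sdp <- sqrt((length(loo) - 1) / length(loo) *
                    sum((loo - mean(loo))^2))
    } else {
      sdp <- NA_real_
    }
    paired <- FALSE
  }
  tibble::tibble(
    covariate = rows$covariate[1],
    percent_wt = pw,
    percent_slip = 100 - pw,
    keq = if (pw < 100 && pw > 0) pw / (100 - pw) else
      ifelse(pw >= 100, Inf, 0),
    sd_percent = sdp,
    n_peaks_wt = nrow(wt),
    n_peaks_slip = nrow(slip),
    paired = paired
  )
}

#' Equilibrium constant from a percent population
#'
#' `Keq = percent_wt / (100 - percent_wt)`, using the SLIP-to-WT direction
#' (`Keq = [WT]/[SLIP]`, so a 50:50 mixture has `Keq = 1` and WT-favoured
#' conditions have `Keq > 1`).
#'
#' @param percent_wt Percentage of the WT conformer, strictly between 0
#'   and 100. Values of exactly 0 or 100 correspond to a conformationally
#'   locked protein whose equilibrium constant is out of the measurable
#'   domain (reported in tables as "<1" / ">99"); these raise an error.
#' @return `Keq` (dimensionless), vectorised over `percent_wt`.
#' @examples
#' keq_from_percent(50)     # 1
#' keq_from_percent(200/3)  # 2: the 2:1 WT/SLIP plateau
#' @export
keq_from_percent <- function(percent_wt) {
  if (any(!is.finite(percent_wt)) ||
      any(percent_wt <= 0) || any(percent_wt >= 100)) {
    stop("percent_wt must lie strictly between 0 and 100; a locked ",
         "conformation (0 or 100) has no finite equilibrium constant",
         call. = FALSE)
  }
  percent_wt / (100 - percent_wt)
}

#' Percent population from an equilibrium constant
#'
#' Inverse of [keq_from_percent()]: `percent_wt = 100 * keq / (1 + keq)`.
#'
#' @param keq Equilibrium constant `[WT]/[SLIP]`, > 0.
#' @return Percentage of WT conformer, vectorised.
#' @export
percent_from_keq <- function(keq) {
  if (any(!is.finite(keq)) || any(keq <= 0)) {
    stop("keq must be finite and positive", call. = FALSE)
  }
  100 * keq / (1 + keq)
}

#' Scale conformer concentrations by relative peak volumes
#'
#' The volume-accounting step of the titration analysis: peaks that show no
#' chemical-shift perturbation on ligand binding report the total
#' concentration of their conformer (bound plus unbound). Comparing their
#' volumes at a titration point to the zero-ligand reference scales the
#' known zero-ligand concentrations to the current ones:
#' `C_WT,T = C_WT,0 * (V_WT / V_WT,0)` and
#' `C_SLIP = C_SLIP,0 * (V_SLIP / V_SLIP,0)`.
#' When several unperturbed peaks qualify, the per-peak volume ratios are
#' averaged. Per-peak response factors cancel in the ratios, so the scaling
#' needs no volume calibration.
#'
#' @param volumes Peak-volume rows for one condition (columns `peak_id`,
#'   `conformer`, `volume`, optional `unperturbed`).
#' @param reference Peak-volume rows for the zero-ligand reference
#'   condition, same format. Peaks are matched by `peak_id`.
#' @param c_wt_0,c_slip_0 Zero-ligand concentrations of the two conformers
#'   (µM).
#' @param use_unperturbed_only If `TRUE` (default), only peaks flagged
#'   `unperturbed` enter the ratios; the flag must be present and mark at
#'   least one peak per conformer.
#' @return A one-row tibble with `c_wt_total` and `c_slip` (µM), and the
#'   per-conformer mean volume ratios.
#' @export
scale_concentrations <- function(volumes, reference, c_wt_0, c_slip_0,
                                 use_unperturbed_only = TRUE) {
  stopifnot(is.numeric(c_wt_0), is.numeric(c_slip_0),
            c_wt_0 >= 0, c_slip_0 >= 0)
  volumes <- as_tibble_checked(volumes, c("peak_id", "conformer", "volume"))
  reference <- as_tibble_checked(reference,
                                 c("peak_id", "conformer", "volume"))
  if (use_unperturbed_only) {
    for (nm in c("volumes", "reference")) {
      tb <- get(nm)
      if (!"unperturbed" %in% names(tb)) {
        stop("no 'unperturbed' column in ", nm,
             "; cannot select unperturbed peaks", call. = FALSE)
      }
    }
    keep <- reference$peak_id[as.logical(reference$unperturbed)]
    keep <- intersect(keep, volumes$peak_id[as.logical(volumes$unperturbed)])
    volumes <- volumes[volumes$peak_id %in% keep, , drop = FALSE]
    reference <- reference[reference$peak_id %in% keep, , drop = FALSE]
  }
  ratio_for <- function(conf) {
    v <- volumes[volumes$conformer == conf, , drop = FALSE]
    r <- reference[reference$conformer == conf, , drop = FALSE]
    m <- match(v$peak_id, r$peak_id)
    if (nrow(v) == 0L || anyNA(m)) {
      stop("no usable unperturbed ", conf,
           " peaks shared between condition and reference", call. = FALSE)
    }
    v0 <- r$volume[m]
    if (any(v0 <= 0)) {
      stop("zero reference volume for ", conf, " peak(s): ",
           paste(v$peak_id[v0 <= 0], collapse = ", "), call. = FALSE)
    }
    mean(v$volume / v0)
  }
  rw <- ratio_for("WT")
  rs <- ratio_for("SLIP")
  tibble::tibble(
    c_wt_total = c_wt_0 * rw,
    c_slip = c_slip_0 * rs,
    ratio_wt = rw,
    ratio_slip = rs
  )
}
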