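# PRM quantification: integrate transitions, filter interference by spectral
# contrast (dotp) and mass error, normalize to TIC and to a constitutive
# reference peptide, and impute left-censored zeros.  The normalization chain
# is ordered (raw -> interference filter -> TIC -> optional reference ->
# imputation) and each step records itself in a provenance attribute so that
# out-of-order calls fail loudly.

provenance <- function(x) attr(x, "provenance") %||% character()

add_provenance <- function(x, step) {
  attr(x, "provenance") <- c(provenance(x), step)
  x
}

require_provenance <- function(x, present = character(), absent = character(),
                               op = "this operation") {
  prov <- provenance(x)
  miss <- setdiff(present, prov)
  if (length(miss) > 0) {
    abort(sprintf("%s requires prior step(s): %s (provenance so far: %s).",
                  op, paste(miss, collapse = ", "),
                  paste(prov, collapse = " -> ")),
          class = "evpanel_provenance_error")
  }
  bad <- intersect(absent, prov)
  if (length(bad) > 0) {
    abort(sprintf("%s must come before step(s): %s (provenance so far: %s).",
                  op, paste(bad, collapse = ", "),
                  paste(prov, collapse = " -> ")),
          class = "evpanel_provenance_error")
  }
  invisible(x)
}

#' Integrate a chromatographic peak with endpoint-baseline subtraction
#'
#' Trapezoidal integration of `intensity - baseline` over the window, where the
#' baseline is the mean of the trace intensity at the two window endpoints;
#' the result is floored at 0.
#'
#' @param trace Data frame with numeric columns `time` (minutes) and
#'   `intensity`.
#' @param window Length-2 numeric `(start, end)` in minutes.
#' @return A single non-negative area (intensity x minutes).
#' @export
integrate_peak <- function(trace, window) {
  stopifnot(is.data.frame(trace), all(c("time", "intensity") %in% names(trace)))
  if (length(window) != 2L || !is.numeric(window) || window[2] <= window[1]) {
    abort("`window` must be numeric (start, end) with end > start.",
          class = "evpanel_integration_error")
  }
  keep <- trace$time >= window[1] & trace$time <= window[2]
  if (sum(keep) < 2L) {
    abort("Fewer than 2 trace samples fall inside the integration window.",
          class = "evpanel_integration_error")
  }
  tt <- trace$time[keep]
  yy <- trace$intensity[keep]
  ord <- order(tt)
  tt <- tt[ord]; yy <- yy[ord]
  baseline <- mean(c(yy[1L], yy[length(yy)]))
  y0 <- yy - baseline
  area <- sum(diff(tt) * (head(y0, -1) + y0[-1]) / 2)
  max(area, 0)
}

#' Spectral contrast score (dotp) between library and observed transitions
#'
#' Normalized dot product of the element-wise square roots of the library
#' relative intensities and the observed transition areas.  Scale-invariant in
#' either argument; returns 0 when either vector is all zero.
#'
#' @param library_intensities,observed_areas Equal-length non-negative vectors.
#' @return Score in `[0, 1]`.
#' @export
dotp <- function(library_intensities, observed_areas) {
  if (length(library_intensities) != length(observed_areas) ||
      length(library_intensities) < 1L) {
    abort("dotp() needs two equal-length vectors of length >= 1.",
          class = "evpanel_contract_error")
  }
  if (any(library_intensities < 0) || any(observed_areas < 0)) {
    abort("dotp() inputs must be non-negative.",
          class = "evpanel_contract_error")
  }
  l <- sqrt(library_intensities)
  o <- sqrt(observed_areas)
  nl <- sqrt(sum(l^2)); no <- sqrt(sum(o^2))
  if (nl == 0 || no == 0) return(0)
  min(sum(l * o) / (nl * no), 1)
}

#' Collapse a transition report to peptide-level areas with interference zeroing
#'
#' Each peptide-by-sample cell's area is the sum of its transition areas.  A
#' cell is zeroed (flag `interference_zeroed`) when its dotp against the
#' library pattern is strictly below `dotp_min`, when its absolute
#' area-weighted mean mass error strictly exceeds `ppm_max` (if `ppm_max` is
#' given), or when fewer than `min_transitions` transitions have positive area.
#'
#' @param report Transition-report tibble (see
#'   [generate_transition_chromatograms()] for the columns) including
#'   `library_relative_intensity`.
#' @param dotp_min Minimum spectral contrast score (cells with dotp strictly
#'   below are zeroed; a cell exactly at the threshold is retained).
#' @param ppm_max Maximum tolerated absolute mass error in ppm, or `NULL` to
#'   skip the mass-error rule.
#' @param min_transitions Minimum number of detected (positive-area)
#'   transitions required to measure a peak area.
#' @return An `ev_quant` long tibble (`sample_id`, `protein_id`,
#'   `peptide_sequence`, `abundance`, `dotp`, `mass_error_ppm`, `n_detected`,
#'   `flag`) with a per-sample TIC attribute (sum of all raw transition areas)
#'   and provenance `"interference_filter"`.
#' @export
apply_interference_filter <- function(report, dotp_min = 0.8, ppm_max = 20,
                                      min_transitions = 3L) {
  needed <- c("sample_id", "peptide_sequence", "area",
              "library_relative_intensity", "mass_error_ppm")
  miss <- setdiff(needed, names(report))
  if (length(miss) > 0) {
    abort(paste0("Report is missing column(s): ", paste(miss, collapse = ", ")),
          class = "evpanel_schema_error")
  }
  if (!"protein_id" %in% names(report)) report$protein_id <- NA_character_
  min_transitions <- check_count(min_transitions, "min_transitions", min = 1L)

  tic <- report |>
    group_by(.data$sample_id) |>
    summarise(tic = sum(.data$area), .groups = "drop")

  cells <- report |>
    group_by(.data$sample_id, .data$protein_id, .data$peptide_sequence) |>
    summarise(
      raw_area = sum(.data$area),
      dotp = dotp(.data$library_relative_intensity, .data$area),
      mass_error_ppm = if (sum(.data$area) > 0) {
        abs(sum(.data$mass_error_ppm * .data$area) / sum(.data$area))
      } else {
        NA_real_
      },
      n_detected = sum(.data$area > 0),
      .groups = "drop"
    ) |>
    mutate(
      zeroed = .data$dotp < dotp_min |
        (!is.null(ppm_max) & !is.na(.data$mass_error_ppm) &
           .data$mass_error_ppm > (ppm_max %||% Inf)) |
        .data$n_detected < min_transitions,
      abundance = if_else(.data$zeroed, 0, .data$raw_area),
      flag = if_else(.data$zeroed, "interference_zeroed", "detected")
    ) |>
    select("sample_id", "protein_id", "peptide_sequence", "abundance",
           "dotp", "mass_error_ppm", "n_detected", "flag")

  out <- structure(cells, class = c("ev_quant", class(cells)),
                   tic = setNames(tic$tic, tic$sample_id))
  add_provenance(out, "interference_filter")
}

#' Normalize peptide areas to the total ion current
#'
#' Divides every cell by its sample's TIC (by default the sum of all raw
#' transition areas of that run, recorded by [apply_interference_filter()]);
#' a user-supplied named TIC vector overrides the default.
#'
#' @param quant An `ev_quant` tibble with provenance `interference_filter`.
#' @param tic Optional named numeric vector of per-sample TICs (> 0).
#' @return The quant table with `abundance` TIC-scaled, provenance `"tic"`.
#' @export
tic_normalize <- function(quant, tic = NULL) {
  require_provenance(quant, present = "interference_filter",
                     absent = c("tic", "imputed"), op = "tic_normalize()")
  tic <- tic %||% attr(quant, "tic")
  samples <- unique(quant$sample_id)
  miss <- setdiff(samples, names(tic))
  if (length(miss) > 0) {
    abort(paste0("No TIC supplied for sample(s): ", paste(miss, collapse = ", ")),
          class = "evpanel_normalization_error")
  }
  bad <- names(tic)[!is.finite(tic) | tic <= 0]
  bad <- intersect(bad, samples)
  if (length(bad) > 0) {
    abort(paste0("Non-positive TIC for sample(s): ", paste(bad, collapse = ", ")),
          class = "evpanel_normalization_error")
  }
  quant$abundance <- quant$abundance / unname(tic[quant$sample_id])
  add_provenance(quant, "tic")
}

#' Normalize to a constitutive reference peptide
#'
#' Divides every sample's abundances by that sample's reference-peptide value
#' (default the CD9 extracellular-region peptide `EVQEFYK`), correcting for
#' differences in vesicle recovery; the reference row becomes identically 1.
#'
#' @param quant An `ev_quant` tibble, TIC-normalized, not yet imputed.
#' @param reference_peptide Reference peptide sequence.
#' @return The quant table with provenance `"reference"`.
#' @export
reference_normalize <- function(quant, reference_peptide = "EVQEFYK") {
  require_provenance(quant, present = "tic",
                     absent = c("reference", "imputed"),
                     op = "reference_normalize()")
  ref <- quant |>
    filter(.data$peptide_sequence == reference_peptide) |>
    select("sample_id", ref_value = "abundance")
  samples <- unique(quant$sample_id)
  bad <- union(setdiff(samples, ref$sample_id),
               ref$sample_id[ref$ref_value <= 0])
  if (length(bad) > 0) {
    abort(paste0("Reference peptide '", reference_peptide,
                 "' missing or zero in sample(s): ",
                 paste(sort(bad), collapse = ", ")),
          class = "evpanel_normalization_error")
  }
  quant <- left_join(quant, ref, by = "sample_id") |>
    mutate(abundance = .data$abundance / .data$ref_value) |>
    select(-"ref_value")
  add_provenance(quant, "reference")
}

#' Impute missing-not-at-random zeros with the peptide's minimum detected value
#'
#' Normalized areas of 0 are assumed censored below the detection limit and
#' replaced by the lowest positive value observed for that peptide across
#' samples (flag `imputed`).  Peptides never detected in any sample are
#' dropped with a warning.
#'
#' @param quant An `ev_quant` tibble, normalized (TIC at least).
#' @return The quant table with no zero abundances, provenance `"imputed"`.
#' @export
impute_mnar <- function(quant) {
  require_provenance(quant, present = "tic", absent = "imputed",
                     op = "impute_mnar()")
  mins <- quant |>
    group_by(.data$peptide_sequence) |>
    summarise(row_min = ifelse(any(.data$abundance > 0),
                               min(.data$abundance[.data$abundance > 0]),
                               NA_real_),
              .groups = "drop")
  dropped <- mins$peptide_sequence[is.na(mins$row_min)]
  if (length(dropped) > 0) {
    warn(paste0("Dropping peptide(s) with no detected value in any sample: ",
                paste(dropped, collapse = ", ")),
         class = "evpanel_dropped_peptides")
  }
  quant <- quant |>
    filter(!.data$peptide_sequence %in% dropped) |>
    left_join(mins, by = "peptide_sequence") |>
    mutate(
      flag = if_else(.data$abundance == 0, "imputed", .data$flag),
      abundance = if_else(.data$abundance == 0, .data$row_min, .data$abundance)
    ) |>
    select(-"row_min")
  add_provenance(quant, "imputed")
}

#' Reshape an `ev_quant` table to a samples-by-peptides tibble
#'
#' @param quant An `ev_quant` long tibble.
#' @return A tibble with one row per sample: `sample_id` plus one numeric
#'   column per peptide.
#' @export
quant_wide <- function(quant) {
  quant |>
    select("sample_id", "peptide_sequence", "abundance") |>
    pivot_wider(names_from = "peptide_sequence", values_from = "abundance") |>
    arrange(.data$sample_id)
}

#' Reshape an `ev_quant` table to a peptides-by-samples matrix
#'
#' @param quant An `ev_quant` long tibble.
#' @return A numeric matrix, peptides as rows, samples as columns.
#' @export
quant_matrix <- function(quant) {
  wide <- quant_wide(quant)
  m <- t(as.matrix(wide[, -1, drop = FALSE]))
  colnames(m) <- wide$sample_id
  m
}

#' Calibrate observed retention times against library iRT
#'
#' Least-squares line `observed = slope * irt + intercept` over the spiked
#' retention-time standards; the calibration passes QC when the Pearson
#' correlation strictly exceeds 0.95.
#'
#' @param observed_rt Observed retention times (minutes) of the standards.
#' @param irt Predicted iRT values of the same standards.
#' @param r_min QC threshold on the Pearson correlation (strict `>`).
#' @return An `ev_rt_calibration` list: `slope`, `intercept`, `pearson_r`,
#'   `residuals`, `passes_qc`.
#' @export
calibrate_rt <- function(observed_rt, irt, r_min = 0.95) {
  if (length(observed_rt) != length(irt) || length(irt) < 3L) {
    abort("Retention-time calibration needs >= 3 paired standards.",
          class = "evpanel_calibration_error")
  }
  fit <- lm(observed_rt ~ irt)
  r <- cor(observed_rt, irt)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    pearson_r = r,
    residuals = unname(stats::residuals(fit)),
    passes_qc = isTRUE(r > r_min)
  ), class = "ev_rt_calibration")
}

#' @export
print.ev_rt_calibration <- function(x, ...) {
  cat(sprintf("<ev_rt_calibration> slope %.4f, intercept %.3f min, r = %.4f (%s)\n",
              x$slope, x$intercept, x$pearson_r,
              if (x$passes_qc) "passes QC" else "FAILS QC"))
  invisible(x)
}

#' Schedule acquisition windows around predicted retention times
#'
#' Windows are centered at the calibrated prediction `slope * irt + intercept`
#' plus any supplied cumulative drift offset, with total width `width` (e.g.
#' 8 min for static scheduling, 3 min with real-time drift correction).
#'
#' @param calibration An `ev_rt_calibration` that passes QC.
#' @param irt Per-peptide iRT values (optionally named).
#' @param width Total window width in minutes (> 0).
#' @param drift_offsets Optional per-peptide cumulative drift correction in
#'   minutes (scalar or one value per peptide).
#' @return A tibble with `irt`, `predicted_rt`, `start`, `end`.
#' @export
schedule_windows <- function(calibration, irt, width, drift_offsets = NULL) {
  stopifnot(inherits(calibration, "ev_rt_calibration"))
  if (!isTRUE(calibration$passes_qc)) {
    abort("Retention-time calibration does not pass QC (r <= threshold).",
          class = "evpanel_qc_error")
  }
  if (!is.numeric(width) || length(width) != 1 || width <= 0) {
    abort("`width` must be a single positive number of minutes.",
          class = "evpanel_contract_error")
  }
  drift <- drift_offsets %||% 0
  if (!length(drift) %in% c(1L, length(irt))) {
    abort("`drift_offsets` must be scalar or one per peptide.",
          class = "evpanel_contract_error")
  }
  center <- calibration$slope * irt + calibration$intercept + drift
  tibble(
    peptide = names(irt) %||% as.character(seq_along(irt)),
    irt = unname(irt),
    predicted_rt = unname(center),
    start = unname(center - width / 2),
    end = unname(center + width / 2)
  )
}
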