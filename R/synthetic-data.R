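# Synthetic PRM cohorts, transition chromatogram reports and ELISA plates with
# planted ground truth.  Every downstream stage of the pipeline is exercised
# against these generators, so their statistical structure is part of the
# package contract: log-normal peptide abundances, a multiplicative per-sample
# loading factor (what TIC normalization must remove), left-censoring below a
# detection limit (missing not at random), library-independent transition
# patterns for interference cells, and 4PL-governed optical densities.

#' Cohort configuration for the synthetic study generator
#'
#' @param n_case,n_control Number of case (HGSC) and control (benign) samples.
#' @param n_peptides Total number of monitored peptides, including the
#'   constitutive reference peptide.
#' @param planted_effects Named numeric vector of linear case/control fold
#'   changes keyed by peptide sequence (e.g. `c(QGGFLGLSNIK = 3.14)`); peptides
#'   not named have fold 1.  An unnamed vector is assigned to the first
#'   non-reference peptides in order.
#' @param base_log_abundance_mean,base_log_abundance_sd Mean and sd of the
#'   per-peptide baseline abundance on the natural-log scale.
#' @param noise_cv Within-group biological coefficient of variation
#'   (multiplicative log-normal noise on the linear scale).
#' @param tic_cv Coefficient of variation of the per-sample multiplicative
#'   loading factor.
#' @param detection_limit_quantile Fraction in `[0, 1)`: cells whose
#'   loading-adjusted abundance falls below this quantile of the global
#'   abundance distribution are censored (area 0, flagged).
#' @param interference_fraction Fraction of peptide-by-sample cells whose
#'   transition pattern is drawn independently of the spectral library.
#' @param reference_peptide_id Sequence of the constitutive reference peptide
#'   (CD9 analog); its planted fold is fixed at 1 and it is exempt from
#'   censoring and interference.
#' @param seed Integer seed; identical configs and seeds give identical output.
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_case,
                          n_control,
                          n_peptides = 25L,
                          planted_effects = numeric(),
                          base_log_abundance_mean = 14,
                          base_log_abundance_sd = 1.5,
                          noise_cv = 0.2,
                          tic_cv = 0.25,
                          detection_limit_quantile = 0,
                          interference_fraction = 0,
                          reference_peptide_id = "EVQEFYK",
                          seed = 1L) {
  cfg <- list(
    n_case = check_count(n_case, "n_case"),
    n_control = check_count(n_control, "n_control"),
    n_peptides = check_count(n_peptides, "n_peptides", min = 2L),
    planted_effects = planted_effects,
    base_log_abundance_mean = base_log_abundance_mean,
    base_log_abundance_sd = base_log_abundance_sd,
    noise_cv = check_fraction(noise_cv, "noise_cv", 0, Inf),
    tic_cv = check_fraction(tic_cv, "tic_cv", 0, Inf),
    detection_limit_quantile =
      check_fraction(detection_limit_quantile, "detection_limit_quantile",
                     0, 1, open_hi = TRUE),
    interference_fraction =
      check_fraction(interference_fraction, "interference_fraction", 0, 1),
    reference_peptide_id = reference_peptide_id,
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(cfg$planted_effects) > 0) {
    if (any(!is.finite(cfg$planted_effects)) || any(cfg$planted_effects <= 0)) {
      abort("`planted_effects` must all be positive finite fold changes.",
            class = "evpanel_config_error")
    }
    if (cfg$reference_peptide_id %in% names(cfg$planted_effects) &&
        cfg$planted_effects[[cfg$reference_peptide_id]] != 1) {
      abort("`planted_effects`: the reference peptide must have fold change 1.",
            class = "evpanel_config_error")
    }
  }
  structure(cfg, class = "cohort_config")
}

#' Preset cohort configurations matching the two study designs
#'
#' `"cohort1"` is 10 cases vs 9 controls; `"cohort2"` is 30 vs 30.
#'
#' @param name One of `"cohort1"`, `"cohort2"`.
#' @param ... Overrides passed on to [cohort_config()].
#' @export
cohort_preset <- function(name = c("cohort1", "cohort2"), ...) {
  name <- match.arg(name)
  sizes <- switch(name, cohort1 = c(10L, 9L), cohort2 = c(30L, 30L))
  args <- utils::modifyList(list(n_case = sizes[1], n_control = sizes[2]), list(...))
  do.call(cohort_config, args)
}

# deterministic tryptic-looking sequences: 7-18 aa, no W, single terminal K/R
synthetic_peptide_ids <- function(n, exclude = character()) {
  aa <- strsplit("ACDEFGHILMNQSTVY", "")[[1]]
  out <- character(0)
  while (length(out) < n) {
    len <- sample(7:18, 1L)
    seqs <- paste0(paste(sample(aa, len - 1L, replace = TRUE), collapse = ""),
                   sample(c("K", "R"), 1L))
    if (!seqs %in% c(out, exclude)) out <- c(out, seqs)
  }
  out
}

#' Generate a synthetic PRM quantification study
#'
#' Draws a peptide-by-sample table of true abundances: per-peptide baselines
#' are log-normal, case samples carry the planted fold changes, every sample is
#' scaled by a multiplicative loading factor, and cells whose loading-adjusted
#' abundance falls below the configured detection-limit quantile are left-
#' censored (recorded area 0).  Interference flags are assigned here and
#' consumed by [generate_transition_chromatograms()].
#'
#' @param config A [cohort_config()].
#' @return An `ev_study` list: `abundances` (long tibble with per-cell truth
#'   flags), `metadata` (sample table), `truth` (planted fold per peptide),
#'   and the `config`.
#' @export
generate_quant_study <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created by cohort_config().",
          class = "evpanel_config_error")
  }
  withr::with_seed(config$seed, {
    n_samp <- config$n_case + config$n_control
    meta <- tibble(
      sample_id = sprintf("S%02d", seq_len(n_samp)),
      group = rep(c("HGSC", "Benign"), c(config$n_case, config$n_control)),
      figo_stage = NA_character_,
      age = round(runif(n_samp, 40, 80))
    )
    meta$figo_stage[meta$group == "HGSC"] <-
      sample(c("I", "II", "III"), config$n_case, replace = TRUE)

    eff <- config$planted_effects
    if (length(eff) > 0 && is.null(names(eff))) {
      names(eff) <- synthetic_peptide_ids(length(eff),
                                          exclude = config$reference_peptide_id)
    }
    n_fill <- config$n_peptides - 1L - length(eff)
    if (n_fill < 0) {
      abort("`n_peptides` too small for the planted effects plus reference.",
            class = "evpanel_config_error")
    }
    filler <- synthetic_peptide_ids(n_fill,
                                    exclude = c(config$reference_peptide_id, names(eff)))
    peptides <- c(config$reference_peptide_id, names(eff), filler)
    folds <- setNames(rep(1, length(peptides)), peptides)
    folds[names(eff)] <- unname(eff)

    base_log <- rnorm(length(peptides), config$base_log_abundance_mean,
                      config$base_log_abundance_sd)
    names(base_log) <- peptides
    # constitutive reference sits high in the abundance distribution
    base_log[config$reference_peptide_id] <-
      config$base_log_abundance_mean + 2 * config$base_log_abundance_sd

    loading <- exp(rnorm(n_samp, -lognorm_sigma(config$tic_cv)^2 / 2,
                         lognorm_sigma(config$tic_cv)))
    names(loading) <- meta$sample_id

    cells <- tidyr::expand_grid(peptide_id = peptides, sample_id = meta$sample_id) |>
      left_join(select(meta, "sample_id", "group"), by = "sample_id") |>
      mutate(
        fold = folds[.data$peptide_id],
        noise = rnorm(n(), 0, lognorm_sigma(config$noise_cv)),
        true_abundance = exp(base_log[.data$peptide_id] +
                               log(.data$fold) * (.data$group == "HGSC") +
                               .data$noise),
        loading = loading[.data$sample_id]
      )
    thr <- if (config$detection_limit_quantile > 0) {
      quantile(cells$true_abundance, config$detection_limit_quantile,
               names = FALSE)
    } else {
      -Inf
    }
    cells <- cells |>
      mutate(
        censored = .data$true_abundance < thr &
          .data$peptide_id != config$reference_peptide_id,
        interference = runif(n()) < config$interference_fraction &
          .data$peptide_id != config$reference_peptide_id,
        area = if_else(.data$censored, 0, .data$true_abundance * .data$loading)
      ) |>
      select("peptide_id", "sample_id", "group", "true_abundance", "area",
             "censored", "interference")

    structure(
      list(
        abundances = cells,
        metadata = meta,
        truth = tibble(peptide_id = peptides, fold = unname(folds)),
        config = config
      ),
      class = "ev_study"
    )
  })
}

#' @export
print.ev_study <- function(x, ...) {
  cat(sprintf(
    "<ev_study> %d peptides x %d samples (%d HGSC / %d Benign), %d planted effect(s)\n",
    nrow(x$truth), nrow(x$metadata),
    sum(x$metadata$group == "HGSC"), sum(x$metadata$group == "Benign"),
    sum(x$truth$fold != 1)
  ))
  invisible(x)
}

#' Build a synthetic spectral library for a set of peptides
#'
#' Transition relative intensities decay geometrically (spiky, library-like
#' patterns), product and precursor m/z are drawn uniformly, and iRT values
#' span the configured range.
#'
#' @param peptide_ids Character vector of peptide sequences.
#' @param n_transitions Transitions per peptide.
#' @param intensity_decay Geometric decay ratio between ranked transitions.
#' @param irt_range Range of iRT values assigned (normalized units).
#' @param seed Integer seed.
#' @return A spectral-library tibble, one row per transition.
#' @export
synthetic_library <- function(peptide_ids, n_transitions = 5L,
                              intensity_decay = 0.6,
                              irt_range = c(10, 90), seed = 1L) {
  n_transitions <- check_count(n_transitions, "n_transitions")
  withr::with_seed(seed, {
    purrr::imap(setNames(peptide_ids, peptide_ids), function(pep, nm) {
      rel <- intensity_decay^(seq_len(n_transitions) - 1L)
      tibble(
        peptide_sequence = pep,
        protein_id = paste0("PROT_", substr(pep, 1, 4)),
        precursor_mz = runif(1, 400, 900),
        transition_label = paste0("y", seq_len(n_transitions) + 2L),
        product_mz = sort(runif(n_transitions, 300, 1200)),
        relative_intensity = sample(rel),
        irt = runif(1, irt_range[1], irt_range[2])
      )
    }) |> list_rbind()
  })
}

#' Chromatogram-level simulation settings
#'
#' Transition areas are the analytic integrals of Gaussian elution profiles
#' whose apexes are proportional to library relative intensities scaled by the
#' cell's true signal; only the integrated areas are reported.
#'
#' @param rt_drift_slope,rt_drift_offset Per-sample linear map from library iRT
#'   to observed retention time (minutes): `rt = slope * irt + offset`.
#' @param rt_jitter_sd Per-cell retention-time jitter sd (minutes).
#' @param transition_noise_cv Multiplicative log-normal noise applied per
#'   transition area (0 gives library-exact patterns, dotp = 1).
#' @param mass_error_sd Mass error sd (ppm) for clean cells.
#' @param interference_mass_error_sd Mass error sd (ppm) for interference cells.
#' @export
chromatogram_config <- function(rt_drift_slope = 1,
                                rt_drift_offset = 0,
                                rt_jitter_sd = 0,
                                transition_noise_cv = 0,
                                mass_error_sd = 3,
                                interference_mass_error_sd = 15) {
  structure(list(
    rt_drift_slope = rt_drift_slope,
    rt_drift_offset = rt_drift_offset,
    rt_jitter_sd = rt_jitter_sd,
    transition_noise_cv = check_fraction(transition_noise_cv,
                                         "transition_noise_cv", 0, Inf),
    mass_error_sd = mass_error_sd,
    interference_mass_error_sd = interference_mass_error_sd
  ), class = "chromatogram_config")
}

#' Expand a synthetic study into a transition-level report
#'
#' Each peptide-by-sample cell is split across its library transitions in
#' proportion to the library relative intensities (clean cells) or a pattern
#' drawn independently of the library (interference-flagged cells, giving low
#' expected dotp).  Observed retention times are the library iRT mapped through
#' the configured linear drift plus jitter.  Censored cells keep their rows
#' with area 0 so that minimum-transition rules see them.
#'
#' @param study An `ev_study` from [generate_quant_study()].
#' @param library A spectral-library tibble covering every study peptide.
#' @param chrom A [chromatogram_config()].
#' @param seed Integer seed for the chromatogram-level noise.
#' @return A transition-report tibble (one row per sample x peptide x
#'   transition) with columns `sample_id`, `protein_id`, `peptide_sequence`,
#'   `precursor_mz`, `transition_label`, `product_mz`, `retention_time`,
#'   `area`, `background`, `mass_error_ppm`, `library_relative_intensity`.
#' @export
generate_transition_chromatograms <- function(study, library,
                                              chrom = chromatogram_config(),
                                              seed = study$config$seed + 1L) {
  stopifnot(inherits(study, "ev_study"))
  missing_pep <- setdiff(study$truth$peptide_id, library$peptide_sequence)
  if (length(missing_pep) > 0) {
    abort(paste0("Peptides missing from library: ",
                 paste(missing_pep, collapse = ", ")),
          class = "evpanel_lookup_error")
  }
  withr::with_seed(seed, {
    cells <- study$abundances
    rows <- left_join(cells, library, by = c(peptide_id = "peptide_sequence"),
                      relationship = "many-to-many")
    rows <- rows |>
      group_by(.data$peptide_id, .data$sample_id) |>
      mutate(
        weight = if (first(.data$interference)) {
          w <- rexp(n()); w / sum(w)
        } else {
          .data$relative_intensity / sum(.data$relative_intensity)
        }
      ) |>
      ungroup() |>
      mutate(
        noise = exp(rnorm(n(), 0, lognorm_sigma(chrom$transition_noise_cv))),
        area = .data$area * .data$weight * .data$noise,
        retention_time = chrom$rt_drift_slope * .data$irt +
          chrom$rt_drift_offset + rnorm(n(), 0, chrom$rt_jitter_sd),
        background = 0,
        mass_error_ppm = rnorm(
          n(), 0,
          if_else(.data$interference, chrom$interference_mass_error_sd,
                  chrom$mass_error_sd)
        )
      )
    rows |>
      transmute(
        sample_id = .data$sample_id,
        protein_id = .data$protein_id,
        peptide_sequence = .data$peptide_id,
        precursor_mz = .data$precursor_mz,
        transition_label = .data$transition_label,
        product_mz = .data$product_mz,
        retention_time = .data$retention_time,
        area = .data$area,
        background = .data$background,
        mass_error_ppm = .data$mass_error_ppm,
        library_relative_intensity = .data$relative_intensity
      )
  })
}

#' Generate a synthetic study together with its library and transition report
#'
#' Convenience wrapper: builds a library for the study's peptides, expands the
#' study to transition level, and returns the study with `$library` and
#' `$transition_report` attached.
#'
#' @inheritParams generate_transition_chromatograms
#' @param config A [cohort_config()].
#' @export
simulate_study <- function(config, chrom = chromatogram_config()) {
  study <- generate_quant_study(config)
  study$library <- synthetic_library(study$truth$peptide_id,
                                     seed = config$seed + 2L)
  study$transition_report <-
    generate_transition_chromatograms(study, study$library, chrom)
  study
}

#' Generate a synthetic ELISA plate
#'
#' Standards are a 6-point 3-fold serial dilution from 1000 U/mL down to
#' 1000/3^5 (about 4.1) U/mL, passed through the forward 4PL curve with
#' optional multiplicative OD noise.  Sample concentrations are log-normal per
#' group with the case group scaled by `effect`; each sample is diluted by
#' `dilution_factor` before its OD is generated.
#'
#' @param n_case,n_control Samples per group.
#' @param curve A [four_pl()] parameter set governing OD generation.
#' @param effect Linear case/control fold change on concentration (> 0).
#' @param seed Integer seed.
#' @param noise_cv Multiplicative CV applied to corrected ODs (0 = noise-free).
#' @param control_median_conc Median plasma concentration of the control group
#'   (U/mL, before dilution).
#' @param conc_cv Within-group concentration CV.
#' @param dilution_factor Combined dilution applied before the assay.
#' @param od570 Constant background absorbance added to every well.
#' @param n_standard_points,standard_top,standard_fold Standard-series layout.
#' @param standard_replicates Wells per standard concentration (kits
#'   conventionally run standards in duplicate).
#' @return An `ev_elisa_plate` tibble of wells with a `truth` attribute holding
#'   the generating curve and true sample concentrations.
#' @export
generate_elisa_plate <- function(n_case, n_control,
                                 curve = four_pl(a = 0.05, d = 3.2,
                                                 c = 150, b = 1.2),
                                 effect = 2,
                                 seed = 1L,
                                 noise_cv = 0.05,
                                 control_median_conc = 600,
                                 conc_cv = 0.5,
                                 dilution_factor = 60,
                                 od570 = 0.04,
                                 n_standard_points = 6L,
                                 standard_top = 1000,
                                 standard_fold = 3,
                                 standard_replicates = 2L) {
  if (!is.numeric(effect) || length(effect) != 1 || !is.finite(effect) ||
      effect <= 0) {
    abort("`effect` must be a single positive fold change.",
          class = "evpanel_config_error")
  }
  n_case <- check_count(n_case, "n_case")
  n_control <- check_count(n_control, "n_control")
  withr::with_seed(seed, {
    std_conc <- rep(standard_top / standard_fold^(seq_len(n_standard_points) - 1L),
                    each = check_count(standard_replicates, "standard_replicates"))
    std <- tibble(
      well_id = sprintf("STD%02d", seq_along(std_conc)),
      role = "standard",
      known_concentration = std_conc,
      dilution_factor = 1,
      sample_id = NA_character_,
      group = NA_character_,
      true_concentration = std_conc
    )
    n_samp <- n_case + n_control
    samp <- tibble(
      well_id = sprintf("SMP%02d", seq_len(n_samp)),
      role = "sample",
      known_concentration = NA_real_,
      dilution_factor = dilution_factor,
      sample_id = sprintf("E%02d", seq_len(n_samp)),
      group = rep(c("HGSC", "Benign"), c(n_case, n_control))
    )
    samp$true_concentration <- exp(rnorm(
      n_samp,
      log(control_median_conc) + log(effect) * (samp$group == "HGSC"),
      lognorm_sigma(conc_cv)
    ))
    wells <- bind_rows(std, samp) |>
      mutate(
        assay_conc = .data$true_concentration / .data$dilution_factor,
        corrected = four_pl_forward(.data$assay_conc, curve) *
          exp(rnorm(n(), 0, lognorm_sigma(noise_cv))),
        od570 = od570,
        od450 = .data$corrected + od570
      ) |>
      select("well_id", "role", "od450", "od570", "dilution_factor",
             "known_concentration", "sample_id", "group")
    structure(wells,
              class = c("ev_elisa_plate", class(wells)),
              truth = list(curve = curve,
                           concentrations = select(
                             bind_rows(std, samp),
                             "sample_id", "group", "true_concentration")))
  })
}
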