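# End-to-end discovery pipeline: quantify -> screen -> discover -> attribute,
# with cohort profiles matching the two acquisition designs and a provenance
# record (config hash, seed, step order) embedded in the result bundle.

#' Pipeline configuration
#'
#' Bundles every stage's thresholds under a cohort profile.  `"cohort1"`
#' (static PRM, 10 vs 9) uses dotp >= 0.8, mass error <= 20 ppm and
#' reference-peptide normalization; `"cohort2"` (dynamic-retention-time PRM,
#' 30 vs 30) uses dotp >= 0.4, no mass-error rule and TIC normalization only.
#'
#' @param profile `"cohort1"`, `"cohort2"` or `"custom"`.
#' @param cohort A [cohort_config()] describing the synthetic study to run on
#'   (or `NULL` when supplying a measured transition report to
#'   [run_pipeline()]).
#' @param dotp_min,ppm_max,min_transitions Interference-filter thresholds.
#' @param reference_normalize Apply the reference-peptide step?
#' @param reference_peptide Reference peptide sequence.
#' @param alpha Screening significance level.
#' @param test Screening test (`"wilcoxon"` or `"welch"`).
#' @param force_include Peptides always added to the candidate list.
#' @param split A [split_config()].
#' @param k Panel size for the combinatorial search.
#' @param n_components,cost Panel-model hyperparameters.
#' @param grid A [hyper_grid()] for optional LOOCV triangulation.
#' @param seed Master seed for the run.
#' @export
pipeline_config <- function(profile = c("cohort1", "cohort2", "custom"),
                            cohort = NULL,
                            dotp_min = NULL, ppm_max = NULL,
                            min_transitions = 3L,
                            reference_normalize = NULL,
                            reference_peptide = "EVQEFYK",
                            alpha = 0.05,
                            test = c("wilcoxon", "welch"),
                            force_include = character(),
                            split = split_config(),
                            k = 2L,
                            n_components = 2L,
                            cost = 0.025,
                            grid = hyper_grid(),
                            seed = 1L) {
  profile <- match.arg(profile)
  test <- match.arg(test)
  defaults <- switch(profile,
    cohort1 = list(dotp_min = 0.8, ppm_max = 20, reference_normalize = TRUE),
    cohort2 = list(dotp_min = 0.4, ppm_max = NULL, reference_normalize = FALSE),
    custom = list(dotp_min = 0.8, ppm_max = 20, reference_normalize = TRUE)
  )
  structure(list(
    profile = profile,
    cohort = cohort,
    dotp_min = dotp_min %||% defaults$dotp_min,
    ppm_max = if (profile == "cohort2" && is.null(ppm_max)) NULL
              else ppm_max %||% defaults$ppm_max,
    min_transitions = check_count(min_transitions, "min_transitions"),
    reference_normalize = reference_normalize %||% defaults$reference_normalize,
    reference_peptide = reference_peptide,
    alpha = check_fraction(alpha, "alpha", 0, 1),
    test = test,
    force_include = force_include,
    split = split,
    k = check_count(k, "k"),
    n_components = check_count(n_components, "n_components"),
    cost = cost,
    grid = grid,
    seed = check_count(seed, "seed", min = 0L)
  ), class = "pipeline_config")
}

#' Run the discovery pipeline end to end
#'
#' Quantifies (interference filter, TIC and optional reference normalization,
#' MNAR imputation), screens for differential peptides, searches all
#' `k`-peptide panels on a stratified split, and attributes the top panel by
#' exact Shapley values over the training background.  With no measured
#' report supplied, a synthetic study is simulated from `config$cohort`.
#'
#' @param config A [pipeline_config()].
#' @param transition_report Optional measured transition report tibble.
#' @param metadata Sample metadata tibble (`sample_id`, `group`); required
#'   with a measured report.
#' @return An `ev_pipeline_result` list: `quant`, `volcano`, `panels`,
#'   `top_panel`, `attributions`, `drivers`, `study` (if simulated), and
#'   `provenance` (config hash, seed, step order).  Identical configs give
#'   identical results.
#' @export
run_pipeline <- function(config, transition_report = NULL, metadata = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  study <- NULL
  if (is.null(transition_report)) {
    if (is.null(config$cohort)) {
      abort("Either a transition report or a `cohort` config is required.",
            class = "evpanel_config_error")
    }
    study <- simulate_study(config$cohort)
    transition_report <- study$transition_report
    metadata <- study$metadata
  }
  if (is.null(metadata)) {
    abort("`metadata` is required with a measured transition report.",
          class = "evpanel_config_error")
  }
  labels <- setNames(as.character(metadata$group), metadata$sample_id)

  quant <- apply_interference_filter(transition_report,
                                     dotp_min = config$dotp_min,
                                     ppm_max = config$ppm_max,
                                     min_transitions = config$min_transitions)
  quant <- tic_normalize(quant)
  if (isTRUE(config$reference_normalize)) {
    quant <- reference_normalize(quant, config$reference_peptide)
  }
  quant <- impute_mnar(quant)

  screen_quant <- if (isTRUE(config$reference_normalize)) {
    filter(quant, .data$peptide_sequence != config$reference_peptide)
  } else {
    quant
  }
  volcano <- volcano_table(screen_quant, labels, alpha = config$alpha,
                           test = config$test,
                           force_include = config$force_include)
  candidates <- attr(volcano, "candidates")
  panels <- NULL; top <- NULL; attributions <- NULL; drivers <- NULL
  if (length(candidates) >= config$k) {
    wide <- quant_wide(quant)
    wide <- wide[match(metadata$sample_id, wide$sample_id), ]
    split <- stratified_split(labels[wide$sample_id], config$split)
    panels <- combination_search(wide, labels[wide$sample_id],
                                 candidates = candidates,
                                 k = config$k,
                                 n_components = config$n_components,
                                 cost = config$cost,
                                 split = split)
    top <- panels[1, ]
    feats <- top$features[[1]]
    x_all <- as.matrix(wide[, feats, drop = FALSE])
    bg <- x_all[split$train, , drop = FALSE]
    attributions <- attribute_samples(top$model[[1]], x_all, bg,
                                      sample_ids = wide$sample_id)
    drivers <- rank_drivers(attributions, labels)
  } else {
    warn(sprintf(
      "Only %d candidate feature(s) at alpha = %g; skipping the panel search (k = %d).",
      length(candidates), config$alpha, config$k),
      class = "evpanel_insufficient_candidates")
  }
  structure(list(
    quant = quant,
    volcano = volcano,
    panels = panels,
    top_panel = top,
    attributions = attributions,
    drivers = drivers,
    study = study,
    provenance = list(
      config_hash = rlang::hash(config),
      seed = config$seed,
      steps = provenance(quant),
      package_version = as.character(utils::packageVersion("evpanel"))
    )
  ), class = "ev_pipeline_result")
}

#' @export
print.ev_pipeline_result <- function(x, ...) {
  cat("<ev_pipeline_result>\n")
  cat(sprintf("  quant: %d peptides x %d samples (%s)\n",
              length(unique(x$quant$peptide_sequence)),
              length(unique(x$quant$sample_id)),
              paste(x$provenance$steps, collapse = " -> ")))
  cat(sprintf("  screen: %d significant, %d candidate peptide(s)\n",
              sum(x$volcano$significant), sum(x$volcano$candidate)))
  if (!is.null(x$panels)) {
    cat(sprintf("  panels: %d combination(s); best '%s' test ROC-AUC = %.3f\n",
                attr(x$panels, "n_combinations"), x$top_panel$panel,
                x$top_panel$test_auc))
  }
  invisible(x)
}
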