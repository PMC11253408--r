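# Differential screening of the quantification matrix: two-sample tests,
# volcano-style candidate selection, and Gaussian down-shift imputation for
# discovery-stage (DDA) matrices.

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t statistic with Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b Numeric vectors (>= 2 values each, positive within-group
#'   variance in at least one group).
#' @return A list with `statistic`, `p_value`, `df`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("welch_t() needs >= 2 values per group.",
          class = "evpanel_contract_error")
  }
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) return(list(statistic = 0, p_value = 1, df = NA_real_))
    abort("Both groups have zero variance; Welch t is degenerate.",
          class = "evpanel_contract_error")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Mann-Whitney U with midranks for ties.  The p-value is exact (full
#' enumeration) when the combined sample size is at most 12 and there are no
#' ties, otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param a,b Numeric vectors (>= 1 value each).
#' @return A list with `statistic` (U for the first sample) and `p_value`
#'   (two-sided).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) {
    abort("wilcoxon_rank_sum() needs >= 1 value per group.",
          class = "evpanel_contract_error")
  }
  ties <- any(duplicated(c(a, b)))
  exact <- (length(a) + length(b)) <= 12L && !ties
  ht <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Screen a quantification table for group differences
#'
#' Computes per-peptide log2 fold change (case mean over control mean of
#' normalized abundances), the chosen two-sample test, and a significance call
#' at `alpha`.  The candidate feature list is the union of significant
#' peptides and any `force_include` peptides (e.g. a prior-knowledge antigen
#' kept despite p just above the threshold).
#'
#' @param quant An imputed `ev_quant` tibble (no zero abundances), or any long
#'   tibble with `peptide_sequence`, `sample_id`, `abundance`.
#' @param labels Named character vector of group labels per sample, or a
#'   metadata tibble with `sample_id` and `group`.
#' @param alpha Significance level (strict `p < alpha`).
#' @param test `"wilcoxon"` (rank-sum, the cohort-1 screen) or `"welch"`.
#' @param force_include Peptides added to the candidate list regardless of p.
#' @param case Label treated as the case group (defaults to `"HGSC"` when
#'   present).
#' @param fold_estimator `"arithmetic"` (ratio of group arithmetic means) or
#'   `"geometric"`.
#' @param adjust Optional multiple-testing method passed to [stats::p.adjust()]
#'   (e.g. `"BH"`); `NULL` (default) applies none, matching the screening
#'   procedure.
#' @return An `ev_volcano` tibble: `peptide_sequence`, `protein_id`,
#'   `log2_fold_change`, `statistic`, `p_value`, (`p_adjusted`,) `test_name`,
#'   `significant`, `candidate`, `forced`; the candidate peptides are in
#'   `attr(, "candidates")`.
#' @export
volcano_table <- function(quant, labels, alpha = 0.05,
                          test = c("wilcoxon", "welch"),
                          force_include = character(),
                          case = NULL,
                          fold_estimator = c("arithmetic", "geometric"),
                          adjust = NULL) {
  test <- match.arg(test)
  fold_estimator <- match.arg(fold_estimator)
  if (is.data.frame(labels)) {
    labels <- setNames(as.character(labels$group), labels$sample_id)
  }
  grp <- check_binary_labels(labels, case)
  if (inherits(quant, "ev_quant") && !"imputed" %in% provenance(quant) &&
      any(quant$abundance == 0)) {
    abort("volcano_table() expects an imputed matrix with no zero abundances.",
          class = "evpanel_contract_error")
  }
  gmean <- function(x) exp(mean(log(x)))
  res <- quant |>
    mutate(group = unname(labels[.data$sample_id])) |>
    group_by(.data$peptide_sequence) |>
    summarise(
      protein_id = if ("protein_id" %in% names(quant))
        first(.data$protein_id) else NA_character_,
      log2_fold_change = if (fold_estimator == "arithmetic") {
        log2(mean(.data$abundance[.data$group == grp$case]) /
               mean(.data$abundance[.data$group == grp$control]))
      } else {
        log2(gmean(.data$abundance[.data$group == grp$case]) /
               gmean(.data$abundance[.data$group == grp$control]))
      },
      test_out = list(
        if (test == "wilcoxon") {
          wilcoxon_rank_sum(.data$abundance[.data$group == grp$case],
                            .data$abundance[.data$group == grp$control])
        } else {
          welch_t(.data$abundance[.data$group == grp$case],
                  .data$abundance[.data$group == grp$control])
        }
      ),
      .groups = "drop"
    ) |>
    mutate(
      statistic = map_dbl(.data$test_out, "statistic"),
      p_value = map_dbl(.data$test_out, "p_value"),
      test_name = if (test == "wilcoxon") "wilcoxon" else "welch_t"
    ) |>
    select(-"test_out")
  if (!is.null(adjust)) {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = adjust)
  }
  res <- res |>
    mutate(
      significant = .data$p_value < alpha,
      forced = .data$peptide_sequence %in% force_include,
      candidate = .data$significant | .data$forced
    ) |>
    arrange(.data$p_value)
  structure(res, class = c("ev_volcano", class(res)),
            candidates = res$peptide_sequence[res$candidate],
            alpha = alpha, case = grp$case)
}

#' Gaussian down-shift imputation for matrices with missing values
#'
#' Replaces missing entries column-wise by draws from a normal distribution
#' whose mean is shifted `shift` standard deviations below the observed column
#' mean and whose sd is `width` times the observed column sd — the standard
#' left-tail imputation for abundance matrices already on a log scale.
#'
#' @param x Numeric matrix or samples-in-columns data frame with `NA` for
#'   missing values (log-scale intensities).
#' @param width Imputation sd as a fraction of the observed column sd.
#' @param shift Down-shift in observed-column sd units.
#' @param seed Integer seed (identical seeds give identical imputations).
#' @return Completed matrix of the same shape.
#' @export
downshift_impute <- function(x, width = 0.3, shift = 1.8, seed = 1L) {
  m <- as.matrix(x)
  withr::with_seed(seed, {
    for (j in seq_len(ncol(m))) {
      miss <- is.na(m[, j])
      if (!any(miss)) next
      obs <- m[!miss, j]
      if (length(obs) < 2L) {
        abort(sprintf("Column %d has < 2 observed values; cannot impute.", j),
              class = "evpanel_imputation_error")
      }
      m[miss, j] <- rnorm(sum(miss), mean(obs) - shift * sd(obs),
                          width * sd(obs))
    }
  })
  if (is.data.frame(x)) as_tibble(as.data.frame(m)) else m
}
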