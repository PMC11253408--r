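# Spectral-library curation (which peptides and transitions are worth
# monitoring) and gas-phase-fractionation DIA window-scheme arithmetic.

#' Peptide curation rules
#'
#' @param max_missed_cleavages Maximum tolerated missed tryptic cleavages
#'   (internal K/R not followed by P); 0 removes any missed cleavage.
#' @param forbid_tryptophan Remove peptides containing W (oxidation-prone).
#' @param length_range Allowed peptide length in amino acids, `(min, max)`.
#' @param max_peptides_per_protein Keep at most this many peptides per protein,
#'   ranked by summed library intensity (ties by sequence).
#' @param top_n_transitions Transitions retained per peptide by
#'   [select_top_transitions()].
#' @param max_cv Optional maximum replicate CV (fraction) for a precursor.
#' @param min_product_ions Optional minimum number of library transitions.
#' @export
curation_rules <- function(max_missed_cleavages = 0L,
                           forbid_tryptophan = TRUE,
                           length_range = c(7L, 18L),
                           max_peptides_per_protein = 3L,
                           top_n_transitions = 5L,
                           max_cv = NULL,
                           min_product_ions = NULL) {
  if (length(length_range) != 2L || length_range[1] > length_range[2]) {
    abort("`length_range` must be (min, max) with min <= max.",
          class = "evpanel_config_error")
  }
  structure(list(
    max_missed_cleavages = check_count(max_missed_cleavages,
                                       "max_missed_cleavages", min = 0L),
    forbid_tryptophan = isTRUE(forbid_tryptophan),
    length_range = as.integer(length_range),
    max_peptides_per_protein = check_count(max_peptides_per_protein,
                                           "max_peptides_per_protein"),
    top_n_transitions = check_count(top_n_transitions, "top_n_transitions"),
    max_cv = max_cv,
    min_product_ions = if (is.null(min_product_ions)) NULL else
      check_count(min_product_ions, "min_product_ions")
  ), class = "curation_rules")
}

#' Count missed tryptic cleavages in a peptide sequence
#'
#' A missed cleavage is an internal K or R not followed by proline.
#'
#' @param sequence Character vector of uppercase peptide sequences.
#' @return Integer vector of missed-cleavage counts.
#' @export
missed_cleavages <- function(sequence) {
  vapply(sequence, function(s) {
    chars <- strsplit(s, "")[[1]]
    n <- length(chars)
    if (n < 2L) return(0L)
    sum(chars[-n] %in% c("K", "R") & chars[-1] != "P")
  }, integer(1), USE.NAMES = FALSE)
}

#' Curate a spectral library for monitorable peptides
#'
#' Applies the monitoring rules: removes peptides with missed cleavages beyond
#' the tolerance, containing tryptophan (when forbidden), outside the length
#' range, or failing the optional CV / product-ion minima; then keeps at most
#' `max_peptides_per_protein` peptides per protein, ranked by summed library
#' intensity with ties broken by lexicographic sequence.
#'
#' @param library Spectral-library tibble, one row per transition, with at
#'   least `peptide_sequence`, `protein_id`, `relative_intensity` (optionally
#'   `cv_across_replicates`).
#' @param rules A [curation_rules()] object.
#' @return The curated library tibble (same shape, fewer peptides).
#' @export
curate_peptides <- function(library, rules = curation_rules()) {
  stopifnot(inherits(rules, "curation_rules"))
  seqs <- unique(library$peptide_sequence)
  bad <- seqs[!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seqs)]
  if (length(bad) > 0) {
    abort(paste0("Malformed peptide sequence(s): ", paste(bad, collapse = ", ")),
          class = "evpanel_validation_error")
  }
  per_pep <- library |>
    group_by(.data$peptide_sequence, .data$protein_id) |>
    summarise(
      summed_intensity = sum(.data$relative_intensity),
      n_transitions = n(),
      cv = if ("cv_across_replicates" %in% names(library))
        first(.data$cv_across_replicates) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(
      len = nchar(.data$peptide_sequence),
      mc = missed_cleavages(.data$peptide_sequence),
      keep = .data$mc <= rules$max_missed_cleavages &
        .data$len >= rules$length_range[1] &
        .data$len <= rules$length_range[2] &
        (!rules$forbid_tryptophan | !grepl("W", .data$peptide_sequence)) &
        (is.null(rules$max_cv) | is.na(.data$cv) | .data$cv < (rules$max_cv %||% Inf)) &
        (is.null(rules$min_product_ions) |
           .data$n_transitions >= (rules$min_product_ions %||% 0L))
    ) |>
    filter(.data$keep) |>
    group_by(.data$protein_id) |>
    arrange(desc(.data$summed_intensity), .data$peptide_sequence,
            .by_group = TRUE) |>
    slice_head(n = rules$max_peptides_per_protein) |>
    ungroup()

  library |> filter(.data$peptide_sequence %in% per_pep$peptide_sequence)
}

#' Keep the most intense transitions per peptide
#'
#' Retains the `n` transitions with the highest library relative intensity for
#' each peptide (all of them if fewer exist); ties are broken by ascending
#' product m/z.
#'
#' @param library Spectral-library tibble, one row per transition.
#' @param n Number of transitions to keep (>= 1), e.g. 5 for static PRM and 8
#'   for dynamic-retention-time PRM.
#' @return The restricted library tibble.
#' @export
select_top_transitions <- function(library, n) {
  if (!is_scalar_integerish(n) || n < 1L) {
    abort("`n` must be a single integer >= 1.",
          class = "evpanel_contract_error")
  }
  library |>
    group_by(.data$peptide_sequence) |>
    arrange(desc(.data$relative_intensity), .data$product_mz,
            .by_group = TRUE) |>
    slice_head(n = as.integer(n)) |>
    ungroup()
}

#' Gas-phase-fractionation DIA window scheme
#'
#' Partitions a precursor mass range into contiguous gas-phase fractions (one
#' injection each) and tiles every fraction with isolation windows.  Staggered
#' schemes acquire a second pass offset by half a window width (doubling the
#' windows per injection) so that demultiplexing yields bins of half the
#' window width; non-staggered bins equal the window width.  When the window
#' width does not divide the fraction evenly the final window of a pass
#' overhangs the fraction edge, as acquired in practice.
#'
#' @param low,high Precursor m/z range.
#' @param fraction_width Width of each gas-phase fraction (m/z); must divide
#'   `high - low`.  Defaults to the whole range (a single injection).
#' @param window_width Isolation-window width (m/z).
#' @param staggered Acquire the half-window-offset second pass?
#' @return An `ev_gpf_scheme` list: `mass_range`, `fraction_width`,
#'   `window_width`, `staggered`, `n_injections`, `demux_bin_width`, and a
#'   `windows` tibble (`injection`, `fraction_start`, `fraction_end`, `pass`,
#'   `window_start`, `window_end`).
#' @export
gpf_scheme <- function(low = 300, high = 1000, fraction_width = high - low,
                       window_width = 4, staggered = TRUE) {
  if (!is.numeric(low) || !is.numeric(high) || high <= low) {
    abort("`high` must exceed `low`.", class = "evpanel_scheme_error")
  }
  if (fraction_width <= 0 || window_width <= 0) {
    abort("Widths must be positive.", class = "evpanel_scheme_error")
  }
  n_frac <- (high - low) / fraction_width
  if (abs(n_frac - round(n_frac)) > 1e-9) {
    abort("`fraction_width` must divide the mass range evenly.",
          class = "evpanel_scheme_error")
  }
  n_frac <- as.integer(round(n_frac))
  frac_starts <- low + fraction_width * (seq_len(n_frac) - 1L)
  windows <- purrr::imap(frac_starts, function(fs, i) {
    n_win <- ceiling(fraction_width / window_width - 1e-9)
    s1 <- fs + window_width * (seq_len(n_win) - 1L)
    pass1 <- tibble(injection = i, fraction_start = fs,
                    fraction_end = fs + fraction_width, pass = 1L,
                    window_start = s1, window_end = s1 + window_width)
    if (!staggered) return(pass1)
    s2 <- s1 + window_width / 2
    bind_rows(pass1,
              tibble(injection = i, fraction_start = fs,
                     fraction_end = fs + fraction_width, pass = 2L,
                     window_start = s2, window_end = s2 + window_width))
  }) |> list_rbind()
  structure(list(
    mass_range = c(low, high),
    fraction_width = fraction_width,
    window_width = window_width,
    staggered = isTRUE(staggered),
    n_injections = n_frac,
    demux_bin_width = if (staggered) window_width / 2 else window_width,
    windows = windows
  ), class = "ev_gpf_scheme")
}

#' @export
print.ev_gpf_scheme <- function(x, ...) {
  cat(sprintf(
    "<ev_gpf_scheme> %g-%g m/z: %d injection(s) of %g m/z, %g m/z windows%s, %g m/z demux bins\n",
    x$mass_range[1], x$mass_range[2], x$n_injections, x$fraction_width,
    x$window_width, if (x$staggered) " (staggered)" else "", x$demux_bin_width))
  invisible(x)
}
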