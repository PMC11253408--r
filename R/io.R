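# File formats: Skyline-dialect transition reports (CSV), quantification
# matrices (TSV + QC-flag sidecar + provenance JSON), sample metadata and
# ELISA plates (CSV).  All readers validate schemas and fail with the missing
# column names; numerics use the "." decimal separator only.

skyline_columns <- c(
  sample_id = "Replicate Name",
  protein_id = "Protein Name",
  peptide_sequence = "Peptide Sequence",
  precursor_mz = "Precursor Mz",
  transition_label = "Fragment Ion",
  product_mz = "Product Mz",
  retention_time = "Retention Time",
  area = "Area",
  background = "Background",
  mass_error_ppm = "Mass Error PPM",
  library_relative_intensity = "Library Intensity"
)

transition_numeric_cols <- c("precursor_mz", "product_mz", "retention_time",
                             "area", "background", "mass_error_ppm",
                             "library_relative_intensity")

parse_numeric_strict <- function(x, col, lines) {
  if (any(grepl(",", x), na.rm = TRUE)) {
    abort(sprintf(
      "Column '%s' contains ',' — European decimal commas are not supported; export with '.' decimals.",
      col), class = "evpanel_schema_error")
  }
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "")
  if (length(bad) > 0) {
    abort(sprintf("Column '%s': unparseable numeric value '%s' at line %d.",
                  col, x[bad[1]], lines[bad[1]]),
          class = "evpanel_schema_error")
  }
  out
}

#' Read a transition-level PRM report
#'
#' Accepts Skyline-export column names (`Replicate Name`, `Protein Name`,
#' `Peptide Sequence`, `Precursor Mz`, `Fragment Ion`, `Product Mz`,
#' `Retention Time`, `Area`, `Background`, `Mass Error PPM`,
#' `Library Intensity`) or the package's snake_case equivalents.
#'
#' @param path CSV file path.
#' @return A typed transition-report tibble.
#' @export
read_transition_report <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  nm <- names(raw)
  renames <- skyline_columns[skyline_columns %in% nm]
  for (snake in names(renames)) {
    names(raw)[names(raw) == renames[[snake]]] <- snake
  }
  miss <- setdiff(names(skyline_columns), names(raw))
  if (length(miss) > 0) {
    abort(paste0("Transition report is missing column(s): ",
                 paste(unname(skyline_columns[miss]), collapse = ", ")),
          class = "evpanel_schema_error")
  }
  lines <- seq_len(nrow(raw)) + 1L
  for (col in transition_numeric_cols) {
    raw[[col]] <- parse_numeric_strict(raw[[col]], col, lines)
  }
  inform(sprintf("read_transition_report: %d rows from %s.", nrow(raw), path),
         class = "evpanel_io_info")
  as_tibble(raw[, names(skyline_columns)])
}

#' Read a sample metadata table
#'
#' @param path CSV with columns `sample_id`, `group` (and optionally
#'   `figo_stage`, `age`).
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  miss <- setdiff(c("sample_id", "group"), names(meta))
  if (length(miss) > 0) {
    abort(paste0("Metadata is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "evpanel_schema_error")
  }
  if ("age" %in% names(meta)) {
    meta$age <- parse_numeric_strict(meta$age, "age", seq_len(nrow(meta)) + 1L)
  }
  meta
}

#' Read an ELISA plate table
#'
#' @param path CSV with columns `well_id`, `role` (standard/sample/blank),
#'   `od450`, `od570`, `dilution_factor`, `known_concentration`, `sample_id`,
#'   `group`.
#' @export
read_elisa_plate <- function(path) {
  plate <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  needed <- c("well_id", "role", "od450", "od570", "dilution_factor")
  miss <- setdiff(needed, names(plate))
  if (length(miss) > 0) {
    abort(paste0("ELISA plate is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "evpanel_schema_error")
  }
  lines <- seq_len(nrow(plate)) + 1L
  for (col in intersect(c("od450", "od570", "dilution_factor",
                          "known_concentration"), names(plate))) {
    plate[[col]] <- parse_numeric_strict(plate[[col]], col, lines)
  }
  plate
}

#' Write a quantification table to TSV with QC sidecar and provenance record
#'
#' Writes the peptides-by-samples matrix as TSV, the per-cell QC flags to
#' `<path>.flags.tsv`, and the normalization provenance (ordered steps plus a
#' configuration hash) to `<path>.provenance.json`.
#'
#' @param quant An `ev_quant` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_quant_matrix <- function(quant, path) {
  wide <- quant |>
    select("peptide_sequence", "sample_id", "abundance") |>
    pivot_wider(names_from = "sample_id", values_from = "abundance") |>
    arrange(.data$peptide_sequence)
  readr::write_tsv(wide, path)
  flags <- quant |>
    select("peptide_sequence", "sample_id", "flag") |>
    pivot_wider(names_from = "sample_id", values_from = "flag") |>
    arrange(.data$peptide_sequence)
  readr::write_tsv(flags, paste0(path, ".flags.tsv"))
  prov <- list(steps = provenance(quant),
               hash = rlang::hash(list(provenance(quant), wide$peptide_sequence)))
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a quantification table written by [write_quant_matrix()]
#'
#' @param path TSV path (the sidecar files are located next to it).
#' @return An `ev_quant` long tibble with its provenance restored.
#' @export
read_quant_matrix <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    peptide_sequence = "c", .default = "d"), progress = FALSE)
  long <- pivot_longer(wide, -"peptide_sequence", names_to = "sample_id",
                       values_to = "abundance")
  flags_path <- paste0(path, ".flags.tsv")
  if (file.exists(flags_path)) {
    flags <- readr::read_tsv(flags_path,
                             col_types = readr::cols(.default = "c"),
                             progress = FALSE) |>
      pivot_longer(-"peptide_sequence", names_to = "sample_id",
                   values_to = "flag")
    long <- left_join(long, flags, by = c("peptide_sequence", "sample_id"))
  }
  prov_path <- paste0(path, ".provenance.json")
  out <- structure(long, class = c("ev_quant", class(long)))
  if (file.exists(prov_path)) {
    prov <- jsonlite::read_json(prov_path, simplifyVector = TRUE)
    attr(out, "provenance") <- prov$steps
  }
  out
}
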