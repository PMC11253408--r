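# ELISA quantification: 450/570 nm background correction, 4-parameter-logistic
# standard curves, inverse interpolation with dilution correction, and
# diagnostic evaluation (Mann-Whitney, logistic ROC-AUC, Youden threshold).

#' Four-parameter logistic curve parameters
#'
#' The curve is `y = d + (a - d) / (1 + (x/c)^b)`: `a` is the absorbance
#' asymptote at zero concentration, `d` the asymptote at infinite
#' concentration, `c` the inflection concentration (U/mL) and `b` the slope
#' factor.
#'
#' @param a,d Asymptotes (absorbance); must differ.
#' @param c Inflection concentration (> 0).
#' @param b Slope factor (non-zero; positive for curves rising with
#'   concentration when `a < d`).
#' @export
four_pl <- function(a, d, c, b) {
  if (!is.finite(c) || c <= 0) {
    abort("`c` (inflection concentration) must be > 0.",
          class = "evpanel_config_error")
  }
  if (!is.finite(a) || !is.finite(d) || a == d) {
    abort("Asymptotes `a` and `d` must be finite and distinct.",
          class = "evpanel_config_error")
  }
  if (!is.finite(b) || b == 0) {
    abort("`b` must be non-zero (the curve must be monotone).",
          class = "evpanel_config_error")
  }
  structure(list(a = a, d = d, c = c, b = b), class = "ev_four_pl")
}

#' Forward 4PL: concentration to corrected absorbance
#'
#' @param x Concentrations (>= 0).
#' @param curve A [four_pl()].
#' @export
four_pl_forward <- function(x, curve) {
  stopifnot(inherits(curve, "ev_four_pl"))
  curve$d + (curve$a - curve$d) / (1 + (x / curve$c)^curve$b)
}

#' Inverse 4PL: corrected absorbance to concentration
#'
#' `x = c * ((a - d)/(y - d) - 1)^(1/b)`; defined for `y` strictly between the
#' asymptotes.
#'
#' @param y Corrected absorbances.
#' @param curve A [four_pl()].
#' @return Concentrations (`NaN` outside the open asymptote interval).
#' @export
four_pl_inverse <- function(y, curve) {
  stopifnot(inherits(curve, "ev_four_pl"))
  suppressWarnings(curve$c * ((curve$a - curve$d) / (y - curve$d) - 1)^(1 / curve$b))
}

#' Chromogenic background correction
#'
#' Subtracts the 570 nm reference absorbance from the 450 nm signal.
#'
#' @param od450,od570 Absorbances.
#' @export
background_correct <- function(od450, od570) {
  if (any(!is.finite(od450)) || any(!is.finite(od570))) {
    abort("Absorbances must be finite.", class = "evpanel_contract_error")
  }
  od450 - od570
}

#' Fit a 4PL standard curve
#'
#' Least-squares 4PL fit to (concentration, corrected OD) standard points.
#' Replicate wells at the same concentration are averaged after background
#' correction, before fitting.
#'
#' @param standards Data frame with columns `concentration` (U/mL) and `od`
#'   (corrected absorbance); >= 5 distinct concentrations spanning a monotone
#'   response.
#' @return An `ev_standard_curve` list: `curve` (a [four_pl()]), `rss`,
#'   `residuals`, `data` (the averaged standards with fitted values).
#' @export
fit_standard_curve <- function(standards) {
  stopifnot(all(c("concentration", "od") %in% names(standards)))
  pts <- standards |>
    group_by(.data$concentration) |>
    summarise(od = mean(.data$od), .groups = "drop") |>
    arrange(.data$concentration)
  if (nrow(pts) < 5L) {
    abort("Standard-curve fitting needs >= 5 distinct concentrations.",
          class = "evpanel_curve_error")
  }
  d_od <- diff(pts$od)
  if (!(all(d_od > 0) || all(d_od < 0))) {
    abort("Standards are not monotone in concentration; cannot fit a 4PL.",
          class = "evpanel_curve_error")
  }
  rising <- d_od[1] > 0
  start <- list(
    a = pts$od[1] - 0.05 * abs(pts$od[1]),
    d = pts$od[nrow(pts)] + 0.05 * abs(pts$od[nrow(pts)]),
    c = exp(mean(log(range(pts$concentration)))),
    b = if (rising) 1 else -1
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      od ~ d + (a - d) / (1 + (concentration / c)^b),
      data = pts, start = start,
      lower = c(a = -Inf, d = -Inf, c = 1e-12,
                b = if (rising) 1e-6 else -Inf),
      upper = c(a = Inf, d = Inf, c = Inf,
                b = if (rising) Inf else -1e-6),
      control = nls.control(maxiter = 500)
    ),
    error = function(e) {
      abort(paste0("4PL fit failed to converge: ", conditionMessage(e)),
            class = "evpanel_curve_error")
    }
  )
  est <- coef(fit)
  curve <- four_pl(a = est[["a"]], d = est[["d"]], c = est[["c"]], b = est[["b"]])
  pts$fitted <- four_pl_forward(pts$concentration, curve)
  pts$residual <- pts$od - pts$fitted
  structure(list(curve = curve,
                 rss = sum(pts$residual^2),
                 residuals = pts$residual,
                 data = pts),
            class = "ev_standard_curve")
}

#' @export
print.ev_standard_curve <- function(x, ...) {
  p <- x$curve
  cat(sprintf(
    "<ev_standard_curve> 4PL: a = %.4g, d = %.4g, c = %.4g U/mL, b = %.4g; RSS = %.3g (%d points)\n",
    p$a, p$d, p$c, p$b, x$rss, nrow(x$data)))
  invisible(x)
}

#' Interpolate sample concentrations from a fitted standard curve
#'
#' Inverts the 4PL at each corrected OD and multiplies by the dilution factor
#' (default 60 = twofold times 30-fold).  ODs outside the open asymptote
#' interval are flagged as below/above the quantification limit and reported
#' as `NA`.
#'
#' @param od Corrected absorbances.
#' @param curve A [four_pl()] or an `ev_standard_curve`.
#' @param dilution_factor Combined pre-assay dilution (> 0), scalar or
#'   per-sample.
#' @return A tibble: `od`, `concentration` (U/mL, dilution-corrected), `flag`
#'   (`"ok"`, `"below_loq"`, `"above_loq"`).
#' @export
interpolate_concentration <- function(od, curve, dilution_factor = 60) {
  if (inherits(curve, "ev_standard_curve")) curve <- curve$curve
  stopifnot(inherits(curve, "ev_four_pl"))
  if (any(dilution_factor <= 0)) {
    abort("`dilution_factor` must be > 0.", class = "evpanel_config_error")
  }
  lo <- min(curve$a, curve$d); hi <- max(curve$a, curve$d)
  in_range <- od > lo & od < hi
  conc <- ifelse(in_range, four_pl_inverse(od, curve) * dilution_factor, NA_real_)
  # the zero-concentration asymptote is `a`; ODs beyond it are below the limit
  toward_a <- if (curve$a < curve$d) od <= lo else od >= hi
  tibble(
    od = od,
    concentration = conc,
    flag = dplyr::case_when(in_range ~ "ok",
                            toward_a ~ "below_loq",
                            TRUE ~ "above_loq")
  )
}

#' Youden-optimal diagnostic threshold
#'
#' Scans candidate cut-points at midpoints between sorted unique values and
#' returns the threshold maximizing Youden's J = sensitivity + specificity - 1
#' for the rule "case if value > threshold"; ties are broken toward the higher
#' threshold (higher specificity).
#'
#' @param values Marker values (e.g. concentrations).
#' @param labels Binary labels.
#' @param case Positive-class label.
#' @return A list: `threshold`, `j`, `sensitivity`, `specificity`.
#' @export
optimal_threshold <- function(values, labels, case = NULL) {
  grp <- check_binary_labels(as.character(labels), case)
  is_case <- as.character(labels) == grp$case
  u <- sort(unique(values))
  if (length(u) < 2L) {
    abort("Need at least two distinct values to place a threshold.",
          class = "evpanel_contract_error")
  }
  cand <- (head(u, -1) + u[-1]) / 2
  stats_at <- function(thr) {
    pred <- values > thr
    c(sens = sum(pred & is_case) / sum(is_case),
      spec = sum(!pred & !is_case) / sum(!is_case))
  }
  ss <- vapply(cand, stats_at, numeric(2))
  j <- ss["sens", ] + ss["spec", ] - 1
  best <- max(which(j == max(j)))
  list(threshold = cand[best], j = j[best],
       sensitivity = ss["sens", best], specificity = ss["spec", best])
}

#' Diagnostic evaluation of a single marker
#'
#' Composes the building blocks into one report: Mann-Whitney comparison of
#' the groups, univariate logistic regression with rank ROC-AUC, the Youden
#' threshold with its confusion counts, and (optionally) the same logistic
#' comparison between two strata of the case group (e.g. FIGO stage I vs II).
#'
#' @param values Marker values (finite).
#' @param labels Binary group labels.
#' @param stratum_labels Optional per-sample stratum labels (non-case samples
#'   ignored); a two-level comparison is run when exactly two strata occur.
#' @param case Positive-class label.
#' @return An `ev_marker_report` list: `p_value`, `logistic`, `auc`,
#'   `threshold` (list from [optimal_threshold()]), `confusion`, and `stage`
#'   (or `NULL`).
#' @export
evaluate_marker <- function(values, labels, stratum_labels = NULL,
                            case = NULL) {
  grp <- check_binary_labels(as.character(labels), case)
  is_case <- as.character(labels) == grp$case
  wt <- wilcoxon_rank_sum(values[is_case], values[!is_case])
  lg <- logistic_fit(values, labels, case = grp$case)
  auc <- roc_auc(lg$probabilities, is_case)
  thr <- optimal_threshold(values, labels, case = grp$case)
  pred <- values > thr$threshold
  confusion <- confusion_counts(pred, is_case)
  stage <- NULL
  if (!is.null(stratum_labels)) {
    st <- as.character(stratum_labels)[is_case]
    sv <- values[is_case]
    keep <- !is.na(st)
    lv <- unique(st[keep])
    if (length(lv) == 2L) {
      slg <- logistic_fit(sv[keep], st[keep], case = sort(lv)[2])
      stage <- list(
        levels = sort(lv),
        p_value = wilcoxon_rank_sum(sv[keep][st[keep] == sort(lv)[1]],
                                    sv[keep][st[keep] == sort(lv)[2]])$p_value,
        auc = roc_auc(slg$probabilities, st[keep] == sort(lv)[2])
      )
    }
  }
  structure(list(p_value = wt$p_value, logistic = lg, auc = auc,
                 threshold = thr, confusion = confusion, stage = stage,
                 case = grp$case),
            class = "ev_marker_report")
}

#' @export
print.ev_marker_report <- function(x, ...) {
  cat(sprintf(
    "<ev_marker_report> Mann-Whitney p = %.3g; logistic ROC-AUC = %.3f; Youden threshold = %.4g (J = %.2f, sens %.2f / spec %.2f)\n",
    x$p_value, x$auc, x$threshold$threshold, x$threshold$j,
    x$threshold$sensitivity, x$threshold$specificity))
  if (!is.null(x$stage)) {
    cat(sprintf("  stage %s vs %s: p = %.3g, ROC-AUC = %.3f\n",
                x$stage$levels[1], x$stage$levels[2], x$stage$p_value,
                x$stage$auc))
  }
  invisible(x)
}

#' Quantify an ELISA plate end to end
#'
#' Background-corrects every well, fits the 4PL standard curve on the
#' standard wells, and interpolates sample concentrations with their dilution
#' factors.
#'
#' @param plate An ELISA plate tibble (see [generate_elisa_plate()] /
#'   [read_elisa_plate()] for the columns).
#' @return A list: `standard_curve` (an `ev_standard_curve`) and `samples`
#'   (tibble with `sample_id`, `group`, `od`, `concentration`, `flag`).
#' @export
quantify_plate <- function(plate) {
  stopifnot(all(c("well_id", "role", "od450", "od570", "dilution_factor")
                %in% names(plate)))
  plate$od <- background_correct(plate$od450, plate$od570)
  std <- plate |>
    filter(.data$role == "standard") |>
    transmute(concentration = .data$known_concentration, od = .data$od)
  sc <- fit_standard_curve(std)
  smp <- filter(plate, .data$role == "sample")
  interp <- interpolate_concentration(smp$od, sc, smp$dilution_factor)
  list(standard_curve = sc,
       samples = bind_cols(select(smp, "sample_id", "group"), interp))
}
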