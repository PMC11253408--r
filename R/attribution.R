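# Exact Shapley attribution of panel classifiers.  Coalitions are enumerated
# exhaustively (panels here are small); an absent feature is marginalized by
# substituting the background mean, so for an end-to-end linear pipeline the
# result coincides with w_i * (x_i - mean(background_i)) in composed
# coefficients -- an identity the test suite asserts rather than assumes.

#' Fit the scale/PCA/linear-SVM pipeline as one reusable object
#'
#' @param x Training feature matrix (rows = samples), unscaled.
#' @param y Binary labels.
#' @param n_components PCA components.
#' @param cost SVM cost weight.
#' @param case Positive-class label.
#' @return An `ev_svm_pipeline` list with `scaling`, `projection`, `svm` and a
#'   `decide(x_new)` function mapping original-space features to decision
#'   values.
#' @export
svm_pipeline <- function(x, y, n_components = 2L, cost = 1, case = NULL) {
  fit_svm_pipeline(x, y, n_components, cost, case = case)
}

#' Exact Shapley values for one sample
#'
#' Enumerates all feature coalitions; for each coalition the excluded features
#' are replaced by the column means of the background set and the model is
#' evaluated.  Satisfies efficiency: the values sum to the model's decision
#' for `x` minus the base value (the decision at the background mean).
#'
#' @param model An `ev_svm_pipeline` (or any object with a `decide` function
#'   over original-space feature matrices).
#' @param x Numeric feature vector (one sample, original feature space).
#' @param background Feature matrix used for marginalization (typically the
#'   training split).
#' @param max_features Enumeration bound (default 15).
#' @return Named numeric vector of Shapley values with attributes
#'   `base_value` and `prediction`.
#' @export
exact_shapley <- function(model, x, background, max_features = 15L) {
  bg <- as.matrix(background)
  x <- as.numeric(x)
  p <- length(x)
  if (p != ncol(bg)) {
    abort("`x` and `background` must have the same feature count.",
          class = "evpanel_contract_error")
  }
  if (nrow(bg) < 1L) {
    abort("`background` must be non-empty.", class = "evpanel_contract_error")
  }
  if (p > max_features) {
    abort(sprintf(
      "%d features exceeds the exhaustive-enumeration bound (%d); use a sampling estimator.",
      p, max_features), class = "evpanel_contract_error")
  }
  mu <- colMeans(bg)
  n_sets <- 2^p
  masks <- matrix(FALSE, n_sets, p)
  for (i in seq_len(p)) {
    masks[, i] <- bitwAnd(seq_len(n_sets) - 1L, bitwShiftL(1L, i - 1L)) > 0L
  }
  inputs <- matrix(rep(mu, each = n_sets), n_sets, p)
  for (i in seq_len(p)) inputs[masks[, i], i] <- x[i]
  colnames(inputs) <- colnames(bg)
  v <- model$decide(inputs)
  sizes <- rowSums(masks)
  fact <- factorial(0:p)
  phi <- numeric(p)
  for (i in seq_len(p)) {
    without <- which(!masks[, i])
    with_i <- without + bitwShiftL(1L, i - 1L)
    s <- sizes[without]
    w <- fact[s + 1L] * fact[p - s] / fact[p + 1L]
    phi[i] <- sum(w * (v[with_i] - v[without]))
  }
  names(phi) <- colnames(bg) %||% paste0("x", seq_len(p))
  structure(phi, base_value = v[1L], prediction = v[n_sets])
}

#' Shapley attribution table for a sample set
#'
#' @param model An `ev_svm_pipeline`.
#' @param x Feature matrix of samples to explain (original feature space).
#' @param background Marginalization background (typically the training
#'   split).
#' @param sample_ids Optional sample identifiers.
#' @return An `ev_attribution` long tibble: `sample_id`, `feature`,
#'   `shapley_value`, `base_value`, `prediction`.
#' @export
attribute_samples <- function(model, x, background, sample_ids = NULL) {
  x <- as.matrix(x)
  ids <- sample_ids %||% rownames(x) %||% as.character(seq_len(nrow(x)))
  rows <- purrr::map(seq_len(nrow(x)), function(i) {
    phi <- exact_shapley(model, x[i, ], background)
    tibble(sample_id = ids[i],
           feature = names(phi),
           shapley_value = as.numeric(phi),
           base_value = attr(phi, "base_value"),
           prediction = attr(phi, "prediction"))
  }) |> list_rbind()
  structure(rows, class = c("ev_attribution", class(rows)))
}

#' Rank panel features by attribution strength
#'
#' Orders features by mean absolute Shapley value across samples and reports
#' the class direction: the mean signed value within the case group and the
#' fraction of case samples with a positive contribution (positive values
#' drive case classification).
#'
#' @param attributions An `ev_attribution` tibble from [attribute_samples()].
#' @param labels Optional labels (named by sample id, or a metadata tibble
#'   with `sample_id` and `group`) for the class-direction summary.
#' @param case Positive-class label.
#' @return A tibble ranked by `mean_abs_shapley`.
#' @export
rank_drivers <- function(attributions, labels = NULL, case = NULL) {
  out <- attributions |>
    group_by(.data$feature) |>
    summarise(mean_abs_shapley = mean(abs(.data$shapley_value)),
              mean_shapley = mean(.data$shapley_value),
              .groups = "drop")
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      labels <- setNames(as.character(labels$group), labels$sample_id)
    }
    grp <- check_binary_labels(labels, case)
    dir <- attributions |>
      mutate(group = unname(labels[.data$sample_id])) |>
      filter(.data$group == grp$case) |>
      group_by(.data$feature) |>
      summarise(mean_shapley_case = mean(.data$shapley_value),
                frac_positive_in_case = mean(.data$shapley_value > 0),
                .groups = "drop")
    out <- left_join(out, dir, by = "feature")
  }
  arrange(out, desc(.data$mean_abs_shapley))
}
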