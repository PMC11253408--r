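# ggplot2 views of the result objects.

#' Volcano plot of a differential screen
#'
#' @param object An `ev_volcano` tibble from [volcano_table()].
#' @param label_top Number of top peptides to label.
#' @param ... Unused.
#' @export
autoplot.ev_volcano <- function(object, label_top = 5L, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$log2_fold_change, y = -log10(.data$p_value),
                 colour = .data$candidate)) +
    geom_point(alpha = 0.8) +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    labs(x = "log2(fold change)", y = "-log10(p-value)",
         colour = "candidate") +
    theme_bw()
}

#' @rdname autoplot.ev_volcano
#' @export
plot_volcano <- function(object, ...) autoplot.ev_volcano(object, ...)

#' ROC curve for a score vector
#'
#' @param scores Decision values or probabilities.
#' @param labels Binary labels (`TRUE`/case = positive).
#' @param case Positive-class label.
#' @export
plot_roc <- function(scores, labels, case = NULL) {
  is_case <- if (is.logical(labels)) labels else {
    grp <- check_binary_labels(labels, case)
    as.character(labels) == grp$case
  }
  ord <- order(scores, decreasing = TRUE)
  tpr <- c(0, cumsum(is_case[ord]) / sum(is_case))
  fpr <- c(0, cumsum(!is_case[ord]) / sum(!is_case))
  auc <- roc_auc(scores, is_case)
  ggplot(tibble(fpr = fpr, tpr = tpr), aes(.data$fpr, .data$tpr)) +
    geom_line() +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("ROC-AUC = %.3f", auc)) +
    theme_bw()
}

#' Standard-curve plot with fitted 4PL
#'
#' @param object An `ev_standard_curve`.
#' @param ... Unused.
#' @export
autoplot.ev_standard_curve <- function(object, ...) {
  pts <- object$data
  grid <- tibble(concentration = exp(seq(log(min(pts$concentration)),
                                         log(max(pts$concentration)),
                                         length.out = 200)))
  grid$od <- four_pl_forward(grid$concentration, object$curve)
  ggplot(pts, aes(.data$concentration, .data$od)) +
    geom_line(data = grid, colour = "grey40") +
    geom_point() +
    scale_x_log10() +
    labs(x = "Concentration (U/mL)", y = "Corrected OD (450-570 nm)") +
    theme_bw()
}

#' Panel-search summary plot: held-out ROC-AUC by rank
#'
#' @param object An `ev_panel_search` from [combination_search()].
#' @param top Number of top panels shown.
#' @param ... Unused.
#' @export
autoplot.ev_panel_search <- function(object, top = 20L, ...) {
  df <- as_tibble(object) |>
    slice_head(n = top) |>
    mutate(rank = row_number())
  ggplot(df, aes(.data$rank, .data$test_auc)) +
    geom_point() +
    geom_hline(yintercept = 0.5, linetype = "dotted") +
    labs(x = "Panel rank", y = "Held-out ROC-AUC") +
    theme_bw()
}
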