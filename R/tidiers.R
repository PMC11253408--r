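# broom-style tidiers for the fitted objects.

#' @export
tidy.ev_svm <- function(x, ...) {
  tibble(term = c(paste0("w", seq_along(x$weights)), "bias"),
         estimate = c(unname(x$weights), x$bias))
}

#' @export
glance.ev_svm <- function(x, ...) {
  tibble(cost = x$cost, n_weights = length(x$weights), case = x$case)
}

#' @export
tidy.ev_standard_curve <- function(x, ...) {
  p <- x$curve
  tibble(term = c("a", "d", "c", "b"),
         estimate = c(p$a, p$d, p$c, p$b))
}

#' @export
glance.ev_standard_curve <- function(x, ...) {
  tibble(rss = x$rss, n_points = nrow(x$data),
         inflection = x$curve$c, rising = x$curve$a < x$curve$d)
}

#' @export
tidy.ev_panel_search <- function(x, ...) {
  as_tibble(x) |> select(-"model", -"features")
}

#' @export
glance.ev_panel_search <- function(x, ...) {
  tibble(n_combinations = attr(x, "n_combinations"),
         k = attr(x, "k"),
         n_fits = attr(x, "n_fits"),
         best_panel = x$panel[1],
         best_test_auc = x$test_auc[1])
}

#' @export
tidy.ev_logistic <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' @export
glance.ev_logistic <- function(x, ...) {
  tibble(separation = x$separation, case = x$case,
         deviance = x$fit$deviance, n = length(x$probabilities))
}

#' @export
tidy.ev_rt_calibration <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept))
}

#' @export
glance.ev_rt_calibration <- function(x, ...) {
  tibble(pearson_r = x$pearson_r, passes_qc = x$passes_qc)
}
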