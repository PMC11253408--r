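# Combinatorial biomarker panel discovery: z-scoring, stratified splitting,
# PCA + linear-SVM pipelines tuned by leave-one-out cross-validation, an
# exhaustive search over feature subsets scored by held-out ROC-AUC, and the
# unsupervised (k-means / V-measure) and univariate (logistic) companions.
#
# All fitting statistics (scaling, PCA loadings, SVM weights) are functions of
# the training split only; the held-out set is touched exactly once per
# candidate panel, for scoring.

#' Train/test split configuration
#'
#' Either a per-class test fraction (round-half-up per class) or explicit
#' per-class test counts; splits are always stratified.
#'
#' @param test_fraction Fraction of each class reserved for testing.
#' @param test_counts Optional named integer vector (per class label) of exact
#'   test counts, overriding `test_fraction`.
#' @param random_state Integer seed making the split deterministic.
#' @param n_repeats Number of independent repeated splits drawn by callers that
#'   iterate (seeded `random_state + 0:(n_repeats-1)`).
#' @export
split_config <- function(test_fraction = 0.30, test_counts = NULL,
                         random_state = 0L, n_repeats = 10L) {
  check_fraction(test_fraction, "test_fraction", 0, 1, open_hi = TRUE)
  if (test_fraction <= 0) {
    abort("`test_fraction` must be in (0, 1).", class = "evpanel_config_error")
  }
  structure(list(
    test_fraction = test_fraction,
    test_counts = test_counts,
    stratified = TRUE,
    random_state = check_count(random_state, "random_state", min = 0L),
    n_repeats = check_count(n_repeats, "n_repeats")
  ), class = "split_config")
}

#' SVM hyperparameter grid
#'
#' @param c_values Positive SVM cost weights.
#' @param n_components_values PCA component counts (>= 1).
#' @export
hyper_grid <- function(c_values = c(0.025, 0.05, 0.1, 0.25, 0.5, 1, 2),
                       n_components_values = c(2L, 3L, 5L, 10L)) {
  if (any(c_values <= 0) || any(n_components_values < 1)) {
    abort("`c_values` must be > 0 and `n_components_values` >= 1.",
          class = "evpanel_config_error")
  }
  structure(list(c_values = c_values,
                 n_components_values = as.integer(n_components_values)),
            class = "hyper_grid")
}

#' Z-score features by training-set statistics
#'
#' Centers and scales columns by the training mean and population
#' (n-denominator) standard deviation, and applies the same parameters to a
#' second matrix (no test leakage).
#'
#' @param train Numeric matrix/data frame of training features (rows =
#'   samples).
#' @param apply_to Optional matrix scaled with the training parameters.
#' @return A list: `train` (scaled matrix), `applied` (or `NULL`), `center`,
#'   `scale`.
#' @export
zscore_scale <- function(train, apply_to = NULL) {
  x <- as.matrix(train)
  if (nrow(x) < 2L) {
    abort("zscore_scale() needs >= 2 training samples.",
          class = "evpanel_contract_error")
  }
  mu <- colMeans(x)
  sdp <- sqrt(colMeans(sweep(x, 2, mu)^2))
  zero <- colnames(x)[sdp == 0] %||% which(sdp == 0)
  if (any(sdp == 0)) {
    abort(paste0("Zero-variance feature(s) in training data: ",
                 paste(zero, collapse = ", ")),
          class = "evpanel_scaling_error")
  }
  scale_with <- function(m) sweep(sweep(as.matrix(m), 2, mu), 2, sdp, "/")
  list(train = scale_with(x),
       applied = if (is.null(apply_to)) NULL else scale_with(apply_to),
       center = mu, scale = sdp)
}

#' Stratified train/test split
#'
#' Draws per-class test sets of size `round(class_size * test_fraction)`
#' (round half up) or of the explicit per-class counts, deterministically
#' under `random_state`.
#'
#' @param labels Vector of class labels, one per sample.
#' @param config A [split_config()].
#' @return A list with integer index vectors `train` and `test`
#'   (disjoint, covering all samples).
#' @export
stratified_split <- function(labels, config = split_config()) {
  stopifnot(inherits(config, "split_config"))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    abort("Both classes must be present to split.",
          class = "evpanel_split_error")
  }
  sizes <- table(labels)
  if (any(sizes < 2L)) {
    abort("Every class needs >= 2 members to split.",
          class = "evpanel_split_error")
  }
  counts <- if (!is.null(config$test_counts)) {
    miss <- setdiff(classes, names(config$test_counts))
    if (length(miss) > 0) {
      abort(paste0("`test_counts` missing class(es): ",
                   paste(miss, collapse = ", ")),
            class = "evpanel_split_error")
    }
    config$test_counts[classes]
  } else {
    setNames(floor(sizes[classes] * config$test_fraction + 0.5), classes)
  }
  if (any(counts > sizes[classes]) || any(counts < 0)) {
    abort("Per-class test counts exceed class sizes.",
          class = "evpanel_split_error")
  }
  test <- withr::with_seed(config$random_state, {
    unlist(lapply(classes, function(cl) {
      idx <- which(labels == cl)
      sort(sample(idx, counts[[cl]]))
    }), use.names = FALSE)
  })
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Fit a PCA projection on training data
#'
#' Projects onto the top eigenvectors of the training covariance; the returned
#' loadings and center are reusable on held-out data via [pca_apply()].
#'
#' @param x Numeric matrix (rows = samples), typically z-scored.
#' @param n_components Number of components (<= min(n samples, n features)).
#' @return A list: `scores`, `loadings`, `center`, `sdev`.
#' @export
pca_project <- function(x, n_components) {
  x <- as.matrix(x)
  n_components <- check_count(n_components, "n_components")
  if (n_components > min(dim(x))) {
    abort("`n_components` exceeds min(n samples, n features).",
          class = "evpanel_projection_error")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  if (sum(pc$sdev > max(pc$sdev) * 1e-9) < n_components &&
      n_components > 1L) {
    abort("Training data is rank-deficient below `n_components`.",
          class = "evpanel_projection_error")
  }
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
       center = pc$center,
       sdev = pc$sdev)
}

#' Apply a fitted PCA projection to new data
#'
#' @param x Numeric matrix in the original feature space.
#' @param fit A projection from [pca_project()].
#' @export
pca_apply <- function(x, fit) {
  sweep(as.matrix(x), 2, fit$center) %*% fit$loadings
}

#' Train a soft-margin linear SVM
#'
#' Minimizes `0.5 * ||w||^2 + C * sum(hinge losses)` (C-classification,
#' linear kernel) with a tightened optimizer tolerance so the solution is
#' comparable against a quadratic-programming reference.  The decision value
#' is `w . x + b`, oriented so positive values indicate the case class.
#'
#' @param x Numeric matrix of (projected) training features.
#' @param y Binary labels.
#' @param cost SVM cost weight C (> 0).
#' @param case Label treated as the positive/case class.
#' @param tolerance Termination tolerance of the dual optimizer; tighten
#'   (e.g. `1e-10`) when comparing against a quadratic-programming reference.
#' @return An `ev_svm` list: `weights`, `bias`, `cost`, `case`, `control`.
#' @export
train_linear_svm <- function(x, y, cost = 1, case = NULL, tolerance = 1e-6) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (length(unique(y)) < 2L) {
    abort("SVM training needs both classes present.",
          class = "evpanel_training_error")
  }
  if (cost <= 0) {
    abort("`cost` must be > 0.", class = "evpanel_config_error")
  }
  grp <- check_binary_labels(y, case)
  yf <- factor(y, levels = c(grp$control, grp$case))
  fit <- e1071::svm(x, yf, kernel = "linear", cost = cost, scale = FALSE,
                    tolerance = tolerance)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  f <- drop(x %*% w) + b
  pred <- as.character(predict(fit, x))
  if (mean((f > 0) == (pred == grp$case)) < 0.5) {
    w <- -w
    b <- -b
  }
  structure(list(weights = w, bias = b, cost = cost,
                 case = grp$case, control = grp$control),
            class = "ev_svm")
}

#' Decision values of a linear SVM
#'
#' @param model An `ev_svm`.
#' @param x Feature matrix in the space the model was trained on.
#' @return Numeric decision values (positive = case).
#' @export
svm_decision <- function(model, x) {
  drop(as.matrix(x) %*% model$weights) + model$bias
}

#' @export
print.ev_svm <- function(x, ...) {
  cat(sprintf("<ev_svm> linear, C = %g, %d weight(s); positive = %s\n",
              x$cost, length(x$weights), x$case))
  invisible(x)
}

#' Matthews correlation coefficient from confusion counts
#'
#' Returns 0 when the denominator is 0.
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @export
mcc <- function(tp, fp, tn, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

confusion_counts <- function(pred_case, is_case) {
  list(tp = sum(pred_case & is_case), fp = sum(pred_case & !is_case),
       tn = sum(!pred_case & !is_case), fn = sum(!pred_case & is_case))
}

# fit scale -> PCA -> SVM on train rows; return model + scorer for new data
fit_svm_pipeline <- function(x_train, y_train, n_components, cost, case = NULL) {
  sc <- zscore_scale(x_train)
  pr <- pca_project(sc$train, n_components)
  svm <- train_linear_svm(pr$scores, y_train, cost = cost, case = case)
  list(
    scaling = sc, projection = pr, svm = svm,
    decide = function(x_new) {
      z <- sweep(sweep(as.matrix(x_new), 2, sc$center), 2, sc$scale, "/")
      svm_decision(svm, pca_apply(z, pr))
    }
  )
}

#' Leave-one-out cross-validation of the scale/PCA/SVM pipeline
#'
#' Refits the entire pipeline (scaling, PCA, SVM) on every leave-one-out
#' training set and predicts the held-out sample; the Matthews correlation
#' coefficient and mean accuracy are computed on the pooled predictions
#' (per-fold MCC is undefined for single samples).
#'
#' @param x Feature matrix (rows = samples), unscaled.
#' @param y Binary labels.
#' @param n_components PCA components inside each fold.
#' @param cost SVM cost.
#' @param case Positive-class label.
#' @return A list: `mcc`, `accuracy`, `predictions` tibble.
#' @export
loocv_score <- function(x, y, n_components = 2L, cost = 1, case = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (nrow(x) < 3L || length(unique(y)) < 2L) {
    abort("LOOCV needs >= 3 samples and both classes.",
          class = "evpanel_contract_error")
  }
  grp <- check_binary_labels(y, case)
  preds <- rep(NA, nrow(x))
  for (i in seq_len(nrow(x))) {
    y_tr <- y[-i]
    if (length(unique(y_tr)) < 2L) {
      warn(sprintf("LOOCV fold %d loses a class entirely; skipped.", i),
           class = "evpanel_fold_skipped")
      next
    }
    pipe <- fit_svm_pipeline(x[-i, , drop = FALSE], y_tr,
                             n_components, cost, case = grp$case)
    preds[i] <- pipe$decide(x[i, , drop = FALSE]) > 0
  }
  keep <- !is.na(preds)
  is_case <- y[keep] == grp$case
  cc <- confusion_counts(as.logical(preds[keep]), is_case)
  list(
    mcc = mcc(cc$tp, cc$fp, cc$tn, cc$fn),
    accuracy = (cc$tp + cc$tn) / sum(unlist(cc)),
    predictions = tibble(index = which(keep),
                         truth = y[keep],
                         predicted_case = as.logical(preds[keep]))
  )
}

#' LOOCV score table over a hyperparameter grid
#'
#' Runs [loocv_score()] for every (cost, components) cell of the grid and
#' flags cells whose mean accuracy exceeds the selection threshold.
#'
#' @param x Feature matrix, `y` binary labels (training split).
#' @param y Binary labels.
#' @param grid A [hyper_grid()].
#' @param threshold Mean-accuracy selection threshold (strict `>`).
#' @param case Positive-class label.
#' @return A tibble with `cost`, `n_components`, `mcc`, `accuracy`, `flagged`;
#'   the total number of model fits is in `attr(, "n_fits")`.
#' @export
grid_triangulate <- function(x, y, grid = hyper_grid(), threshold = 0.90,
                             case = NULL) {
  stopifnot(inherits(grid, "hyper_grid"))
  cells <- tidyr::expand_grid(cost = grid$c_values,
                              n_components = grid$n_components_values)
  max_pc <- min(nrow(as.matrix(x)) - 1L, ncol(as.matrix(x)))
  cells <- filter(cells, .data$n_components <= max_pc)
  if (nrow(cells) == 0) {
    abort("Grid is empty after removing infeasible component counts.",
          class = "evpanel_config_error")
  }
  res <- cells |>
    mutate(score = map2(.data$cost, .data$n_components,
                        ~ loocv_score(x, y, n_components = .y, cost = .x,
                                      case = case)),
           mcc = map_dbl(.data$score, "mcc"),
           accuracy = map_dbl(.data$score, "accuracy"),
           flagged = .data$accuracy > threshold) |>
    select(-"score")
  attr(res, "n_fits") <- nrow(res) * nrow(as.matrix(x))
  res
}

#' Exhaustive combinatorial panel search
#'
#' Fits the scale/PCA/linear-SVM pipeline once per unordered `k`-subset of the
#' candidate features on the fixed training split, scores each panel by
#' rank-based ROC-AUC on the fixed held-out split, and ranks panels by test
#' AUC (ties by LOOCV training MCC, then lexicographic feature ids).  With 22
#' candidates and `k = 2` this evaluates `choose(22, 2) = 231` panels.
#'
#' @param features Samples-by-features tibble or matrix; a `sample_id` column,
#'   if present, is carried as row identity.
#' @param labels Binary labels, one per row of `features`.
#' @param candidates Feature (column) names to search over; defaults to all.
#' @param k Panel size (>= 1).
#' @param n_components PCA components per panel fit (<= k).
#' @param cost SVM cost weight.
#' @param split A [split_config()] or an explicit `list(train=, test=)` of row
#'   indices.
#' @param compute_loocv Also compute the LOOCV training score per panel?
#' @param case Positive-class label.
#' @return An `ev_panel_search` tibble: `panel` (feature ids, collapsed),
#'   `features` (list-column), `test_auc`, `tp`, `fp`, `tn`, `fn`,
#'   `loocv_mcc`, `loocv_accuracy`, `model` (list-column of fitted
#'   pipelines), ranked best first; the split and fit count are attributes.
#' @export
combination_search <- function(features, labels, candidates = NULL, k = 2L,
                               n_components = 2L, cost = 0.025,
                               split = split_config(),
                               compute_loocv = TRUE, case = NULL) {
  k <- check_count(k, "k")
  n_components <- check_count(n_components, "n_components")
  if (n_components > k) {
    abort("`n_components` must not exceed the panel size `k`.",
          class = "evpanel_contract_error")
  }
  feats <- as_tibble(features)
  sample_ids <- if ("sample_id" %in% names(feats)) feats$sample_id else
    as.character(seq_len(nrow(feats)))
  feats <- select(feats, -dplyr::any_of("sample_id"))
  candidates <- candidates %||% names(feats)
  miss <- setdiff(candidates, names(feats))
  if (length(miss) > 0) {
    abort(paste0("Candidate feature(s) absent from data: ",
                 paste(miss, collapse = ", ")),
          class = "evpanel_contract_error")
  }
  if (k > length(candidates)) {
    abort("`k` exceeds the number of candidate features.",
          class = "evpanel_contract_error")
  }
  labels <- as.character(labels)
  grp <- check_binary_labels(labels, case)
  if (inherits(split, "split_config")) split <- stratified_split(labels, split)
  x <- as.matrix(feats[, candidates, drop = FALSE])
  tr <- split$train; te <- split$test
  subsets <- utils::combn(sort(candidates), k, simplify = FALSE)

  rows <- purrr::map(subsets, function(fs) {
    xt <- x[tr, fs, drop = FALSE]
    pipe <- fit_svm_pipeline(xt, labels[tr], n_components, cost,
                             case = grp$case)
    dec <- pipe$decide(x[te, fs, drop = FALSE])
    is_case <- labels[te] == grp$case
    cc <- confusion_counts(dec > 0, is_case)
    lo <- if (compute_loocv) {
      loocv_score(xt, labels[tr], n_components, cost, case = grp$case)
    } else {
      list(mcc = NA_real_, accuracy = NA_real_)
    }
    tibble(
      panel = paste(fs, collapse = " + "),
      features = list(fs),
      test_auc = roc_auc(dec, is_case),
      tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
      loocv_mcc = lo$mcc, loocv_accuracy = lo$accuracy,
      model = list(pipe)
    )
  }) |> list_rbind()

  rows <- arrange(rows, desc(.data$test_auc), desc(.data$loocv_mcc),
                  .data$panel)
  n_loocv_fits <- if (compute_loocv) length(subsets) * length(tr) else 0L
  inform(sprintf("combination_search: %d panel(s) of size %d evaluated (%d model fits).",
                 length(subsets), k, length(subsets) + n_loocv_fits),
         class = "evpanel_fit_count")
  structure(rows, class = c("ev_panel_search", class(rows)),
            split = split, sample_ids = sample_ids, k = k,
            n_combinations = length(subsets),
            n_fits = length(subsets) + n_loocv_fits,
            case = grp$case)
}

#' Rank-based ROC area under the curve
#'
#' `(concordant pairs + 0.5 * tied pairs) / (n_case * n_control)`: the
#' probability that a random case scores above a random control, computed via
#' midranks.
#'
#' @param scores Numeric decision values or predicted probabilities.
#' @param labels Logical (`TRUE` = case) or binary labels.
#' @param case Positive-class label when `labels` is not logical.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, case = NULL) {
  is_case <- if (is.logical(labels)) labels else {
    grp <- check_binary_labels(labels, case)
    as.character(labels) == grp$case
  }
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) {
    abort("roc_auc() needs both classes present.",
          class = "evpanel_contract_error")
  }
  r <- rank(scores)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# entropy in nats over a label vector
label_entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

#' V-measure between a clustering and reference labels
#'
#' Harmonic mean of homogeneity (`1 - H(truth|cluster)/H(truth)`) and
#' completeness (`1 - H(cluster|truth)/H(cluster)`); invariant to permuting
#' cluster ids.
#'
#' @param truth Reference labels.
#' @param cluster Cluster assignments.
#' @export
v_measure <- function(truth, cluster) {
  truth <- as.character(truth); cluster <- as.character(cluster)
  n <- length(truth)
  stopifnot(length(cluster) == n)
  h_t <- label_entropy(truth); h_c <- label_entropy(cluster)
  cond <- function(a, b) {
    # H(a | b)
    sum(vapply(split(a, b), function(ai) length(ai) / n * label_entropy(ai),
               numeric(1)))
  }
  hom <- if (h_t == 0) 1 else 1 - cond(truth, cluster) / h_t
  comp <- if (h_c == 0) 1 else 1 - cond(cluster, truth) / h_c
  if (hom + comp == 0) return(0)
  2 * hom * comp / (hom + comp)
}

#' k-means clustering scored by V-measure against known labels
#'
#' Lloyd's algorithm with multiple restarts (best inertia kept), compared to
#' the true labels by V-measure.
#'
#' @param x Scaled feature matrix (rows = samples).
#' @param true_labels Reference labels.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param n_init Number of random restarts.
#' @return A list: `cluster` (assignments), `v_measure`, `kmeans` (the
#'   [stats::kmeans()] fit).
#' @export
kmeans_vmeasure <- function(x, true_labels, k = 2L, seed = 1L, n_init = 10L) {
  x <- as.matrix(x)
  k <- check_count(k, "k")
  if (k > nrow(x)) {
    abort("`k` exceeds the number of samples.",
          class = "evpanel_contract_error")
  }
  km <- withr::with_seed(seed, kmeans(x, centers = k, nstart = n_init))
  list(cluster = km$cluster,
       v_measure = v_measure(true_labels, km$cluster),
       kmeans = km)
}

#' Univariate logistic regression for a single marker
#'
#' Maximum-likelihood fit (intercept + slope) by iteratively reweighted least
#' squares.  Perfect separation is detected and flagged; coefficients at the
#' iteration cap are returned with a warning in that case.
#'
#' @param x Marker values.
#' @param y Binary labels.
#' @param case Positive-class label.
#' @return An `ev_logistic` list: `coefficients` (intercept, slope),
#'   `probabilities`, `separation`, `case`, `fit`.
#' @export
logistic_fit <- function(x, y, case = NULL) {
  if (any(!is.finite(x))) {
    abort("Marker values must be finite.", class = "evpanel_contract_error")
  }
  grp <- check_binary_labels(as.character(y), case)
  yy <- as.integer(as.character(y) == grp$case)
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(yy ~ x, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separation) {
    warn("Perfect separation detected; coefficients reported at the iteration cap.",
         class = "evpanel_separation")
  }
  structure(list(coefficients = setNames(coef(fit), c("intercept", "slope")),
                 probabilities = unname(fitted(fit)),
                 separation = separation, case = grp$case, fit = fit),
            class = "ev_logistic")
}
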