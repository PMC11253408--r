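# Panel discovery: scaling, splitting, PCA, linear SVM, LOOCV, the
# combinatorial search, rank AUC, k-means/V-measure and logistic regression.

test_that("z-scoring uses training-population statistics with no test leakage", {
  sc <- zscore_scale(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(drop(sc$train), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  set.seed(2)
  tr <- matrix(stats::rnorm(40, 5, 3), 20, 2)
  te <- matrix(stats::rnorm(10, 9, 3), 5, 2)
  out <- zscore_scale(tr, te)
  expect_equal(unname(colMeans(out$train)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(sqrt(colMeans(out$train^2))), c(1, 1), tolerance = 1e-12)
  # test set scaled with train parameters keeps its own (nonzero) mean
  expect_gt(abs(mean(out$applied)), 0.5)
  bad <- cbind(tr, 7)
  colnames(bad) <- c("f1", "f2", "flat")
  expect_error(zscore_scale(bad), regexp = "flat",
               class = "evpanel_scaling_error")
})

test_that("stratified splits honour explicit per-class counts and fraction rounding", {
  labs1 <- rep(c("HGSC", "Benign"), c(10, 9))
  sp <- stratified_split(labs1, split_config(
    test_counts = c(HGSC = 4, Benign = 3), random_state = 6))
  expect_equal(sum(labs1[sp$test] == "HGSC"), 4)
  expect_equal(sum(labs1[sp$test] == "Benign"), 3)
  expect_setequal(c(sp$train, sp$test), seq_along(labs1))
  expect_length(intersect(sp$train, sp$test), 0)
  labs2 <- rep(c("HGSC", "Benign"), c(30, 30))
  sp2 <- stratified_split(labs2, split_config(
    test_counts = c(HGSC = 10, Benign = 10), random_state = 1))
  expect_equal(length(sp2$test), 20)
  # fraction path: round half up per class (10 * .3 = 3; 9 * .3 = 2.7 -> 3)
  sp3 <- stratified_split(labs1, split_config(test_fraction = 0.3,
                                              random_state = 0))
  expect_equal(sum(labs1[sp3$test] == "HGSC"), 3)
  expect_equal(sum(labs1[sp3$test] == "Benign"), 3)
  expect_identical(
    stratified_split(labs1, split_config(random_state = 42)),
    stratified_split(labs1, split_config(random_state = 42)))
  expect_error(stratified_split(rep("A", 5), split_config()),
               class = "evpanel_split_error")
  expect_error(stratified_split(c("A", "A", "B"), split_config()),
               class = "evpanel_split_error")
})

test_that("PCA projection preserves variance and detects planted structure", {
  set.seed(5)
  x <- matrix(stats::rnorm(60), 20, 3)
  pr <- pca_project(x, 3)
  expect_equal(sum(apply(pr$scores, 2, var)), sum(apply(x, 2, var)),
               tolerance = 1e-9)
  x2 <- matrix(stats::rnorm(20), 10, 2)
  pr2 <- pca_project(x2, 2)
  recon <- pr2$scores %*% t(pr2$loadings) +
    matrix(pr2$center, 10, 2, byrow = TRUE)
  expect_equal(recon, x2, tolerance = 1e-9)
  # planted 1-D structure dominates the first component
  t_ <- stats::rnorm(50, sd = 4)
  x3 <- cbind(t_, 0.8 * t_, -0.5 * t_) + matrix(stats::rnorm(150, sd = 0.3), 50)
  pr3 <- pca_project(x3, 1)
  expect_gt(pr3$sdev[1]^2 / sum(pr3$sdev^2), 0.90)
  expect_error(pca_project(x2, 5), class = "evpanel_projection_error")
  # rank-deficient: duplicated column pair
  xd <- cbind(t_, t_)
  expect_error(pca_project(xd, 2), class = "evpanel_projection_error")
})

test_that("linear SVM separates 1-D data with a boundary inside the gap", {
  x <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y <- c("Benign", "Benign", "HGSC", "HGSC")
  m <- train_linear_svm(x, y, cost = 100)
  boundary <- -m$bias / m$weights
  expect_gt(boundary, -1); expect_lt(boundary, 1)
  expect_equal(svm_decision(m, x) > 0, y == "HGSC")
  expect_error(train_linear_svm(x, rep("HGSC", 4)),
               class = "evpanel_training_error")
})

test_that("duplicating every sample while halving C leaves the decision function unchanged", {
  set.seed(9)
  x <- cbind(c(stats::rnorm(6, 1.2), stats::rnorm(6, -1.2)), stats::rnorm(12))
  y <- rep(c("HGSC", "Benign"), each = 6)
  m1 <- train_linear_svm(x, y, cost = 1, tolerance = 1e-10)
  m2 <- train_linear_svm(rbind(x, x), c(y, y), cost = 0.5, tolerance = 1e-10)
  expect_equal(m1$weights, m2$weights, tolerance = 1e-5)
  expect_equal(m1$bias, m2$bias, tolerance = 1e-5)
})

test_that("SVM weights match a brute-force quadratic-programming dual solution", {
  set.seed(5)
  for (cost in c(0.25, 1)) {
    x <- cbind(c(stats::rnorm(6, 1.5), stats::rnorm(6, -1.5)), stats::rnorm(12))
    y <- rep(c("HGSC", "Benign"), each = 6)
    ora <- qp_svm_oracle(x, y == "HGSC", cost)
    m <- train_linear_svm(x, y, cost = cost, tolerance = 1e-10)
    expect_equal(m$weights, ora$weights, tolerance = 1e-4,
                 ignore_attr = TRUE)
    expect_equal(m$bias, ora$bias, tolerance = 1e-4)
  }
})

test_that("MCC matches its closed form and LOOCV is perfect on separable data", {
  expect_equal(mcc(tp = 8, fp = 0, tn = 10, fn = 2), 80 / sqrt(9600))
  expect_equal(mcc(0, 0, 0, 0), 0)
  set.seed(3)
  x <- cbind(c(stats::rnorm(8, 5), stats::rnorm(8, -5)), stats::rnorm(16))
  y <- rep(c("HGSC", "Benign"), each = 8)
  lo <- loocv_score(x, y, n_components = 2, cost = 10)
  expect_equal(lo$mcc, 1)
  expect_equal(lo$accuracy, 1)
})

test_that("LOOCV MCC under label permutation is centred on zero", {
  set.seed(3)
  x <- matrix(stats::rnorm(19 * 2), 19, 2)
  y0 <- rep(c("HGSC", "Benign"), c(10, 9))
  mccs <- vapply(1:200, function(i) {
    withr::with_seed(i, loocv_score(x, sample(y0), 2, 1)$mcc)
  }, numeric(1))
  expect_lt(abs(mean(mccs)), 0.25)
})

test_that("grid triangulation scores every feasible cell and flags accurate ones", {
  set.seed(14)
  x <- cbind(c(stats::rnorm(8, 4), stats::rnorm(8, -4)), stats::rnorm(16),
             stats::rnorm(16))
  y <- rep(c("HGSC", "Benign"), each = 8)
  g1 <- grid_triangulate(x, y, hyper_grid(c_values = 1,
                                          n_components_values = 2))
  expect_equal(nrow(g1), 1)
  g <- grid_triangulate(x, y, hyper_grid(c_values = c(0.5, 1, 2),
                                         n_components_values = c(2, 3)))
  expect_equal(nrow(g), 6)
  expect_true(all(g$flagged))
  expect_equal(attr(g, "n_fits"), 6 * 16)
})

test_that("the combinatorial search enumerates all subsets and ranks by held-out AUC", {
  set.seed(6)
  n <- 19
  feats <- as.data.frame(matrix(stats::rnorm(n * 22), n, 22))
  names(feats) <- sprintf("PEP%02d", 1:22)
  y <- rep(c("HGSC", "Benign"), c(10, 9))
  ps <- suppressMessages(combination_search(
    feats, y, k = 2, n_components = 2, cost = 0.025,
    split = split_config(test_counts = c(HGSC = 4, Benign = 3),
                         random_state = 6),
    compute_loocv = FALSE))
  expect_equal(nrow(ps), choose(22, 2))
  expect_equal(attr(ps, "n_combinations"), 231)
  expect_true(all(diff(ps$test_auc) <= 1e-12))
  expect_true(all(ps$tp + ps$fp + ps$tn + ps$fn == 7))
  # k = 1 gives one panel per candidate
  ps1 <- suppressMessages(combination_search(
    feats, y, candidates = names(feats)[1:5], k = 1, n_components = 1,
    cost = 1, split = split_config(random_state = 2), compute_loocv = FALSE))
  expect_equal(nrow(ps1), 5)
  # k = |candidates| equals a single full-feature fit
  cand <- names(feats)[1:3]
  sp <- stratified_split(y, split_config(random_state = 3))
  ps_full <- suppressMessages(combination_search(
    feats, y, candidates = cand, k = 3, n_components = 2, cost = 1,
    split = sp, compute_loocv = FALSE))
  expect_equal(nrow(ps_full), 1)
  direct <- svm_pipeline(as.matrix(feats[sp$train, cand]), y[sp$train],
                         n_components = 2, cost = 1)
  expect_equal(ps_full$test_auc,
               roc_auc(direct$decide(as.matrix(feats[sp$test, cand])),
                       y[sp$test] == "HGSC"))
  expect_error(
    suppressMessages(combination_search(feats, y, k = 1, n_components = 2)),
    class = "evpanel_contract_error")
})

test_that("panel models never touch the held-out split during fitting", {
  set.seed(8)
  feats <- as.data.frame(matrix(stats::rnorm(19 * 4), 19, 4))
  names(feats) <- c("A", "B", "C", "D")
  y <- rep(c("HGSC", "Benign"), c(10, 9))
  sp <- stratified_split(y, split_config(random_state = 5))
  ps <- suppressMessages(combination_search(
    feats, y, k = 2, n_components = 2, cost = 1, split = sp,
    compute_loocv = FALSE))
  m <- ps$model[[1]]
  fs <- ps$features[[1]]
  xt <- as.matrix(feats[sp$train, fs])
  expect_equal(m$scaling$center, colMeans(xt), tolerance = 1e-12)
  refit <- svm_pipeline(xt, y[sp$train], 2, 1)
  expect_equal(m$svm$weights, refit$svm$weights, tolerance = 1e-9)
})

test_that("the top-ranked pair recovers two planted biomarkers in a large cohort", {
  run <- function(s) {
    cfg <- cohort_config(100, 100, n_peptides = 6,
                         planted_effects = c(AAAAAAK = 2.4, CCCCCCK = 2.4),
                         noise_cv = 0.5, tic_cv = 0, seed = s)
    st <- generate_quant_study(cfg)
    w <- study_wide(st)
    labs <- study_labels(st)[w$sample_id]
    ps <- suppressMessages(combination_search(
      w, labs, k = 2, n_components = 2, cost = 1,
      split = split_config(test_counts = c(HGSC = 35, Benign = 35),
                           random_state = s),
      compute_loocv = FALSE))
    setequal(ps$features[[1]], c("AAAAAAK", "CCCCCCK"))
  }
  hits <- vapply(1:100, run, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("rank AUC counts concordant and tied pairs", {
  expect_equal(roc_auc(c(1, 2, 10, 20), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8),
                       c("Benign", "Benign", "HGSC", "HGSC"), case = "HGSC"),
               0.75)
  # binary predictions: 8/10 sensitivity, 10/10 specificity -> 0.90
  pred <- c(rep(1, 8), rep(0, 2), rep(0, 10))
  lab <- c(rep(TRUE, 10), rep(FALSE, 10))
  expect_equal(roc_auc(pred, lab), 0.90)
  set.seed(10)
  for (i in 1:20) {
    s <- stats::rnorm(12); l <- sample(c(TRUE, FALSE), 12, TRUE)
    if (length(unique(l)) < 2) next
    expect_equal(roc_auc(s, l) + roc_auc(-s, l), 1, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)),
               class = "evpanel_contract_error")
})

test_that("k-means clustering of separated blobs reaches V-measure 1 and nulls score near 0", {
  set.seed(21)
  x <- rbind(matrix(stats::rnorm(40, 6), 20), matrix(stats::rnorm(40, -6), 20))
  truth <- rep(c("a", "b"), each = 20)
  km <- kmeans_vmeasure(x, truth, k = 2, seed = 1)
  expect_equal(km$v_measure, 1)
  # label-permutation invariance of the V-measure itself
  swapped <- ifelse(km$cluster == 1, 2, 1)
  expect_equal(v_measure(truth, swapped), v_measure(truth, km$cluster))
  # random labels at large n: near zero
  big <- matrix(stats::rnorm(4000), 2000, 2)
  rand <- sample(c("a", "b"), 2000, TRUE)
  kmr <- kmeans_vmeasure(big, rand, k = 2, seed = 2)
  expect_lt(kmr$v_measure, 0.02)
})

test_that("logistic regression matches an independent optimizer and preserves rank AUC", {
  set.seed(30)
  x <- stats::rnorm(20)
  y <- ifelse(stats::runif(20) < stats::plogis(0.5 + 1.2 * x), "HGSC", "Benign")
  if (length(unique(y)) < 2) y[1:2] <- c("HGSC", "Benign")
  fit <- logistic_fit(x, y, case = "HGSC")
  nll <- function(beta) {
    eta <- beta[1] + beta[2] * x
    -sum((y == "HGSC") * eta - log(1 + exp(eta)))
  }
  ref <- stats::optim(c(0, 0), nll, method = "BFGS",
                      control = list(reltol = 1e-14))
  expect_equal(unname(fit$coefficients), ref$par, tolerance = 1e-4)
  if (fit$coefficients["slope"] > 0) {
    expect_equal(roc_auc(fit$probabilities, y == "HGSC"),
                 roc_auc(x, y == "HGSC"), tolerance = 1e-12)
  }
  # labels independent of x: slope near zero
  set.seed(31)
  x2 <- stats::rnorm(400)
  y2 <- rep(c("HGSC", "Benign"), 200)
  fit2 <- logistic_fit(x2, y2, case = "HGSC")
  expect_lt(abs(fit2$coefficients["slope"]), 0.3)
  # perfect separation is flagged
  expect_warning(
    fit3 <- logistic_fit(c(1, 2, 3, 10, 11, 12),
                         rep(c("Benign", "HGSC"), each = 3), case = "HGSC"),
    class = "evpanel_separation")
  expect_true(fit3$separation)
})
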