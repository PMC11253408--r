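# Shared fixtures and independent oracles, built in code.

# one peptide x sample cell expanded to transition rows
make_cell_rows <- function(sample_id, peptide, lib_int, areas,
                           ppm = 0, protein = "PROT1") {
  tibble::tibble(
    sample_id = sample_id,
    protein_id = protein,
    peptide_sequence = peptide,
    precursor_mz = 500,
    transition_label = paste0("y", seq_along(lib_int) + 2L),
    product_mz = 600 + seq_along(lib_int),
    retention_time = 30,
    area = areas,
    background = 0,
    mass_error_ppm = rep_len(ppm, length(lib_int)),
    library_relative_intensity = lib_int
  )
}

# long abundance tibble from an ev_study, bypassing the chromatogram layer
study_long <- function(study) {
  dplyr::transmute(study$abundances,
                   peptide_sequence = peptide_id,
                   sample_id = sample_id,
                   abundance = area)
}

study_wide <- function(study) {
  tidyr::pivot_wider(study_long(study),
                     names_from = "peptide_sequence",
                     values_from = "abundance")
}

study_labels <- function(study) {
  stats::setNames(study$metadata$group, study$metadata$sample_id)
}

# exact two-sided Mann-Whitney p by full enumeration of rank assignments
enumerate_mw_p <- function(a, b) {
  n <- length(a) + length(b)
  pooled <- c(a, b)
  u_of <- function(idx_a) {
    r <- rank(pooled)
    sum(r[idx_a]) - length(idx_a) * (length(idx_a) + 1) / 2
  }
  u_obs <- u_of(seq_along(a))
  all_u <- apply(utils::combn(n, length(a)), 2, function(ix) {
    r <- rank(pooled)
    sum(r[ix]) - length(a) * (length(a) + 1) / 2
  })
  mu <- length(a) * length(b) / 2
  mean(abs(all_u - mu) >= abs(u_obs - mu))
}

# Shapley values by averaging marginal contributions over all permutations
permutation_shapley <- function(predict_fun, x, mu) {
  p <- length(x)
  perms <- gtools_permutations(p)
  phi <- numeric(p)
  for (r in seq_len(nrow(perms))) {
    z <- mu
    prev <- predict_fun(matrix(z, 1))
    for (j in perms[r, ]) {
      z[j] <- x[j]
      cur <- predict_fun(matrix(z, 1))
      phi[j] <- phi[j] + (cur - prev)
      prev <- cur
    }
  }
  phi / nrow(perms)
}

# all permutations of 1..n (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- (1:n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# SVM primal weights/bias via a QP solve of the dual (kernlab::ipop)
qp_svm_oracle <- function(x, y_case, cost) {
  yn <- ifelse(y_case, 1, -1)
  H <- (yn %*% t(yn)) * (x %*% t(x))
  n <- length(yn)
  qp <- kernlab::ipop(c = rep(-1, n), H = H, A = t(yn), b = 0, r = 0,
                      l = rep(0, n), u = rep(cost, n), sigf = 9)
  a <- kernlab::primal(qp)
  w <- drop(t(a * yn) %*% x)
  free <- a > 1e-6 & a < cost - 1e-6
  b <- mean(yn[free] - x[free, , drop = FALSE] %*% w)
  list(weights = w, bias = b, alpha = a)
}
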