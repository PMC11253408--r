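# Quantification chain: peak integration, dotp, interference filter,
# TIC/reference normalization, MNAR imputation, RT calibration and windows.

test_that("integrate_peak recovers simple geometries and the Gaussian closed form", {
  # triangle of height h and base w with zero endpoints -> h*w/2
  tri <- data.frame(time = c(0, 1, 2), intensity = c(0, 10, 0))
  expect_equal(integrate_peak(tri, c(0, 2)), 10 * 2 / 2)
  # identically zero trace
  z <- data.frame(time = seq(0, 2, 0.1), intensity = 0)
  expect_equal(integrate_peak(z, c(0, 2)), 0)
  # Gaussian: apex 100, sd 0.1 min, window +/- 4 sd vs closed form
  tt <- seq(29.5, 30.5, by = 0.002)
  g <- data.frame(time = tt, intensity = 100 * exp(-(tt - 30)^2 / (2 * 0.1^2)))
  a <- integrate_peak(g, c(30 - 0.4, 30 + 0.4))
  expect_equal(a, 100 * 0.1 * sqrt(2 * pi), tolerance = 0.01)
  expect_error(integrate_peak(tri, c(5, 6)), class = "evpanel_integration_error")
  expect_error(integrate_peak(tri, c(2, 0)), class = "evpanel_integration_error")
})

test_that("dotp matches hand-computed values and is scale invariant", {
  expect_equal(dotp(c(2, 4, 6), c(1, 2, 3)), 1)
  expect_equal(dotp(c(1, 0), c(0, 1)), 0)
  expect_equal(dotp(c(4, 1, 1), c(1, 1, 4)), 5 / 6)
  expect_equal(dotp(c(0, 0), c(0, 0)), 0)
  set.seed(42)
  for (i in 1:25) {
    l <- stats::runif(5); o <- stats::runif(5); c_ <- stats::runif(1, 0.1, 50)
    expect_equal(dotp(l, c_ * o), dotp(l, o), tolerance = 1e-12)
  }
  expect_error(dotp(c(1, 2), c(1, 2, 3)), class = "evpanel_contract_error")
  expect_error(dotp(c(1, -1), c(1, 1)), class = "evpanel_contract_error")
})

test_that("interference filter applies strict dotp, ppm and transition-count rules", {
  lib <- c(4, 1, 1)
  # cell A: proportional pattern, dotp 1
  # cell B: pattern (1,1,4), dotp exactly 5/6
  # cell C: only 2 detected transitions
  # cell D: clean pattern but mass error above tolerance
  rep_ <- dplyr::bind_rows(
    make_cell_rows("S1", "PEPTIDEK", lib, c(40, 10, 10)),
    make_cell_rows("S1", "ELGPYTLDR", lib, c(10, 10, 40)),
    make_cell_rows("S2", "PEPTIDEK", lib, c(40, 10, 0)),
    make_cell_rows("S2", "ELGPYTLDR", lib, c(40, 10, 10), ppm = 20.5)
  )
  q <- apply_interference_filter(rep_, dotp_min = 0.8, ppm_max = 20,
                                 min_transitions = 3)
  val <- function(s, p) q$abundance[q$sample_id == s & q$peptide_sequence == p]
  flg <- function(s, p) q$flag[q$sample_id == s & q$peptide_sequence == p]
  expect_equal(val("S1", "PEPTIDEK"), 60)
  expect_equal(flg("S1", "PEPTIDEK"), "detected")
  expect_equal(val("S1", "ELGPYTLDR"), 60)        # dotp 5/6 > 0.8 retained
  expect_equal(val("S2", "PEPTIDEK"), 0)          # 2 transitions < 3
  expect_equal(flg("S2", "PEPTIDEK"), "interference_zeroed")
  expect_equal(val("S2", "ELGPYTLDR"), 0)         # 20.5 ppm > 20
  # boundary semantics: a cell exactly at the dotp threshold is retained,
  # strictly below is zeroed
  q2 <- apply_interference_filter(rep_, dotp_min = 5 / 6, ppm_max = NULL,
                                  min_transitions = 3)
  expect_equal(q2$flag[q2$sample_id == "S1" & q2$peptide_sequence == "ELGPYTLDR"],
               "detected")
  q3 <- apply_interference_filter(rep_, dotp_min = 5 / 6 + 1e-9,
                                  ppm_max = NULL, min_transitions = 3)
  expect_equal(q3$flag[q3$sample_id == "S1" & q3$peptide_sequence == "ELGPYTLDR"],
               "interference_zeroed")
  # mass error exactly at the tolerance is retained (strict >)
  q4 <- apply_interference_filter(
    make_cell_rows("S9", "PEPTIDEK", lib, c(40, 10, 10), ppm = 20),
    dotp_min = 0.8, ppm_max = 20, min_transitions = 3)
  expect_equal(q4$flag, "detected")
})

test_that("TIC normalization divides by per-sample totals and removes planted loading exactly", {
  lib <- c(1, 1)
  rep_ <- dplyr::bind_rows(
    make_cell_rows("A", "PEPTIDEK", lib, c(6, 4)),
    make_cell_rows("A", "ELGPYTLDR", lib, c(50, 40)),
    make_cell_rows("B", "PEPTIDEK", lib, c(12, 8)),
    make_cell_rows("B", "ELGPYTLDR", lib, c(100, 80))
  )
  q <- apply_interference_filter(rep_, min_transitions = 2) |>
    tic_normalize(tic = c(A = 100, B = 200))
  expect_equal(q$abundance[q$sample_id == "A" & q$peptide_sequence == "PEPTIDEK"], 0.1)
  expect_equal(q$abundance[q$sample_id == "B" & q$peptide_sequence == "PEPTIDEK"], 0.1)
  # multiplying a whole sample by a loading factor leaves TIC-normalized values unchanged
  rep_loaded <- dplyr::mutate(rep_, area = area * ifelse(sample_id == "B", 7, 1))
  q0 <- apply_interference_filter(rep_, min_transitions = 2) |> tic_normalize()
  q1 <- apply_interference_filter(rep_loaded, min_transitions = 2) |> tic_normalize()
  expect_equal(q1$abundance, q0$abundance, tolerance = 1e-12)
  expect_error(
    tic_normalize(apply_interference_filter(rep_, min_transitions = 2),
                  tic = c(A = 0, B = 200)),
    class = "evpanel_normalization_error")
})

test_that("normalization steps enforce their order through provenance", {
  rep_ <- make_cell_rows("A", "PEPTIDEK", c(1, 1), c(5, 5))
  q <- apply_interference_filter(rep_, min_transitions = 2)
  expect_error(reference_normalize(q), class = "evpanel_provenance_error")
  expect_error(impute_mnar(q), class = "evpanel_provenance_error")
  qt <- tic_normalize(q)
  expect_error(tic_normalize(qt), class = "evpanel_provenance_error")
  qi <- impute_mnar(qt)
  expect_error(reference_normalize(qi), class = "evpanel_provenance_error")
})

test_that("reference normalization fixes the reference row at 1 and is scale invariant", {
  lib <- c(1, 1)
  rep_ <- dplyr::bind_rows(
    make_cell_rows("A", "EVQEFYK", lib, c(10, 10)),
    make_cell_rows("A", "PEPTIDEK", lib, c(30, 10)),
    make_cell_rows("B", "EVQEFYK", lib, c(20, 20)),
    make_cell_rows("B", "PEPTIDEK", lib, c(60, 20))
  )
  q <- apply_interference_filter(rep_, min_transitions = 2) |>
    tic_normalize() |> reference_normalize()
  expect_true(all(q$abundance[q$peptide_sequence == "EVQEFYK"] == 1))
  # doubling one sample's entire column does not change its normalized values
  rep2 <- dplyr::mutate(rep_, area = area * ifelse(sample_id == "B", 2, 1))
  q2 <- apply_interference_filter(rep2, min_transitions = 2) |>
    tic_normalize() |> reference_normalize()
  expect_equal(q2$abundance, q$abundance, tolerance = 1e-12)
  # missing reference in a sample is an error listing the sample
  rep3 <- dplyr::filter(rep_, !(sample_id == "B" & peptide_sequence == "EVQEFYK"))
  expect_error(
    apply_interference_filter(rep3, min_transitions = 2) |>
      tic_normalize() |> reference_normalize(),
    regexp = "B", class = "evpanel_normalization_error")
})

test_that("MNAR imputation fills zeros with row minima and drops all-missing peptides", {
  lib <- c(1, 1)
  rep_ <- dplyr::bind_rows(
    make_cell_rows("A", "PEPTIDEK", lib, c(0, 0)),
    make_cell_rows("B", "PEPTIDEK", lib, c(3, 2)),
    make_cell_rows("C", "PEPTIDEK", lib, c(6, 4)),
    make_cell_rows("A", "ELGPYTLDR", lib, c(2, 2)),
    make_cell_rows("B", "ELGPYTLDR", lib, c(4, 4)),
    make_cell_rows("C", "ELGPYTLDR", lib, c(8, 8)),
    make_cell_rows("A", "GONEPEPK", lib, c(0, 0)),
    make_cell_rows("B", "GONEPEPK", lib, c(0, 0)),
    make_cell_rows("C", "GONEPEPK", lib, c(0, 0))
  )
  q <- apply_interference_filter(rep_, min_transitions = 2) |>
    tic_normalize(tic = c(A = 1, B = 1, C = 1))
  expect_warning(qi <- impute_mnar(q), class = "evpanel_dropped_peptides")
  expect_false("GONEPEPK" %in% qi$peptide_sequence)
  row <- qi[qi$peptide_sequence == "PEPTIDEK", ]
  expect_equal(sort(row$abundance), c(5, 5, 10))
  expect_equal(row$flag[row$sample_id == "A"], "imputed")
  # detected cells are never altered
  other <- qi[qi$peptide_sequence == "ELGPYTLDR", ]
  expect_equal(sort(other$abundance), c(4, 8, 16))
  expect_true(all(other$flag == "detected"))
  expect_true(all(qi$abundance > 0))
})

test_that("the full chain recovers planted folds: exactly at zero noise, within 10% at CV 10%", {
  # zero-noise: loading + reference normalization cancel exactly
  cfg0 <- cohort_config(6, 6, n_peptides = 8,
                        planted_effects = c(QGGFLGLSNIK = 8.86),
                        noise_cv = 0, tic_cv = 0.4, seed = 13)
  st0 <- simulate_study(cfg0)
  q0 <- apply_interference_filter(st0$transition_report, min_transitions = 3) |>
    tic_normalize() |> reference_normalize() |> impute_mnar()
  labs <- study_labels(st0)
  cell <- q0[q0$peptide_sequence == "QGGFLGLSNIK", ]
  ratio <- mean(cell$abundance[labs[cell$sample_id] == "HGSC"]) /
    mean(cell$abundance[labs[cell$sample_id] == "Benign"])
  expect_equal(ratio, 8.86, tolerance = 1e-9)
  # noisy: within 10% at CV 10%, n = 30/30
  cfg1 <- cohort_config(30, 30, n_peptides = 20,
                        planted_effects = c(QGGFLGLSNIK = 3.14, DISEMFLQIYK = 8.86),
                        noise_cv = 0.1, tic_cv = 0.3, seed = 17)
  st1 <- simulate_study(cfg1)
  q1 <- apply_interference_filter(st1$transition_report, min_transitions = 3) |>
    tic_normalize() |> reference_normalize() |> impute_mnar()
  labs1 <- study_labels(st1)
  for (pep in c("QGGFLGLSNIK", "DISEMFLQIYK")) {
    cell <- q1[q1$peptide_sequence == pep, ]
    ratio <- mean(cell$abundance[labs1[cell$sample_id] == "HGSC"]) /
      mean(cell$abundance[labs1[cell$sample_id] == "Benign"])
    planted <- st1$truth$fold[st1$truth$peptide_id == pep]
    expect_lt(abs(ratio / planted - 1), 0.10)
  }
})

test_that("retention-time calibration enforces the strict r > 0.95 gate", {
  irt <- c(10, 30, 50, 70, 90)
  cal <- calibrate_rt(0.5 * irt + 3, irt)
  expect_equal(cal$pearson_r, 1)
  expect_equal(cal$slope, 0.5, tolerance = 1e-12)
  expect_equal(cal$intercept, 3, tolerance = 1e-12)
  expect_true(cal$passes_qc)
  anti <- calibrate_rt(-0.5 * irt + 60, irt)
  expect_equal(anti$pearson_r, -1)
  expect_false(anti$passes_qc)
  # correlation just under the gate fails (strict >)
  set.seed(4)
  repeat {
    obs <- irt + stats::rnorm(5, 0, 12)
    r <- stats::cor(obs, irt)
    if (r > 0.90 && r < 0.95) break
  }
  expect_false(calibrate_rt(obs, irt)$passes_qc)
  expect_error(calibrate_rt(c(1, 2), c(1, 2)),
               class = "evpanel_calibration_error")
})

test_that("acquisition windows are centered on predicted retention times", {
  cal <- calibrate_rt(c(10, 20, 30, 40), c(10, 20, 30, 40))
  w8 <- schedule_windows(cal, c(p = 40), width = 8)
  expect_equal(c(w8$start, w8$end), c(36, 44))
  w3 <- schedule_windows(cal, c(p = 40), width = 3, drift_offsets = 0.5)
  expect_equal(c(w3$start, w3$end), c(39, 42))
  many <- schedule_windows(cal, c(10, 25, 40), width = 3)
  many0 <- schedule_windows(cal, c(10, 25, 40), width = 3,
                            drift_offsets = c(0, 0, 0))
  expect_equal(many, many0)
  expect_error(schedule_windows(cal, 40, width = 0),
               class = "evpanel_contract_error")
  bad <- calibrate_rt(c(40, 10, 30, 20), c(10, 20, 30, 40))
  expect_error(schedule_windows(bad, 40, width = 8),
               class = "evpanel_qc_error")
})
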