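test_that("control normalization rescales to control mean 1", {
  expect_equal(normalize_to_control(0.4, rep(0.8, 5)), 0.5)
  ctrl <- c(0.7, 0.9, 1.1, 0.5)
  expect_equal(mean(normalize_to_control(ctrl, ctrl)), 1.0)
  expect_equal(normalize_to_control(c(1, 2), c(2, 2, 2)), c(0.5, 1))
  expect_error(normalize_to_control(1, numeric(0)), "control")
  expect_error(normalize_to_control(1, c(-1, -3)), "positive")
})

test_that("coefficient of variation is sample SD over mean", {
  expect_equal(coefficient_of_variation(rep(3, 10)), 0)
  expect_equal(coefficient_of_variation(c(2, 4)), sqrt(2) / 3)
  v <- c(0.65, 1.35, 1)                 # mean 1, sd 0.35
  expect_equal(coefficient_of_variation(v), sd(v))
  expect_error(coefficient_of_variation(5), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("rank-sum test matches exact enumeration for small samples", {
  r <- wilcoxon_rank_sum(1:3, 4:6, alternative = "less")
  expect_equal(r$p_value, 1 / 20)       # all 3 low ranks: 1 of C(6,3)
  expect_equal(r$U, 0)
  # identical samples: no separation
  expect_gte(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)
  # agreement with full enumeration over random tie-free inputs, n_x+n_y <= 10
  set.seed(101)
  for (rep in 1:20) {
    nx <- sample(2:6, 1); nyy <- sample(2:min(6, 10 - nx), 1)
    v <- sample(seq(0.01, 0.99, by = 0.01), nx + nyy)
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    for (alt in c("two.sided", "less", "greater")) {
      expect_equal(wilcoxon_rank_sum(x, y, alt)$p_value,
                   wilcox_exact_enum(x, y, alt), tolerance = 1e-12)
    }
  }
  # clearly shifted larger samples are strongly significant
  set.seed(7)
  big <- wilcoxon_rank_sum(rnorm(30, 0), rnorm(30, 2))
  expect_lt(big$p_value, 0.001)
})

test_that("sample-size formula gives the canonical 16 and scales correctly", {
  expect_equal(sample_size_two_groups(
    stat_params(alpha = 0.05, power = 0.8, sd = 0.5, fold = 1.5)), 16L)
  # halving sd quarters n (same delta): ceil(15.698/4) = 4
  expect_equal(sample_size_two_groups(stat_params(sd = 0.25, fold = 1.5)), 4L)
  # fold 2.0: ceil(2 * 7.849 * 0.25 / 1) = 4
  expect_equal(sample_size_two_groups(stat_params(sd = 0.5, fold = 2)), 4L)
  expect_error(stat_params(fold = 1), "fold")
  expect_error(stat_params(fold = 0.8), "fold")
  # monotonicity: non-increasing in fold, non-decreasing in sd and power
  n_by_fold <- vapply(c(1.2, 1.5, 2, 3), function(f)
    sample_size_two_groups(stat_params(fold = f)), integer(1))
  expect_true(all(diff(n_by_fold) <= 0))
  n_by_sd <- vapply(c(0.2, 0.5, 1), function(s)
    sample_size_two_groups(stat_params(sd = s)), integer(1))
  expect_true(all(diff(n_by_sd) >= 0))
  n_by_pw <- vapply(c(0.7, 0.8, 0.9, 0.95), function(p)
    sample_size_two_groups(stat_params(power = p)), integer(1))
  expect_true(all(diff(n_by_pw) >= 0))
})

test_that("dynamic-range calibration reproduces the percent-of-max arithmetic", {
  cal <- calibrate_dynamic_range(list("0" = c(0.1, 0.1), "1" = c(1.1, 1.1)))
  expect_equal(percent_of_max(cal, 0.97), 87)   # (0.97-0.1)/(1.1-0.1)
  expect_equal(percent_of_max(cal, cal$floor_GR), 0)
  expect_equal(percent_of_max(cal, cal$ceiling_GR), 100)
  # perfectly linear series: R^2 = 1, slope = ceiling - floor
  lin <- calibrate_dynamic_range(list("0" = 0.1, "0.5" = 0.6, "1" = 1.1))
  expect_equal(lin$fit$r_squared, 1)
  expect_equal(lin$fit$slope, lin$ceiling_GR - lin$floor_GR)
  expect_equal(lin$conditions$percent_of_max, c(0, 50, 100))
  expect_error(calibrate_dynamic_range(list("0.3" = 1, "1" = 2)),
               "0 and a 1")
  expect_error(calibrate_dynamic_range(list("0" = c(2, 2), "1" = c(1, 1))),
               "degenerate")
})

test_that("cell classification fractions are exact, order-invariant and sum to 1", {
  expect_equal(as.character(classify_cells(
    data.frame(ratio1 = 0.5, ratio2 = 0.6), 0.2)$class), "di+/+")
  expect_equal(as.character(classify_cells(
    data.frame(ratio1 = 0.5, ratio2 = 0.05), 0.2)$class), "mono+/-")
  expect_equal(as.character(classify_cells(
    data.frame(ratio1 = 0.05, ratio2 = 0.01), 0.2)$class), "di-/-")
  # constructed 10-cell set: 4 di+/+, 3 mono, 3 di-/- by hand count
  cells <- data.frame(
    ratio1 = c(0.5, 0.9, 0.3, 0.4, 0.5, 0.05, 0.6, 0.01, 0.1, 0.15),
    ratio2 = c(0.6, 0.5, 0.25, 0.9, 0.1, 0.70, 0.1, 0.05, 0.1, 0.02))
  cl <- classify_cells(cells, 0.2)
  expect_equal(unname(cl$fractions), c(0.4, 0.3, 0.3))
  expect_equal(sum(cl$fractions), 1)
  perm <- cells[sample(nrow(cells)), ]
  expect_equal(classify_cells(perm, 0.2)$fractions, cl$fractions)
  expect_error(classify_cells(cells[0, ], 0.2), "no cells")
  # default threshold rule: mean + 3 SD of the floor controls
  ctrl <- c(0.01, 0.03, 0.02, 0.04)
  expect_equal(positivity_threshold_from_controls(ctrl),
               mean(ctrl) + 3 * sd(ctrl))
})

test_that("allelic fold ratios divide RNA- by RNA+ per cell", {
  cells <- data.frame(nucleus_id = 1:3,
                      ratio1 = c(0.8, 0.8, 0.9),
                      ratio2 = c(0.4, 0.8, 0.3),
                      rna_positive1 = c(FALSE, FALSE, TRUE),
                      rna_positive2 = c(TRUE, TRUE, FALSE))
  a <- allelic_fold_ratio(cells)
  expect_equal(a$per_cell$allelic_ratio, c(2, 1, 1 / 3))
  expect_equal(a$median_ratio, 1)
  # identical alleles give ratio exactly 1
  same <- data.frame(nucleus_id = 1L, ratio1 = 0.5, ratio2 = 0.5,
                     rna_positive1 = TRUE, rna_positive2 = FALSE)
  expect_equal(allelic_fold_ratio(same)$per_cell$allelic_ratio, 1)
  # cells with zero/invalid RNA+ ratio or ambiguous tags are skipped
  bad <- rbind(cells,
               data.frame(nucleus_id = 4L, ratio1 = 0.5, ratio2 = 0,
                          rna_positive1 = FALSE, rna_positive2 = TRUE),
               data.frame(nucleus_id = 5L, ratio1 = 0.5, ratio2 = 0.4,
                          rna_positive1 = TRUE, rna_positive2 = TRUE))
  a2 <- allelic_fold_ratio(bad)
  expect_equal(nrow(a2$per_cell), 3L)
  expect_equal(a2$n_skipped, 2L)
  expect_error(allelic_fold_ratio(bad[4:5, ]), "no cells")
})
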