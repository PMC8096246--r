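lin_idx <- function(y, x, ny) (x - 1L) * ny + y

test_that("the rim is a concentric band inside the nucleus, excluding other loci", {
  ny <- 64L
  locus <- lin_idx(32L, 32L, ny)
  nucleus <- as.integer(1:(64 * 64))
  rim <- make_rim(locus, width = 5, nucleus_mask = nucleus,
                  other_loci_masks = list(), dim = c(64L, 64L))
  ry <- (rim - 1L) %% ny + 1L; rx <- (rim - 1L) %/% ny + 1L
  d <- sqrt((ry - 32)^2 + (rx - 32)^2)
  expect_false(locus %in% rim)            # disjoint from locus
  expect_true(all(d >= 1 & d <= 6))       # concentric band of width ~5
  expect_gt(length(rim), 50)

  # clipped to the nucleus but still usable at the edge
  nuc_half <- nucleus[(nucleus - 1L) %/% ny + 1L <= 33L]
  rim_e <- make_rim(locus, 5, nuc_half, list(), c(64L, 64L))
  expect_true(all(rim_e %in% nuc_half))
  expect_true(length(rim_e) > 0 && length(rim_e) < length(rim))

  # neighbouring locus pixels (dilated by 1) are excluded: set-algebra oracle
  other <- lin_idx(32L, 38L, ny)
  rim_x <- make_rim(locus, 5, nucleus, list(other), c(64L, 64L))
  oy <- 32; ox <- 38
  banned <- as.integer(outer((oy - 1):(oy + 1),
                             ((ox - 1):(ox + 1) - 1) * ny, `+`))
  expect_length(intersect(rim_x, banned), 0L)
  expect_true(all(rim_x %in% rim))
})

test_that("the G/R formula follows direct substitution and its edge cases", {
  m <- data.frame(I_Locus_Ch1 = 300, I_Rim_Ch1 = 100,
                  I_Locus_Ch2 = 200, I_Rim_Ch2 = 100)
  expect_equal(compute_ratio(m)$ratio_GR, 0.5)
  # sensor at rim level: floored to 0, still valid
  m2 <- transform(m, I_Locus_Ch2 = 90)
  expect_equal(compute_ratio(m2)$ratio_GR, 0)
  # identical channels: ratio 1
  m3 <- data.frame(I_Locus_Ch1 = 250, I_Rim_Ch1 = 50,
                   I_Locus_Ch2 = 250, I_Rim_Ch2 = 50)
  expect_equal(compute_ratio(m3)$ratio_GR, 1)
  # vanishing detector signal: invalid, not an exception
  m4 <- data.frame(I_Locus_Ch1 = 100, I_Rim_Ch1 = 100,
                   I_Locus_Ch2 = 200, I_Rim_Ch2 = 100)
  r4 <- compute_ratio(m4)
  expect_false(r4$valid)
  expect_true(is.na(r4$ratio_GR))
})

toy_locus_stack <- function(det_locus = 300, det_rim = 100,
                            sen_locus = 200, sen_rim = 100) {
  ny <- 48L
  det <- matrix(det_rim, ny, ny); sen <- matrix(sen_rim, ny, ny)
  mask <- as.integer(outer(23:25, (23:25 - 1L) * ny, `+`))
  det[mask] <- det_locus; sen[mask] <- sen_locus
  list(stack = image_stack(list(detector = det, sensor = sen)),
       locus = list(locus_id = 1L, nucleus_id = 1L, unified_mask = mask,
                    status = "paired"),
       rim = make_rim(mask, 5, as.integer(1:(ny * ny)), list(),
                      c(ny, ny)))
}

test_that("measure_locus reproduces hand-computed means and ratio", {
  t <- toy_locus_stack()
  m <- measure_locus(t$stack, t$locus, t$rim)
  expect_equal(m$I_Locus_Ch1, 300); expect_equal(m$I_Rim_Ch1, 100)
  expect_equal(m$I_Locus_Ch2, 200); expect_equal(m$I_Rim_Ch2, 100)
  expect_equal(m$ratio_GR, 0.5)
  expect_true(m$valid)
  # constant image: denominator 0, invalid
  tc <- toy_locus_stack(100, 100, 100, 100)
  mc <- measure_locus(tc$stack, tc$locus, tc$rim, epsilon = 1e-9)
  expect_false(mc$valid)
  # empty rim marks the locus invalid with a reason
  me <- measure_locus(t$stack, t$locus, integer(0))
  expect_false(me$valid)
  expect_equal(me$reason, "empty_rim")
})

test_that("ratio is invariant to channel offsets and linear in channel gains", {
  t <- toy_locus_stack()
  base <- measure_locus(t$stack, t$locus, t$rim)$ratio_GR
  for (cc in c(50, 500)) {
    st <- t$stack
    st$channels$sensor <- st$channels$sensor + cc
    expect_equal(measure_locus(st, t$locus, t$rim)$ratio_GR, base)
    st2 <- t$stack
    st2$channels$detector <- st2$channels$detector + cc
    expect_equal(measure_locus(st2, t$locus, t$rim)$ratio_GR, base)
  }
  for (k in c(0.5, 2, 3.7)) {
    st <- t$stack
    st$channels$sensor <- st$channels$sensor * k
    expect_equal(measure_locus(st, t$locus, t$rim)$ratio_GR, k * base)
    st2 <- t$stack
    st2$channels$detector <- st2$channels$detector * k
    expect_equal(measure_locus(st2, t$locus, t$rim)$ratio_GR, base / k)
  }
})

test_that("the pipeline recovers true ratios on simulated fields", {
  # noise off: median relative error <= 2%
  p <- small_params(noise = "none", seed = 17L)
  sp <- generate_specimen(p)
  q <- quantify_stack(sp$stack)
  m <- q$measurements[q$measurements$valid, ]
  expect_gte(nrow(m), 6)
  expect_lte(median(abs(m$ratio_GR - 0.8) / 0.8), 0.02)
  # shot + read noise at default SNR: median relative error <= 10%
  pn <- small_params(noise = "shot_read", n_nuclei = 6L, seed = 18L,
                     image_shape = c(320L, 320L))
  spn <- generate_specimen(pn)
  qn <- quantify_stack(spn$stack)
  mn <- qn$measurements[qn$measurements$valid, ]
  expect_gte(nrow(mn), 8)
  expect_lte(median(abs(mn$ratio_GR - 0.8) / 0.8), 0.10)
})

test_that("averaging more optical slices does not increase measurement spread", {
  p <- small_params(n_z_slices = 5L, n_nuclei = 6L, seed = 19L,
                    image_shape = c(320L, 320L), chromatic_shift = c(1, -1))
  sp <- generate_specimen(p)
  cfg1 <- default_config(); cfg1$quantification$z_mode <- "per_slice"
  cfg1$quantification$k_slices <- 1L
  cfg3 <- default_config(); cfg3$quantification$z_mode <- "per_slice"
  cfg3$quantification$k_slices <- 3L
  m1 <- quantify_stack(sp$stack, cfg1)$measurements
  m3 <- quantify_stack(sp$stack, cfg3)$measurements
  err <- function(m) abs(m$ratio_GR[m$valid] - 0.8)
  # allow a little sampling slack on the no-increase property (n is small)
  expect_lte(sd(err(m3)), sd(err(m1)) * 1.15)
})

test_that("allelic aggregation applies the two-focus exclusion rule", {
  meas <- data.frame(
    locus_id = 1:8,
    nucleus_id = c(1L, 1L, 2L, 2L, 2L, 3L, 4L, 4L),
    ratio_GR = c(0.8, 0.4, 0.7, 0.6, 0.5, 0.9, 0.8, NA),
    valid = c(rep(TRUE, 7), FALSE))
  pop <- aggregate_cells(meas, "population")
  expect_equal(nrow(pop$loci), 7L)        # all valid loci retained
  al <- aggregate_cells(meas, "allelic")
  # nucleus 2 (>2 foci: replication) and nuclei 3, 4 (<2 valid) excluded
  expect_equal(al$cells$nucleus_id, 1L)
  expect_equal(attr(al, "n_excluded_gt2"), 1L)
  expect_equal(attr(al, "n_excluded_lt2"), 2L)
  expect_equal(sort(c(al$cells$ratio1, al$cells$ratio2)), c(0.4, 0.8))
})
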