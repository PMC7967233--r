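test_that("base disk geometry follows the configuration", {
  cfg <- synth_config("solid-round", "isolated", 10, 197, seed = 1)
  cs <- make_base_disk(cfg)
  expect_identical(dim(cs$image$intensity), c(40L, 40L))
  # ground truth is a centered disk of 20 px diameter
  expect_equal(sum(cs$ground_truth), sum(disk_mask(40, 10, (40 + 1) / 2)))
  ctr <- which(cs$ground_truth, arr.ind = TRUE)
  expect_equal(unname(colMeans(ctr)), c(20.5, 20.5), tolerance = 1e-9)

  cfg5 <- synth_config(diameter_mm = 5)
  expect_identical(dim(make_base_disk(cfg5)$image$intensity), c(20L, 20L))
})

test_that("noise level decreases with tube current and is reproducible", {
  mk <- function(mA, seed = 3) make_base_disk(
    synth_config("solid-round", "isolated", 20, mA, seed = seed))
  bgvar <- function(cs) {
    bg <- !cs$ground_truth & row(cs$ground_truth) < 10
    sd(cs$image$intensity[bg] - cs$clean[bg])
  }
  s30 <- bgvar(mk(30)); s197 <- bgvar(mk(197))
  expect_gt(s30, s197)
  # empirical sigma of the additive field matches the configured scaling
  # (within 10%; intensity clipping at 0/1 slightly truncates the noisiest
  # settings)
  expect_equal(s197, 0.05, tolerance = 0.1)
  expect_gt(s30 / s197, 2.2)
  expect_lt(s30 / s197, sqrt(197 / 30) * 1.1)

  a <- mk(99); b <- mk(99)
  expect_identical(a$image$intensity, b$image$intensity)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("irregular warping preserves area and image/GT consistency", {
  cfg <- synth_config("solid-irregular", "isolated", 10, Inf, seed = 8)
  base <- make_base_disk(cfg)

  # zero-amplitude warp is the identity
  same <- warp_irregular(base, max_amplitude = 0)
  expect_equal(same$image$intensity, base$image$intensity)
  expect_identical(same$ground_truth, base$ground_truth)

  for (s in 1:5) {
    cfgs <- synth_config("solid-irregular", "isolated", 10, Inf, seed = 50 + s)
    w <- warp_irregular(make_base_disk(cfgs))
    ratio <- sum(w$ground_truth) / sum(make_base_disk(cfgs)$ground_truth)
    expect_gt(ratio, 0.8); expect_lt(ratio, 1.2)
    # thresholding the clean warped image recovers the warped ground truth
    thr <- w$clean > (0.65 + 0.15) / 2
    expect_gt(dice(thr, w$ground_truth), 0.95)
  }
})

test_that("category alterations carry their defining features", {
  # sub-solid: contrast ~ 0.15 on the noiseless image
  ss <- make_phantom_case(synth_config("sub-solid", "isolated", 20, Inf, seed = 4))
  core <- ss$ground_truth & fmmseg:::shift_mat(ss$ground_truth, 3, 0, FALSE) &
    fmmseg:::shift_mat(ss$ground_truth, -3, 0, FALSE) &
    fmmseg:::shift_mat(ss$ground_truth, 0, 3, FALSE) &
    fmmseg:::shift_mat(ss$ground_truth, 0, -3, FALSE)
  bg <- !ss$ground_truth & row(ss$ground_truth) < 15
  contrast <- mean(ss$clean[core]) - mean(ss$clean[bg])
  expect_equal(contrast, 0.15, tolerance = 0.03 / 0.15)

  # cavitary: ground truth is the ring only; cavity sits at background level
  cv <- make_phantom_case(synth_config("cavitary", "isolated", 20, Inf, seed = 4))
  expect_false(any(cv$ground_truth[cv$cavity]))
  expect_lt(mean(cv$clean[cv$cavity & !fmmseg:::mask_border(cv$cavity)]), 0.3)
  expect_error(make_phantom_case(synth_config("cavitary", ring_thickness_mm = 0)),
               "invalid cavitary")
  expect_error(make_phantom_case(synth_config("cavitary", diameter_mm = 10,
                                              ring_thickness_mm = 6)),
               "invalid cavitary")

  # juxtavascular: vessel pixels are excluded from the ground truth
  jv <- make_phantom_case(synth_config("solid-round", "juxtavascular", 10, Inf, seed = 4))
  vessel_cols <- which(apply(jv$clean > 0.5, 2, all))
  expect_gt(length(vessel_cols), 0)
  expect_false(any(jv$ground_truth[, vessel_cols]))

  # juxtapleural: wall excluded from lung mask, GT inside the lung
  jp <- make_phantom_case(synth_config("solid-round", "juxtapleural", 10, Inf, seed = 4))
  expect_true(any(!jp$image$lung_mask))
  expect_true(all(jp$image$lung_mask[jp$ground_truth]))
})

test_that("every ground truth lies inside the lung mask", {
  for (cat_ in c("solid-round", "sub-solid", "cavitary"))
    for (sub in c("isolated", "juxtapleural", "juxtavascular")) {
      cs <- make_phantom_case(synth_config(cat_, sub, 10, 99, seed = 17))
      expect_true(all(cs$image$lung_mask[cs$ground_truth]),
                  info = paste(cat_, sub))
    }
})

test_that("dataset sweeps are deterministic with balanced cells", {
  ds <- make_dataset(n_per_cell = 1, seed = 2)
  expect_equal(nrow(ds$manifest), 12L)       # 4 categories x 3 subcategories
  expect_equal(length(ds$cases), 12L)
  ds2 <- make_dataset(n_per_cell = 1, seed = 2)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$cases[[5]]$image$intensity, ds2$cases[[5]]$image$intensity)

  counts <- phantom_reference_counts()
  expect_equal(sum(counts$n), 108L)
  expect_equal(tapply(counts$n, counts$category, sum)[["solid-round"]], 36L)
  expect_equal(tapply(counts$n, counts$category, sum)[["cavitary"]], 18L)

  # a scaled-down reference layout drives per-cell counts
  small <- counts; small$n <- pmax(1L, small$n %/% 6L)
  ds3 <- make_dataset(small, seed = 3)
  expect_equal(nrow(ds3$manifest), sum(small$n))
  expect_equal(sum(ds3$manifest$category == "solid-round"), 6L)
})
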