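test_that("tube rasterisation matches the per-voxel distance oracle", {
  set.seed(5)
  for (i in 1:10) {
    a <- runif(3, 3, 13); b <- runif(3, 3, 13); r <- runif(1, 0.5, 2)
    m <- rasterize_tubes(list(rbind(a, b)), r, c(16L, 16L, 16L))
    # oracle: direct point-to-segment distance at every voxel
    u <- b - a; len2 <- sum(u^2)
    expect_oracle <- array(0L, c(16, 16, 16))
    for (z in 1:16) for (y in 1:16) for (x in 1:16) {
      p <- c(z, y, x) - a
      tt <- if (len2 > 0) min(max(sum(p * u) / len2, 0), 1) else 0
      dv <- p - tt * u
      if (sum(dv^2) <= r^2) expect_oracle[z, y, x] <- 1L
    }
    expect_equal(unclass(m)[], expect_oracle[], ignore_attr = TRUE)
  }
})

test_that("straight tubes have translation-invariant cross-sections and thin tubes stay connected", {
  line <- rbind(c(3, 8, 8), c(14, 8, 8))   # axial straight line
  m <- unclass(rasterize_tubes(list(line), 1, c(16L, 16L, 16L)))
  counts <- apply(m[4:13, , ], 1, sum)
  expect_true(all(counts == counts[1]))
  thin <- unclass(rasterize_tubes(list(rbind(c(2, 2, 2), c(14, 13, 11))), 0.5,
                                  c(16L, 16L, 16L)))
  expect_true(all(apply(thin, 1, sum)[2:14] >= 1))
  expect_equal(count_components(thin), 1L)
  two <- rasterize_tubes(list(rbind(c(3, 4, 4), c(13, 4, 4)),
                              rbind(c(3, 12, 12), c(13, 12, 12))),
                         c(1, 1), c(16L, 16L, 16L))
  expect_equal(count_components(unclass(two)), 2L)
  empty <- rasterize_tubes(list(), numeric(0), c(8L, 8L, 8L))
  expect_equal(sum(empty), 0)
})

test_that("phantoms are reproducible and honour the geometry contracts", {
  cfg <- phantom_config(shape = c(48L, 48L, 48L), target_fg_fraction = 9e-4,
                        seed = 21L)
  p1 <- generate_phantom(cfg)
  p2 <- generate_phantom(cfg)
  expect_identical(unclass(p1$intensity)[], unclass(p2$intensity)[])
  expect_identical(unclass(p1$vessel_gt)[], unclass(p2$vessel_gt)[])
  # vessels strictly inside the brain
  expect_equal(sum(unclass(p1$vessel_gt) & !unclass(p1$brain_mask)), 0)
  # achieved fraction within +/-30% of the 0.09% target
  frac <- sum(p1$vessel_gt) / sum(p1$brain_mask)
  expect_gte(frac, 0.00063); expect_lte(frac, 0.00117)
  # empty boundary slices: no mask voxels, no intensity
  mz <- ceiling(cfg$empty_margin_fraction * 48)
  expect_equal(sum(unclass(p1$brain_mask)[c(1:mz, 48 - 1:mz + 1), , ]), 0)
  expect_equal(sum(unclass(p1$intensity)[c(1:mz, 48 - 1:mz + 1), , ]), 0)
})

test_that("phantom intensities are dark-vessel uint16 with a bright tissue mode", {
  ph <- tiny_phantom()
  img <- unclass(ph$intensity)
  expect_true(all(img >= 0 & img <= 65535 & img %% 1 == 0))
  vg <- unclass(ph$vessel_gt) == 1L
  brain <- unclass(ph$brain_mask) == 1L
  expect_lt(mean(img[vg]), mean(img[brain & !vg]))
  # histogram of brain voxels: bright unimodal tissue with a dark vessel tail
  bv <- img[brain]
  expect_lt(quantile(bv, 0.001), 0.5 * median(bv))
})

test_that("a bright runaway stack is neutralised by min-max normalisation", {
  dim3 <- c(32L, 32L, 32L)
  pa <- generate_phantom(phantom_config(shape = dim3, tissue_mean = 11000,
                                        seed = 31L))
  pb <- generate_phantom(phantom_config(shape = dim3, tissue_mean = 37000,
                                        noise_sigma = 1200, seed = 31L))
  expect_gt(mean(unclass(pb$intensity)), 2.5 * mean(unclass(pa$intensity)))
  na <- minmax_normalize(pa$intensity)
  nb <- minmax_normalize(pb$intensity)
  for (n in list(na, nb)) {
    expect_gte(min(n), 0); expect_lte(max(n), 1)
  }
  # after normalisation the two stacks live on the same scale again
  expect_lt(abs(median(unclass(nb)[unclass(pb$brain_mask) == 1]) -
                median(unclass(na)[unclass(pa$brain_mask) == 1])), 0.25)
})
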