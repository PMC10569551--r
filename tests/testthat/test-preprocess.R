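test_that("extract_roi crops the mask bounding box and zeroes outside it", {
  v <- array(7, c(10, 10, 10))
  m <- array(0L, c(10, 10, 10))
  m[3:5, 3:5, 3:5] <- 1L            # nonzero on half-open [2,5) in 0-based terms
  m[4, 4, 4] <- 0L                  # hole inside the box
  r <- extract_roi(as_volume(v, "uint16"), as_mask(m))
  expect_identical(dim(r$volume), c(3L, 3L, 3L))
  expect_equal(r$geometry$bbox_low, c(2L, 2L, 2L))
  expect_equal(r$geometry$bbox_high, c(5L, 5L, 5L))
  expect_equal(unclass(r$volume)[2, 2, 2], 0)   # out-of-mask voxel zeroed
  expect_equal(sum(unclass(r$volume) == 7), 26)

  all1 <- as_mask(array(1L, c(10, 10, 10)))
  r2 <- extract_roi(as_volume(v, "uint16"), all1)
  expect_identical(dim(r2$volume), c(10L, 10L, 10L))
  expect_equal(r2$geometry$bbox_low, c(0L, 0L, 0L))

  expect_error(extract_roi(as_volume(v, "uint16"),
                           as_mask(array(0L, c(10, 10, 10)))), "empty")
})

test_that("pad_to_block pads to the smallest block multiple and is idempotent", {
  g0 <- structure(list(original_shape = c(400L, 33L, 320L),
                       bbox_low = c(0L, 0L, 0L), bbox_high = c(400L, 33L, 320L),
                       pad = c(0L, 0L, 0L), block = NA_integer_),
                  class = "vs_geometry")
  v <- as_volume(array(1, c(400, 33, 320)), "float")
  p <- pad_to_block(v, g0, 32L)
  expect_identical(dim(p$volume), c(416L, 64L, 320L))
  expect_equal(p$geometry$pad, c(16L, 31L, 0L))
  p2 <- pad_to_block(p$volume, p$geometry, 32L)
  expect_identical(dim(p2$volume), dim(p$volume))
  expect_equal(p2$geometry$pad, p$geometry$pad)
  # padding is zero-valued at the high end
  expect_equal(sum(unclass(p$volume)), 400 * 33 * 320)
  expect_true(all(unclass(p$volume)[401:416, , ] == 0))
})

test_that("gaussian smoothing preserves constants and the unit impulse mass", {
  cv <- as_volume(array(3.5, c(8, 8, 8)), "float")
  expect_equal(unclass(gaussian_smooth(cv, 1.2))[], unclass(cv)[],
               tolerance = 1e-12, ignore_attr = TRUE)
  v <- as_volume(array(runif(8^3), c(8, 8, 8)), "float")
  expect_identical(gaussian_smooth(v, 0), v)
  expect_error(gaussian_smooth(v, -1), "non-negative")
  imp <- array(0, c(15, 15, 15)); imp[8, 8, 8] <- 1
  sm <- unclass(gaussian_smooth(as_volume(imp, "float"), 0.5))
  expect_lt(abs(sum(sm) - 1), 1e-3)
  # oracle: the discrete separable kernel is normalised, so the response at
  # the impulse equals the central kernel weight cubed
  off <- -2:2
  k <- exp(-off^2 / (2 * 0.5^2)); k <- k / sum(k)
  expect_equal(sm[8, 8, 8], k[3]^3, tolerance = 1e-12)
})

test_that("min-max normalisation maps to [0,1] and ignores affine rescaling", {
  v <- array(c(0, 5, 10), c(3, 1, 1))
  n <- unclass(minmax_normalize(as_volume(v, "float")))
  expect_equal(as.vector(n), c(0, 0.5, 1))
  expect_equal(unique(as.vector(unclass(minmax_normalize(
    as_volume(array(4, c(2, 2, 2)), "float"))))), 0)
  set.seed(3)
  r <- array(runif(4^3, 38, 24063), c(4, 4, 4))
  n1 <- minmax_normalize(as_volume(r, "float"))
  n2 <- minmax_normalize(as_volume(2.5 * r + 100, "float"))
  expect_equal(unclass(n1)[], unclass(n2)[], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_gte(min(n1), 0); expect_lte(max(n1), 1)
})

test_that("patchify tiles lexicographically and rejects non-divisible axes", {
  g <- structure(list(original_shape = c(64L, 64L, 32L),
                      bbox_low = c(0L, 0L, 0L), bbox_high = c(64L, 64L, 32L),
                      pad = c(0L, 0L, 0L), block = 32L),
                 class = "vs_geometry")
  v <- array(0, c(64, 64, 32))
  # constant value per 32-block so the expected ordering is readable
  v[1:32, 1:32, ] <- 1; v[1:32, 33:64, ] <- 2
  v[33:64, 1:32, ] <- 3; v[33:64, 33:64, ] <- 4
  ps <- patchify(as_volume(v, "float"), g, 32L)
  expect_equal(ps$grid_shape, c(2, 2, 1))
  expect_length(ps$patches, 4L)
  expect_equal(vapply(ps$patches, function(p) p[1, 1, 1], numeric(1)),
               c(1, 2, 3, 4))   # (z,y,x) lexicographic, x fastest
  one <- patchify(as_volume(v[1:32, 1:32, 1:32], "float"), g, 32L)
  expect_length(one$patches, 1L)
  expect_equal(one$patches[[1]], v[1:32, 1:32, 1:32], ignore_attr = TRUE)
  expect_error(patchify(as_volume(array(0, c(33, 33, 33)), "float"), g, 32L),
               "multiple")
  # 416 x 416 x 320 at block 32 gives the full-stack patch count
  expect_equal(prod(c(416, 416, 320) %/% 32), 1690)
})

test_that("reassemble is the exact inverse of the pre-processing geometry", {
  set.seed(4)
  for (i in 1:25) {
    orig <- sample(40:72, 3, TRUE)
    lo <- sapply(orig, function(n) sample(0:(n - 20), 1))
    len <- sapply(seq_len(3), function(a) sample(8:(orig[a] - lo[a]), 1))
    v <- array(0, orig)
    m <- array(0L, orig)
    idx <- lapply(1:3, function(a) (lo[a] + 1):(lo[a] + len[a]))
    v[idx[[1]], idx[[2]], idx[[3]]] <- runif(prod(len))
    m[idx[[1]], idx[[2]], idx[[3]]] <- 1L
    r <- extract_roi(as_volume(v, "float"), as_mask(m))
    p <- pad_to_block(r$volume, r$geometry, 8L)
    ps <- patchify(p$volume, p$geometry, 8L)
    back <- reassemble(ps)
    expect_identical(bare_arr(unclass(back)), v)
  }
  # missing patch is rejected
  g <- structure(list(original_shape = c(16L, 16L, 16L),
                      bbox_low = c(0L, 0L, 0L), bbox_high = c(16L, 16L, 16L),
                      pad = c(0L, 0L, 0L), block = 8L), class = "vs_geometry")
  ps <- patchify(as_volume(array(1, c(16, 16, 16)), "float"), g, 8L)
  ps$patches <- ps$patches[-1]
  expect_error(reassemble(ps), "patch count")
})

test_that("geometry survives its JSON sidecar round trip", {
  ph <- tiny_phantom()
  r <- extract_roi(ph$intensity, ph$brain_mask)
  p <- pad_to_block(r$volume, r$geometry, 16L)
  f <- tempfile(fileext = ".json")
  write_geometry(p$geometry, f)
  g2 <- read_geometry(f)
  expect_equal(unclass(g2), unclass(p$geometry))
})

test_that("the pre-processing chain runs in the fixed order and yields [0,1] patches", {
  ph <- tiny_phantom()
  ps <- preprocess_stack(ph$intensity, ph$brain_mask,
                         preprocess_config(block = 16L))
  expect_s3_class(ps, "vs_patchset")
  rng <- range(unlist(lapply(ps$patches, range)))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
  expect_equal(length(ps$patches), prod(ps$grid_shape))
})
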