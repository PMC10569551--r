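test_that("focal loss matches cross-entropy at gamma 0 and its closed form", {
  set.seed(6)
  p <- array(runif(1000, 0.01, 0.99), c(10, 10, 10))
  y <- array(rbinom(1000, 1, 0.3), c(10, 10, 10))
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))   # independent formula
  expect_lt(abs(focal_loss(p, y, gamma = 0) - bce), 1e-9)
  # spot values: -ln 0.5 at (y=1, p=0.5, g=0); (0.1)^2 * (-ln 0.9) at g=2
  expect_equal(focal_loss(0.5, 1, gamma = 0), 0.693147, tolerance = 1e-6)
  expect_lt(abs(focal_loss(0.9, 1, gamma = 2) - 0.1^2 * (-log(0.9))), 1e-8)
  # perfect hard predictions: eps-dominated bound near zero
  expect_lt(focal_loss(c(0, 1, 1), c(0, 1, 1), gamma = 2), 1e-10)
  expect_error(focal_loss(p, y, gamma = -1), "gamma")
})

test_that("focal loss is non-negative and decreases as p moves toward y", {
  for (gamma in c(0, 1, 2)) {
    grid <- seq(0.05, 0.95, by = 0.05)
    l1 <- vapply(grid, function(p) focal_loss(p, 1, gamma), numeric(1))
    l0 <- vapply(grid, function(p) focal_loss(p, 0, gamma), numeric(1))
    expect_true(all(l1 >= 0) && all(l0 >= 0))
    expect_true(all(diff(l1) < 0))   # toward y = 1: decreasing in p
    expect_true(all(diff(l0) > 0))   # toward y = 0: increasing in p
  }
  # analytic gradient agrees with finite differences
  set.seed(7)
  p <- runif(20, 0.05, 0.95); y <- rbinom(20, 1, 0.5)
  g <- focal_loss(p, y, 2, grad = TRUE)$grad
  eps <- 1e-6
  for (i in c(1, 7, 13)) {
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    num <- (focal_loss(pp, y, 2) - focal_loss(pm, y, 2)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("augmentation flips image and label together and keeps labels binary", {
  set.seed(8)
  img <- array(runif(6^3), c(6, 6, 6))
  lab <- array(rbinom(6^3, 1, 0.2), c(6, 6, 6))
  # flips are involutions
  expect_identical(murivess:::flip_axis(murivess:::flip_axis(img, 2L), 2L), img)
  expect_identical(murivess:::flip_axis(murivess:::flip_axis(img, 3L), 3L), img)
  # forced flips: with apply_prob 1 both axes flip, identically for both
  cfg <- augment_config(brightness_sigma = 0, noise_sigma = 0, apply_prob = 1)
  a <- augment(img, lab, cfg)
  expect_identical(a$image,
                   murivess:::flip_axis(murivess:::flip_axis(img, 3L), 2L))
  expect_identical(a$label,
                   murivess:::flip_axis(murivess:::flip_axis(lab, 3L), 2L))
  # seeded reproducibility and binary labels under noise transforms
  cfg2 <- augment_config()
  set.seed(99); a1 <- augment(img, lab, cfg2)
  set.seed(99); a2 <- augment(img, lab, cfg2)
  expect_identical(a1, a2)
  expect_setequal(unique(as.vector(a1$label)), unique(as.vector(lab)))
  expect_gte(min(a1$image), 0); expect_lte(max(a1$image), 1)
  expect_error(augment(img, lab[1:5, , ], cfg2), "shape")
})

test_that("the patch split is disjoint, exhaustive and seeded", {
  patches <- lapply(1:10, function(i) list(id = i))
  sp <- split_patches(patches, 0.8, seed = 1)
  expect_length(sp$train, 8L)
  expect_length(sp$val, 2L)
  ids <- c(vapply(sp$train, `[[`, numeric(1), "id"),
           vapply(sp$val, `[[`, numeric(1), "id"))
  expect_setequal(ids, 1:10)
  sp2 <- split_patches(patches, 0.8, seed = 1)
  expect_identical(sp, sp2)
  sp3 <- split_patches(patches, 0.8, seed = 2)
  expect_false(identical(sp$train, sp3$train))
  expect_error(split_patches(patches[1:4], 0.8, 1), "at least 5")
})

test_that("early stopping matches hand-simulated decision sequences", {
  # 1.0 then 0.9 improves; three flat epochs exhaust patience 3 at epoch 5
  r <- early_stop_epoch(c(1.0, 0.9, 0.9, 0.9, 0.9, 0.9), patience = 3,
                        min_delta = 1e-4)
  expect_equal(r$stop_epoch, 5L)
  expect_equal(r$best_epoch, 2L)
  # monotone improvement with ample patience runs to the end
  r2 <- early_stop_epoch(seq(1, 0.1, by = -0.1), patience = 30)
  expect_equal(r2$stop_epoch, 10L)
  expect_equal(r2$best_epoch, 10L)
  # improvement below min_delta does not reset patience
  r3 <- early_stop_epoch(c(1, 0.99995, 0.9999, 0.99985), patience = 2,
                         min_delta = 1e-4)
  expect_equal(r3$stop_epoch, 3L)
  expect_equal(r3$best_epoch, 1L)
  # a late real improvement resets the counter (patience 30 default scale)
  losses <- c(seq(0.5, 0.3, length.out = 5), rep(0.3, 29), 0.2, rep(0.2, 30))
  r4 <- early_stop_epoch(losses, patience = 30, min_delta = 1e-4)
  expect_equal(r4$best_epoch, 35L)
  expect_equal(r4$stop_epoch, 65L)
})

test_that("a short training run descends and restores the best weights", {
  phs <- lapply(41:44, function(s)
    generate_phantom(phantom_config(shape = c(32L, 32L, 32L),
                                    target_fg_fraction = 0.003,
                                    radius_range = c(1, 2), seed = s)))
  pool <- unlist(lapply(seq_along(phs), function(j)
    labelled_patches(phs[[j]], config = preprocess_config(), tag = j)),
    recursive = FALSE)
  m <- build_unet(unet_config(filters = c(2L, 4L, 4L, 4L, 4L, 2L)), seed = 9)
  cfg <- train_config(max_epochs = 3L, patience = 3L, batch_size = 2L,
                      learning_rate = 3e-3, augment_copies = 1L, seed = 9L)
  tr <- train_model(m, pool[1:3], pool[4], cfg)
  expect_s3_class(tr$history, "tbl_df")
  expect_lte(nrow(tr$history), 3L)
  expect_lt(tr$history$train_loss[nrow(tr$history)], tr$history$train_loss[1])
  # training is reproducible given the seed
  tr2 <- train_model(m, pool[1:3], pool[4], cfg)
  expect_identical(tr$history, tr2$history)
  expect_identical(tr$params$final$w, tr2$params$final$w)
})

test_that("leave-one-out folds never leak the held-out stack and reproduce", {
  phs <- lapply(51:53, function(s)
    generate_phantom(phantom_config(shape = c(48L, 48L, 48L),
                                    target_fg_fraction = 0.004,
                                    radius_range = c(1, 2), seed = s)))
  tc <- train_config(max_epochs = 2L, patience = 2L, batch_size = 4L,
                     learning_rate = 3e-3, augment_copies = 0L, seed = 5L)
  grid <- list(postprocess_config(t = 0.45),
               postprocess_config("region_growing", t = 0.3, s = 0.45))
  cfg <- unet_config(filters = c(2L, 4L, 4L, 4L, 4L, 2L))
  r <- run_loocv(phs, tc, preprocess_config(), grid, cfg)
  expect_equal(sort(unique(r$per_fold$fold)), 1:3)
  expect_equal(nrow(r$per_fold), 3L * 2L)     # folds x grid settings
  expect_equal(nrow(r$average), 2L)
  expect_true(all(c("accuracy", "recall", "precision", "dsc") %in%
                  names(r$per_fold)))
  # averages are the unweighted means of the per-fold rows
  sel <- r$per_fold$mode == "threshold"
  expect_equal(r$average$dsc[r$average$mode == "threshold"],
               mean(r$per_fold$dsc[sel]))
  r2 <- run_loocv(phs, tc, preprocess_config(), grid, cfg)
  expect_identical(r$per_fold, r2$per_fold)
  expect_error(run_loocv(phs[1], tc), "at least 2")
})
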