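test_that("sampled poses respect activity contact geometry", {
  body <- body_model()
  st <- sample_pose(body, "standing", 0)
  expect_equal(unname(st[c("l_foot", "r_foot"), "z"]), c(0, 0))
  expect_gt(st["head", "z"], 1000)
  pl <- sample_pose(body, "plank", 0)
  expect_gte(sum(pl[, "z"] == 0), 4) # hands + feet
  expect_identical(sample_pose(body, "squat", 3), sample_pose(body, "squat", 3))
  expect_false(identical(sample_pose(body, "squat", 3),
                         sample_pose(body, "squat", 4)))
  expect_error(sample_pose(body, "cartwheel", 1), "standing")
})

test_that("renderer produces two above-half-max components for standing", {
  cfg <- mask_scene_cfg()
  clean <- render_pressure(sample_pose(body_model(), "standing", 1), cfg)
  expect_true(all(clean >= 0))
  half <- (clean >= max(clean) / 2) * 1
  expect_equal(brute_n_components(half), 2)
})

test_that("renderer is linear in body weight below the ceiling and zero without contacts", {
  cfg <- tiny_scene_cfg()
  pose <- sample_pose(body_model(), "standing", 2)
  f1 <- render_pressure(pose, cfg, weight_kg = 1)
  f2 <- render_pressure(pose, cfg, weight_kg = 2)
  expect_lt(max(f2), cfg$max_pressure) # below clip
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
  airborne <- pose
  airborne[, 3] <- airborne[, 3] + 100
  expect_equal(render_pressure(airborne, cfg), matrix(0, 32, 20))
})

test_that("renderer is translation-equivariant on integer-tactel shifts", {
  cfg <- tiny_scene_cfg()
  pose <- sample_pose(body_model(), "standing", 7)
  pitch_x <- cfg$mat_length_mm / cfg$frame_h
  pitch_y <- cfg$mat_width_mm / cfg$frame_w
  shifted <- pose
  shifted[, 1] <- shifted[, 1] + 3 * pitch_x
  shifted[, 2] <- shifted[, 2] + 2 * pitch_y
  f0 <- render_pressure(pose, cfg, weight_kg = 10)
  f1 <- render_pressure(shifted, cfg, weight_kg = 10)
  expect_equal(f1[4:32, 3:20], f0[1:29, 1:18], tolerance = 1e-10)
})

test_that("corrupt is the identity when all noise sources are off", {
  cfg <- tiny_scene_cfg()
  cfg$noise_sigma <- 0; cfg$spurious_blob_rate <- 0
  clean <- render_pressure(sample_pose(body_model(), "squat", 1), cfg)
  expect_identical(corrupt(clean, cfg, 5), clean)
})

test_that("additive noise is zero-mean at the Monte-Carlo level", {
  cfg <- scene_config(grid_h = 16, grid_w = 8, frame_h = 100, frame_w = 100,
                      noise_sigma = 0.5, spurious_blob_rate = 0)
  clean <- matrix(5, 100, 100) # mid-range: clipping not triggered pre-clip check
  out <- corrupt(clean, cfg, rng_seed = 8, clip = FALSE)
  expect_lt(abs(mean(out - clean)), 3 * 0.5 / sqrt(length(clean)))
})

test_that("spurious blob count follows the configured Poisson rate", {
  cfg <- scene_config(grid_h = 16, grid_w = 8, frame_h = 64, frame_w = 40,
                      noise_sigma = 0, spurious_blob_rate = 3,
                      spurious_blob_size = 3)
  clean <- matrix(0, 64, 40)
  counts <- vapply(1:100, function(i) {
    out <- corrupt(clean, cfg, rng_seed = 100 + i)
    brute_n_components((out > 1) * 1)
  }, numeric(1))
  m <- mean(counts)
  expect_gte(m, 2); expect_lte(m, 4) # Poisson(3) CI; merging only lowers it
  expect_identical(corrupt(clean, cfg, 55), corrupt(clean, cfg, 55))
})

test_that("corruption preserves shape and respects sensor bounds", {
  cfg <- tiny_scene_cfg()
  clean <- render_pressure(sample_pose(body_model(), "plank", 3), cfg)
  out <- corrupt(clean, cfg, 9)
  expect_identical(dim(out), dim(clean))
  expect_true(all(out >= 0 & out <= cfg$max_pressure))
})

test_that("dataset splits are activity-disjoint and deterministic", {
  cfg <- tiny_scene_cfg()
  ds <- make_dataset(120, cfg, body_model(), val_activities = c("sit", "squat"))
  sp <- ds$split
  expect_equal(intersect(sp$activity[sp$split == "val"],
                         sp$activity[sp$split %in% c("train", "test")]),
               character(0))
  expect_setequal(unique(sp$activity[sp$split == "val"]), c("sit", "squat"))
  n_rest <- sum(sp$split != "val")
  expect_equal(sum(sp$split == "train"), round(0.8 * n_rest))
  ds2 <- make_dataset(120, cfg, body_model(), val_activities = c("sit", "squat"))
  expect_identical(ds$split, ds2$split)
  expect_identical(ds$scenes[[5]]$noisy, ds2$scenes[[5]]$noisy)
  expect_error(make_dataset(5, cfg), ">= 10")
})
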