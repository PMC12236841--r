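test_that("forced counts: 10 cells x 16 pairs, no orphans", {
  gt <- plant_ground_truth(n_cells = 10, pairs_per_cell = 16,
                           orphan_rate = 0, seed = 3)
  expect_equal(sum(gt$puncta$channel == "ribbon"), 160)
  expect_equal(sum(gt$puncta$channel == "receptor"), 160)
  expect_true(all(!is.na(gt$puncta$pair_id)))
  expect_equal(length(unique(gt$puncta$pair_id)), 160)
})

test_that("pair structure: every pair_id on exactly one punctum per channel, within cleft distance", {
  gt <- plant_ground_truth(n_cells = 5, seed = 11)
  p <- gt$puncta[!is.na(gt$puncta$pair_id), ]
  tab <- table(p$pair_id, p$channel)
  expect_true(all(tab == 1))
  wide <- merge(p[p$channel == "ribbon", c("pair_id", "x_um", "y_um", "z_um")],
                p[p$channel == "receptor", c("pair_id", "x_um", "y_um", "z_um")],
                by = "pair_id")
  d <- sqrt((wide$x_um.x - wide$x_um.y)^2 + (wide$y_um.x - wide$y_um.y)^2 +
              (wide$z_um.x - wide$z_um.y)^2)
  expect_equal(d, rep(gt$cleft_um, nrow(wide)), tolerance = 1e-9)
})

test_that("all-orphan receptor channel has zero pair ids", {
  gt <- plant_ground_truth(n_cells = 3, pairs_per_cell = 0,
                           orphan_rate = c(ribbon = 0, receptor = 1),
                           seed = 2)
  expect_equal(sum(!is.na(gt$puncta$pair_id)), 0)
  expect_equal(unique(gt$puncta$channel), character(0))
  # orphan_rate is per planted pair, so zero pairs also means zero orphans
  expect_equal(nrow(gt$puncta), 0)
})

test_that("generation is a pure function of its seed", {
  a <- plant_ground_truth(seed = 99)
  b <- plant_ground_truth(seed = 99)
  expect_identical(a, b)
  c <- plant_ground_truth(seed = 100)
  expect_false(identical(a$puncta, c$puncta))
})

test_that("volumes are positive and inside the admissible synapse range", {
  gt <- plant_ground_truth(n_cells = 8, seed = 5)
  expect_true(all(gt$puncta$volume_um3 > 0.04))
  expect_true(all(gt$puncta$volume_um3 < 5))
})

test_that("degenerate volume distributions are rejected", {
  expect_error(
    plant_ground_truth(n_cells = 2, volume_dist = function(n) rep(0, n),
                       seed = 1),
    "outside \\(0, Inf\\)")
  expect_error(
    plant_ground_truth(n_cells = 2, volume_dist = function(n) rep(-1, n),
                       seed = 1),
    "outside \\(0, Inf\\)")
})
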