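test_that("Richardson-Lucy fixed points: delta PSF, uniform image, n_iter = 0", {
  set.seed(3)
  g <- array(rgamma(20 * 18 * 12, 3), c(20, 18, 12))
  delta <- make_psf(truncate = 0)
  expect_equal(richardson_lucy(g, delta, 10), g)
  psf <- make_psf(0.2, 0.4, truncate = 2)
  expect_equal(richardson_lucy(g, psf, 0), g)
  u <- array(5, c(20, 18, 12))
  expect_equal(richardson_lucy(u, psf, 5), u, tolerance = 1e-8)
})

test_that("Richardson-Lucy conserves flux and sharpens a blurred point source", {
  psf <- make_psf(0.2, 0.4, voxel_dims = c(0.11, 0.11, 0.2))
  g <- array(0, c(41, 41, 21))
  g[21, 21, 11] <- 1000
  blurred <- cochleaquant:::psf_convolve(g, psf)
  dec <- richardson_lucy(blurred, psf, 10)
  expect_equal(sum(dec), sum(blurred), tolerance = 1e-3)
  fwhm_x <- function(a) {
    prof <- a[, 21, 11]
    sum(prof >= max(prof) / 2)
  }
  expect_lt(fwhm_x(dec), fwhm_x(blurred))
  expect_true(all(dec >= 0))
})

test_that("PSF larger than the grid is rejected", {
  psf <- make_psf(0.5, 1.5)
  expect_error(richardson_lucy(array(1, c(5, 5, 3)), psf), "larger")
})

test_that("size gate: 19-voxel blob excluded, 25-voxel blob kept, oversize excluded", {
  g <- array(0, c(40, 40, 12))
  g[2:20, 2, 2] <- 100            # 19 voxels in a line
  g[30:34, 30:34, 8] <- 100       # 25 voxels
  cfg <- segmentation_config(refine = "none")
  seg <- segment_objects(g, cfg)
  expect_equal(nrow(seg$objects), 1L)
  expect_equal(seg$objects$n_vox, 25L)
  big <- array(0, c(30, 30, 30))
  big[2:24, 2:14, 2:8] <- 100     # 23*13*7 = 2093 voxels
  expect_equal(nrow(segment_objects(big, cfg)$objects), 0L)
})

test_that("3D components match the flood-fill oracle on random grids", {
  set.seed(21)
  cfg <- segmentation_config(size_min_vox = 1, size_max_vox = 10^6,
                             refine = "none")
  for (i in 1:10) {
    g <- array((runif(24 * 20 * 8) < 0.25) * 100, c(24, 20, 8))
    seg <- segment_objects(g, cfg)
    oracle <- flood_fill_count(g > 0, 26)
    expect_equal(nrow(seg$objects), oracle$count)
    # identical partition up to label renaming
    expect_equal(table(table(oracle$labels[oracle$labels > 0])),
                 table(table(seg$labels[seg$labels > 0])))
  }
})

test_that("object volume arithmetic matches the voxel gate bounds", {
  expect_equal(object_volume(20, c(0.11, 0.11, 0.2)), 0.0484)
  expect_equal(object_volume(2000, c(0.11, 0.11, 0.2)), 4.84)
  expect_equal(object_volume(1, c(1, 1, 1)), 1)
  expect_error(object_volume(0), "positive")
})

test_that("segmentation flags border-touching and sub-resolution objects", {
  g <- array(0, c(30, 30, 10))
  g[1:4, 2:8, 2:4] <- 100         # touches x = 0 border
  g[15:25, 15, 6] <- 100          # 1-voxel-thin in y and z
  cfg <- segmentation_config(size_min_vox = 5, size_max_vox = 5000,
                             refine = "none")
  seg <- segment_objects(g, cfg)
  expect_equal(nrow(seg$objects), 2L)
  expect_true(any(seg$objects$border_flag))
  expect_true(any(seg$objects$subresolution_flag))
})

test_that("pairing: overlap pair, distant orphans, one-to-one matching", {
  mk_seg <- function(coords_list) {
    g <- array(0, c(40, 40, 16))
    for (co in coords_list) g[co$x, co$y, co$z] <- 100
    segment_objects(g, segmentation_config(size_min_vox = 5,
                                           size_max_vox = 5000,
                                           refine = "none"))
  }
  rib <- mk_seg(list(list(x = 5:9, y = 5:9, z = 3:5)))
  rec <- mk_seg(list(list(x = 7:11, y = 5:9, z = 3:5)))
  pr <- pair_synapses(rib, rec)
  expect_equal(nrow(pr$pairs), 1L)
  expect_gt(pr$pairs$overlap_vox, 0)

  far <- mk_seg(list(list(x = 32:36, y = 30:34, z = 10:12)))
  pr2 <- pair_synapses(rib, far, radius_um = 1)
  expect_equal(nrow(pr2$pairs), 0L)
  expect_equal(length(pr2$orphan_ribbons), 1L)
  expect_equal(length(pr2$orphan_receptors), 1L)
})

test_that("planted pairs are recovered through the full volumetric pipeline", {
  gt <- plant_ground_truth(n_cells = 3, seed = 31)
  st <- render_stack(gt, make_psf(), seed = 131)
  vol <- measure_synapse_volumes(st)
  n_planted <- length(unique(na.omit(gt$puncta$pair_id)))
  expect_gte(nrow(vol$pairs$pairs), ceiling(0.95 * n_planted))
  # every returned object satisfies the voxel gate exactly
  for (seg in list(vol$ribbons, vol$receptors)) {
    expect_true(all(seg$objects$n_vox >= 20 & seg$objects$n_vox <= 2000))
    expect_equal(seg$objects$volume_um3,
                 seg$objects$n_vox * prod(st$voxel_dims))
  }
  # orphan-orphan false pairs are rare: matched pairs should not exceed
  # planted pairs by more than the occasional coincidence
  expect_lte(nrow(vol$pairs$pairs), n_planted + 2)
})
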