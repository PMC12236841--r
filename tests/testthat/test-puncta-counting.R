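test_that("max projection: identity on single slice, forced single-voxel case", {
  g <- array(runif(5 * 4), c(5, 4, 1))
  expect_equal(max_projection(g), g[, , 1])
  z <- array(0, c(6, 5, 3))
  expect_true(all(max_projection(z) == 0))
  z[3, 2, 2] <- 7
  p <- max_projection(z)
  expect_equal(p[3, 2], 7)
  expect_equal(sum(p), 7)
  expect_error(max_projection(matrix(1, 2, 2)), "3D")
})

test_that("binarize: constant image empty, two-level image splits cleanly, threshold logged", {
  const <- matrix(5, 10, 10)
  m <- binarize(const)
  expect_false(any(m))
  two <- matrix(0, 10, 10); two[3:5, 3:5] <- 100
  for (meth in c("robust_background", "otsu")) {
    m2 <- binarize(two, method = meth)
    expect_equal(unname(which(m2)), unname(which(two == 100)))
    expect_true(is.numeric(attr(m2, "threshold")))
  }
  expect_error(binarize(two, method = "magic"), "arg")
})

test_that("raising the threshold never increases foreground area", {
  set.seed(7)
  img <- matrix(rgamma(64 * 64, 2, 0.5), 64, 64)
  thrs <- quantile(img, seq(0.1, 0.95, by = 0.05))
  areas <- vapply(thrs, function(t) sum(binarize(img, threshold = t)),
                  numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("product image: annihilator, identity, arithmetic and shape checks", {
  a <- matrix(runif(30, 0, 255), 6, 5)
  expect_true(all(product_image(a, a * 0) == 0))
  expect_equal(product_image(a, a * 0 + 1), a)
  m255 <- matrix(255, 3, 3)
  expect_equal(max(product_image(m255, m255)), 65025)
  expect_error(product_image(a, t(a)), "same shape")
})

test_that("count_particles matches the flood-fill oracle exactly on random masks", {
  set.seed(11)
  for (i in 1:25) {
    mask <- matrix(runif(64 * 64) < runif(1, 0.2, 0.6), 64, 64)
    expect_equal(count_particles(mask, min_area_px = 1),
                 flood_fill_count(mask, 26)$count)
  }
})

test_that("count_particles: empty mask, forced blobs, area gate and ROI membership", {
  empty <- matrix(FALSE, 20, 20)
  expect_equal(count_particles(empty), 0L)
  m <- matrix(FALSE, 20, 20)
  m[2:3, 2:3] <- TRUE; m[10:11, 13:14] <- TRUE; m[17:18, 4:5] <- TRUE
  expect_equal(count_particles(m, min_area_px = 1), 3L)
  expect_equal(count_particles(m, min_area_px = 5), 0L)
  roi <- structure(list(cell_id = 1L,
                        mask = cbind(matrix(TRUE, 20, 10),
                                     matrix(FALSE, 20, 10)),
                        region_label = "apex"), class = "roi2d")
  expect_equal(count_particles(m, roi, min_area_px = 1), 2L)
})

test_that("external ROI masks pass through with matching ids", {
  lab <- matrix(0L, 30, 30)
  lab[2:6, 2:6] <- 3L; lab[10:14, 10:14] <- 7L
  rois <- derive_rois(mode = "external", roi_source = lab)
  expect_equal(length(rois), 2L)
  expect_equal(vapply(rois, `[[`, integer(1), "cell_id"), c(3L, 7L))
  expect_equal(sum(rois[[1]]$mask), 25)
})

test_that("auto ROIs find each planted cell once; blank channel warns empty", {
  fx <- tiny_stack(seed = 9, n_cells = 3)
  rois <- derive_rois(max_projection(fx$stack$channels$cell))
  expect_equal(length(rois), 3L)
  cells <- fx$gt$cells
  vx <- fx$stack$voxel_dims
  hits <- vapply(seq_len(nrow(cells)), function(i) {
    px <- pmax(1, round(cells$cx_um[i] / vx[1]))
    py <- pmax(1, round(cells$cy_um[i] / vx[2]))
    sum(vapply(rois, function(r) r$mask[px, py], logical(1)))
  }, numeric(1))
  expect_true(all(hits == 1))
  expect_warning(r0 <- derive_rois(matrix(5, 50, 50)), "no ROIs")
  expect_equal(length(r0), 0L)
})

test_that("counting recovers planted counts on a small noisy field", {
  fx <- tiny_stack(seed = 12, n_cells = 3)
  cnt <- count_synapses(fx$stack)
  tru <- cochleaquant:::ground_truth_counts(fx$gt)
  expect_equal(nrow(cnt), 3L)
  for (col in c("n_ribbon", "n_receptor", "n_colocalized")) {
    expect_lt(abs(sum(cnt[[col]]) - sum(tru[[col]])) / sum(tru[[col]]), 0.1)
  }
  expect_true(all(cnt$n_colocalized <=
                    pmin(cnt$n_ribbon, cnt$n_receptor) + 2))
  prov <- attr(cnt, "provenance")
  expect_true(is.numeric(prov$threshold_ribbon))
})

test_that("counts are invariant under a global intensity rescale", {
  fx <- tiny_stack(seed = 13, n_cells = 2)
  st2 <- fx$stack
  st2$channels <- lapply(st2$channels, function(g) g * 2)
  rois <- derive_rois(max_projection(fx$stack$channels$cell))
  c1 <- count_synapses(fx$stack, rois)
  c2 <- count_synapses(st2, rois)
  expect_equal(c1$n_ribbon, c2$n_ribbon)
  expect_equal(c1$n_receptor, c2$n_receptor)
  expect_equal(c1$n_colocalized, c2$n_colocalized)
})

test_that("an all-zero receptor channel forces zero colocalized counts", {
  fx <- tiny_stack(seed = 14, n_cells = 2)
  st <- fx$stack
  st$channels$receptor <- st$channels$receptor * 0
  rois <- derive_rois(max_projection(st$channels$cell))
  cnt <- count_synapses(st, rois)
  expect_true(all(cnt$n_colocalized == 0))
  expect_true(all(cnt$n_receptor == 0))
})
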