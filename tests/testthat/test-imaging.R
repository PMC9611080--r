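test_that("thickness projections count voxels times pitch", {
  lab <- array(0L, c(6, 6, 20))
  lab[2:5, 2:5, 6:15] <- 10L  # slab 10 voxels thick along z
  v <- label_volume(lab, 0.2)
  pr <- thickness_projection(v, 10L, "z")
  expect_equal(dim(pr$map), c(6L, 6L))
  expect_true(all(pr$map[2:5, 2:5] == 2.0))
  expect_true(all(pr$map[1, ] == 0))
  # absent tissue: all-zero map
  expect_true(all(thickness_projection(v, 3L, "z")$map == 0))
  expect_error(thickness_projection(v, 77L, "z"), "unknown tissue")
})

test_that("projections conserve tissue volume along every axis for all labels", {
  vol <- default_phantom()
  vv <- prod(vol$pitch)
  counts <- label_counts(vol)
  for (ax in c("x", "y", "z")) {
    for (id in counts$id) {
      pr <- thickness_projection(vol, id, ax)
      expect_equal(sum(pr$map) * prod(pr$pixel_mm),
                   counts$count[counts$id == id] * vv,
                   tolerance = 1e-9)
    }
  }
})

test_that("band integration averages the in-band images and is linear", {
  arr <- array(0, c(5, 4, 3))
  wl <- c(640, 650, 700, 760, 770)
  arr <- array(seq_len(5 * 12), c(5, 4, 3))
  attr(arr, "wavelengths") <- wl
  one <- spectral_integrate(arr, 650, 650)
  expect_equal(one, arr[2, , ])
  band <- spectral_integrate(arr, 650, 760)
  expect_equal(band, (arr[2, , ] + arr[3, , ] + arr[4, , ]) / 3)
  arr2 <- arr * 2.5
  attr(arr2, "wavelengths") <- wl
  expect_equal(spectral_integrate(arr2, 650, 760), band * 2.5)
  expect_error(spectral_integrate(arr, 655, 656), "empty spectral band")
  # the default 10 nm grid holds 12 samples between 650 and 760 nm
  expect_equal(sum(seq(400, 1100, 10) >= 650 & seq(400, 1100, 10) <= 760), 12L)
})

test_that("log display clamps at the floor and preserves ordering", {
  img <- matrix(c(1, 10, 1e-12, 0.5), 2, 2)
  out <- to_log_display(img, floor = 1e-8)
  expect_equal(out[1, 1], 0)
  expect_equal(out[2, 1], 1)
  expect_equal(out[1, 2], -8)   # below floor: clamped
  expect_true(all(order(img[img > 1e-8]) == order(out[img > 1e-8])))
  expect_error(to_log_display(img, floor = 0), "positive")
})
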