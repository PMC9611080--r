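test_that("unit factors, empty ranges and unit scaling are exact identities", {
  vol <- default_phantom()
  idt <- apply_joint_inflammation(vol, inflammation_spec(fluid_factor = 1,
                                                         membrane_factor = 1))
  expect_identical(idt$labels, vol$labels)
  expect_identical(apply_tendon_rupture(vol, 6L, c(30, 30))$labels, vol$labels)
  expect_identical(scale_geometry(vol, c(1, 1, 1))$labels, vol$labels)
})

test_that("combined inflammation reaches the target volume ratios with bone intact", {
  vol <- default_phantom()
  inf <- apply_joint_inflammation(vol, inflammation_preset("inflamed-combined"))
  ar <- attr(inf, "achieved_ratios")
  expect_lt(abs(ar[["fluid"]] / 7.5 - 1), 0.05)
  expect_lt(abs(ar[["membrane"]] / 3.0 - 1), 0.05)
  # interior displacement is near-rigid: bone voxel count changes < 2%
  expect_lt(abs(sum(inf$labels == 10L) / sum(vol$labels == 10L) - 1), 0.02)
  # outside the axial extent nothing moves
  yc <- (seq_len(dim(vol$labels)[2]) - 0.5) * vol$pitch[2]
  far <- which(abs(yc - 24.5) > 5)
  expect_identical(inf$labels[, far, ], vol$labels[, far, ])
})

test_that("membrane-only and fluid-only presets hit their own targets", {
  vol <- default_phantom()
  mem <- apply_joint_inflammation(vol, inflammation_preset("inflamed-membrane"))
  am <- attr(mem, "achieved_ratios")
  expect_lt(abs(am[["membrane"]] / 3 - 1), 0.05)
  expect_lt(abs(am[["fluid"]] - 1), 0.05)
  fl <- apply_joint_inflammation(vol, inflammation_preset("inflamed-fluid"))
  af <- attr(fl, "achieved_ratios")
  expect_lt(abs(af[["fluid"]] / 7.5 - 1), 0.05)
})

test_that("inflammation validates its inputs", {
  expect_error(inflammation_spec(fluid_factor = 0.5), ">= 1")
  expect_error(inflammation_spec(extent_mm = 0), "positive")
  novo <- label_volume(array(1L, c(8, 8, 8)), 0.5)
  expect_error(apply_joint_inflammation(novo, inflammation_spec()),
               "no synovial cavity")
})

test_that("tendon rupture clears the range, leaves the rest bit-identical", {
  vol <- default_phantom()
  rng <- c(30, 32)
  out <- apply_tendon_rupture(vol, 6L, rng)
  yc <- (seq_len(dim(vol$labels)[2]) - 0.5) * vol$pitch[2]
  iys <- which(yc >= rng[1] & yc < rng[2])
  expect_equal(sum(out$labels[, iys, ] == 6L), 0L)
  # the gap is filled with subcutis, nothing else changes in the range
  changed <- vol$labels[, iys, ] == 6L
  expect_true(all(out$labels[, iys, ][changed] == 1L))
  expect_identical(out$labels[, -iys, ], vol$labels[, -iys, ])
  expect_error(apply_tendon_rupture(vol, 9L, c(0, 1), replacement = 1L), NA)
  expect_error(apply_tendon_rupture(label_volume(array(1L, c(4, 4, 4)), 1),
                                    6L, c(0, 1)), "absent")
})

test_that("geometry scaling resamples by nearest neighbour", {
  vol <- default_phantom()
  sc <- scale_geometry(vol, c(1, 0.75, 1))
  expect_equal(dim(sc$labels), c(160L, 240L, 133L))
  expect_equal(sc$pitch, vol$pitch)  # physical pitch unchanged
  expect_true(all(unique(c(sc$labels)) %in% unique(c(vol$labels))))
  expect_error(scale_geometry(vol, c(1, 0.001, 1)), "empty axis")
  expect_error(scale_geometry(vol, c(-1, 1, 1)), "positive")
})

test_that("down-up scaling round trip approximately preserves label fractions", {
  # nearest-neighbour resampling cannot represent structures thinner than
  # the resampling cell, so the check covers the bulky labels; voxel-thin
  # shells (cartilage discs, ligaments) alias under f = 0.5 by construction
  vol <- default_phantom()
  for (f in c(0.5, 2)) {
    rt <- scale_geometry(scale_geometry(vol, rep(f, 3)), rep(1 / f, 3))
    c0 <- tabulate(vol$labels + 1L, 16L) / length(vol$labels)
    c1 <- tabulate(rt$labels + 1L, 16L) / length(rt$labels)
    big <- which(c0 > 0.01)
    expect_true(all(abs(c1[big] / c0[big] - 1) < 0.03))
  }
})
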