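test_that("free-path sampling follows the exponential closed form", {
  expect_equal(sample_step(1, exp(-1)), 1)
  expect_equal(sample_step(0, 0.5), Inf)  # vacuum: ballistic to boundary
  expect_lt(sample_step(2, 1 - 1e-12), 1e-9)
  set.seed(1)
  u <- runif(2e5)
  s <- -log(u) / 2
  expect_lt(abs(mean(s) - 0.5), 3 * sd(s) / sqrt(length(s)))
})

test_that("Henyey-Greenstein sampling has mean polar cosine g and unit norm", {
  set.seed(2)
  n <- 5e4
  u <- matrix(runif(2 * n), ncol = 2)
  for (g in c(0, 0.75, 0.9)) {
    ct <- vapply(seq_len(n), function(i)
      scatter_hg(c(0, 0, 1), g, u[i, 1], u[i, 2])[3], numeric(1))
    expect_lt(abs(mean(ct) - g), 3 * sd(ct) / sqrt(n))
  }
  # g = 0 reduces to cos(theta) = 2 u - 1 exactly
  d <- scatter_hg(c(0, 0, 1), 0, 0.3, 0)
  expect_equal(d[3], 2 * 0.3 - 1)
  # rotated from an oblique incoming direction, still unit length
  set.seed(3)
  for (i in 1:50) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    out <- scatter_hg(v, 0.9, runif(1), runif(1))
    expect_lt(abs(sqrt(sum(out^2)) - 1), 1e-9)
  }
})

test_that("Fresnel reflectance covers matched, normal and critical cases", {
  expect_equal(fresnel(1.4, 1.4, 0.7)$R, 0)
  expect_equal(fresnel(1, 1.5, 1)$R, 0.04)
  tir <- fresnel(1.5, 1, cos(60 * pi / 180))  # past the 41.8 deg critical angle
  expect_equal(tir$R, 1)
  expect_true(tir$tir)
  r <- fresnel(1, 1.33, cos(0.5))
  expect_gte(r$R, 0); expect_lte(r$R, 1)
  # Snell: sin(theta_t) = sin(theta_i) / 1.33
  expect_equal(acos(r$cos_theta_t), asin(sin(0.5) / 1.33))
})

test_that("roulette is unbiased and leaves healthy packets alone", {
  expect_equal(roulette(0.5, 1e-4, 10, 0.99), 0.5)
  expect_equal(roulette(1e-5, 1e-4, 10, 0.05), 1e-4)  # survivor carries 10x
  expect_equal(roulette(1e-5, 1e-4, 10, 0.5), 0)
  set.seed(4)
  u <- runif(2e5)
  after <- ifelse(u < 0.1, 1e-5 * 10, 0)
  expect_lt(abs(mean(after) - 1e-5), 3 * sd(after) / sqrt(length(after)))
})

test_that("launched packets have unit weight and uniform positions", {
  m <- launch_packets(5e4, 32, 64, seed = 3)
  expect_true(all(m[, "w"] == 1))
  expect_true(all(m[, "x"] >= 0 & m[, "x"] <= 32))
  px <- chisq.test(table(cut(m[, "x"], seq(0, 32, 4))))$p.value
  py <- chisq.test(table(cut(m[, "y"], seq(0, 64, 8))))$p.value
  expect_gt(px, 0.01)
  expect_gt(py, 0.01)
})

test_that("traversal spends optical depth voxel by voxel and mirrors laterally", {
  # homogeneous: interaction at step / mu_t
  v <- label_volume(array(1L, c(10, 10, 10)), 1)
  tr <- traverse(v, c(0, 0.5), pos = c(5, 5, 0), dir = c(0, 0, 1), step = 2)
  expect_equal(tr$event, "interaction")
  expect_equal(tr$pos[3], 4)
  # two voxels, second mu_t doubled: step 1.5 with first face at depth 1
  v2 <- label_volume(array(c(1L, 2L), c(1, 1, 2)), 1)
  tr2 <- traverse(v2, c(0, 1, 2), pos = c(0.5, 0.5, 0), dir = c(0, 0, 1),
                  step = 1.5)
  expect_equal(tr2$pos[3], 1.25)  # remaining quarter of a first-voxel free path
  # mirror at the y limit flips the y direction component
  v3 <- label_volume(array(0L, c(4, 4, 4)), 1)
  tr3 <- traverse(v3, c(0.1), pos = c(2, 3.9, 0.5), dir = c(0, 0.6, 0.8),
                  step = 50)
  expect_equal(tr3$dir, c(0, -0.6, 0.8))
  expect_equal(tr3$event, "exit_forward")
  expect_error(traverse(v3, c(0.1), pos = c(NaN, 1, 1), dir = c(0, 0, 1), 1),
               "non-finite")
})

test_that("an all-ambient grid transmits everything", {
  v <- label_volume(array(0L, c(8, 8, 10)), 0.5)
  r <- run_simulation(v, flat_spectra(1, 1, 0.5, 1.4),
                      simulation_config(n_photons = 2000, wavelength = 600))
  expect_equal(unname(r$totals["T"]), 1)
  expect_equal(unname(r$totals["R"]), 0)
})

test_that("pure absorbers follow Beer-Lambert across optical depths", {
  for (tau in c(0.5, 1, 2)) {
    v <- slab_volume(4, 4, 10, 0.1)  # 1 mm thick
    r <- run_simulation(v, flat_spectra(tau, 0, 0, 1),
                        simulation_config(n_photons = 1e5, wavelength = 600))
    expected <- exp(-tau)
    se <- sqrt(expected * (1 - expected) / 1e5)
    expect_lt(abs(r$totals[["T"]] - expected), 3 * se)
  }
})

test_that("an absorbing index-mismatched slab reflects the Fresnel fraction", {
  v <- slab_volume(4, 4, 10, 0.5)  # 5 mm, mu_a 2/mm: interior never returns
  r <- run_simulation(v, flat_spectra(2, 0, 0, 1.5),
                      simulation_config(n_photons = 1e5, wavelength = 600))
  se <- sqrt(0.04 * 0.96 / 1e5)
  expect_lt(abs(r$totals[["R"]] - 0.04), 3 * se)
})

test_that("the classic scattering-slab benchmark is reproduced within 1%", {
  # optical thickness 2, albedo 0.9, g = 0.75, matched boundaries:
  # reference total diffuse reflectance 0.09739, transmittance 0.66096
  v <- slab_volume(10, 10, 4, 0.05)  # 0.2 mm thick
  r <- run_simulation(v, flat_spectra(1, 9, 0.75, 1),
                      simulation_config(n_photons = 1e6, wavelength = 600))
  expect_lt(abs(r$totals[["R"]] / 0.09739 - 1), 0.01)
  expect_lt(abs(r$totals[["T"]] / 0.66096 - 1), 0.01)
})

test_that("energy is conserved when absorption is recorded", {
  v <- slab_volume(10, 10, 10, 0.2)
  r <- run_simulation(v, flat_spectra(0.5, 5, 0.8, 1.4),
                      simulation_config(n_photons = 5e4, wavelength = 600,
                                        record_absorption = TRUE))
  total <- sum(r$totals[c("R", "T", "A")])
  expect_lt(abs(total - 1), 1e-3)
  expect_equal(sum(r$absorbed), unname(r$totals["A"]), tolerance = 1e-9)
  expect_true(all(r$reflectance >= 0) && all(r$transmittance >= 0))
})

test_that("mirror boundaries emulate a laterally infinite medium", {
  cfg <- function(seed) simulation_config(n_photons = 2e5, wavelength = 600,
                                          seed = seed)
  sp <- flat_spectra(1, 9, 0.75, 1)
  small <- run_simulation(slab_volume(4, 4, 10, 0.2), sp, cfg(1))
  large <- run_simulation(slab_volume(30, 30, 10, 0.2), sp, cfg(2))
  se <- sqrt(small$totals[["T"]] * (1 - small$totals[["T"]]) / 2e5)
  expect_lt(abs(small$totals[["T"]] - large$totals[["T"]]), 3 * sqrt(2) * se)
  expect_lt(abs(small$totals[["R"]] - large$totals[["R"]]),
            3 * sqrt(2) * sqrt(small$totals[["R"]] / 2e5))
})

test_that("identical seeds give bit-identical images", {
  v <- slab_volume(10, 10, 10, 0.2)
  sp <- flat_spectra(0.5, 5, 0.8, 1.4)
  r1 <- run_simulation(v, sp, simulation_config(n_photons = 2e4, seed = 9,
                                                wavelength = 600))
  r2 <- run_simulation(v, sp, simulation_config(n_photons = 2e4, seed = 9,
                                                wavelength = 600))
  expect_identical(r1$reflectance, r2$reflectance)
  expect_identical(r1$transmittance, r2$transmittance)
  r3 <- run_simulation(v, sp, simulation_config(n_photons = 2e4, seed = 10,
                                                wavelength = 600))
  expect_false(identical(r1$transmittance, r3$transmittance))
})

test_that("spectral sweeps reproduce single runs and stack correctly", {
  v <- slab_volume(6, 6, 6, 0.2)
  sp <- flat_spectra(0.5, 3, 0.7, 1.4)
  single <- run_simulation(v, sp, simulation_config(n_photons = 5e3, seed = 5,
                                                    wavelength = 500))
  sw <- spectral_sweep(v, sp, wavelengths = 500,
                       config = simulation_config(n_photons = 5e3, seed = 5))
  expect_identical(sw$transmittance[1, , ], single$transmittance)
  sw3 <- spectral_sweep(v, sp, wavelengths = c(500, 600, 700),
                        config = simulation_config(n_photons = 2e3, seed = 5))
  expect_equal(dim(sw3$transmittance), c(3L, 6L, 6L))
  # wavelength substreams are independent: different images per wavelength
  expect_false(identical(sw3$transmittance[1, , ], sw3$transmittance[2, , ]))
})
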