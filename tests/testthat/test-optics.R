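test_that("the shipped default table is complete and valid", {
  sp <- default_spectra()
  expect_s3_class(sp, "optical_spectra")
  expect_equal(sort(unique(sp$tissue_id)), 1:15)
  expect_equal(range(sp$wavelength), c(400, 1100))
  expect_equal(length(unique(sp$wavelength)), 71L)
  expect_true(all(sp$mu_a >= 0 & sp$mu_s >= 0))
  expect_true(all(sp$g > -1 & sp$g < 1))
  expect_true(all(sp$n >= 1))
})

test_that("spectra validation rejects physical-invariant violations", {
  row <- function(...) data.frame(tissue_id = 1L, wavelength = 550,
                                  mu_a = 0.1, mu_s = 1, g = 0.9, n = 1.4, ...)
  bad_g <- row(); bad_g$g <- 1.2
  expect_error(spectra_table(bad_g), "anisotropy")
  bad_n <- row(); bad_n$n <- 0.9
  expect_error(spectra_table(bad_n), "refractive")
  bad_mu <- row(); bad_mu$mu_a <- -1
  expect_error(spectra_table(bad_mu), "mu_a")
  dup <- rbind(row(), row())
  expect_error(spectra_table(dup), "duplicate wavelength 550")
})

test_that("CSV round trip preserves the table and unit conversion works", {
  sp <- default_spectra(seq(400, 1100, 100))
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra(sp, f)
  back <- load_spectra(f, require_all = TRUE)
  expect_equal(back$mu_a, sp$mu_a, tolerance = 1e-12)
  # a cm^-1 table is converted to mm^-1 on load
  cm <- as.data.frame(sp)
  cm$mu_a <- cm$mu_a * 10; cm$mu_s <- cm$mu_s * 10
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(cm, f2, row.names = FALSE)
  back2 <- load_spectra(f2, unit = "cm-1")
  expect_equal(back2$mu_a, sp$mu_a, tolerance = 1e-12)
  # an incomplete table is rejected when completeness is required
  part <- as.data.frame(sp)[sp$tissue_id != 7L, ]
  f3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(part, f3, row.names = FALSE)
  expect_error(load_spectra(f3), "missing tissue row set")
})

test_that("properties interpolate linearly and respect the table range", {
  sp <- default_spectra()
  at <- properties_at(sp, 10, 860)
  row <- sp[sp$tissue_id == 10 & sp$wavelength == 860, ]
  expect_equal(at$mu_a, row$mu_a)
  mid <- properties_at(sp, 10, 865)
  nxt <- properties_at(sp, 10, 870)
  expect_equal(mid$mu_a, (at$mu_a + nxt$mu_a) / 2)
  expect_equal(mid$n, row$n)
  # ambient medium is empty space
  amb <- properties_at(sp, 0, 700)
  expect_equal(unlist(amb), c(mu_a = 0, mu_s = 0, g = 0, n = 1))
  expect_error(properties_at(sp, 1, 1150), "outside tabulated range")
  expect_error(properties_at(sp, 99, 700), "no optical properties")
})

test_that("disease-state overrides scale or replace the chosen fields", {
  sp <- default_spectra()
  ov <- arthritic_overrides()
  sp2 <- apply_spectra_overrides(sp, ov)
  sel <- sp$tissue_id == 12
  expect_equal(sp2$mu_s[sel], sp$mu_s[sel] * 5)
  expect_equal(sp2$mu_a[sel], sp$mu_a[sel] * 2)
  abs_ov <- data.frame(tissue_id = 1L, field = "n", factor = NA_real_,
                       value = 1.5)
  sp3 <- apply_spectra_overrides(sp, abs_ov)
  expect_true(all(sp3$n[sp3$tissue_id == 1] == 1.5))
  expect_error(apply_spectra_overrides(sp, data.frame(tissue_id = 1,
    field = "mu_x", factor = 2, value = NA)), "unknown property")
  # the shipped YAML template applies identically to the built-in preset
  yml <- system.file("extdata", "arthritic_overrides.yaml",
                     package = "fingerphantom")
  expect_equal(apply_spectra_overrides(sp, yml)$mu_s,
               apply_spectra_overrides(sp, arthritic_overrides())$mu_s)
})
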