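test_that("tissue table has 15 uniquely ranked tissues and resolves aliases", {
  tt <- tissue_table()
  expect_equal(nrow(tt), 15L)
  expect_equal(sort(tt$id), 1:15)
  expect_equal(sort(tt$priority_rank), 1:15)
  expect_equal(tissue_id("joint capsule"), tissue_id("synovial membrane"))
  expect_error(tissue_table(priority = c("bone", "tendon")), "permutation")
  expect_error(tissue_id("cartilago"), "unknown tissue")
})

test_that("label volumes enforce their invariants", {
  expect_error(label_volume(array(0.5, c(2, 2, 2))), "integer")
  expect_error(label_volume(array(0L, c(2, 2, 2)), pitch = -1), "positive")
  expect_error(label_volume(matrix(0L, 2, 2)), "3D")
  expect_error(label_volume(array(16L, c(2, 2, 2))), "0..15")
})

test_that("default phantom has all 15 tissues on the reference grid", {
  vol <- default_phantom()
  expect_equal(length(vol$labels), 6809600L)
  expect_equal(dim(vol$labels), c(160L, 320L, 133L))
  expect_equal(vol$pitch, rep(0.2, 3))
  counts <- label_counts(vol)
  expect_equal(sort(counts$id), 1:15)
  # label partition: per-label counts sum to the non-ambient total
  expect_equal(sum(counts$count), sum(vol$labels != 0L))
})

test_that("phantom generation is deterministic and honours feature toggles", {
  m1 <- generate_phantom()
  expect_identical(m1$labels, default_phantom()$labels)
  nojoint <- generate_phantom(phantom_params(features = list(joints = FALSE)))
  expect_false(any(nojoint$labels == tissue_id("synovial cavity")))
  expect_false(any(nojoint$labels == tissue_id("synovial membrane")))
})

test_that("grids too small for the anatomy raise explicit sizing errors", {
  # joints cannot even be placed on a 12 mm long grid
  expect_error(phantom_params(dims = c(30L, 60L, 24L)), "inside the grid")
  # joints fit but the finger cross-section does not
  expect_error(generate_phantom(phantom_params(dims = c(60L, 320L, 50L))),
               "too small")
})

test_that("structural validation passes by default and flags injected defects", {
  vol <- default_phantom()
  rep <- validate_phantom(vol)
  expect_true(rep$pass)
  expect_true(all(rep$checks))
  # put a bone voxel on the outer surface: the bone-interior check must fail
  lab <- vol$labels
  surf <- which(lab == tissue_id("epidermis"))[1]
  lab[surf] <- tissue_id("bone")
  # expose it to ambient by clearing the voxel one x-step outward if needed
  bad <- validate_phantom(label_volume(lab, vol$pitch))
  expect_false(bad$checks[["bone_interior"]] && bad$checks[["skin_encloses"]])
})

test_that("resolve_overlaps matches the exhaustive per-voxel oracle", {
  tt <- tissue_table()
  set.seed(42)
  for (rep in 1:3) {
    shp <- c(sample(4:9, 1), sample(4:9, 1), sample(4:9, 1))
    masks <- list(
      "bone" = array(runif(prod(shp)) < 0.4, shp),
      "tendon" = array(runif(prod(shp)) < 0.4, shp),
      "artery" = array(runif(prod(shp)) < 0.3, shp)
    )
    got <- resolve_overlaps(masks, tt, pitch = 0.2)
    expect_identical(got$labels, oracle_resolve(masks, tt))
  }
})

test_that("resolve_overlaps honours priority and rejects shape mismatch", {
  tt <- tissue_table()
  a <- array(FALSE, c(2, 2, 2)); a[1, 1, 1] <- TRUE
  b <- a
  out <- resolve_overlaps(list("artery" = a, "bone" = b), tt)
  expect_equal(out$labels[1, 1, 1], tissue_id("artery"))  # artery outranks bone
  # disjoint masks: plain union
  b2 <- array(FALSE, c(2, 2, 2)); b2[2, 2, 2] <- TRUE
  out2 <- resolve_overlaps(list("artery" = a, "bone" = b2), tt)
  expect_equal(sum(out2$labels != 0), 2L)
  expect_error(resolve_overlaps(list("artery" = a,
                                     "bone" = array(FALSE, c(3, 2, 2))), tt),
               "share one grid shape")
})

test_that("cleanup removes stray voxels, fills holes, matches the oracle, and is idempotent", {
  # a stray voxel of label 10 inside label 1 is reassigned to 1
  lab <- array(1L, c(5, 5, 5)); lab[3, 3, 3] <- 10L
  out <- cleanup_labels(label_volume(lab, 0.2))
  expect_equal(out$labels[3, 3, 3], 1L)
  # a single-voxel hole surrounded by label 6 is filled with 6
  lab2 <- array(6L, c(5, 5, 5)); lab2[3, 3, 3] <- 0L
  out2 <- cleanup_labels(label_volume(lab2, 0.2))
  expect_equal(out2$labels[3, 3, 3], 6L)
  # already-clean volume is a fixed point
  clean <- array(rep(c(1L, 2L), each = 32), c(4, 4, 4))
  expect_identical(cleanup_labels(label_volume(clean, 0.2))$labels, clean)
  # random grids: agree with the brute-force majority-filter oracle and
  # applying twice equals applying once
  set.seed(7)
  for (rep in 1:3) {
    lab3 <- array(sample(0:3, 10^3, replace = TRUE, prob = c(.6, .2, .1, .1)),
                  c(10, 10, 10))
    got <- cleanup_labels(label_volume(lab3, 0.2))
    expect_identical(got$labels, oracle_cleanup(lab3))
    expect_identical(cleanup_labels(got)$labels, got$labels)
  }
})
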