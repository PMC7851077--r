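test_that("phantom generation is deterministic and respects the spec", {
  sp <- small_spec(include_posterior = TRUE)
  a <- generate_vertebra_phantom(sp)
  b <- generate_vertebra_phantom(sp)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$mask$labels, b$mask$labels)
  expect_true(any(a$mask$labels == 2L))

  no_post <- generate_vertebra_phantom(small_spec(include_posterior = FALSE))
  expect_false(any(no_post$mask$labels == 2L))

  # degenerate noise: every interior body voxel is exactly the trabecular
  # mean, every other body voxel is shell
  flat <- generate_vertebra_phantom(small_spec(trab_hu_sd = 0))
  vals <- flat$image$values[flat$mask$labels == 1L]
  expect_true(all(vals %in% c(180, 600)))
  expect_true(any(vals == 180))
})

test_that("phantom spec invariants are enforced", {
  expect_error(phantom_spec(shell_thickness = 20), "shell_thickness")
  expect_error(phantom_spec(trab_hu_sd = -1), "trab_hu_sd")
  expect_error(phantom_spec(body_height = -5), "positive")
  # body smaller than the voxel grid can resolve
  expect_error(generate_vertebra_phantom(
    phantom_spec(body_half_axes = c(0.4, 0.4), shell_thickness = 0.1,
                 voxel_spacing = c(1, 1, 1))), "grid too small")
})

test_that("posterior elements are attached to the body", {
  ph <- generate_vertebra_phantom(small_spec(include_posterior = TRUE))
  l <- ph$mask$labels
  post <- which(l == 2L, arr.ind = TRUE)
  # at least one label-2 voxel has a face-adjacent label-1 voxel
  touches <- FALSE
  for (r in seq_len(nrow(post))) {
    i <- post[r, 1]; j <- post[r, 2]; k <- post[r, 3]
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
               nb[, 1] <= dim(l)[1] & nb[, 2] <= dim(l)[2] &
               nb[, 3] <= dim(l)[3], , drop = FALSE]
    if (any(l[nb] == 1L)) { touches <- TRUE; break }
  }
  expect_true(touches)
})

test_that("contrast enhancement shifts labelled voxels as specified", {
  ph <- small_phantom()
  plain <- ph$image
  fg <- ph$mask$labels > 0L

  exact <- apply_contrast(plain, ph$mask, contrast_spec(30, 0))
  d <- exact$values - plain$values
  expect_true(all(abs(d[fg] - 30) < 1e-9))
  expect_true(all(d[!fg] == 0))

  ident <- apply_contrast(plain, ph$mask, contrast_spec(0, 0))
  expect_identical(ident$values, plain$values)

  noisy <- apply_contrast(plain, ph$mask, contrast_spec(30, 10, seed = 3))
  doff <- (noisy$values - plain$values)[fg]
  n <- sum(fg)
  expect_lt(abs(mean(doff) - 30), 3 * 10 / sqrt(n) + 1e-9)
  expect_gt(mean(noisy$values[fg]), mean(plain$values[fg]))  # monotonicity
  # determinism
  noisy2 <- apply_contrast(plain, ph$mask, contrast_spec(30, 10, seed = 3))
  expect_identical(noisy$values, noisy2$values)

  expect_error(contrast_spec(hu_offset_mean = -5), "hu_offset_mean")
})

test_that("slice-thickness resampling averages slices and votes labels", {
  ph <- small_phantom()
  expect_identical(resample_slice_thickness(ph$image, 2, 1)$values,
                   ph$image$values)

  const <- image_volume(array(7, c(4, 6, 4)))
  r <- resample_slice_thickness(const, 2, 3)
  expect_equal(dim(r$values), c(4, 2, 4))
  expect_true(all(r$values == 7))
  expect_equal(r$spacing, c(1, 3, 1))

  # slices valued 0,3,6,9,12,15 along axis 3 -> group means 3 and 12
  v <- array(0, c(2, 2, 6))
  for (k in 1:6) v[, , k] <- 3 * (k - 1)
  r2 <- resample_slice_thickness(image_volume(v), 3, 3)
  expect_equal(unique(as.numeric(r2$values[, , 1])), 3)
  expect_equal(unique(as.numeric(r2$values[, , 2])), 12)

  expect_error(resample_slice_thickness(image_volume(v), 3, 7), "factor")

  # majority vote with tie resolved toward foreground
  lab <- array(0L, c(1, 1, 4))
  lab[1, 1, ] <- c(0L, 1L, 1L, 1L)   # group1: 0,1 tie -> 1; group2: 1,1 -> 1
  rl <- resample_slice_thickness(label_mask(lab), 3, 2)
  expect_equal(as.integer(rl$labels), c(1L, 1L))
})

test_that("body voxel fraction is approximately conserved under 3x resampling", {
  ph <- generate_vertebra_phantom(phantom_spec())
  m1 <- ph$mask
  m3 <- resample_slice_thickness(m1, 2, 3)
  frac1 <- mean(m1$labels == 1L)
  frac3 <- mean(m3$labels == 1L)
  expect_lt(abs(frac3 - frac1) / frac1, 0.10)
})

test_that("paired cohorts have the specified structure", {
  cs <- cohort_spec(n_pairs = 9, strength_decrement_fraction = 0.15,
                    base_spec = small_spec(), seed = 11)
  coh <- generate_cohort(cs)
  expect_length(coh, 18)
  man <- cohort_manifest(coh)
  expect_equal(sort(unique(man$pair_id)), 1:9)
  expect_equal(sum(man$group == "healthy"), 9)
  # pairs share geometry seed
  expect_equal(man$seed[man$group == "healthy"],
               man$seed[man$group == "weakened"])

  # decrement -> 0 limit: paired phantoms become identical
  cs0 <- cohort_spec(n_pairs = 2, strength_decrement_fraction = 1e-9,
                     base_spec = small_spec(), seed = 11)
  coh0 <- generate_cohort(cs0)
  expect_equal(coh0[[1]]$image$values, coh0[[2]]$image$values,
               tolerance = 1e-5)
  expect_identical(coh0[[1]]$mask$labels, coh0[[2]]$mask$labels)

  expect_error(cohort_spec(strength_decrement_fraction = 1.2),
               "strength_decrement_fraction")
})

test_that("cohorts round-trip to disk with a manifest", {
  cs <- cohort_spec(n_pairs = 2, base_spec = small_spec(), seed = 4)
  coh <- generate_cohort(cs)
  d <- tempfile()
  man <- write_cohort(coh, d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  expect_true(all(file.exists(man$image_path)))
  expect_true(all(file.exists(man$mask_path)))
  back <- read_volume(man$image_path[1])
  expect_equal(back$values, coh[[1]]$image$values, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("healthy member is stronger in nearly all pairs at 15% decrement", {
  cs <- cohort_spec(n_pairs = 9, strength_decrement_fraction = 0.15,
                    base_spec = small_spec(), seed = 5)
  coh <- generate_cohort(cs)
  fl <- vapply(coh, function(ph)
    vertebra_failure_load(ph$image, ph$mask, edge_mm = 2, n_increments = 10,
                          band_fraction = 0.05)$result$failure_load,
    numeric(1))
  healthy <- fl[seq(1, 18, by = 2)]
  weakened <- fl[seq(2, 18, by = 2)]
  expect_gte(sum(healthy > weakened), 8)
})
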