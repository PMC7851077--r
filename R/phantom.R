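#' Synthetic vertebra phantom specification
#'
#' Describes an idealised vertebra: an elliptical-cylinder body with a dense
#' cortical shell and a spatially correlated Gaussian trabecular HU field,
#' optionally with posterior elements (two cylindrical pedicles, a connecting
#' lamina and a rectangular spinous process) attached to the posterior face.
#' Defaults correspond to an adult lumbar vertebra at 1 mm isotropic voxels.
#'
#' @param body_half_axes Ellipse half-axes (x, y) of the body cross-section, mm.
#' @param body_height Body height along z (superior-inferior), mm.
#' @param shell_thickness Cortical shell thickness, mm; must be smaller than
#'   the smallest half-axis.
#' @param shell_hu HU assigned to shell (and endplate) voxels.
#' @param trab_hu_mean,trab_hu_sd Mean and standard deviation of the
#'   trabecular HU field.
#' @param trab_correlation_length Gaussian correlation length of the
#'   trabecular field, mm.
#' @param include_posterior Attach posterior elements (label 2)?
#' @param posterior_hu Mean HU of posterior-element bone.
#' @param voxel_spacing Voxel spacing, mm (length 3).
#' @param margin Background margin around the bone, mm.
#' @param seed Integer seed; output is bit-identical for identical spec+seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_half_axes = c(18, 14), body_height = 28,
                         shell_thickness = 1.5, shell_hu = 600,
                         trab_hu_mean = 180, trab_hu_sd = 50,
                         trab_correlation_length = 3,
                         include_posterior = FALSE, posterior_hu = 250,
                         voxel_spacing = c(1, 1, 1), margin = 2, seed = 1L) {
  geom <- c(body_half_axes, body_height, shell_thickness,
            trab_correlation_length, voxel_spacing, margin)
  if (any(!is.finite(geom)) || any(geom <= 0))
    stopf("all geometric fields of a phantom_spec must be positive")
  if (shell_thickness >= min(body_half_axes))
    stopf("shell_thickness must be smaller than min(body_half_axes)")
  if (!is_scalar_number(trab_hu_sd) || trab_hu_sd < 0)
    stopf("trab_hu_sd must be >= 0")
  structure(list(body_half_axes = as.numeric(body_half_axes),
                 body_height = body_height,
                 shell_thickness = shell_thickness, shell_hu = shell_hu,
                 trab_hu_mean = trab_hu_mean, trab_hu_sd = trab_hu_sd,
                 trab_correlation_length = trab_correlation_length,
                 include_posterior = isTRUE(include_posterior),
                 posterior_hu = posterior_hu,
                 voxel_spacing = as.numeric(voxel_spacing),
                 margin = margin, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Contrast-medium enhancement specification
#'
#' Intravenous contrast medium raises the attenuation of perfused bone; the
#' model adds a smooth random HU offset field (given mean and sd) to all
#' labelled voxels.
#'
#' @param hu_offset_mean Mean HU increase (must be >= 0).
#' @param hu_offset_sd Spatial standard deviation of the offset field.
#' @param correlation_length Smoothness of the offset field, mm.
#' @param seed Integer seed.
#' @export
contrast_spec <- function(hu_offset_mean = 30, hu_offset_sd = 10,
                          correlation_length = 5, seed = 1L) {
  if (!is_scalar_number(hu_offset_mean) || hu_offset_mean < 0)
    stopf("hu_offset_mean must be >= 0 (contrast enhancement raises HU)")
  if (!is_scalar_number(hu_offset_sd) || hu_offset_sd < 0)
    stopf("hu_offset_sd must be >= 0")
  structure(list(hu_offset_mean = hu_offset_mean,
                 hu_offset_sd = hu_offset_sd,
                 correlation_length = correlation_length,
                 seed = as.integer(seed)),
            class = "contrast_spec")
}

#' Paired-cohort specification
#'
#' A paired design of healthy phantoms and matched "fractured-analog"
#' phantoms whose bone HU is reduced so that the predicted failure load drops
#' by approximately `strength_decrement_fraction`.
#'
#' @param n_pairs Number of matched pairs.
#' @param strength_decrement_fraction Target relative strength drop, in (0,1).
#' @param base_spec A `phantom_spec` giving the cohort's nominal anatomy.
#' @param seed Integer seed for between-subject variation.
#' @export
cohort_spec <- function(n_pairs = 9, strength_decrement_fraction = 0.15,
                        base_spec = phantom_spec(), seed = 1L) {
  if (!is_scalar_number(strength_decrement_fraction) ||
      strength_decrement_fraction <= 0 || strength_decrement_fraction >= 1)
    stopf("strength_decrement_fraction must lie in (0, 1)")
  if (!is_scalar_number(n_pairs) || n_pairs < 1)
    stopf("n_pairs must be a positive count")
  stopifnot(inherits(base_spec, "phantom_spec"))
  structure(list(n_pairs = as.integer(n_pairs),
                 strength_decrement_fraction = strength_decrement_fraction,
                 base_spec = base_spec, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Separable Gaussian smoothing of a 3D array; sigma in voxels per axis.
gauss_smooth3 <- function(arr, sigma) {
  for (a in 1:3) {
    s <- sigma[a]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r):r)^2 / (2 * s^2)); k <- k / sum(k)
    arr <- conv_axis(arr, k, a)
  }
  arr
}

# Convolve along one axis with kernel k (odd length), replicate padding.
conv_axis <- function(arr, k, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dp <- dim(x)
  m <- matrix(x, nrow = dp[1])
  r <- (length(k) - 1L) / 2L
  idx <- c(rep(1L, r), seq_len(dp[1]), rep(dp[1], r))
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, nrow = dp[1], ncol = ncol(m))
  for (t in seq_along(k))
    out <- out + k[t] * mp[t:(t + dp[1] - 1L), , drop = FALSE]
  y <- array(out, dp)
  aperm(y, order(perm))
}

# Standardized correlated Gaussian field on the grid: unit kernel-smoothed
# white noise, normalized to zero mean / unit sd over `which_idx`.
correlated_field <- function(dm, sigma_vox, which_idx) {
  w <- array(stats::rnorm(prod(dm)), dm)
  f <- gauss_smooth3(w, sigma_vox)
  sel <- f[which_idx]
  s <- stats::sd(sel)
  if (!is.finite(s) || s == 0) s <- 1
  (f - mean(sel)) / s
}

#' Generate a synthetic vertebra image/mask pair
#'
#' Builds the phantom described by a [phantom_spec()]: label 1 voxels form an
#' elliptical cylinder of the given height with a high-HU cortical shell and
#' endplates and a correlated Gaussian trabecular interior; label 2 voxels
#' (if requested) form pedicles, lamina and spinous process attached to the
#' posterior (+y) face. Deterministic for a fixed spec and seed.
#'
#' @param spec A `phantom_spec`.
#' @return A list with elements `image` (an `image_volume`) and `mask`
#'   (a `label_mask`) on a shared grid.
#' @export
generate_vertebra_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$voxel_spacing
  a <- spec$body_half_axes[1]; b <- spec$body_half_axes[2]
  h <- spec$body_height; mg <- spec$margin
  post_depth <- if (spec$include_posterior) 0.45 * b + 11 else 0
  extent <- c(2 * a + 2 * mg, 2 * b + 2 * mg + post_depth, h + 2 * mg)
  dm <- ceiling(extent / sp)
  ax_names <- c("x", "y", "z")
  for (axn in 1:3) {
    need <- c(2 * a, 2 * b, h)[axn]
    if (floor(need / sp[axn]) < 2)
      stopf("grid too small along %s: body extent %.1f mm < 2 voxels at spacing %.1f mm",
            ax_names[axn], need, sp[axn])
  }
  cx <- mg + a; cy <- mg + b; z0 <- mg; z1 <- mg + h
  xs <- (seq_len(dm[1]) - 0.5) * sp[1]
  ys <- (seq_len(dm[2]) - 0.5) * sp[2]
  zs <- (seq_len(dm[3]) - 0.5) * sp[3]
  X <- array(rep(xs, times = dm[2] * dm[3]), dm)
  Y <- array(rep(rep(ys, each = dm[1]), times = dm[3]), dm)
  Z <- array(rep(zs, each = dm[1] * dm[2]), dm)

  rr <- ((X - cx) / a)^2 + ((Y - cy) / b)^2
  in_z <- Z >= z0 & Z <= z1
  body <- rr <= 1 & in_z
  t <- spec$shell_thickness
  inner <- ((X - cx) / (a - t))^2 + ((Y - cy) / (b - t))^2 <= 1 &
    Z >= z0 + t & Z <= z1 - t
  shell <- body & !inner
  labels <- array(0L, dm)
  labels[body] <- 1L

  if (spec$include_posterior) {
    zc <- (z0 + z1) / 2
    ped_r <- max(2.5, 0.16 * min(a, b))
    y_surf <- cy + b          # posterior extremity of the body (midline)
    ped_len <- 6
    ped <- ((X - (cx - 0.5 * a))^2 + (Z - zc)^2 <= ped_r^2 |
              (X - (cx + 0.5 * a))^2 + (Z - zc)^2 <= ped_r^2) &
      Y >= cy & Y <= y_surf + ped_len
    lam <- abs(X - cx) <= 0.55 * a & Y >= y_surf + ped_len - 0.5 &
      Y <= y_surf + ped_len + 2.5 & abs(Z - zc) <= 3
    spin <- abs(X - cx) <= 2 & Y >= y_surf + ped_len + 2 &
      Y <= y_surf + ped_len + 10 & abs(Z - zc) <= 4
    post <- (ped | lam | spin) & labels == 0L
    labels[post] <- 2L
  }

  values <- array(0, dm)  # soft-tissue/water background at 0 HU
  fg <- labels > 0L
  interior <- labels == 1L & !shell
  with_seed(spec$seed, {
    if (spec$trab_hu_sd > 0 || spec$include_posterior) {
      sel <- if (any(interior)) which(interior) else which(fg)
      f <- correlated_field(dm, spec$trab_correlation_length / sp, sel)
    } else f <- array(0, dm)
  })
  values[interior] <- spec$trab_hu_mean + spec$trab_hu_sd * f[interior]
  values[shell] <- spec$shell_hu
  if (spec$include_posterior) {
    post_idx <- labels == 2L
    values[post_idx] <- spec$posterior_hu + spec$trab_hu_sd * f[post_idx]
  }
  list(image = image_volume(values, spacing = sp),
       mask = label_mask(labels, spacing = sp))
}

#' Strip posterior elements from a mask
#'
#' Relabels all label-2 voxels as background, leaving the body untouched;
#' used to compare the same phantom with and without posterior elements.
#'
#' @param mask A `label_mask`.
#' @export
strip_posterior <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  l <- mask$labels
  l[l == 2L] <- 0L
  label_mask(l, spacing = mask$spacing, origin = mask$origin)
}

#' Apply contrast-medium enhancement
#'
#' Adds a smooth random HU offset field (mean `hu_offset_mean`, spatial sd
#' `hu_offset_sd`) to all labelled voxels; background is unchanged.
#' Deterministic for a fixed seed. With `hu_offset_sd = 0` every labelled
#' voxel is raised by exactly the mean.
#'
#' @param img An `image_volume`.
#' @param mask The matching `label_mask`.
#' @param c A `contrast_spec`.
#' @return A new `image_volume`.
#' @export
apply_contrast <- function(img, mask, c = contrast_spec()) {
  stopifnot(inherits(img, "image_volume"), inherits(mask, "label_mask"),
            inherits(c, "contrast_spec"))
  check_same_grid(img, mask)
  fg <- which(mask$labels > 0L)
  if (length(fg) == 0L) return(img)
  values <- img$values
  if (c$hu_offset_sd > 0) {
    with_seed(c$seed, {
      f <- correlated_field(grid_dim(img), c$correlation_length / img$spacing, fg)
    })
    offset <- c$hu_offset_mean + c$hu_offset_sd * f[fg]
  } else {
    offset <- rep(c$hu_offset_mean, length(fg))
  }
  values[fg] <- values[fg] + offset
  image_volume(values, spacing = img$spacing, origin = img$origin)
}

#' Resample slice thickness by block averaging
#'
#' Emulates thick-slice reconstruction (partial-volume averaging): groups of
#' `factor` consecutive slices along `axis` are averaged into one and the
#' spacing along that axis is multiplied by `factor`. Trailing remainder
#' slices are dropped. Label masks are resampled by per-voxel majority vote
#' over the slice group, with ties resolved toward foreground (and toward the
#' body among foreground labels).
#'
#' @param img An `image_volume` or `label_mask`.
#' @param axis Axis index (1, 2 or 3) along which slices are stacked.
#' @param factor Integer >= 1; number of slices merged into one.
#' @return Object of the same class on the coarsened grid.
#' @export
resample_slice_thickness <- function(img, axis, factor) {
  UseMethod("resample_slice_thickness")
}

slab_index <- function(n, factor) {
  m <- n %/% factor
  if (m < 1) stopf("factor (%d) exceeds slice count (%d)", factor, n)
  m
}

# Reorder so the resampled axis comes first; returns permutation used.
to_first <- function(arr, axis) aperm(arr, c(axis, setdiff(1:3, axis)))

#' @export
resample_slice_thickness.image_volume <- function(img, axis, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stopf("factor must be >= 1")
  if (factor == 1L) return(img)
  dm <- grid_dim(img)
  m <- slab_index(dm[axis], factor)
  x <- to_first(img$values, axis)
  x <- x[seq_len(m * factor), , , drop = FALSE]
  dim(x) <- c(factor, m, dm[setdiff(1:3, axis)])
  out <- colMeans(x)                      # averages over the slice group
  perm <- c(axis, setdiff(1:3, axis))
  out <- aperm(array(out, c(m, dm[setdiff(1:3, axis)])), order(perm))
  spacing <- img$spacing; spacing[axis] <- spacing[axis] * factor
  image_volume(out, spacing = spacing, origin = img$origin)
}

#' @export
resample_slice_thickness.label_mask <- function(img, axis, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stopf("factor must be >= 1")
  if (factor == 1L) return(img)
  dm <- grid_dim(img)
  m <- slab_index(dm[axis], factor)
  x <- to_first(img$labels, axis)
  x <- x[seq_len(m * factor), , , drop = FALSE]
  dim(x) <- c(factor, m * prod(dm[setdiff(1:3, axis)]))
  labs <- sort(unique(as.integer(x)))
  counts <- vapply(labs, function(l) colSums(x == l), numeric(ncol(x)))
  counts <- matrix(counts, ncol = length(labs))
  # majority vote; ties resolved toward foreground, then the lower label
  n_fg <- if (any(labs > 0)) rowSums(counts[, labs > 0, drop = FALSE]) else 0
  win <- labs[max.col(counts, ties.method = "first")]
  if (0L %in% labs) {
    bg_count <- counts[, match(0L, labs)]
    tied_bg <- win == 0L & n_fg >= bg_count & n_fg > 0
    if (any(tied_bg)) {
      fg_counts <- counts[, labs > 0, drop = FALSE]
      fg_labs <- labs[labs > 0]
      win[tied_bg] <- fg_labs[max.col(fg_counts[tied_bg, , drop = FALSE],
                                      ties.method = "first")]
    }
  }
  out <- array(win, c(m, dm[setdiff(1:3, axis)]))
  perm <- c(axis, setdiff(1:3, axis))
  out <- aperm(out, order(perm))
  spacing <- img$spacing; spacing[axis] <- spacing[axis] * factor
  label_mask(out, spacing = spacing, origin = img$origin)
}

#' Generate a paired healthy / weakened cohort
#'
#' Draws `n_pairs` subjects with between-subject anatomical and HU variation
#' around `base_spec`. Each pair shares geometry and noise seed; the
#' "weakened" member (fractured-analog) has its trabecular and shell HU
#' reduced so that the density-derived strength limits drop by approximately
#' `strength_decrement_fraction` (the apparent density is scaled by
#' `(1 - d)^(1/1.88)`, the reciprocal of the strength-density exponent).
#' As the decrement tends to 0 the paired phantoms become identical.
#'
#' @param c A `cohort_spec`.
#' @return A list of length `2 * n_pairs`; each element has `image`, `mask`,
#'   `pair_id`, `group` ("healthy" or "weakened"), `phantom_id` and `seed`.
#'   The cohort manifest is attached as attribute `"manifest"` (data frame).
#' @export
generate_cohort <- function(c) {
  stopifnot(inherits(c, "cohort_spec"))
  bs <- c$base_spec
  n <- c$n_pairs
  subj <- with_seed(c$seed, list(
    trab = bs$trab_hu_mean + stats::rnorm(n, 0, 25),
    shell = bs$shell_hu + stats::rnorm(n, 0, 40),
    scale_a = stats::runif(n, 0.95, 1.05),
    scale_b = stats::runif(n, 0.95, 1.05),
    seeds = vapply(seq_len(n), function(i) derive_seed(c$seed, i), 1L)
  ))
  r <- (1 - c$strength_decrement_fraction)^(1 / 1.88)
  weaken_hu <- function(hu) ((47 + 1.122 * hu) * r - 47) / 1.122
  out <- vector("list", 2L * n)
  man <- list()
  k <- 0L
  for (i in seq_len(n)) {
    for (grp in c("healthy", "weakened")) {
      sp <- bs
      sp$body_half_axes <- bs$body_half_axes *
        c(subj$scale_a[i], subj$scale_b[i])
      sp$trab_hu_mean <- subj$trab[i]
      sp$shell_hu <- subj$shell[i]
      sp$seed <- subj$seeds[i]
      if (grp == "weakened") {
        sp$trab_hu_mean <- weaken_hu(sp$trab_hu_mean)
        sp$shell_hu <- weaken_hu(sp$shell_hu)
      }
      ph <- generate_vertebra_phantom(sp)
      k <- k + 1L
      out[[k]] <- list(image = ph$image, mask = ph$mask, pair_id = i,
                       group = grp,
                       phantom_id = sprintf("P%02d_%s", i, grp),
                       seed = subj$seeds[i])
      man[[k]] <- data.frame(phantom_id = out[[k]]$phantom_id, pair_id = i,
                             group = grp, seed = subj$seeds[i])
    }
  }
  attr(out, "manifest") <- do.call(rbind, man)
  out
}

#' @rdname generate_cohort
#' @param cohort The list returned by `generate_cohort`.
#' @export
cohort_manifest <- function(cohort) attr(cohort, "manifest")

#' @rdname generate_cohort
#' @param dir Output directory; one NIfTI image/mask pair per phantom plus
#'   `manifest.csv` (phantom id, pair id, group, seed, file paths).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort_manifest(cohort)
  man$image_path <- file.path(dir, paste0(man$phantom_id, "_image.nii.gz"))
  man$mask_path <- file.path(dir, paste0(man$phantom_id, "_mask.nii.gz"))
  for (i in seq_along(cohort)) {
    write_volume(cohort[[i]]$image, man$image_path[i])
    write_volume(cohort[[i]]$mask, man$mask_path[i])
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
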