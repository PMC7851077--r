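#' CT-like image volumes and label masks
#'
#' An `image_volume` holds a 3D scalar field of Hounsfield units on a regular
#' grid with voxel spacing and world origin in mm. A `label_mask` holds small
#' non-negative integer labels on the same grid (0 = background, 1 = vertebral
#' body, 2 = posterior elements).
#'
#' World convention: the centre of voxel (i, j, k) (1-based array indices)
#' lies at `origin + (i - 0.5, j - 0.5, k - 0.5) * spacing`; the volume spans
#' `[origin, origin + dim * spacing]`. Axis 3 (z) is the superior-inferior
#' axis of the vertebra.
#'
#' @param values 3D numeric array of HU values (finite).
#' @param spacing Voxel spacing in mm, length-3 positive numeric.
#' @param origin World coordinate (mm) of the volume's corner, length 3.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stopf("`values` must be a 3D array (got %s dimensions)",
          if (is.array(values)) length(dim(values)) else "no")
  if (!all(is.finite(values))) stopf("`values` must be finite")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("`spacing` must be 3 positive numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stopf("`origin` must be 3 finite numbers")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @param labels 3D array of small non-negative integers.
#' @rdname image_volume
#' @export
label_mask <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stopf("`labels` must be a 3D array")
  if (any(labels < 0) || any(labels != round(labels)))
    stopf("`labels` must be non-negative integers")
  v <- image_volume(array(as.integer(labels), dim(labels)), spacing, origin)
  structure(list(labels = v$values, spacing = v$spacing, origin = v$origin),
            class = "label_mask")
}

#' @export
#' @method print image_volume
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
#' @method print label_mask
print.label_mask <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<label_mask> %s voxels, labels: %s\n",
              paste(dim(x$labels), collapse = "x"),
              paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

grid_dim <- function(x) dim(if (inherits(x, "label_mask")) x$labels else x$values)

same_grid <- function(a, b) {
  identical(grid_dim(a), grid_dim(b)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

check_same_grid <- function(img, mask) {
  if (!same_grid(img, mask))
    stopf("image and mask must share grid shape, spacing and origin")
  invisible(TRUE)
}

#' Read / write volumes as NIfTI
#'
#' Spacing and origin are carried in the NIfTI sform (code 2, axis-aligned).
#' Only 3D volumes are accepted; non-3D data is an error.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns an `image_volume`; `read_label_mask` a
#'   `label_mask`; the writers return `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("file does not exist: %s", path)
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) != 3L)
    stopf("expected 3D data in %s, got dim = (%s)", path,
          paste(dim(arr), collapse = ", "))
  x <- RNifti::xform(nii)
  if (is.matrix(x) && all(dim(x) == c(4, 4)) && any(x[1:3, 1:3] != 0)) {
    spacing <- sqrt(colSums(x[1:3, 1:3]^2))
    origin <- x[1:3, 4]
  } else {
    spacing <- RNifti::pixdim(nii)[1:3]
    origin <- c(0, 0, 0)
  }
  image_volume(arr, spacing = spacing, origin = origin)
}

#' @param vol An `image_volume` or `label_mask`.
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  arr <- if (inherits(vol, "label_mask")) vol$labels else vol$values
  nii <- RNifti::asNifti(arr)
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  nii <- RNifti::`sform<-`(nii, structure(m, code = 2L))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_label_mask <- function(path) {
  v <- read_volume(path)
  label_mask(round(v$values), spacing = v$spacing, origin = v$origin)
}

# World coordinates of all voxel centres along one axis.
axis_centers <- function(vol, axis) {
  n <- grid_dim(vol)[axis]
  vol$origin[axis] + (seq_len(n) - 0.5) * vol$spacing[axis]
}

#' Mean HU over the voxel centres inside a tetrahedron
#'
#' Averages the image over voxels whose centres lie inside (or on the
#' boundary of) the tetrahedron; when no centre is contained, falls back to
#' the voxel nearest the centroid. The result is invariant under permutation
#' of the four vertices.
#'
#' @param img An `image_volume`.
#' @param tet_vertices 4x3 matrix of vertex coordinates in mm.
#' @return Mean HU (scalar).
#' @export
element_mean_hu <- function(img, tet_vertices) {
  v <- as.matrix(tet_vertices)
  if (!all(dim(v) == c(4, 3))) stopf("`tet_vertices` must be 4x3")
  d <- rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ])
  vol6 <- det(t(d))
  if (abs(vol6) < 1e-12)
    stopf("degenerate (zero-volume) tetrahedron")
  dm <- grid_dim(img)
  lo <- img$origin; hi <- img$origin + dm * img$spacing
  if (any(apply(v, 2, min) < lo - 1e-9) || any(apply(v, 2, max) > hi + 1e-9))
    stopf("tetrahedron extends outside the image volume")
  # candidate voxels from the bounding box
  idx <- lapply(1:3, function(a) {
    r <- range(v[, a])
    i0 <- max(1L, floor((r[1] - img$origin[a]) / img$spacing[a] + 0.5))
    i1 <- min(dm[a], ceiling((r[2] - img$origin[a]) / img$spacing[a] + 0.5))
    if (i0 > i1) integer(0) else i0:i1
  })
  inside_vals <- numeric(0)
  if (all(lengths(idx) > 0)) {
    g <- expand.grid(i = idx[[1]], j = idx[[2]], k = idx[[3]])
    pts <- cbind(img$origin[1] + (g$i - 0.5) * img$spacing[1],
                 img$origin[2] + (g$j - 0.5) * img$spacing[2],
                 img$origin[3] + (g$k - 0.5) * img$spacing[3])
    lam <- barycentric(v, pts)
    tol <- 1e-9
    ok <- lam[, 1] >= -tol & lam[, 2] >= -tol & lam[, 3] >= -tol &
      lam[, 4] >= -tol
    if (any(ok))
      inside_vals <- img$values[cbind(g$i[ok], g$j[ok], g$k[ok])]
  }
  if (length(inside_vals) > 0) return(mean(inside_vals))
  cen <- colMeans(v)
  ci <- pmin(pmax(round((cen - img$origin) / img$spacing + 0.5), 1), dm)
  img$values[ci[1], ci[2], ci[3]]
}

# Barycentric coordinates of points `pts` (n x 3) w.r.t. tetrahedron `v` (4x3).
barycentric <- function(v, pts) {
  A <- cbind(v[1, ] - v[4, ], v[2, ] - v[4, ], v[3, ] - v[4, ])
  rel <- sweep(pts, 2, v[4, ])
  lam123 <- t(solve(A, t(rel)))
  cbind(lam123, 1 - rowSums(lam123))
}
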