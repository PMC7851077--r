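#' Voxel region to linear tetrahedral mesh
#'
#' Coarsens the labelled voxel region to cubic cells of side approximately
#' `target_edge_mm` (a cell is kept when at least half of its voxels are
#' foreground), then splits every kept cell into 6 conforming linear
#' tetrahedra sharing the cell's main diagonal (Kuhn split). Element labels
#' (body = 1, posterior = 2) are inherited by majority vote over the cell's
#' foreground voxels, ties toward the body.
#'
#' @param mask A `label_mask` with at least one foreground voxel.
#' @param img Optional `image_volume` on the same grid (stored for mapping).
#' @param target_edge_mm Requested cell edge length, mm; must be at least the
#'   largest voxel spacing.
#' @return A `tet_mesh`: list with `nodes` (n x 3, mm), `tets` (m x 4 node
#'   indices, positively oriented), `element_label`, `node_sets` (empty until
#'   [extract_boundary_sets()]), and structured-grid metadata used by the
#'   fast material-mapping path.
#' @export
voxel_to_tet <- function(mask, img = NULL, target_edge_mm) {
  stopifnot(inherits(mask, "label_mask"))
  if (!is.null(img)) check_same_grid(img, mask)
  if (!any(mask$labels > 0L)) stopf("mask is empty: no foreground voxels")
  sp <- mask$spacing
  if (target_edge_mm < max(sp) - 1e-9)
    stopf("target_edge_mm (%.2f) must be >= max voxel spacing (%.2f)",
          target_edge_mm, max(sp))
  k <- pmax(1L, as.integer(round(target_edge_mm / sp)))
  dm <- grid_dim(mask)
  nc <- dm %/% k
  if (any(nc < 1L)) stopf("mask grid too small for target edge length")

  # block-reduce label counts to cells
  crop <- mask$labels[seq_len(nc[1] * k[1]), seq_len(nc[2] * k[2]),
                      seq_len(nc[3] * k[3]), drop = FALSE]
  count_label <- function(l) block_sum(crop == l, k, nc)
  n_vox <- prod(k)
  c1 <- count_label(1L); c2 <- count_label(2L)
  keep <- (c1 + c2) >= n_vox / 2
  if (!any(keep)) stopf("mask is empty after coarsening: no cell is at least half foreground")
  cell_idx <- which(keep, arr.ind = TRUE)          # M x 3 cell indices
  lab <- ifelse(c2[keep] > c1[keep], 2L, 1L)       # ties toward body

  # node grid at cell corners; only nodes used by kept cells are emitted
  nn <- nc + 1L
  node_id <- function(i, j, kk) (kk - 1L) * nn[1] * nn[2] + (j - 1L) * nn[1] + i
  corner <- kuhn_corners()
  M <- nrow(cell_idx)
  glob <- matrix(0L, M, 8)
  for (cc in 1:8)
    glob[, cc] <- node_id(cell_idx[, 1] + corner[cc, 1],
                          cell_idx[, 2] + corner[cc, 2],
                          cell_idx[, 3] + corner[cc, 3])
  used <- sort(unique(as.integer(glob)))
  remap <- integer(nn[1] * nn[2] * nn[3])
  remap[used] <- seq_along(used)
  # node coordinates (cell corners sit on voxel boundaries)
  u0 <- used - 1L
  ci <- u0 %% nn[1]; cj <- (u0 %/% nn[1]) %% nn[2]; ck <- u0 %/% (nn[1] * nn[2])
  nodes <- cbind(mask$origin[1] + ci * k[1] * sp[1],
                 mask$origin[2] + cj * k[2] * sp[2],
                 mask$origin[3] + ck * k[3] * sp[3])

  lt <- kuhn_tets()                                # 6 x 4 local corner ids
  tets <- matrix(0L, 6L * M, 4)
  for (t in 1:6)
    tets[seq.int(t, by = 6L, length.out = M), ] <-
      matrix(remap[glob[, lt[t, ]]], M, 4)
  element_label <- rep(lab, each = 6L)
  mesh <- structure(list(nodes = nodes, tets = tets,
                         element_label = element_label,
                         node_sets = list(),
                         cell_index = cell_idx, vox_per_cell = k,
                         local_tet = rep(1:6, times = M),
                         spacing = sp, origin = mask$origin,
                         target_edge_mm = target_edge_mm,
                         image = img, mask = mask),
                    class = "tet_mesh")
  stopifnot(min(tet_volumes(mesh)) > 0)
  mesh
}

# Sum of `arr` (logical/numeric) over k-blocks; returns array of dim nc.
block_sum <- function(arr, k, nc) {
  dim(arr) <- c(k[1], nc[1], k[2], nc[2], k[3], nc[3])
  x <- aperm(arr, c(1, 3, 5, 2, 4, 6))
  dim(x) <- c(prod(k), prod(nc))
  array(colSums(x), nc)
}

# Cube corner offsets (0/1) indexed 1..8.
kuhn_corners <- function() {
  as.matrix(expand.grid(i = 0:1, j = 0:1, k = 0:1))
}

# Six tetrahedra of the Kuhn split, as rows of corner ids into
# kuhn_corners(), each positively oriented. All share the main diagonal
# (0,0,0)-(1,1,1), making the split conforming across identical cells.
kuhn_tets <- function() {
  corner_id <- function(v) 1L + v[1] + 2L * v[2] + 4L * v[3]
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- matrix(0L, 6, 4)
  ey <- diag(3)
  for (p in seq_len(6)) {
    v <- c(0, 0, 0)
    ids <- corner_id(v)
    for (step in 1:3) {
      v <- v + ey[perms[p, step], ]
      ids <- c(ids, corner_id(v))
    }
    # fix orientation: signed volume sign equals the permutation's sign
    verts <- kuhn_corners()[ids, ]
    vol <- det(rbind(verts[2, ] - verts[1, ], verts[3, ] - verts[1, ],
                     verts[4, ] - verts[1, ]))
    if (vol < 0) ids[3:4] <- ids[4:3]
    out[p, ] <- ids
  }
  out
}

#' Signed tetrahedron volumes of a mesh
#'
#' @param mesh A `tet_mesh`.
#' @return Numeric vector of element volumes (mm^3), positive for a valid mesh.
#' @export
tet_volumes <- function(mesh) {
  n <- mesh$nodes; t <- mesh$tets
  a <- n[t[, 2], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  b <- n[t[, 3], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  d <- n[t[, 4], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
     a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
     a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

#' @rdname tet_volumes
#' @export
mesh_volume <- function(mesh) sum(tet_volumes(mesh))

# All faces (sorted node triples) with their multiplicity; key encodes the
# triple as a double (safe below ~2^17 nodes).
face_table <- function(tets, n_nodes) {
  f <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
             tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  lo <- pmin(f[, 1], f[, 2], f[, 3])
  hi <- pmax(f[, 1], f[, 2], f[, 3])
  mid <- f[, 1] + f[, 2] + f[, 3] - lo - hi
  fs <- cbind(lo, mid, hi)
  key <- (fs[, 1] - 1) * n_nodes^2 + (fs[, 2] - 1) * n_nodes + fs[, 3]
  list(faces = fs, key = key)
}

boundary_node_ids <- function(tets, n_nodes) {
  ft <- face_table(tets, n_nodes)
  once <- !(duplicated(ft$key) | duplicated(ft$key, fromLast = TRUE))
  unique(as.integer(ft$faces[once, ]))
}

#' Extract inferior/superior boundary node sets of the vertebral body
#'
#' Finds the surface nodes of the body-labelled sub-mesh and fills
#' `node_sets$inferior_body` (surface nodes within `band_fraction` of the
#' body's minimum z) and `node_sets$superior_body` (analogous at maximum z).
#' Nodes belonging to posterior elements are never included, so the fixed
#' support and the displacement load act on the vertebral body only.
#'
#' @param mesh A `tet_mesh` with body-labelled elements.
#' @param band_fraction Band height as a fraction of the body z-extent.
#' @return The mesh with `node_sets` filled (disjoint, non-empty).
#' @export
extract_boundary_sets <- function(mesh, band_fraction = 0.02) {
  stopifnot(inherits(mesh, "tet_mesh"))
  body <- mesh$tets[mesh$element_label == 1L, , drop = FALSE]
  if (nrow(body) == 0L) stopf("mesh has no body-labelled elements")
  surf <- boundary_node_ids(body, nrow(mesh$nodes))
  post_nodes <- unique(as.integer(
    mesh$tets[mesh$element_label == 2L, , drop = FALSE]))
  surf <- setdiff(surf, post_nodes)
  z <- mesh$nodes[, 3]
  zr <- range(z[unique(as.integer(body))])
  band <- band_fraction * (zr[2] - zr[1])
  inf_set <- surf[z[surf] <= zr[1] + band + 1e-9]
  sup_set <- surf[z[surf] >= zr[2] - band - 1e-9]
  if (length(inf_set) == 0L || length(sup_set) == 0L)
    stopf("boundary band produced an empty node set; geometry too thin for band_fraction = %g",
          band_fraction)
  if (length(intersect(inf_set, sup_set)) > 0L)
    stopf("inferior and superior bands overlap; reduce band_fraction")
  mesh$node_sets <- list(inferior_body = sort(inf_set),
                         superior_body = sort(sup_set))
  mesh
}

#' Drop posterior elements from a mesh
#'
#' Returns the sub-mesh of body-labelled elements with nodes renumbered and
#' unused nodes removed, leaving the body discretisation bit-identical to
#' the input mesh. This is the clean way to compare a vertebra with and
#' without posterior elements: re-meshing a stripped mask would also change
#' the body cells at the junction.
#'
#' @param mesh A `tet_mesh`.
#' @return A `tet_mesh` containing only label-1 elements (node sets cleared;
#'   re-run [extract_boundary_sets()]).
#' @export
drop_posterior_elements <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  keep <- mesh$element_label == 1L
  if (!any(keep)) stopf("mesh has no body-labelled elements")
  tets <- mesh$tets[keep, , drop = FALSE]
  used <- sort(unique(as.integer(tets)))
  remap <- integer(nrow(mesh$nodes))
  remap[used] <- seq_along(used)
  out <- mesh
  out$nodes <- mesh$nodes[used, , drop = FALSE]
  out$tets <- matrix(remap[tets], ncol = 4)
  out$element_label <- mesh$element_label[keep]
  out$node_sets <- list()
  if (!is.null(mesh$cell_index)) {
    cell_keep <- keep[seq.int(1L, nrow(mesh$tets), by = 6L)]
    out$cell_index <- mesh$cell_index[cell_keep, , drop = FALSE]
    out$local_tet <- mesh$local_tet[keep]
  }
  out
}

#' @export
#' @method print tet_mesh
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d tetrahedra (%d body, %d posterior), volume %.0f mm^3\n",
              nrow(x$nodes), nrow(x$tets), sum(x$element_label == 1L),
              sum(x$element_label == 2L), mesh_volume(x)))
  if (length(x$node_sets))
    cat(sprintf("  node sets: %s\n",
                paste(sprintf("%s (n=%d)", names(x$node_sets),
                              lengths(x$node_sets)), collapse = ", ")))
  invisible(x)
}

#' Export a mesh (and materials) as an Abaqus-dialect .inp file
#'
#' Writes nodes, C3D4 elements, element sets and, when a material table is
#' given, per-bin `*SOLID SECTION` / `*MATERIAL` cards with engineering
#' constants. Element axial moduli are grouped into `n_bins` equal-width bins
#' for export practicality; in-memory analyses always use per-element
#' materials.
#'
#' @param mesh A `tet_mesh`.
#' @param path Output file path.
#' @param materials Optional material table from [map_mesh()].
#' @param n_bins Number of modulus bins for the export.
#' @export
write_abaqus_inp <- function(mesh, path, materials = NULL, n_bins = 100) {
  con <- file(path, "w")
  on.exit(close(con))
  wr <- function(...) writeLines(sprintf(...), con)
  wr("*HEADING")
  wr("vertfe voxel-based tetrahedral vertebra model")
  wr("*NODE")
  writeLines(sprintf("%d, %.6g, %.6g, %.6g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  wr("*ELEMENT, TYPE=C3D4, ELSET=ALL")
  writeLines(sprintf("%d, %d, %d, %d, %d", seq_len(nrow(mesh$tets)),
                     mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                     mesh$tets[, 4]), con)
  for (nm in names(mesh$node_sets)) {
    wr("*NSET, NSET=%s", toupper(nm))
    ids <- mesh$node_sets[[nm]]
    writeLines(sapply(split(ids, ceiling(seq_along(ids) / 8)),
                      paste, collapse = ", "), con)
  }
  if (!is.null(materials)) {
    ez <- materials$Ez
    br <- seq(min(ez), max(ez), length.out = n_bins + 1)
    bin <- pmin(pmax(findInterval(ez, br, rightmost.closed = TRUE), 1L), n_bins)
    for (b in sort(unique(bin))) {
      ids <- which(bin == b)
      wr("*ELSET, ELSET=MATBIN%d", b)
      writeLines(sapply(split(ids, ceiling(seq_along(ids) / 8)),
                        paste, collapse = ", "), con)
      wr("*SOLID SECTION, ELSET=MATBIN%d, MATERIAL=MAT%d", b, b)
      m <- materials[ids[1], ]
      wr("*MATERIAL, NAME=MAT%d", b)
      wr("*ELASTIC, TYPE=ENGINEERING CONSTANTS")
      wr("%.6g, %.6g, %.6g, %.4g, %.4g, %.4g, %.6g, %.6g",
         m$Ex, m$Ey, m$Ez, m$nu_xy, m$nu_xz, m$nu_xz, m$Gxy, m$Gxz)
      wr("%.6g", m$Gyz)
    }
  }
  invisible(path)
}

#' Mesh sensitivity study
#'
#' Runs the full failure-load pipeline at each requested cell edge length and
#' reports element count, failure load and the relative change between
#' consecutive edges, mirroring the convergence study practitioners run to
#' pick a mesh-independent element size.
#'
#' @param mask,img Phantom mask and image.
#' @param edges Cell edge lengths in mm (e.g. `c(1, 1.5, 2, 2.5, 3)`).
#' @param ... Passed to [vertebra_failure_load()].
#' @return data.frame with columns `edge_mm`, `n_elements`, `failure_load`,
#'   `rel_change` (NA for the first row).
#' @export
mesh_sensitivity_study <- function(mask, img, edges, ...) {
  rows <- lapply(edges, function(e) {
    r <- vertebra_failure_load(img, mask, edge_mm = e, ...)
    data.frame(edge_mm = e, n_elements = nrow(r$mesh$tets),
               failure_load = r$result$failure_load)
  })
  out <- do.call(rbind, rows)
  out$rel_change <- c(NA, diff(out$failure_load) /
                        utils::head(out$failure_load, -1))
  out
}
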