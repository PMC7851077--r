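#' Density and material-property mapping
#'
#' The quantitative-CT material chain: Hounsfield units are converted to
#' apparent density (mg/cm^3), apparent density to ash density (g/cm^3), and
#' densities to transversely isotropic elastic moduli (MPa, z = the
#' superior-inferior axis) and principal-stress strength limits (MPa) with a
#' plastic strain parameter. Units follow a consistent mm-MPa-N system.
#'
#' Low-attenuation voxels (fat, marrow) drive the affine relations negative,
#' so apparent density is clamped below at `floor_rho` (1 mg/cm^3), the axial
#' modulus at `floor_E` (0.01 MPa) and the plastic strain parameter at 0.
#'
#' @param hu Hounsfield units (vectorised).
#' @param floor_rho Lower clamp for apparent density, mg/cm^3.
#' @return `hu_to_apparent_density`: apparent density in mg/cm^3.
#' @export
hu_to_apparent_density <- function(hu, floor_rho = 1) {
  if (any(!is.finite(hu))) stopf("HU values must be finite")
  pmax(47 + 1.122 * hu, floor_rho)
}

#' @param rho_app Apparent density, mg/cm^3 (vectorised).
#' @rdname hu_to_apparent_density
#' @return `apparent_to_ash`: ash density in g/cm^3 (0.6 of apparent density,
#'   with the mg-to-g unit change).
#' @export
apparent_to_ash <- function(rho_app) {
  if (any(rho_app < 0)) stopf("rho_app must be >= 0")
  0.6 * rho_app / 1000
}

#' @param floor_E Lower clamp for the axial modulus, MPa.
#' @rdname hu_to_apparent_density
#' @return `density_to_moduli`: data.frame with axial modulus `Ez`
#'   (`-349 + 5.82 * rho_app`, clamped), transverse moduli
#'   `Ex = Ey = 0.333 Ez` and shear moduli `Gxy = 0.121 Ez`,
#'   `Gxz = Gyz = 0.157 Ez` (ratios applied to the clamped Ez).
#' @export
density_to_moduli <- function(rho_app, floor_E = 0.01) {
  if (any(rho_app < 0)) stopf("rho_app must be >= 0")
  Ez <- pmax(-349 + 5.82 * rho_app, floor_E)
  data.frame(Ez = Ez, Ex = 0.333 * Ez, Ey = 0.333 * Ez,
             Gxy = 0.121 * Ez, Gxz = 0.157 * Ez, Gyz = 0.157 * Ez)
}

#' @param rho_ash Ash density, g/cm^3 (vectorised).
#' @rdname hu_to_apparent_density
#' @return `strength_limits`: data.frame with the maximum principal stress
#'   limit `sigma_max` (`137 * rho_ash^1.88` below the 0.317 g/cm^3 branch
#'   point, `114 * rho_ash^1.72` at and above it; the branches agree within
#'   2% there), the minimum principal stress limit magnitude
#'   `sigma_min = 65.1 * rho_ash^1.93`, and the plastic strain parameter
#'   `eps_AB = -0.00315 + 0.0728 * rho_ash` clamped below at 0.
#' @export
strength_limits <- function(rho_ash) {
  if (any(rho_ash < 0)) stopf("rho_ash must be >= 0")
  sigma_max <- ifelse(rho_ash < 0.317,
                      137 * rho_ash^1.88,
                      114 * rho_ash^1.72)
  data.frame(sigma_max = sigma_max,
             sigma_min = 65.1 * rho_ash^1.93,
             eps_AB = pmax(-0.00315 + 0.0728 * rho_ash, 0))
}

#' Default Poisson ratios for vertebral bone
#'
#' The transversely isotropic moduli ratios come with no published Poisson
#' ratios here; these defaults (in-plane `nu_xy` = 0.381, out-of-plane
#' `nu_xz` = `nu_yz` = 0.104, strain-per-strain under in-plane stress) are in
#' the range used for trabecular bone and keep the 6x6 elasticity tensor
#' symmetric positive definite for the whole physiological HU range.
#'
#' @export
default_poisson <- function() c(nu_xy = 0.381, nu_xz = 0.104)

#' Transversely isotropic elasticity tensor (6x6, Voigt)
#'
#' Builds the stiffness tensor from the axial modulus and the fixed ratios
#' (`Ex = Ey = 0.333 Ez`, `Gxy = 0.121 Ez`, `Gxz = Gyz = 0.157 Ez`), with
#' the material z-axis aligned to the global z-axis. Voigt order
#' (xx, yy, zz, yz, xz, xy) with engineering shear strains. Since every
#' modulus is proportional to `Ez` and the Poisson ratios are fixed, the
#' tensor is `Ez` times a unit-modulus tensor; that unit tensor is cached.
#'
#' @param Ez Axial elastic modulus, MPa (scalar).
#' @param nu_xy,nu_xz Poisson ratios.
#' @return 6x6 numeric matrix (MPa). Errors if the tensor is not positive
#'   definite.
#' @export
elastic_tensor <- function(Ez, nu_xy = 0.381, nu_xz = 0.104) {
  C <- Ez * unit_elastic_tensor(nu_xy, nu_xz)
  C
}

unit_tensor_cache <- new.env(parent = emptyenv())

unit_elastic_tensor <- function(nu_xy = 0.381, nu_xz = 0.104) {
  key <- sprintf("%.10g_%.10g", nu_xy, nu_xz)
  if (!is.null(unit_tensor_cache[[key]])) return(unit_tensor_cache[[key]])
  Ex <- 0.333; Ez <- 1
  S <- matrix(0, 6, 6)
  S[1, 1] <- S[2, 2] <- 1 / Ex
  S[3, 3] <- 1 / Ez
  S[1, 2] <- S[2, 1] <- -nu_xy / Ex
  S[1, 3] <- S[3, 1] <- S[2, 3] <- S[3, 2] <- -nu_xz / Ex
  S[4, 4] <- S[5, 5] <- 1 / 0.157
  S[6, 6] <- 1 / 0.121
  C <- tryCatch(solve(S), error = function(e) NULL)
  ok <- !is.null(C) && all(eigen(C, symmetric = TRUE,
                                 only.values = TRUE)$values > 0)
  if (!ok) {
    warning("transversely isotropic tensor not positive definite; ",
            "falling back to isotropic nu = 0.3", call. = FALSE)
    nu <- 0.3
    lam <- nu / ((1 + nu) * (1 - 2 * nu)); mu <- 1 / (2 * (1 + nu))
    C <- matrix(0, 6, 6)
    C[1:3, 1:3] <- lam; diag(C)[1:3] <- lam + 2 * mu; diag(C)[4:6] <- mu
  }
  C <- (C + t(C)) / 2
  unit_tensor_cache[[key]] <- C
  C
}

#' Map image HU onto mesh elements as materials
#'
#' Computes one material record per tetrahedron from the element's mean HU
#' (voxel centres inside the element; see [element_mean_hu()]), running the
#' full density-modulus-strength chain. For structured voxel meshes from
#' [voxel_to_tet()] a fast path exploits that all cells are congruent, and
#' gives results identical to the per-element fallback.
#'
#' When a mask is available (`foreground_only = TRUE`, the default for
#' meshes built by [voxel_to_tet()]), the element average is restricted to
#' foreground (labelled) voxels, mirroring how a body-fitted mesh samples
#' bone only; elements whose voxels are all background fall back to the
#' unrestricted mean, then to the centroid voxel.
#'
#' @param mesh A `tet_mesh`.
#' @param img An `image_volume` covering the mesh (defaults to the image
#'   stored on the mesh).
#' @param nu_xy,nu_xz Poisson ratios applied to every element.
#' @param floor_rho,floor_E Clamps forwarded to the mapping chain.
#' @param foreground_only Restrict HU averaging to foreground voxels of
#'   `mask` (ignored when no mask is available).
#' @param mask `label_mask` used for foreground restriction; defaults to the
#'   mask the mesh was built from.
#' @return data.frame of class `element_material_table` with one row per
#'   element: `hu`, `rho_app`, `rho_ash`, moduli, strength limits, `eps_AB`
#'   and the Poisson ratios.
#' @export
map_mesh <- function(mesh, img = mesh$image, nu_xy = 0.381, nu_xz = 0.104,
                     floor_rho = 1, floor_E = 0.01,
                     foreground_only = TRUE, mask = mesh$mask) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (is.null(img)) stopf("no image supplied or stored on the mesh")
  fg <- if (foreground_only && !is.null(mask)) mask$labels > 0L else NULL
  hu <- if (!is.null(mesh$cell_index)) structured_element_hu(mesh, img, fg)
        else apply_element_hu(mesh, img, fg)
  rho_app <- hu_to_apparent_density(hu, floor_rho)
  rho_ash <- apparent_to_ash(rho_app)
  mod <- density_to_moduli(rho_app, floor_E)
  str <- strength_limits(rho_ash)
  out <- cbind(data.frame(element = seq_along(hu), hu = hu,
                          rho_app = rho_app, rho_ash = rho_ash),
               mod, str)
  out$nu_xy <- nu_xy
  out$nu_xz <- nu_xz
  class(out) <- c("element_material_table", "data.frame")
  out
}

apply_element_hu <- function(mesh, img, fg = NULL) {
  vapply(seq_len(nrow(mesh$tets)), function(e) {
    verts <- mesh$nodes[mesh$tets[e, ], ]
    if (is.null(fg)) return(element_mean_hu(img, verts))
    hu_all <- element_mean_hu(img, verts)
    sel <- contained_voxels(img, verts)
    if (nrow(sel) == 0L) return(hu_all)
    keep <- fg[sel]
    if (!any(keep)) return(hu_all)
    mean(img$values[sel[keep, , drop = FALSE]])
  }, numeric(1))
}

# Index matrix (i, j, k) of voxels whose centres lie inside the tetrahedron.
contained_voxels <- function(img, verts) {
  dm <- grid_dim(img)
  idx <- lapply(1:3, function(a) {
    r <- range(verts[, a])
    i0 <- max(1L, floor((r[1] - img$origin[a]) / img$spacing[a] + 0.5))
    i1 <- min(dm[a], ceiling((r[2] - img$origin[a]) / img$spacing[a] + 0.5))
    if (i0 > i1) integer(0) else i0:i1
  })
  if (any(lengths(idx) == 0)) return(matrix(integer(0), 0, 3))
  g <- expand.grid(i = idx[[1]], j = idx[[2]], k = idx[[3]])
  pts <- cbind(img$origin[1] + (g$i - 0.5) * img$spacing[1],
               img$origin[2] + (g$j - 0.5) * img$spacing[2],
               img$origin[3] + (g$k - 0.5) * img$spacing[3])
  lam <- barycentric(verts, pts)
  tol <- 1e-9
  ok <- lam[, 1] >= -tol & lam[, 2] >= -tol & lam[, 3] >= -tol &
    lam[, 4] >= -tol
  as.matrix(g[ok, , drop = FALSE])
}

# Fast path: every cell is congruent, so the assignment of local voxel
# centres to the 6 local tetrahedra is computed once and reused.
structured_element_hu <- function(mesh, img, fg = NULL) {
  k <- mesh$vox_per_cell; sp <- mesh$spacing
  cells <- mesh$cell_index
  M <- nrow(cells)
  loc <- as.matrix(expand.grid(i = seq_len(k[1]), j = seq_len(k[2]),
                               kk = seq_len(k[3])))
  pts <- cbind((loc[, 1] - 0.5) * sp[1], (loc[, 2] - 0.5) * sp[2],
               (loc[, 3] - 0.5) * sp[3])
  corner <- kuhn_corners(); lt <- kuhn_tets()
  cell_mm <- k * sp
  tol <- 1e-9
  membership <- vector("list", 6)
  for (t in 1:6) {
    verts <- sweep(corner[lt[t, ], ], 2, cell_mm, `*`)
    lam <- barycentric(verts, pts)
    membership[[t]] <- which(rowSums(lam >= -tol) == 4L)
  }
  dmimg <- grid_dim(img)
  base <- cbind((cells[, 1] - 1L) * k[1], (cells[, 2] - 1L) * k[2],
                (cells[, 3] - 1L) * k[3])
  hu <- numeric(6L * M)
  for (t in 1:6) {
    mem <- membership[[t]]
    acc <- numeric(M)
    if (length(mem) > 0) {
      if (!is.null(fg)) {
        accf <- numeric(M); cntf <- numeric(M)
        for (m in mem) {
          sel <- cbind(base[, 1] + loc[m, 1], base[, 2] + loc[m, 2],
                       base[, 3] + loc[m, 3])
          v <- img$values[sel]
          f <- fg[sel]
          acc <- acc + v
          accf <- accf + v * f
          cntf <- cntf + f
        }
        vals <- ifelse(cntf > 0, accf / pmax(cntf, 1), acc / length(mem))
      } else {
        for (m in mem) {
          ii <- base[, 1] + loc[m, 1]; jj <- base[, 2] + loc[m, 2]
          kk <- base[, 3] + loc[m, 3]
          acc <- acc + img$values[cbind(ii, jj, kk)]
        }
        vals <- acc / length(mem)
      }
    } else {
      # no voxel centre inside this local tet: centroid-nearest voxel
      verts <- sweep(corner[lt[t, ], ], 2, cell_mm, `*`)
      cen <- colMeans(verts)
      ci <- pmin(pmax(round(cen / sp + 0.5), 1), k)
      ii <- base[, 1] + ci[1]; jj <- base[, 2] + ci[2]; kk <- base[, 3] + ci[3]
      vals <- img$values[cbind(ii, jj, kk)]
    }
    hu[seq.int(t, by = 6L, length.out = M)] <- vals
  }
  hu
}

#' Write the per-element material table as CSV
#'
#' @param materials Table from [map_mesh()].
#' @param path Output CSV path.
#' @export
write_material_table <- function(materials, path) {
  utils::write.csv(as.data.frame(materials), path, row.names = FALSE)
  invisible(path)
}
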