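# Shared fixtures, built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- force(expr)
  fixture_env[[name]]
}

# A reduced vertebra (half-size body) that meshes and solves in well under a
# second; used wherever the full default phantom is not the point.
small_spec <- function(...) {
  phantom_spec(body_half_axes = c(9, 7), body_height = 12,
               shell_thickness = 1.5, trab_correlation_length = 2,
               seed = 7L, ...)
}

small_phantom <- function() cached("small_phantom",
                                   generate_vertebra_phantom(small_spec()))

small_mesh <- function() cached("small_mesh", {
  ph <- small_phantom()
  extract_boundary_sets(voxel_to_tet(ph$mask, ph$image, 2), 0.05)
})

small_materials <- function() cached("small_materials", map_mesh(small_mesh()))

# An all-foreground cuboid mask: nx x ny x nz voxels of label 1.
cuboid_mask <- function(nx, ny, nz, spacing = c(1, 1, 1)) {
  label_mask(array(1L, c(nx, ny, nz)), spacing = spacing)
}

cuboid_image <- function(nx, ny, nz, hu = 200, spacing = c(1, 1, 1)) {
  image_volume(array(hu, c(nx, ny, nz)), spacing = spacing)
}

# Isotropic material table (nu = 0 unless given); exercises the generic
# per-element assembly path since the moduli ratios are not the standard ones.
isotropic_materials <- function(n, E = 1000, nu = 0) {
  G <- E / (2 * (1 + nu))
  data.frame(element = seq_len(n), hu = NA, rho_app = NA, rho_ash = NA,
             Ez = E, Ex = E, Ey = E, Gxy = G, Gxz = G, Gyz = G,
             sigma_max = Inf, sigma_min = Inf, eps_AB = 0,
             nu_xy = nu, nu_xz = nu)
}

# Independent quadrature oracle for the element stiffness: numerically
# integrates t(B) C B with shape-function gradients obtained by central
# finite differences of the barycentric coordinates at 4 interior points.
element_stiffness_quadrature <- function(verts, C, h = 1e-5) {
  # N_a at point p: barycentric coordinates ordered to match vertex order
  bary <- function(p) {
    A <- cbind(verts[1, ] - verts[4, ], verts[2, ] - verts[4, ],
               verts[3, ] - verts[4, ])
    l123 <- solve(A, p - verts[4, ])
    c(l123, 1 - sum(l123))
  }
  vol <- abs(det(rbind(verts[2, ] - verts[1, ], verts[3, ] - verts[1, ],
                       verts[4, ] - verts[1, ]))) / 6
  # 4-point symmetric quadrature (degree 2) on the tetrahedron
  a <- (5 + 3 * sqrt(5)) / 20; b <- (5 - sqrt(5)) / 20
  qp <- rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
  Ke <- matrix(0, 12, 12)
  for (q in 1:4) {
    p <- as.numeric(t(verts) %*% qp[q, ])
    gradN <- matrix(0, 4, 3)
    for (d in 1:3) {
      e <- numeric(3); e[d] <- h
      gradN[, d] <- (bary(p + e) - bary(p - e)) / (2 * h)
    }
    B <- matrix(0, 6, 12)
    for (aa in 1:4) {
      g <- gradN[aa, ]
      cset <- (3 * (aa - 1) + 1):(3 * aa)
      B[1, cset[1]] <- g[1]; B[2, cset[2]] <- g[2]; B[3, cset[3]] <- g[3]
      B[4, cset[2]] <- g[3]; B[4, cset[3]] <- g[2]
      B[5, cset[1]] <- g[3]; B[5, cset[3]] <- g[1]
      B[6, cset[1]] <- g[2]; B[6, cset[2]] <- g[1]
    }
    Ke <- Ke + (vol / 4) * t(B) %*% C %*% B
  }
  Ke
}
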