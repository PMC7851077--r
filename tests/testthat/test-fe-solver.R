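test_that("element stiffness has the rigid-body null space and symmetry", {
  verts <- rbind(c(0, 0, 0), c(2, 0.2, 0), c(0.3, 1.8, 0.1), c(0.2, 0.4, 2.2))
  mat <- map_mesh(voxel_to_tet(cuboid_mask(1, 1, 1), cuboid_image(1, 1, 1), 1))[1, ]
  Ke <- element_stiffness(verts, mat)
  expect_equal(Ke, t(Ke), tolerance = 1e-12)
  for (d in 1:3) {
    u <- rep(0, 12); u[seq(d, 12, by = 3)] <- 1    # rigid translation
    expect_lt(max(abs(Ke %*% u)), 1e-9 * max(abs(Ke)))
  }
  degen <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 0))
  expect_error(element_stiffness(degen, mat), "volume")
})

test_that("element stiffness matches an independent quadrature oracle", {
  # unit regular tetrahedron, isotropic E = 1, nu = 0
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                 c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  iso <- isotropic_materials(1, E = 1, nu = 0)[1, ]
  C <- diag(c(1, 1, 1, 0.5, 0.5, 0.5))
  Ke <- element_stiffness(verts, iso)
  Kq <- element_stiffness_quadrature(verts, C)
  expect_equal(Ke, Kq, tolerance = 1e-6)

  # irregular tetrahedron with the transversely isotropic bone tensor
  verts2 <- rbind(c(0, 0, 0), c(1.7, 0.1, 0.2), c(0.2, 2.1, 0.3),
                  c(0.4, 0.3, 1.6))
  mat <- map_mesh(voxel_to_tet(cuboid_mask(1, 1, 1),
                               cuboid_image(1, 1, 1, hu = 300), 1))[1, ]
  C2 <- elastic_tensor(mat$Ez)
  expect_equal(element_stiffness(verts2, mat),
               element_stiffness_quadrature(verts2, C2),
               tolerance = 1e-5)
})

test_that("assembly scatters element matrices and keeps the null space", {
  mask <- cuboid_mask(1, 1, 1)
  mesh <- voxel_to_tet(mask, cuboid_image(1, 1, 1, 300), 1)
  mat <- map_mesh(mesh)
  sys <- assemble(mesh, mat)
  # sum of all element matrices equals the dense global
  Kdense <- as.matrix(sys$K)
  Ksum <- matrix(0, sys$ndof, sys$ndof)
  for (e in seq_len(nrow(mesh$tets))) {
    Ke <- element_stiffness(mesh$nodes[mesh$tets[e, ], ], mat[e, ])
    dofs <- as.integer(rbind(3 * mesh$tets[e, ] - 2, 3 * mesh$tets[e, ] - 1,
                             3 * mesh$tets[e, ]))
    Ksum[dofs, dofs] <- Ksum[dofs, dofs] + Ke
  }
  expect_equal(Kdense, Ksum, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(Kdense, t(Kdense), tolerance = 1e-9, ignore_attr = TRUE)
  # global rigid translation in the null space
  for (d in 1:3) {
    u <- rep(0, sys$ndof); u[seq(d, sys$ndof, by = 3)] <- 1
    expect_lt(max(abs(sys$K %*% u)), 1e-8 * max(abs(Kdense)))
  }
})

test_that("disconnected regions assemble block-diagonally", {
  lab <- array(0L, c(5, 1, 1)); lab[c(1, 5)] <- 1L
  mask <- label_mask(lab)
  img <- image_volume(array(300, c(5, 1, 1)))
  mesh <- voxel_to_tet(mask, img, 1)
  mat <- map_mesh(mesh)
  sys <- assemble(mesh, mat)
  n1 <- unique(as.integer(mesh$tets[1:6, ]))
  n2 <- unique(as.integer(mesh$tets[7:12, ]))
  expect_length(intersect(n1, n2), 0)
  d1 <- as.integer(outer(3 * (n1 - 1), 1:3, `+`))
  d2 <- as.integer(outer(3 * (n2 - 1), 1:3, `+`))
  expect_equal(max(abs(sys$K[d1, d2])), 0)
})

test_that("solve_increment is linear and balanced", {
  mesh <- small_mesh()
  mat <- small_materials()
  sys <- assemble(mesh, mat)
  bc <- compression_bc(mesh)
  z <- solve_increment(sys, bc, 0)
  expect_equal(max(abs(z$u)), 0)
  expect_equal(z$force, 0)
  a <- solve_increment(sys, bc, 0.5)
  b <- solve_increment(sys, bc, 1)
  expect_equal(2 * a$u, b$u, tolerance = 1e-9)
  expect_equal(2 * a$force, b$force, tolerance = 1e-9)
  expect_lt(a$equilibrium_residual, 1e-8)
  expect_lt(b$equilibrium_residual, 1e-8)
})

test_that("the cuboid patch test reproduces uniform strain exactly", {
  nx <- 4; nz <- 4
  mesh <- voxel_to_tet(cuboid_mask(nx, nx, nz), cuboid_image(nx, nx, nz), 1)
  E <- 1200; strain <- -0.01
  mat <- isotropic_materials(nrow(mesh$tets), E = E, nu = 0)
  sys <- assemble(mesh, mat)
  surf <- vertfe:::boundary_node_ids(mesh$tets, nrow(mesh$nodes))
  dofs <- as.integer(outer(3 * (surf - 1), 1:3, `+`))
  uvals <- numeric(length(dofs))
  zcol <- mesh$nodes[surf, 3]
  uvals[(2 * length(surf) + 1):(3 * length(surf))] <- strain * zcol
  sol <- vertfe:::solve_dirichlet(sys, dofs, uvals)
  S <- vertfe:::element_stresses_voigt(sys, sol$u)
  # interior stress uniform: sigma_zz = E * strain, all others zero
  expect_lt(max(abs(S[, 3] - E * strain)), 1e-8 * abs(E * strain))
  expect_lt(max(abs(S[, -3])), 1e-7)
  # reaction on the top face equals E * A * strain
  top <- surf[mesh$nodes[surf, 3] == nz]
  reaction <- sum(sol$reactions[3 * top])
  expect_equal(reaction, E * nx * nx * strain, tolerance = 1e-8)

  pr <- vertfe:::principal_from_voigt(S)
  expect_lt(max(abs(pr[, "s3"] - E * strain)), 1e-6)
  expect_lt(max(abs(pr[, "s1"])), 1e-6)
})

test_that("principal stresses match eigen decomposition on random tensors", {
  set.seed(42)
  S <- matrix(stats::rnorm(200 * 6, sd = 10), 200, 6)
  S[1, ] <- c(5, 5, 5, 0, 0, 0)              # isotropic degenerate case
  S[2, ] <- 0                                 # zero stress
  pr <- vertfe:::principal_from_voigt(S)
  for (i in seq_len(nrow(S))) {
    A <- matrix(c(S[i, 1], S[i, 6], S[i, 5],
                  S[i, 6], S[i, 2], S[i, 4],
                  S[i, 5], S[i, 4], S[i, 3]), 3, 3)
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(unname(pr[i, "s1"]), max(ev), tolerance = 1e-8)
    expect_equal(unname(pr[i, "s3"]), min(ev), tolerance = 1e-8)
  }
})

test_that("zero displacement gives zero element stresses", {
  mesh <- small_mesh()
  mat <- small_materials()
  pr <- element_principal_stresses(rep(0, 3 * nrow(mesh$nodes)), mesh, mat)
  expect_equal(max(abs(pr)), 0)
})

test_that("knockdown factor 1 disables damage and leaves a linear curve", {
  mesh <- small_mesh()
  mat <- small_materials()
  bc <- compression_bc(mesh, n_increments = 6)
  res <- run_compression(mesh, mat, bc,
                         solver_options(knockdown_factor = 1,
                                        stop_force_fraction = 0.001))
  f <- res$reaction_forces
  expect_equal(f[1], 0)
  expect_equal(f, f[7] * (0:6) / 6, tolerance = 1e-9)
  expect_equal(res$failure_load, f[7])
})

test_that("compression produces a peaked curve with bookkeeping intact", {
  mesh <- small_mesh()
  mat <- small_materials()
  bc <- compression_bc(mesh, n_increments = 10)
  res <- run_compression(mesh, mat, bc)
  expect_equal(res$displacements[1], 0)
  expect_equal(res$reaction_forces[1], 0)
  expect_equal(res$failure_load, max(res$reaction_forces))
  expect_gt(res$failure_load, 0)
  expect_gt(res$n_failed, 0)
  expect_equal(res$n_failed, sum(res$failed_elements_per_increment))
  expect_true(all(res$equilibrium_residuals < 1e-8))
  # determinism
  res2 <- run_compression(mesh, mat, bc)
  expect_identical(res$reaction_forces, res2$reaction_forces)
})

test_that("scaling strengths and displacement by k scales the curve by k", {
  mesh <- small_mesh()
  mat <- small_materials()
  bc1 <- compression_bc(mesh, strain = 0.004, n_increments = 8)
  bc2 <- compression_bc(mesh, strain = 0.008, n_increments = 8)
  mat2 <- mat
  mat2$sigma_max <- 2 * mat$sigma_max
  mat2$sigma_min <- 2 * mat$sigma_min
  r1 <- run_compression(mesh, mat, bc1)
  r2 <- run_compression(mesh, mat2, bc2)
  expect_equal(r2$failure_load, 2 * r1$failure_load, tolerance = 1e-12)
  expect_equal(r2$reaction_forces, 2 * r1$reaction_forces, tolerance = 1e-12)
  expect_identical(r2$failed_elements_per_increment,
                   r1$failed_elements_per_increment)
})

test_that("singular boundary conditions raise an informative error", {
  mesh <- small_mesh()
  mat <- small_materials()
  sys <- assemble(mesh, mat)
  # constrain a single node: rigid-body modes remain
  expect_error(vertfe:::solve_dirichlet(sys, 1:3, rep(0, 3)),
               "singular|boundary")
})
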