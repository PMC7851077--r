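#' Boundary conditions for displacement-controlled compression
#'
#' The inferior body surface is fully constrained; the superior body surface
#' is driven downward by a prescribed z-displacement (negative = compression)
#' applied in equal increments, with the driven nodes also held at zero x/y
#' displacement (platen-like loading).
#'
#' @param fixed_nodes Node ids with all displacement components zero.
#' @param driven_nodes Node ids with prescribed z-displacement.
#' @param total_displacement Final z-displacement of the driven nodes, mm
#'   (negative for compression).
#' @param n_increments Number of equal displacement increments (>= 1).
#' @export
boundary_conditions <- function(fixed_nodes, driven_nodes,
                                total_displacement, n_increments = 20) {
  fixed_nodes <- as.integer(fixed_nodes); driven_nodes <- as.integer(driven_nodes)
  if (length(fixed_nodes) == 0L || length(driven_nodes) == 0L)
    stopf("fixed and driven node sets must be non-empty")
  if (length(intersect(fixed_nodes, driven_nodes)) > 0L)
    stopf("fixed and driven node sets must be disjoint")
  if (!is_scalar_number(total_displacement))
    stopf("total_displacement must be a number (mm)")
  if (n_increments < 1) stopf("n_increments must be >= 1")
  structure(list(fixed_nodes = fixed_nodes, driven_nodes = driven_nodes,
                 total_displacement = total_displacement,
                 n_increments = as.integer(n_increments)),
            class = "boundary_conditions")
}

#' @param mesh A `tet_mesh` with node sets from [extract_boundary_sets()].
#' @param strain Applied apparent axial strain; total displacement is
#'   `-strain` times the body z-extent. The default 0.4% is roughly three
#'   times the compressive failure strain implied by the density-strength
#'   relations, so the force-displacement peak falls mid-ramp and is well
#'   resolved by the increments.
#' @rdname boundary_conditions
#' @export
compression_bc <- function(mesh, strain = 0.004, n_increments = 20) {
  if (length(mesh$node_sets) == 0L)
    stopf("mesh has no node sets; run extract_boundary_sets() first")
  body_nodes <- unique(as.integer(
    mesh$tets[mesh$element_label == 1L, , drop = FALSE]))
  h <- diff(range(mesh$nodes[body_nodes, 3]))
  boundary_conditions(mesh$node_sets$inferior_body,
                      mesh$node_sets$superior_body,
                      total_displacement = -strain * h,
                      n_increments = n_increments)
}

#' Solver options for the progressive-failure compression run
#'
#' Element failure is brittle-damage: an element whose maximum principal
#' stress exceeds its tensile limit, or whose minimum principal stress drops
#' below minus its compressive limit, has all moduli multiplied by
#' `knockdown_factor`. Elements exactly at a limit are not failed (strict
#' inequality). Optionally an element also fails when the magnitude of its
#' axial strain exceeds its plastic-strain parameter (`use_strain_cap`).
#'
#' @param knockdown_factor Stiffness multiplier applied to failed elements,
#'   in (0, 1].
#' @param max_damage_iterations_per_increment Cap on re-solves per increment.
#' @param stop_force_fraction Stop early when the reaction force falls below
#'   this fraction of the running peak, in (0, 1].
#' @param use_strain_cap Also fail elements on |axial strain| > eps_AB?
#' @export
solver_options <- function(knockdown_factor = 0.01,
                           max_damage_iterations_per_increment = 8,
                           stop_force_fraction = 0.6,
                           use_strain_cap = FALSE) {
  if (!is_scalar_number(knockdown_factor) ||
      knockdown_factor <= 0 || knockdown_factor > 1)
    stopf("knockdown_factor must be in (0, 1]")
  if (max_damage_iterations_per_increment < 1)
    stopf("max_damage_iterations_per_increment must be >= 1")
  if (!is_scalar_number(stop_force_fraction) ||
      stop_force_fraction <= 0 || stop_force_fraction > 1)
    stopf("stop_force_fraction must be in (0, 1]")
  structure(list(knockdown_factor = knockdown_factor,
                 max_damage_iterations_per_increment =
                   as.integer(max_damage_iterations_per_increment),
                 stop_force_fraction = stop_force_fraction,
                 use_strain_cap = isTRUE(use_strain_cap)),
            class = "solver_options")
}

# 6x12 strain-displacement operator of a constant-strain tetrahedron.
# Voigt order (xx, yy, zz, yz, xz, xy), engineering shear strains.
tet_B <- function(verts) {
  D <- rbind(verts[2, ] - verts[1, ], verts[3, ] - verts[1, ],
             verts[4, ] - verts[1, ])
  vol <- det(t(D)) / 6
  if (vol <= 0) stopf("element has non-positive volume")
  Ginv <- solve(t(D))                      # d(xi_a)/d(x_j) in rows
  grads <- rbind(-colSums(Ginv), Ginv)     # 4 x 3 shape gradients
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    g <- grads[a, ]
    cset <- (3 * (a - 1) + 1):(3 * a)
    B[1, cset[1]] <- g[1]
    B[2, cset[2]] <- g[2]
    B[3, cset[3]] <- g[3]
    B[4, cset[2]] <- g[3]; B[4, cset[3]] <- g[2]
    B[5, cset[1]] <- g[3]; B[5, cset[3]] <- g[1]
    B[6, cset[1]] <- g[2]; B[6, cset[2]] <- g[1]
  }
  list(B = B, volume = vol)
}

# Elasticity tensor from a material record (one row of a material table or a
# plain list with the same fields).
material_tensor <- function(material) {
  m <- as.list(material)
  S <- matrix(0, 6, 6)
  S[1, 1] <- 1 / m$Ex; S[2, 2] <- 1 / m$Ey; S[3, 3] <- 1 / m$Ez
  S[1, 2] <- S[2, 1] <- -m$nu_xy / m$Ex
  S[1, 3] <- S[3, 1] <- S[2, 3] <- S[3, 2] <- -m$nu_xz / m$Ex
  S[4, 4] <- 1 / m$Gyz; S[5, 5] <- 1 / m$Gxz; S[6, 6] <- 1 / m$Gxy
  C <- solve(S)
  (C + t(C)) / 2
}

#' Element stiffness matrix of a linear tetrahedron
#'
#' `K_e = V * t(B) C B` with the constant strain-displacement operator `B`
#' and the transversely isotropic tensor `C` built from the material record
#' (material z-axis = global z). Dof order is (ux, uy, uz) per vertex.
#'
#' @param tet_vertices 4x3 vertex coordinate matrix (mm), positively oriented.
#' @param material Material record with fields `Ez`, `Ex`, `Ey`, `Gxy`,
#'   `Gxz`, `Gyz`, `nu_xy`, `nu_xz`.
#' @return 12x12 symmetric stiffness matrix (N/mm).
#' @export
element_stiffness <- function(tet_vertices, material) {
  bv <- tet_B(as.matrix(tet_vertices))
  C <- material_tensor(material)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stopf("elasticity tensor not positive definite for this element")
  Ke <- bv$volume * t(bv$B) %*% C %*% bv$B
  (Ke + t(Ke)) / 2
}

# ---- assembly ---------------------------------------------------------------

# An fe_system bundles the global sparse stiffness with enough per-element
# structure to rescale element contributions (damage) and evaluate stresses
# without reassembling from scratch.
#
# Patterns: congruent elements share a geometry pattern (the 6 local
# tetrahedra of a structured voxel mesh); pattern p stores Ke (12x12, unit
# modulus), CB (6x12, unit modulus) and volume. Element e has pattern
# pattern_id[e] and modulus scale[e] = Ez_e.
assemble_system <- function(mesh, materials) {
  M <- nrow(mesh$tets)
  stopifnot(nrow(materials) == M)
  ndof <- 3L * nrow(mesh$nodes)
  dofmat <- matrix(0L, M, 12)
  for (a in 1:4) for (comp in 1:3)
    dofmat[, 3L * (a - 1L) + comp] <- 3L * (mesh$tets[, a] - 1L) + comp
  referenced <- unique(as.integer(mesh$tets))
  if (length(referenced) < nrow(mesh$nodes))
    warning(sprintf("%d dangling node(s) referenced by no element",
                    nrow(mesh$nodes) - length(referenced)), call. = FALSE)
  Cu <- unit_elastic_tensor(materials$nu_xy[1], materials$nu_xz[1])
  same_nu <- all(materials$nu_xy == materials$nu_xy[1]) &&
    all(materials$nu_xz == materials$nu_xz[1])
  # the shared unit tensor is valid only for the standard modulus ratios
  table_ratios <- isTRUE(all.equal(materials$Ex, 0.333 * materials$Ez)) &&
    isTRUE(all.equal(materials$Ey, 0.333 * materials$Ez)) &&
    isTRUE(all.equal(materials$Gxy, 0.121 * materials$Ez)) &&
    isTRUE(all.equal(materials$Gxz, 0.157 * materials$Ez)) &&
    isTRUE(all.equal(materials$Gyz, 0.157 * materials$Ez))
  structured <- !is.null(mesh$local_tet) && same_nu && table_ratios
  if (structured) {
    k <- mesh$vox_per_cell; cell_mm <- k * mesh$spacing
    corner <- kuhn_corners(); lt <- kuhn_tets()
    patterns <- lapply(1:6, function(t) {
      verts <- sweep(corner[lt[t, ], ], 2, cell_mm, `*`)
      bv <- tet_B(verts)
      list(Ke = bv$volume * t(bv$B) %*% Cu %*% bv$B,
           CB = Cu %*% bv$B, B = bv$B, volume = bv$volume)
    })
    pattern_id <- mesh$local_tet
  } else {
    patterns <- lapply(seq_len(M), function(e) {
      bv <- tet_B(mesh$nodes[mesh$tets[e, ], ])
      Ce <- material_tensor(materials[e, ]) / materials$Ez[e]
      list(Ke = bv$volume * t(bv$B) %*% Ce %*% bv$B,
           CB = Ce %*% bv$B, B = bv$B, volume = bv$volume)
    })
    pattern_id <- seq_len(M)
  }
  scale <- materials$Ez
  K <- build_K(dofmat, patterns, pattern_id, scale, ndof)
  list(K = K, ndof = ndof, dofmat = dofmat, patterns = patterns,
       pattern_id = pattern_id, scale = scale, mesh = mesh,
       materials = materials)
}

# Global sparse stiffness from per-pattern element matrices; `mult` is an
# optional per-element extra factor (damage), `subset` restricts to elements.
build_K <- function(dofmat, patterns, pattern_id, scale, ndof,
                    mult = NULL, subset = NULL) {
  if (is.null(subset)) subset <- seq_along(pattern_id)
  ii <- jj <- vector("list", length(patterns))
  xx <- vector("list", length(patterns))
  row_rep <- rep(1:12, each = 12); col_rep <- rep(1:12, times = 12)
  n_used <- 0L
  for (p in seq_along(patterns)) {
    els <- subset[pattern_id[subset] == p]
    if (length(els) == 0L) next
    n_used <- n_used + 1L
    dm <- dofmat[els, , drop = FALSE]
    s <- scale[els]
    if (!is.null(mult)) s <- s * mult[els]
    keflat <- as.vector(patterns[[p]]$Ke)
    ii[[p]] <- as.integer(dm[, row_rep])
    jj[[p]] <- as.integer(dm[, col_rep])
    xx[[p]] <- as.vector(outer(s, keflat))
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(ndof, ndof))
}

#' Assemble the global stiffness matrix
#'
#' Standard scatter-add of element stiffness matrices into a sparse
#' symmetric global matrix. Congruent elements of structured voxel meshes
#' share cached element matrices. Dangling nodes trigger a warning.
#'
#' @param mesh A `tet_mesh`.
#' @param materials Material table from [map_mesh()].
#' @return An `fe_system` list whose `K` is the assembled sparse matrix.
#' @export
assemble <- function(mesh, materials) {
  sys <- assemble_system(mesh, materials)
  class(sys) <- "fe_system"
  sys
}

# Solve K u = 0 subject to u[dofs] = vals; returns u and reactions K u.
# `chol_cache` (environment) reuses the symbolic+numeric factorisation.
solve_dirichlet <- function(sys, dofs, vals, chol_cache = NULL) {
  ndof <- sys$ndof
  free <- setdiff(seq_len(ndof), dofs)
  u <- numeric(ndof)
  u[dofs] <- vals
  rhs <- -(sys$K[free, dofs, drop = FALSE] %*% vals)
  ch <- NULL
  if (!is.null(chol_cache) && !is.null(chol_cache$ch) &&
      isTRUE(chol_cache$valid)) {
    ch <- chol_cache$ch
  } else {
    Kff <- Matrix::forceSymmetric(sys$K[free, free, drop = FALSE])
    ch <- tryCatch({
      if (!is.null(chol_cache) && !is.null(chol_cache$ch))
        update(chol_cache$ch, Kff)
      else Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE)
    }, error = function(e)
      stopf("constrained stiffness is singular or indefinite (%s); inspect the boundary node sets",
            conditionMessage(e)))
    if (!is.null(chol_cache)) {
      chol_cache$ch <- ch
      chol_cache$valid <- TRUE
    }
  }
  u[free] <- as.numeric(solve(ch, rhs))
  r <- as.numeric(sys$K %*% u)
  list(u = u, reactions = r, free = free)
}

#' Solve one displacement increment
#'
#' Imposes the Dirichlet conditions (fixed nodes zero in all components;
#' driven nodes at `prescribed_fraction * total_displacement` in z, zero in
#' x/y) on the current stiffness and returns displacements and reactions.
#' At equilibrium the summed z-reactions of the driven and fixed sets cancel.
#'
#' @param sys An `fe_system` from [assemble()].
#' @param bc A `boundary_conditions` object.
#' @param prescribed_fraction Fraction of `total_displacement` applied.
#' @return list with `u` (length 3*n nodes), `reaction_driven_z`,
#'   `reaction_fixed_z`, `force` (compressive reaction, N, positive) and
#'   `equilibrium_residual`.
#' @export
solve_increment <- function(sys, bc, prescribed_fraction) {
  dd <- dirichlet_dofs(bc)
  sol <- solve_dirichlet(sys, dd$dofs,
                         dd$unit_vals * prescribed_fraction *
                           bc$total_displacement)
  summarize_increment(sol, bc)
}

dirichlet_dofs <- function(bc) {
  fdofs <- as.integer(outer(3L * (bc$fixed_nodes - 1L), 1:3, `+`))
  ddofs <- as.integer(outer(3L * (bc$driven_nodes - 1L), 1:3, `+`))
  dofs <- c(fdofs, ddofs)
  unit <- numeric(length(dofs))
  driven_z <- length(fdofs) + seq.int(2L * length(bc$driven_nodes) + 1L,
                                      3L * length(bc$driven_nodes))
  # outer() flattens column-major: the driven block lists all x dofs, then
  # all y, then all z; the z entries are its final third
  unit[driven_z] <- 1
  list(dofs = dofs, unit_vals = unit,
       fixed_z_dofs = 3L * bc$fixed_nodes,
       driven_z_dofs = 3L * bc$driven_nodes)
}

summarize_increment <- function(sol, bc) {
  rd <- sum(sol$reactions[3L * bc$driven_nodes])
  rf <- sum(sol$reactions[3L * bc$fixed_nodes])
  list(u = sol$u, reaction_driven_z = rd, reaction_fixed_z = rf,
       force = -rd,
       equilibrium_residual = abs(rd + rf) / max(abs(rd), 1))
}

# ---- stress evaluation ------------------------------------------------------

# Per-element Voigt stresses (M x 6) for displacement vector u; `mult` is the
# per-element damage factor.
element_stresses_voigt <- function(sys, u, mult = NULL) {
  M <- nrow(sys$dofmat)
  S <- matrix(0, M, 6)
  for (p in seq_along(sys$patterns)) {
    els <- which(sys$pattern_id == p)
    if (length(els) == 0L) next
    U <- matrix(u[sys$dofmat[els, ]], nrow = length(els))
    S[els, ] <- U %*% t(sys$patterns[[p]]$CB)
  }
  s <- sys$scale
  if (!is.null(mult)) s <- s * mult
  S * s
}

# Per-element axial strain (eps_zz) for displacement vector u.
element_axial_strain <- function(sys, u) {
  M <- nrow(sys$dofmat)
  ez <- numeric(M)
  for (p in seq_along(sys$patterns)) {
    els <- which(sys$pattern_id == p)
    if (length(els) == 0L) next
    U <- matrix(u[sys$dofmat[els, ]], nrow = length(els))
    ez[els] <- U %*% sys$patterns[[p]]$B[3, ]
  }
  ez
}

# Closed-form eigenvalues of many symmetric 3x3 tensors (rows of Voigt
# stresses); returns extreme eigenvalues (s1 = max, s3 = min).
principal_from_voigt <- function(S) {
  s11 <- S[, 1]; s22 <- S[, 2]; s33 <- S[, 3]
  s23 <- S[, 4]; s13 <- S[, 5]; s12 <- S[, 6]
  q <- (s11 + s22 + s33) / 3
  p2 <- (s11 - q)^2 + (s22 - q)^2 + (s33 - q)^2 +
    2 * (s12^2 + s13^2 + s23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  scale_ref <- pmax(abs(s11), abs(s22), abs(s33), abs(s12), abs(s13),
                    abs(s23), 1e-300)
  iso <- p <= 1e-12 * scale_ref
  ps <- ifelse(iso, 1, p)    # avoid division by ~0; overwritten below
  b11 <- (s11 - q) / ps; b22 <- (s22 - q) / ps; b33 <- (s33 - q) / ps
  b12 <- s12 / ps; b13 <- s13 / ps; b23 <- s23 / ps
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  s1 <- q + 2 * p * cos(phi)
  s3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  s1[iso] <- q[iso]; s3[iso] <- q[iso]
  cbind(s1 = s1, s3 = s3)
}

#' Per-element principal stresses
#'
#' Computes the constant stress tensor `C B u_e` of every element and returns
#' its largest and smallest eigenvalues (maximum and minimum principal
#' stress). Damage factors, when supplied, scale each element's tensor.
#'
#' @param u Global displacement vector (3 per node).
#' @param mesh A `tet_mesh`.
#' @param materials Material table from [map_mesh()].
#' @param damage Optional per-element stiffness multipliers.
#' @return Matrix with columns `s1` (max) and `s3` (min), MPa.
#' @export
element_principal_stresses <- function(u, mesh, materials, damage = NULL) {
  sys <- assemble_system(mesh, materials)
  S <- element_stresses_voigt(sys, u, damage)
  principal_from_voigt(S)
}

# ---- progressive failure ----------------------------------------------------

#' Displacement-controlled compression to failure
#'
#' Ramps the prescribed compression in `bc$n_increments` equal increments.
#' At each increment the linear system is solved and elements whose maximum
#' principal stress exceeds `sigma_max` or whose minimum principal stress
#' drops below `-sigma_min` (strict inequalities) are failed: their moduli
#' are multiplied by `knockdown_factor` and the increment is re-solved until
#' no new failures occur or the iteration cap is reached. The run stops early
#' once the reaction force falls below `stop_force_fraction` of the running
#' peak. The failure load is the peak of the recorded force-displacement
#' curve.
#'
#' Because the response between damage events is linear in the prescribed
#' displacement, factorisations are reused and solutions rescaled whenever no
#' new damage occurred.
#'
#' @param mesh A `tet_mesh` with boundary node sets.
#' @param materials Material table from [map_mesh()].
#' @param bc A `boundary_conditions` object.
#' @param options A `solver_options` object.
#' @return A `failure_load_result`: `displacements` (mm, prescribed, starting
#'   at 0), `reaction_forces` (N, compressive positive, starting at 0),
#'   `failure_load` (N), `failed_elements_per_increment`,
#'   `equilibrium_residuals`, `n_failed`, and `warnings`.
#' @export
run_compression <- function(mesh, materials, bc, options = solver_options()) {
  stopifnot(inherits(bc, "boundary_conditions"),
            inherits(options, "solver_options"))
  sys <- assemble_system(mesh, materials)
  M <- nrow(sys$dofmat)
  dd <- dirichlet_dofs(bc)
  cache <- new.env(parent = emptyenv()); cache$valid <- FALSE
  failed <- logical(M)
  dmg <- rep(1, M)
  warnings <- character(0)
  disps <- 0; forces <- 0; eq_res <- numeric(0)
  failed_per_inc <- integer(0)
  sd_unit <- NULL   # unit-displacement solution for the current K
  solve_unit <- function() {
    sol <- solve_dirichlet(sys, dd$dofs, dd$unit_vals * bc$total_displacement,
                           chol_cache = cache)
    S <- element_stresses_voigt(sys, sol$u, dmg)
    pr <- principal_from_voigt(S)
    ez <- if (options$use_strain_cap) element_axial_strain(sys, sol$u) else NULL
    list(sol = sol, pr = pr, ez = ez,
         force = -sum(sol$reactions[3L * bc$driven_nodes]),
         resid = abs(sum(sol$reactions[3L * bc$driven_nodes]) +
                       sum(sol$reactions[3L * bc$fixed_nodes])) /
           max(abs(sum(sol$reactions[3L * bc$driven_nodes])), 1))
  }
  aborted <- FALSE
  for (inc in seq_len(bc$n_increments)) {
    frac <- inc / bc$n_increments
    n_new_inc <- 0L
    iter <- 0L
    repeat {
      if (is.null(sd_unit)) {
        sd_unit <- tryCatch(solve_unit(), error = function(e) e)
        if (inherits(sd_unit, "error")) {
          warnings <- c(warnings, sprintf(
            "increment %d: %s; returning curve so far", inc,
            conditionMessage(sd_unit)))
          sd_unit <- NULL
          aborted <- TRUE
          break
        }
      }
      s1 <- frac * sd_unit$pr[, "s1"]
      s3 <- frac * sd_unit$pr[, "s3"]
      new_fail <- !failed & (s1 > materials$sigma_max |
                               s3 < -materials$sigma_min)
      if (options$use_strain_cap)
        new_fail <- new_fail |
          (!failed & materials$eps_AB > 0 &
             abs(frac * sd_unit$ez) > materials$eps_AB)
      if (!any(new_fail)) break
      iter <- iter + 1L
      if (iter > options$max_damage_iterations_per_increment) {
        warnings <- c(warnings, sprintf(
          "increment %d: damage iteration cap (%d) reached with %d pending failures",
          inc, options$max_damage_iterations_per_increment, sum(new_fail)))
        break
      }
      failed[new_fail] <- TRUE
      n_new_inc <- n_new_inc + sum(new_fail)
      if (options$knockdown_factor < 1) {
        delta <- build_K(sys$dofmat, sys$patterns, sys$pattern_id, sys$scale,
                         sys$ndof,
                         mult = rep(options$knockdown_factor - 1, M),
                         subset = which(new_fail))
        sys$K <- sys$K + delta
        dmg[new_fail] <- options$knockdown_factor
        cache$valid <- FALSE
        sd_unit <- NULL
      }
    }
    if (aborted) break
    disps <- c(disps, frac * bc$total_displacement)
    forces <- c(forces, frac * sd_unit$force)
    eq_res <- c(eq_res, sd_unit$resid)
    failed_per_inc <- c(failed_per_inc, n_new_inc)
    if (utils::tail(forces, 1) <
        options$stop_force_fraction * max(forces)) break
  }
  structure(list(displacements = disps, reaction_forces = forces,
                 failure_load = max(forces),
                 failed_elements_per_increment = failed_per_inc,
                 equilibrium_residuals = eq_res,
                 n_failed = sum(failed), damage = dmg,
                 warnings = warnings),
            class = "failure_load_result")
}

#' @export
#' @method print failure_load_result
print.failure_load_result <- function(x, ...) {
  cat(sprintf("<failure_load_result> failure load %.1f N over %d increments; %d elements failed%s\n",
              x$failure_load, length(x$reaction_forces) - 1L, x$n_failed,
              if (length(x$warnings)) sprintf(" (%d warnings)",
                                              length(x$warnings)) else ""))
  invisible(x)
}

#' Export a force-displacement curve as CSV and a JSON summary
#'
#' @param result A `failure_load_result`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @export
write_result <- function(result, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(data.frame(displacement_mm = result$displacements,
                                force_N = result$reaction_forces),
                     csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(failure_load = result$failure_load,
                              n_failed = result$n_failed,
                              warnings = result$warnings),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(result)
}
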