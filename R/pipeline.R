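#' Failure load of a labelled vertebra volume
#'
#' One-call pipeline: voxel-to-tetrahedron meshing at the requested edge
#' length, boundary-set extraction, HU-to-material mapping, and the
#' displacement-controlled compression to failure.
#'
#' @param img An `image_volume`.
#' @param mask The matching `label_mask`.
#' @param edge_mm Mesh cell edge length, mm.
#' @param band_fraction Boundary band fraction for [extract_boundary_sets()].
#' @param strain Applied apparent axial strain (see [compression_bc()]).
#' @param n_increments Displacement increments.
#' @param options A `solver_options` object.
#' @param nu_xy,nu_xz Poisson ratios for the material mapping.
#' @return list with `result` (a `failure_load_result`), `mesh`,
#'   `materials` and `bc`.
#' @export
vertebra_failure_load <- function(img, mask, edge_mm = 2,
                                  band_fraction = 0.02, strain = 0.004,
                                  n_increments = 20,
                                  options = solver_options(),
                                  nu_xy = 0.381, nu_xz = 0.104) {
  mesh <- voxel_to_tet(mask, img, target_edge_mm = edge_mm)
  mesh <- extract_boundary_sets(mesh, band_fraction = band_fraction)
  materials <- map_mesh(mesh, img, nu_xy = nu_xy, nu_xz = nu_xz)
  bc <- compression_bc(mesh, strain = strain, n_increments = n_increments)
  res <- run_compression(mesh, materials, bc, options = options)
  list(result = res, mesh = mesh, materials = materials, bc = bc)
}

#' Experiment configuration for phantom condition grids
#'
#' Declarative description of a phantom experiment: base anatomy, the
#' scan-condition grid (slice-thickness factor and contrast on/off), mesh
#' edge length, solver settings and explicit seeds (wall-clock seeding is
#' never used).
#'
#' @param base_spec A `phantom_spec`.
#' @param n_phantoms Number of phantoms (subjects).
#' @param slice_factors Integer slice-averaging factors (1 = thin slices).
#' @param contrast Logical conditions for contrast enhancement.
#' @param contrast_spec A `contrast_spec` used when contrast is on.
#' @param slice_axis Axis along which thick slices are reconstructed
#'   (2 = the anterior-posterior axis, mimicking sagittal reformation).
#' @param edge_mm,band_fraction,strain,n_increments,options Pipeline settings.
#' @param seed Master seed; per-phantom and per-condition seeds derive from it.
#' @export
experiment_config <- function(base_spec = phantom_spec(), n_phantoms = 7,
                              slice_factors = c(1L, 3L),
                              contrast = c(FALSE, TRUE),
                              contrast_spec = vertfe::contrast_spec(),
                              slice_axis = 2L, edge_mm = 2,
                              band_fraction = 0.02, strain = 0.004,
                              n_increments = 20,
                              options = solver_options(), seed = 1L) {
  if (length(slice_factors) == 0L || length(contrast) == 0L)
    stopf("condition grid must be non-empty")
  if (any(slice_factors < 1)) stopf("slice_factors must be >= 1")
  structure(list(base_spec = base_spec, n_phantoms = as.integer(n_phantoms),
                 slice_factors = as.integer(slice_factors),
                 contrast = as.logical(contrast),
                 contrast_spec = contrast_spec,
                 slice_axis = as.integer(slice_axis),
                 edge_mm = edge_mm, band_fraction = band_fraction,
                 strain = strain, n_increments = as.integer(n_increments),
                 options = options, seed = as.integer(seed)),
            class = "experiment_config")
}

# Provenance hash of a config: md5 of its serialisation.
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f, version = 2)
  unname(tools::md5sum(f))
}

phantom_for_subject <- function(cfg, i, include_posterior = NULL) {
  sp <- cfg$base_spec
  if (!is.null(include_posterior)) sp$include_posterior <- include_posterior
  sp$trab_hu_mean <- with_seed(derive_seed(cfg$seed, c(i, 1L)),
                               sp$trab_hu_mean + stats::rnorm(1, 0, 25))
  sp$shell_hu <- with_seed(derive_seed(cfg$seed, c(i, 2L)),
                           sp$shell_hu + stats::rnorm(1, 0, 40))
  sp$seed <- derive_seed(cfg$seed, c(i, 3L))
  sp
}

run_cell <- function(cfg, img, mask, slice_factor, with_contrast, cseed) {
  if (with_contrast) {
    cs <- cfg$contrast_spec
    cs$seed <- cseed
    img <- apply_contrast(img, mask, cs)
  }
  if (slice_factor > 1L) {
    img <- resample_slice_thickness(img, cfg$slice_axis, slice_factor)
    mask <- resample_slice_thickness(mask, cfg$slice_axis, slice_factor)
  }
  # structured cells cannot subdivide a voxel, so thick-slice conditions are
  # meshed at the coarser of the requested edge and the slice thickness
  edge <- max(cfg$edge_mm, mask$spacing)
  vertebra_failure_load(img, mask, edge_mm = edge,
                        band_fraction = cfg$band_fraction,
                        strain = cfg$strain,
                        n_increments = cfg$n_increments,
                        options = cfg$options)
}

#' Run a phantom-by-scan-condition grid
#'
#' Simulates every phantom under every combination of slice-thickness factor
#' and contrast condition, mirroring how the same vertebra is reconstructed
#' under different scan settings. Per-cell failures are recorded in the
#' `error` column and do not abort the grid. Deterministic for a fixed
#' config.
#'
#' @param cfg An `experiment_config`.
#' @return Long-format data.frame: one row per (phantom, condition) with
#'   `phantom_id`, `slice_factor`, `contrast`, `failure_load`, `n_elements`,
#'   `seed`, `config_hash` (provenance) and `error` (NA when the cell
#'   succeeded).
#' @export
run_condition_grid <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  chash <- config_hash(cfg)
  rows <- list()
  for (i in seq_len(cfg$n_phantoms)) {
    sp <- phantom_for_subject(cfg, i)
    ph <- generate_vertebra_phantom(sp)
    for (sf in cfg$slice_factors) for (ct in cfg$contrast) {
      cell <- tryCatch({
        r <- run_cell(cfg, ph$image, ph$mask, sf, ct,
                      derive_seed(cfg$seed, c(i, 4L)))
        data.frame(phantom_id = sprintf("P%02d", i), slice_factor = sf,
                   contrast = ct, failure_load = r$result$failure_load,
                   n_elements = nrow(r$mesh$tets), seed = sp$seed,
                   config_hash = chash, error = NA_character_)
      }, error = function(e)
        data.frame(phantom_id = sprintf("P%02d", i), slice_factor = sf,
                   contrast = ct, failure_load = NA_real_,
                   n_elements = NA_integer_, seed = sp$seed,
                   config_hash = chash, error = conditionMessage(e)))
      rows[[length(rows) + 1L]] <- cell
    }
  }
  do.call(rbind, rows)
}

#' Posterior-element effect with repeat runs
#'
#' For each subject, the same phantom (generated with posterior elements) is
#' simulated with and without the posterior elements. The "without" variant
#' drops the label-2 elements from the already-built mesh
#' ([drop_posterior_elements()]), so the body discretisation is identical in
#' both runs and the comparison isolates the posterior contribution. The
#' whole comparison is repeated with reseeded trabecular noise for a
#' reproducibility (RMSCV) estimate.
#'
#' @param cfg An `experiment_config`.
#' @param n_tries Number of repeat runs (>= 2 for an RMSCV).
#' @param reseed_tries Reseed the trabecular noise between tries (the solver
#'   itself is deterministic, so with `FALSE` the repeats are identical and
#'   the RMSCV is exactly zero).
#' @return list with the long `table`, per-subject `percent_diff` (try 1),
#'   `mean_pct`/`sd_pct`, paired `t_paired`, and `rmscv_with`/
#'   `rmscv_without` across tries.
#' @export
run_posterior_comparison <- function(cfg, n_tries = 2, reseed_tries = TRUE) {
  stopifnot(inherits(cfg, "experiment_config"))
  rows <- list()
  for (i in seq_len(cfg$n_phantoms)) {
    for (try in seq_len(n_tries)) {
      sp <- phantom_for_subject(cfg, i, include_posterior = TRUE)
      if (reseed_tries)
        sp$seed <- derive_seed(cfg$seed, c(i, 3L, try)) # reseeded noise per try
      ph <- generate_vertebra_phantom(sp)
      full_mesh <- voxel_to_tet(ph$mask, ph$image, cfg$edge_mm)
      for (with_post in c(TRUE, FALSE)) {
        mesh <- if (with_post) full_mesh else drop_posterior_elements(full_mesh)
        mesh <- extract_boundary_sets(mesh, band_fraction = cfg$band_fraction)
        materials <- map_mesh(mesh)
        bc <- compression_bc(mesh, strain = cfg$strain,
                             n_increments = cfg$n_increments)
        res <- run_compression(mesh, materials, bc, options = cfg$options)
        rows[[length(rows) + 1L]] <-
          data.frame(phantom_id = sprintf("P%02d", i), try = try,
                     posterior = with_post,
                     failure_load = res$failure_load)
      }
    }
  }
  tab <- do.call(rbind, rows)
  t1 <- tab[tab$try == 1L, ]
  fl_with <- t1$failure_load[t1$posterior]
  fl_without <- t1$failure_load[!t1$posterior]
  pct <- percent_difference(fl_with, fl_without)
  by_subject <- function(post) lapply(split(
    tab$failure_load[tab$posterior == post],
    tab$phantom_id[tab$posterior == post]), identity)
  list(table = tab, percent_diff = pct, mean_pct = mean(pct),
       sd_pct = stats::sd(pct),
       t_paired = t_tests(fl_with, fl_without, paired = TRUE),
       rmscv_with = if (n_tries >= 2) rmscv(by_subject(TRUE)) else NA_real_,
       rmscv_without = if (n_tries >= 2) rmscv(by_subject(FALSE)) else NA_real_)
}

#' Healthy versus weakened cohort comparison
#'
#' Generates a paired cohort ([generate_cohort()]), predicts every phantom's
#' failure load and compares the groups with both the paired t-test (the
#' design is matched pairs) and Welch's unpaired test.
#'
#' @param cspec A `cohort_spec`.
#' @param edge_mm,band_fraction,strain,n_increments,options Pipeline settings.
#' @return list with the per-phantom `table`, group `mean_healthy`/
#'   `sd_healthy`/`mean_weakened`/`sd_weakened`, `t_paired`, `t_welch` and
#'   `direction` ("healthy > weakened" when the means are ordered that way).
#' @export
run_cohort_comparison <- function(cspec, edge_mm = 2.5, band_fraction = 0.02,
                                  strain = 0.004, n_increments = 20,
                                  options = solver_options()) {
  stopifnot(inherits(cspec, "cohort_spec"))
  cohort <- generate_cohort(cspec)
  rows <- lapply(cohort, function(ph) {
    r <- vertebra_failure_load(ph$image, ph$mask, edge_mm = edge_mm,
                               band_fraction = band_fraction, strain = strain,
                               n_increments = n_increments, options = options)
    data.frame(phantom_id = ph$phantom_id, pair_id = ph$pair_id,
               group = ph$group, failure_load = r$result$failure_load)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$pair_id, tab$group), ]
  h <- tab$failure_load[tab$group == "healthy"]
  w <- tab$failure_load[tab$group == "weakened"]
  list(table = tab,
       mean_healthy = mean(h), sd_healthy = stats::sd(h),
       mean_weakened = mean(w), sd_weakened = stats::sd(w),
       t_paired = t_tests(h, w, paired = TRUE),
       t_welch = t_tests(h, w, paired = FALSE),
       direction = if (mean(h) > mean(w)) "healthy > weakened"
                   else "healthy <= weakened")
}
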