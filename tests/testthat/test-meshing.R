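test_that("a single kept cell yields 6 positively oriented tets of full volume", {
  mask <- cuboid_mask(1, 1, 1)
  img <- cuboid_image(1, 1, 1)
  mesh <- voxel_to_tet(mask, img, 1)
  expect_equal(nrow(mesh$tets), 6)
  vols <- tet_volumes(mesh)
  expect_true(all(vols > 0))
  expect_equal(sum(vols), 1)
  expect_equal(nrow(mesh$nodes), 8)
})

test_that("a 2x2x2 mm cube at 1 mm edge gives 48 tets of total volume 8", {
  mesh <- voxel_to_tet(cuboid_mask(2, 2, 2), cuboid_image(2, 2, 2), 1)
  expect_equal(nrow(mesh$tets), 48)
  expect_equal(sum(tet_volumes(mesh)), 8)
})

test_that("degenerate meshing inputs error", {
  empty <- label_mask(array(0L, c(3, 3, 3)))
  expect_error(voxel_to_tet(empty, NULL, 1), "empty")
  expect_error(voxel_to_tet(cuboid_mask(3, 3, 3), NULL, 0.5),
               "voxel spacing")
})

test_that("interior faces are shared by exactly 2 tets, boundary by 1", {
  for (mesh in list(voxel_to_tet(cuboid_mask(2, 2, 2), NULL, 1),
                    small_mesh())) {
    ft <- vertfe:::face_table(mesh$tets, nrow(mesh$nodes))
    counts <- table(table(ft$key))
    expect_true(all(names(counts) %in% c("1", "2")))
  }
})

test_that("mesh volume matches the voxel-counted mask volume at 1 mm edge", {
  ph <- small_phantom()
  mesh <- voxel_to_tet(ph$mask, ph$image, 1)
  vox_vol <- sum(ph$mask$labels > 0L) * prod(ph$mask$spacing)
  expect_lt(abs(mesh_volume(mesh) - vox_vol) / vox_vol, 0.10)
})

test_that("boundary sets select inferior/superior body surface nodes", {
  # single-cell cube with band 0.5: bottom face carries 4 corner nodes in
  # the 6-tet split (enumerated oracle), top face the other 4
  mesh <- voxel_to_tet(cuboid_mask(1, 1, 1), NULL, 1)
  mesh <- extract_boundary_sets(mesh, 0.45)
  expect_length(mesh$node_sets$inferior_body, 4)
  expect_length(mesh$node_sets$superior_body, 4)
  expect_length(intersect(mesh$node_sets$inferior_body,
                          mesh$node_sets$superior_body), 0)
  expect_true(all(mesh$nodes[mesh$node_sets$inferior_body, 3] == 0))
  expect_true(all(mesh$nodes[mesh$node_sets$superior_body, 3] == 1))

  # posterior-element nodes never enter the boundary sets
  php <- generate_vertebra_phantom(small_spec(include_posterior = TRUE))
  mp <- extract_boundary_sets(voxel_to_tet(php$mask, php$image, 2), 0.05)
  post_nodes <- unique(as.integer(mp$tets[mp$element_label == 2L, ]))
  expect_length(intersect(mp$node_sets$inferior_body, post_nodes), 0)
  expect_length(intersect(mp$node_sets$superior_body, post_nodes), 0)

  expect_error(extract_boundary_sets(
    voxel_to_tet(cuboid_mask(1, 1, 1), NULL, 1), 1), "overlap")
})

test_that("element labels are inherited by majority vote", {
  ph <- generate_vertebra_phantom(small_spec(include_posterior = TRUE))
  mesh <- voxel_to_tet(ph$mask, ph$image, 2)
  expect_setequal(unique(mesh$element_label), c(1L, 2L))
  expect_gt(sum(mesh$element_label == 1L), sum(mesh$element_label == 2L))
})

test_that("Abaqus export writes nodes, elements and material bins", {
  mesh <- small_mesh()
  mat <- small_materials()
  f <- tempfile(fileext = ".inp")
  write_abaqus_inp(mesh, f, materials = mat, n_bins = 10)
  lines <- readLines(f)
  expect_true(any(grepl("^\\*NODE", lines)))
  expect_true(any(grepl("TYPE=C3D4", lines)))
  expect_true(any(grepl("^\\*SOLID SECTION", lines)))
  expect_true(any(grepl("ENGINEERING CONSTANTS", lines)))
  n_mat <- sum(grepl("^\\*MATERIAL", lines))
  expect_equal(n_mat, sum(grepl("^\\*SOLID SECTION", lines)))
  expect_gte(n_mat, 1)
  expect_lte(n_mat, 10)
})

test_that("mesh sensitivity study reports decreasing element counts", {
  ph <- small_phantom()
  tab5 <- mesh_sensitivity_study(ph$mask, ph$image, c(1, 1.5, 2, 2.5, 3),
                                 n_increments = 4, band_fraction = 0.05)
  expect_equal(nrow(tab5), 5)

  # achievable distinct cell sizes (requested edges snap to voxel multiples)
  tab <- mesh_sensitivity_study(ph$mask, ph$image, c(1, 2, 3),
                                n_increments = 6, band_fraction = 0.05)
  expect_equal(nrow(tab), 3)
  expect_true(all(diff(tab$n_elements) < 0))
  expect_true(is.na(tab$rel_change[1]))
  expect_true(all(!is.na(tab$rel_change[-1])))

  tab1 <- mesh_sensitivity_study(ph$mask, ph$image, 2, n_increments = 4,
                                 band_fraction = 0.05)
  expect_equal(nrow(tab1), 1)
  expect_true(is.na(tab1$rel_change))
})

test_that("dropping posterior elements preserves the body sub-mesh exactly", {
  ph <- generate_vertebra_phantom(small_spec(include_posterior = TRUE))
  full <- voxel_to_tet(ph$mask, ph$image, 2)
  body <- drop_posterior_elements(full)
  expect_true(all(body$element_label == 1L))
  expect_equal(nrow(body$tets), sum(full$element_label == 1L))
  expect_equal(sum(tet_volumes(body)),
               sum(tet_volumes(full)[full$element_label == 1L]))
  # element HU of the shared body elements is unchanged
  hu_full <- map_mesh(full)$hu[full$element_label == 1L]
  hu_body <- map_mesh(body)$hu
  expect_equal(hu_body, hu_full, tolerance = 1e-12)
})
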