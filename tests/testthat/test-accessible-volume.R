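test_that("free-space accessible volume matches the analytic sphere", {
  av <- accessible_volume(point_structure(), 1,
                          dye_parameters(linker_length = 15, grid_spacing = 0.9))
  expect_true(av$ok)
  vol <- av$n_points * av$grid_spacing^3
  expect_lt(abs(vol / (4 / 3 * pi * 15^3) - 1), 0.05)
  # centroid of a symmetric ball sits on the attachment atom
  expect_lt(sqrt(sum(av$mean_position^2)), 1e-9)
})

test_that("mean position equals the brute-force centroid of the grid cloud", {
  s <- build_polyproline(0)
  av <- accessible_volume(s, s$attachment_atoms[1],
                          dye_parameters(linker_length = 8, grid_spacing = 1))
  expect_equal(as.numeric(av$mean_position), as.numeric(colMeans(av$points)))
  expect_equal(av$n_points, nrow(av$points))
})

test_that("degenerate linker collapses the AV onto the attachment site", {
  av <- accessible_volume(point_structure(), 1,
                          dye_parameters(linker_length = 1, linker_width = 1,
                                         dye_radius = 0.5, grid_spacing = 1))
  expect_true(av$ok)
  expect_lte(sqrt(sum(av$mean_position^2)), 1)
})

test_that("adding obstacle atoms never increases the AV point count", {
  base <- point_structure()
  dye <- dye_parameters(linker_length = 6, linker_width = 2, dye_radius = 2,
                        grid_spacing = 1)
  set.seed(11)
  for (rep in 1:4) {
    s <- base
    n_prev <- accessible_volume(s, 1, dye)$n_points
    for (k in 1:4) {
      xyz <- runif(3, -6, 6)
      s$atoms <- rbind(s$atoms,
                       data.frame(name = "C", resno = 1L, resid = "OBS",
                                  element = "C", vdw = 1.7,
                                  x = xyz[1], y = xyz[2], z = xyz[3]))
      n_now <- accessible_volume(s, 1, dye)$n_points
      expect_lte(n_now, n_prev)
      n_prev <- n_now
    }
  }
})

test_that("a fully buried attachment site yields the empty-AV failure state", {
  # cage of carbon atoms on a radius-2.5 shell around the attachment point
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  dirs <- dirs / sqrt(rowSums(dirs^2)) * 2.5
  s <- point_structure()
  s$atoms <- rbind(s$atoms,
                   data.frame(name = "C", resno = 1L, resid = "OBS",
                              element = "C", vdw = 1.7,
                              x = dirs[, 1], y = dirs[, 2], z = dirs[, 3]))
  av <- accessible_volume(s, 1, dye_parameters(linker_length = 3,
                                               linker_width = 1,
                                               dye_radius = 1,
                                               grid_spacing = 0.5))
  expect_false(av$ok)
  expect_equal(av$n_points, 0L)
  ok_av <- accessible_volume(point_structure(), 1,
                             dye_parameters(3, 1, 1, 0.5))
  expect_error(mean_position_distance(av, ok_av), "unreachable")
})

test_that("mean-position distance is the Euclidean centroid distance", {
  dye <- dye_parameters(linker_length = 6, grid_spacing = 0.75)
  s <- two_point_structure(20)
  av1 <- accessible_volume(s, 1, dye)
  av2 <- accessible_volume(s, 2, dye)
  expect_equal(mean_position_distance(av1, av1), 0)
  # symmetric free-space AVs centre on their attachment atoms 20 A apart
  # (each sees the other attachment atom, but it is outside linker reach)
  expect_equal(mean_position_distance(av1, av2), 20, tolerance = 0.02)
  expect_equal(mean_position_distance(av1, av2),
               mean_position_distance(av2, av1))
})

test_that("dye parameter invariants are enforced", {
  expect_error(dye_parameters(grid_spacing = 5, linker_width = 4.5),
               "grid_spacing")
  expect_error(dye_parameters(linker_length = -1))
})
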