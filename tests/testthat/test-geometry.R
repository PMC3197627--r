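test_that("bilayer midplane follows the leaflet means", {
  expect_equal(bilayer_midplane(c(rep(20, 10), rep(-20, 10)))$z0, 0)
  expect_equal(bilayer_midplane(c(rep(25, 10), rep(-15, 10)))$z0, 5)
  # brute-force comparison on random leaflet populations
  set.seed(4)
  for (k in 1:5) {
    up <- rnorm(30, 19, 1.5); lo <- rnorm(25, -19, 1.5)
    m <- bilayer_midplane(c(up, lo))
    expect_equal(m$z0, (mean(up) + mean(lo)) / 2, tolerance = 1e-12)
    expect_true(m$ok)
  }
  # unimodal phosphate distribution is flagged, not silently used
  expect_false(bilayer_midplane(rnorm(40, 0, 2))$ok)
})

test_that("helix axis fit recovers orientation with the documented sign", {
  pep <- tm2_peptides("WY_scan")
  h <- build_ideal_helix(pep[pep$id == "TarEc_WT", ])
  # the canonicalized C-alpha trace lies exactly along z
  ca <- as.matrix(h$atoms[h$atoms$atom == "CA", c("x", "y", "z")])
  axa <- helix_axis(ca)
  expect_equal(abs(axa[3]), 1, tolerance = 1e-6)
  # backbone-bead centroids spiral slightly; their axis is within 0.2 degrees
  cg <- map_to_cg(h)
  bb <- cg$xyz[cg$beads$role == "BB", ]
  ax <- helix_axis(bb)
  expect_lt(acos(min(1, abs(ax[3]))) * 180 / pi, 0.2)
  expect_gt(ax[3], 0)  # points C-terminus -> N-terminus (= +z as built)
  # 30 degree rotation about y is recovered
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3, byrow = TRUE)
  ax2 <- helix_axis(bb %*% t(R))
  expect_equal(acos(ax2[3]) * 180 / pi, 30, tolerance = 0.5 / 30)
  # reversing bead order flips only the sign convention
  ax3 <- helix_axis(bb[nrow(bb):1, ])
  expect_equal(abs(sum(ax * ax3)), 1, tolerance = 1e-8)
  expect_error(helix_axis(bb[1:4, ]), "at least 6")
  expect_error(helix_axis(matrix(rep(c(1, 1, 1), 8), 8, 3, byrow = TRUE)),
               "degenerate")
})

test_that("imposed pose parameters are recovered within stated tolerances", {
  spec <- synthetic_spec(shift_mean = 1.5, shift_sd = 0, tilt_mean = 10,
                         tilt_sd = 0, rotation_mean = 40, rotation_kappa = 1e8,
                         ar1 = 0, noise_sd = 0, n_replicas = 1, n_frames = 4)
  ens <- generate_ensemble(spec, seed = 3)
  g <- trajectory_geometry(ens$trajectories[[1]])
  expect_true(all(abs(g$z_shift - 1.5) <= 0.1))
  expect_true(all(abs(g$tilt - 10) <= 0.5))
  expect_true(all(abs(circ_diff_deg(g$rotation, 40)) <= 2))
  expect_true(all(g$is_tm))
})

test_that("an upright centred helix reports zero shift and tilt", {
  spec <- synthetic_spec(shift_mean = 0, shift_sd = 0, tilt_mean = 0,
                         tilt_sd = 0, ar1 = 0, noise_sd = 0,
                         n_replicas = 1, n_frames = 2)
  g <- trajectory_geometry(generate_ensemble(spec, seed = 1)$trajectories[[1]])
  expect_equal(g$z_shift, c(0, 0), tolerance = 1e-6)
  expect_equal(g$tilt, c(0, 0), tolerance = 1e-5)
})

test_that("measures are invariant under whole-frame rigid motions about z", {
  spec <- synthetic_spec(shift_mean = 1, shift_sd = 0.3, tilt_mean = 15,
                         tilt_sd = 2, rotation_mean = 70, rotation_kappa = 10,
                         ar1 = 0, noise_sd = 0.2, n_replicas = 1, n_frames = 6)
  ens <- generate_ensemble(spec, seed = 8)
  tr <- ens$trajectories[[1]]
  g0 <- trajectory_geometry(tr)
  # rotate every frame about the box-centre z axis (gauge transformation)
  phi <- 117 * pi / 180
  R <- matrix(c(cos(phi), -sin(phi), 0, sin(phi), cos(phi), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  cen <- c(tr$box[1, 1:2] / 2, 0)
  tr2 <- tr
  tr2$frames <- lapply(tr$frames, function(f) {
    sweep(sweep(f, 2, cen) %*% t(R), 2, -cen)
  })
  g1 <- trajectory_geometry(tr2)
  expect_equal(g1$z_shift, g0$z_shift, tolerance = 1e-8)
  expect_equal(g1$tilt, g0$tilt, tolerance = 1e-8)
  expect_equal(circ_diff_deg(g1$rotation, g0$rotation), rep(0, 6), tolerance = 1e-6)
  # rigid translation (with z re-centring of the bilayer) is also invariant
  tr3 <- tr
  tr3$frames <- lapply(tr$frames, function(f) sweep(f, 2, c(-3, 4, 7)))
  g2 <- trajectory_geometry(tr3)
  expect_equal(g2$z_shift, g0$z_shift, tolerance = 1e-6)
  expect_equal(g2$tilt, g0$tilt, tolerance = 1e-8)
})

test_that("transmembrane classification uses inclusive thresholds", {
  # boundary tilt = 50 is transmembrane (inclusive)
  spec <- synthetic_spec(shift_mean = 0, shift_sd = 0, tilt_mean = 50,
                         tilt_sd = 0, ar1 = 0, noise_sd = 0,
                         n_replicas = 1, n_frames = 2)
  g <- trajectory_geometry(generate_ensemble(spec, seed = 2)$trajectories[[1]])
  expect_equal(g$tilt, c(50, 50), tolerance = 1e-6)
  expect_true(all(g$is_tm))
  # a helix lying along one leaflet (tilt ~90, termini same side) is interfacial
  spec2 <- synthetic_spec(shift_mean = 17, shift_sd = 0, tilt_mean = 88,
                          tilt_sd = 0, ar1 = 0, noise_sd = 0,
                          n_replicas = 1, n_frames = 2)
  g2 <- trajectory_geometry(generate_ensemble(spec2, seed = 2)$trajectories[[1]])
  expect_false(any(g2$is_tm))
  # rotation flagged undefined when the axis is nearly in-plane
  expect_false(any(g2$rotation_defined))
})
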