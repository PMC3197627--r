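test_that("analytic forces match the finite-difference gradient oracle", {
  sys <- random_system(n = 50, seed = 42, chain = TRUE)
  sys$bonds <- tibble::tibble(i = 1:3, j = 2:4, b0 = c(4, 4.5, 5), k = 12.5)
  sys$angles <- tibble::tibble(i = 1, j = 2, k = 3, theta0 = 120, ka = 25)
  sys$dihedrals <- tibble::tibble(i = 1, j = 2, k = 3, l = 4, phi0 = 60, kd = 50)
  ff <- martini_forcefield()
  fr <- compute_forces(sys, ff)
  E_of <- function(xyz) {
    s <- sys; s$xyz <- xyz
    compute_forces(s, ff)$energies$potential
  }
  h <- 1e-5
  set.seed(1)
  worst <- 0
  for (i in sample(50, 15)) {
    for (d in 1:3) {
      xp <- sys$xyz; xm <- sys$xyz
      xp[i, d] <- xp[i, d] + h
      xm[i, d] <- xm[i, d] - h
      fd <- -(E_of(xp) - E_of(xm)) / (2 * h)
      denom <- max(abs(fd), abs(fr$forces[i, d]))
      if (denom > 1e-6) worst <- max(worst, abs(fd - fr$forces[i, d]) / denom)
    }
  }
  expect_lt(worst, 1e-4)
  # Newton's third law: internal forces sum to zero
  expect_lt(max(abs(colSums(fr$forces))), 1e-8)
})

test_that("pair interactions are exactly zero at the 12 A cutoff", {
  ff <- martini_forcefield()
  beads <- tibble::tibble(name = "X", type = c("P4", "C1"), charge = c(1, -1),
                          mass = 72, molecule = "W", mol_id = 1:2, resid = 1:2,
                          resname = "W", role = "W")
  sys <- pistonsim:::new_cg_system(beads, rbind(c(5, 5, 5), c(17, 5, 5)),
                                   box = c(40, 40, 40))
  fr <- compute_forces(sys, ff)
  expect_identical(max(abs(fr$forces)), 0)
  expect_identical(fr$energies$potential, 0)
})

test_that("overlapping beads raise an error naming the pair", {
  beads <- tibble::tibble(name = "X", type = "P4", charge = 0, mass = 72,
                          molecule = "W", mol_id = 1:2, resid = 1:2,
                          resname = "W", role = "W")
  sys <- pistonsim:::new_cg_system(beads, rbind(c(5, 5, 5), c(5.05, 5, 5)),
                                   box = c(40, 40, 40))
  expect_error(compute_forces(sys), "overlapping beads 1 and 2")
})

test_that("neighbour list equals brute-force enumeration, including periodic images", {
  set.seed(99)
  for (trial in 1:3) {
    sys <- random_system(n = 100, box = c(28, 34, 40), min_sep = 1,
                         seed = 100 + trial, charged = FALSE)
    nl <- neighbor_list(sys, 12)
    bf <- oracle_pairs(sys$xyz, sys$box, 12)
    expect_setequal(pair_key(nl), pair_key(bf))
    expect_equal(nrow(nl), nrow(bf))
  }
  # beads straddling the boundary at 1 A image distance
  beads <- tibble::tibble(name = "X", type = "P4", charge = 0, mass = 72,
                          molecule = "W", mol_id = 1:2, resid = 1:2,
                          resname = "W", role = "W")
  sys <- pistonsim:::new_cg_system(beads, rbind(c(0.5, 5, 5), c(29.5, 5, 5)),
                                   box = c(30, 30, 30))
  nl <- neighbor_list(sys, 12)
  expect_equal(nrow(nl), 1)
  # empty system -> empty list
  empty <- pistonsim:::new_cg_system(beads[0, ], matrix(0, 0, 3), box = c(30, 30, 30))
  expect_equal(nrow(neighbor_list(empty, 12)), 0)
  # too-small box is refused
  expect_error(neighbor_list(pistonsim:::new_cg_system(
    beads, rbind(c(1, 1, 1), c(2, 2, 2)), box = c(20, 30, 30)), 12),
    "box too small")
})

test_that("Berendsen thermostat scaling has its fixed point at T_ref", {
  p <- engine_params()
  expect_identical(berendsen_lambda(p$t_ref, p), 1)
  expect_gt(berendsen_lambda(200, p), 1)
  expect_lt(berendsen_lambda(500, p), 1)
  expect_equal(berendsen_mu(p$p_ref, p), 1)
})

test_that("trajectories are deterministic given seed and configuration", {
  sys <- lj_fluid(n_side = 4, box_len = 26)
  ff <- martini_forcefield()
  r1 <- run_md(sys, ff, engine_params(dt = 0.02), nsteps = 200, seed = 5,
               sample_every = 50, frame_every = 100)
  r2 <- run_md(sys, ff, engine_params(dt = 0.02), nsteps = 200, seed = 5,
               sample_every = 50, frame_every = 100)
  expect_identical(r1$system$xyz, r2$system$xyz)
  expect_identical(r1$velocities, r2$velocities)
  expect_identical(r1$energies, r2$energies)
})

test_that("centre-of-mass momentum stays removed", {
  sys <- lj_fluid(n_side = 4, box_len = 26)
  ff <- martini_forcefield()
  r <- run_md(sys, ff, engine_params(dt = 0.02), nsteps = 1000, seed = 3,
              sample_every = 0)
  drift <- colSums(r$velocities * sys$beads$mass) / sum(sys$beads$mass)
  expect_lt(max(abs(drift)), 1e-6)
})

test_that("energy report is internally consistent", {
  sys <- lj_fluid(n_side = 4, box_len = 26)
  r <- run_md(sys, martini_forcefield(), engine_params(dt = 0.02), nsteps = 100,
              seed = 2, sample_every = 10)
  e <- r$energies
  expect_true(all(e$ekin >= 0))
  expect_equal(e$etot, e$epot + e$ekin)
  ndf <- 3 * nrow(sys$beads) - 3
  expect_equal(e$temperature, 2 * e$ekin / (ndf * 0.0083144621), tolerance = 1e-10)
})
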