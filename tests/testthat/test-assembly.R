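test_that("preformed bilayer builds two leaflets with balanced occupancy", {
  spec <- assembly_spec(n_lipid = 32, n_water = 150, box = c(33, 33, 66),
                       mode = "preformed_bilayer", seed = 2)
  sys <- build_system(spec)
  ph <- sys$xyz[sys$beads$role == "PO4", 3]
  mid <- median(ph)
  expect_equal(sum(ph > mid), 16)
  expect_equal(sum(ph <= mid), 16)
  # phosphates confined to two narrow slabs
  expect_lt(sd(ph[ph > mid]), 2)
  expect_lt(sd(ph[ph <= mid]), 2)
  expect_equal(sum(sys$beads$molecule == "W"), 150)
})

test_that("system building is deterministic and respects the distance floor", {
  spec <- assembly_spec(n_lipid = 24, n_water = 120, box = c(32, 32, 48),
                       mode = "self_assembly", seed = 9, min_dist = 2.5)
  a <- build_system(spec)
  b <- build_system(spec)
  expect_identical(a$xyz, b$xyz)
  # no inter-molecular pair below the threshold (bonded intra pairs may be)
  nl <- neighbor_list(a, 2.5)
  mol <- a$beads$mol_id
  inter <- nl[mol[nl[, 1]] != mol[nl[, 2]], , drop = FALSE]
  expect_equal(nrow(inter), 0)
})

test_that("helix insertion reserves space and spans the preformed bilayer", {
  pep <- tm2_peptides("WY_scan")
  cg <- map_to_cg(build_ideal_helix(pep[pep$id == "TarEc_WT", ]))
  spec <- assembly_spec(n_lipid = 32, n_water = 150, box = c(34, 34, 66),
                       mode = "preformed_bilayer", seed = 4)
  sys <- build_system(spec, cg)
  bb <- sys$xyz[sys$beads$role == "BB", ]
  ph <- sys$xyz[sys$beads$role == "PO4", 3]
  expect_gt(max(bb[, 3]), max(ph) - 5)
  expect_lt(min(bb[, 3]), min(ph) + 5)
  nl <- neighbor_list(sys, 2.0)
  mol <- sys$beads$mol_id
  expect_equal(nrow(nl[mol[nl[, 1]] != mol[nl[, 2]], , drop = FALSE]), 0)
})

test_that("replica runs are isolated, seeded and tolerant of failures", {
  spec <- assembly_spec(n_lipid = 12, n_water = 60, box = c(26, 26, 40),
                       mode = "self_assembly", seed = 1)
  reps <- run_ensemble(spec, n_replicas = 2, length_ns = 0.004, seed = 3,
                       equil_ps = 2, n_frames = 4, barostat = FALSE)
  expect_length(reps, 2)
  expect_true(all(vapply(reps, `[[`, logical(1), "ok")))
  expect_false(identical(reps[[1]]$trajectory$frames[[1]],
                         reps[[2]]$trajectory$frames[[1]]))
  expect_equal(reps[[1]]$manifest$seed + 7919, reps[[2]]$manifest$seed)

  # serial and parallel execution agree replica by replica
  reps_par <- run_ensemble(spec, n_replicas = 2, length_ns = 0.004, seed = 3,
                           workers = 2, equil_ps = 2, n_frames = 4,
                           barostat = FALSE)
  expect_equal(reps_par[[1]]$trajectory$frames, reps[[1]]$trajectory$frames)
  expect_equal(reps_par[[2]]$trajectory$frames, reps[[2]]$trajectory$frames)

  # a broken system is reported as a failed replica, not an exception
  bad <- build_system(spec)
  bad$xyz[2, ] <- bad$xyz[1, ]
  r <- run_replica(bad, length_ns = 0.001, seed = 1, equil_ps = 0.01)
  expect_false(r$ok)
  expect_match(r$error, "overlap|non-finite")
})

test_that("short self-assembly dynamics drives hydrophobic aggregation", {
  # scaled-down dispersion: lipid tails cluster within a few hundred ps
  spec <- assembly_spec(n_lipid = 20, n_water = 110, box = c(30, 30, 42),
                       mode = "self_assembly", seed = 6, min_dist = 2.6)
  sys <- build_system(spec)
  ff <- martini_forcefield()
  sys <- minimize_system(sys, ff, nsteps = 150)
  tail_contacts <- function(s) {
    idx <- which(s$beads$name %in% c("C2A", "C3A", "C2B", "C3B"))
    nl <- neighbor_list(s, 6)
    sum(nl[, 1] %in% idx & nl[, 2] %in% idx &
          s$beads$mol_id[nl[, 1]] != s$beads$mol_id[nl[, 2]])
  }
  before <- tail_contacts(sys)
  eq <- run_md(sys, ff, engine_params(dt = 0.002), nsteps = 2000, seed = 2,
               sample_every = 0)
  pr <- run_md(eq$system, ff, engine_params(dt = 0.02), nsteps = 25000,
               velocities = eq$velocities, sample_every = 0)
  after <- tail_contacts(pr$system)
  expect_gt(after, 2 * max(before, 1))
})

test_that("bilayer integrity metric distinguishes intact from dispersed states", {
  spec <- assembly_spec(n_lipid = 32, n_water = 100, box = c(33, 33, 66),
                       mode = "preformed_bilayer", seed = 2)
  sys <- build_system(spec)
  tr <- pistonsim:::new_trajectory(list(sys$xyz), matrix(sys$box, 1, 3), 0, sys$beads)
  expect_true(all(bilayer_integrity(tr)$intact))
  disp <- build_system(assembly_spec(n_lipid = 32, n_water = 100,
                                     box = c(33, 33, 66),
                                     mode = "self_assembly", seed = 3))
  tr2 <- pistonsim:::new_trajectory(list(disp$xyz), matrix(disp$box, 1, 3), 0, disp$beads)
  expect_false(any(bilayer_integrity(tr2)$intact))
})
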