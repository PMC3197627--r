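test_that("forcefield table is symmetric, total, and physically ordered", {
  ff <- martini_forcefield()
  expect_equal(length(ff$types), 18)
  expect_true(all(ff$epsilon == t(ff$epsilon)))
  expect_true(all(ff$epsilon > 0))
  expect_true(all(ff$sigma > 0))
  # every pair of shipped types resolves (no silent defaults)
  for (a in ff$types) for (b in ff$types) {
    p <- ff_pair(ff, a, b)
    expect_true(is.finite(p$epsilon) && is.finite(p$sigma))
  }
  expect_error(ff_pair(ff, "P4", "Z9"), "unknown bead type")
  # hydrophobic mismatch: water-tail far weaker than water-water
  expect_lt(ff$epsilon["P4", "C1"], ff$epsilon["P4", "P4"])
  # charged-apolar uses the long-sigma super-repulsive level
  expect_equal(ff$sigma["Q0", "C1"], 6.2)
})

test_that("pair potential and force vanish at and beyond the cutoff", {
  pp <- pair_potential(c(8, 11.999, 12, 13), epsilon = 3.5, sigma = 4.7, qq = 1)
  # both vanish continuously approaching the cutoff ...
  expect_true(abs(pp$energy[2]) < 1e-8 && abs(pp$force[2]) < 1e-4)
  expect_identical(pp$energy[3:4], c(0, 0))
  expect_identical(pp$force[3:4], c(0, 0))
  expect_true(pp$energy[1] != 0)
})

test_that("CG mapping has one backbone bead per residue and table-driven sidechains", {
  map <- cg_mapping_table()
  h <- build_ideal_helix(strrep("A", 30))
  cg <- map_to_cg(h)
  expect_equal(sum(cg$beads$role == "BB"), 30)
  expect_equal(nrow(cg$beads), 30)  # Ala: backbone only

  pep <- tm2_peptides("WY_scan")
  wt <- pep[pep$id == "TarEc_WT", ]
  cgwt <- map_to_cg(build_ideal_helix(wt))
  # per-residue bead counts agree with the shipped mapping table
  for (r in unique(cgwt$beads$resid)) {
    rn <- cgwt$beads$resname[cgwt$beads$resid == r][1]
    expect_equal(sum(cgwt$beads$resid == r), sum(map$residue == rn), label = rn)
  }
  trp <- cgwt$beads[cgwt$beads$resname == "TRP", ]
  expect_gt(nrow(trp), 3)  # backbone + multi-bead ring
})

test_that("mapping is approximately 4 heavy atoms per bead", {
  pep <- tm2_peptides("WY_scan")
  wt <- pep[pep$id == "TarEc_WT", ]
  h <- build_ideal_helix(wt)
  cg <- map_to_cg(h)
  ratio <- nrow(h$atoms) / nrow(cg$beads)
  expect_true(ratio >= 3 && ratio <= 5)  # 4:1 within +/-25%
})

test_that("basic sidechains carry a +1 charged bead; termini are uncharged", {
  pep <- tm2_peptides("Basic_Trg")
  mut <- pep[pep$id == "T215R", ]
  cg <- map_to_cg(build_ideal_helix(mut))
  arg <- cg$beads[cg$beads$resid == 215, ]
  expect_true(any(arg$charge == 1 & substr(arg$type, 1, 1) == "Q"))
  term <- cg$beads[cg$beads$resid %in% range(cg$beads$resid) & cg$beads$role == "BB", ]
  expect_true(all(term$charge == 0))
})

test_that("lipid and water construction has documented counts and charges", {
  sys <- build_lipid_and_water(128, 3000)
  lip <- sys$beads[sys$beads$molecule == "DPPC", ]
  expect_equal(length(unique(lip$mol_id)), 128)
  expect_equal(sum(sys$beads$molecule == "W"), 3000)
  # each lipid is zwitterionic: +1 choline, -1 phosphate, net 0
  per <- tapply(lip$charge, lip$mol_id, sum)
  expect_true(all(per == 0))
  expect_equal(sum(lip$charge[lip$name == "NC3"]), 128)
  # single isolated lipid is a valid topology
  one <- build_lipid_and_water(1, 0)
  expect_equal(nrow(one$beads), 12)
  expect_true(all(one$bonds$i <= 12 & one$bonds$j <= 12))
})

test_that("total system charge equals the peptide charged-bead sum", {
  pep <- tm2_peptides("WY_scan")
  wt <- pep[pep$id == "TarEc_WT", ]
  cg <- map_to_cg(build_ideal_helix(wt))
  sys <- cg_concat(cg, build_lipid_and_water(16, 100))
  expect_equal(system_charge(sys), sum(cg$beads$charge))
})

test_that("peptide bonded terms restrain the mapped ideal geometry", {
  pep <- tm2_peptides("WY_scan")
  cg <- map_to_cg(build_ideal_helix(pep[pep$id == "TarEc_WT", ]))
  expect_true(all(is.finite(cg$bonds$b0)))
  expect_true(all(is.finite(cg$angles$theta0)))
  expect_true(all(is.finite(cg$dihedrals$phi0)))
  bb <- which(cg$beads$role == "BB")
  expect_equal(nrow(cg$angles), length(bb) - 2)
  expect_equal(nrow(cg$dihedrals), length(bb) - 3)
  # the restrained minimum is the built structure: forces are tiny there
  cg$box <- c(40, 40, 70)
  cg$xyz <- sweep(cg$xyz, 2, -c(20, 20, 35))
  f <- compute_forces(cg)
  expect_equal(f$energies$bond, 0, tolerance = 1e-8)
  expect_equal(f$energies$angle, 0, tolerance = 1e-8)
  expect_equal(f$energies$dihedral, 0, tolerance = 1e-8)
})
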