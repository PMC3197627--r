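# Coarse-grained mapping (~4 heavy atoms per bead) and molecule topologies.

#' Residue-to-bead mapping table
#'
#' The shipped MARTINI-style mapping: one backbone bead (N0 for helical
#' backbone, atoms N/CA/C/O) per residue plus zero or more sidechain beads,
#' each listing the heavy atoms whose centroid defines the bead position.
#' Arg/Lys carry a charged Qd (+1) sidechain bead; Asp/Glu a Qa (-1) bead.
#'
#' @return tibble with columns residue, bead, type, charge, atoms (list of
#'   atom-name vectors).
#' @export
cg_mapping_table <- function() {
  m <- read.csv(pkg_extdata("cg_residue_mapping.csv"), stringsAsFactors = FALSE)
  tibble(residue = m$residue, bead = m$bead, type = m$type, charge = m$charge,
         atoms = strsplit(m$atoms, ";", fixed = TRUE))
}

empty_bonds <- function() tibble(i = integer(), j = integer(), b0 = numeric(), k = numeric())
empty_angles <- function() tibble(i = integer(), j = integer(), k = integer(),
                                  theta0 = numeric(), ka = numeric())
empty_dihedrals <- function() tibble(i = integer(), j = integer(), k = integer(),
                                     l = integer(), phi0 = numeric(), kd = numeric())

new_cg_system <- function(beads, xyz, bonds = empty_bonds(), angles = empty_angles(),
                          dihedrals = empty_dihedrals(), box = c(NA_real_, NA_real_, NA_real_)) {
  structure(list(beads = beads, xyz = xyz, bonds = bonds, angles = angles,
                 dihedrals = dihedrals, box = box), class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat("<cg_system> ", nrow(x$beads), " beads, ",
      nrow(x$bonds), " bonds, ", nrow(x$angles), " angles, ",
      nrow(x$dihedrals), " dihedral restraints\n", sep = "")
  if (!anyNA(x$box)) cat("box:", paste(sprintf("%.1f", x$box), collapse = " x "), "A\n")
  invisible(x)
}

#' Map an atomistic helix to coarse-grained beads
#'
#' Each bead is placed at the centroid of its mapped heavy atoms. Bonded
#' terms restrain the mapped geometry: harmonic bonds between backbone
#' neighbours and between all bead pairs within a residue, cosine-harmonic
#' angles over backbone triples, and harmonic dihedral restraints over
#' backbone quadruples; their equilibrium values are measured on the ideal
#' mapped structure so the restraints maintain helicity. Termini are
#' uncharged (the charge column comes from the mapping table only).
#'
#' @param helix an `atomistic_helix` from [build_ideal_helix()].
#' @param k_bond harmonic bond constant (kJ/mol/A^2).
#' @param k_angle cosine-harmonic backbone angle constant (kJ/mol).
#' @param k_dihedral backbone dihedral restraint constant (kJ/mol/rad^2);
#'   calibrated so helicity persists at 323 K.
#' @return a `cg_system` fragment (molecule `"PEP"`).
#' @export
map_to_cg <- function(helix, k_bond = 12.5, k_angle = 100, k_dihedral = 100) {
  stopifnot(inherits(helix, "atomistic_helix"))
  map <- cg_mapping_table()
  atoms <- helix$atoms
  resids <- sort(unique(atoms$resid))
  beads <- list(); xyz <- list()
  for (r in resids) {
    res <- atoms[atoms$resid == r, ]
    resname <- res$resname[1]
    mm <- map[map$residue == resname, ]
    if (!nrow(mm)) abort(paste0("residue absent from mapping table: ", resname))
    for (k in seq_len(nrow(mm))) {
      sel <- res[res$atom %in% mm$atoms[[k]], ]
      if (!nrow(sel)) abort(paste0("no atoms for bead ", mm$bead[k], " of ", resname))
      beads[[length(beads) + 1]] <- tibble(
        name = mm$bead[k], type = mm$type[k], charge = mm$charge[k],
        mass = .const$bead_mass, molecule = "PEP", mol_id = 1L,
        resid = r, resname = resname,
        role = if (mm$bead[k] == "BB") "BB" else "SC")
      xyz[[length(xyz) + 1]] <- c(mean(sel$x), mean(sel$y), mean(sel$z))
    }
  }
  beads <- bind_rows(beads)
  xyz <- do.call(rbind, xyz)

  bonds <- list(); angles <- list(); dihedrals <- list()
  dist_ij <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  bb <- which(beads$name == "BB")
  # backbone chain bonds
  if (length(bb) > 1) {
    for (k in seq_len(length(bb) - 1)) {
      i <- bb[k]; j <- bb[k + 1]
      bonds[[length(bonds) + 1]] <- tibble(i = i, j = j, b0 = dist_ij(i, j), k = k_bond)
    }
  }
  # intra-residue bead network (rigidifies multi-bead sidechains)
  for (r in resids) {
    idx <- which(beads$resid == r)
    if (length(idx) > 1) {
      cmb <- utils::combn(idx, 2)
      for (c_ in seq_len(ncol(cmb))) {
        i <- cmb[1, c_]; j <- cmb[2, c_]
        bonds[[length(bonds) + 1]] <- tibble(i = i, j = j, b0 = dist_ij(i, j), k = k_bond)
      }
    }
  }
  angle_of <- function(i, j, k) {
    u <- xyz[i, ] - xyz[j, ]; v <- xyz[k, ] - xyz[j, ]
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }
  if (length(bb) > 2) {
    for (k in seq_len(length(bb) - 2)) {
      tr <- bb[k:(k + 2)]
      th0 <- angle_of(tr[1], tr[2], tr[3])
      angles[[length(angles) + 1]] <- tibble(
        i = tr[1], j = tr[2], k = tr[3], theta0 = th0, ka = k_angle)
    }
  }
  if (length(bb) > 3) {
    for (k in seq_len(length(bb) - 3)) {
      q <- bb[k:(k + 3)]
      phi0 <- dihedral_angle(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ])
      dihedrals[[length(dihedrals) + 1]] <- tibble(
        i = q[1], j = q[2], k = q[3], l = q[4], phi0 = phi0, kd = k_dihedral)
    }
  }
  new_cg_system(beads, xyz,
                if (length(bonds)) bind_rows(bonds) else empty_bonds(),
                if (length(angles)) bind_rows(angles) else empty_angles(),
                if (length(dihedrals)) bind_rows(dihedrals) else empty_dihedrals())
}

# single DPPC template, head at z = 0 and tails toward -z
dppc_template <- function(k_bond = 12.5, k_angle = 25) {
  nm <- c("NC3", "PO4", "GL1", "GL2", "C1A", "C2A", "C3A", "C4A",
          "C1B", "C2B", "C3B", "C4B")
  ty <- c("Q0", "Qa", "Na", "Na", rep("C1", 8))
  q <- c(1, -1, rep(0, 10))
  s <- 4.2  # initial bead spacing, relaxes toward b0 = 4.7 in equilibration
  xyz <- rbind(
    c(0, 0, 0), c(0, 0, -s), c(0, 0, -2 * s), c(2.5, 0, -2.2 * s),
    c(0, 0, -3 * s), c(0, 0, -4 * s), c(0, 0, -5 * s), c(0, 0, -6 * s),
    c(2.5, 0, -3.2 * s), c(2.5, 0, -4.2 * s), c(2.5, 0, -5.2 * s), c(2.5, 0, -6.2 * s))
  beads <- tibble(name = nm, type = ty, charge = q, mass = .const$bead_mass,
                  molecule = "DPPC", mol_id = 1L, resid = 1L, resname = "DPPC",
                  role = nm)
  bidx <- rbind(c(1, 2), c(2, 3), c(3, 4), c(3, 5), c(5, 6), c(6, 7), c(7, 8),
                c(4, 9), c(9, 10), c(10, 11), c(11, 12))
  bonds <- tibble(i = bidx[, 1], j = bidx[, 2],
                  b0 = c(4.7, 4.7, 3.7, 4.7, 4.7, 4.7, 4.7, 4.7, 4.7, 4.7, 4.7),
                  k = k_bond)
  aidx <- rbind(c(2, 3, 4), c(2, 3, 5), c(3, 5, 6), c(5, 6, 7), c(6, 7, 8),
                c(4, 9, 10), c(9, 10, 11), c(10, 11, 12))
  angles <- tibble(i = aidx[, 1], j = aidx[, 2], k = aidx[, 3],
                   theta0 = c(120, rep(180, 7)), ka = k_angle)
  new_cg_system(beads, xyz, bonds, angles)
}

water_template <- function() {
  new_cg_system(tibble(name = "W", type = "P4", charge = 0,
                       mass = .const$bead_mass, molecule = "W", mol_id = 1L,
                       resid = 1L, resname = "W", role = "W"),
                matrix(0, 1, 3))
}

#' Concatenate coarse-grained fragments
#'
#' Bead indices in bonded terms are offset; molecule ids are renumbered
#' consecutively within each molecule name.
#'
#' @param ... `cg_system` fragments.
#' @param box box vector (A) for the combined system (optional).
#' @return a `cg_system`.
#' @export
cg_concat <- function(..., box = NULL) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  stopifnot(all(vapply(parts, inherits, logical(1), "cg_system")))
  off <- 0L; mol_off <- 0L
  beads <- list(); xyz <- list(); bonds <- list(); angles <- list(); dih <- list()
  for (p in parts) {
    b <- p$beads
    b$mol_id <- b$mol_id + mol_off
    mol_off <- max(b$mol_id)
    beads[[length(beads) + 1]] <- b
    xyz[[length(xyz) + 1]] <- p$xyz
    if (nrow(p$bonds)) bonds[[length(bonds) + 1]] <- mutate(p$bonds, i = .data$i + off, j = .data$j + off)
    if (nrow(p$angles)) angles[[length(angles) + 1]] <- mutate(p$angles, i = .data$i + off,
                                                               j = .data$j + off, k = .data$k + off)
    if (nrow(p$dihedrals)) dih[[length(dih) + 1]] <- mutate(p$dihedrals, i = .data$i + off,
                                                            j = .data$j + off, k = .data$k + off,
                                                            l = .data$l + off)
    off <- off + nrow(p$beads)
  }
  beads <- bind_rows(beads)
  out <- new_cg_system(beads, do.call(rbind, xyz),
                       if (length(bonds)) bind_rows(bonds) else empty_bonds(),
                       if (length(angles)) bind_rows(angles) else empty_angles(),
                       if (length(dih)) bind_rows(dih) else empty_dihedrals())
  if (!is.null(box)) out$box <- box
  out
}

# rigid-body transform: xyz <- xyz %*% t(R) + shift
cg_transform <- function(sys, R = diag(3), shift = c(0, 0, 0)) {
  sys$xyz <- sweep(sys$xyz %*% t(R), 2, -shift)
  sys
}

#' Build lipid and water fragments
#'
#' Produces `n_lipid` DPPC molecules (zwitterionic: choline +1, phosphate -1)
#' and `n_water` single-bead P4 waters on a simple non-overlapping grid.
#' Spatial arrangement for simulation is the assembly module's job
#' ([build_system()]); this constructor guarantees valid topology and counts.
#'
#' @param n_lipid,n_water molecule counts (`n_lipid` > 0, `n_water` >= 0).
#' @return a `cg_system`.
#' @export
build_lipid_and_water <- function(n_lipid, n_water) {
  stopifnot(n_lipid > 0, n_water >= 0)
  lip <- dppc_template()
  nx <- ceiling(sqrt(n_lipid))
  lipids <- lapply(seq_len(n_lipid) - 1L, function(k) {
    cg_transform(lip, shift = c(8 * (k %% nx), 8 * (k %/% nx), 0))
  })
  waters <- NULL
  if (n_water > 0) {
    w <- water_template()
    nwx <- ceiling(n_water^(1 / 3))
    waters <- lapply(seq_len(n_water) - 1L, function(k) {
      cg_transform(w, shift = c(4.7 * (k %% nwx), 4.7 * ((k %/% nwx) %% nwx),
                                40 + 4.7 * (k %/% (nwx * nwx))))
    })
  }
  do.call(cg_concat, c(lipids, waters))
}

#' Total charge of a coarse-grained system
#' @param sys a `cg_system`.
#' @return net charge in elementary charges.
#' @export
system_charge <- function(sys) sum(sys$beads$charge)
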