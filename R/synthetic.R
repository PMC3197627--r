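# Synthetic CG frames of a helix in a bilayer with prescribed shift/tilt/
# rotation distributions, so every analysis stage is testable without MD.

#' Specification for synthetic trajectories
#'
#' Per-frame helix pose parameters are drawn from stationary AR(1) processes:
#' z-shift Gaussian (A), tilt Gaussian truncated to [0, 90] deg, rotation a
#' wrapped distribution with von Mises concentration `rotation_kappa`
#' (sampled exactly von Mises when `ar1 = 0`, otherwise as a wrapped
#' Gaussian AR(1) with matched stationary spread 1/sqrt(kappa)). Each bead
#' additionally receives isotropic Gaussian positional noise. Two phosphate
#' leaflets are placed at `leaflet_z` on a lateral grid.
#'
#' @param shift_mean,shift_sd Gaussian z-shift parameters (A).
#' @param tilt_mean,tilt_sd Gaussian tilt parameters (deg).
#' @param rotation_mean,rotation_kappa von Mises rotation parameters (deg, -).
#' @param ar1 lag-1 autocorrelation of all three pose series (0 <= ar1 < 1).
#' @param noise_sd per-bead positional noise (A).
#' @param leaflet_z phosphate leaflet z positions (A), length 2.
#' @param tilt_azimuth lab-frame direction (deg from +x) toward which the
#'   helix leans.
#' @param n_replicas,n_frames ensemble dimensions.
#' @param n_phosphate phosphate beads per leaflet.
#' @param box box lengths (A).
#' @param dt_frame frame spacing (ps).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shift_mean = 0, shift_sd = 0.5,
                           tilt_mean = 10, tilt_sd = 3,
                           rotation_mean = 0, rotation_kappa = 8,
                           ar1 = 0.8, noise_sd = 0.5,
                           leaflet_z = c(-19.5, 19.5), tilt_azimuth = 0,
                           n_replicas = 10, n_frames = 100, n_phosphate = 64,
                           box = c(60, 60, 80), dt_frame = 100) {
  stopifnot(shift_sd >= 0, tilt_sd >= 0, rotation_kappa >= 0,
            ar1 >= 0, ar1 < 1, noise_sd >= 0, length(leaflet_z) == 2)
  structure(as.list(environment()), class = "synthetic_spec")
}

ar1_gaussian <- function(n, mean, sd, rho) {
  if (sd == 0) return(rep(mean, n))
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  if (n > 1) {
    innov_sd <- sd * sqrt(1 - rho^2)
    for (t in 2:n) x[t] <- rho * x[t - 1] + rnorm(1, 0, innov_sd)
  }
  mean + x
}

rot_z <- function(a) {
  a <- deg2rad(a)
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}
rot_y <- function(a) {
  a <- deg2rad(a)
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}

# base CG helix posed along +z with mean backbone z = 0; returns the fragment
# plus the azimuth of the reference sidechain vector in the base pose
base_cg_helix <- function(peptide_cg, reference_resid) {
  beads <- peptide_cg$beads
  xyz <- peptide_cg$xyz
  # align the backbone-bead principal axis exactly with +z, so imposed pose
  # parameters are recovered without a residual mapping offset
  ax <- helix_axis(xyz[beads$role == "BB", , drop = FALSE])
  xyz <- xyz %*% t(rotation_to_z(ax))
  bbz <- mean(xyz[beads$role == "BB", 3])
  xyz[, 3] <- xyz[, 3] - bbz
  sc_idx <- which(beads$role == "SC" & beads$resid == reference_resid)
  bb_idx <- which(beads$role == "BB" & beads$resid == reference_resid)
  if (!length(sc_idx) || length(bb_idx) != 1)
    abort("reference residue has no sidechain bead")
  v <- colMeans(xyz[sc_idx, , drop = FALSE]) - xyz[bb_idx, ]
  alpha0 <- rad2deg(atan2(v[2], v[1]))
  list(xyz = xyz, beads = beads, alpha0 = alpha0)
}

#' Generate a synthetic ensemble with known ground truth
#'
#' Frames contain a rigid ideal CG helix posed at sampled (shift, tilt,
#' rotation) plus per-bead noise, and two phosphate leaflet grids. The
#' imposed per-frame pose parameters are returned alongside, so analysis
#' recovery can be checked against ground truth.
#'
#' @param spec a [synthetic_spec()].
#' @param peptide one-row peptide tibble; default the Tar wildtype fixture.
#' @param seed RNG seed for the whole ensemble.
#' @return list: `trajectories` (list of `cg_trajectory`), `truth` (tibble:
#'   replica, frame, shift, tilt, rotation), `reference_resid`.
#' @export
generate_ensemble <- function(spec, peptide = NULL, seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(peptide)) {
    pep <- tm2_peptides("WY_scan")
    peptide <- pep[pep$id == "TarEc_WT", ]
  }
  cg <- map_to_cg(build_ideal_helix(peptide))
  ref_resid <- pick_reference_resid(cg$beads)
  base <- base_cg_helix(cg, ref_resid)
  nb <- nrow(base$xyz)

  # phosphate leaflets on a lateral grid
  ng <- ceiling(sqrt(spec$n_phosphate))
  gx <- (seq_len(ng) - 0.5) / ng * spec$box[1]
  grid <- expand.grid(x = gx, y = (seq_len(ng) - 0.5) / ng * spec$box[2])
  grid <- grid[seq_len(spec$n_phosphate), ]
  ph_beads <- tibble(name = "PO4", type = "Qa", charge = -1,
                     mass = .const$bead_mass, molecule = "DPPC",
                     mol_id = seq_len(2 * spec$n_phosphate),
                     resid = seq_len(2 * spec$n_phosphate), resname = "DPPC",
                     role = "PO4")
  beads <- bind_rows(base$beads, ph_beads)
  centre <- c(spec$box[1] / 2, spec$box[2] / 2, spec$box[3] / 2)

  set.seed(seed)
  trajs <- list(); truth <- list()
  for (r in seq_len(spec$n_replicas)) {
    shift <- ar1_gaussian(spec$n_frames, spec$shift_mean, spec$shift_sd, spec$ar1)
    tilt <- pmin(90, pmax(0, ar1_gaussian(spec$n_frames, spec$tilt_mean,
                                          spec$tilt_sd, spec$ar1)))
    rot <- if (spec$ar1 == 0 && spec$rotation_kappa > 0) {
      rvonmises_deg(spec$n_frames, spec$rotation_mean, spec$rotation_kappa)
    } else {
      sdrot <- if (spec$rotation_kappa > 0) rad2deg(1 / sqrt(spec$rotation_kappa)) else 103.9
      wrap_deg(ar1_gaussian(spec$n_frames, 0, sdrot, spec$ar1) + spec$rotation_mean)
    }
    frames <- vector("list", spec$n_frames)
    for (f in seq_len(spec$n_frames)) {
      R <- rot_z(spec$tilt_azimuth) %*% rot_y(tilt[f]) %*%
        rot_z(rot[f] - base$alpha0)
      hx <- base$xyz %*% t(R)
      hx[, 3] <- hx[, 3] + shift[f]
      ph_up <- cbind(grid$x, grid$y, spec$leaflet_z[2] + centre[3] * 0)
      ph_lo <- cbind(grid$x, grid$y, spec$leaflet_z[1])
      ph <- rbind(ph_up, ph_lo)
      ph[, 1:2] <- ph[, 1:2] - rep(centre[1:2], each = nrow(ph))
      fr <- rbind(hx, ph)
      if (spec$noise_sd > 0)
        fr <- fr + matrix(rnorm(length(fr), 0, spec$noise_sd), nrow(fr), 3)
      fr <- sweep(fr, 2, -centre)  # place in box
      frames[[f]] <- fr
    }
    trajs[[r]] <- new_trajectory(frames,
                                 matrix(spec$box, spec$n_frames, 3, byrow = TRUE),
                                 (seq_len(spec$n_frames) - 1) * spec$dt_frame,
                                 beads)
    truth[[r]] <- tibble(replica = r, frame = seq_len(spec$n_frames),
                         shift = shift, tilt = tilt, rotation = rot)
  }
  list(trajectories = trajs, truth = bind_rows(truth),
       reference_resid = ref_resid)
}

#' Synthetic phenotype suite mirroring the WY scan
#'
#' Seven labelled ensembles with imposed mean shifts
#' {-1.0, -0.75, -0.5, 0, +0.5, +0.75, +1.0} A for
#' {WYm3, WYm2, WYm1, WT, WYp1, WYp2, WYp3}, so the active-minus-inactive
#' group contrast is 1.5 A; cytoplasmic (negative) shifts carry
#' kinase-inactive labels and periplasmic shifts kinase-active labels. The
#' `"null"` suite imposes zero shift everywhere (negative control).
#'
#' @param effect `"piston"` (default) or `"null"`.
#' @param n_replicas,n_frames ensemble dimensions per peptide.
#' @param seed RNG seed.
#' @param ... further arguments to [synthetic_spec()].
#' @return list: `ensembles` (named list of trajectory lists), `truth_means`
#'   (tibble id/imposed shift), `peptides` (fixture metadata).
#' @export
generate_phenotype_suite <- function(effect = "piston", n_replicas = 10,
                                     n_frames = 100, seed = 1, ...) {
  ids <- c("WYm3", "WYm2", "WYm1", "TarEc_WT", "WYp1", "WYp2", "WYp3")
  shifts <- c(-1.0, -0.75, -0.5, 0, 0.5, 0.75, 1.0)
  if (effect == "null") shifts <- rep(0, 7)
  peptides <- tm2_peptides("WY_scan")
  ens <- list()
  for (k in seq_along(ids)) {
    spec <- synthetic_spec(shift_mean = shifts[k], n_replicas = n_replicas,
                           n_frames = n_frames, ...)
    pep <- peptides[peptides$id == ids[k], ]
    ens[[ids[k]]] <- generate_ensemble(spec, pep, seed = seed + 977 * k)
  }
  list(ensembles = lapply(ens, `[[`, "trajectories"),
       truth_means = tibble(id = ids, imposed_shift = shifts),
       peptides = peptides)
}
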