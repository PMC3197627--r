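# R surface over the compiled MD kernels.

#' Engine parameters
#'
#' Defaults follow the production protocol: 20 fs timestep, Berendsen
#' thermostat at 323 K (tau_T = 1 ps), semi-isotropic Berendsen barostat at
#' 1 bar (compressibility 3e-5 1/bar, tau_P = 10 ps), neighbour list with a
#' 2 A skin rebuilt every 10 steps.
#'
#' @param dt timestep (ps).
#' @param t_ref reference temperature (K).
#' @param tau_t temperature coupling time (ps).
#' @param p_ref reference pressure (bar).
#' @param tau_p pressure coupling time (ps).
#' @param compressibility isothermal compressibility (1/bar).
#' @param skin neighbour-list skin (A).
#' @param nlist_every neighbour-list rebuild interval (steps).
#' @param com_every centre-of-mass motion removal interval (steps).
#' @return list of class `engine_params`.
#' @export
engine_params <- function(dt = 0.02, t_ref = 323, tau_t = 1, p_ref = 1,
                          tau_p = 10, compressibility = 3e-5,
                          skin = 2, nlist_every = 10, com_every = 100) {
  stopifnot(dt > 0, tau_t > 0, tau_p > 0)
  structure(list(dt = dt, t_ref = t_ref, tau_t = tau_t, p_ref = p_ref,
                 tau_p = tau_p, compressibility = compressibility, skin = skin,
                 nlist_every = nlist_every, com_every = com_every),
            class = "engine_params")
}

pack_system <- function(sys, ff) {
  stopifnot(inherits(sys, "cg_system"), inherits(ff, "cg_forcefield"))
  ti <- match(sys$beads$type, ff$types)
  if (anyNA(ti))
    abort(paste0("bead type absent from forcefield table: ",
                 sys$beads$type[is.na(ti)][1]))
  bonds <- as.matrix(sys$bonds[, c("i", "j")]) - 1L
  storage.mode(bonds) <- "integer"
  angles <- as.matrix(sys$angles[, c("i", "j", "k")]) - 1L
  storage.mode(angles) <- "integer"
  dihs <- as.matrix(sys$dihedrals[, c("i", "j", "k", "l")]) - 1L
  storage.mode(dihs) <- "integer"
  excl <- bonds
  if (nrow(excl)) excl <- unique(t(apply(excl, 1, sort)))
  storage.mode(excl) <- "integer"
  list(type = as.integer(ti - 1L), charge = sys$beads$charge, mass = sys$beads$mass,
       eps = ff$epsilon, sig = ff$sigma, r1lj = ff$r1_lj, rc = ff$r_cut,
       felec = ff$f_elec,
       bonds = bonds, b0 = sys$bonds$b0, kb = sys$bonds$k,
       angles = angles, th0 = sys$angles$theta0, ka = sys$angles$ka,
       dihs = dihs, phi0 = sys$dihedrals$phi0, kd = sys$dihedrals$kd,
       excl = excl)
}

#' Forces and energies of a configuration
#'
#' Evaluates the full force field (force-shifted Lennard-Jones and Coulomb
#' under the minimum-image convention, bonds, angles, dihedral restraints)
#' at the current coordinates. Forces are the exact negative gradient of the
#' implemented potentials; pair terms are identically zero at and beyond the
#' cutoff.
#'
#' @param sys a `cg_system` with a valid box.
#' @param ff a [martini_forcefield()].
#' @return list: `forces` (N x 3 matrix, kJ/mol/A), `energies` (one-row
#'   tibble), `virial` (diagonal, kJ/mol).
#' @export
compute_forces <- function(sys, ff = martini_forcefield()) {
  p <- pack_system(sys, ff)
  res <- cpp_forces(sys$xyz, sys$box, p$type, p$charge, p$mass, p$eps, p$sig,
                    p$r1lj, p$rc, p$felec, p$bonds, p$b0, p$kb,
                    p$angles, p$th0, p$ka, p$dihs, p$phi0, p$kd, p$excl)
  list(forces = res$forces,
       energies = tibble(lj = res$lj, coulomb = res$coulomb, bond = res$bond,
                         angle = res$angle, dihedral = res$dihedral,
                         potential = res$lj + res$coulomb + res$bond +
                           res$angle + res$dihedral),
       virial = res$virial)
}

#' Neighbour list by cell search
#'
#' All bead pairs within `r_cut + skin` under periodic minimum image,
#' including pairs straddling the box boundary.
#'
#' @param sys a `cg_system`.
#' @param r_cut cutoff (A).
#' @param skin extra margin (A).
#' @return two-column integer matrix of 1-based pairs (i < j).
#' @export
neighbor_list <- function(sys, r_cut = 12, skin = 0) {
  cpp_pair_list(sys$xyz, sys$box, r_cut + skin)
}

#' Berendsen thermostat velocity-scaling factor
#'
#' lambda = sqrt(1 + (dt/tau_T)(T_ref/T - 1)); lambda = 1 at T = T_ref.
#'
#' @param t_inst instantaneous temperature (K).
#' @param params an [engine_params()].
#' @return scaling factor.
#' @export
berendsen_lambda <- function(t_inst, params = engine_params()) {
  sqrt(1 + params$dt / params$tau_t * (params$t_ref / t_inst - 1))
}

#' Berendsen barostat box-scaling factor
#'
#' mu = (1 - (dt/tau_P) kappa (P_ref - P))^(1/3), applied jointly to the
#' lateral (x, y) and independently to the normal (z) box dimension.
#'
#' @param p_inst instantaneous pressure component (bar).
#' @param params an [engine_params()].
#' @return scaling factor.
#' @export
berendsen_mu <- function(p_inst, params = engine_params()) {
  (1 - params$dt / params$tau_p * params$compressibility *
     (params$p_ref - p_inst))^(1 / 3)
}

#' Maxwell-Boltzmann velocities
#'
#' @param sys a `cg_system`.
#' @param temperature target temperature (K).
#' @param seed RNG seed.
#' @return N x 3 velocity matrix (A/ps) with zero centre-of-mass momentum.
#' @export
init_velocities <- function(sys, temperature = 323, seed = 1) {
  set.seed(seed)
  n <- nrow(sys$beads)
  sdv <- sqrt(.const$kB * temperature / (0.01 * sys$beads$mass))
  v <- matrix(rnorm(3 * n), n, 3) * sdv
  com <- colSums(v * sys$beads$mass) / sum(sys$beads$mass)
  sweep(v, 2, com)
}

#' Steepest-descent energy minimization
#'
#' @param sys a `cg_system`.
#' @param ff forcefield.
#' @param nsteps maximum iterations.
#' @param fmax_tol force convergence threshold (kJ/mol/A).
#' @param step0 initial displacement (A).
#' @return the system with relaxed coordinates.
#' @export
minimize_system <- function(sys, ff = martini_forcefield(), nsteps = 500,
                            fmax_tol = 10, step0 = 0.2) {
  p <- pack_system(sys, ff)
  res <- cpp_minimize(sys$xyz, sys$box, p$type, p$charge, p$mass, p$eps, p$sig,
                      p$r1lj, p$rc, p$felec, p$bonds, p$b0, p$kb,
                      p$angles, p$th0, p$ka, p$dihs, p$phi0, p$kd, p$excl,
                      as.integer(nsteps), fmax_tol, step0)
  sys$xyz <- res$xyz
  attr(sys, "minimization") <- list(energy = res$energy, fmax = res$fmax,
                                    steps = res$steps)
  sys
}

#' Run coarse-grained molecular dynamics
#'
#' Leapfrog integration with optional Berendsen thermostat and semi-isotropic
#' Berendsen barostat. Deterministic: the same system, velocities and
#' parameters give a bit-identical trajectory.
#'
#' @param sys a `cg_system` with box.
#' @param ff forcefield.
#' @param params [engine_params()].
#' @param nsteps number of steps.
#' @param velocities N x 3 matrix; defaults to Maxwell-Boltzmann at
#'   `params$t_ref` with `seed`.
#' @param seed seed for velocity generation when `velocities` is NULL.
#' @param thermostat,barostat logical switches.
#' @param sample_every energy-sampling stride (steps); 0 disables.
#' @param frame_every frame-output stride (steps); 0 disables.
#' @param t0 time origin (ps).
#' @return list with `system` (final state), `velocities`, `energies`
#'   (tibble time series), and `trajectory` (a `cg_trajectory` or NULL).
#' @export
run_md <- function(sys, ff = martini_forcefield(), params = engine_params(),
                   nsteps = 1000, velocities = NULL, seed = 1,
                   thermostat = TRUE, barostat = FALSE,
                   sample_every = 100, frame_every = 0, t0 = 0) {
  p <- pack_system(sys, ff)
  if (is.null(velocities)) velocities <- init_velocities(sys, params$t_ref, seed)
  res <- cpp_run_md(sys$xyz, velocities, sys$box, p$type, p$charge, p$mass,
                    p$eps, p$sig, p$r1lj, p$rc, p$felec,
                    p$bonds, p$b0, p$kb, p$angles, p$th0, p$ka,
                    p$dihs, p$phi0, p$kd, p$excl,
                    as.integer(nsteps), params$dt,
                    thermostat, params$t_ref, params$tau_t,
                    barostat, params$p_ref, params$tau_p, params$compressibility,
                    as.integer(params$nlist_every), params$skin,
                    as.integer(params$com_every),
                    as.integer(sample_every), as.integer(frame_every), t0)
  out_sys <- sys
  out_sys$xyz <- res$xyz
  out_sys$box <- as.numeric(res$box)
  traj <- NULL
  if (frame_every > 0 && length(res$frames)) {
    traj <- new_trajectory(res$frames, res$frame_box, res$frame_time, sys$beads)
  }
  energies <- as_tibble(as.data.frame(res$energies))
  if (sample_every <= 0) energies <- energies[0, ]
  list(system = out_sys, velocities = res$vel,
       energies = energies, trajectory = traj)
}

new_trajectory <- function(frames, box, time, beads) {
  structure(list(frames = frames, box = box, time = time, beads = beads),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory> ", length(x$frames), " frames x ", nrow(x$beads),
      " beads, t = ", if (length(x$time)) paste0(min(x$time), "..", max(x$time)) else "-",
      " ps\n", sep = "")
  invisible(x)
}
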