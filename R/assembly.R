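# Starting-configuration builders and ensemble execution.

#' Assembly specification
#'
#' Defaults follow the production setup: 128 DPPC, 3000 CG waters, a
#' 65 x 65 x 100 A box. `self_assembly` disperses lipids and waters randomly
#' around the helix; `preformed_bilayer` builds two leaflets on a lateral
#' grid with the helix inserted transmembrane and water slabs above and
#' below.
#'
#' @param n_lipid,n_water molecule counts.
#' @param box box lengths (A).
#' @param mode `"self_assembly"` or `"preformed_bilayer"`.
#' @param min_dist minimum allowed bead-bead distance when placing (A).
#' @param seed placement seed.
#' @param max_tries placement attempts per molecule before giving up.
#' @return list of class `assembly_spec`.
#' @export
assembly_spec <- function(n_lipid = 128, n_water = 3000, box = c(65, 65, 100),
                          mode = "preformed_bilayer", min_dist = 2.5, seed = 1,
                          max_tries = 200) {
  stopifnot(mode %in% c("self_assembly", "preformed_bilayer"),
            n_lipid > 0, n_water >= 0, length(box) == 3)
  structure(as.list(environment()), class = "assembly_spec")
}

random_rotation <- function() {
  # uniform random rotation via quaternion
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# grid-hash overlap checker over periodic box
make_occupancy <- function(box, cell = 3) {
  env <- new.env(parent = emptyenv())
  nc <- pmax(1L, floor(box / cell))
  list(
    key = function(p) {
      i <- floor((p[, 1] %% box[1]) / box[1] * nc[1])
      j <- floor((p[, 2] %% box[2]) / box[2] * nc[2])
      k <- floor((p[, 3] %% box[3]) / box[3] * nc[3])
      paste(i, j, k)
    },
    env = env, nc = nc, box = box
  )
}

occ_clash <- function(occ, pts, min_dist) {
  box <- occ$box; nc <- occ$nc
  for (r in seq_len(nrow(pts))) {
    p <- pts[r, ]
    i <- floor((p[1] %% box[1]) / box[1] * nc[1])
    j <- floor((p[2] %% box[2]) / box[2] * nc[2])
    k <- floor((p[3] %% box[3]) / box[3] * nc[3])
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      key <- paste((i + di) %% nc[1], (j + dj) %% nc[2], (k + dk) %% nc[3])
      other <- occ$env[[key]]
      if (!is.null(other)) {
        for (q in seq_len(nrow(other))) {
          d <- p - other[q, ]
          d <- d - box * round(d / box)
          if (sum(d^2) < min_dist^2) return(TRUE)
        }
      }
    }
  }
  FALSE
}

occ_add <- function(occ, pts) {
  keys <- occ$key(pts)
  for (r in seq_len(nrow(pts))) {
    key <- keys[r]
    occ$env[[key]] <- rbind(occ$env[[key]], pts[r, , drop = FALSE])
  }
  occ
}

#' Build a starting configuration
#'
#' @param spec an [assembly_spec()].
#' @param peptide_cg optional `cg_system` helix fragment from [map_to_cg()];
#'   placed at the box centre (transmembrane along z in preformed mode).
#' @return a `cg_system` with box set; deterministic given `spec$seed`.
#' @export
build_system <- function(spec, peptide_cg = NULL) {
  stopifnot(inherits(spec, "assembly_spec"))
  set.seed(spec$seed)
  box <- spec$box
  centre <- box / 2
  occ <- make_occupancy(box, cell = max(3, spec$min_dist))
  parts <- list()

  helix <- NULL
  if (!is.null(peptide_cg)) {
    helix <- peptide_cg
    helix$xyz <- sweep(helix$xyz, 2, -centre)
    occ <- occ_add(occ, helix$xyz)
    parts[[length(parts) + 1]] <- helix
  }

  lip <- dppc_template()
  if (spec$mode == "preformed_bilayer") {
    n_per <- spec$n_lipid / 2
    if (n_per != round(n_per)) abort("preformed bilayer needs an even lipid count")
    # lateral sites on a grid sized for the lipid count; every placement is
    # clash-checked against everything already present (helix included),
    # retrying with fresh rotations and growing lateral jitter so lipids can
    # pack between helix sidechains
    ng <- ceiling(sqrt(n_per))
    spacing <- box[1:2] / ng
    base <- expand.grid(i = seq_len(ng) - 0.5, j = seq_len(ng) - 0.5)
    sites <- rbind(base[sample(nrow(base)), ], base[sample(nrow(base)), ])
    flip <- diag(c(1, -1, -1))  # tails up for the lower leaflet
    for (leaf in c(1, -1)) {
      placed <- 0L
      for (s in seq_len(nrow(sites))) {
        if (placed >= n_per) break
        xy0 <- c(sites$i[s] * spacing[1], sites$j[s] * spacing[2])
        zhead <- centre[3] + leaf * 23
        for (t in 1:24) {
          jit <- if (t == 1) c(0, 0) else (runif(2) - 0.5) * spacing * 0.8 * t / 24
          xy <- xy0 + jit
          R <- rot_z(runif(1, 0, 360))
          if (leaf < 0) R <- flip %*% R
          frag <- cg_transform(lip, R, c(xy[1], xy[2], zhead))
          if (!occ_clash(occ, frag$xyz, spec$min_dist)) {
            parts[[length(parts) + 1]] <- frag
            occ <- occ_add(occ, frag$xyz)
            placed <- placed + 1L
            break
          }
        }
      }
      if (placed < n_per)
        abort("could not place all lipids; increase the box size")
    }
    water_ok <- function(p) abs(((p[, 3] - centre[3] + box[3] / 2) %% box[3]) -
                                  box[3] / 2) > 27
  } else {
    for (k in seq_len(spec$n_lipid)) {
      done <- FALSE
      for (t in seq_len(spec$max_tries)) {
        R <- random_rotation()
        pos <- runif(3) * box
        frag <- cg_transform(lip, R, pos)
        if (!occ_clash(occ, frag$xyz, spec$min_dist)) {
          parts[[length(parts) + 1]] <- frag
          occ <- occ_add(occ, frag$xyz)
          done <- TRUE
          break
        }
      }
      if (!done) abort("could not place lipids without overlap; increase the box size")
    }
    water_ok <- function(p) rep(TRUE, nrow(p))
  }

  if (spec$n_water > 0) {
    w <- water_template()
    placed <- 0L
    tries <- 0L
    max_total <- spec$n_water * spec$max_tries
    while (placed < spec$n_water && tries < max_total) {
      tries <- tries + 1L
      pos <- matrix(runif(3) * box, 1, 3)
      if (!water_ok(pos)) next
      if (occ_clash(occ, pos, spec$min_dist)) next
      parts[[length(parts) + 1]] <- cg_transform(w, shift = pos[1, ])
      occ <- occ_add(occ, pos)
      placed <- placed + 1L
    }
    if (placed < spec$n_water)
      abort("could not place all waters without overlap; increase the box size")
  }
  do.call(cg_concat, c(parts, list(box = box)))
}

#' Run one simulation replica
#'
#' Steepest-descent minimization, short equilibration at a reduced timestep
#' (2 fs), then production at the full timestep with thermostat and
#' semi-isotropic barostat. Engine failures (overlaps, non-finite
#' coordinates) are caught and reported in the result, not thrown.
#'
#' @param system a `cg_system` from [build_system()].
#' @param length_ns production length (ns).
#' @param seed velocity seed.
#' @param ff forcefield.
#' @param params [engine_params()].
#' @param equil_ps equilibration length (ps) at dt = 2 fs.
#' @param n_frames approximate number of production frames to keep.
#' @param barostat logical.
#' @return list of class `md_replica`: ok, trajectory, energies, manifest,
#'   error (NULL if ok).
#' @export
run_replica <- function(system, length_ns = 1, seed = 1,
                        ff = martini_forcefield(), params = engine_params(),
                        equil_ps = 25, n_frames = 100, barostat = TRUE) {
  manifest <- list(seed = seed, length_ns = length_ns, equil_ps = equil_ps,
                   dt_ps = params$dt, t_ref = params$t_ref,
                   n_beads = nrow(system$beads), box = system$box,
                   barostat = barostat)
  out <- tryCatch({
    sys <- minimize_system(system, ff, nsteps = 300)
    eq_params <- params
    eq_params$dt <- 0.002
    nsteps_eq <- max(1L, round(equil_ps / eq_params$dt))
    eq <- run_md(sys, ff, eq_params, nsteps = nsteps_eq, seed = seed,
                 thermostat = TRUE, barostat = FALSE, sample_every = 0)
    nsteps <- max(1L, round(length_ns * 1000 / params$dt))
    frame_every <- max(1L, nsteps %/% n_frames)
    prod <- run_md(eq$system, ff, params, nsteps = nsteps,
                   velocities = eq$velocities, thermostat = TRUE,
                   barostat = barostat,
                   sample_every = max(1L, nsteps %/% 200),
                   frame_every = frame_every)
    list(ok = TRUE, trajectory = prod$trajectory, energies = prod$energies,
         system = prod$system, manifest = manifest, error = NULL)
  }, error = function(e) {
    list(ok = FALSE, trajectory = NULL, energies = NULL, system = NULL,
         manifest = manifest, error = conditionMessage(e))
  })
  structure(out, class = "md_replica")
}

#' Run an ensemble of replicas
#'
#' Replicas are independent: each gets its own deterministically derived
#' seed (assembly seed in self-assembly mode, velocity seed always), and no
#' state is shared, so results do not depend on execution order or worker
#' count.
#'
#' @param spec an [assembly_spec()].
#' @param peptide_cg optional helix fragment.
#' @param n_replicas number of replicas.
#' @param length_ns production length per replica (ns).
#' @param seed base seed; replica r uses seed + r.
#' @param workers parallel worker processes (forked; 1 = serial).
#' @param ... passed to [run_replica()].
#' @return list of `md_replica` results, length `n_replicas`.
#' @export
run_ensemble <- function(spec, peptide_cg = NULL, n_replicas = 4,
                         length_ns = 1, seed = 1, workers = 1, ...) {
  one <- function(r) {
    sp <- spec
    sp$seed <- seed + r
    sys <- build_system(sp, peptide_cg)
    run_replica(sys, length_ns = length_ns, seed = seed + 7919 * r, ...)
  }
  if (workers > 1) {
    parallel::mclapply(seq_len(n_replicas), one, mc.cores = workers,
                       mc.set.seed = FALSE)
  } else {
    lapply(seq_len(n_replicas), one)
  }
}

#' Phosphate slab check for an intact bilayer
#'
#' A frame passes when the phosphate z-distribution (circularly centred)
#' splits into two leaflets of similar occupancy separated by at least
#' `min_sep`, each tighter than `max_spread`.
#'
#' @param traj a `cg_trajectory` containing PO4 beads.
#' @param min_sep minimum leaflet separation (A).
#' @param max_spread maximum within-leaflet sd (A).
#' @return tibble per frame: separation, sd_upper, sd_lower, n_upper,
#'   n_lower, intact.
#' @export
bilayer_integrity <- function(traj, min_sep = 15, max_spread = 6) {
  ph <- which(traj$beads$role == "PO4")
  stopifnot(length(ph) >= 4)
  rows <- lapply(seq_along(traj$frames), function(f) {
    z <- traj$frames[[f]][ph, 3]
    L <- traj$box[f, 3]
    zc <- bilayer_center_z(traj$frames[[f]], traj$beads, L)
    z <- (z - zc + L / 2) %% L - L / 2
    med <- median(z)
    up <- z[z >= med]; lo <- z[z < med]
    sep <- mean(up) - mean(lo)
    tibble(frame = f, separation = sep, sd_upper = sd(up), sd_lower = sd(lo),
           n_upper = length(up), n_lower = length(lo),
           intact = sep >= min_sep && sd(up) <= max_spread && sd(lo) <= max_spread &&
             min(length(up), length(lo)) >= 0.3 * length(z))
  })
  bind_rows(rows)
}
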