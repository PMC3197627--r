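# Per-frame helix position/orientation relative to the bilayer.
# Sign convention: the helix is built N-terminus (periplasmic side) at +z,
# and a positive z-shift is displacement toward the periplasm.

#' Analysis conventions
#'
#' @param reference_resid residue (full-protein numbering) whose sidechain
#'   defines the rotation angle; `NULL` picks the tryptophan of a WY pair
#'   nearest the helix (the cytoplasmic aromatic anchor), falling back to any
#'   residue with a sidechain bead nearest the helix centre.
#' @param flat_tilt_deg below this tilt the rotation zero-reference switches
#'   from the tilt direction (degenerate as tilt -> 0) to the lab +x axis.
#' @param rotation_max_tilt above this tilt (deg) the helix axis is nearly in
#'   the membrane plane and the rotation angle is flagged undefined.
#' @param tm_tilt_max,tm_shift_max transmembrane classification thresholds
#'   (inclusive): tilt <= 50 deg, |shift| <= 15 A, plus terminal backbone
#'   beads on opposite sides of the midplane.
#' @param min_leaflet_sep minimum separation (A) of the two leaflet phosphate
#'   means for a frame to count as having a detectable bilayer.
#' @return list of class `geometry_conventions`.
#' @export
geometry_conventions <- function(reference_resid = NULL, flat_tilt_deg = 2,
                                 rotation_max_tilt = 85, tm_tilt_max = 50,
                                 tm_shift_max = 15, min_leaflet_sep = 10) {
  structure(list(reference_resid = reference_resid, flat_tilt_deg = flat_tilt_deg,
                 rotation_max_tilt = rotation_max_tilt, tm_tilt_max = tm_tilt_max,
                 tm_shift_max = tm_shift_max, min_leaflet_sep = min_leaflet_sep),
            class = "geometry_conventions")
}

#' Bilayer midplane from phosphate z-coordinates
#'
#' Leaflets are assigned by sign relative to the phosphate median; the
#' midplane is the midpoint of the two leaflet mean z values.
#'
#' @param z_phosphate numeric vector of phosphate bead z (A), already
#'   unwrapped/centred on the bilayer.
#' @param min_leaflet_sep minimum mean-leaflet separation (A) for a
#'   detectable bilayer.
#' @return list: `z0`, leaflet means, counts, and `ok` (FALSE when a leaflet
#'   has fewer than 2 lipids or the leaflets are not separated).
#' @export
bilayer_midplane <- function(z_phosphate, min_leaflet_sep = 10) {
  # initial split at the median, then iterate the threshold to the midpoint
  # of the two leaflet means (a 1-d k-means step); the median alone
  # misassigns when the leaflets are unequally populated
  t <- median(z_phosphate)
  m_up <- m_lo <- NA_real_
  for (it in 1:10) {
    up <- z_phosphate[z_phosphate >= t]
    lo <- z_phosphate[z_phosphate < t]
    if (length(up) < 2 || length(lo) < 2) break
    m_up <- mean(up); m_lo <- mean(lo)
    t_new <- (m_up + m_lo) / 2
    if (isTRUE(all.equal(t_new, t))) break
    t <- t_new
  }
  up <- z_phosphate[z_phosphate >= t]
  lo <- z_phosphate[z_phosphate < t]
  ok <- length(up) >= 2 && length(lo) >= 2
  m_up <- mean(up); m_lo <- mean(lo)
  sep <- m_up - m_lo
  ok <- ok && is.finite(sep) && sep >= min_leaflet_sep
  list(z0 = (m_up + m_lo) / 2, upper = m_up, lower = m_lo,
       n_upper = length(up), n_lower = length(lo), separation = sep, ok = ok)
}

#' Helix axis from backbone bead coordinates
#'
#' Least-squares principal axis of the backbone beads, with the sign chosen
#' so the vector points from the C-terminal to the N-terminal bead
#' (cytoplasm to periplasm).
#'
#' @param bb N x 3 matrix of backbone bead coordinates, ordered N- to
#'   C-terminus.
#' @return unit 3-vector.
#' @export
helix_axis <- function(bb) {
  if (nrow(bb) < 6) abort("helix axis needs at least 6 backbone beads")
  cen <- colMeans(bb)
  cc <- sweep(bb, 2, cen)
  sv <- svd(cc)
  if (sv$d[1] < 1e-8) abort("degenerate backbone geometry")
  ax <- sv$v[, 1]
  if (sum(ax * (bb[1, ] - bb[nrow(bb), ])) < 0) ax <- -ax
  ax
}

# unwrap a bead chain: each bead is moved to the periodic image closest to
# the previous bead, so molecules longer than half the box unwrap correctly
# (consecutive helix beads are only a few A apart)
unwrap_chain <- function(xyz, box) {
  if (nrow(xyz) < 2) return(xyz)
  for (d in 1:3) {
    steps <- diff(xyz[, d])
    steps <- steps - box[d] * round(steps / box[d])
    xyz[, d] <- xyz[1, d] + c(0, cumsum(steps))
  }
  xyz
}

pick_reference_resid <- function(beads) {
  pep <- beads[beads$molecule == "PEP" & beads$role == "SC", ]
  if (!nrow(pep)) return(NA_integer_)
  bb <- beads[beads$molecule == "PEP" & beads$role == "BB", ]
  resn <- bb$resname[match(sort(unique(bb$resid)), bb$resid)]
  resids <- sort(unique(bb$resid))
  wy <- which(resn == "TRP" & c(resn[-1], "") == "TYR")
  cand <- if (length(wy)) resids[wy] else resids[resn %in% unique(pep$resname)]
  if (!length(cand)) return(NA_integer_)
  centre <- mean(range(resids))
  cand[which.min(abs(cand - centre))]
}

# z of the bilayer centre by circular mean over the periodic box. The
# hydrophobic core (tail/glycerol beads) is a single compact slab and is
# unambiguous; the two phosphate leaflets alone are nearly antipodal when
# their separation approaches half the box, so they are only a fallback
# (synthetic frames carry phosphates only).
bilayer_center_z <- function(xyz, beads, box_z) {
  core <- which(beads$molecule == "DPPC" &
                  !(beads$role %in% c("NC3", "PO4")))
  ref <- if (length(core) >= 4) core else which(beads$role == "PO4")
  theta <- xyz[ref, 3] / box_z * 2 * pi
  atan2(mean(sin(theta)), mean(cos(theta))) / (2 * pi) * box_z
}

frame_geometry_one <- function(xyz, box, beads, conv) {
  is_pep <- beads$molecule == "PEP"
  bb_idx <- which(is_pep & beads$role == "BB")
  ph_idx <- which(beads$role == "PO4")
  if (length(bb_idx) < 6) abort("fewer than 6 backbone beads in frame")
  if (length(ph_idx) < 4) abort("fewer than 4 phosphate beads in frame")

  # centre the bilayer at z = 0
  zph_raw <- xyz[ph_idx, 3]
  zc <- bilayer_center_z(xyz, beads, box[3])
  recenter <- function(z) (z - zc + box[3] / 2) %% box[3] - box[3] / 2
  zph <- recenter(zph_raw)

  mid <- bilayer_midplane(zph, conv$min_leaflet_sep)

  # unwrap helix beads along the chain, then recentre z
  pep_idx <- which(is_pep)
  pep <- unwrap_chain(xyz[pep_idx, , drop = FALSE], box)
  pep[, 3] <- pep[, 3] - zc -
    box[3] * round((mean(pep[, 3]) - zc) / box[3])
  bb <- pep[match(bb_idx, pep_idx), , drop = FALSE]

  z_shift <- mean(bb[, 3]) - mid$z0
  ax <- helix_axis(bb)
  tilt_raw <- rad2deg(acos(max(-1, min(1, ax[3]))))
  tilt <- min(tilt_raw, 180 - tilt_raw)

  # rotation: angle of the reference sidechain vector about the axis,
  # measured from the in-plane lean direction (or +x when nearly upright)
  ref_resid <- conv$reference_resid
  if (is.null(ref_resid) || is.na(ref_resid)) ref_resid <- pick_reference_resid(beads)
  rotation <- NA_real_
  rotation_defined <- FALSE
  if (!is.na(ref_resid) && tilt <= conv$rotation_max_tilt) {
    sc_idx <- which(is_pep & beads$role == "SC" & beads$resid == ref_resid)
    bbr_idx <- which(is_pep & beads$role == "BB" & beads$resid == ref_resid)
    if (length(sc_idx) && length(bbr_idx) == 1) {
      sc <- colMeans(pep[match(sc_idx, pep_idx), , drop = FALSE])
      v <- sc - pep[match(bbr_idx, pep_idx), ]
      vperp <- v - sum(v * ax) * ax
      d <- if (tilt < conv$flat_tilt_deg) c(1, 0, 0) else c(ax[1], ax[2], 0)
      ref0 <- d - sum(d * ax) * ax
      nref <- sqrt(sum(ref0^2))
      if (nref > 1e-10 && sqrt(sum(vperp^2)) > 1e-10) {
        ref0 <- ref0 / nref
        cr <- pracma_cross(ref0, vperp)
        rotation <- wrap_deg(rad2deg(atan2(sum(cr * ax), sum(ref0 * vperp))))
        rotation_defined <- TRUE
      }
    }
  }

  straddle <- (bb[1, 3] - mid$z0) * (bb[nrow(bb), 3] - mid$z0) < 0
  # thresholds are inclusive; allow for floating-point round-off at the edge
  is_tm <- mid$ok && tilt <= conv$tm_tilt_max + 1e-9 && straddle &&
    abs(z_shift) <= conv$tm_shift_max + 1e-9

  tibble(z_shift = z_shift, tilt = tilt, rotation = rotation,
         rotation_defined = rotation_defined, is_tm = is_tm,
         bilayer_ok = mid$ok)
}

#' Per-frame helix geometry of a trajectory
#'
#' For every frame: the bilayer is re-centred at z = 0 (circular mean of the
#' phosphate z distribution), the midplane computed from the two leaflet
#' phosphate means, and the helix measured as signed z-shift of the mean
#' backbone position (positive = periplasmic), tilt of the backbone
#' principal axis from the bilayer normal folded to [0, 90] degrees, and
#' rotation of the reference sidechain vector about the axis in [-180, 180).
#' Frames are classified transmembrane (tilt <= 50 deg, terminal backbone
#' beads on opposite sides of the midplane, |shift| <= 15 A) or interfacial;
#' interfacial frames are excluded downstream, not dropped here.
#'
#' @param traj a `cg_trajectory` (its beads need `role` and `molecule`
#'   columns; see [infer_roles()]).
#' @param conventions a [geometry_conventions()].
#' @param replica optional replica label stored in the output.
#' @return tibble: frame, time, replica, z_shift (A), tilt (deg), rotation
#'   (deg), rotation_defined, is_tm, bilayer_ok.
#' @export
trajectory_geometry <- function(traj, conventions = geometry_conventions(),
                                replica = NA_integer_) {
  stopifnot(inherits(traj, "cg_trajectory"))
  rows <- lapply(seq_along(traj$frames), function(f) {
    g <- frame_geometry_one(traj$frames[[f]], traj$box[f, ], traj$beads, conventions)
    g$frame <- f
    g$time <- traj$time[f]
    g
  })
  out <- bind_rows(rows)
  out$replica <- replica
  select(out, "frame", "time", "replica", "z_shift", "tilt", "rotation",
         "rotation_defined", "is_tm", "bilayer_ok")
}

#' Geometry over an ensemble of trajectories
#'
#' @param trajs list of `cg_trajectory` objects (one per replica).
#' @param conventions a [geometry_conventions()].
#' @return tibble as [trajectory_geometry()], with `replica` set from the
#'   list position (or names).
#' @export
ensemble_geometry <- function(trajs, conventions = geometry_conventions()) {
  bind_rows(lapply(seq_along(trajs), function(r) {
    trajectory_geometry(trajs[[r]], conventions, replica = r)
  }))
}
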