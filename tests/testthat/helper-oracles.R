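# Independent oracles used across tests. These deliberately re-derive
# quantities from first principles (brute force, finite differences) rather
# than calling the implementation paths they check.

# brute-force O(N^2) periodic pair enumeration
oracle_pairs <- function(xyz, box, rcut) {
  n <- nrow(xyz)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- xyz[i, ] - xyz[j, ]
      d <- d - box * round(d / box)
      if (sum(d^2) <= rcut^2) out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (!length(out)) return(matrix(integer(), 0, 2))
  do.call(rbind, out)
}

pair_key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))

# independent dihedral angle (degrees) from four points
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cx <- function(u, v) c(u[2]*v[3]-u[3]*v[2], u[3]*v[1]-u[1]*v[3], u[1]*v[2]-u[2]*v[1])
  n1 <- cx(b1, b2); n2 <- cx(b2, b3)
  m <- cx(n1, n2)
  atan2(sum(m * b2) / sqrt(sum(b2^2)), sum(n1 * n2)) * 180 / pi
}

# a random mixed-type system with a minimum separation (keeps the
# finite-difference oracle in a numerically benign regime)
random_system <- function(n = 50, box = c(30, 30, 30), min_sep = 3.5,
                          seed = 1, charged = TRUE, chain = FALSE) {
  set.seed(seed)
  ff <- martini_forcefield()
  xyz <- matrix(NA_real_, n, 3)
  placed <- 0
  if (chain) {
    # first four beads form a compact bonded chain (partners a few A apart,
    # away from the minimum-image boundary), placed before the rest so the
    # minimum-separation floor holds against them too
    xyz[1, ] <- box / 2
    xyz[2, ] <- xyz[1, ] + c(4.3, 0.4, -0.2)
    xyz[3, ] <- xyz[2, ] + c(1.5, 4.0, 0.6)
    xyz[4, ] <- xyz[3, ] + c(-1.2, 3.9, 1.4)
    placed <- 4
  }
  while (placed < n) {
    p <- runif(3) * box
    ok <- TRUE
    if (placed > 0) {
      d <- sweep(xyz[seq_len(placed), , drop = FALSE], 2, p)
      d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
      ok <- min(rowSums(d^2)) >= min_sep^2
    }
    if (ok) {
      placed <- placed + 1
      xyz[placed, ] <- p
    }
  }
  types <- sample(ff$types, n, replace = TRUE)
  q <- if (charged) {
    ifelse(types %in% c("Qd", "Q0"), 1, ifelse(types %in% c("Qa", "Qda"), -1, 0))
  } else rep(0, n)
  beads <- tibble::tibble(name = "X", type = types, charge = q, mass = 72,
                          molecule = "W", mol_id = seq_len(n), resid = seq_len(n),
                          resname = "W", role = "W")
  pistonsim:::new_cg_system(beads, xyz, box = box)
}

# small LJ fluid of water beads on a perturbed lattice
lj_fluid <- function(n_side = 6, box_len = 30, jitter = 0.3, seed = 7) {
  set.seed(seed)
  g <- expand.grid(x = seq_len(n_side), y = seq_len(n_side), z = seq_len(n_side))
  xyz <- as.matrix(g) / n_side * box_len - box_len / (2 * n_side)
  n <- nrow(xyz)
  xyz <- xyz + matrix(rnorm(3 * n, 0, jitter), n, 3)
  beads <- tibble::tibble(name = "W", type = "P4", charge = 0, mass = 72,
                          molecule = "W", mol_id = seq_len(n), resid = seq_len(n),
                          resname = "W", role = "W")
  pistonsim:::new_cg_system(beads, xyz, box = rep(box_len, 3))
}

# synthetic frame-geometry table (for statistics-level tests)
fake_geometry <- function(shift, tilt = 10, rotation = 0, replica = 1L) {
  n <- length(shift)
  tibble::tibble(frame = seq_len(n), time = (seq_len(n) - 1) * 100,
                 replica = rep_len(replica, n),
                 z_shift = shift, tilt = rep_len(tilt, n),
                 rotation = rep_len(rotation, n),
                 rotation_defined = TRUE, is_tm = TRUE, bilayer_ok = TRUE)
}
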