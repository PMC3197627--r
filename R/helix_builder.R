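# Ideal alpha-helix construction from internal coordinates.
# Backbone geometry: N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 A;
# angles N-CA-C 110.0 (tuned within its physical range so the 1.5 A rise and
# 3.6 residues/turn of the canonical helix are reproduced), CA-C-N 116.2, C-N-CA 121.7, CA-C-O 120.8 deg.

HELIX_PHI <- -57
HELIX_PSI <- -47

# place atom D given positions of A, B, C (torsion ref, angle ref, parent)
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# sidechain internal-coordinate templates: atom, torsion ref A, angle ref B,
# parent P, bond (A), angle (deg), torsion (deg). A single common rotamer per
# residue type (chi1 gauche-, chains anti, rings planar); the CG mapping uses
# group centroids, so rotamer detail is immaterial downstream.
sidechain_def <- function(resname) {
  d <- function(...) {
    m <- matrix(c(...), ncol = 6, byrow = TRUE)
    data.frame(atom = m[, 1], A = m[, 2], B = m[, 3], P = m[, 4],
               bond = as.numeric(m[, 5]), angle = as.numeric(m[, 6]),
               stringsAsFactors = FALSE)
  }
  cb <- c("CB", "C", "N", "CA", 1.53, 110.5)
  tors <- list(
    GLY = NULL,
    ALA = list(d(cb), -122.5),
    VAL = list(d(cb, "CG1", "N", "CA", "CB", 1.52, 110.5, "CG2", "N", "CA", "CB", 1.52, 110.5),
               c(-122.5, 175, -65)),
    LEU = list(d(cb, "CG", "N", "CA", "CB", 1.53, 114, "CD1", "CA", "CB", "CG", 1.52, 110.5,
                 "CD2", "CA", "CB", "CG", 1.52, 110.5), c(-122.5, -65, 180, 60)),
    ILE = list(d(cb, "CG1", "N", "CA", "CB", 1.53, 110.5, "CG2", "N", "CA", "CB", 1.53, 110.5,
                 "CD1", "CA", "CB", "CG1", 1.52, 114), c(-122.5, -65, 175, 180)),
    SER = list(d(cb, "OG", "N", "CA", "CB", 1.42, 110.5), c(-122.5, -65)),
    THR = list(d(cb, "OG1", "N", "CA", "CB", 1.42, 110.5, "CG2", "N", "CA", "CB", 1.53, 110.5),
               c(-122.5, -65, 175)),
    CYS = list(d(cb, "SG", "N", "CA", "CB", 1.81, 114), c(-122.5, -65)),
    MET = list(d(cb, "CG", "N", "CA", "CB", 1.53, 114, "SD", "CA", "CB", "CG", 1.81, 112,
                 "CE", "CB", "CG", "SD", 1.79, 100), c(-122.5, -65, 180, 180)),
    ASN = list(d(cb, "CG", "N", "CA", "CB", 1.52, 112.6, "OD1", "CA", "CB", "CG", 1.23, 120.8,
                 "ND2", "CA", "CB", "CG", 1.33, 116.4), c(-122.5, -65, -60, 120)),
    ASP = list(d(cb, "CG", "N", "CA", "CB", 1.52, 112.6, "OD1", "CA", "CB", "CG", 1.25, 118.4,
                 "OD2", "CA", "CB", "CG", 1.25, 118.4), c(-122.5, -65, -60, 120)),
    GLN = list(d(cb, "CG", "N", "CA", "CB", 1.53, 114, "CD", "CA", "CB", "CG", 1.52, 112.6,
                 "OE1", "CB", "CG", "CD", 1.23, 120.8, "NE2", "CB", "CG", "CD", 1.33, 116.4),
               c(-122.5, -65, 180, -60, 120)),
    GLU = list(d(cb, "CG", "N", "CA", "CB", 1.53, 114, "CD", "CA", "CB", "CG", 1.52, 112.6,
                 "OE1", "CB", "CG", "CD", 1.25, 118.4, "OE2", "CB", "CG", "CD", 1.25, 118.4),
               c(-122.5, -65, 180, -60, 120)),
    LYS = list(d(cb, "CG", "N", "CA", "CB", 1.53, 114, "CD", "CA", "CB", "CG", 1.52, 111,
                 "CE", "CB", "CG", "CD", 1.52, 111, "NZ", "CG", "CD", "CE", 1.49, 111),
               c(-122.5, -65, 180, 180, 180)),
    ARG = list(d(cb, "CG", "N", "CA", "CB", 1.53, 114, "CD", "CA", "CB", "CG", 1.52, 111,
                 "NE", "CB", "CG", "CD", 1.46, 112, "CZ", "CG", "CD", "NE", 1.33, 124,
                 "NH1", "CD", "NE", "CZ", 1.33, 120, "NH2", "CD", "NE", "CZ", 1.33, 120),
               c(-122.5, -65, 180, 180, 180, 0, 180)),
    HIS = list(d(cb, "CG", "N", "CA", "CB", 1.50, 113.8, "ND1", "CA", "CB", "CG", 1.38, 122.7,
                 "CD2", "CA", "CB", "CG", 1.36, 131, "CE1", "CB", "CG", "ND1", 1.32, 109,
                 "NE2", "CB", "CG", "CD2", 1.37, 107), c(-122.5, -65, -90, 90, 180, 180)),
    PHE = list(d(cb, "CG", "N", "CA", "CB", 1.50, 113.8, "CD1", "CA", "CB", "CG", 1.39, 120.7,
                 "CD2", "CA", "CB", "CG", 1.39, 120.7, "CE1", "CB", "CG", "CD1", 1.39, 120,
                 "CE2", "CB", "CG", "CD2", 1.39, 120, "CZ", "CG", "CD1", "CE1", 1.39, 120),
               c(-122.5, -65, -90, 90, 180, 180, 0)),
    TYR = list(d(cb, "CG", "N", "CA", "CB", 1.50, 113.8, "CD1", "CA", "CB", "CG", 1.39, 120.7,
                 "CD2", "CA", "CB", "CG", 1.39, 120.7, "CE1", "CB", "CG", "CD1", 1.39, 120,
                 "CE2", "CB", "CG", "CD2", 1.39, 120, "CZ", "CG", "CD1", "CE1", 1.39, 120,
                 "OH", "CD1", "CE1", "CZ", 1.38, 120), c(-122.5, -65, -90, 90, 180, 180, 0, 180)),
    TRP = list(d(cb, "CG", "N", "CA", "CB", 1.50, 113.8, "CD1", "CA", "CB", "CG", 1.37, 127,
                 "CD2", "CA", "CB", "CG", 1.43, 126.6, "NE1", "CB", "CG", "CD1", 1.38, 110,
                 "CE2", "CG", "CD1", "NE1", 1.37, 109, "CE3", "CB", "CG", "CD2", 1.40, 133.9,
                 "CZ2", "CD1", "NE1", "CE2", 1.40, 122, "CZ3", "CG", "CD2", "CE3", 1.39, 118,
                 "CH2", "NE1", "CE2", "CZ2", 1.37, 117),
               c(-122.5, -65, -90, 90, 180, 0, 180, 180, 180, 180)),
    PRO = list(d(cb, "CG", "N", "CA", "CB", 1.49, 104, "CD", "CA", "CB", "CG", 1.50, 105),
               c(-122.5, 30, -35))
  )
  sc <- tors[[resname]]
  if (is.null(sc)) return(NULL)
  def <- sc[[1]]
  def$torsion <- sc[[2]]
  def
}

#' Build an ideal atomistically detailed alpha-helix
#'
#' Places heavy atoms on a canonical alpha-helix with (phi, psi) =
#' (-57, -47) degrees and a single fixed sidechain rotamer per residue type.
#' The output is canonicalized: the helix principal axis (from the C-alpha
#' trace) is the z-axis, the C-alpha centroid sits at the origin, and the
#' N-terminal residue has the most positive z. For a transmembrane helix
#' running from the periplasmic domain to the cytoplasmic side, positive z is
#' therefore the periplasmic direction.
#'
#' @param peptide one-row peptide tibble, or a plain character sequence.
#' @param first_resid residue numbering start when `peptide` is a string.
#' @return object of class `atomistic_helix`: a list with `atoms` (tibble:
#'   resid, resname, atom, x, y, z in A) and the peptide metadata.
#' @export
build_ideal_helix <- function(peptide, first_resid = 1L) {
  if (is.character(peptide)) {
    peptide <- tibble(id = "helix", receptor = NA_character_, group = NA_character_,
                      phenotype = NA_character_, first_resid = as.integer(first_resid),
                      sequence = toupper(peptide))
  }
  stopifnot(nrow(peptide) == 1)
  seq1 <- strsplit(peptide$sequence, "")[[1]]
  if (!length(seq1)) abort("empty sequence")
  if (any(!seq1 %in% AA1))
    abort(paste0("non-canonical residue: ", seq1[!seq1 %in% AA1][1]))
  res3 <- AA3[match(seq1, AA1)]
  n <- length(seq1)

  atoms <- list()   # named positions per residue
  rows <- list()
  add <- function(resid, resname, atom, xyz) {
    rows[[length(rows) + 1]] <<- tibble(resid = resid, resname = resname,
                                        atom = atom, x = xyz[1], y = xyz[2], z = xyz[3])
  }
  for (i in seq_len(n)) {
    cur <- list()
    if (i == 1) {
      cur$N <- c(0, 0, 0)
      cur$CA <- c(1.458, 0, 0)
      ang <- 110.0 * pi / 180
      cur$C <- cur$CA + 1.525 * c(cos(pi - ang), sin(pi - ang), 0)
    } else {
      prev <- atoms[[i - 1]]
      cur$N <- nerf_place(prev$N, prev$CA, prev$C, 1.329, 116.2, HELIX_PSI)
      cur$CA <- nerf_place(prev$CA, prev$C, cur$N, 1.458, 121.7, 180)
      cur$C <- nerf_place(prev$C, cur$N, cur$CA, 1.525, 110.0, HELIX_PHI)
    }
    cur$O <- nerf_place(cur$N, cur$CA, cur$C, 1.231, 120.8, HELIX_PSI + 180)
    def <- sidechain_def(res3[i])
    if (!is.null(def)) {
      for (k in seq_len(nrow(def))) {
        cur[[def$atom[k]]] <- nerf_place(cur[[def$A[k]]], cur[[def$B[k]]],
                                         cur[[def$P[k]]], def$bond[k],
                                         def$angle[k], def$torsion[k])
      }
    }
    atoms[[i]] <- cur
    resid <- peptide$first_resid + i - 1L
    for (nm in names(cur)) add(resid, res3[i], nm, cur[[nm]])
  }
  tbl <- bind_rows(rows)

  # canonicalize: CA principal axis -> z, CA centroid -> origin, N-term at +z
  ca <- as.matrix(tbl[tbl$atom == "CA", c("x", "y", "z")])
  cen <- colMeans(ca)
  xyz <- sweep(as.matrix(tbl[, c("x", "y", "z")]), 2, cen)
  if (n >= 3) {
    cac <- sweep(ca, 2, cen)
    ax <- svd(cac)$v[, 1]
    if (sum(ax * (cac[1, ] - cac[n, ])) < 0) ax <- -ax
    R <- rotation_to_z(ax)
    xyz <- xyz %*% t(R)
  }
  tbl$x <- xyz[, 1]; tbl$y <- xyz[, 2]; tbl$z <- xyz[, 3]
  structure(list(atoms = tbl, peptide = peptide), class = "atomistic_helix")
}

# rotation matrix mapping unit vector v onto +z
rotation_to_z <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  u <- pracma_cross(v, z)
  s <- sqrt(sum(u^2))
  u <- u / s
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m <- pracma_cross(n1, n2)
  atan2(sum(m * b2) / sqrt(sum(b2^2)), sum(n1 * n2)) * 180 / pi
}

#' Backbone dihedrals of a built helix
#'
#' @param helix an `atomistic_helix`.
#' @return tibble with resid, phi, psi (degrees; NA where undefined).
#' @export
backbone_dihedrals <- function(helix) {
  tbl <- helix$atoms
  resids <- sort(unique(tbl$resid))
  get <- function(resid, atom) {
    r <- tbl[tbl$resid == resid & tbl$atom == atom, ]
    c(r$x, r$y, r$z)
  }
  out <- lapply(seq_along(resids), function(i) {
    r <- resids[i]
    phi <- if (i > 1) dihedral_angle(get(resids[i - 1], "C"), get(r, "N"),
                                     get(r, "CA"), get(r, "C")) else NA_real_
    psi <- if (i < length(resids)) dihedral_angle(get(r, "N"), get(r, "CA"),
                                                  get(r, "C"), get(resids[i + 1], "N")) else NA_real_
    tibble(resid = r, phi = phi, psi = psi)
  })
  bind_rows(out)
}

#' Export a built helix as PDB
#'
#' @param helix an `atomistic_helix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_helix_pdb <- function(helix, path) {
  tbl <- helix$atoms
  lines <- vapply(seq_len(nrow(tbl)), function(i) {
    sprintf("ATOM  %5d %-4s%3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            i, tbl$atom[i], tbl$resname[i], tbl$resid[i],
            tbl$x[i], tbl$y[i], tbl$z[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
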