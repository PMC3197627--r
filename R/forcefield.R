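#' MARTINI-style coarse-grained forcefield table
#'
#' Loads the shipped interaction table: 18 bead subtypes in four main classes
#' (P polar, Q charged, N mixed, C apolar), a symmetric matrix of interaction
#' levels, and the level-to-Lennard-Jones lookup (9 levels; epsilon from
#' 5.6 kJ/mol supra-attractive down to 2.0 kJ/mol, sigma 4.7 A except the
#' super-repulsive level's 6.2 A). Lennard-Jones terms are force-shifted to
#' zero between `r1_lj` (9 A) and `r_cut` (12 A); Coulomb terms between 0 and
#' `r_cut`, screened by a relative dielectric `eps_r` (default 15).
#'
#' @param eps_r relative dielectric constant for the screened Coulomb term.
#' @return An object of class `cg_forcefield`: bead type names, dense
#'   `epsilon`/`sigma` matrices (kJ/mol, A), cutoffs, and the electrostatic
#'   prefactor.
#' @export
martini_forcefield <- function(eps_r = 15) {
  lev <- read.csv(pkg_extdata("martini_style_levels.csv"), stringsAsFactors = FALSE)
  mat <- read.csv(pkg_extdata("martini_style_matrix.csv"), row.names = 1,
                  stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(mat)
  stopifnot(identical(rownames(mat), colnames(mat)), all(mat == t(mat)))
  eps <- matrix(lev$epsilon_kjmol[match(mat, lev$level)], nrow(mat),
                dimnames = dimnames(mat))
  sig <- matrix(lev$sigma_A[match(mat, lev$level)], nrow(mat),
                dimnames = dimnames(mat))
  if (anyNA(eps)) abort("interaction matrix contains a level absent from the level table")
  structure(list(
    types = rownames(mat),
    main_class = substr(rownames(mat), 1, 1),
    levels = mat,
    epsilon = eps,
    sigma = sig,
    r1_lj = 9,
    r_cut = 12,
    eps_r = eps_r,
    f_elec = .const$f_elec / eps_r
  ), class = "cg_forcefield")
}

#' Pairwise Lennard-Jones parameters for two bead types
#'
#' @param ff a [martini_forcefield()] object.
#' @param type_a,type_b bead subtype names (e.g. `"P4"`, `"C1"`).
#' @return tibble with one row: epsilon (kJ/mol), sigma (A), level.
#' @export
ff_pair <- function(ff, type_a, type_b) {
  stopifnot(inherits(ff, "cg_forcefield"))
  if (!type_a %in% ff$types || !type_b %in% ff$types)
    abort(paste0("unknown bead type: ", setdiff(c(type_a, type_b), ff$types)[1]))
  tibble(type_a = type_a, type_b = type_b,
         level = ff$levels[type_a, type_b],
         epsilon = ff$epsilon[type_a, type_b],
         sigma = ff$sigma[type_a, type_b])
}

#' Shifted nonbonded pair potential and force
#'
#' Evaluates the force-shifted Lennard-Jones (plus screened Coulomb) pair
#' interaction used by the engine. Both the potential and its derivative are
#' continuous and reach exactly zero at `r >= r_cut`. Used mainly for
#' inspection and testing; the engine evaluates the identical functional form
#' in compiled code.
#'
#' @param r distances (A), vectorised.
#' @param epsilon,sigma Lennard-Jones parameters (kJ/mol, A).
#' @param qq product of charges (e^2), default 0.
#' @param ff forcefield (for cutoffs and the electrostatic prefactor).
#' @return tibble with columns r, energy (kJ/mol), force (kJ/mol/A; -dV/dr).
#' @export
pair_potential <- function(r, epsilon, sigma, qq = 0, ff = martini_forcefield()) {
  shift_const <- function(p, r1, rc) {
    d <- rc - r1
    A <- -p * ((p + 4) * rc - (p + 1) * r1) / (rc^(p + 2) * d^2)
    B <- p * ((p + 3) * rc - (p + 1) * r1) / (rc^(p + 2) * d^3)
    C <- 1 / rc^p - (A / 3) * d^3 - (B / 4) * d^4
    list(A = A, B = B, C = C)
  }
  term <- function(r, p, r1, rc) {
    s <- shift_const(p, r1, rc)
    inside <- r < rc
    d <- pmax(r - r1, 0)
    phi <- ifelse(inside, 1 / r^p - (s$A / 3) * d^3 - (s$B / 4) * d^4 - s$C, 0)
    f <- ifelse(inside, p / r^(p + 1) + s$A * d^2 + s$B * d^3, 0)
    list(phi = phi, f = f)
  }
  t6 <- term(r, 6, ff$r1_lj, ff$r_cut)
  t12 <- term(r, 12, ff$r1_lj, ff$r_cut)
  t1 <- term(r, 1, 0, ff$r_cut)
  c6 <- 4 * epsilon * sigma^6
  c12 <- 4 * epsilon * sigma^12
  tibble(r = r,
         energy = c12 * t12$phi - c6 * t6$phi + ff$f_elec * qq * t1$phi,
         force = c12 * t12$f - c6 * t6$f + ff$f_elec * qq * t1$f)
}
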