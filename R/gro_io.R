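# GRO-format trajectory I/O. Internal units are A; GRO files are nm, fixed
# width, so coordinates round-trip to 0.001 nm.

#' Write a trajectory (or single system) as concatenated GRO frames
#'
#' @param x a `cg_trajectory` or `cg_system`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gro <- function(x, path) {
  if (inherits(x, "cg_system")) {
    x <- new_trajectory(list(x$xyz), matrix(x$box, 1, 3), 0, x$beads)
  }
  stopifnot(inherits(x, "cg_trajectory"))
  beads <- x$beads
  n <- nrow(beads)
  con <- file(path, "w")
  on.exit(close(con))
  atomno <- seq_len(n) %% 100000L
  resid <- beads$resid %% 100000L
  for (f in seq_along(x$frames)) {
    xyz <- x$frames[[f]] / 10  # A -> nm
    writeLines(sprintf("pistonsim frame t= %.3f ps", x$time[f]), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       resid, substr(beads$resname, 1, 5),
                       substr(beads$name, 1, 5), atomno,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", x$box[f, 1] / 10,
                       x$box[f, 2] / 10, x$box[f, 3] / 10), con)
  }
  invisible(path)
}

#' Read a sequence of GRO frames
#'
#' Accepts the fixed-width GRO layout with one or more concatenated frames.
#' Frame times are taken from `t=` in the title line when present. Malformed
#' records raise an error naming the offending line.
#'
#' @param path GRO file.
#' @return a `cg_trajectory` (coordinates in A). Bead metadata (resid,
#'   resname, name) is parsed from the file; `role` is inferred from bead
#'   names via [infer_roles()].
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  ln <- 1L
  frames <- list(); boxes <- list(); times <- numeric(); beads <- NULL
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1L; next }
    title <- lines[ln]
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    times <- c(times, if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else NA_real_)
    if (ln + 1L > length(lines)) abort(paste0("truncated GRO file at line ", ln))
    natoms <- suppressWarnings(as.integer(trimws(lines[ln + 1L])))
    if (is.na(natoms) || natoms <= 0)
      abort(paste0("invalid atom count at line ", ln + 1L))
    a0 <- ln + 2L
    a1 <- a0 + natoms - 1L
    if (a1 + 1L > length(lines))
      abort(paste0("missing box line: frame starting at line ", ln,
                   " ends beyond end of file (expected box at line ", a1 + 1L, ")"))
    al <- lines[a0:a1]
    bad <- which(nchar(al) < 44)
    if (length(bad)) abort(paste0("malformed GRO atom line at line ", a0 + bad[1] - 1L))
    resid <- as.integer(substr(al, 1, 5))
    resname <- trimws(substr(al, 6, 10))
    name <- trimws(substr(al, 11, 15))
    x <- as.numeric(substr(al, 21, 28))
    y <- as.numeric(substr(al, 29, 36))
    z <- as.numeric(substr(al, 37, 44))
    if (anyNA(x) || anyNA(y) || anyNA(z) || anyNA(resid))
      abort(paste0("malformed GRO atom line at line ",
                   a0 + which(is.na(x) | is.na(y) | is.na(z) | is.na(resid))[1] - 1L))
    bx <- suppressWarnings(as.numeric(strsplit(trimws(lines[a1 + 1L]), "\\s+")[[1]]))
    if (length(bx) < 3 || anyNA(bx[1:3]))
      abort(paste0("malformed or missing box line at line ", a1 + 1L))
    if (is.null(beads)) {
      beads <- tibble(name = name, resid = resid, resname = resname)
      beads$role <- infer_roles(beads)
      beads$molecule <- ifelse(resname == "DPPC", "DPPC",
                               ifelse(resname == "W", "W", "PEP"))
    }
    frames[[length(frames) + 1]] <- cbind(x, y, z) * 10
    boxes[[length(boxes) + 1]] <- bx[1:3] * 10
    ln <- a1 + 2L
  }
  if (!length(frames)) abort("no frames found")
  new_trajectory(frames, do.call(rbind, boxes), times, beads)
}

#' Infer analysis roles from bead names
#'
#' `BB` beads are helix backbone, `SC*` helix sidechain, `PO4` phosphate;
#' everything else keeps its own name as role.
#'
#' @param beads bead tibble with a `name` column.
#' @return character vector of roles.
#' @export
infer_roles <- function(beads) {
  ifelse(beads$name == "BB", "BB",
         ifelse(grepl("^SC", beads$name), "SC", beads$name))
}
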