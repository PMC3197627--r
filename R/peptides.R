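AA1 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE","LEU","LYS",
         "MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

RECEPTORS <- c("Tar_Ecoli", "Tar_Styphimurium", "Trg_Ecoli")
PHENOTYPES <- c("wildtype", "kinase_active", "kinase_inactive", "mixed")
GROUPS <- c("WY_scan", "WA_point", "Arg_scan_Tar", "Basic_Trg")

validate_peptides <- function(tbl) {
  nc <- nchar(tbl$sequence)
  if (any(nc < 20 | nc > 40))
    abort("helix length must be between 20 and 40 residues")
  bad <- vapply(strsplit(tbl$sequence, ""), function(s) any(!s %in% AA1), logical(1))
  if (any(bad))
    abort(paste0("non-canonical residue in peptide: ", tbl$id[bad][1]))
  if (any(!tbl$phenotype %in% PHENOTYPES)) abort("unknown phenotype label")
  if (any(!tbl$receptor %in% RECEPTORS)) abort("unknown receptor")
  invisible(tbl)
}

#' TM2 helix peptide fixtures
#'
#' Returns the shipped TM2 helix set for one mutant group, always including
#' the matching wildtype: the WY-scan of the cytoplasmic W/Y anchor pair of
#' E. coli Tar, the Trp-to-Ala point mutants of the two anchoring tryptophans
#' (W192, W209), the arginine-scanning mutants of S. typhimurium Tar (F189R,
#' W192R, W209R), and the basic core mutants of E. coli Trg (T215K, T215R,
#' L216R). Kinase phenotypes are experimental labels carried as metadata,
#' never computed. The shipped sequences are synthetic stand-ins constructed
#' to satisfy the documented anchor-residue positions and helix lengths (see
#' the package vignette); they are not database sequences.
#'
#' @param group one of `"WY_scan"`, `"WA_point"`, `"Arg_scan_Tar"`,
#'   `"Basic_Trg"`, or `"all"`.
#' @return tibble with columns id, receptor, group, phenotype, first_resid,
#'   sequence, and a `mutations` list-column of (position, from, to) tibbles
#'   relative to the group wildtype.
#' @export
tm2_peptides <- function(group = "all") {
  if (!group %in% c(GROUPS, "all"))
    abort(paste0("unknown fixture group: ", group))
  tbl <- read_helix_fasta(pkg_extdata("tm2_helices_synthetic.fasta"))
  mut <- read.csv(pkg_extdata("tm2_mutations_synthetic.csv"), stringsAsFactors = FALSE)
  tbl$mutations <- lapply(tbl$id, function(id) {
    m <- mut[mut$id == id, c("position", "from", "to")]
    as_tibble(m)
  })
  if (group == "all") return(tbl)
  wt_of <- c(WY_scan = "TarEc_WT", WA_point = "TarEc_WT",
             Arg_scan_Tar = "TarSt_WT", Basic_Trg = "TrgEc_WT")
  keep <- tbl$group == group | tbl$id == wt_of[[group]]
  out <- tbl[keep, ]
  out$group <- group
  out
}

#' Read helix peptides from FASTA
#'
#' Structured headers of the form `id|receptor|group|phenotype|first_resid`
#' are parsed into full metadata; plain headers get the id only, with
#' remaining fields supplied from an optional side-car JSON file (a list of
#' records keyed by id with fields receptor, group, phenotype, first_resid).
#'
#' @param path FASTA file.
#' @param metadata optional path to a side-car JSON metadata file.
#' @return tibble of peptides.
#' @export
read_helix_fasta <- function(path, metadata = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr_idx <- grep("^>", lines)
  if (!length(hdr_idx)) abort("no FASTA records found")
  ends <- c(hdr_idx[-1] - 1, length(lines))
  recs <- lapply(seq_along(hdr_idx), function(k) {
    header <- sub("^>", "", lines[hdr_idx[k]])
    seq <- paste0(lines[(hdr_idx[k] + 1):ends[k]], collapse = "")
    fields <- strsplit(header, "|", fixed = TRUE)[[1]]
    if (length(fields) == 5) {
      tibble(id = fields[1], receptor = fields[2], group = fields[3],
             phenotype = fields[4], first_resid = as.integer(fields[5]),
             sequence = toupper(gsub("\\s", "", seq)))
    } else {
      tibble(id = fields[1], receptor = NA_character_, group = NA_character_,
             phenotype = NA_character_, first_resid = NA_integer_,
             sequence = toupper(gsub("\\s", "", seq)))
    }
  })
  tbl <- bind_rows(recs)
  if (!is.null(metadata)) {
    meta <- jsonlite::read_json(metadata, simplifyVector = TRUE)
    for (f in c("receptor", "group", "phenotype", "first_resid")) {
      if (f %in% names(meta)) {
        v <- meta[[f]][match(tbl$id, meta$id)]
        tbl[[f]] <- ifelse(is.na(tbl[[f]]), v, tbl[[f]])
      }
    }
    tbl$first_resid <- as.integer(tbl$first_resid)
  }
  if (!anyNA(tbl$receptor)) validate_peptides(tbl)
  tbl
}

#' Apply point mutations to a helix peptide
#'
#' Positions use full-protein numbering; position p maps to local index
#' p - first_resid + 1. Each `from` residue must match the current sequence at
#' its position, so mutation lists cross-check the fixture they describe.
#' Substitutions are order-independent.
#'
#' @param peptide one-row peptide tibble (as from [tm2_peptides()]).
#' @param mutations tibble/data.frame with columns position, from, to; may be
#'   empty.
#' @param id optional new id for the mutant.
#' @return a new one-row peptide tibble of identical length.
#' @export
apply_mutations <- function(peptide, mutations, id = NULL) {
  stopifnot(nrow(peptide) == 1)
  seq <- strsplit(peptide$sequence, "")[[1]]
  first <- peptide$first_resid
  if (nrow(mutations)) {
    idx <- mutations$position - first + 1L
    if (any(idx < 1 | idx > length(seq)))
      abort(paste0("mutation position ", mutations$position[idx < 1 | idx > length(seq)][1],
                   " outside helix [", first, ", ", first + length(seq) - 1L, "]"))
    mism <- seq[idx] != mutations$from
    if (any(mism))
      abort(paste0("from-residue mismatch at position ",
                   mutations$position[mism][1], ": found ", seq[idx][mism][1],
                   ", expected ", mutations$from[mism][1]))
    if (any(!mutations$to %in% AA1)) abort("mutant residue is not a canonical amino acid")
    seq[idx] <- mutations$to
  }
  out <- peptide
  out$sequence <- paste0(seq, collapse = "")
  out$mutations <- list(as_tibble(mutations))
  if (!is.null(id)) out$id <- id
  out
}

#' Write helix peptides to FASTA with structured headers
#'
#' @param peptides peptide tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_helix_fasta <- function(peptides, path) {
  lines <- unlist(lapply(seq_len(nrow(peptides)), function(k) {
    p <- peptides[k, ]
    c(paste0(">", p$id, "|", p$receptor, "|", p$group, "|", p$phenotype, "|",
             p$first_resid), p$sequence)
  }))
  writeLines(lines, path)
  invisible(path)
}
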