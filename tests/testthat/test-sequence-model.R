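test_that("fixture groups contain the documented peptides with their wildtype", {
  wy <- tm2_peptides("WY_scan")
  expect_equal(nrow(wy), 7)
  expect_setequal(wy$id, c("TarEc_WT", "WYm3", "WYm2", "WYm1", "WYp1", "WYp2", "WYp3"))
  expect_equal(sum(wy$phenotype == "kinase_inactive"), 3)
  expect_equal(sum(wy$phenotype == "kinase_active"), 3)

  wa <- tm2_peptides("WA_point")
  expect_setequal(wa$id, c("TarEc_WT", "W192A", "W209A", "W192A_W209A"))

  arg <- tm2_peptides("Arg_scan_Tar")
  expect_setequal(arg$id, c("TarSt_WT", "F189R", "W192R", "W209R"))
  expect_true(all(arg$receptor == "Tar_Styphimurium"))

  trg <- tm2_peptides("Basic_Trg")
  expect_setequal(trg$id, c("TrgEc_WT", "T215K", "T215R", "L216R"))
  expect_equal(trg$phenotype[trg$id == "L216R"], "kinase_inactive")

  expect_error(tm2_peptides("WX_scan"), "unknown fixture group")
})

test_that("sequences are valid helix peptides with anchors at documented positions", {
  all_pep <- tm2_peptides("all")
  expect_true(all(nchar(all_pep$sequence) >= 20 & nchar(all_pep$sequence) <= 40))
  at <- function(id, pos) {
    p <- all_pep[all_pep$id == id, ]
    substr(p$sequence, pos - p$first_resid + 1, pos - p$first_resid + 1)
  }
  expect_equal(at("TarEc_WT", 192), "W")
  expect_equal(at("TarEc_WT", 209), "W")
  expect_equal(at("TarEc_WT", 210), "Y")
  expect_equal(at("TarSt_WT", 189), "F")
  expect_equal(at("TrgEc_WT", 215), "T")
  expect_equal(at("TrgEc_WT", 216), "L")
  expect_equal(at("W209R", 209), "R")
})

test_that("applying shipped mutation lists to the wildtype reproduces every fixture", {
  all_pep <- tm2_peptides("all")
  wt_of <- c(WY_scan = "TarEc_WT", WA_point = "TarEc_WT",
             Arg_scan_Tar = "TarSt_WT", Basic_Trg = "TrgEc_WT")
  muts <- all_pep[all_pep$phenotype != "wildtype", ]
  for (k in seq_len(nrow(muts))) {
    m <- muts[k, ]
    wt <- all_pep[all_pep$id == wt_of[[m$group]], ]
    regen <- apply_mutations(wt, m$mutations[[1]])
    expect_identical(regen$sequence, m$sequence, label = m$id)
  }
})

test_that("mutations are order-independent and validated", {
  wt <- tm2_peptides("WY_scan")
  wt <- wt[wt$id == "TarEc_WT", ]
  m <- data.frame(position = c(192, 209), from = c("W", "W"), to = c("A", "A"))
  a <- apply_mutations(wt, m)
  b <- apply_mutations(wt, m[2:1, ])
  expect_identical(a$sequence, b$sequence)
  expect_equal(nchar(a$sequence), nchar(wt$sequence))

  # empty mutation set is the identity
  expect_identical(apply_mutations(wt, m[0, ])$sequence, wt$sequence)

  # wrong from-residue names the position and the found residue
  bad <- data.frame(position = 209, from = "F", to = "A")
  expect_error(apply_mutations(wt, bad), "209.*found W", )
  out <- data.frame(position = 500, from = "W", to = "A")
  expect_error(apply_mutations(wt, out), "outside")
})

test_that("full-protein position maps bijectively onto local indices", {
  pep <- tm2_peptides("Basic_Trg")
  p <- pep[pep$id == "TrgEc_WT", ]
  positions <- p$first_resid:(p$first_resid + nchar(p$sequence) - 1)
  local <- positions - p$first_resid + 1
  expect_equal(length(unique(local)), nchar(p$sequence))
  expect_equal(range(local), c(1, nchar(p$sequence)))
})

test_that("FASTA round trip preserves peptides; plain FASTA gets metadata side-car", {
  pep <- tm2_peptides("WA_point")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_helix_fasta(pep, f)
  back <- read_helix_fasta(f)
  expect_equal(back$sequence, pep$sequence)
  expect_equal(back$first_resid, pep$first_resid)

  plain <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">mypep", "AFLVWLAIVLAILVFAILIALWYIRKLALS"), plain)
  meta <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(id = "mypep", receptor = "Tar_Ecoli",
                            group = "WY_scan", phenotype = "wildtype",
                            first_resid = 188),
                       meta, auto_unbox = TRUE)
  got <- read_helix_fasta(plain, metadata = meta)
  expect_equal(got$receptor, "Tar_Ecoli")
  expect_equal(got$first_resid, 188L)
})
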