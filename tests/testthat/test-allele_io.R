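test_that("FASTA read-back preserves records, order and sequence content", {
  u <- znf_canonical_unit()
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">al1", strrep(u, 11), ">al2 some description", strrep(u, 11)), f)
  seqs <- read_allele_fasta(f)
  expect_identical(names(seqs), c("al1", "al2"))
  expect_identical(unname(nchar(seqs)), c(924L, 924L))
  expect_identical(unname(seqs[[1]]), strrep(u, 11))
})

test_that("ambiguity codes are rejected with the offending position", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGTNACGT"), f)
  expect_error(read_allele_fasta(f), "position 5")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), f)
  expect_error(read_allele_fasta(f), "duplicate.*a")
})

test_that("an empty FASTA yields an empty set with a warning", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), f)
  expect_warning(seqs <- read_allele_fasta(f), "empty")
  expect_length(seqs, 0)
})

test_that("exact 84-bp tiling decomposes into complete units", {
  u <- znf_canonical_unit()
  units <- decompose_minisatellite(strrep(u, 3))
  expect_equal(nrow(units), 3L)
  expect_true(all(units$complete))
  expect_identical(units$index, 0:2)
  expect_identical(unique(units$nt), u)
})

test_that("a first unit with a 9-nt in-frame deletion is segmented as a 75-nt unit", {
  u <- znf_canonical_unit()
  # remove codons 5-7 (aa 4-6), taking out the first zinc-binding cysteine
  u_del <- paste0(substr(u, 1, 12), substr(u, 22, 84))
  units <- decompose_minisatellite(paste0(u_del, strrep(u, 10)))
  expect_equal(nchar(units$nt[1]), 75L)
  expect_false(units$complete[1])
  expect_true(all(units$complete[-1]))
  expect_true(all(nchar(units$nt[-1]) == 84L))
})

test_that("unsegmentable lengths raise an error reporting the remainder", {
  expect_error(decompose_minisatellite(strrep("ACGT", 25)), "remainder")
})

test_that("decomposition round-trips byte-for-byte on simulated alleles", {
  fam <- suppressWarnings(simulate_allele_family(simulation_config(seed = 7)))
  for (nm in names(fam$alleles)) {
    units <- decompose_minisatellite(fam$alleles[[nm]])
    expect_identical(paste(units$nt, collapse = ""), unname(fam$alleles[[nm]]))
    expect_identical(units$nt, fam$leaf_units[[nm]])  # true boundaries recovered
  }
})

test_that("translation is frame-0 standard code with stop-codon flagging", {
  u <- znf_canonical_unit()
  units <- translate_units(decompose_minisatellite(strrep(u, 2)))
  expect_equal(nchar(units$aa), nchar(units$nt) / 3)
  expect_identical(units$aa[1], "TGEKCPECGKAFSQSSNLQKHQRTHTGE")
  # 75-nt unit -> 25 residues
  u_del <- paste0(substr(u, 1, 12), substr(u, 22, 84))
  units2 <- translate_units(decompose_minisatellite(paste0(u_del, u, u)))
  expect_equal(nchar(units2$aa[1]), 25L)
  # in-frame stop: truncation + incomplete flag, not fatal
  u_stop <- u
  substr(u_stop, 31, 33) <- "TAA"
  units3 <- decompose_minisatellite(paste0(u_stop, u, u))
  expect_warning(units3 <- translate_units(units3), "stop codon")
  expect_false(units3$complete[1])
  expect_equal(nchar(units3$aa[1]), 10L)
})

test_that("contact positions anchor at the first His (helix +7)", {
  pos <- resolve_contact_positions(canon_aa)
  expect_identical(pos$aa_idx, c(12L, 16L, 19L))
  expect_identical(pos$nt_idx, c(36:38, 48:50, 57:59))
  # determinism: same peptide, same indices
  expect_identical(resolve_contact_positions(canon_aa), pos)
  # extended offset set resolves relative to the same anchor
  pos2 <- resolve_contact_positions(canon_aa, c(-5L, -2L, 1L))
  expect_identical(pos2$aa_idx, c(8L, 11L, 14L))
})

test_that("units missing a zinc-ligand cysteine fail contact resolution", {
  aa_del <- paste0(substr(canon_aa, 1, 4), substr(canon_aa, 8, 28))  # drop C,P,E
  expect_error(resolve_contact_positions(aa_del), "pattern not found")
})

test_that("contact extraction returns the field's triplet notation", {
  seq3 <- paste0(unit_with_contacts("TDK"), unit_with_contacts("ASQ"),
                 znf_canonical_unit())
  a <- znf_array(seq3, "trip")
  expect_identical(a$contacts, c("TDK", "ASQ", "SNK"))
  # broken first unit yields the placeholder
  u <- znf_canonical_unit()
  u_del <- paste0(substr(u, 1, 12), substr(u, 22, 84))
  b <- znf_array(paste0(u_del, u, u), "mut")
  expect_identical(b$contacts[1], "---")
  expect_identical(b$contacts[-1], c("SNK", "SNK"))
})

test_that("pattern-mode filtering keeps canonical units and drops Cys-less ones", {
  u <- znf_canonical_unit()
  a <- znf_array(strrep(u, 4), "ok")
  expect_true(all(a$kept))
  u_del <- paste0(substr(u, 1, 12), substr(u, 22, 84))
  b <- znf_array(paste0(u_del, u, u), "broken_first")
  expect_identical(b$kept, c(FALSE, TRUE, TRUE))
})

test_that("profile-mode filtering applies the strictly-above bit-score rule", {
  prof <- matrix(0, 28, 20, dimnames = list(NULL, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  prof[1, "T"] <- 17.7   # canonical unit scores exactly the threshold
  a <- znf_array(strrep(znf_canonical_unit(), 3), "edge",
                 model = confidence_model("profile", profile = prof))
  expect_false(any(a$kept))          # 17.7 is not above 17.7
  prof[1, "T"] <- 17.8
  b <- filter_repeats(a, confidence_model("profile", profile = prof))
  expect_true(all(b$kept))
  expect_error(confidence_model("profile"), "requires")
})

test_that("the allele table serializes one row per allele", {
  u <- znf_canonical_unit()
  arrays <- list(znf_array(strrep(u, 3), "x"), znf_array(strrep(u, 4), "y"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_allele_table(arrays, f)
  tab <- read.delim(f)
  expect_identical(tab$name, c("x", "y"))
  expect_identical(tab$n_units, c(3L, 4L))
})
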