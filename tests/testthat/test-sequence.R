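test_that("sequence parsing records residues, numbering and caps", {
  ef1 <- parse_sequence("DYATLQLQEGRLHFMFDLG", label = "EF1", capped = TRUE)
  expect_equal(length(ef1), 19L)
  expect_equal(ef1$residues$code[1], "D")
  expect_equal(ef1$residues$code[19], "G")
  expect_equal(ef1$n_term_cap, "ACE")
  expect_equal(ef1$c_term_cap, "NME")
  expect_equal(ef1$residues$index, 1:19)

  ef2 <- parse_sequence("DFATVQLRNGFPYFSYDLG", label = "EF2")
  expect_equal(ef2$residues$code[8], "R")
  expect_equal(ef2$residues$code[17], "D")
  expect_true(is.na(ef2$n_term_cap))

  g <- parse_sequence("G")
  expect_equal(length(g), 1L)

  expect_error(parse_sequence("DYAXLQ"), "position 4")
  expect_error(parse_sequence(""))
})

test_that("polarity classification is total, pure and matches the four groups", {
  expect_equal(classify_residue("R"), "positive-polar")
  expect_equal(classify_residue("L"), "non-polar")
  expect_equal(classify_residue("Q"), "uncharged-polar")
  expect_equal(classify_residue("D"), "negative-polar")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  cls <- classify_residue(aa)
  expect_equal(length(cls), 20L)
  expect_true(all(cls %in% c("positive-polar", "negative-polar",
                             "uncharged-polar", "non-polar")))
  expect_identical(cls, classify_residue(aa))
  expect_error(classify_residue("B"), "invalid residue")
})

test_that("facing pairs follow the (i, L - i) register", {
  ef1 <- hairpin_peptide("EF1")
  fp <- facing_pairs(ef1)
  expect_equal(nrow(fp), 8L)
  expect_true(all(fp$i + fp$j == 19L))
  expect_true(all(fp$j - fp$i >= 2L))
  reg <- fp[fp$kind == "hbond-register", ]
  expect_equal(reg$i, c(2L, 4L, 6L, 8L))
  expect_equal(reg$j, c(17L, 15L, 13L, 11L))

  five <- parse_sequence("AAAAA")
  fp5 <- facing_pairs(five)
  expect_equal(nrow(fp5), 1L)
  expect_equal(c(fp5$i, fp5$j), c(1L, 4L))

  expect_error(facing_pairs(parse_sequence("AAAA")), "at least 5")

  ef2 <- hairpin_peptide("EF2")
  expect_equal(facing_pairs(ef2)[, c("i", "j")], fp[, c("i", "j")])
})

test_that("facing pairs are disjoint and sum to L for arbitrary lengths", {
  set.seed(42)
  for (L in sample(5:30, 8)) {
    s <- parse_sequence(paste(sample(c("A", "Q", "R", "D"), L, TRUE),
                              collapse = ""))
    fp <- facing_pairs(s)
    expect_true(all(fp$i + fp$j == L))
    expect_equal(anyDuplicated(c(fp$i, fp$j)), 0L)
  }
})

test_that("register hydrogen bonds reproduce the HB1..HB8 table", {
  ef1 <- hairpin_peptide("EF1")
  hb <- hbond_register(ef1)
  expect_equal(nrow(hb), 8L)
  expect_equal(anyDuplicated(hb$label), 0L)
  expect_equal(hb$label, paste0("HB", 1:8))
  # HB1: TYR2-NH ... OC-ASP17
  expect_equal(hb$donor_residue[hb$label == "HB1"], 2L)
  expect_equal(hb$acceptor_residue[hb$label == "HB1"], 17L)
  expect_equal(hb$donor_name[hb$label == "HB1"], "TYR")
  expect_equal(hb$acceptor_name[hb$label == "HB1"], "ASP")
  # HB4: THR4-CO ... HN-MET15 (donor 15, acceptor 4)
  expect_equal(hb$donor_residue[hb$label == "HB4"], 15L)
  expect_equal(hb$acceptor_residue[hb$label == "HB4"], 4L)
  expect_equal(hb$donor_name[hb$label == "HB4"], "MET")
  # two bonds per even register pair
  for (i in c(2L, 4L, 6L, 8L)) {
    j <- 19L - i
    sub <- hb[(hb$donor_residue == i & hb$acceptor_residue == j) |
                (hb$donor_residue == j & hb$acceptor_residue == i), ]
    expect_equal(nrow(sub), 2L)
  }
  # EF2: HB7 = ARG8-NH...OC-PHE11, HB8 = reverse direction
  ef2 <- hairpin_peptide("EF2")
  hb2 <- hbond_register(ef2)
  expect_equal(hb2$donor_residue[hb2$label == "HB7"], 8L)
  expect_equal(hb2$acceptor_residue[hb2$label == "HB7"], 11L)
  expect_equal(hb2$donor_name[hb2$label == "HB7"], "ARG")
  expect_equal(hb2$donor_residue[hb2$label == "HB8"], 11L)
  expect_equal(hb2$acceptor_residue[hb2$label == "HB8"], 8L)
})

test_that("hydrophobic and ionic pair identification matches the census", {
  ef1 <- hairpin_peptide("EF1")
  ph1 <- hydrophobic_pairs(ef1)
  expect_equal(nrow(ph1), 3L)
  expect_equal(ph1$i, c(3L, 5L, 7L))
  expect_equal(ph1$j, c(16L, 14L, 12L))

  ef2 <- hairpin_peptide("EF2")
  expect_equal(nrow(hydrophobic_pairs(ef2)), 2L)

  allq <- parse_sequence(strrep("Q", 19))
  expect_equal(nrow(hydrophobic_pairs(allq)), 0L)

  ion1 <- ionic_pairs(ef1)
  expect_equal(nrow(ion1), 1L)
  expect_equal(c(ion1$i, ion1$j), c(9L, 11L))
  expect_equal(c(ion1$residue_i, ion1$residue_j), c("E", "R"))
  expect_equal(nrow(ionic_pairs(ef2)), 0L)
  expect_equal(nrow(ionic_pairs(parse_sequence(strrep("A", 19)))), 0L)
})

test_that("non-covalent census totals separate the two peptides", {
  c1 <- noncovalent_census(hairpin_peptide("EF1"))
  expect_equal(c1$n_hbond_registers, 4L)
  expect_equal(c1$n_hydrophobic, 3L)
  expect_equal(c1$n_ionic, 1L)
  expect_equal(c1$total, 8L)

  c2 <- noncovalent_census(hairpin_peptide("EF2"))
  expect_equal(c2$n_hydrophobic, 2L)
  expect_equal(c2$n_ionic, 0L)
  expect_equal(c2$total, 6L)

  cg <- noncovalent_census(parse_sequence(strrep("G", 19)))
  expect_equal(cg$total, 8L)  # 4 register + 4 all-non-polar odd pairs

  # determinism under re-parse
  again <- noncovalent_census(parse_sequence("DYATLQLQEGRLHFMFDLG"))
  expect_equal(again$total, c1$total)
  tab <- census_table(c1)
  expect_equal(nrow(tab), 8L)
  expect_named(tab, c("pair_i", "pair_j", "kind", "residue_i", "residue_j"))
})
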