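test_that("degen1 fixes the canonical codon family recodings", {
  # single-codon amino acids are invariant
  expect_equal(degen1_codon("ATG"), "ATG")
  expect_equal(degen1_codon("TGG"), "TGG")
  # merged leucine and arginine families; split serine families
  expect_equal(degen1_codon("CTG"), "YTN")
  expect_equal(degen1_codon("TTA"), "YTN")
  expect_equal(degen1_codon("AGA"), "MGN")
  expect_equal(degen1_codon("CGC"), "MGN")
  expect_equal(degen1_codon("TCT"), "TCN")
  expect_equal(degen1_codon("AGC"), "AGY")
  # missing positions degenerate to N; stops flagged
  expect_equal(degen1_codon("AT?"), "ATN")
  expect_equal(degen1_codon("???"), "NNN")
  expect_warning(out <- degen1_codon("TAA"), "stop codon")
  expect_equal(out, "NNN")
  expect_error(degen1_codon("AT"), "3 characters")
})

test_that("degen1 equals the synonymous-connectivity oracle on all codons", {
  oracle <- oracle_degen1_map()
  tab <- degen1_table()
  got <- stats::setNames(tab$degen1, tab$codon)
  for (cod in names(oracle)) {
    expect_equal(unname(got[cod]), unname(oracle[cod]), label = cod)
  }
  # stops map to NNN
  for (cod in c("TAA", "TAG", "TGA")) {
    expect_equal(unname(got[cod]), "NNN")
  }
  # 21 synonymous families (serine splits; leucine and arginine merge),
  # each with a distinct cover triplet
  expect_equal(length(unique(oracle)), 21)
})

test_that("synonymous neighbors recode identically and translation is preserved", {
  sense <- names(oracle_code)[oracle_code != "*"]
  for (c1 in sense) {
    d1 <- degen1_codon(c1)
    for (c2 in sense) {
      if (sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]]) == 1 &&
          oracle_code[c1] == oracle_code[c2]) {
        expect_equal(d1, degen1_codon(c2), label = paste(c1, c2))
      }
    }
    # translation commutes with degen1 (family covers translate to their
    # family's amino acid; both serine families stay serine)
    expect_equal(degenphy:::translate_codons(d1),
                 unname(oracle_code[c1]), label = c1)
  }
})

test_that("degen1 recoding of matrices is idempotent and shape-preserving", {
  g <- random_gene(n_taxa = 6, n_codons = 40, seed = 11)
  g$seq[1, 7:12] <- "?"
  g$seq[4, 1] <- "R"
  sm <- concatenate_genes(list(g))
  r1 <- degen1_recode(sm)
  expect_equal(dim(r1$matrix), dim(sm$matrix))
  sm2 <- supermatrix(r1$matrix, sm$charsets, "degen1")
  r2 <- degen1_recode(sm2)
  expect_identical(r2$matrix, r1$matrix)
})

test_that("degen1 removes synonymous divergence entirely", {
  # build two sequences differing only by chains of single-site synonymous
  # substitutions (stay within the synonymous-connectivity family; a
  # serine TCN codon can never reach AGY synonymously)
  fam_map <- oracle_degen1_map()
  withr::with_seed(7, {
    sense <- names(oracle_code)[oracle_code != "*"]
    c1 <- sample(sense, 200, replace = TRUE)
    c2 <- vapply(c1, function(cod) {
      syn <- sense[fam_map[sense] == fam_map[cod]]
      sample(rep(syn, 2), 1)
    }, character(1))
  })
  m <- rbind(a = unlist(strsplit(c1, "")), b = unlist(strsplit(c2, "")))
  sm <- supermatrix(m)
  rec <- degen1_recode(sm)
  expect_equal(sum(rec$matrix["a", ] != rec$matrix["b", ]), 0)
})

test_that("first-position Leu/Arg classification follows the rule", {
  expect_equal(classify_nt1("TTA"), "LRall1")
  expect_equal(classify_nt1("CGC"), "LRall1")
  expect_equal(classify_nt1("ATG"), "noLRall1")
  expect_equal(classify_nt1("N??"), "unassigned")
  expect_equal(classify_nt1("TAA"), "unassigned")
  # exhaustively: LRall1 iff the amino acid is Leu or Arg
  sense <- names(oracle_code)[oracle_code != "*"]
  for (cod in sense) {
    want <- if (oracle_code[cod] %in% c("L", "R")) "LRall1" else "noLRall1"
    expect_equal(classify_nt1(cod), want, label = cod)
  }
})

test_that("treatment extraction keeps the column bookkeeping", {
  g <- random_gene(n_taxa = 5, n_codons = 30, seed = 3)
  sm <- concatenate_genes(list(g))
  nt1 <- extract_treatment(sm, "nt1")
  nt2 <- extract_treatment(sm, "nt2")
  nt3 <- extract_treatment(sm, "nt3")
  expect_equal(ncol(nt1$matrix), 30)
  expect_equal(ncol(nt2$matrix), 30)
  expect_equal(ncol(nt3$matrix), 30)
  expect_identical(extract_treatment(sm, "nt123")$matrix, sm$matrix)

  # the partition halves split each first-position cell exactly once
  p1 <- extract_treatment(sm, "noLRall1_nt2")
  p2 <- extract_treatment(sm, "LRall1_nt3")
  in1 <- p1$matrix[, 1:30] != "?"
  in2 <- p2$matrix[, 1:30] != "?"
  expect_true(all(xor(in1, in2)))
  # and carry all nt2 / nt3 columns respectively
  expect_identical(p1$matrix[, 31:60], nt2$matrix)
  expect_identical(p2$matrix[, 31:60], nt3$matrix)
})

test_that("matrices without Leu/Arg put all first positions in noLRall1", {
  m <- rbind(a = strsplit("ATGGGGATG", "")[[1]],
             b = strsplit("GGGATGGGG", "")[[1]])
  sm <- supermatrix(m)
  p1 <- extract_treatment(sm, "noLRall1_nt2")
  p2 <- extract_treatment(sm, "LRall1_nt3")
  expect_true(all(p1$matrix[, 1:3] != "?"))
  expect_true(all(p2$matrix[, 1:3] == "?"))
})

test_that("amino-acid extraction translates and marks unknowns", {
  m <- rbind(a = strsplit("ATGAAA", "")[[1]],
             b = strsplit("NNNAAA", "")[[1]])
  sm <- supermatrix(m)
  aa <- extract_treatment(sm, "aa")
  expect_equal(paste(aa$matrix["a", ], collapse = ""), "MK")
  expect_equal(paste(aa$matrix["b", ], collapse = ""), "XK")

  # translation commutes with degen1 on unambiguous matrices
  g <- random_gene(n_taxa = 4, n_codons = 25, seed = 21)
  sm2 <- concatenate_genes(list(g))
  aa_direct <- extract_treatment(sm2, "aa")$matrix
  deg <- degen1_recode(sm2)
  aa_deg <- extract_treatment(
    supermatrix(deg$matrix, sm2$charsets), "aa"
  )$matrix
  expect_identical(aa_deg, aa_direct)
})
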