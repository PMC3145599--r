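test_that("FASTA parsing enforces the alignment contract", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ATGAAA", ">s2", "ATGAAG"), f)
  aln <- read_gene_alignment(f, "fasta")
  expect_equal(nrow(aln$seq), 2)
  expect_equal(ncol(aln$seq), 6)
  expect_equal(rownames(aln$seq), c("s1", "s2"))

  writeLines(c(">s1", "ATGAAA", ">s2", "ATGAA"), f)
  expect_error(read_gene_alignment(f, "fasta"), "differ in length")

  writeLines(c(">s1", "ATGAAA", ">s1", "ATGAAG"), f)
  expect_error(read_gene_alignment(f, "fasta"), "duplicate")

  writeLines(c(">s1", "ATGAAJ", ">s2", "ATGAAG"), f)
  expect_error(read_gene_alignment(f, "fasta"), "'J'")
})

test_that("alignments round-trip through all three formats", {
  g <- random_gene(n_taxa = 5, n_codons = 20, seed = 42)
  g$seq[2, 4:9] <- "?"
  g$seq[3, 10] <- "-"
  for (fmt in c("fasta", "phylip", "nexus")) {
    f <- withr::local_tempfile()
    write_gene_alignment(g, f, fmt)
    back <- read_gene_alignment(f, fmt, gene = g$gene)
    expect_identical(back$seq, g$seq, label = fmt)
  }
})

test_that("reading-frame validation finds stops and frame defects", {
  aln <- gene_alignment(c(a = "ATGTAAGGG", b = "ATGAAAGGG"))
  rep <- validate_reading_frame(aln)
  expect_true(rep$frame_ok)
  expect_equal(rep$stops$a, 1L)
  expect_equal(length(rep$stops$b), 0L)

  aln5 <- gene_alignment(c(a = "ATGAA"))
  expect_false(validate_reading_frame(aln5)$frame_ok)

  # ambiguous codons that cannot be resolved are skipped
  alnq <- gene_alignment(c(a = "TR?TAA"))
  expect_equal(validate_reading_frame(alnq)$stops$a, 1L)
})

test_that("concatenation reproduces the multi-gene layouts", {
  # the eleven genes added to the ten-gene matrix sum to 6,375 bp
  lens11 <- c(750, 840, 402, 444, 501, 594, 705, 324, 666, 747, 402)
  genes <- lapply(seq_along(lens11), function(i) {
    gene_alignment(
      matrix("A", 2, lens11[i], dimnames = list(c("x", "y"), NULL)),
      gene = paste0("g", i)
    )
  })
  sm <- concatenate_genes(genes)
  expect_equal(ncol(sm$matrix), 6375)
  expect_equal(length(sm$charsets), 11)

  # identity for a single gene
  g1 <- random_gene(3, 5, seed = 1)
  sm1 <- concatenate_genes(list(g1))
  expect_identical(sm1$matrix, g1$seq)
  expect_equal(sm1$charsets[[g1$gene]], c(0, 15))

  # disjoint taxa produce complementary '?' blocks
  ga <- gene_alignment(c(X = "ATGAAA"), gene = "a")
  gb <- gene_alignment(c(Y = "ATGAAAGGG"), gene = "b")
  sm2 <- concatenate_genes(list(ga, gb))
  expect_equal(dim(sm2$matrix), c(2L, 15L))
  expect_equal(paste(sm2$matrix["X", ], collapse = ""),
               "ATGAAA?????????")
  expect_equal(paste(sm2$matrix["Y", ], collapse = ""),
               "??????ATGAAAGGG")

  expect_error(concatenate_genes(list()), "no gene")
  expect_error(concatenate_genes(list(ga, ga)), "duplicate gene")
})

test_that("per-gene extraction inverts concatenation", {
  genes <- lapply(1:4, function(i) {
    random_gene(n_taxa = 3, n_codons = 3 + i, gene = paste0("g", i),
                seed = i)
  })
  sm <- concatenate_genes(genes)
  for (g in genes) {
    expect_identical(extract_gene(sm, g$gene)$seq, g$seq)
  }
  expect_equal(
    sum(vapply(sm$charsets, function(iv) iv[2] - iv[1], numeric(1))),
    ncol(sm$matrix)
  )
})

test_that("sampling designs mask taxon-by-gene blocks", {
  ga <- gene_alignment(
    matrix("A", 4, 6, dimnames = list(paste0("t", 1:4), NULL)), gene = "a"
  )
  gb <- gene_alignment(
    matrix("C", 4, 9, dimnames = list(paste0("t", 1:4), NULL)), gene = "b"
  )
  sm <- concatenate_genes(list(ga, gb))

  full <- design_spec("full", paste0("t", 1:4))
  expect_identical(apply_design(sm, full)$matrix, sm$matrix)

  d <- design_spec("blk", paste0("t", 1:4),
                   gene_coverage = list(t3 = "a", t4 = "a"))
  masked <- apply_design(sm, d)
  expect_true(all(masked$matrix[c("t3", "t4"), 7:15] == "?"))
  expect_true(all(masked$matrix[c("t1", "t2"), 7:15] == "C"))
  expect_equal(missing_fraction(masked), 18 / 60)

  drop <- design_spec("drop", paste0("t", 1:3))
  expect_false("t4" %in% rownames(apply_design(sm, drop)$matrix))

  expect_error(apply_design(sm, design_spec("bad", "t9")), "unknown taxa")
  expect_error(
    apply_design(sm, design_spec("bad", "t1",
                                 gene_coverage = list(t1 = "zz"))),
    "unknown genes"
  )
  expect_error(design_spec("bad", "t1", gene_coverage = list(t1 = character(0))),
               "no covered gene")
})

test_that("missing_fraction counts '?' and optionally gaps", {
  m <- matrix("A", 2, 4, dimnames = list(c("a", "b"), NULL))
  expect_equal(missing_fraction(supermatrix(m)), 0)
  m[1, 1] <- "?"
  m[2, 2] <- "-"
  sm <- supermatrix(m)
  expect_equal(missing_fraction(sm), 1 / 8)
  expect_equal(missing_fraction(sm, include_gaps = TRUE), 2 / 8)
  mq <- matrix("?", 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_equal(missing_fraction(supermatrix(mq)), 1)
})

test_that("masking is monotone in missing fraction", {
  genes <- lapply(1:3, function(i) {
    random_gene(n_taxa = 5, n_codons = 4, gene = paste0("g", i), seed = i)
  })
  sm <- concatenate_genes(genes)
  taxa <- rownames(sm$matrix)
  base <- missing_fraction(sm)
  withr::with_seed(9, {
    for (k in 1:5) {
      cov <- stats::setNames(lapply(taxa, function(tx) {
        sample(names(sm$charsets), sample(1:3, 1))
      }), taxa)
      d <- design_spec(paste0("d", k), taxa, cov)
      expect_gte(missing_fraction(apply_design(sm, d)), base)
    }
  })
})

test_that("supermatrix NEXUS round-trip preserves matrix and charsets", {
  genes <- lapply(1:3, function(i) {
    random_gene(n_taxa = 4, n_codons = 3 + i, gene = paste0("g", i),
                seed = 10 + i)
  })
  sm <- concatenate_genes(genes)
  sm$matrix[2, 5] <- "?"
  f <- withr::local_tempfile(fileext = ".nex")
  write_supermatrix(sm, f, "nexus")
  back <- read_supermatrix(f, "nexus")
  expect_identical(back$matrix, sm$matrix)
  expect_identical(back$charsets, lapply(sm$charsets, as.integer))
  # 1-based inclusive rendering of a half-open interval
  expect_true(any(grepl("charset g1 = 1-12;", readLines(f))))
})
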