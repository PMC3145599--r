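test_that("neighbor-joining inverts the additive four-taxon example", {
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  expect_true(has_clade(tr, c("A", "B")))
  cd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(cd, d, tolerance = 1e-12)
  # exact branch lengths A:1 B:2 internal:1 C:3 D:4
  lens <- sort(tr$edge.length)
  expect_equal(lens, c(1, 1, 2, 3, 4), tolerance = 1e-12)
})

test_that("three taxa give the closed-form star", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_equal(ape::Ntip(tr), 3)
  # three-point formulas: a = (2+3-4)/2, b = (2+4-3)/2, c = (3+4-2)/2
  got <- tr$edge.length[match(1:3, tr$edge[, 2])]
  expect_equal(got[match("a", tr$tip.label)], 0.5)
  expect_equal(got[match("b", tr$tip.label)], 1.5)
  expect_equal(got[match("c", tr$tip.label)], 2.5)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("tree-derived distances are inverted exactly over random trees", {
  withr::with_seed(100, {
    for (k in 1:20) {
      tr <- ape::rtree(8)
      d <- ape::cophenetic.phylo(tr)
      est <- neighbor_joining(d)
      expect_equal(rf_distance(est, tr), 0)
      cd <- ape::cophenetic.phylo(est)[rownames(d), colnames(d)]
      expect_lt(max(abs(cd - d)), 1e-9)
    }
  })
})

test_that("neighbor-joining agrees with the reference implementation", {
  withr::with_seed(41, {
    n <- 10
    x <- matrix(runif(n * n), n, n)
    d <- (x + t(x)) / 2
    diag(d) <- 0
    d <- d + 2  # metric-ish noise matrix
    diag(d) <- 0
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
  })
  expect_equal(rf_distance(neighbor_joining(d), ape::nj(as.dist(d))), 0)
})

test_that("Robinson-Foulds distance counts bipartition differences", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)
  expect_equal(rf_distance(t2, t1), 2)
  t3 <- ape::read.tree(text = "((a,b),(c,e));")
  expect_error(rf_distance(t1, t3), "taxon sets")
  skip_if_not_installed("phangorn")
  withr::with_seed(17, {
    for (k in 1:10) {
      a <- ape::rtree(9)
      b <- ape::rtree(9)
      b$tip.label <- sample(a$tip.label)
      expect_equal(rf_distance(a, b), phangorn::RF.dist(a, b))
    }
  })
})

test_that("bootstrap resampling is reproducible and preserves width", {
  g <- random_gene(4, 20, seed = 5)
  r1 <- bootstrap_resample(g$seq, n = 3, unit = "site", seed = 99)
  r2 <- bootstrap_resample(g$seq, n = 3, unit = "site", seed = 99)
  expect_identical(r1, r2)
  expect_equal(ncol(r1[[1]]), ncol(g$seq))

  rc <- bootstrap_resample(g$seq, n = 2, unit = "codon", seed = 1)[[1]]
  expect_equal(ncol(rc), ncol(g$seq))
  # codon resampling keeps triplets intact
  cods <- degenphy:::codon_matrix(rc)
  src <- degenphy:::codon_matrix(g$seq)
  expect_true(all(cods %in% as.vector(src)))

  expect_error(
    bootstrap_resample(g$seq[, 1:19, drop = FALSE], n = 1, unit = "codon"),
    "divisible by 3"
  )
})

test_that("site resampling draws columns uniformly", {
  # 40 distinct columns (base-4 encoding over 3 rows); tally which source
  # column each resampled column came from across 250 replicates
  nts <- c("A", "C", "G", "T")
  enc <- sapply(0:39, function(j) {
    nts[1 + c(j %% 4, (j %/% 4) %% 4, (j %/% 16) %% 4)]
  })
  rownames(enc) <- c("r1", "r2", "r3")
  reps <- bootstrap_resample(enc, n = 250, unit = "site", seed = 12345)
  keys <- apply(enc, 2, paste, collapse = "")
  drawn <- unlist(lapply(reps, function(r) {
    match(apply(r, 2, paste, collapse = ""), keys)
  }))
  expect_equal(length(drawn), 250 * 40)
  gof <- suppressWarnings(
    stats::chisq.test(table(factor(drawn, levels = 1:40)))
  )
  expect_gt(gof$p.value, 0.01)
})

test_that("bootstrap support counts matching bipartitions", {
  ref <- ape::read.tree(text = "((a,b),((c,d),e));")
  reps_same <- replicate(4, ref, simplify = FALSE)
  s1 <- support_from_replicates(ref, reps_same)
  labs <- suppressWarnings(as.numeric(s1$node.label))
  expect_true(all(labs[!is.na(labs)] == 100))

  # a bipartition present in 3 of 4 replicates reports 75
  alt <- ape::read.tree(text = "((a,c),((b,d),e));")
  s2 <- support_from_replicates(ref, c(replicate(3, ref, simplify = FALSE),
                                       list(alt)))
  cd_support <- clade_support(s2, c("c", "d"))
  ab_support <- clade_support(s2, c("a", "b"))
  expect_equal(cd_support, 75)
  expect_equal(ab_support, 75)

  # a reference edge absent from every replicate reports 0
  s3 <- support_from_replicates(ref, replicate(3, alt, simplify = FALSE))
  expect_equal(clade_support(s3, c("a", "b")), 0)

  bad <- ape::read.tree(text = "((a,b),(c,x));")
  expect_error(support_from_replicates(ref, list(bad)), "taxon set")

  # the majority-rule consensus keeps exactly the >50% bipartitions
  cons <- majority_consensus(c(replicate(3, ref, simplify = FALSE),
                               list(alt)))
  expect_true(has_clade(cons, c("c", "d")))
  expect_true(has_clade(cons, c("a", "b")))
})

test_that("support is invariant to replicate order and taxon relabeling", {
  withr::with_seed(8, {
    ref <- ape::rtree(7)
    reps <- replicate(6, ape::rtree(7), simplify = FALSE)
    reps <- lapply(reps, function(t) {
      t$tip.label <- sample(ref$tip.label)
      t
    })
  })
  s_fwd <- support_from_replicates(ref, reps)
  s_rev <- support_from_replicates(ref, rev(reps))
  expect_identical(s_fwd$node.label, s_rev$node.label)

  # relabel all taxa consistently: support values travel with the clades
  perm <- stats::setNames(paste0("x", seq_along(ref$tip.label)),
                          ref$tip.label)
  relab <- function(t) {
    t$tip.label <- unname(perm[t$tip.label])
    t
  }
  s_perm <- support_from_replicates(relab(ref), lapply(reps, relab))
  pp <- ape::prop.part(ref)
  labs <- attr(pp, "labels")
  for (k in seq_along(pp)) {
    clade <- labs[pp[[k]]]
    if (length(clade) < 2 || length(clade) > 5) next
    expect_equal(clade_support(s_perm, unname(perm[clade])),
                 clade_support(s_fwd, clade))
  }
})

test_that("design/treatment support tables follow the reporting rules", {
  ref <- ape::read.tree(text = "((a,b),((c,d),e));")
  alt <- ape::read.tree(text = "((a,c),((b,d),e));")
  tr <- support_from_replicates(ref, c(replicate(3, ref, simplify = FALSE),
                                       list(alt)))
  report <- compare_designs(
    list("D/degen1" = tr),
    list(cd = c("c", "d"), ab = c("a", "b"), off_design = c("a", "zz"),
         absent = c("a", "d"))
  )
  expect_equal(report$clade, c("cd", "ab", "off_design", "absent"))
  expect_equal(report[["D/degen1"]], c("75", "75", "N/A", "<50"))
})
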