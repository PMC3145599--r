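test_that("two-taxon site likelihoods match closed forms", {
  mod <- gtr_model()
  tr0 <- ape::read.tree(text = "(a:0,b:0);")
  m <- rbind(a = "A", b = "A")
  expect_equal(exp(site_loglikelihoods(tr0, m, mod)[1]), 0.25,
               tolerance = 1e-12)
  # at large distance the joint probability approaches pi_i * pi_j
  tr_far <- ape::read.tree(text = "(a:25,b:25);")
  expect_equal(exp(site_loglikelihoods(tr_far, m, mod)[1]), 0.0625,
               tolerance = 1e-6)
  m2 <- rbind(a = "A", b = "T")
  expect_equal(exp(site_loglikelihoods(tr_far, m2, mod)[1]), 0.0625,
               tolerance = 1e-6)
})

test_that("pruning equals exhaustive enumeration on small fixtures", {
  withr::with_seed(2, {
    tr4 <- ape::rtree(4)
    m4 <- matrix(sample(c("A", "C", "G", "T", "R", "-", "?"), 40,
                        replace = TRUE),
                 4, 10, dimnames = list(tr4$tip.label, NULL))
    tr5 <- ape::rtree(5)
    m5 <- matrix(sample(c("A", "C", "G", "T", "Y", "N"), 50,
                        replace = TRUE),
                 5, 10, dimnames = list(tr5$tip.label, NULL))
  })
  models <- list(
    gtr_model(),
    gtr_model(pi = c(0.1, 0.2, 0.3, 0.4), rates = c(1, 2, 3, 1.5, 2.5, 1),
              alpha = 0.7, p_inv = 0.2, n_categories = 4)
  )
  for (mod in models) {
    expect_lt(
      max(abs(site_loglikelihoods(tr4, m4, mod) -
                brute_site_loglik(tr4, m4, mod))),
      1e-10
    )
    expect_lt(
      max(abs(site_loglikelihoods(tr5, m5, mod) -
                brute_site_loglik(tr5, m5, mod))),
      1e-10
    )
  }
})

test_that("likelihood is invariant to rerooting and child order", {
  withr::with_seed(6, {
    tr <- ape::rtree(6)
    m <- matrix(sample(c("A", "C", "G", "T"), 6 * 30, replace = TRUE),
                6, 30, dimnames = list(tr$tip.label, NULL))
  })
  mod <- gtr_model(pi = c(0.3, 0.2, 0.25, 0.25),
                   rates = c(1, 3, 1, 1, 3, 1), alpha = 1)
  base <- sum(site_loglikelihoods(tr, m, mod))
  un <- ape::unroot(tr)
  expect_equal(sum(site_loglikelihoods(un, m, mod)), base,
               tolerance = 1e-8)
  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  expect_equal(sum(site_loglikelihoods(rot, m, mod)), base,
               tolerance = 1e-8)
  re <- ape::root(un, outgroup = tr$tip.label[3], resolve.root = TRUE)
  expect_equal(sum(site_loglikelihoods(re, m, mod)), base,
               tolerance = 1e-8)
})

test_that("one category and zero p_inv reduce to plain GTR", {
  withr::with_seed(13, {
    tr <- ape::rtree(5)
    m <- matrix(sample(c("A", "C", "G", "T"), 5 * 40, replace = TRUE),
                5, 40, dimnames = list(tr$tip.label, NULL))
  })
  plain <- gtr_model(pi = c(0.3, 0.2, 0.2, 0.3), rates = c(1, 2, 1, 1, 2, 1))
  red <- gtr_model(pi = c(0.3, 0.2, 0.2, 0.3), rates = c(1, 2, 1, 1, 2, 1),
                   alpha = 5, p_inv = 0, n_categories = 1)
  expect_equal(site_loglikelihoods(tr, m, red),
               site_loglikelihoods(tr, m, plain), tolerance = 1e-12)
})

test_that("plain GTR site likelihoods agree with phangorn", {
  skip_if_not_installed("phangorn")
  tr <- ape::read.tree(text = "((a:0.1,b:0.15):0.08,(c:0.12,d:0.2):0.05,e:0.3);")
  dat <- withr::with_seed(1, {
    phangorn::simSeq(tr, l = 500, Q = c(1, 2, 1.5, 1.2, 3, 1),
                     bf = c(0.3, 0.2, 0.2, 0.3))
  })
  m <- toupper(as.character(dat))
  rownames(m) <- names(dat)
  mod <- gtr_model(pi = c(0.3, 0.2, 0.2, 0.3), rates = c(1, 2, 1.5, 1.2, 3, 1))
  fit <- phangorn::pml(tr, phangorn::phyDat(as.character(dat)),
                       bf = c(0.3, 0.2, 0.2, 0.3),
                       Q = c(1, 2, 1.5, 1.2, 3, 1), k = 1)
  expect_equal(sum(site_loglikelihoods(tr, m, mod)), fit$logLik,
               tolerance = 1e-6)
})

test_that("branch-length optimization ascends to a fixed point", {
  skip_if_not_installed("phangorn")
  tr <- ape::read.tree(text = "((a:0.1,b:0.15):0.08,(c:0.12,d:0.2):0.05,e:0.3);")
  dat <- withr::with_seed(22, {
    phangorn::simSeq(tr, l = 40000, Q = rep(1, 6), bf = rep(0.25, 4))
  })
  m <- toupper(as.character(dat))
  rownames(m) <- names(dat)
  mod <- gtr_model()
  start <- tr
  start$edge.length <- rep(0.05, nrow(tr$edge))
  ll0 <- tree_loglik(start, m, mod)
  opt <- optimize_branch_lengths(start, m, mod)
  expect_gte(attr(opt, "logLik"), ll0)
  expect_equal(attr(opt, "logLik"), tree_loglik(opt, m, mod),
               tolerance = 1e-9)
  # optimizing again changes nothing beyond tolerance
  opt2 <- optimize_branch_lengths(opt, m, mod)
  expect_lt(abs(attr(opt2, "logLik") - attr(opt, "logLik")), 1e-4)
  # branch-length recovery on long sequences (match edges by the tip sets
  # below them)
  key <- function(t) {
    vapply(seq_len(nrow(t$edge)), function(e) {
      tips <- if (t$edge[e, 2] <= ape::Ntip(t)) {
        t$tip.label[t$edge[e, 2]]
      } else {
        sort(ape::extract.clade(t, t$edge[e, 2])$tip.label)
      }
      paste(tips, collapse = "+")
    }, character(1))
  }
  true_len <- stats::setNames(tr$edge.length, key(tr))
  est_len <- stats::setNames(opt$edge.length, key(opt))
  shared <- intersect(names(true_len), names(est_len))
  expect_gt(length(shared), 5)
  expect_true(all(abs(est_len[shared] / true_len[shared] - 1) < 0.1))
})
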