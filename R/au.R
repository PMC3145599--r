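# RELL multiscale bootstrap and the approximately unbiased (AU) topology
# test: resampled site log-likelihoods at several scale factors, a
# probit-scale weighted least-squares fit of signed distance and curvature,
# and the AU p-value for each candidate tree.

#' Build a site log-likelihood matrix for candidate trees
#'
#' Optimizes branch lengths of each candidate on the data and records
#' per-site log-likelihoods (trees x sites). Identical topologies are
#' deduplicated before scoring.
#'
#' @param trees List of \code{phylo} candidate topologies.
#' @param m Matrix-like nucleotide object.
#' @param model A \code{gtr_model}.
#' @param optimize Optimize branch lengths first (default TRUE).
#' @return Matrix (trees x sites) with attribute \code{trees} (the scored
#'   trees, branch lengths optimized) and \code{logLik} per tree.
#' @export
site_loglik_matrix <- function(trees, m, model, optimize = TRUE) {
  if (length(trees) == 0) stop_input("empty tree set")
  # deduplicate identical topologies
  keep <- integer(0)
  for (k in seq_along(trees)) {
    dup <- any(vapply(keep, function(j) {
      rf_distance(trees[[j]], trees[[k]]) == 0
    }, logical(1)))
    if (!dup) keep <- c(keep, k)
  }
  trees <- trees[keep]
  scored <- vector("list", length(trees))
  L <- NULL
  w <- NULL
  for (k in seq_along(trees)) {
    tr <- trees[[k]]
    if (optimize) tr <- optimize_branch_lengths(tr, m, model)
    s <- site_loglikelihoods(tr, m, model)
    pat <- attr(s, "patterns")
    if (is.null(L)) {
      L <- matrix(0, length(trees), length(pat))
      w <- attr(s, "weights")
    }
    L[k, ] <- pat
    scored[[k]] <- tr
  }
  rownames(L) <- paste0("tree", seq_along(trees))
  attr(L, "weights") <- w
  attr(L, "trees") <- scored
  attr(L, "logLik") <- as.vector(L %*% w)
  L
}

#' Multiscale RELL bootstrap proportions
#'
#' For each scale factor r, draws round(r x n_sites) sites with replacement,
#' sums per-tree site log-likelihoods, and records the fraction of
#' replicates in which each tree attains the maximum (ties split equally).
#'
#' @param L Site log-likelihood matrix (trees x sites), or with a
#'   \code{weights} attribute for compressed patterns.
#' @param scales Positive scale factors (default 0.5 to 1.4 by 0.1).
#' @param reps Replicates per scale.
#' @param seed Integer seed (reproducible; caller's RNG untouched).
#' @return Matrix of bootstrap proportions (trees x scales), attributes
#'   \code{scales} and \code{reps}.
#' @export
rell_bootstrap <- function(L, scales = seq(0.5, 1.4, by = 0.1),
                           reps = 10000L, seed = 1L) {
  if (is.null(dim(L)) || nrow(L) < 1) stop_input("empty tree set")
  if (reps < 1) stop_input("reps must be >= 1")
  if (any(scales <= 0)) stop_input("scales must be positive")
  w <- attr(L, "weights")
  n_sites <- if (is.null(w)) ncol(L) else sum(w)
  prob <- if (is.null(w)) rep(1 / ncol(L), ncol(L)) else w / sum(w)
  ntree <- nrow(L)
  bp <- matrix(0, ntree, length(scales),
               dimnames = list(rownames(L), paste0("r", scales)))
  with_seed(seed, {
    for (s in seq_along(scales)) {
      nr <- max(1L, round(scales[s] * n_sites))
      counts <- stats::rmultinom(reps, nr, prob)
      scores <- L %*% counts  # trees x reps
      mx <- apply(scores, 2, max)
      winners <- sweep(scores, 2, mx, ">=")
      share <- sweep(winners, 2, colSums(winners), "/")
      bp[, s] <- rowMeans(share)
    }
  })
  attr(bp, "scales") <- scales
  attr(bp, "reps") <- reps
  bp
}

#' Approximately unbiased (AU) test from multiscale bootstrap proportions
#'
#' Fits, per tree, the probit-transformed proportions to the signed
#' distance / curvature model z(r) = d sqrt(r) + c / sqrt(r) by weighted
#' least squares across scales, and reports p_au = P(Z > d - c). Scales
#' with proportions exactly 0 or 1 are excluded from the fit; when fewer
#' than two scales remain the degenerate path returns p = 0 (tree never
#' wins) or p = 1 (tree always wins).
#'
#' @param bp Proportions matrix from \code{\link{rell_bootstrap}}.
#' @param scales Scale factors (default from \code{bp}).
#' @param reps Replicates per scale (default from \code{bp}).
#' @return Data frame with one row per tree: \code{tree}, \code{d},
#'   \code{c}, \code{p_au}, \code{bp1} (proportion nearest scale 1),
#'   \code{degenerate}, \code{rss} (weighted fit residual).
#' @export
au_test <- function(bp, scales = attr(bp, "scales"),
                    reps = attr(bp, "reps")) {
  if (is.null(scales)) stop_input("scale factors unknown")
  if (is.null(reps)) reps <- 10000L
  s1 <- which.min(abs(scales - 1))
  out <- data.frame(
    tree = rownames(bp), d = NA_real_, c = NA_real_, p_au = NA_real_,
    bp1 = bp[, s1], degenerate = FALSE, rss = NA_real_,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(nrow(bp))) {
    p <- bp[k, ]
    usable <- p > 0 & p < 1
    if (sum(usable) < 2) {
      out$degenerate[k] <- TRUE
      out$p_au[k] <- if (mean(p) >= 0.5) 1 else 0
      next
    }
    r <- scales[usable]
    pu <- p[usable]
    z <- stats::qnorm(1 - pu)
    # delta-method weights for the probit transform
    varz <- pu * (1 - pu) / (reps * stats::dnorm(z)^2)
    X <- cbind(sqrt(r), 1 / sqrt(r))
    fit <- stats::lm.wfit(X, z, w = 1 / varz)
    d <- fit$coefficients[1]
    cc <- fit$coefficients[2]
    if (anyNA(c(d, cc))) {
      out$degenerate[k] <- TRUE
      out$p_au[k] <- if (mean(p) >= 0.5) 1 else 0
      next
    }
    out$d[k] <- d
    out$c[k] <- cc
    out$p_au[k] <- stats::pnorm(d - cc, lower.tail = FALSE)
    out$rss[k] <- sum(fit$residuals^2 / varz)
  }
  out
}

#' Run the AU test on a set of candidate trees
#'
#' Convenience wrapper: scores candidates (\code{\link{site_loglik_matrix}}),
#' runs the multiscale RELL bootstrap and the AU fit.
#'
#' @inheritParams site_loglik_matrix
#' @inheritParams rell_bootstrap
#' @return The \code{\link{au_test}} data frame with an extra
#'   \code{logLik} column; attribute \code{trees} carries the scored trees.
#' @export
au_test_trees <- function(trees, m, model,
                          scales = seq(0.5, 1.4, by = 0.1),
                          reps = 10000L, seed = 1L) {
  L <- site_loglik_matrix(trees, m, model)
  bp <- rell_bootstrap(L, scales = scales, reps = reps, seed = seed)
  res <- au_test(bp)
  res$logLik <- attr(L, "logLik")
  attr(res, "trees") <- attr(L, "trees")
  res
}

#' One-step NNI neighborhood candidate topologies
#'
#' The NJ tree for a distance matrix plus all of its one-step
#' nearest-neighbor-interchange rearrangements, deduplicated.
#'
#' @param d Distance matrix.
#' @return List of \code{phylo} topologies (first = the NJ tree).
#' @export
candidate_topologies <- function(d) {
  base <- neighbor_joining(d)
  nbs <- nni_neighbors(base)
  out <- list(base)
  for (tr in nbs) {
    if (all(vapply(out, function(x) rf_distance(x, tr) > 0, logical(1)))) {
      out[[length(out) + 1L]] <- tr
    }
  }
  out
}

# All one-step NNI rearrangements of an unrooted binary tree.
nni_neighbors <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  E <- tree$edge
  internal <- which(E[, 2] > n)
  out <- list()
  for (e in internal) {
    for (swap in 1:2) {
      tr2 <- one_nni(tree, e, swap)
      if (!is.null(tr2)) out[[length(out) + 1L]] <- tr2
    }
  }
  out
}

one_nni <- function(tree, e, swap) {
  n <- length(tree$tip.label)
  E <- tree$edge
  a <- E[e, 1]; b <- E[e, 2]  # internal edge a-b
  kids_b <- E[E[, 1] == b, 2]
  kids_a <- setdiff(E[E[, 1] == a, 2], b)
  if (length(kids_b) < 2 || length(kids_a) < 1) return(NULL)
  # swap one child of b with one neighbor of a
  x <- kids_a[1]
  y <- kids_b[swap]
  E2 <- E
  E2[E[, 1] == a & E[, 2] == x, 2] <- y
  E2[E[, 1] == b & E[, 2] == y, 2] <- x
  tr2 <- tree
  tr2$edge <- E2
  tr2$edge.length <- NULL
  attr(tr2, "order") <- NULL
  tr2 <- ape::read.tree(text = ape::write.tree(tr2))
  tr2
}

#' Best candidate tree under a monophyly constraint
#'
#' Filters candidates to those containing (or, with \code{exclude = TRUE},
#' lacking) the constraint bipartition, optimizes branch lengths on each
#' survivor, and returns the highest-likelihood tree.
#'
#' @param m Matrix-like nucleotide object.
#' @param model A \code{gtr_model}.
#' @param constraint Character vector of taxa required to be monophyletic.
#' @param candidates List of candidate topologies.
#' @param exclude Require the constraint to be absent instead.
#' @return The best tree (branch lengths optimized) with attribute
#'   \code{logLik}.
#' @export
constrained_best_tree <- function(m, model, constraint, candidates,
                                  exclude = FALSE) {
  if (length(candidates) == 0) stop_input("empty candidate set")
  sel <- vapply(candidates, function(tr) {
    hc <- has_clade(tr, constraint)
    if (exclude) !hc else hc
  }, logical(1))
  if (!any(sel)) {
    stop_input("no candidate satisfies the constraint")
  }
  best <- NULL
  best_ll <- -Inf
  for (tr in candidates[sel]) {
    opt <- optimize_branch_lengths(tr, m, model)
    if (attr(opt, "logLik") > best_ll) {
      best <- opt
      best_ll <- attr(opt, "logLik")
    }
  }
  best
}
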