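# Site log-likelihoods on fixed topologies under GTR+Gamma(+I) via the
# Felsenstein pruning algorithm, and coordinate-wise branch-length
# optimization.

#' Construct a GTR+Gamma(+I) substitution model
#'
#' @param pi Equilibrium frequencies over A, C, G, T (summing to 1).
#' @param rates Six exchangeabilities (order AC, AG, AT, CG, CT, GT);
#'   positive; rescaled internally so the mean rate is 1.
#' @param alpha Gamma shape for among-site rate variation
#'   (\code{Inf} = rate homogeneity).
#' @param p_inv Proportion of invariable sites in \[0, 1).
#' @param n_categories Discrete-Gamma category count (median-of-bin rates,
#'   renormalized to mean 1).
#' @return An object of class \code{gtr_model}.
#' @export
gtr_model <- function(pi = rep(0.25, 4), rates = rep(1, 6), alpha = Inf,
                      p_inv = 0, n_categories = 4L) {
  pi <- as.numeric(pi)
  if (length(pi) != 4 || any(pi <= 0) || abs(sum(pi) - 1) > 1e-8) {
    stop_input("pi must be 4 positive frequencies summing to 1")
  }
  if (length(rates) != 6 || any(rates <= 0)) {
    stop_input("need 6 positive exchangeabilities")
  }
  if (p_inv < 0 || p_inv >= 1) stop_input("p_inv must be in [0, 1)")
  if (!is.infinite(alpha) && alpha <= 0) stop_input("alpha must be > 0")
  names(pi) <- NT4
  if (is.infinite(alpha) || n_categories == 1L) {
    cat_rates <- 1
  } else {
    k <- as.integer(n_categories)
    cat_rates <- stats::qgamma((seq_len(k) - 0.5) / k, shape = alpha,
                               rate = alpha)
    cat_rates <- cat_rates / mean(cat_rates)
  }
  structure(
    list(pi = pi, rates = rates, alpha = alpha, p_inv = p_inv,
         n_categories = length(cat_rates), cat_rates = cat_rates,
         Q = gtr_rate_matrix(pi, rates)),
    class = "gtr_model"
  )
}

#' @export
print.gtr_model <- function(x, ...) {
  cat(sprintf(
    "GTR model: pi = (%s), rates = (%s), alpha = %s, p_inv = %.3g, %d cat.\n",
    paste(sprintf("%.3f", x$pi), collapse = ", "),
    paste(sprintf("%.3g", x$rates), collapse = ", "),
    if (is.infinite(x$alpha)) "Inf" else sprintf("%.3g", x$alpha),
    x$p_inv, x$n_categories
  ))
  invisible(x)
}

# Tip partial-likelihood row sets: IUPAC state memberships as 0/1.
tip_partials <- function(chars) {
  sets <- IUPAC_SETS
  vapply(chars, function(ch) {
    s <- sets[[ch]]
    if (is.null(s)) stop_input("unknown character '", ch, "'")
    as.numeric(NT4 %in% s)
  }, numeric(4))
}

# Compress alignment columns into unique site patterns.
compress_patterns <- function(m) {
  keys <- apply(m, 2, paste, collapse = "\r")
  u <- !duplicated(keys)
  idx <- match(keys, keys[u])
  list(patterns = m[, u, drop = FALSE],
       weights = as.vector(table(factor(idx, levels = seq_len(sum(u))))),
       map = idx)
}

# Pruning over one rate category; returns per-pattern log-likelihood.
prune_loglik <- function(tree, tipL, pfns, pi) {
  n <- length(tree$tip.label)
  npat <- ncol(tipL[[1]])
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode <- n + tr$Nnode
  partial <- vector("list", nnode)
  logscale <- rep(0, npat)
  for (i in seq_len(n)) partial[[i]] <- tipL[[i]]
  edges <- tr$edge
  elen <- tr$edge.length
  children <- split(seq_len(nrow(edges)), edges[, 1])
  for (nd in unique(edges[, 1])) {
    L <- matrix(1, 4, npat)
    for (e in children[[as.character(nd)]]) {
      child <- edges[e, 2]
      P <- pfns[[e]]
      L <- L * (P %*% partial[[child]])
    }
    mx <- apply(L, 2, max)
    mx[mx <= 0] <- 1
    partial[[nd]] <- sweep(L, 2, mx, "/")
    logscale <- logscale + log(mx)
  }
  root <- edges[nrow(edges), 1]
  lik <- colSums(pi * partial[[root]])
  log(lik) + logscale
}

#' Per-site log-likelihoods of an alignment on a fixed tree
#'
#' Felsenstein pruning over site patterns; discrete-Gamma rate categories
#' are averaged, invariable sites handled as the standard proportion-
#' invariable mixture. Ambiguity codes are partial state sets; \code{?},
#' \code{-} and \code{N} are fully unknown.
#'
#' @param tree \code{phylo} tree with branch lengths, tips matching the
#'   matrix rows.
#' @param m Matrix-like nucleotide object.
#' @param model A \code{gtr_model}.
#' @return Numeric vector of per-site log-likelihoods (alignment order),
#'   with attributes \code{patterns} (per-pattern values) and
#'   \code{weights}.
#' @export
site_loglikelihoods <- function(tree, m, model) {
  x <- matrix_of(m)
  if (!setequal(rownames(x), tree$tip.label)) {
    stop_input("tree taxa and matrix taxa differ")
  }
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop_input("tree needs nonnegative branch lengths")
  }
  cp <- compress_patterns(x)
  pats <- cp$patterns
  tr <- ape::reorder.phylo(tree, "postorder")
  ord <- match(tr$tip.label, rownames(pats))
  tipL <- lapply(ord, function(i) tip_partials(pats[i, ]))
  pfn <- gtr_transition_fn(model$pi, model$Q)
  npat <- ncol(pats)
  mix <- matrix(0, length(model$cat_rates), npat)
  for (k in seq_along(model$cat_rates)) {
    r <- model$cat_rates[k]
    pfns <- lapply(tr$edge.length, function(t) pfn(r * t))
    mix[k, ] <- prune_loglik(tr, tipL, pfns, model$pi)
  }
  # average categories in likelihood space, stably
  mmax <- apply(mix, 2, max)
  lik_var <- exp(sweep(mix, 2, mmax, "-"))
  ll <- mmax + log(colMeans(lik_var))
  if (model$p_inv > 0) {
    # invariable-site component: pattern compatible with a single constant
    # state s contributes pi_s (summed over compatible s)
    const_lik <- vapply(seq_len(npat), function(j) {
      memb <- vapply(pats[, j], function(ch) {
        as.numeric(NT4 %in% IUPAC_SETS[[ch]])
      }, numeric(4))
      sum(model$pi * (rowSums(memb) == nrow(pats)))
    }, numeric(1))
    ll <- log(model$p_inv * const_lik + (1 - model$p_inv) * exp(ll))
  }
  out <- ll[cp$map]
  attr(out, "patterns") <- ll
  attr(out, "weights") <- cp$weights
  out
}

#' Total log-likelihood of an alignment on a tree
#'
#' @inheritParams site_loglikelihoods
#' @return Numeric scalar.
#' @export
tree_loglik <- function(tree, m, model) {
  s <- site_loglikelihoods(tree, m, model)
  sum(attr(s, "patterns") * attr(s, "weights"))
}

# Inward (postorder) partial likelihoods per rate category, with
# per-pattern log-scaling. Returns post[[node]] (4 x npat) and
# lsc[[node]] (npat).
inward_pass <- function(tr, tipL, elen, pfn, rate) {
  n <- length(tr$tip.label)
  E <- tr$edge
  nnode <- n + tr$Nnode
  post <- vector("list", nnode)
  lsc <- vector("list", nnode)
  npat <- ncol(tipL[[1]])
  for (i in seq_len(n)) {
    post[[i]] <- tipL[[i]]
    lsc[[i]] <- rep(0, npat)
  }
  Ps <- lapply(elen, function(t) pfn(rate * t))
  for (nd in unique(E[, 1])) {
    L <- matrix(1, 4, npat)
    sc <- rep(0, npat)
    for (e in which(E[, 1] == nd)) {
      ch <- E[e, 2]
      L <- L * (Ps[[e]] %*% post[[ch]])
      sc <- sc + lsc[[ch]]
    }
    mx <- apply(L, 2, max)
    mx[mx <= 0] <- 1
    post[[nd]] <- sweep(L, 2, mx, "/")
    lsc[[nd]] <- sc + log(mx)
  }
  list(post = post, lsc = lsc, Ps = Ps)
}

# Outward pass: for each edge e = (p, v), S[[e]] (4 x npat) is the
# pi-weighted likelihood flow at p excluding the subtree below v, with
# log-scale slsc[[e]]. The total likelihood factorizes per edge as
# sum_ij S_e(i) P_e(i,j) post_v(j).
outward_pass <- function(tr, inw, pi) {
  n <- length(tr$tip.label)
  E <- tr$edge
  nnode <- n + tr$Nnode
  npat <- ncol(inw$post[[1]])
  root <- E[nrow(E), 1]
  H <- vector("list", nnode)
  Hlsc <- vector("list", nnode)
  H[[root]] <- matrix(pi, 4, npat)
  Hlsc[[root]] <- rep(0, npat)
  S <- vector("list", nrow(E))
  slsc <- vector("list", nrow(E))
  # reverse postorder: parents before children
  for (e in rev(seq_len(nrow(E)))) {
    p <- E[e, 1]; v <- E[e, 2]
    Sm <- H[[p]]
    sc <- Hlsc[[p]]
    for (e2 in which(E[, 1] == p)) {
      if (e2 == e) next
      ch <- E[e2, 2]
      Sm <- Sm * (inw$Ps[[e2]] %*% inw$post[[ch]])
      sc <- sc + inw$lsc[[ch]]
    }
    mx <- apply(Sm, 2, max)
    mx[mx <= 0] <- 1
    Sm <- sweep(Sm, 2, mx, "/")
    sc <- sc + log(mx)
    S[[e]] <- Sm
    slsc[[e]] <- sc
    if (v > n) {
      H[[v]] <- crossprod(inw$Ps[[e]], Sm)
      Hlsc[[v]] <- sc
    }
  }
  list(S = S, slsc = slsc)
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate-wise one-dimensional maximization over branches. Each cycle
#' computes inside and outside partial likelihoods once, profiles every
#' branch against them, and accepts the sweep only if the total
#' log-likelihood improves, so the reported log-likelihood is
#' non-decreasing across cycles.
#'
#' @param tree \code{phylo} tree (initial branch lengths used as the
#'   starting point; missing lengths start at 0.1).
#' @param m Matrix-like nucleotide object.
#' @param model A \code{gtr_model}.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_cycles Cycle cap (warning on non-convergence).
#' @param t_max Upper bound per branch.
#' @return The tree with optimized branch lengths; attribute
#'   \code{logLik}.
#' @export
optimize_branch_lengths <- function(tree, m, model, tol = 1e-6,
                                    max_cycles = 50L, t_max = 10) {
  x <- matrix_of(m)
  if (!setequal(rownames(x), tree$tip.label)) {
    stop_input("tree taxa and matrix taxa differ")
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(0.1, nrow(tr$edge))
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  cp <- compress_patterns(x)
  pats <- cp$patterns
  w <- cp$weights
  npat <- ncol(pats)
  ord <- match(tr$tip.label, rownames(pats))
  tipL <- lapply(ord, function(i) tip_partials(pats[i, ]))
  pfn <- gtr_transition_fn(model$pi, model$Q)
  k <- length(model$cat_rates)
  const_lik <- if (model$p_inv > 0) {
    vapply(seq_len(npat), function(j) {
      memb <- vapply(pats[, j], function(ch) {
        as.numeric(NT4 %in% IUPAC_SETS[[ch]])
      }, numeric(4))
      sum(model$pi * (rowSums(memb) == nrow(pats)))
    }, numeric(1))
  } else {
    NULL
  }
  mix_to_ll <- function(cat_ll) {
    # cat_ll: npat x k matrix of per-category log-likelihoods
    mmax <- apply(cat_ll, 1, max)
    ll <- mmax + log(rowMeans(exp(cat_ll - mmax)))
    if (!is.null(const_lik)) {
      ll <- log(model$p_inv * const_lik + (1 - model$p_inv) * exp(ll))
    }
    ll
  }
  passes <- function(elen) {
    lapply(seq_len(k), function(c) {
      inw <- inward_pass(tr, tipL, elen, pfn, model$cat_rates[c])
      out <- outward_pass(tr, inw, model$pi)
      list(inw = inw, out = out)
    })
  }
  total_from_passes <- function(ps) {
    root <- tr$edge[nrow(tr$edge), 1]
    cat_ll <- vapply(seq_len(k), function(c) {
      lik <- colSums(model$pi * ps[[c]]$inw$post[[root]])
      log(lik) + ps[[c]]$inw$lsc[[root]]
    }, numeric(npat))
    sum(mix_to_ll(matrix(cat_ll, ncol = k)) * w)
  }
  edge_profile <- function(ps, e) {
    Svs <- lapply(ps, function(p) p$out$S[[e]])
    posts <- lapply(ps, function(p) p$inw$post[[tr$edge[e, 2]]])
    lscs <- lapply(seq_len(k), function(c) {
      ps[[c]]$out$slsc[[e]] + ps[[c]]$inw$lsc[[tr$edge[e, 2]]]
    })
    function(t) {
      cat_ll <- vapply(seq_len(k), function(c) {
        P <- pfn(model$cat_rates[c] * t)
        lik <- colSums(crossprod(P, Svs[[c]]) * posts[[c]])
        lik[lik < 1e-300] <- 1e-300
        log(lik) + lscs[[c]]
      }, numeric(npat))
      sum(mix_to_ll(matrix(cat_ll, ncol = k)) * w)
    }
  }
  elen <- tr$edge.length
  ps <- passes(elen)
  ll_old <- total_from_passes(ps)
  converged <- FALSE
  for (cycle in seq_len(max_cycles)) {
    proposal <- elen
    for (e in seq_along(elen)) {
      f <- edge_profile(ps, e)
      opt <- stats::optimize(f, c(0, t_max), maximum = TRUE, tol = 1e-8)
      if (opt$objective > f(elen[e])) proposal[e] <- opt$maximum
    }
    ps_new <- passes(proposal)
    ll_new <- total_from_passes(ps_new)
    if (ll_new < ll_old) {
      # simultaneous update overshot: fall back to true coordinate ascent
      # (partials refreshed after every branch), which cannot decrease
      # the likelihood beyond numerical noise
      proposal <- elen
      for (e in seq_along(elen)) {
        f <- edge_profile(passes(proposal), e)
        opt <- stats::optimize(f, c(0, t_max), maximum = TRUE, tol = 1e-8)
        if (opt$objective > f(proposal[e])) proposal[e] <- opt$maximum
      }
      ps_new <- passes(proposal)
      ll_new <- total_from_passes(ps_new)
      if (ll_new < ll_old) {
        # no ascent direction left: converged at the current lengths
        converged <- TRUE
        break
      }
    }
    improved <- ll_new - ll_old
    elen <- proposal
    ps <- ps_new
    ll_old <- ll_new
    if (improved < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("branch-length optimization did not converge in ",
            max_cycles, " cycles; returning best so far")
  }
  tr$edge.length <- elen
  attr(tr, "logLik") <- ll_old
  tr
}
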