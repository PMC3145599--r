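# Pairwise distances: p-distance, GTR model estimation by composite
# pairwise likelihood, and per-pair GTR maximum-likelihood distances.

NT4 <- c("A", "C", "G", "T")

# character matrix -> integer codes 1..4, NA for anything ambiguous/missing
nt_codes <- function(m) {
  codes <- match(matrix_of(m), NT4)
  matrix(codes, nrow = nrow(matrix_of(m)),
         dimnames = dimnames(matrix_of(m)))
}

#' Pairwise p-distance with pairwise deletion
#'
#' Proportion of differing sites among the columns where both taxa carry
#' unambiguous A/C/G/T states.
#'
#' @param m A matrix-like object (\code{supermatrix}, \code{recoded_matrix}
#'   or character matrix).
#' @return Symmetric distance matrix with attribute \code{kind = "p"}.
#' @export
pairwise_p_distance <- function(m) {
  x <- nt_codes(m)
  n <- nrow(x)
  if (n < 2) stop_input("need at least 2 taxa")
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(x[i, ]) & !is.na(x[j, ])
      nc <- sum(ok)
      if (nc == 0) {
        stop_input("no comparable columns for pair ",
                   rownames(x)[i], " / ", rownames(x)[j])
      }
      d[i, j] <- d[j, i] <- sum(x[i, ok] != x[j, ok]) / nc
    }
  }
  attr(d, "kind") <- "p"
  d
}

# 4x4 pattern-count tables for every pair (ordered states).
pair_pattern_counts <- function(x) {
  n <- nrow(x)
  out <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(x[i, ]) & !is.na(x[j, ])
      tab <- matrix(0, 4, 4)
      if (any(ok)) {
        t2 <- table(factor(x[i, ok], levels = 1:4),
                    factor(x[j, ok], levels = 1:4))
        tab <- matrix(as.numeric(t2), 4, 4)
      }
      k <- k + 1L
      out[[k]] <- list(i = i, j = j, counts = tab)
    }
  }
  out
}

# Build a GTR rate matrix from pi and 6 exchangeabilities (order
# AC, AG, AT, CG, CT, GT), normalized to mean rate 1.
gtr_rate_matrix <- function(pi, rates) {
  R <- matrix(0, 4, 4)
  R[lower.tri(R)] <- rates[c(1, 2, 3, 4, 5, 6)]
  # fill: positions (2,1)=AC,(3,1)=AG,(4,1)=AT,(3,2)=CG,(4,2)=CT,(4,3)=GT
  R <- R + t(R)
  Q <- R %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q / scale
}

# Eigendecomposition of a reversible Q via symmetrization; returns a
# function t -> P(t).
gtr_transition_fn <- function(pi, Q) {
  sp <- sqrt(pi)
  S <- diag(sp) %*% Q %*% diag(1 / sp)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  V <- es$vectors
  lam <- es$values
  A <- diag(1 / sp) %*% V
  B <- t(V) %*% diag(sp)
  function(t) {
    P <- A %*% (exp(lam * t) * B)
    P[P < 0] <- 0
    P
  }
}

pair_loglik_fn <- function(pi, Q) {
  pfn <- gtr_transition_fn(pi, Q)
  function(counts, t) {
    P <- pfn(t)
    M <- pi * P  # joint prob of ordered pair
    M[M < 1e-300] <- 1e-300
    sum(counts * log(M))
  }
}

#' Estimate GTR model parameters from a nucleotide matrix
#'
#' Equilibrium frequencies are the matrix-wide empirical frequencies of
#' unambiguous states. The six exchangeabilities are estimated by
#' maximizing the sum over all taxon pairs of pairwise GTR log-likelihoods
#' (composite likelihood), with each pair's branch length profiled out by
#' one-dimensional optimization. Deterministic given the matrix.
#'
#' @param m Matrix-like nucleotide object.
#' @param t_max Branch-length cap (substitutions/site).
#' @return List with \code{pi} (named frequencies), \code{rates} (named
#'   exchangeabilities, GT = 1), and \code{logLik}.
#' @export
estimate_gtr_params <- function(m, t_max = 10) {
  x <- nt_codes(m)
  if (nrow(x) < 2) stop_input("need at least 2 taxa")
  cnt <- table(factor(x, levels = 1:4))
  pi <- as.numeric(cnt) / sum(cnt)
  names(pi) <- NT4
  pairs <- pair_pattern_counts(x)
  off_diag <- sum(vapply(pairs, function(p) {
    sum(p$counts) - sum(diag(p$counts))
  }, numeric(1)))
  if (off_diag == 0) {
    stop_input("no variable sites: exchangeabilities unidentifiable")
  }
  obj <- function(logr) {
    rates <- c(exp(pmin(pmax(logr, -12), 12)), 1)
    Q <- gtr_rate_matrix(pi, rates)
    llfn <- pair_loglik_fn(pi, Q)
    tot <- 0
    for (p in pairs) {
      opt <- stats::optimize(function(t) llfn(p$counts, t),
                             c(1e-9, t_max), maximum = TRUE,
                             tol = 1e-8)
      tot <- tot + opt$objective
    }
    -tot
  }
  # moment start: pooled mismatch counts F_ij imply s_ij ~ F_ij/(pi_i pi_j)
  pooled <- Reduce("+", lapply(pairs, function(p) p$counts))
  pooled <- pooled + t(pooled) + 0.5  # symmetrize; guard zeros
  s0 <- pooled / outer(pi, pi)
  ord <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  s6 <- apply(ord, 1, function(ij) s0[ij[1], ij[2]])
  start <- log(s6[1:5] / s6[6])
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-9))
  for (restart in 1:3) {
    if (fit$convergence == 0) break
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-9))
  }
  rates <- c(exp(fit$par), 1)
  names(rates) <- c("AC", "AG", "AT", "CG", "CT", "GT")
  list(pi = pi, rates = rates, logLik = -fit$value)
}

#' Pairwise GTR maximum-likelihood distances
#'
#' For each taxon pair, finds the branch length maximizing the pairwise
#' likelihood under fixed shared GTR parameters. Saturated pairs are capped
#' at \code{t_max} and flagged.
#'
#' @param m Matrix-like nucleotide object.
#' @param params Model parameters from \code{\link{estimate_gtr_params}}
#'   (list with \code{pi} and \code{rates}).
#' @param t_max Distance cap (substitutions/site).
#' @return Symmetric distance matrix, attribute \code{kind = "gtr"} and
#'   \code{capped} (logical matrix).
#' @export
gtr_ml_distance <- function(m, params = NULL, t_max = 10) {
  x <- nt_codes(m)
  n <- nrow(x)
  if (is.null(params)) params <- estimate_gtr_params(m, t_max = t_max)
  pi <- params$pi
  if (abs(sum(pi) - 1) > 1e-8 || any(params$rates <= 0)) {
    stop_input("invalid GTR parameters")
  }
  Q <- gtr_rate_matrix(pi, params$rates)
  llfn <- pair_loglik_fn(pi, Q)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  capped <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (p in pair_pattern_counts(x)) {
    if (sum(p$counts) == 0) {
      stop_input("no comparable columns for pair ",
                 rownames(x)[p$i], " / ", rownames(x)[p$j])
    }
    if (sum(p$counts) == sum(diag(p$counts))) {
      t_hat <- 0
    } else {
      opt <- stats::optimize(function(t) llfn(p$counts, t),
                             c(1e-10, t_max), maximum = TRUE, tol = 1e-10)
      t_hat <- opt$maximum
      # saturated: likelihood still increasing at the cap
      if (t_hat > t_max - 1e-4 ||
          llfn(p$counts, t_max) > opt$objective) {
        t_hat <- t_max
        capped[p$i, p$j] <- capped[p$j, p$i] <- TRUE
      }
    }
    d[p$i, p$j] <- d[p$j, p$i] <- t_hat
  }
  if (any(capped)) {
    warning(sum(capped) / 2, " saturated pair(s) capped at t_max = ", t_max)
  }
  attr(d, "kind") <- "gtr"
  attr(d, "capped") <- capped
  d
}
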