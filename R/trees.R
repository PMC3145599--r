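# Neighbor-joining, bipartitions, Robinson-Foulds distance, bootstrap
# resampling and bootstrap support mapping.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative neighbor-joining (Q-criterion join selection,
#' two-point branch-length formulas). Taxa are processed in lexicographic
#' label order and ties broken by the lowest (row, column) index pair, so
#' the result is deterministic. Negative branch-length estimates are
#' clamped to zero.
#'
#' @param d Symmetric distance matrix with taxon dimnames.
#' @return An unrooted \code{ape::phylo} tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop_input("neighbor-joining needs at least 3 taxa")
  if (is.null(rownames(d))) stop_input("distance matrix needs taxon names")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  labels <- rownames(d)
  # each active cluster holds a newick fragment without trailing length
  frags <- labels
  bl <- function(x) {
    formatC(max(x, 0), digits = 17, format = "g")
  }
  while (length(frags) > 3) {
    N <- nrow(d)
    r <- rowSums(d)
    Q <- (N - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)
    ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
    i <- ij[1, 1]; j <- ij[1, 2]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))
    bj <- d[i, j] - bi
    newfrag <- paste0("(", frags[i], ":", bl(bi), ",",
                      frags[j], ":", bl(bj), ")")
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frags <- c(frags[keep], newfrag)
    d <- d2
  }
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- paste0("(", frags[1], ":", bl(b1), ",", frags[2], ":", bl(b2),
                ",", frags[3], ":", bl(b3), ");")
  ape::read.tree(text = nwk)
}

# Canonical nontrivial bipartitions of an unrooted tree as strings.
# Each split is represented by the side NOT containing the reference taxon
# (the lexicographically smallest label), sorted and joined.
tree_splits <- function(tree) {
  tips <- tree$tip.label
  ref <- min(tips)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (cl in pp) {
    side <- labs[cl]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2 && length(side) <= length(tips) - 2) {
      out <- c(out, paste(sort(side), collapse = "\r"))
    }
  }
  unique(out)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of nontrivial bipartitions.
#'
#' @param a,b \code{phylo} trees over the same taxon set.
#' @return Nonnegative integer.
#' @export
rf_distance <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) {
    stop_input("trees have different taxon sets")
  }
  sa <- tree_splits(a)
  sb <- tree_splits(b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

#' Test whether a taxon set forms a clade (bipartition) in a tree
#'
#' @param tree A \code{phylo} tree.
#' @param taxa Character vector of tip labels.
#' @return TRUE if the set is one side of a bipartition of the unrooted
#'   tree (trivial splits included).
#' @export
has_clade <- function(tree, taxa) {
  tips <- tree$tip.label
  taxa <- intersect(taxa, tips)
  k <- length(taxa)
  if (k < 2 || k > length(tips) - 2) {
    return(k == 1 || k == length(tips) - 1 || k == length(tips))
  }
  ref <- min(tips)
  side <- if (ref %in% taxa) setdiff(tips, taxa) else taxa
  key <- paste(sort(side), collapse = "\r")
  key %in% tree_splits(tree)
}

#' Bootstrap-resample alignment columns
#'
#' Draws columns (or whole codons) with replacement to the original width.
#' Reproducible from the seed; the caller's RNG state is untouched.
#'
#' @param m Matrix-like object.
#' @param n Number of replicates.
#' @param unit \code{"site"} or \code{"codon"}.
#' @param seed Integer seed.
#' @return List of character matrices.
#' @export
bootstrap_resample <- function(m, n, unit = c("site", "codon"), seed = 1L) {
  unit <- match.arg(unit)
  x <- matrix_of(m)
  nc <- ncol(x)
  if (n < 1) stop_input("n must be >= 1")
  if (unit == "codon" && nc %% 3L != 0L) {
    stop_input("codon resampling needs a width divisible by 3")
  }
  with_seed(seed, {
    lapply(seq_len(n), function(k) {
      if (unit == "site") {
        cols <- sample.int(nc, nc, replace = TRUE)
      } else {
        cod <- sample.int(nc %/% 3L, nc %/% 3L, replace = TRUE)
        cols <- as.vector(rbind(3L * cod - 2L, 3L * cod - 1L, 3L * cod))
      }
      x[, cols, drop = FALSE]
    })
  })
}

#' Map bootstrap support onto a reference tree
#'
#' Annotates each internal edge of the reference with the percentage of
#' replicate trees containing the same bipartition. Support appears as
#' internal node labels in the returned tree.
#'
#' @param reference A \code{phylo} tree.
#' @param replicates List of \code{phylo} trees over the same taxa.
#' @return The reference tree with \code{node.label} support percentages
#'   (root label empty).
#' @export
support_from_replicates <- function(reference, replicates) {
  for (tr in replicates) {
    if (!setequal(tr$tip.label, reference$tip.label)) {
      stop_input("replicate taxon set differs from reference")
    }
  }
  rep_splits <- lapply(replicates, tree_splits)
  counts <- table(unlist(rep_splits))
  tips <- reference$tip.label
  ref <- min(tips)
  pp <- ape::prop.part(reference)
  labs <- attr(pp, "labels")
  node_lab <- character(length(pp))
  for (k in seq_along(pp)) {
    side <- labs[pp[[k]]]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) < 2 || length(side) > length(tips) - 2) {
      node_lab[k] <- ""
      next
    }
    key <- paste(sort(side), collapse = "\r")
    hit <- counts[key]
    pct <- if (is.na(hit)) 0 else 100 * as.numeric(hit) / length(replicates)
    node_lab[k] <- trimws(formatC(pct, format = "fg", digits = 4))
  }
  reference$node.label <- node_lab
  reference
}

#' Majority-rule consensus of replicate trees
#'
#' @param trees List of \code{phylo} trees over the same taxa.
#' @param p Proportion threshold (default 0.5 = majority rule).
#' @return A \code{phylo} consensus tree.
#' @export
majority_consensus <- function(trees, p = 0.5) {
  ape::consensus(trees, p = p, check.labels = TRUE)
}

#' Bootstrap support of a tree-building pipeline
#'
#' Convenience wrapper: resamples columns, rebuilds a tree per replicate
#' with \code{tree_fun}, and maps support onto the reference tree.
#'
#' @param m Matrix-like object.
#' @param tree_fun Function taking a character matrix and returning a
#'   \code{phylo} tree.
#' @param reference Reference tree (default \code{tree_fun} on the full
#'   matrix).
#' @param n Replicates.
#' @param unit Resampling unit.
#' @param seed Seed.
#' @return The reference tree with support labels; attribute
#'   \code{replicates} holds the replicate trees.
#' @export
bootstrap_support <- function(m, tree_fun, reference = NULL, n = 200L,
                              unit = c("site", "codon"), seed = 1L) {
  unit <- match.arg(unit)
  x <- matrix_of(m)
  if (is.null(reference)) reference <- tree_fun(x)
  reps <- bootstrap_resample(x, n = n, unit = unit, seed = seed)
  rep_trees <- lapply(reps, tree_fun)
  out <- support_from_replicates(reference, rep_trees)
  attr(out, "replicates") <- rep_trees
  out
}

#' Support of a focal clade in an annotated tree
#'
#' @param tree Tree with support node labels (see
#'   \code{\link{support_from_replicates}}).
#' @param taxa Focal clade taxon set.
#' @return Support percentage if the bipartition is present, otherwise NA.
#' @export
clade_support <- function(tree, taxa) {
  tips <- tree$tip.label
  taxa <- intersect(taxa, tips)
  if (length(taxa) < 2 || length(taxa) > length(tips) - 2) return(NA_real_)
  ref <- min(tips)
  want <- if (ref %in% taxa) setdiff(tips, taxa) else taxa
  want_key <- paste(sort(want), collapse = "\r")
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  for (k in seq_along(pp)) {
    side <- labs[pp[[k]]]
    if (ref %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "\r")
    if (key == want_key) {
      v <- suppressWarnings(as.numeric(tree$node.label[k]))
      return(v)
    }
  }
  NA_real_
}
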