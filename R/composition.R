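# Among-taxon base-compositional heterogeneity: composition tables,
# chi-square homogeneity tests, and Euclidean compositional distances.

#' Tally per-taxon nucleotide composition
#'
#' Counts unambiguous A/C/G/T states per taxon; ambiguity codes, \code{?}
#' and \code{-} are excluded entirely. With \code{drop_invariant}, columns
#' whose non-missing unambiguous states are all identical are excluded
#' before tallying. A pre-computed column mask (e.g. the invariable-site
#' mask of a degen1 recoding, see \code{\link{degen1_invariant_mask}}) can
#' be supplied instead via \code{keep_columns}.
#'
#' @param x A \code{supermatrix}, \code{recoded_matrix} or character matrix
#'   of nucleotides.
#' @param drop_invariant Drop invariable columns before counting.
#' @param keep_columns Optional logical or integer vector selecting columns
#'   to tally (applied before \code{drop_invariant}).
#' @param label Provenance label (e.g. \code{"nt3"}).
#' @return An object of class \code{composition_table}: list with
#'   \code{counts} (taxa x 4), \code{proportions}, \code{total_characters},
#'   \code{label} and \code{degenerate} (no counted columns).
#' @export
composition_table <- function(x, drop_invariant = FALSE, keep_columns = NULL,
                              label = NULL) {
  m <- matrix_of(x)
  if (is.null(label)) {
    label <- if (inherits(x, "recoded_matrix")) x$treatment
             else if (inherits(x, "supermatrix")) x$treatment
             else "nt"
  }
  if (any(m %in% c(LETTERS[!LETTERS %in% DNA_CHARS], "*"))) {
    stop_input("composition test is defined for nucleotide matrices only")
  }
  if (!is.null(keep_columns)) m <- m[, keep_columns, drop = FALSE]
  if (drop_invariant && ncol(m) > 0) {
    inv <- invariant_columns(m)
    m <- m[, !inv, drop = FALSE]
  }
  nts <- c("A", "C", "G", "T")
  counts <- t(apply(m, 1, function(row) {
    tab <- table(factor(row, levels = nts))
    as.integer(tab)
  }))
  if (nrow(m) == 1) counts <- matrix(counts, nrow = 1)
  dimnames(counts) <- list(rownames(m), nts)
  totals <- rowSums(counts)
  props <- counts / ifelse(totals > 0, totals, NA_real_)
  structure(
    list(counts = counts, proportions = props,
         total_characters = ncol(m), label = label,
         degenerate = ncol(m) == 0 || all(totals == 0)),
    class = "composition_table"
  )
}

# TRUE for columns whose non-missing unambiguous states are all identical
# (includes all-missing columns).
invariant_columns <- function(m) {
  nts <- c("A", "C", "G", "T")
  apply(m, 2, function(col) {
    obs <- unique(col[col %in% nts])
    length(obs) <= 1
  })
}

#' Invariable-site mask computed on the degen1 recoding
#'
#' A column is invariable in the degen1 data set when, among taxa with
#' data there, the recoded symbols (including degenerate IUPAC codes) are
#' all identical -- i.e. the column shows no nonsynonymous variation.
#' Returns, over source columns, TRUE where the degen1 recoding is
#' variable; composition tests "after eliminating invariable sites"
#' restrict any character set to these columns via its own source-column
#' mapping.
#'
#' @param sm A \code{supermatrix}.
#' @param code Genetic code table id.
#' @return Logical vector over source columns: TRUE where the degen1
#'   recoding is variable.
#' @export
degen1_invariant_mask <- function(sm, code = "1") {
  rec <- suppressWarnings(degen1_recode(sm, code = code))
  m <- rec$matrix
  m[sm$matrix == "?"] <- "?"  # unsequenced cells stay missing
  inv <- apply(m, 2, function(col) {
    obs <- unique(col[!col %in% c("?", "-")])
    length(obs) <= 1
  })
  !inv
}

#' @export
print.composition_table <- function(x, ...) {
  cat("composition_table (", x$label, "): ", nrow(x$counts), " taxa, ",
      x$total_characters, " columns\n", sep = "")
  invisible(x)
}

#' Chi-square test of among-taxon compositional homogeneity
#'
#' Standard R x C contingency chi-square of taxa against \{A, C, G, T\}
#' counts, df = (taxa - 1) x 3, upper-tail p-value. Taxa with zero counted
#' states are dropped; fewer than two usable taxa is an error. Expected
#' cells below 5 raise a validity flag, not an error.
#'
#' @param ct A \code{composition_table}.
#' @return List with \code{statistic}, \code{df}, \code{p_value},
#'   \code{n_taxa} and \code{small_expected} flag.
#' @export
chisq_homogeneity <- function(ct) {
  counts <- ct$counts
  usable <- rowSums(counts) > 0
  counts <- counts[usable, , drop = FALSE]
  if (nrow(counts) < 2) {
    stop_input("need at least 2 taxa with counted states")
  }
  # drop all-zero state columns (keeps chisq.test well-defined)
  keep <- colSums(counts) > 0
  counts2 <- counts[, keep, drop = FALSE]
  ht <- suppressWarnings(stats::chisq.test(counts2, correct = FALSE))
  structure(
    list(
      statistic = unname(ht$statistic),
      df = (nrow(counts) - 1L) * 3L,
      p_value = stats::pchisq(unname(ht$statistic),
                              df = (nrow(counts) - 1L) * 3L,
                              lower.tail = FALSE),
      n_taxa = nrow(counts),
      small_expected = any(ht$expected < 5),
      label = ct$label
    ),
    class = "homogeneity_result"
  )
}

#' @export
print.homogeneity_result <- function(x, ...) {
  cat(sprintf(
    "chi-square homogeneity (%s): X2 = %.3f, df = %d, p = %.4g (%d taxa)%s\n",
    x$label, x$statistic, x$df, x$p_value, x$n_taxa,
    if (x$small_expected) " [expected cell < 5]" else ""
  ))
  invisible(x)
}

#' Euclidean compositional distances
#'
#' Pairwise Euclidean distances between taxa's 4-vector nucleotide
#' proportions, the four states treated as independent characters. These
#' distances reflect compositional heterogeneity only.
#'
#' @param ct A \code{composition_table}.
#' @return Symmetric distance matrix with attribute \code{kind = "comp"}.
#' @export
euclidean_comp_distances <- function(ct) {
  totals <- rowSums(ct$counts)
  if (any(totals == 0)) {
    stop_input("taxa with zero counted states: ",
               paste(rownames(ct$counts)[totals == 0], collapse = ", "))
  }
  d <- as.matrix(stats::dist(ct$proportions, method = "euclidean"))
  attr(d, "kind") <- "comp"
  d
}
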