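# Character treatments: degen1 synonymous degeneration, codon-position
# subsets, the noLRall1+nt2 / LRall1+nt3 partition, and amino acids.
#
# degen1 replaces every codon by the fully degenerate IUPAC triplet of its
# synonymous family -- the set of sense codons interconvertible by synonymous
# single-nucleotide changes. Under the standard code this merges the two
# leucine codon blocks (TTR and CTN) and the two arginine blocks (CGN and
# AGR), which are connected by synonymous first-position changes, while the
# two serine blocks (TCN and AGY) remain separate: no single synonymous
# change links them. All synonymous signal is thereby removed from the
# matrix; nonsynonymous differences are retained.

the <- new.env(parent = emptyenv())

get_code_table <- function(code = "1") {
  key <- paste0("code_", code)
  if (is.null(the[[key]])) {
    gc <- Biostrings::getGeneticCode(code)
    the[[key]] <- stats::setNames(as.character(gc), names(gc))
  }
  the[[key]]
}

sense_codons <- function(code = "1") {
  tab <- get_code_table(code)
  names(tab)[tab != "*"]
}

# Synonymous families: sense codons grouped by amino acid, then split into
# connected components under single-nucleotide-change adjacency (this keeps
# the two serine blocks apart and merges the Leu and Arg blocks).
degen1_families <- function(code = "1") {
  key <- paste0("fam_", code)
  if (!is.null(the[[key]])) return(the[[key]])
  tab <- get_code_table(code)
  sense <- names(tab)[tab != "*"]
  fams <- list()
  for (aa in unique(tab[sense])) {
    cods <- sense[tab[sense] == aa]
    remaining <- cods
    while (length(remaining) > 0) {
      comp <- remaining[1]
      repeat {
        nb <- remaining[vapply(remaining, function(c2) {
          any(vapply(comp, function(c1) {
            sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]]) == 1L
          }, logical(1)))
        }, logical(1))]
        nb <- union(comp, nb)
        if (length(nb) == length(comp)) break
        comp <- nb
      }
      fams[[length(fams) + 1L]] <- sort(comp)
      remaining <- setdiff(remaining, comp)
    }
  }
  the[[key]] <- fams
  fams
}

family_cover <- function(codons) {
  chars <- do.call(rbind, strsplit(codons, ""))
  paste(vapply(1:3, function(p) iupac_encode(chars[, p]), character(1)),
        collapse = "")
}

# per-position IUPAC union of a set of (possibly ambiguous) triplets
triplet_union <- function(triplets) {
  chars <- do.call(rbind, strsplit(triplets, ""))
  paste(vapply(1:3, function(p) {
    iupac_encode(unique(unlist(lapply(chars[, p], iupac_expand))))
  }, character(1)), collapse = "")
}

# codon -> degen1 triplet lookup for unambiguous codons; stops map to NNN.
degen1_map <- function(code = "1") {
  key <- paste0("map_", code)
  if (!is.null(the[[key]])) return(the[[key]])
  tab <- get_code_table(code)
  map <- stats::setNames(rep("NNN", length(tab)), names(tab))
  for (fam in degen1_families(code)) {
    map[fam] <- family_cover(fam)
  }
  the[[key]] <- map
  map
}

expand_codon <- function(codon) {
  pos <- strsplit(codon, "")[[1]]
  sets <- lapply(pos, iupac_expand)
  as.vector(outer(
    outer(sets[[1]], sets[[2]], paste0), sets[[3]], paste0
  ))
}

#' degen1-recode a single codon
#'
#' Maps a codon to the fully degenerate IUPAC triplet of its synonymous
#' family. Codons containing ambiguity codes, \code{?} or \code{-} are
#' expanded to their compatible sense codons; determinable positions are
#' degenerated and undeterminable positions become \code{N}. In-frame stop
#' codons map to \code{"NNN"} with a warning (they indicate an upstream
#' error).
#'
#' @param codon 3-character DNA string.
#' @param code Genetic code table id.
#' @return 3-character string over IUPAC codes.
#' @export
degen1_codon <- function(codon, code = "1") {
  if (nchar(codon) != 3) stop_input("codon must have 3 characters: ", codon)
  codon <- toupper(codon)
  map <- degen1_map(code)
  hit <- map[codon]
  if (!is.na(hit)) {
    if (get_code_table(code)[codon] == "*") {
      warning("in-frame stop codon ", codon, " recoded to NNN")
    }
    return(unname(hit))
  }
  key <- paste0("amb_", code)
  if (is.null(the[[key]])) the[[key]] <- new.env(parent = emptyenv())
  cache <- the[[key]]
  if (!is.null(cache[[codon]])) return(cache[[codon]])
  compat <- expand_codon(codon)
  tab <- get_code_table(code)
  compat <- compat[tab[compat] != "*"]
  out <- if (length(compat) == 0) "NNN" else triplet_union(unname(map[compat]))
  cache[[codon]] <- out
  out
}

codon_strings <- function(chars) {
  n <- length(chars)
  if (n %% 3L != 0L) stop_input("sequence length not divisible by 3")
  paste0(chars[seq(1, n, 3)], chars[seq(2, n, 3)], chars[seq(3, n, 3)])
}

check_in_frame <- function(sm) {
  for (g in names(sm$charsets)) {
    iv <- sm$charsets[[g]]
    if ((iv[2] - iv[1]) %% 3L != 0L) {
      stop_input("charset '", g, "' is out of frame (length ",
                 iv[2] - iv[1], ")")
    }
  }
  invisible(TRUE)
}

recoded_matrix <- function(m, treatment, source_columns) {
  structure(
    list(matrix = m, treatment = treatment, source_columns = source_columns),
    class = "recoded_matrix"
  )
}

#' @export
print.recoded_matrix <- function(x, ...) {
  cat("recoded_matrix (", x$treatment, "): ", nrow(x$matrix), " taxa x ",
      ncol(x$matrix), " columns\n", sep = "")
  invisible(x)
}

# Vectorized per-codon mapping over a matrix: taxa x codons codon strings.
codon_matrix <- function(m) {
  nc <- ncol(m)
  if (nc %% 3L != 0L) stop_input("matrix width not divisible by 3")
  ncod <- nc %/% 3L
  cods <- matrix(
    paste0(m[, seq(1, nc, 3)], m[, seq(2, nc, 3)], m[, seq(3, nc, 3)]),
    nrow = nrow(m), dimnames = list(rownames(m), NULL)
  )
  cods
}

#' degen1-recode a supermatrix
#'
#' Applies \code{\link{degen1_codon}} to every codon of every taxon.
#' Dimensions are unchanged and the operation is idempotent. In-frame stop
#' codons are recoded to \code{NNN} with a single summary warning.
#'
#' @param sm A \code{supermatrix} with in-frame charsets.
#' @param code Genetic code table id.
#' @return A \code{recoded_matrix} with treatment \code{"degen1"}.
#' @export
degen1_recode <- function(sm, code = "1") {
  check_in_frame(sm)
  m <- sm$matrix
  cods <- codon_matrix(m)
  uc <- unique(as.vector(cods))
  tab <- get_code_table(code)
  n_stop <- sum(!is.na(tab[as.vector(cods)]) & tab[as.vector(cods)] == "*")
  mapped <- vapply(
    uc,
    function(cd) suppressWarnings(degen1_codon(cd, code)),
    character(1)
  )
  if (n_stop > 0) {
    warning(n_stop, " in-frame stop codon(s) recoded to NNN")
  }
  rec <- matrix(mapped[cods], nrow = nrow(m))
  out <- matrix("", nrow = nrow(m), ncol = ncol(m),
                dimnames = dimnames(m))
  out[, seq(1, ncol(m), 3)] <- substr(rec, 1, 1)
  out[, seq(2, ncol(m), 3)] <- substr(rec, 2, 2)
  out[, seq(3, ncol(m), 3)] <- substr(rec, 3, 3)
  recoded_matrix(out, "degen1", seq_len(ncol(m)) - 1L)
}

#' Classify a codon's first position as LRall1 or noLRall1
#'
#' First positions of leucine and arginine codons can change synonymously
#' (\code{LRall1}); all other sense codons' first positions cannot
#' (\code{noLRall1}). Codons whose amino acid cannot be determined
#' (missing, ambiguous across the boundary, or stop) are \code{unassigned}.
#'
#' @param codon 3-character DNA string.
#' @param code Genetic code table id.
#' @return \code{"LRall1"}, \code{"noLRall1"} or \code{"unassigned"}.
#' @export
classify_nt1 <- function(codon, code = "1") {
  if (nchar(codon) != 3) stop_input("codon must have 3 characters: ", codon)
  codon <- toupper(codon)
  tab <- get_code_table(code)
  compat <- if (!is.na(tab[codon])) codon else expand_codon(codon)
  aas <- unique(tab[compat])
  aas <- aas[aas != "*"]
  if (length(aas) == 0) return("unassigned")
  lr <- aas %in% c("L", "R")
  if (all(lr)) "LRall1" else if (!any(lr)) "noLRall1" else "unassigned"
}

# Translation resolving ambiguity codes; degen1 family-cover triplets
# (e.g. "YTN" for the merged leucine family, "MGN" for arginine) translate
# to their family's amino acid even where the positionwise cover also
# matches codons of other families.
translate_codons <- function(cods, code = "1", ambiguous = "X") {
  tab <- get_code_table(code)
  ckey <- paste0("covaa_", code)
  if (is.null(the[[ckey]])) {
    fams <- degen1_families(code)
    the[[ckey]] <- stats::setNames(
      vapply(fams, function(f) unname(tab[f[1]]), character(1)),
      vapply(fams, family_cover, character(1))
    )
  }
  cover_aa <- the[[ckey]]
  uc <- unique(cods)
  out <- vapply(uc, function(cd) {
    hit <- tab[cd]
    if (!is.na(hit)) return(unname(hit))
    fam <- cover_aa[cd]
    if (!is.na(fam)) return(unname(fam))
    compat <- expand_codon(cd)
    aas <- unique(unname(tab[compat]))
    if (length(aas) == 1) aas else ambiguous
  }, character(1))
  unname(out[match(cods, uc)])
}

#' Extract a character treatment from a codon supermatrix
#'
#' Supported treatments: \code{nt123} (identity), \code{nt1}, \code{nt2},
#' \code{nt3} (codon-position subsets), \code{degen1}, \code{aa}
#' (translation; undeterminable codons become \code{X}), and the
#' mostly-nonsynonymous / mostly-synonymous partition halves
#' \code{noLRall1_nt2} and \code{LRall1_nt3}. The partition halves carry all
#' relevant codon-position columns with non-member cells masked as \code{?},
#' because the Leu/Arg classification is a property of each taxon's codon,
#' not of a column.
#'
#' @param sm A \code{supermatrix} with in-frame charsets.
#' @param treatment Treatment label.
#' @param code Genetic code table id.
#' @return A \code{recoded_matrix}; \code{source_columns} maps output columns
#'   to 0-based source columns (codon index for \code{aa}).
#' @export
extract_treatment <- function(sm,
                              treatment = c("nt123", "nt1", "nt2", "nt3",
                                            "degen1", "aa",
                                            "noLRall1_nt2", "LRall1_nt3"),
                              code = "1") {
  treatment <- match.arg(treatment)
  check_in_frame(sm)
  m <- sm$matrix
  nc <- ncol(m)
  pos_cols <- function(p) seq(p, nc, 3L)
  if (treatment == "nt123") {
    return(recoded_matrix(m, "nt123", seq_len(nc) - 1L))
  }
  if (treatment %in% c("nt1", "nt2", "nt3")) {
    p <- as.integer(substr(treatment, 3, 3))
    cols <- pos_cols(p)
    return(recoded_matrix(m[, cols, drop = FALSE], treatment, cols - 1L))
  }
  if (treatment == "degen1") {
    return(degen1_recode(sm, code = code))
  }
  cods <- codon_matrix(m)
  if (treatment == "aa") {
    uc <- unique(as.vector(cods))
    aa_map <- stats::setNames(translate_codons(uc, code = code), uc)
    aam <- matrix(aa_map[cods], nrow = nrow(m), dimnames = list(rownames(m), NULL))
    aam[aam == "*"] <- "X"
    return(recoded_matrix(aam, "aa", seq_len(ncol(cods)) - 1L))
  }
  # partition halves: per-cell Leu/Arg classification of first positions
  uc <- unique(as.vector(cods))
  cls_map <- stats::setNames(
    vapply(uc, classify_nt1, character(1), code = code), uc
  )
  cls <- matrix(cls_map[cods], nrow = nrow(m))
  nt1m <- m[, pos_cols(1L), drop = FALSE]
  if (treatment == "noLRall1_nt2") {
    nt1m[cls != "noLRall1"] <- "?"
    out <- cbind(nt1m, m[, pos_cols(2L), drop = FALSE])
    src <- c(pos_cols(1L), pos_cols(2L)) - 1L
  } else {
    nt1m[cls != "LRall1"] <- "?"
    out <- cbind(nt1m, m[, pos_cols(3L), drop = FALSE])
    src <- c(pos_cols(1L), pos_cols(3L)) - 1L
  }
  rownames(out) <- rownames(m)
  recoded_matrix(out, treatment, src)
}

#' Export the degen1 codon mapping table
#'
#' @param code Genetic code table id.
#' @return Data frame with columns \code{codon}, \code{amino_acid},
#'   \code{degen1}.
#' @export
degen1_table <- function(code = "1") {
  tab <- get_code_table(code)
  map <- degen1_map(code)
  data.frame(
    codon = names(tab),
    amino_acid = unname(tab),
    degen1 = unname(map[names(tab)]),
    stringsAsFactors = FALSE
  )
}
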