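# Gene alignments, supermatrices, and taxon-by-gene sampling designs.

#' Construct a gene alignment
#'
#' A gene alignment is an in-frame protein-coding nucleotide alignment:
#' a character matrix (taxa in rows, sites in columns) over uppercase IUPAC
#' DNA codes plus the alignment gap \code{-} and the missing/unsequenced
#' symbol \code{?}.
#'
#' @param seqs Character matrix with unique row names (taxon labels), or a
#'   named character vector of equal-length sequence strings.
#' @param gene Gene label.
#' @return An object of class \code{gene_alignment}: a list with elements
#'   \code{gene} (label) and \code{seq} (character matrix).
#' @export
gene_alignment <- function(seqs, gene = "gene") {
  if (is.character(seqs) && !is.matrix(seqs)) {
    if (is.null(names(seqs))) stop_input("sequences must be named")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1) {
      stop_input(
        "alignment rows differ in length (",
        paste(unique(lens), collapse = ", "), ")"
      )
    }
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
    seqs <- m
  }
  if (!is.matrix(seqs)) stop_input("seqs must be a matrix or character vector")
  if (is.null(rownames(seqs))) stop_input("sequence matrix must have row names")
  if (anyDuplicated(rownames(seqs))) {
    stop_input(
      "duplicate taxon label(s): ",
      paste(unique(rownames(seqs)[duplicated(rownames(seqs))]), collapse = ", ")
    )
  }
  seqs[] <- toupper(seqs)
  check_dna_chars(seqs, paste0("gene '", gene, "'"))
  structure(list(gene = gene, seq = seqs), class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(
    "gene_alignment '", x$gene, "': ", nrow(x$seq), " taxa x ",
    ncol(x$seq), " bp\n", sep = ""
  )
  invisible(x)
}

#' Construct a supermatrix
#'
#' A supermatrix is a concatenated multi-gene character matrix together with
#' charsets mapping each gene to a half-open, 0-based column interval.
#'
#' @param m Character matrix (taxa x columns) with unique row names.
#' @param charsets Named list of integer vectors \code{c(start, end)}
#'   (half-open, 0-based). Intervals must be disjoint and jointly cover all
#'   columns.
#' @param treatment Provenance label for the character treatment
#'   (default \code{"nt123"}).
#' @return An object of class \code{supermatrix}.
#' @export
supermatrix <- function(m, charsets = NULL, treatment = "nt123") {
  if (!is.matrix(m) || is.null(rownames(m))) {
    stop_input("supermatrix needs a character matrix with row names")
  }
  if (anyDuplicated(rownames(m))) stop_input("duplicate taxon labels")
  if (is.null(charsets)) {
    charsets <- list(gene = c(0L, ncol(m)))
  }
  ivs <- do.call(rbind, charsets)
  if (any(ivs[, 1] >= ivs[, 2])) stop_input("empty charset interval")
  o <- order(ivs[, 1])
  cover <- ivs[o, , drop = FALSE]
  if (cover[1, 1] != 0 || cover[nrow(cover), 2] != ncol(m) ||
      (nrow(cover) > 1 && any(cover[-1, 1] != cover[-nrow(cover), 2]))) {
    stop_input("charsets must be disjoint and cover all columns")
  }
  structure(
    list(matrix = m, charsets = charsets, treatment = treatment),
    class = "supermatrix"
  )
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(
    "supermatrix: ", nrow(x$matrix), " taxa x ", ncol(x$matrix),
    " columns, ", length(x$charsets), " charset(s), treatment '",
    x$treatment, "'\n", sep = ""
  )
  invisible(x)
}

taxa_of <- function(x) {
  if (inherits(x, "supermatrix")) rownames(x$matrix)
  else if (inherits(x, "gene_alignment")) rownames(x$seq)
  else rownames(x)
}

matrix_of <- function(x) {
  if (inherits(x, "supermatrix")) x$matrix
  else if (inherits(x, "gene_alignment")) x$seq
  else if (inherits(x, "recoded_matrix")) x$matrix
  else x
}

#' Validate reading frame and scan for internal stop codons
#'
#' Reports, per taxon, the 0-based codon indices that translate to a stop
#' codon, and flags alignments whose length is not divisible by 3. Codons
#' containing ambiguity, \code{?} or \code{-} that cannot be resolved to a
#' single amino acid are skipped.
#'
#' @param aln A \code{gene_alignment} (or character matrix).
#' @param code Genetic code table id (\code{"1"} = standard).
#' @return A list with \code{frame_ok} (logical), \code{length} and
#'   \code{stops}, a named list of integer vectors of 0-based stop codon
#'   indices per taxon.
#' @export
validate_reading_frame <- function(aln, code = "1") {
  m <- matrix_of(aln)
  len <- ncol(m)
  frame_ok <- (len %% 3L) == 0L
  stops <- stats::setNames(vector("list", nrow(m)), rownames(m))
  if (frame_ok) {
    ncod <- len %/% 3L
    for (i in seq_len(nrow(m))) {
      cods <- codon_strings(m[i, , drop = TRUE])
      aa <- translate_codons(cods, code = code, ambiguous = "X")
      stops[[i]] <- which(aa == "*") - 1L
    }
  }
  list(frame_ok = frame_ok, length = len, stops = stops)
}

#' Concatenate gene alignments into a supermatrix
#'
#' Taxa are the union of the genes' taxa in lexicographic order; a taxon
#' absent from a gene receives \code{?} across that gene's interval.
#' Charsets record each gene's column interval in input order.
#'
#' @param genes List of \code{gene_alignment} objects with unique gene labels.
#' @return A \code{supermatrix}.
#' @export
concatenate_genes <- function(genes) {
  if (length(genes) == 0) stop_input("no gene alignments supplied")
  gnames <- vapply(genes, function(g) g$gene, character(1))
  if (anyDuplicated(gnames)) {
    stop_input(
      "duplicate gene name(s): ",
      paste(unique(gnames[duplicated(gnames)]), collapse = ", ")
    )
  }
  taxa <- sort(unique(unlist(lapply(genes, function(g) rownames(g$seq)))))
  lens <- vapply(genes, function(g) ncol(g$seq), integer(1))
  total <- sum(lens)
  m <- matrix("?", nrow = length(taxa), ncol = total,
              dimnames = list(taxa, NULL))
  charsets <- list()
  at <- 0L
  for (k in seq_along(genes)) {
    g <- genes[[k]]
    cols <- at + seq_len(lens[k])
    m[rownames(g$seq), cols] <- g$seq
    charsets[[gnames[k]]] <- c(at, at + lens[k])
    at <- at + lens[k]
  }
  supermatrix(m, charsets)
}

#' Extract one gene's alignment from a supermatrix
#'
#' @param sm A \code{supermatrix}.
#' @param gene Gene name present in the charsets.
#' @return A \code{gene_alignment}.
#' @export
extract_gene <- function(sm, gene) {
  iv <- sm$charsets[[gene]]
  if (is.null(iv)) stop_input("unknown gene: ", gene)
  gene_alignment(sm$matrix[, (iv[1] + 1L):iv[2], drop = FALSE], gene = gene)
}

#' Specify a taxon-by-gene sampling design
#'
#' A design restricts a supermatrix to a taxon subset and masks, per taxon,
#' the genes for which that taxon has no data (those blocks become \code{?}).
#'
#' @param name Design label (e.g. \code{"A"}).
#' @param included_taxa Character vector of taxon labels.
#' @param gene_coverage Named list mapping each included taxon to the genes
#'   it has data for; taxa omitted from the list keep all genes.
#' @return An object of class \code{design_spec}.
#' @export
design_spec <- function(name, included_taxa, gene_coverage = list()) {
  if (length(included_taxa) == 0) stop_input("design includes no taxa")
  covered <- vapply(
    included_taxa,
    function(tx) {
      gc <- gene_coverage[[tx]]
      is.null(gc) || length(gc) > 0
    },
    logical(1)
  )
  if (!all(covered)) {
    stop_input(
      "taxa with no covered gene: ",
      paste(included_taxa[!covered], collapse = ", ")
    )
  }
  structure(
    list(name = name, included_taxa = included_taxa,
         gene_coverage = gene_coverage),
    class = "design_spec"
  )
}

#' Apply a sampling design to a supermatrix
#'
#' Restricts rows to the design's taxa and overwrites, for each taxon, the
#' intervals of genes outside its coverage with \code{?}. Charsets are
#' preserved.
#'
#' @param sm A \code{supermatrix}.
#' @param design A \code{design_spec}.
#' @return A \code{supermatrix}.
#' @export
apply_design <- function(sm, design) {
  taxa <- design$included_taxa
  missing_taxa <- setdiff(taxa, rownames(sm$matrix))
  if (length(missing_taxa) > 0) {
    stop_input("design references unknown taxa: ",
               paste(missing_taxa, collapse = ", "))
  }
  genes <- names(sm$charsets)
  bad_genes <- setdiff(unlist(design$gene_coverage), genes)
  if (length(bad_genes) > 0) {
    stop_input("design references unknown genes: ",
               paste(unique(bad_genes), collapse = ", "))
  }
  m <- sm$matrix[taxa, , drop = FALSE]
  for (tx in taxa) {
    gc <- design$gene_coverage[[tx]]
    if (is.null(gc)) next
    for (g in setdiff(genes, gc)) {
      iv <- sm$charsets[[g]]
      m[tx, (iv[1] + 1L):iv[2]] <- "?"
    }
  }
  supermatrix(m, sm$charsets, sm$treatment)
}

#' Fraction of missing data in a supermatrix
#'
#' Counts \code{?} cells (unsequenced/unsampled data) by default; alignment
#' gaps \code{-} are included only when \code{include_gaps = TRUE}.
#'
#' @param sm A \code{supermatrix} (or character matrix).
#' @param include_gaps Also count \code{-} cells.
#' @return Fraction in \[0, 1\].
#' @export
missing_fraction <- function(sm, include_gaps = FALSE) {
  m <- matrix_of(sm)
  if (length(m) == 0) stop_input("empty matrix")
  miss <- m == "?"
  if (include_gaps) miss <- miss | m == "-"
  sum(miss) / length(m)
}
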