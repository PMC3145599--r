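# Sequence matrix I/O: FASTA, relaxed PHYLIP, NEXUS (DATA + SETS blocks).
# Readers preserve '?' and '-' exactly and enforce the package's error
# contracts (ragged rows, duplicate labels, unknown symbols).

read_fasta_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop_input("not a FASTA file: ", path)
  idx <- cumsum(hdr)
  labels <- trimws(sub("^>", "", lines[hdr]))
  labels <- sub("\\s.*$", "", labels)
  seqs <- vapply(
    split(lines[!hdr], idx[!hdr]),
    function(x) paste(gsub("\\s", "", x), collapse = ""),
    character(1)
  )
  if (length(seqs) != length(labels)) stop_input("FASTA record with no sequence")
  names(seqs) <- labels
  seqs_to_matrix(seqs)
}

seqs_to_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    stop_input(
      "alignment rows differ in length (",
      paste(unique(lens), collapse = ", "), ")"
    )
  }
  if (anyDuplicated(names(seqs))) {
    stop_input(
      "duplicate taxon label(s): ",
      paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", ")
    )
  }
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

write_fasta_matrix <- function(m, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(m))) {
    s <- paste(m[i, ], collapse = "")
    chunks <- substring(s, seq(1, nchar(s), width),
                        pmin(seq(1, nchar(s), width) + width - 1L, nchar(s)))
    writeLines(c(paste0(">", rownames(m)[i]), chunks), con)
  }
  invisible(path)
}

# Relaxed PHYLIP: "ntax nchar" header, then whitespace-separated name and
# sequence (sequence may continue on following unlabeled lines; sequential).
read_phylip_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hd <- scan(text = lines[1], what = integer(), quiet = TRUE)
  if (length(hd) != 2) stop_input("not a PHYLIP file: ", path)
  ntax <- hd[1]; nchar_ <- hd[2]
  toks <- lines[-1]
  labels <- character(0); seqs <- character(0)
  for (ln in toks) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(seqs) < ntax || nchar(seqs[length(seqs)]) >= nchar_) {
      labels <- c(labels, parts[1])
      seqs <- c(seqs, paste(parts[-1], collapse = ""))
    } else {
      seqs[length(seqs)] <- paste0(seqs[length(seqs)],
                                   paste(parts, collapse = ""))
    }
  }
  if (length(seqs) != ntax) {
    stop_input("PHYLIP header declares ", ntax, " taxa, found ", length(seqs))
  }
  if (any(nchar(seqs) != nchar_)) {
    stop_input("PHYLIP sequence length mismatch with header")
  }
  names(seqs) <- labels
  seqs_to_matrix(seqs)
}

write_phylip_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(m), ncol(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(rownames(m)[i], paste(m[i, ], collapse = "")), con)
  }
  invisible(path)
}

read_nexus_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  if (!grepl("#NEXUS", txt, ignore.case = TRUE)) {
    stop_input("not a NEXUS file: ", path)
  }
  # MATRIX block: between "matrix" and ";"
  mstart <- grep("^\\s*matrix\\s*$", lines, ignore.case = TRUE)
  if (length(mstart) != 1) stop_input("NEXUS file lacks a MATRIX block")
  mend <- mstart + grep("^\\s*;", lines[(mstart + 1):length(lines)])[1]
  body <- lines[(mstart + 1):(mend - 1)]
  body <- body[nzchar(trimws(body))]
  labels <- character(0); seqs <- character(0)
  for (ln in body) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    lab <- gsub("^'|'$", "", parts[1])
    s <- paste(parts[-1], collapse = "")
    j <- match(lab, labels)
    if (is.na(j)) {
      labels <- c(labels, lab); seqs <- c(seqs, s)
    } else {
      seqs[j] <- paste0(seqs[j], s)  # interleaved continuation
    }
  }
  names(seqs) <- labels
  m <- seqs_to_matrix(seqs)
  # CHARSET lines: "charset name = a-b;" (1-based inclusive)
  charsets <- NULL
  cs_lines <- grep("^\\s*charset\\s", lines, ignore.case = TRUE, value = TRUE)
  if (length(cs_lines) > 0) {
    charsets <- list()
    for (ln in cs_lines) {
      mt <- regmatches(
        ln,
        regexec("charset\\s+(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)", ln,
                ignore.case = TRUE)
      )[[1]]
      if (length(mt) == 4) {
        charsets[[mt[2]]] <- c(as.integer(mt[3]) - 1L, as.integer(mt[4]))
      }
    }
    if (length(charsets) == 0) charsets <- NULL
  }
  list(matrix = m, charsets = charsets)
}

write_nexus_matrix <- function(m, path, charsets = NULL,
                               datatype = "dna") {
  con <- file(path, "w")
  on.exit(close(con))
  quote_lab <- function(x) ifelse(grepl("\\s", x), paste0("'", x, "'"), x)
  writeLines("#NEXUS", con)
  writeLines("", con)
  writeLines("begin data;", con)
  writeLines(
    sprintf("  dimensions ntax=%d nchar=%d;", nrow(m), ncol(m)), con
  )
  writeLines(
    sprintf("  format datatype=%s missing=? gap=-;", datatype), con
  )
  writeLines("matrix", con)
  labs <- format(quote_lab(rownames(m)))
  for (i in seq_len(nrow(m))) {
    writeLines(paste(labs[i], paste(m[i, ], collapse = "")), con)
  }
  writeLines(";", con)
  writeLines("end;", con)
  if (!is.null(charsets)) {
    writeLines("", con)
    writeLines("begin sets;", con)
    for (g in names(charsets)) {
      iv <- charsets[[g]]
      # half-open 0-based interval -> 1-based inclusive NEXUS range
      writeLines(sprintf("  charset %s = %d-%d;", g, iv[1] + 1L, iv[2]), con)
    }
    writeLines("end;", con)
  }
  invisible(path)
}

#' Read a gene alignment from file
#'
#' @param path Input file.
#' @param format One of \code{"fasta"}, \code{"phylip"}, \code{"nexus"}.
#' @param gene Gene label (defaults to the file name without extension).
#' @return A \code{gene_alignment}.
#' @export
read_gene_alignment <- function(path,
                                format = c("fasta", "phylip", "nexus"),
                                gene = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("file not found: ", path)
  if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(path))
  m <- switch(format,
    fasta = read_fasta_matrix(path),
    phylip = read_phylip_matrix(path),
    nexus = read_nexus_matrix(path)$matrix
  )
  gene_alignment(m, gene = gene)
}

#' Write a gene alignment to file
#'
#' @param aln A \code{gene_alignment}.
#' @param path Output file.
#' @param format One of \code{"fasta"}, \code{"phylip"}, \code{"nexus"}.
#' @return The path, invisibly.
#' @export
write_gene_alignment <- function(aln, path,
                                 format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  switch(format,
    fasta = write_fasta_matrix(aln$seq, path),
    phylip = write_phylip_matrix(aln$seq, path),
    nexus = write_nexus_matrix(aln$seq, path)
  )
  invisible(path)
}

#' Write a supermatrix to file
#'
#' NEXUS output carries a SETS block with per-gene charsets rendered as
#' 1-based inclusive ranges; FASTA and PHYLIP drop charset information.
#'
#' @param sm A \code{supermatrix}.
#' @param path Output file.
#' @param format One of \code{"nexus"}, \code{"phylip"}, \code{"fasta"}.
#' @return The path, invisibly.
#' @export
write_supermatrix <- function(sm, path,
                              format = c("nexus", "phylip", "fasta")) {
  format <- match.arg(format)
  if (length(sm$matrix) == 0) stop_input("empty matrix")
  switch(format,
    nexus = write_nexus_matrix(sm$matrix, path, charsets = sm$charsets),
    phylip = write_phylip_matrix(sm$matrix, path),
    fasta = write_fasta_matrix(sm$matrix, path)
  )
  invisible(path)
}

#' Read a supermatrix from file
#'
#' @param path Input file.
#' @param format One of \code{"nexus"}, \code{"phylip"}, \code{"fasta"}.
#' @return A \code{supermatrix}; charsets are recovered from the NEXUS SETS
#'   block when present, otherwise a single charset spanning all columns.
#' @export
read_supermatrix <- function(path, format = c("nexus", "phylip", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("file not found: ", path)
  if (format == "nexus") {
    nx <- read_nexus_matrix(path)
    check_dna_chars(nx$matrix, "supermatrix")
    supermatrix(nx$matrix, nx$charsets)
  } else {
    m <- switch(format,
      phylip = read_phylip_matrix(path),
      fasta = read_fasta_matrix(path)
    )
    check_dna_chars(m, "supermatrix")
    supermatrix(m)
  }
}
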