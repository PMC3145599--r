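# Shared low-level helpers: IUPAC nucleotide sets, RNG scoping, input checks.

# IUPAC code -> set of unambiguous nucleotides. '?' and '-' expand to the full
# set for recoding purposes but are distinguished everywhere counts matter.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  `?` = c("A", "C", "G", "T"), `-` = c("A", "C", "G", "T")
)

DNA_CHARS <- names(IUPAC_SETS)

# set of nucleotides (sorted) -> IUPAC code
iupac_encode <- local({
  tab <- c(
    A = "A", C = "C", G = "G", T = "T",
    AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
    CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N"
  )
  function(nts) {
    key <- paste(sort(unique(nts)), collapse = "")
    code <- tab[[key]]
    if (is.null(code)) stop("cannot encode nucleotide set: ", key)
    code
  }
})

iupac_expand <- function(ch) {
  s <- IUPAC_SETS[[ch]]
  if (is.null(s)) stop("unknown nucleotide character: '", ch, "'")
  s
}

#' Evaluate an expression with a temporarily seeded RNG
#'
#' Saves and restores the global random seed so that seeded package
#' operations do not perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Deterministic per-substream seed derivation, kept below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 65011) * 32749 + 7919 * index) %% 2147483647L
}

stop_input <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_dna_chars <- function(m, context = "alignment") {
  bad <- setdiff(unique(as.vector(m)), DNA_CHARS)
  if (length(bad) > 0) {
    stop_input(
      "unknown character(s) in ", context, ": ",
      paste0("'", bad, "'", collapse = ", ")
    )
  }
  invisible(TRUE)
}
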