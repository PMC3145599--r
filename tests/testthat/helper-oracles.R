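# Independent oracles and small fixture builders shared across tests.

# All 64 codons in a fixed order.
all_codons <- function() {
  nts <- c("A", "C", "G", "T")
  as.vector(outer(outer(nts, nts, paste0), nts, paste0))
}

# Standard genetic code as used by the oracles (independent of the
# package's Biostrings-backed table; hand-entered).
oracle_code <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# Oracle degen1 map: connected components of the graph on sense codons
# whose edges are single-position synonymous changes; per component, the
# positionwise minimal IUPAC cover.
oracle_degen1_map <- function() {
  iupac <- c(
    A = "A", C = "C", G = "G", T = "T",
    AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
    CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N"
  )
  sense <- names(oracle_code)[oracle_code != "*"]
  splitc <- strsplit(sense, "")
  adj <- outer(seq_along(sense), seq_along(sense), Vectorize(function(i, j) {
    i != j &&
      sum(splitc[[i]] != splitc[[j]]) == 1 &&
      oracle_code[sense[i]] == oracle_code[sense[j]]
  }))
  comp <- rep(NA_integer_, length(sense))
  cid <- 0L
  for (s in seq_along(sense)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  map <- character(length(sense))
  names(map) <- sense
  for (k in unique(comp)) {
    members <- sense[comp == k]
    chars <- do.call(rbind, strsplit(members, ""))
    cover <- paste(vapply(1:3, function(p) {
      key <- paste(sort(unique(chars[, p])), collapse = "")
      iupac[[key]]
    }, character(1)), collapse = "")
    map[members] <- cover
  }
  map
}

# Random in-frame gene alignment (unambiguous sense codons only).
random_gene <- function(n_taxa = 4, n_codons = 10, gene = "g",
                        seed = 1) {
  sense <- names(oracle_code)[oracle_code != "*"]
  withr::with_seed(seed, {
    m <- do.call(rbind, lapply(seq_len(n_taxa), function(i) {
      unlist(strsplit(sample(sense, n_codons, replace = TRUE), ""))
    }))
    rownames(m) <- sprintf("tax%02d", seq_len(n_taxa))
    gene_alignment(m, gene = gene)
  })
}

# Brute-force site log-likelihoods by enumeration over all internal-node
# state assignments (<= 5 taxa).
brute_site_loglik <- function(tree, m, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  E <- tree$edge
  nnode <- n + tree$Nnode
  pfn <- degenphy:::gtr_transition_fn(model$pi, model$Q)
  nt <- c("A", "C", "G", "T")
  sets <- degenphy:::IUPAC_SETS
  vapply(seq_len(ncol(m)), function(site) {
    lik_rate <- vapply(model$cat_rates, function(r) {
      Ps <- lapply(tree$edge.length, function(t) pfn(r * t))
      ints <- (n + 1):nnode
      grid <- expand.grid(rep(list(1:4), length(ints)))
      tot <- 0
      for (g in seq_len(nrow(grid))) {
        st <- integer(nnode)
        st[ints] <- as.integer(grid[g, ])
        p <- model$pi[st[E[nrow(E), 1]]]
        for (e in seq_len(nrow(E))) {
          par <- st[E[e, 1]]
          ch <- E[e, 2]
          if (ch <= n) {
            set <- sets[[m[tree$tip.label[ch], site]]]
            p <- p * sum(Ps[[e]][par, match(set, nt)])
          } else {
            p <- p * Ps[[e]][par, st[ch]]
          }
        }
        tot <- tot + p
      }
      tot
    }, numeric(1))
    avg <- mean(lik_rate)
    if (model$p_inv > 0) {
      memb <- vapply(m[tree$tip.label, site], function(ch) {
        as.numeric(nt %in% sets[[ch]])
      }, numeric(4))
      cl <- sum(model$pi * (rowSums(memb) == ncol(memb)))
      avg <- model$p_inv * cl + (1 - model$p_inv) * avg
    }
    log(avg)
  }, numeric(1))
}
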