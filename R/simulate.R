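# Two-layer codon simulation with lineage-specific GC3 targets.
#
# Layer 1: amino-acid states evolve along the tree under an exchangeable
# replacement process (uniform jump chain over the other 19 residues) at
# nonsyn_rate per unit branch length. Layer 2: each codon's synonymous
# identity is resampled as a Poisson process at syn_rate; a resampled codon
# is drawn from the lineage's codon-usage distribution, tilted so that the
# expected third-position G+C content meets the lineage's GC3 target.
# Branches whose descendant tips all belong to shifted_taxa use the shifted
# target. The result: strong among-taxon composition heterogeneity confined
# to synonymously variable sites, with near-homogeneous nonsynonymous sites
# and clean tree signal in the amino-acid layer.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulation configuration
#'
#' @param tree A \code{phylo} tree with branch lengths (time units; layer
#'   rates multiply these), or NULL to simulate a birth-death tree.
#' @param n_taxa Taxon count when simulating the tree.
#' @param gene_lengths Integer vector of per-gene codon counts.
#' @param nonsyn_rate Amino-acid replacement events per codon per unit
#'   branch length.
#' @param syn_rate Synonymous resampling events per codon per unit branch
#'   length.
#' @param base_gc3 Third-position G+C target in (0, 1) for unshifted
#'   lineages.
#' @param shifted_taxa Taxa whose subtending branches use
#'   \code{shifted_gc3}.
#' @param shifted_gc3 GC3 target for shifted lineages.
#' @param gc3_targets Optional named vector of per-taxon GC3 targets
#'   overriding \code{base_gc3} on those taxa's terminal branches
#'   (background compositional variation among lineages).
#' @param code Genetic code table id.
#' @param seed Integer root seed; per-gene substreams are derived
#'   deterministically.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(tree = NULL, n_taxa = 12L,
                       gene_lengths = c(500L, 550L, 484L, 500L, 482L, 484L),
                       nonsyn_rate = 1, syn_rate = 20,
                       base_gc3 = 0.4, shifted_taxa = character(0),
                       shifted_gc3 = 0.9, gc3_targets = NULL,
                       code = "1", seed = 1L) {
  if (nonsyn_rate < 0 || syn_rate < 0) stop_input("rates must be >= 0")
  for (g in c(base_gc3, shifted_gc3, gc3_targets)) {
    if (g <= 0 || g >= 1) stop_input("GC3 targets must be in (0, 1)")
  }
  structure(
    list(tree = tree, n_taxa = n_taxa, gene_lengths = gene_lengths,
         nonsyn_rate = nonsyn_rate, syn_rate = syn_rate,
         base_gc3 = base_gc3, shifted_taxa = shifted_taxa,
         shifted_gc3 = shifted_gc3, gc3_targets = gc3_targets,
         code = code, seed = seed),
    class = "sim_config"
  )
}

#' Simulate a birth-death tree
#'
#' @param n_taxa Number of tips (>= 3).
#' @param birth,death Birth-death rates.
#' @param seed Integer seed.
#' @return A \code{phylo} tree with positive branch lengths.
#' @export
simulate_tree <- function(n_taxa, birth = 1, death = 0, seed = 1L) {
  if (n_taxa < 3) stop_input("need at least 3 taxa")
  if (birth <= 0 || death < 0 || death >= birth) {
    stop_input("need birth > 0 and 0 <= death < birth")
  }
  tr <- with_seed(seed, ape::rphylo(n_taxa, birth = birth, death = death))
  tr$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  tr$edge.length[tr$edge.length <= 0] <- 1e-6
  tr
}

# Synonymous families (as codon character matrices) and per-family codon
# weights for a GC3 tilt g: weight(codon) = prod over the family's variable
# positions of g (G/C) or 1-g (A/T).
family_draw_tables <- function(code = "1") {
  key <- paste0("drawtab_", code)
  if (!is.null(the[[key]])) return(the[[key]])
  fams <- degen1_families(code)
  tab <- get_code_table(code)
  aa_of <- vapply(fams, function(f) unname(tab[f[1]]), character(1))
  # serine has two families; index families by amino acid
  by_aa <- split(seq_along(fams), aa_of)
  info <- lapply(fams, function(f) {
    chars <- do.call(rbind, strsplit(f, ""))
    varpos <- which(apply(chars, 2, function(x) length(unique(x)) > 1))
    gc_cnt <- rowSums(matrix(chars[, varpos, drop = FALSE] %in% c("G", "C"),
                             nrow = nrow(chars)))
    at_cnt <- length(varpos) - gc_cnt
    gc3 <- chars[, 3] %in% c("G", "C")
    list(codons = f, gc_cnt = gc_cnt, at_cnt = at_cnt, gc3 = gc3)
  })
  fam_of <- integer(0)
  for (fi in seq_along(fams)) {
    fam_of[fams[[fi]]] <- fi
  }
  out <- list(families = info, by_aa = by_aa, aa_of = aa_of,
              fam_of = fam_of)
  the[[key]] <- out
  out
}

# codon sampling weights for all sense codons of one amino acid at tilt g
aa_codon_weights <- function(aa, g, dt) {
  fam_idx <- dt$by_aa[[aa]]
  codons <- character(0)
  w <- numeric(0)
  for (fi in fam_idx) {
    f <- dt$families[[fi]]
    codons <- c(codons, f$codons)
    w <- c(w, g^f$gc_cnt * (1 - g)^f$at_cnt)
  }
  list(codons = codons, w = w / sum(w))
}

# Expected GC3 of a freshly drawn codon for a uniform random amino acid at
# tilt g. Used to solve for the effective tilt that realizes a GC3 target.
expected_gc3 <- function(g, dt) {
  e <- vapply(AA20, function(aa) {
    cw <- aa_codon_weights(aa, g, dt)
    gc3 <- vapply(cw$codons, function(cd) {
      substr(cd, 3, 3) %in% c("G", "C")
    }, logical(1))
    sum(cw$w * gc3)
  }, numeric(1))
  mean(e)
}

# Solve expected_gc3(g*) = target. Errors when the target lies outside the
# reachable range of the code (Met/Trp fix their third position).
solve_gc3_tilt <- function(target, code = "1") {
  dt <- family_draw_tables(code)
  lo <- expected_gc3(1e-6, dt)
  hi <- expected_gc3(1 - 1e-6, dt)
  if (target <= lo || target >= hi) {
    stop_input(sprintf(
      "GC3 target %.3f unreachable under this code (range %.3f-%.3f)",
      target, lo, hi
    ))
  }
  stats::uniroot(function(g) expected_gc3(g, dt) - target,
                 c(1e-6, 1 - 1e-6), tol = 1e-9)$root
}

# Draw codons for amino acids `aas` at tilt g (vectorized by amino acid).
# Used after a nonsynonymous event, which is free to choose among all of
# the new amino acid's codon families.
draw_codons <- function(aas, g, dt) {
  out <- character(length(aas))
  for (aa in unique(aas)) {
    idx <- which(aas == aa)
    cw <- aa_codon_weights(aa, g, dt)
    out[idx] <- cw$codons[
      sample.int(length(cw$codons), length(idx), replace = TRUE, prob = cw$w)
    ]
  }
  out
}

# Resample codons within their CURRENT synonymous family (a chain of
# single-site synonymous changes can never leave the family, so e.g. a
# TCN serine codon cannot become AGY synonymously).
draw_codons_within_family <- function(codons, g, dt) {
  out <- character(length(codons))
  fams <- dt$fam_of[codons]
  for (fi in unique(fams)) {
    idx <- which(fams == fi)
    f <- dt$families[[fi]]
    w <- g^f$gc_cnt * (1 - g)^f$at_cnt
    out[idx] <- f$codons[
      sample.int(length(f$codons), length(idx), replace = TRUE,
                 prob = w / sum(w))
    ]
  }
  out
}

# Apply k>=1 uniform amino-acid replacement events to each flagged site.
jump_aa <- function(aa, k) {
  for (step in seq_len(max(k))) {
    act <- which(k >= step)
    if (length(act) == 0) break
    cur <- aa[act]
    nxt <- AA20[sample.int(20L, length(act), replace = TRUE)]
    clash <- nxt == cur
    while (any(clash)) {
      nxt[clash] <- AA20[sample.int(20L, sum(clash), replace = TRUE)]
      clash <- nxt == cur & clash
    }
    aa[act] <- nxt
  }
  aa
}

#' Simulate a codon supermatrix with known ground truth
#'
#' Runs the two-layer codon simulation along the configuration's tree for
#' each gene (independent substreams derived from the root seed) and
#' concatenates the genes into a supermatrix.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List with \code{supermatrix}, and \code{manifest} (true tree,
#'   per-taxon realized GC3, per-gene parameters, effective tilts, seed).
#' @export
simulate_supermatrix <- function(cfg) {
  tree <- cfg$tree
  if (is.null(tree)) {
    tree <- simulate_tree(cfg$n_taxa, seed = derive_seed(cfg$seed, 0L))
  }
  if (length(setdiff(cfg$shifted_taxa, tree$tip.label)) > 0) {
    stop_input("shifted_taxa not in tree")
  }
  dt <- family_draw_tables(cfg$code)
  tilt_base <- solve_gc3_tilt(cfg$base_gc3, cfg$code)
  tilt_shift <- if (length(cfg$shifted_taxa) > 0) {
    solve_gc3_tilt(cfg$shifted_gc3, cfg$code)
  } else {
    tilt_base
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- length(tr$tip.label)
  E <- tr$edge
  root <- E[nrow(E), 1]
  # a branch uses the shifted tilt when all its descendant tips are shifted
  desc <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(E))) {
    desc[[E[e, 1]]] <- c(desc[[E[e, 1]]], desc[[E[e, 2]]])
  }
  edge_shifted <- vapply(seq_len(nrow(E)), function(e) {
    d <- desc[[E[e, 2]]]
    length(cfg$shifted_taxa) > 0 && all(d %in% cfg$shifted_taxa)
  }, logical(1))
  # background per-taxon targets apply on terminal branches only
  edge_tilt <- rep(NA_real_, nrow(E))
  if (!is.null(cfg$gc3_targets)) {
    bad <- setdiff(names(cfg$gc3_targets), tr$tip.label)
    if (length(bad) > 0) stop_input("gc3_targets taxa not in tree: ",
                                    paste(bad, collapse = ", "))
    for (e in seq_len(nrow(E))) {
      ch <- E[e, 2]
      if (ch <= n && tr$tip.label[ch] %in% names(cfg$gc3_targets) &&
          !edge_shifted[e]) {
        edge_tilt[e] <- solve_gc3_tilt(
          cfg$gc3_targets[[tr$tip.label[ch]]], cfg$code
        )
      }
    }
  }
  genes <- vector("list", length(cfg$gene_lengths))
  for (gi in seq_along(cfg$gene_lengths)) {
    ncod <- cfg$gene_lengths[gi]
    genes[[gi]] <- with_seed(derive_seed(cfg$seed, gi), {
      aa_states <- vector("list", n + tr$Nnode)
      cod_states <- vector("list", n + tr$Nnode)
      aa_states[[root]] <- AA20[sample.int(20L, ncod, replace = TRUE)]
      cod_states[[root]] <- draw_codons(aa_states[[root]], tilt_base, dt)
      for (e in rev(seq_len(nrow(E)))) {  # preorder traversal
        par <- E[e, 1]; ch <- E[e, 2]
        b <- tr$edge.length[e]
        g_here <- if (edge_shifted[e]) {
          tilt_shift
        } else if (!is.na(edge_tilt[e])) {
          edge_tilt[e]
        } else {
          tilt_base
        }
        k_aa <- stats::rpois(ncod, cfg$nonsyn_rate * b)
        k_syn <- stats::rpois(ncod, cfg$syn_rate * b)
        aa <- aa_states[[par]]
        if (any(k_aa > 0)) aa <- jump_aa(aa, k_aa)
        cod <- cod_states[[par]]
        redraw_aa <- which(k_aa > 0)
        redraw_syn <- which(k_aa == 0 & k_syn > 0)
        if (length(redraw_aa) > 0) {
          cod[redraw_aa] <- draw_codons(aa[redraw_aa], g_here, dt)
        }
        if (length(redraw_syn) > 0) {
          cod[redraw_syn] <- draw_codons_within_family(cod[redraw_syn],
                                                       g_here, dt)
        }
        aa_states[[ch]] <- aa
        cod_states[[ch]] <- cod
      }
      m <- do.call(rbind, lapply(seq_len(n), function(i) {
        strsplit(paste(cod_states[[i]], collapse = ""), "")[[1]]
      }))
      rownames(m) <- tr$tip.label
      m[order(rownames(m)), , drop = FALSE]
    })
    genes[[gi]] <- gene_alignment(genes[[gi]], gene = sprintf("gene%02d", gi))
  }
  sm <- concatenate_genes(genes)
  nt3 <- extract_treatment(sm, "nt3")$matrix
  gc3 <- apply(nt3, 1, function(row) {
    mean(row[row %in% NT4] %in% c("G", "C"))
  })
  manifest <- list(
    tree = ape::write.tree(tree),
    seed = cfg$seed,
    gene_lengths = cfg$gene_lengths,
    nonsyn_rate = cfg$nonsyn_rate,
    syn_rate = cfg$syn_rate,
    base_gc3 = cfg$base_gc3,
    shifted_taxa = cfg$shifted_taxa,
    shifted_gc3 = cfg$shifted_gc3,
    gc3_targets = cfg$gc3_targets,
    tilt_base = tilt_base,
    tilt_shift = tilt_shift,
    realized_gc3 = gc3
  )
  list(supermatrix = sm, manifest = manifest, tree = tree, genes = genes)
}

# Fixed 12-taxon truth tree for the rogue-taxon benchmark: a deep outgroup
# on a long stem, radiation-like short internal branches, and a nested
# fast-evolving taxon (ROGUE) whose terminal branch carries the extreme
# composition shift.
ROGUE_TREE <- paste0(
  "(OUT:0.5,(((t01:0.1,t02:0.1):0.015,(t03:0.1,(ROGUE:0.3,t04:0.1)",
  ":0.015):0.015):0.015,((t05:0.1,t06:0.1):0.015,((t07:0.1,t08:0.1):0.015,",
  "(t09:0.1,t10:0.1):0.015):0.015):0.015):0.015);"
)

# Background third-position G+C targets for the rogue benchmark: moderate
# lineage-to-lineage GC3 variation (as multi-gene insect data sets show at
# synonymous sites) on top of which the ROGUE taxon is extreme (0.9).
ROGUE_BACKGROUND_GC3 <- c(t07 = 0.75, t09 = 0.65, t02 = 0.3)

#' Benchmark fixture presets
#'
#' \describe{
#'   \item{rogue_taxon}{12 taxa, 6 genes (3,000 codons), one taxon
#'     (\code{ROGUE}) with GC3 target 0.9 against a 0.4 background with
#'     moderate lineage-to-lineage GC3 variation, nested inside the ingroup
#'     with a long terminal branch; third positions are heavily resampled
#'     (near-saturated) while the amino-acid layer carries clean tree
#'     signal.}
#'   \item{homogeneous_null}{The same tree and rates with a single shared
#'     GC3 target and no shift; for calibration.}
#'   \item{design_abcd}{20 taxa x 8 genes homogeneous matrix plus the four
#'     taxon-by-gene sampling-design masks: A = taxon subset x gene subset,
#'     B = taxon subset x all genes, C = all taxa x gene subset, D = B and
#'     C combined, leaving a missing block.}
#' }
#'
#' @param preset Preset name.
#' @param seed Integer seed.
#' @param dir Optional directory; when given, writes per-gene FASTA,
#'   per-design NEXUS supermatrices, the true tree (newick) and the
#'   manifest (JSON).
#' @return List with \code{supermatrix}, \code{tree}, \code{manifest},
#'   \code{genes}, and for \code{design_abcd} also \code{designs} (list of
#'   \code{design_spec}) and \code{masked} (per-design supermatrices).
#' @export
make_benchmark_fixture <- function(preset = c("rogue_taxon", "design_abcd",
                                              "homogeneous_null"),
                                   seed = 1L, dir = NULL) {
  preset <- match.arg(preset)
  if (preset %in% c("rogue_taxon", "homogeneous_null")) {
    rogue <- preset == "rogue_taxon"
    cfg <- sim_config(
      tree = ape::read.tree(text = ROGUE_TREE),
      shifted_taxa = if (rogue) "ROGUE" else character(0),
      gc3_targets = if (rogue) ROGUE_BACKGROUND_GC3 else NULL,
      seed = seed
    )
    out <- simulate_supermatrix(cfg)
    out$config <- cfg
  } else {
    tree <- simulate_tree(20L, seed = derive_seed(seed, 99L))
    # rescale to radiation-like depth comparable to the fixed benchmark tree
    tree$edge.length <- tree$edge.length *
      (0.25 / max(ape::node.depth.edgelength(tree)))
    cfg <- sim_config(
      tree = tree, n_taxa = 20L,
      gene_lengths = rep.int(110L, 8L),
      seed = seed
    )
    out <- simulate_supermatrix(cfg)
    out$config <- cfg
    taxa <- sort(tree$tip.label)
    sub_taxa <- taxa[seq_len(10L)]
    genes <- names(out$supermatrix$charsets)
    sub_genes <- genes[1:4]
    cov_sub <- stats::setNames(
      rep(list(sub_genes), length(taxa)), taxa
    )
    cov_d <- stats::setNames(lapply(taxa, function(tx) {
      if (tx %in% sub_taxa) genes else sub_genes
    }), taxa)
    designs <- list(
      A = design_spec("A", sub_taxa, cov_sub[sub_taxa]),
      B = design_spec("B", sub_taxa),
      C = design_spec("C", taxa, cov_sub),
      D = design_spec("D", taxa, cov_d)
    )
    out$designs <- designs
    out$masked <- lapply(designs, function(d) apply_design(out$supermatrix, d))
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (g in out$genes) {
      write_gene_alignment(g, file.path(dir, paste0(g$gene, ".fasta")),
                           format = "fasta")
    }
    if (!is.null(out$masked)) {
      for (nm in names(out$masked)) {
        write_supermatrix(out$masked[[nm]],
                          file.path(dir, paste0("design_", nm, ".nex")))
      }
    } else {
      write_supermatrix(out$supermatrix, file.path(dir, "supermatrix.nex"))
    }
    ape::write.tree(out$tree, file.path(dir, "true_tree.nwk"))
    jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
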