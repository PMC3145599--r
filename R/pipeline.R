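# Full-analysis orchestration: designs x treatments, composition reports,
# NJ + bootstrap trees, support comparison across designs, and AU tests.

#' Verbal category for a bootstrap support value
#'
#' 70-79\% is "moderate", 80-89\% "strong", >= 90\% "very strong";
#' 50-69\% is "weak" and below 50\% "unsupported".
#'
#' @param bp Bootstrap percentage (vectorized).
#' @return Character vector of categories.
#' @export
support_category <- function(bp) {
  out <- rep(NA_character_, length(bp))
  out[!is.na(bp) & bp < 50] <- "unsupported"
  out[!is.na(bp) & bp >= 50 & bp < 70] <- "weak"
  out[!is.na(bp) & bp >= 70 & bp < 80] <- "moderate"
  out[!is.na(bp) & bp >= 80 & bp < 90] <- "strong"
  out[!is.na(bp) & bp >= 90] <- "very strong"
  out
}

#' Compare focal-clade support across designs and treatments
#'
#' Builds the design-by-treatment support table: one row per focal clade,
#' one column per (design, treatment) combination. Cells hold the
#' bootstrap percentage of the matching bipartition (restricted to the
#' design's taxa), \code{"<50"} when the bipartition is absent from the
#' supported tree or below 50, and \code{"N/A"} when fewer than two of the
#' clade's taxa are sampled in the design.
#'
#' @param results Named list (names like \code{"D/degen1"}) of trees with
#'   support node labels (see \code{\link{support_from_replicates}}).
#' @param focal_clades Named list of taxon sets.
#' @return Data frame: first column \code{clade}, then one column per
#'   result.
#' @export
compare_designs <- function(results, focal_clades) {
  if (length(results) == 0) stop_input("no results")
  if (is.null(names(results))) stop_input("results must be named")
  out <- data.frame(clade = names(focal_clades), stringsAsFactors = FALSE)
  for (nm in names(results)) {
    tree <- results[[nm]]
    col <- vapply(focal_clades, function(taxa) {
      present <- intersect(taxa, tree$tip.label)
      if (length(present) < 2) return("N/A")
      s <- clade_support(tree, taxa)
      if (is.na(s) || s < 50) "<50" else trimws(formatC(s, format = "fg", digits = 4))
    }, character(1))
    out[[nm]] <- unname(col)
  }
  out
}

#' Run the full diagnostic analysis
#'
#' End-to-end pipeline on a simulated benchmark or user-supplied
#' supermatrix: builds the requested designs, recodes each under the
#' requested character treatments, runs compositional chi-square tests
#' (whole character set and after eliminating degen1-invariable sites),
#' infers NJ trees from GTR-ML and Euclidean compositional distances with
#' bootstrap support, tabulates focal-clade support across designs and
#' treatments, and runs AU tests for focal-clade constraints. All outputs
#' are written to \code{out_dir} and returned.
#'
#' @param preset Benchmark preset name (see
#'   \code{\link{make_benchmark_fixture}}), ignored when \code{sm} given.
#' @param sm Optional \code{supermatrix} to analyze instead of a preset.
#' @param designs Optional named list of \code{design_spec}; defaults to
#'   the preset's designs or the full matrix as design "full".
#' @param treatments Character treatments to run.
#' @param focal_clades Named list of taxon sets; defaults, for the rogue
#'   preset, to the rogue-plus-sister clade and the rogue-free clade.
#' @param boot_reps Bootstrap replicates (default 200).
#' @param au_reps RELL replicates per scale.
#' @param seed Integer seed for all resampling.
#' @param out_dir Report directory (created; existing files overwritten).
#' @param run_au Run the AU-test stage (branch-length optimization on NNI
#'   candidates; the slowest stage).
#' @return List with \code{composition} (data frame),
#'   \code{support_report}, \code{trees} (named list), \code{au} (data
#'   frame or NULL), \code{manifest}.
#' @export
run_full_analysis <- function(preset = "rogue_taxon", sm = NULL,
                              designs = NULL,
                              treatments = c("nt123", "degen1",
                                             "noLRall1_nt2"),
                              focal_clades = NULL,
                              boot_reps = 200L, au_reps = 2000L,
                              seed = 1L, out_dir = tempfile("degenphy_run"),
                              run_au = TRUE) {
  manifest <- list(seed = seed, boot_reps = boot_reps, au_reps = au_reps,
                   treatments = treatments)
  truth <- NULL
  if (is.null(sm)) {
    fx <- make_benchmark_fixture(preset, seed = seed)
    sm <- fx$supermatrix
    truth <- fx$tree
    manifest$preset <- preset
    manifest$simulation <- fx$manifest
    if (!is.null(fx$designs)) designs <- fx$designs
  }
  if (is.null(designs)) {
    designs <- list(full = design_spec("full", sort(rownames(sm$matrix))))
  }
  if (is.null(focal_clades)) {
    focal_clades <- if ("ROGUE" %in% rownames(sm$matrix)) {
      list(rogue_sister = c("ROGUE", "t04"),
           rogue_free_clade = c("t05", "t06", "t07", "t08", "t09", "t10"))
    } else {
      list()
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # composition report (Table 3 layout): chi-square per design x charset,
  # whole set and after eliminating degen1-invariable sites
  comp_rows <- list()
  trees <- list()
  rep_id <- 0L
  for (dn in names(designs)) {
    smd <- apply_design(sm, designs[[dn]])
    inv_keep <- degen1_invariant_mask(smd)
    for (cs in c("nt3", "noLRall1_nt2")) {
      rec <- extract_treatment(smd, cs)
      for (drop_inv in c(FALSE, TRUE)) {
        keep <- if (drop_inv) {
          inv_keep[rec$source_columns + 1L]
        } else {
          NULL
        }
        ct <- composition_table(rec, keep_columns = keep)
        hr <- tryCatch(chisq_homogeneity(ct), error = function(e) NULL)
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          design = dn, charset = cs,
          invariable_removed = drop_inv,
          n_taxa = if (is.null(hr)) NA else hr$n_taxa,
          characters = ct$total_characters,
          statistic = if (is.null(hr)) NA else hr$statistic,
          df = if (is.null(hr)) NA else hr$df,
          p_value = if (is.null(hr)) NA else hr$p_value,
          stringsAsFactors = FALSE
        )
      }
    }
    # trees per treatment: GTR-ML distance NJ with bootstrap support, and
    # the Euclidean compositional distance NJ for the untreated matrix
    for (tt in treatments) {
      rep_id <- rep_id + 1L
      rec <- extract_treatment(smd, tt)
      # model parameters estimated once per (design, treatment); bootstrap
      # replicates reuse them and re-estimate distances only
      prm <- suppressWarnings(estimate_gtr_params(rec$matrix))
      tree_fun <- function(x) {
        neighbor_joining(suppressWarnings(gtr_ml_distance(x, prm)))
      }
      unit <- if (tt %in% c("nt123", "degen1")) "codon" else "site"
      tr <- bootstrap_support(rec$matrix, tree_fun, n = boot_reps,
                              unit = if (tt == "noLRall1_nt2") "site" else unit,
                              seed = derive_seed(seed, rep_id))
      key <- paste(dn, tt, sep = "/")
      trees[[key]] <- tr
      ape::write.tree(tr, file.path(out_dir, paste0(
        "nj_", dn, "_", tt, ".nwk"
      )))
    }
    rep_id <- rep_id + 1L
    comp_tree <- neighbor_joining(
      euclidean_comp_distances(composition_table(extract_treatment(smd, "nt3")))
    )
    trees[[paste(dn, "comp_nt3", sep = "/")]] <- comp_tree
    ape::write.tree(comp_tree,
                    file.path(out_dir, paste0("njcomp_", dn, "_nt3.nwk")))
  }
  composition <- do.call(rbind, comp_rows)
  utils::write.table(composition,
                     file.path(out_dir, "composition_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  support_report <- NULL
  if (length(focal_clades) > 0) {
    supported <- trees[!grepl("/comp_nt3$", names(trees))]
    support_report <- compare_designs(supported, focal_clades)
    utils::write.table(support_report,
                       file.path(out_dir, "support_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  au <- NULL
  if (run_au && length(focal_clades) > 0) {
    dn <- names(designs)[length(designs)]
    smd <- apply_design(sm, designs[[dn]])
    rec <- extract_treatment(smd, "degen1")
    prm <- suppressWarnings(estimate_gtr_params(rec))
    d <- suppressWarnings(gtr_ml_distance(rec, prm))
    cands <- candidate_topologies(d)
    model <- gtr_model(pi = prm$pi, rates = prm$rates)
    # cheap pre-scoring of candidates (single optimization cycle), then a
    # full-precision AU test of best-with vs best-without each clade
    pre_ll <- vapply(cands, function(tr) {
      attr(suppressWarnings(
        optimize_branch_lengths(tr, rec, model, max_cycles = 1L)
      ), "logLik")
    }, numeric(1))
    au_rows <- list()
    for (cl in names(focal_clades)) {
      sel <- vapply(cands, function(tr) has_clade(tr, focal_clades[[cl]]),
                    logical(1))
      if (!any(sel) || all(sel)) next
      best_with <- cands[sel][[which.max(pre_ll[sel])]]
      best_without <- cands[!sel][[which.max(pre_ll[!sel])]]
      res <- au_test_trees(list(best_with, best_without), rec, model,
                           reps = au_reps,
                           seed = derive_seed(seed, 1000L + length(au_rows)))
      au_rows[[cl]] <- data.frame(
        constraint = cl, design = dn,
        tree = c("best_with_clade", "best_without_clade")[
          seq_len(nrow(res))],
        logLik = res$logLik, p_au = res$p_au,
        stringsAsFactors = FALSE
      )
    }
    if (length(au_rows) > 0) {
      au <- do.call(rbind, au_rows)
      rownames(au) <- NULL
      utils::write.table(au, file.path(out_dir, "au_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  manifest$versions <- list(
    degenphy = as.character(utils::packageVersion("degenphy")),
    R = paste(R.version$major, R.version$minor, sep = ".")
  )
  if (!is.null(truth)) manifest$true_tree <- ape::write.tree(truth)
  jsonlite::write_json(manifest, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  list(composition = composition, support_report = support_report,
       trees = trees, au = au, manifest = manifest, out_dir = out_dir)
}
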