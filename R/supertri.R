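# SuperTRI support aggregation: bootstrap of the weighted MRP matrix (SBP),
# reproduction indices across window trees, node-signal classification and
# robust-conflict detection.

# splits credited to one bootstrap replicate: those present in every
# equally-parsimonious optimum (strict consensus of the optimum set), so a
# replicate that under-constrains part of the topology does not inject
# arbitrary resolutions; heuristic searches yield a single tree and use it
replicate_splits <- function(tree, taxa) {
  optima <- attr(tree, "optima")
  if (is.null(optima) || length(optima) <= 1L) {
    return(tree_splits(tree, taxa))
  }
  Reduce(intersect, lapply(optima, tree_splits, taxa = taxa))
}

#' Bootstrap supertree support (SBP) from a weighted MRP matrix
#'
#' Characters are resampled with replacement (weights travel with the
#' characters), a minimum-length supertree is found per replicate, and the
#' SuperTRI bootstrap percentage of a split is 100 x the fraction of
#' replicate optima containing it. A 50% majority-rule consensus of the
#' replicate trees is also returned.
#'
#' @param mrp a `mito_mrp`.
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param search search mode passed to [mrp_supertree()].
#' @param n_restarts heuristic restarts per replicate (default 2; the
#'   full-data search can afford more).
#' @return list with `sbp` (data.frame `bipartition`, `sbp` in \[0, 100\],
#'   sorted decreasing), `consensus` (50% majority-rule `phylo`), `n_reps`.
#' @export
supertri_bootstrap <- function(mrp, n_reps = 1000L, seed = 1L,
                               search = "auto", n_restarts = 2L) {
  stopifnot(ncol(mrp$X) >= 1L)
  taxa <- mrp$taxa
  nchar <- ncol(mrp$X)
  trees <- withr_seed(seed, {
    rep_seeds <- sample.int(.Machine$integer.max, n_reps)
    lapply(seq_len(n_reps), function(r) {
      idx <- sample.int(nchar, nchar, replace = TRUE)
      boot <- structure(list(X = mrp$X[, idx, drop = FALSE],
                             weights = mrp$weights[idx],
                             provenance = mrp$provenance[idx, , drop = FALSE],
                             taxa = taxa), class = "mito_mrp")
      mrp_supertree(boot, search = search, seed = rep_seeds[r],
                    n_restarts = n_restarts)
    })
  })
  counts <- table(unlist(lapply(trees, replicate_splits,
                                taxa = sort(taxa))))
  sbp <- data.frame(bipartition = names(counts),
                    sbp = 100 * as.numeric(counts) / n_reps,
                    stringsAsFactors = FALSE)
  sbp <- sbp[order(-sbp$sbp, sbp$bipartition), , drop = FALSE]
  rownames(sbp) <- NULL
  cons <- tree_from_splits(sbp$bipartition[sbp$sbp > 50], sort(taxa))
  list(sbp = sbp, consensus = cons, n_reps = n_reps)
}

# Build a (possibly multifurcating) tree from mutually compatible canonical
# splits. Rooting at the reference taxon turns every canonical ingroup into
# a clade; compatible clades form a laminar family, so they nest directly.
tree_from_splits <- function(keys, taxa) {
  clades <- lapply(keys, split_members)
  clades <- clades[order(-lengths(clades))]
  build <- function(members, cl) {
    inside <- cl[vapply(cl, function(x) all(x %in% members), logical(1))]
    tops <- inside[!vapply(seq_along(inside), function(i)
      any(vapply(seq_along(inside), function(j)
        i != j && all(inside[[i]] %in% inside[[j]]) &&
          length(inside[[j]]) > length(inside[[i]]), logical(1))),
      logical(1))]
    used <- unlist(tops)
    parts <- c(lapply(tops, function(m)
                 build(m, inside[vapply(inside, function(x)
                   all(x %in% m) && length(x) < length(m), logical(1))])),
               as.list(setdiff(members, used)))
    if (length(parts) == 1L) return(parts[[1L]])
    paste0("(", paste(unlist(parts), collapse = ","), ")")
  }
  nwk <- build(taxa, clades)
  ape::read.tree(text = paste0(nwk, ";"))
}

#' Reproduction index of a bipartition across window trees
#'
#' Counts in how many of the per-window (consensus) trees the split occurs.
#'
#' @param bipartition canonical split key (see [canonical_split()]).
#' @param window_trees list of `phylo` trees, one per window.
#' @return integer count.
#' @export
reproduction_index <- function(bipartition, window_trees) {
  if (inherits(window_trees, "phylo")) window_trees <- list(window_trees)
  taxa <- sort(window_trees[[1L]]$tip.label)
  sum(vapply(window_trees,
             function(tr) bipartition %in% tree_splits(tr, taxa),
             logical(1)))
}

#' Classify the phylogenetic signal behind a node
#'
#' A node robust in the main analysis (`pp >= 0.95`) that is recovered with
#' high supertree bootstrap (`sbp >= 95`) and reproduced in at least half
#' of the window trees carries signal spread along the whole genome
#' (`"signal_genome_wide"`). A node with `sbp < 95` reproduced in fewer
#' than half of the window trees has weak or locally confined signal
#' (`"signal_weak_or_local"`). Everything else is `"intermediate"`.
#'
#' @param pp support in the main whole-alignment analysis, in \[0, 1\].
#' @param sbp SuperTRI bootstrap percentage, in \[0, 100\].
#' @param nrep reproduction index (0..n_windows).
#' @param n_windows number of windows (default 10).
#' @return classification label (character scalar); vectorized over inputs.
#' @export
classify_node <- function(pp, sbp, nrep, n_windows = 10L) {
  half <- ceiling(n_windows / 2)
  ifelse(pp >= 0.95 & sbp >= 95 & nrep >= half, "signal_genome_wide",
         ifelse(sbp < 95 & nrep < half, "signal_weak_or_local",
                "intermediate"))
}

#' Detect robust topological conflict (suspected contamination)
#'
#' A split strongly supported in the main analysis (`pp >= pp_min`) that is
#' incompatible with a split of high supertree bootstrap (`sbp >= sbp_min`)
#' signals that at least one genome may be a partial chimera (contamination
#' or a nuclear mitochondrial insertion): the whole-alignment signal and the
#' window-aggregated signal then disagree robustly.
#'
#' @param main_splits data.frame with `bipartition`, `pp`.
#' @param sbp_table data.frame with `bipartition`, `sbp` (from
#'   [supertri_bootstrap()]).
#' @param taxa leaf universe.
#' @param pp_min,sbp_min thresholds (0.95 and 95).
#' @return data.frame of conflicting pairs: `main_bipartition`, `pp`,
#'   `super_bipartition`, `sbp`.
#' @export
detect_conflicts <- function(main_splits, sbp_table, taxa,
                             pp_min = 0.95, sbp_min = 95) {
  hi_main <- main_splits[main_splits$pp >= pp_min, , drop = FALSE]
  hi_sup <- sbp_table[sbp_table$sbp >= sbp_min, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(hi_main))) {
    for (j in seq_len(nrow(hi_sup))) {
      if (!splits_compatible(hi_main$bipartition[i],
                             hi_sup$bipartition[j], taxa)) {
        rows[[length(rows) + 1L]] <- data.frame(
          main_bipartition = hi_main$bipartition[i],
          pp = hi_main$pp[i],
          super_bipartition = hi_sup$bipartition[j],
          sbp = hi_sup$sbp[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(main_bipartition = character(0), pp = numeric(0),
                      super_bipartition = character(0), sbp = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Assemble the per-node support table
#'
#' Joins, for every split supported in the main analysis, its main support
#' (PP), SuperTRI bootstrap percentage (SBP), reproduction index across the
#' window trees, and the signal classification; conflicts detected between
#' the main analysis and the supertree are attached as attribute
#' `conflicts` and flagged per split in `conflict_suspect`.
#'
#' @param main_splits data.frame `bipartition`, `pp` (main-analysis splits
#'   with their support).
#' @param sbp_table data.frame from [supertri_bootstrap()].
#' @param window_trees list of per-window consensus trees.
#' @param taxa leaf universe.
#' @param n_windows number of windows; defaults to `length(window_trees)`.
#' @return data.frame `bipartition`, `pp`, `sbp`, `nrep`, `label`,
#'   `conflict_suspect`, with attribute `conflicts`.
#' @export
node_support_table <- function(main_splits, sbp_table, window_trees, taxa,
                               n_windows = length(window_trees)) {
  sbp <- sbp_table$sbp[match(main_splits$bipartition,
                             sbp_table$bipartition)]
  sbp[is.na(sbp)] <- 0
  nrep <- vapply(main_splits$bipartition, reproduction_index,
                 integer(1), window_trees = window_trees)
  out <- data.frame(bipartition = main_splits$bipartition,
                    pp = main_splits$pp, sbp = sbp, nrep = nrep,
                    label = classify_node(main_splits$pp, sbp, nrep,
                                          n_windows),
                    stringsAsFactors = FALSE)
  conf <- detect_conflicts(main_splits, sbp_table, taxa)
  out$conflict_suspect <- out$bipartition %in% conf$main_bipartition
  attr(out, "conflicts") <- conf
  rownames(out) <- NULL
  out
}
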