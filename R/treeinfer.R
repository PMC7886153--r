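# Desk-scale per-window tree inference: neighbor joining on p-distances with
# column bootstrap, plus import of externally produced tree samples.

#' Neighbor-joining tree from a p-distance matrix
#'
#' Standard neighbor-joining agglomeration (ape's implementation), with
#' negative branch lengths clamped to zero and the deficit transferred to
#' the adjacent branch so path lengths are preserved. Deterministic given
#' the input.
#'
#' @param dm a [p_distance_matrix()] result, or a plain symmetric matrix
#'   with dimnames.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "mito_distmat")) dm$d else as.matrix(dm)
  if (anyNA(d)) {
    stop("distance matrix contains undefined entries", call. = FALSE)
  }
  if (nrow(d) < 3L) stop("need at least 3 taxa", call. = FALSE)
  tr <- ape::nj(d)
  clamp_negative_branches(tr)
}

# Zero out negative branch lengths; the deficit is moved to the adjacent
# branch (the sibling edge at the same node), preserving tip-to-tip paths
# along that cherry. Standard post-processing for NJ.
clamp_negative_branches <- function(tr) {
  el <- tr$edge.length
  neg <- which(el < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sibs <- which(tr$edge[, 1L] == parent & seq_along(el) != e)
    if (length(sibs)) {
      el[sibs[1L]] <- el[sibs[1L]] + el[e]
    }
    el[e] <- 0
  }
  el[el < 0] <- 0
  tr$edge.length <- el
  tr
}

#' Bootstrap NJ trees by column resampling
#'
#' Resamples alignment columns with replacement `n_reps` times and builds a
#' neighbor-joining tree per replicate. Reproducible under `seed`.
#'
#' @param aln a `mito_alignment`.
#' @param n_reps number of replicates (>= 1).
#' @param seed integer RNG seed.
#' @return an object of class `mito_treesample`: list with `trees`
#'   (a `multiPhylo`), `label` and `n`.
#' @export
bootstrap_trees <- function(aln, n_reps = 100L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  L <- aln_length(aln)
  trees <- withr_seed(seed, {
    lapply(seq_len(n_reps), function(i) {
      cols <- sample.int(L, L, replace = TRUE)
      sub <- aln
      sub$matrix <- aln$matrix[, cols, drop = FALSE]
      nj_tree(p_distance_matrix(sub))
    })
  })
  tree_sample(trees, label = "bootstrap")
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a tree sample
#'
#' @param trees list of `phylo` trees (or a `multiPhylo`) over one leaf set.
#' @param label window or source label.
#' @return a `mito_treesample`.
#' @export
tree_sample <- function(trees, label = NA_character_) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    tl <- sort(trees[[i]]$tip.label)
    if (!identical(tl, ref)) {
      diff <- sort(union(setdiff(tl, ref), setdiff(ref, tl)))
      stop("leaf-set mismatch across trees; symmetric difference: ",
           paste(diff, collapse = ", "), call. = FALSE)
    }
  }
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, label = label, n = length(trees)),
            class = "mito_treesample")
}

#' @export
print.mito_treesample <- function(x, ...) {
  cat("Tree sample '", x$label, "': ", x$n, " trees over ",
      length(x$trees[[1L]]$tip.label), " leaves\n", sep = "")
  invisible(x)
}

#' Read trees from Newick or NEXUS
#'
#' Newick files hold one tree per line; NEXUS trees blocks may carry a
#' translate table, which is honored. All trees must share one leaf set.
#'
#' @param path file path.
#' @param format `"newick"`, `"nexus"`, or `"auto"` (by extension).
#' @param label sample label.
#' @return a `mito_treesample`.
#' @export
read_trees <- function(path, format = c("auto", "newick", "nexus"),
                       label = basename(path)) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("nex", "nexus", "nxs", "t", "trees"))
      "nexus" else "newick"
  }
  trees <- if (format == "nexus") ape::read.nexus(path)
           else ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  tree_sample(trees, label = label)
}

#' Write trees as Newick, one per line
#'
#' @param ts a `mito_treesample` or list of trees.
#' @param path output path.
#' @export
write_trees <- function(ts, path) {
  trees <- if (inherits(ts, "mito_treesample")) ts$trees else ts
  ape::write.tree(trees, file = path)
  invisible(path)
}
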