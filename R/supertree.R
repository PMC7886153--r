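# Minimum-weighted-length supertree search over the MRP matrix: exhaustive
# enumeration by stepwise leaf insertion (small n), branch-and-bound on the
# same recursion, and NNI hill-climbing with random restarts for larger n.

# Unrooted binary topologies are manipulated as nested lists (a leaf is a
# character scalar; an internal vertex a list of subtrees; the top level is
# the basal trifurcation) and converted to phylo via newick when scored.

nested_newick <- function(x) {
  if (is.character(x)) return(x)
  paste0("(", paste(vapply(x, nested_newick, character(1)), collapse = ","),
         ")")
}

nested_to_phylo <- function(x) {
  ape::read.tree(text = paste0(nested_newick(x), ";"))
}

# all child slots (edges) of a nested tree, as index paths
nested_slots <- function(x, path = integer(0)) {
  if (is.character(x)) return(list())
  out <- list()
  for (i in seq_along(x)) {
    out[[length(out) + 1L]] <- c(path, i)
    out <- c(out, nested_slots(x[[i]], c(path, i)))
  }
  out
}

# insert `leaf` on the edge above the subtree at index path `slot`
nested_insert <- function(x, slot, leaf) {
  if (length(slot) == 1L) {
    x[[slot]] <- list(x[[slot]], leaf)
    return(x)
  }
  x[[slot[1L]]] <- nested_insert(x[[slot[1L]]], slot[-1L], leaf)
  x
}

# canonical newick for deterministic tie-breaking: root at the smallest
# tip, sort sibling subtrees by their canonical strings, recursively
canonical_newick <- function(tree) {
  tree <- ape::unroot(tree)
  og <- min(tree$tip.label)
  tree <- ape::root(tree, outgroup = og, resolve.root = TRUE)
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  build <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    ks <- sort(vapply(kids[[as.character(node)]], build, character(1)))
    paste0("(", paste(ks, collapse = ","), ")")
  }
  paste0(build(n + 1L), ";")
}

#' Minimum-weighted-length MRP supertree
#'
#' Finds a topology minimizing the weighted Fitch length over the MRP
#' characters. `"exhaustive"` enumerates every unrooted binary topology by
#' stepwise leaf insertion (feasible to ~8 taxa); `"branch_and_bound"` runs
#' the same recursion pruning partial trees that already exceed the best
#' complete score (exact; practical to ~15 taxa); `"nni_hillclimb"` starts
#' from a neighbor-joining tree on MRP row distances and improves by
#' nearest-neighbor interchanges with random restarts. Ties are resolved to
#' the lexicographically smallest canonical newick among optima (exact
#' searches) or the first optimum found (heuristic, seed-reproducible).
#'
#' @param mrp a `mito_mrp` with at least one character and >= 4 taxa.
#' @param search search mode; `"auto"` picks exhaustive for n <= 8,
#'   branch-and-bound for n <= 15, hill-climbing otherwise.
#' @param seed RNG seed (heuristic restarts).
#' @param n_restarts random restarts for the heuristic (default 10).
#' @return a `phylo` tree with attributes `score` (the weighted length) and
#'   `search`.
#' @export
mrp_supertree <- function(mrp, search = c("auto", "exhaustive",
                                          "branch_and_bound",
                                          "nni_hillclimb"),
                          seed = 1L, n_restarts = 10L) {
  search <- match.arg(search)
  if (ncol(mrp$X) == 0L) stop("MRP matrix has no characters", call. = FALSE)
  n <- length(mrp$taxa)
  if (n < 4L) stop("need at least 4 taxa", call. = FALSE)
  if (search == "auto") {
    search <- if (n <= 8L) "exhaustive"
              else if (n <= 15L) "branch_and_bound"
              else "nni_hillclimb"
  }
  res <- switch(search,
    exhaustive = search_insertion(mrp, prune = FALSE),
    branch_and_bound = search_insertion(mrp, prune = TRUE),
    nni_hillclimb = search_nni(mrp, seed = seed, n_restarts = n_restarts))
  tree <- res$tree
  attr(tree, "score") <- res$score
  attr(tree, "search") <- search
  if (!is.null(res$optima)) attr(tree, "optima") <- res$optima
  tree
}

# exact search by stepwise insertion; prune = TRUE gives branch-and-bound.
# Partial-tree scores are monotone in leaf addition, so pruning at
# score > best is safe; ties (==) are kept so the optimum set is complete.
search_insertion <- function(mrp, prune) {
  taxa <- mrp$taxa
  best <- new.env(parent = emptyenv())
  best$score <- Inf
  best$newicks <- character(0)
  best$trees <- list()
  partial_score <- function(nested, k) {
    sub <- restrict_mrp(mrp, taxa[seq_len(k)])
    if (ncol(sub$X) == 0L) return(0)
    parsimony_length(nested_to_phylo(nested), sub)
  }
  recurse <- function(nested, k) {
    if (prune && k > 4L) {
      if (partial_score(nested, k) > best$score) return(invisible())
    }
    if (k == length(taxa)) {
      sc <- parsimony_length(nested_to_phylo(nested), mrp)
      if (sc < best$score - 1e-9) {
        best$score <- sc
        best$newicks <- character(0)
        best$trees <- list()
      }
      if (sc <= best$score + 1e-9) {
        tr <- nested_to_phylo(nested)
        cn <- canonical_newick(tr)
        if (!cn %in% best$newicks) {
          best$newicks <- c(best$newicks, cn)
          best$trees[[length(best$trees) + 1L]] <- tr
        }
      }
      return(invisible())
    }
    leaf <- taxa[k + 1L]
    for (slot in nested_slots(nested)) {
      recurse(nested_insert(nested, slot, leaf), k + 1L)
    }
    invisible()
  }
  recurse(list(taxa[1L], taxa[2L], taxa[3L]), 3L)
  ord <- order(best$newicks)
  list(tree = best$trees[[ord[1L]]], score = best$score,
       optima = best$trees[ord], newicks = best$newicks[ord])
}

# restrict an MRP matrix to a taxon subset, dropping characters that become
# uninformative there
restrict_mrp <- function(mrp, taxa_sub) {
  X <- mrp$X[taxa_sub, , drop = FALSE]
  ones <- colSums(X == 1L, na.rm = TRUE)
  zeros <- colSums(X == 0L, na.rm = TRUE)
  keep <- ones >= 2L & zeros >= 2L
  structure(list(X = X[, keep, drop = FALSE], weights = mrp$weights[keep],
                 provenance = mrp$provenance[keep, , drop = FALSE],
                 taxa = taxa_sub), class = "mito_mrp")
}

# NJ start on weighted normalized mismatch between MRP rows, then greedy
# NNI; repeated from randomized starts
search_nni <- function(mrp, seed, n_restarts) {
  taxa <- mrp$taxa
  withr_seed(seed, {
    d <- mrp_row_distance(mrp)
    start <- ape::unroot(nj_tree(d))
    cands <- list(start)
    for (r in seq_len(n_restarts)) {
      cands[[r + 1L]] <- ape::rtree(length(taxa), rooted = FALSE,
                                    tip.label = sample(taxa))
    }
    best_tree <- NULL; best_score <- Inf
    for (tr in cands) {
      res <- nni_climb(tr, mrp)
      if (res$score < best_score - 1e-9) {
        best_score <- res$score
        best_tree <- res$tree
      }
    }
    list(tree = best_tree, score = best_score)
  })
}

mrp_row_distance <- function(mrp) {
  X <- mrp$X
  w <- mrp$weights
  n <- nrow(X)
  d <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- !is.na(X[i, ]) & !is.na(X[j, ])
      tw <- sum(w[ok])
      d[i, j] <- d[j, i] <- if (tw > 0)
        sum(w[ok] * (X[i, ok] != X[j, ok])) / tw else 0.5
    }
  }
  d
}

nni_climb <- function(tree, mrp) {
  score <- parsimony_length(tree, mrp)
  repeat {
    nbrs <- phangorn::nni(tree)
    scores <- vapply(nbrs, parsimony_length, numeric(1), mrp = mrp)
    if (min(scores) < score - 1e-9) {
      i <- which.min(scores)
      tree <- nbrs[[i]]
      score <- scores[i]
    } else {
      return(list(tree = tree, score = score))
    }
  }
}
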