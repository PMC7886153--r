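# Canonical bipartitions (splits). A split is stored as its canonical
# ingroup: the side NOT containing the reference taxon (the
# lexicographically smallest identifier of the leaf universe), with members
# sorted and joined by commas. A split is informative when both sides have
# at least two taxa. Taxon identifiers must not contain commas.

split_key <- function(members) paste(sort(members), collapse = ",")

split_members <- function(key) strsplit(key, ",", fixed = TRUE)[[1L]]

#' Canonicalize a bipartition
#'
#' @param members character vector: one side of the split.
#' @param taxa the full leaf universe.
#' @return the canonical key (comma-joined sorted ingroup, the side not
#'   containing the reference taxon), or `NA` if uninformative.
#' @export
canonical_split <- function(members, taxa) {
  ref <- min(taxa)
  side <- if (ref %in% members) setdiff(taxa, members) else members
  if (length(side) < 2L || length(side) > length(taxa) - 2L) {
    return(NA_character_)
  }
  split_key(side)
}

#' Informative splits of a tree
#'
#' @param tree a `phylo` (rooted or unrooted).
#' @param taxa leaf universe; defaults to the tree's tips.
#' @return character vector of canonical split keys (unique).
#' @export
tree_splits <- function(tree, taxa = tree$tip.label) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(idx) canonical_split(labs[idx], taxa),
                 character(1))
  unique(keys[!is.na(keys)])
}

#' Are two splits compatible?
#'
#' Splits A|A' and B|B' on one leaf set are compatible iff at least one of
#' the four intersections A&B, A&B', A'&B, A'&B' is empty (they can coexist
#' in one tree).
#'
#' @param key1,key2 canonical split keys.
#' @param taxa leaf universe.
#' @return logical.
#' @export
splits_compatible <- function(key1, key2, taxa) {
  a <- split_members(key1); b <- split_members(key2)
  ac <- setdiff(taxa, a);   bc <- setdiff(taxa, b)
  !length(intersect(a, b)) || !length(intersect(a, bc)) ||
    !length(intersect(ac, b)) || !length(intersect(ac, bc))
}

#' Bipartition frequencies in a tree sample
#'
#' Counts every informative split across the sample (split and complement
#' are pooled through canonicalization) and reports occurrence frequencies,
#' dropping splits below a support floor.
#'
#' @param ts a `mito_treesample`.
#' @param floor minimum frequency retained (default 0.05).
#' @return data.frame with `bipartition` (canonical key), `support`
#'   (frequency in \[0, 1\]) and `window` (the sample label), sorted by
#'   decreasing support.
#' @export
bipartition_frequencies <- function(ts, floor = 0.05) {
  stopifnot(inherits(ts, "mito_treesample"), ts$n >= 1L)
  taxa <- sort(ts$trees[[1L]]$tip.label)
  counts <- table(unlist(lapply(ts$trees, tree_splits, taxa = taxa)))
  support <- as.numeric(counts) / ts$n
  keep <- support >= floor
  out <- data.frame(bipartition = names(counts)[keep],
                    support = support[keep],
                    window = ts$label, stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$bipartition), , drop = FALSE]
  rownames(out) <- NULL
  out
}
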