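# Shared helpers: independent oracles and random-instance generators used
# across the unit and acceptance suites.

# random aligned sequences over the full alphabet (optionally with gaps /
# ambiguity codes), named taxa
random_alignment <- function(n = 5, L = 40, alphabet = c("A", "C", "G", "T"),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(sample(alphabet, n * L, replace = TRUE), n, L,
              dimnames = list(paste0("t", seq_len(n)), NULL))
  alignment(m)
}

# random informative binary MRP matrix with real-valued weights
random_mrp <- function(n_taxa, n_char, seed) {
  set.seed(seed)
  taxa <- paste0("t", seq_len(n_taxa))
  cols <- lapply(seq_len(n_char), function(i) {
    k <- sample(2:(n_taxa - 2), 1)
    as.integer(taxa %in% sample(taxa, k))
  })
  X <- do.call(cbind, cols)
  rownames(X) <- taxa
  structure(list(X = X, weights = stats::runif(n_char, 0.1, 1),
                 provenance = data.frame(window = "w",
                                         bipartition = as.character(seq_len(n_char)),
                                         stringsAsFactors = FALSE),
                 taxa = taxa), class = "mito_mrp")
}

# independent weighted parsimony score via phangorn's Fitch implementation
phangorn_score <- function(tree, mrp) {
  ch <- matrix(as.character(mrp$X), nrow(mrp$X),
               dimnames = dimnames(mrp$X))
  ch[is.na(ch)] <- "?"
  pd <- phangorn::phyDat(ch, type = "USER", levels = c("0", "1"),
                         ambiguity = "?")
  per_pattern <- phangorn::parsimony(tree, pd, method = "fitch",
                                     site = "site")
  sum(mrp$weights * per_pattern[attr(pd, "index")])
}

# brute-force optimum over every unrooted topology, scored by the
# independent oracle; returns best score and canonical newicks of optima
brute_force_optima <- function(mrp, tol = 1e-9) {
  at <- phangorn::allTrees(length(mrp$taxa), rooted = FALSE,
                           tip.label = mrp$taxa)
  scores <- vapply(at, phangorn_score, numeric(1), mrp = mrp)
  best <- min(scores)
  idx <- which(scores <= best + tol)
  list(score = best,
       newicks = sort(vapply(at[idx], mitophylo:::canonical_newick,
                             character(1))))
}
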