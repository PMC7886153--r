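# Seeded synthetic-data generation: Yule trees, GTR+Gamma+I sequence
# simulation with optional clade composition shift, and perturbation
# injectors (near-duplicate haplotypes, chimeric genomes, single-genome
# insertions) that create exactly the conditions the curation and
# conflict-detection rules are meant to handle.

#' Simulation configuration
#'
#' @param n_taxa number of tips.
#' @param birth_rate Yule speciation rate (per lineage per time unit).
#' @param L alignment columns.
#' @param gtr_rates 6 GTR exchangeabilities (order AC, AG, AT, CG, CT, GT).
#' @param base_freq stationary frequencies (A, C, G, T), summing to 1; the
#'   default echoes mammalian mitochondrial A-richness.
#' @param gamma_alpha shape of the discrete-gamma rate heterogeneity.
#' @param p_inv proportion of invariant sites in \[0, 1).
#' @param clade_shift optional list `list(taxa =, base =, delta =)`: the
#'   named clade evolves under stationary frequencies with `delta` added to
#'   `base` (renormalized), emulating lineage-specific compositional drift.
#' @param seed RNG seed recorded in all outputs.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 12L, birth_rate = 0.2, L = 6000L,
                       gtr_rates = c(1, 8, 1, 1, 8, 1),
                       base_freq = c(0.31, 0.26, 0.13, 0.30),
                       gamma_alpha = 0.5, p_inv = 0.425,
                       clade_shift = NULL, seed = 1L) {
  stopifnot(abs(sum(base_freq) - 1) < 1e-8, all(gtr_rates > 0),
            p_inv >= 0, p_inv < 1, gamma_alpha > 0)
  structure(list(n_taxa = as.integer(n_taxa), birth_rate = birth_rate,
                 L = as.integer(L), gtr_rates = gtr_rates,
                 base_freq = base_freq, gamma_alpha = gamma_alpha,
                 p_inv = p_inv, clade_shift = clade_shift,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth tree conditioned on the number of tips, with tips labelled
#' `t01, t02, ...`. Reproducible under the config seed.
#'
#' @param cfg a [sim_config()].
#' @return a rooted ultrametric `phylo`.
#' @export
simulate_yule_tree <- function(cfg) {
  stopifnot(cfg$n_taxa >= 2L)
  tr <- withr_seed(cfg$seed, {
    ape::rphylo(cfg$n_taxa, birth = cfg$birth_rate, death = 0)
  })
  tr$tip.label <- sprintf("t%02d", seq_len(cfg$n_taxa))
  tr
}

# GTR rate matrix from exchangeabilities and stationary frequencies,
# scaled so the expected substitution rate is 1
gtr_Q <- function(rates, bf) {
  Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  Q["A", "C"] <- rates[1]; Q["A", "G"] <- rates[2]; Q["A", "T"] <- rates[3]
  Q["C", "G"] <- rates[4]; Q["C", "T"] <- rates[5]; Q["G", "T"] <- rates[6]
  Q <- Q + t(Q)
  Q <- Q * rep(bf, each = 4)     # q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  Q / sum(-diag(Q) * bf)
}

# transition probabilities exp(Q t) via eigendecomposition
gtr_P <- function(Q, t) {
  e <- eigen(Q)
  P <- Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P / rowSums(P)
}

shifted_bf <- function(bf, base, delta) {
  names(bf) <- DNA_BASES
  bf[base] <- bf[base] + delta
  if (any(bf <= 0)) stop("clade shift drives a frequency below 0",
                         call. = FALSE)
  bf / sum(bf)
}

#' Simulate sequences along a tree under GTR+Gamma+I
#'
#' Site rates follow a 4-category discrete gamma with a proportion
#' `p_inv` of invariant sites. When `cfg$clade_shift` names a clade, that
#' clade (stem branch included) evolves under shifted stationary
#' frequencies, producing a compositional outlier lineage while the
#' topology stays well defined.
#'
#' @param tree a `phylo` with branch lengths (expected substitutions per
#'   site).
#' @param cfg a [sim_config()].
#' @return a `mito_alignment` with each taxon its own species; attribute
#'   `sim_seed` records the seed.
#' @export
simulate_sequences <- function(tree, cfg) {
  stopifnot(!is.null(tree$edge.length))
  L <- cfg$L
  bf <- cfg$base_freq
  aln_mat <- withr_seed(cfg$seed + 1L, {
    rates <- phangorn::discrete.gamma(cfg$gamma_alpha, 4)
    site_cat <- sample.int(4L, L, replace = TRUE)
    inv <- stats::runif(L) < cfg$p_inv
    m <- matrix("", length(tree$tip.label), L,
                dimnames = list(tree$tip.label, NULL))
    # invariant sites: one stationary draw shared by all taxa
    if (any(inv)) {
      draws <- sample(DNA_BASES, sum(inv), replace = TRUE, prob = bf)
      m[, inv] <- rep(draws, each = nrow(m))
    }
    for (k in 1:4) {
      sites <- which(!inv & site_cat == k)
      if (!length(sites)) next
      m[, sites] <- sim_category(tree, length(sites), cfg, rates[k])
    }
    m
  })
  aln <- alignment(aln_mat,
                   species = stats::setNames(rownames(aln_mat),
                                             rownames(aln_mat)))
  attr(aln, "sim_seed") <- cfg$seed
  aln
}

# simulate one rate category; applies the clade shift if configured
sim_category <- function(tree, l, cfg, rate) {
  Q6 <- cfg$gtr_rates
  bf <- cfg$base_freq
  shift <- cfg$clade_shift
  need_anc <- !is.null(shift)
  sim <- phangorn::simSeq(tree, l = l, Q = Q6, bf = bf, rate = rate,
                          ancestral = need_anc)
  chr <- toupper(as.character(sim))
  if (is.null(shift)) {
    return(chr[tree$tip.label, , drop = FALSE])
  }
  tips <- shift$taxa
  stopifnot(all(tips %in% tree$tip.label),
            length(tips) < length(tree$tip.label))
  bf2 <- shifted_bf(bf, shift$base, shift$delta)
  Qm <- gtr_Q(Q6, bf2)
  tipidx <- match(tips, tree$tip.label)
  node <- if (length(tips) == 1L) tipidx else ape::getMRCA(tree, tips)
  stem_edge <- which(tree$edge[, 2L] == node)
  parent <- tree$edge[stem_edge, 1L]
  # ancestral rows of simSeq(ancestral=TRUE) are named by node number
  anc <- chr[as.character(parent), ]
  # evolve the stem under the shifted model
  P <- gtr_P(Qm, tree$edge.length[stem_edge] * rate)
  stem_seq <- vapply(anc, function(b)
    sample(DNA_BASES, 1L, prob = P[b, ]), character(1))
  if (length(tips) == 1L) {
    chr[tips, ] <- stem_seq
    return(chr[tree$tip.label, , drop = FALSE])
  }
  sub <- ape::extract.clade(tree, node)
  resim <- phangorn::simSeq(sub, l = l, Q = Q6, bf = bf2, rate = rate,
                            rootseq = tolower(stem_seq))
  rchr <- toupper(as.character(resim))
  chr[rownames(rchr), ] <- rchr
  chr[tree$tip.label, , drop = FALSE]
}

#' Append near-duplicate conspecific haplotypes
#'
#' Adds `k` copies of a taxon's sequence, each mutated at random sites so
#' that all pairwise distances among the copies and the original stay at or
#' below `max_d`. Copies are labelled `<taxon>_dup1 ...` and share the
#' original's species label -- exactly the redundancy the 1% dereplication
#' rule removes.
#'
#' @param aln a `mito_alignment` with species labels.
#' @param species taxon identifier whose species gets the duplicates.
#' @param k number of copies.
#' @param max_d maximum pairwise divergence among copies (< 0.01).
#' @param seed RNG seed.
#' @return the augmented `mito_alignment`.
#' @export
inject_near_duplicates <- function(aln, species, k = 2L, max_d = 0.005,
                                   seed = 1L) {
  stopifnot(species %in% aln_taxa(aln))
  L <- aln_length(aln)
  n_mut <- floor(max_d * L / 2)
  rowseq <- aln$matrix[species, ]
  new_rows <- withr_seed(seed, {
    lapply(seq_len(k), function(i) {
      r <- rowseq
      if (n_mut > 0) {
        sites <- sample.int(L, n_mut)
        r[sites] <- vapply(r[sites], function(b) {
          pool <- setdiff(DNA_BASES, b)
          sample(pool, 1L)
        }, character(1))
      }
      r
    })
  })
  m <- rbind(aln$matrix, do.call(rbind, new_rows))
  dup_names <- paste0(species, "_dup", seq_len(k))
  rownames(m) <- c(aln_taxa(aln), dup_names)
  sp <- aln$species
  fam <- aln$family
  if (!is.null(sp)) {
    sp[dup_names] <- sp[[species]]
  }
  if (!is.null(fam)) fam[dup_names] <- fam[[species]]
  alignment(m, species = sp, family = fam)
}

#' Replace part of a genome with another taxon's sequence (chimera)
#'
#' Overwrites the host's cells on the given column interval(s) with the
#' donor's, emulating a partially contaminated or Numt-bearing assembly.
#' The injected truth is recorded in attribute `chimera_manifest`.
#'
#' @param aln a `mito_alignment`.
#' @param host,donor distinct taxon identifiers.
#' @param intervals list of `c(start, end)` column intervals (1-based
#'   inclusive; several intervals accommodate wrapped windows). An empty
#'   list is a no-op.
#' @return the modified `mito_alignment`.
#' @export
inject_chimera <- function(aln, host, donor, intervals) {
  stopifnot(host %in% aln_taxa(aln), donor %in% aln_taxa(aln),
            host != donor)
  cols <- interval_columns(intervals, aln_length(aln))
  out <- aln
  out$matrix[host, cols] <- aln$matrix[donor, cols]
  attr(out, "chimera_manifest") <- list(host = host, donor = donor,
                                        columns = cols)
  out
}

#' Insert a single-genome insertion (gap columns in all other taxa)
#'
#' Adds `length` new columns after column `position`; only `taxon` carries
#' residues there, every other row gets gaps -- the singleton-insertion
#' pattern the indel filter deletes. Inserted column positions are recorded
#' in attribute `insertion_manifest`.
#'
#' @param aln a `mito_alignment`.
#' @param taxon carrier taxon (or several, for a shared insertion).
#' @param position column after which to insert (0 = prepend).
#' @param length number of inserted columns (0 = no-op).
#' @param seed RNG seed for the inserted residues.
#' @return the modified `mito_alignment`.
#' @export
inject_singleton_insertion <- function(aln, taxon, position, length,
                                       seed = 1L) {
  stopifnot(all(taxon %in% aln_taxa(aln)),
            position >= 0, position <= aln_length(aln))
  if (length == 0L) return(aln)
  block <- matrix("-", nrow(aln$matrix), length)
  rownames(block) <- aln_taxa(aln)
  block[taxon, ] <- withr_seed(seed, {
    matrix(sample(DNA_BASES, length(taxon) * length, replace = TRUE),
           nrow = length(taxon))
  })
  m <- cbind(aln$matrix[, seq_len(position), drop = FALSE], block,
             if (position < aln_length(aln))
               aln$matrix[, seq.int(position + 1L, aln_length(aln)),
                          drop = FALSE])
  rownames(m) <- aln_taxa(aln)
  out <- aln
  out$matrix <- m
  attr(out, "insertion_manifest") <- list(taxon = taxon,
                                          columns = position +
                                            seq_len(length))
  out
}

#' Default synthetic study fixture
#'
#' Twelve taxa in four "families" of three on a fixed family-structured
#' topology, with sequences simulated under GTR+Gamma+I (A-rich
#' mitochondrial-like frequencies). Short within-family branches contrast
#' with long family stems, and one lineage (`D3`) sits on a long terminal
#' branch -- the substrate for composition-shift experiments. Returns the
#' alignment, the generating tree, and the species/family maps.
#'
#' @param L alignment length (default 6000).
#' @param seed RNG seed.
#' @param clade_shift optional clade-shift spec passed to [sim_config()].
#' @param scale multiplier on all branch lengths (default 1).
#' @return list with `alignment`, `tree`, `species`, `family`, `config`.
#' @export
simulate_fixture <- function(L = 6000L, seed = 1L, clade_shift = NULL,
                             scale = 1) {
  fams <- LETTERS[1:4]
  taxa <- paste0(rep(fams, each = 3L), 1:3)
  # four families of three, ((x1,x2),x3) within each family
  newick <- paste0(
    "(((A1:0.004,A2:0.004):0.004,A3:0.012):0.35,",
    "((B1:0.004,B2:0.004):0.004,B3:0.012):0.35,",
    "(((C1:0.004,C2:0.004):0.004,C3:0.012):0.14,",
    "((D1:0.004,D2:0.004):0.004,D3:0.25):0.14):0.18);")
  tree <- ape::read.tree(text = newick)
  tree$edge.length <- tree$edge.length * scale
  cfg <- sim_config(n_taxa = 12L, L = L, clade_shift = clade_shift,
                    seed = seed)
  aln <- simulate_sequences(tree, cfg)
  species <- stats::setNames(taxa, taxa)
  family <- stats::setNames(rep(fams, each = 3L), taxa)
  aln$species <- species[aln_taxa(aln)]
  aln$family <- family[aln_taxa(aln)]
  list(alignment = aln, tree = tree, species = species, family = family,
       config = cfg)
}
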