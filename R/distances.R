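# Uncorrected pairwise distances, haplotype dereplication at a divergence
# threshold, and the intra/interspecific distance screening report.

#' Uncorrected (p) distance matrix
#'
#' For every pair of taxa, `d = mismatches / comparable sites`, where a site
#' is comparable iff both cells are unambiguous bases (A, C, G or T): gaps
#' and all IUPAC ambiguity codes are excluded pairwise (complete pairwise
#' deletion). Pairs with zero comparable sites get `NA` with a warning.
#'
#' @param aln a `mito_alignment` with at least two taxa.
#' @return a list of class `mito_distmat`: `taxa`, `d` (symmetric matrix of
#'   proportions, zero diagonal), `n_comp` (symmetric matrix of
#'   pairwise-comparable site counts).
#' @export
p_distance_matrix <- function(aln) {
  m <- aln$matrix
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 taxa", call. = FALSE)
  taxa <- rownames(m)
  # integer-code the bases; 0 = not comparable
  code <- match(m, DNA_BASES, nomatch = 0L)
  dim(code) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  nc <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  diag(nc) <- as.integer(rowSums(code > 0L))
  for (i in seq_len(n - 1L)) {
    ci <- code[i, ]
    for (j in seq.int(i + 1L, n)) {
      cj <- code[j, ]
      comp <- ci > 0L & cj > 0L
      ncmp <- sum(comp)
      nc[i, j] <- nc[j, i] <- ncmp
      if (ncmp == 0L) {
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        mm <- sum(ci[comp] != cj[comp])
        d[i, j] <- d[j, i] <- mm / ncmp
      }
    }
  }
  if (anyNA(d)) {
    warning("some pairs share no comparable sites; distances set to NA",
            call. = FALSE)
  }
  structure(list(taxa = taxa, d = d, n_comp = nc), class = "mito_distmat")
}

#' @export
print.mito_distmat <- function(x, ...) {
  cat("p-distance matrix over", length(x$taxa), "taxa\n")
  cat("range:", format(range(x$d[upper.tri(x$d)], na.rm = TRUE), digits = 4),
      "\n")
  invisible(x)
}

#' Dereplicate near-identical haplotypes within species
#'
#' Within each species, taxa are clustered by single linkage at
#' `d <= threshold` (uncorrected distance) and one representative per
#' cluster is retained: the sequence with the fewest non-ACGT cells, ties
#' broken lexicographically by identifier. Pairs from different species are
#' never merged. This implements retention of only haplotypes separated by
#' more than `threshold` divergence at the intraspecific level.
#'
#' @param aln a `mito_alignment`.
#' @param species_map named character vector taxon -> species; defaults to
#'   `aln$species`.
#' @param threshold divergence threshold in (0, 1); default 0.01 (1%).
#' @param dm optional precomputed [p_distance_matrix()].
#' @return list with `kept` (character vector of retained taxon ids, in
#'   original order), `clusters` (named integer vector of within-species
#'   cluster ids), and `report` (data.frame of dropped taxa with their
#'   representative and distance to it).
#' @export
dereplicate <- function(aln, species_map = aln$species, threshold = 0.01,
                        dm = NULL) {
  if (is.null(species_map)) {
    stop("species_map required (or set aln$species)", call. = FALSE)
  }
  stopifnot(threshold > 0, threshold < 1)
  taxa <- aln_taxa(aln)
  species_map <- check_labels(species_map, taxa, "species")
  if (is.null(dm)) dm <- p_distance_matrix(aln)
  ambig <- rowSums(matrix(!(aln$matrix %in% DNA_BASES), nrow(aln$matrix)))
  names(ambig) <- taxa
  clusters <- integer(0)
  kept <- character(0)
  rep_of <- character(0)
  next_id <- 0L
  for (sp in unique(species_map)) {
    members <- taxa[species_map == sp]
    if (length(members) == 1L) {
      next_id <- next_id + 1L
      clusters[members] <- next_id
      kept <- c(kept, members)
      next
    }
    sub <- dm$d[members, members, drop = FALSE]
    sub[is.na(sub)] <- 1  # incomparable pairs never merge
    hc <- stats::hclust(stats::as.dist(sub), method = "single")
    # single-linkage clusters whose merge height is <= threshold
    cl <- stats::cutree(hc, h = threshold)
    for (k in sort(unique(cl))) {
      cm <- members[cl == k]
      next_id <- next_id + 1L
      clusters[cm] <- next_id
      rep_tax <- cm[order(ambig[cm], cm)][1L]
      kept <- c(kept, rep_tax)
      dropped <- setdiff(cm, rep_tax)
      if (length(dropped)) {
        rep_of[dropped] <- rep_tax
      }
    }
  }
  kept <- taxa[taxa %in% kept]
  dropped <- setdiff(taxa, kept)
  report <- data.frame(
    taxon = dropped,
    species = unname(species_map[dropped]),
    representative = unname(rep_of[dropped]),
    distance = vapply(dropped,
                      function(t) dm$d[t, rep_of[[t]]], numeric(1)),
    stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(kept = kept, clusters = clusters[taxa], report = report)
}

#' Screen pairwise distances against an intraspecific ceiling
#'
#' Reports intraspecific pairs more divergent than `intra_flag` (candidate
#' taxonomic issues: cryptic species, misidentification) and interspecific
#' pairs less divergent than `intra_flag` (candidate synonymy, introgression
#' or recent speciation).
#'
#' @param dm a [p_distance_matrix()] result.
#' @param species_map named character vector taxon -> species.
#' @param intra_flag divergence ceiling; default 0.02 (2%).
#' @return data.frame with columns `taxon1`, `taxon2`, `species1`,
#'   `species2`, `d`, `flag` (`"intraspecific_gt"` / `"interspecific_lt"`).
#' @export
distance_screen <- function(dm, species_map, intra_flag = 0.02) {
  taxa <- dm$taxa
  species_map <- check_labels(species_map, taxa, "species")
  rows <- list()
  n <- length(taxa)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- dm$d[i, j]
      if (is.na(d)) next
      same <- species_map[taxa[i]] == species_map[taxa[j]]
      flag <- if (same && d > intra_flag) "intraspecific_gt"
              else if (!same && d < intra_flag) "interspecific_lt"
              else NA_character_
      if (!is.na(flag)) {
        rows[[length(rows) + 1L]] <- data.frame(
          taxon1 = taxa[i], taxon2 = taxa[j],
          species1 = unname(species_map[taxa[i]]),
          species2 = unname(species_map[taxa[j]]),
          d = d, flag = flag, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(taxon1 = character(0), taxon2 = character(0),
                      species1 = character(0), species2 = character(0),
                      d = numeric(0), flag = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
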