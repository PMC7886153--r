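# Alignment curation: masking ambiguous regions, singleton-indel removal,
# transversion (RY) recoding, protein-coding-gene extraction.

#' Delete alignment columns by interval
#'
#' Removes the listed 1-based inclusive column intervals from an alignment
#' (overlapping intervals are unioned, each column deleted once). Remaining
#' columns are renumbered contiguously; the old-to-new column map is attached
#' as attribute `column_map` (NA for deleted columns).
#'
#' @param aln a `mito_alignment`.
#' @param intervals list of `c(start, end)` pairs, or a 2-column matrix; an
#'   empty list is a no-op.
#' @return the masked `mito_alignment` with attribute `column_map`.
#' @export
mask_regions <- function(aln, intervals) {
  L <- aln_length(aln)
  cols <- interval_columns(intervals, L)
  keep <- setdiff(seq_len(L), cols)
  out <- aln
  out$matrix <- aln$matrix[, keep, drop = FALSE]
  cmap <- rep(NA_integer_, L)
  cmap[keep] <- seq_along(keep)
  attr(out, "column_map") <- cmap
  out
}

interval_columns <- function(intervals, L) {
  if (is.matrix(intervals)) {
    intervals <- lapply(seq_len(nrow(intervals)), function(i) intervals[i, ])
  }
  if (length(intervals) == 0L) return(integer(0))
  cols <- unlist(lapply(intervals, function(iv) {
    iv <- as.integer(iv)
    if (length(iv) != 2L || anyNA(iv) || iv[1L] > iv[2L]) {
      stop("bounds error: interval must be c(start, end) with start <= end",
           call. = FALSE)
    }
    if (iv[1L] < 1L || iv[2L] > L) {
      stop("bounds error: interval [", iv[1L], ", ", iv[2L],
           "] outside alignment columns [1, ", L, "]", call. = FALSE)
    }
    seq.int(iv[1L], iv[2L])
  }))
  sort(unique(cols))
}

#' Detect indel events
#'
#' An indel event is a maximal run of consecutive columns sharing an
#' identical gap-presence vector (which taxa have `-`). For each event the
#' minority state defines the carriers: when the residue-bearing taxa are
#' the minority the event is an insertion carried by them; when the
#' gap-bearing taxa are the minority it is a deletion (ties count as
#' deletions). Gap-free columns belong to no event.
#'
#' @param aln a `mito_alignment`.
#' @return a data.frame with one row per event: `start`, `end`,
#'   `carrier_count`, `polarity` (`"insertion"`/`"deletion"`), and
#'   `carriers` (comma-separated taxon ids).
#' @export
find_indel_events <- function(aln) {
  m <- aln$matrix
  if (ncol(m) == 0L) return(empty_indel_report())
  gap <- m == "-"
  has_gap <- colSums(gap) > 0L
  if (!any(has_gap)) return(empty_indel_report())
  # key each column by its gap-presence vector; break runs on key change
  key <- apply(gap, 2L, function(v) paste(which(v), collapse = ","))
  key[!has_gap] <- NA
  n <- nrow(m)
  events <- list()
  i <- 1L
  L <- ncol(m)
  while (i <= L) {
    if (is.na(key[i])) { i <- i + 1L; next }
    j <- i
    while (j < L && !is.na(key[j + 1L]) && key[j + 1L] == key[i]) j <- j + 1L
    gappers <- which(gap[, i])
    n_gap <- length(gappers)
    n_res <- n - n_gap
    if (n_res < n_gap) {
      carriers <- rownames(m)[-gappers]
      polarity <- "insertion"
    } else {
      carriers <- rownames(m)[gappers]
      polarity <- "deletion"
    }
    events[[length(events) + 1L]] <- data.frame(
      start = i, end = j, carrier_count = length(carriers),
      polarity = polarity, carriers = paste(carriers, collapse = ","),
      stringsAsFactors = FALSE)
    i <- j + 1L
  }
  do.call(rbind, events)
}

empty_indel_report <- function() {
  data.frame(start = integer(0), end = integer(0),
             carrier_count = integer(0), polarity = character(0),
             carriers = character(0), stringsAsFactors = FALSE)
}

#' Remove indels detected in only one genome
#'
#' Drops single-genome indel events. With `mode = "insertions_only"` (the
#' default) only columns of single-carrier insertions are deleted: removing
#' columns of a unique deletion would discard data for every other taxon,
#' defeating the aim of limiting missing data. With `mode = "all_singletons"`
#' the gap run of single-carrier deletions is additionally replaced by the
#' missing symbol `N` in the carrier (columns retained).
#'
#' @param aln a `mito_alignment`.
#' @param mode `"insertions_only"` or `"all_singletons"`.
#' @return a list with `alignment` (curated `mito_alignment`, carrying the
#'   `column_map` attribute when columns were deleted) and `report` (the
#'   indel events acted on, with an `action` column).
#' @export
remove_singleton_indels <- function(aln,
                                    mode = c("insertions_only",
                                             "all_singletons")) {
  mode <- match.arg(mode)
  ev <- find_indel_events(aln)
  single <- ev[ev$carrier_count == 1L, , drop = FALSE]
  out <- aln
  acted <- single[0L, , drop = FALSE]
  ins <- single[single$polarity == "insertion", , drop = FALSE]
  if (mode == "all_singletons") {
    del <- single[single$polarity == "deletion", , drop = FALSE]
    for (r in seq_len(nrow(del))) {
      out$matrix[del$carriers[r], seq.int(del$start[r], del$end[r])] <- "N"
    }
    if (nrow(del)) del$action <- "gaps_to_N"
    acted <- rbind(acted, del)
  }
  if (nrow(ins)) {
    ivs <- lapply(seq_len(nrow(ins)), function(r) c(ins$start[r], ins$end[r]))
    out <- mask_regions(out, ivs)
    ins$action <- "columns_deleted"
    acted <- rbind(acted, ins)
  }
  list(alignment = out, report = acted)
}

#' Transversion (RY) recoding
#'
#' Collapses purines and pyrimidines to suppress transition signal: `G` is
#' replaced by `A` and `T` by `C`. The purine ambiguity `R` maps to `A` and
#' the pyrimidine ambiguity `Y` to `C`; every other ambiguity code mixes the
#' two classes and becomes `N`. Gaps are preserved, so the output alphabet
#' is `{A, C, N, -}`. The operation is idempotent.
#'
#' @param aln a `mito_alignment`.
#' @return the recoded `mito_alignment`.
#' @export
recode_transversions <- function(aln) {
  map <- c(A = "A", G = "A", R = "A",
           C = "C", T = "C", Y = "C",
           S = "N", W = "N", K = "N", M = "N",
           B = "N", D = "N", H = "N", V = "N", N = "N",
           "-" = "-")
  out <- aln
  m <- map[aln$matrix]
  dim(m) <- dim(aln$matrix)
  rownames(m) <- rownames(aln$matrix)
  out$matrix <- m
  out
}

#' Extract concatenated protein-coding genes
#'
#' Concatenates, in genomic order, the columns of plus-strand protein-coding
#' genes, excluding minus-strand genes (in vertebrate mitogenomes, ND6) and
#' all RNA/control-region partitions. A codon-position vector (1, 2, 3
#' repeating per gene from its phase) is attached as attribute
#' `codon_positions`. Genes whose interval length is not a multiple of 3
#' trigger a warning but are kept.
#'
#' @param aln a `mito_alignment`.
#' @param parts partition data.frame as returned by [read_partition()].
#' @return the protein-coding `mito_alignment` with attribute
#'   `codon_positions`.
#' @export
extract_pcg <- function(aln, parts) {
  validate_partition(parts, aln_length(aln))
  keep <- parts$class == "protein_coding" & parts$strand == "+"
  genes <- parts[keep, , drop = FALSE]
  genes <- genes[order(genes$start), , drop = FALSE]
  cols <- integer(0)
  pos <- integer(0)
  for (r in seq_len(nrow(genes))) {
    iv <- seq.int(genes$start[r], genes$end[r])
    if (length(iv) %% 3L != 0L) {
      warning("gene '", genes$gene[r], "' length ", length(iv),
              " is not a multiple of 3", call. = FALSE)
    }
    cols <- c(cols, iv)
    ph <- genes$phase[r]
    pos <- c(pos, rep_len(c(ph:3L, if (ph > 1L) 1L:(ph - 1L)), length(iv)))
  }
  out <- aln
  out$matrix <- aln$matrix[, cols, drop = FALSE]
  attr(out, "codon_positions") <- pos
  attr(out, "source_columns") <- cols
  out
}
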