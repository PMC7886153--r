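# Codon-position base composition, AT3/CG3 strand skews, PCA summary and
# leave-one-out group-mean outlier flagging.

#' Per-taxon base frequencies at each codon position
#'
#' Counts unambiguous A/C/G/T cells only (gaps and ambiguity codes are
#' excluded) and normalizes within each codon position, yielding the 12
#' variables f(base, position) per taxon.
#'
#' @param aln a `mito_alignment` of concatenated protein-coding genes.
#' @param codon_positions integer vector in `{1,2,3}`, one per column;
#'   defaults to the `codon_positions` attribute set by [extract_pcg()].
#' @return data.frame with one row per taxon: `taxon`, the 12 frequency
#'   columns `A1..T3`, and matching count columns `n_A1..n_T3`. Taxa with an
#'   empty position class get `NA` frequencies for that position and are
#'   flagged in the `flagged` column.
#' @export
codon_frequencies <- function(aln,
                              codon_positions = attr(aln, "codon_positions")) {
  if (is.null(codon_positions)) {
    stop("codon_positions required (run extract_pcg or supply the vector)",
         call. = FALSE)
  }
  if (length(codon_positions) != aln_length(aln)) {
    stop("codon_positions length must equal alignment length", call. = FALSE)
  }
  if (!all(codon_positions %in% 1:3)) {
    stop("codon positions must be in 1..3", call. = FALSE)
  }
  m <- aln$matrix
  taxa <- rownames(m)
  vars <- as.vector(outer(DNA_BASES, 1:3, paste0))  # A1 C1 G1 T1 A2 ...
  freq <- matrix(NA_real_, length(taxa), 12,
                 dimnames = list(taxa, vars))
  cnt <- matrix(0L, length(taxa), 12, dimnames = list(taxa, vars))
  for (p in 1:3) {
    cols <- codon_positions == p
    sub <- m[, cols, drop = FALSE]
    for (b in DNA_BASES) {
      cnt[, paste0(b, p)] <- rowSums(sub == b)
    }
    tot <- rowSums(cnt[, paste0(DNA_BASES, p), drop = FALSE])
    for (b in DNA_BASES) {
      freq[, paste0(b, p)] <- ifelse(tot > 0, cnt[, paste0(b, p)] / tot, NA)
    }
  }
  out <- data.frame(taxon = taxa, freq, stringsAsFactors = FALSE)
  counts <- as.data.frame(cnt)
  names(counts) <- paste0("n_", vars)
  out <- cbind(out, counts)
  out$flagged <- apply(freq, 1L, anyNA)
  rownames(out) <- NULL
  out
}

#' Third-codon-position strand skews
#'
#' AT3 skew = (A3 - T3) / (A3 + T3) and CG3 skew = (C3 - G3) / (C3 + G3),
#' computed from third-position frequencies. Positive AT3 skew means excess
#' A over T at third positions. A zero denominator yields `NA`.
#'
#' @param profiles data.frame from [codon_frequencies()] (or any data.frame
#'   with columns `taxon`, `A3`, `C3`, `G3`, `T3`).
#' @return data.frame with `taxon`, `at3_skew`, `cg3_skew`.
#' @export
skews <- function(profiles) {
  at_den <- profiles$A3 + profiles$T3
  cg_den <- profiles$C3 + profiles$G3
  data.frame(
    taxon = profiles$taxon,
    at3_skew = ifelse(!is.na(at_den) & at_den > 0,
                      (profiles$A3 - profiles$T3) / at_den, NA_real_),
    cg3_skew = ifelse(!is.na(cg_den) & cg_den > 0,
                      (profiles$C3 - profiles$G3) / cg_den, NA_real_),
    stringsAsFactors = FALSE)
}

#' PCA of the 12 composition variables
#'
#' Centered (by default unscaled: all variables are proportions on a common
#' scale) principal component analysis of the taxa x 12 frequency matrix.
#'
#' @param profiles data.frame from [codon_frequencies()] (>= 3 rows, no
#'   flagged taxa).
#' @param scale. logical; scale variables to unit variance (default FALSE).
#' @return list with `scores` (taxa x components), `loadings` (variables x
#'   components) and `explained` (fractions of variance, non-increasing,
#'   summing to 1).
#' @export
composition_pca <- function(profiles, scale. = FALSE) {
  vars <- as.vector(outer(DNA_BASES, 1:3, paste0))
  x <- as.matrix(profiles[, vars])
  rownames(x) <- profiles$taxon
  if (nrow(x) < 3L) stop("need at least 3 profiles", call. = FALSE)
  if (anyNA(x)) stop("profiles contain NA frequencies", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (all(sds == 0)) {
    warning("constant composition matrix: zero variance", call. = FALSE)
    k <- min(dim(x))
    return(list(scores = matrix(0, nrow(x), k,
                                dimnames = list(rownames(x), NULL)),
                loadings = matrix(0, ncol(x), k),
                explained = rep(NA_real_, k)))
  }
  if (scale. && any(sds == 0)) {
    stop("cannot scale: some variables are constant", call. = FALSE)
  }
  p <- stats::prcomp(x, center = TRUE, scale. = scale.)
  ev <- p$sdev^2
  list(scores = p$x, loadings = p$rotation, explained = ev / sum(ev))
}

#' Leave-one-out group-mean outlier flagging
#'
#' For each taxon, its value of `variable` is compared with the mean and
#' standard deviation of the *other* members of its group ("mean in other
#' X"); the taxon is flagged when `|value - loo_mean| > z * loo_sd`. Groups
#' smaller than `min_group` produce no flags (noted in the output).
#'
#' @param profiles data.frame with a `taxon` column and the variable.
#' @param group_map named character vector taxon -> group (e.g. family).
#' @param variable column name, e.g. `"G3"`.
#' @param z flagging multiplier (default 2).
#' @param min_group minimum group size for flagging (default 3).
#' @return data.frame with `taxon`, `group`, `value`, `loo_mean`, `loo_sd`,
#'   `flag` (logical) and `note`.
#' @export
group_outliers <- function(profiles, group_map, variable, z = 2,
                           min_group = 3L) {
  if (!variable %in% names(profiles)) {
    stop("no such variable: ", variable, call. = FALSE)
  }
  taxa <- profiles$taxon
  group_map <- check_labels(group_map, taxa, "group")
  v <- profiles[[variable]]
  names(v) <- taxa
  out <- data.frame(taxon = taxa, group = unname(group_map[taxa]),
                    value = unname(v), loo_mean = NA_real_,
                    loo_sd = NA_real_, flag = FALSE, note = "",
                    stringsAsFactors = FALSE)
  for (g in unique(out$group)) {
    idx <- which(out$group == g)
    if (length(idx) < min_group) {
      out$note[idx] <- "group_too_small"
      next
    }
    for (i in idx) {
      rest <- v[taxa[setdiff(idx, i)]]
      mu <- mean(rest)
      s <- stats::sd(rest)
      out$loo_mean[i] <- mu
      out$loo_sd[i] <- s
      out$flag[i] <- abs(v[[i]] - mu) > z * s
    }
  }
  out
}
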