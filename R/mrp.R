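# Weighted MRP matrix construction and weighted Fitch parsimony scoring.

#' Build a weighted MRP matrix from per-window bipartition lists
#'
#' One binary character per (window, bipartition): taxa in the canonical
#' ingroup are coded 1, all other taxa 0, and the character weight is the
#' bipartition's support in its window, so the matrix aggregates both
#' principal and secondary signal across windows. The same split occurring
#' in several windows yields several characters with separate weights.
#' Taxa absent from a window's leaf set (not the usual case here) are coded
#' `NA` and ignored by the parsimony scoring.
#'
#' @param lists list of data.frames as from [bipartition_frequencies()]
#'   (columns `bipartition`, `support`, `window`), one per window, or one
#'   combined data.frame.
#' @param taxa the full taxon universe.
#' @param window_taxa optional named list: window label -> leaf set present
#'   in that window; taxa absent from a character's window are coded `NA`.
#' @return an object of class `mito_mrp`: list with `X` (taxa x characters
#'   0/1/NA integer matrix), `weights`, `provenance` (data.frame `window`,
#'   `bipartition`), `taxa`.
#' @export
build_mrp <- function(lists, taxa, window_taxa = NULL) {
  if (is.data.frame(lists)) lists <- list(lists)
  all <- do.call(rbind, lists)
  if (is.null(all) || nrow(all) == 0L) {
    return(structure(list(X = matrix(integer(0), length(taxa), 0,
                                     dimnames = list(taxa, NULL)),
                          weights = numeric(0),
                          provenance = data.frame(window = character(0),
                                                  bipartition = character(0)),
                          taxa = taxa), class = "mito_mrp"))
  }
  cols <- list(); w <- numeric(0); prov <- list()
  for (r in seq_len(nrow(all))) {
    members <- split_members(all$bipartition[r])
    if (!all(members %in% taxa)) {
      stop("bipartition references unknown taxa: ",
           paste(setdiff(members, taxa), collapse = ", "), call. = FALSE)
    }
    char <- as.integer(taxa %in% members)
    if (!is.null(window_taxa) && !is.null(window_taxa[[all$window[r]]])) {
      char[!(taxa %in% window_taxa[[all$window[r]]])] <- NA_integer_
    }
    k <- sum(char, na.rm = TRUE)
    if (k < 2L || k > sum(!is.na(char)) - 2L) {
      message("skipping uninformative bipartition: ", all$bipartition[r])
      next
    }
    cols[[length(cols) + 1L]] <- char
    w <- c(w, all$support[r])
    prov[[length(prov) + 1L]] <- all[r, c("window", "bipartition")]
  }
  X <- if (length(cols)) do.call(cbind, cols)
       else matrix(integer(0), length(taxa), 0)
  rownames(X) <- taxa
  structure(list(X = X, weights = w,
                 provenance = if (length(prov)) do.call(rbind, prov)
                              else data.frame(window = character(0),
                                              bipartition = character(0)),
                 taxa = taxa),
            class = "mito_mrp")
}

#' @export
print.mito_mrp <- function(x, ...) {
  cat("Weighted MRP matrix:", length(x$taxa), "taxa x", ncol(x$X),
      "binary characters; total weight", format(sum(x$weights), digits = 5),
      "\n")
  invisible(x)
}

#' Write an MRP matrix as NEXUS (weighted characters) or TSV
#'
#' @param mrp a `mito_mrp`.
#' @param path output path.
#' @param format `"nexus"` or `"tsv"`.
#' @export
write_mrp <- function(mrp, path, format = c("nexus", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- as.data.frame(mrp$X)
    names(df) <- paste0("c", seq_len(ncol(mrp$X)))
    df <- cbind(taxon = rownames(mrp$X), df)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  rows <- apply(mrp$X, 1L, function(v)
    paste(ifelse(is.na(v), "?", v), collapse = ""))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               paste0("  DIMENSIONS NTAX=", nrow(mrp$X),
                      " NCHAR=", ncol(mrp$X), ";"),
               "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
               "  MATRIX"), con)
  writeLines(paste("   ", rownames(mrp$X), rows), con)
  writeLines(c("  ;", "END;", "BEGIN ASSUMPTIONS;",
               paste0("  WTSET * supertri = ",
                      paste(sprintf("%g: %d", mrp$weights,
                                    seq_along(mrp$weights)),
                            collapse = ", "), ";"),
               "END;"), con)
  invisible(path)
}

#' Weighted Fitch parsimony length of a tree on an MRP matrix
#'
#' Sum over characters of `weight x` the Fitch minimum number of changes on
#' the tree. Characters are binary; `NA` cells (taxa missing from a
#' character's source window) are treated as `?` and never force a change.
#' The tree's leaves must be a superset of the matrix taxa; extra leaves
#' are pruned before scoring. Scoring is exact on binary trees; on
#' multifurcations children are folded sequentially (an upper bound).
#'
#' @param tree a `phylo`.
#' @param mrp a `mito_mrp`.
#' @return the weighted parsimony length (numeric scalar).
#' @export
parsimony_length <- function(tree, mrp) {
  sum(mrp$weights * fitch_steps(tree, mrp))
}

# Fitch minimum-change counts per character, vectorized across characters.
fitch_steps <- function(tree, mrp) {
  taxa <- mrp$taxa
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) {
    stop("tree is missing leaves: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(tree$tip.label) > length(taxa)) {
    tree <- ape::keep.tip(tree, taxa)
  }
  nchar <- ncol(mrp$X)
  if (nchar == 0L) return(numeric(0))
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  # bitmask states: 1 = {0}, 2 = {1}, 3 = {0,1} (missing)
  tipX <- mrp$X[tree$tip.label, , drop = FALSE]
  state <- matrix(0L, ntip + nnode, nchar)
  state[seq_len(ntip), ] <- ifelse(is.na(tipX), 3L, tipX + 1L)
  cost <- numeric(nchar)
  seen <- integer(ntip + nnode)
  E <- tree$edge
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    s <- state[ch, ]
    if (seen[p] == 0L) {
      state[p, ] <- s
    } else {
      a <- state[p, ]
      inter <- bitwAnd(a, s)
      z <- inter == 0L
      cost <- cost + z
      state[p, ] <- ifelse(z, bitwOr(a, s), inter)
    }
    seen[p] <- seen[p] + 1L
  }
  cost
}
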