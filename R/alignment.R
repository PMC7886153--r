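#' @keywords internal
"_PACKAGE"

# Alphabet handled throughout: the 4 bases, IUPAC ambiguity codes, and gap.
DNA_BASES <- c("A", "C", "G", "T")
DNA_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
DNA_ALPHABET <- c(DNA_BASES, DNA_AMBIG, "-")

#' Construct an alignment object
#'
#' An alignment is a taxa-by-columns character matrix over the nucleotide
#' alphabet (A, C, G, T, IUPAC ambiguity codes, and `-` for gaps), with
#' optional per-taxon species and family labels. Input is case-insensitive;
#' residues are stored uppercase, `?` is normalized to `N` and `U` to `T`.
#' Columns are addressed by 1-based inclusive intervals everywhere.
#'
#' @param matrix character matrix (rows = taxa) or a named character vector
#'   of equal-length sequence strings.
#' @param species optional named character vector mapping taxon -> species.
#' @param family optional named character vector mapping taxon -> family.
#' @return an object of class `mito_alignment` with elements `matrix`
#'   (character matrix with taxon rownames), `species`, `family`.
#' @examples
#' aln <- alignment(c(a = "ACGT", b = "AC-T"))
#' aln_length(aln)
#' @export
alignment <- function(matrix, species = NULL, family = NULL) {
  if (is.character(matrix) && is.null(dim(matrix))) {
    if (is.null(names(matrix))) {
      stop("sequence vector must be named by taxon", call. = FALSE)
    }
    lens <- nchar(matrix)
    if (length(unique(lens)) > 1L) {
      stop("alignment error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")", call. = FALSE)
    }
    m <- do.call(rbind, strsplit(matrix, "", fixed = TRUE))
    rownames(m) <- names(matrix)
    matrix <- m
  }
  if (!is.matrix(matrix) || !is.character(matrix)) {
    stop("matrix must be a character matrix", call. = FALSE)
  }
  taxa <- rownames(matrix)
  if (is.null(taxa) || anyNA(taxa) || any(taxa == "")) {
    stop("identifier error: all taxa must be named", call. = FALSE)
  }
  if (anyDuplicated(taxa)) {
    stop("identifier error: duplicate taxon identifiers: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "), call. = FALSE)
  }
  m <- toupper(matrix)
  m[m == "?"] <- "N"
  m[m == "U"] <- "T"
  bad <- !(m %in% DNA_ALPHABET)
  if (any(bad)) {
    i <- which(bad)[1L]  # column-major position in the original matrix
    nr <- nrow(matrix)
    stop("alphabet error: illegal symbol '", matrix[i],
         "' for taxon '", taxa[(i - 1L) %% nr + 1L], "' at column ",
         (i - 1L) %/% nr + 1L, call. = FALSE)
  }
  dim(m) <- dim(matrix)
  rownames(m) <- taxa
  colnames(m) <- NULL
  structure(
    list(matrix = m,
         species = check_labels(species, taxa, "species"),
         family  = check_labels(family, taxa, "family")),
    class = "mito_alignment")
}

check_labels <- function(x, taxa, what) {
  if (is.null(x)) return(NULL)
  if (is.null(names(x))) {
    if (length(x) != length(taxa)) {
      stop(what, " labels must be named by taxon or match taxa in order",
           call. = FALSE)
    }
    names(x) <- taxa
  }
  missing <- setdiff(taxa, names(x))
  if (length(missing)) {
    stop(what, " labels missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  as.character(x)[match(taxa, names(x))] -> out
  names(out) <- taxa
  out
}

#' @rdname alignment
#' @param x,object a `mito_alignment`
#' @export
aln_length <- function(x) ncol(x$matrix)

#' @rdname alignment
#' @export
aln_taxa <- function(x) rownames(x$matrix)

#' @export
print.mito_alignment <- function(x, ...) {
  cat("Alignment: ", nrow(x$matrix), " taxa, ", ncol(x$matrix),
      " columns\n", sep = "")
  if (!is.null(x$species)) {
    cat("  species labels: ", length(unique(x$species)), " species\n",
        sep = "")
  }
  invisible(x)
}

#' @export
summary.mito_alignment <- function(object, ...) {
  m <- object$matrix
  cat("Alignment of", nrow(m), "taxa x", ncol(m), "columns\n")
  tab <- table(factor(m, levels = DNA_ALPHABET))
  cat("Residue counts:\n")
  print(tab[tab > 0])
  invisible(object)
}

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA, NEXUS (DATA block) and relaxed PHYLIP
#' (whitespace-delimited names of any length). All sequences must have equal
#' length; residues are normalized as in [alignment()].
#'
#' @param path file path.
#' @param format one of `"fasta"`, `"nexus"`, `"phylip-relaxed"`; by default
#'   guessed from the file extension.
#' @param species,family optional label vectors passed to [alignment()].
#' @return a `mito_alignment`.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "nexus",
                                            "phylip-relaxed"),
                           species = NULL, family = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      fa = , fas = , fasta = , fna = "fasta",
      nex = , nexus = , nxs = "nexus",
      phy = , phylip = "phylip-relaxed",
      "fasta")
  }
  seqs <- switch(format,
    fasta = {
      x <- ape::read.FASTA(path)
      vapply(lapply(as.character(x), paste, collapse = ""), identity, "")
    },
    nexus = {
      x <- ape::read.nexus.data(path)
      vapply(lapply(x, paste, collapse = ""), identity, "")
    },
    `phylip-relaxed` = read_phylip_relaxed(path))
  alignment(seqs, species = species, family = family)
}

# Relaxed PHYLIP: header "<ntax> <nchar>", then one record per line,
# name and sequence separated by whitespace (sequence may contain spaces).
read_phylip_relaxed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]),
                                              "\\s+")[[1L]]))
  if (length(hdr) < 2L || anyNA(hdr)) {
    stop("malformed PHYLIP header in ", path, call. = FALSE)
  }
  ntax <- hdr[1L]
  if (length(lines) < ntax + 1L) {
    stop("PHYLIP file declares ", ntax, " taxa but has fewer records",
         call. = FALSE)
  }
  recs <- lines[seq(2L, ntax + 1L)]
  parts <- regmatches(recs, regexpr("\\S+", recs))
  seqs <- gsub("\\s", "", substring(recs, nchar(parts) + 1L))
  names(seqs) <- parts
  seqs
}

#' Write an alignment
#'
#' @param aln a `mito_alignment`.
#' @param path output file path.
#' @param format `"fasta"`, `"nexus"` or `"phylip-relaxed"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path,
                            format = c("fasta", "nexus", "phylip-relaxed")) {
  format <- match.arg(format)
  seqs <- apply(aln$matrix, 1L, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    writeLines(rbind(paste0(">", names(seqs)), seqs), con)
  } else if (format == "phylip-relaxed") {
    writeLines(paste(length(seqs), nchar(seqs[1L])), con)
    writeLines(paste(names(seqs), seqs), con)
  } else {
    writeLines(c("#NEXUS", "BEGIN DATA;",
                 paste0("  DIMENSIONS NTAX=", length(seqs),
                        " NCHAR=", nchar(seqs[1L]), ";"),
                 "  FORMAT DATATYPE=DNA MISSING=N GAP=-;",
                 "  MATRIX"), con)
    writeLines(paste("   ", names(seqs), seqs), con)
    writeLines(c("  ;", "END;"), con)
  }
  invisible(path)
}

#' Read a gene partition table
#'
#' Tab-separated table with header columns `gene`, `start`, `end`, `strand`,
#' `phase`, `class` describing 1-based inclusive gene intervals, coding
#' strand (`+`/`-`), codon phase of the first column (1-3) and a gene class
#' (`protein_coding`, `rRNA`, `tRNA`, `control_region`, `other`).
#'
#' @param path TSV file path.
#' @return a data.frame with the columns above.
#' @export
read_partition <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene", "start", "end", "strand", "phase", "class")
  missing <- setdiff(needed, names(p))
  if (length(missing)) {
    stop("partition table missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_partition(p)
  p
}

validate_partition <- function(p, L = NULL) {
  if (any(p$start < 1L) || any(p$end < p$start)) {
    stop("bounds error: invalid gene interval(s)", call. = FALSE)
  }
  if (!is.null(L) && any(p$end > L)) {
    stop("bounds error: gene interval exceeds alignment length ", L,
         call. = FALSE)
  }
  if (!all(p$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  if (!all(p$phase %in% 1:3)) {
    stop("codon phase must be in 1..3", call. = FALSE)
  }
  invisible(p)
}
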