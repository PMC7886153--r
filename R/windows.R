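# Circular half-overlapping genome windows: k primary blocks tiling the
# alignment plus k half-offset secondary blocks, the last of which wraps
# past the final column, so that every column is covered exactly twice.

#' Build the circular half-overlapping window scheme
#'
#' The alignment is cut into `k` consecutive primary blocks of length
#' `base = floor(L / k)` (the last block absorbs the remainder). A second
#' set of `k` blocks of the same lengths starts `floor((base - 1) / 2)`
#' columns later; the last secondary block wraps circularly past column `L`
#' back to the start. The 2k windows are emitted interleaved in order of
#' start coordinate and labelled with lower-case roman numerals. Every
#' column lies in exactly two windows. For a 14,892-column mitogenome
#' alignment with `k = 5` this yields the ten sub-datasets
#' (i) 1-2978 ... (x) 13401-14892 + 1-1488.
#'
#' @param L alignment length (columns), `L >= 2 * k`.
#' @param k number of primary blocks (default 5, i.e. ten windows).
#' @return an object of class `mito_windows`: list with `L`, `k` and
#'   `windows`, a data.frame with columns `label`, `start`, `end`,
#'   `wrapped`, `start2`, `end2` (`NA` unless wrapped; a wrapped window
#'   covers `start..end` then `start2..end2`).
#' @export
make_windows <- function(L, k = 5L) {
  L <- as.integer(L); k <- as.integer(k)
  if (is.na(L) || is.na(k) || k < 1L || L < 2L * k) {
    stop("parameter error: need L >= 2 * k", call. = FALSE)
  }
  base <- L %/% k
  r <- L - k * base
  off <- (base - 1L) %/% 2L
  starts <- ends <- integer(0)
  s2 <- e2 <- integer(0)
  for (m in seq_len(k)) {
    p_start <- (m - 1L) * base + 1L
    p_len <- if (m == k) base + r else base
    # primary
    starts <- c(starts, p_start); ends <- c(ends, p_start + p_len - 1L)
    s2 <- c(s2, NA_integer_); e2 <- c(e2, NA_integer_)
    # secondary of the same length, shifted by off
    q_start <- p_start + off
    q_end <- q_start + p_len - 1L
    if (q_end > L) {
      starts <- c(starts, q_start); ends <- c(ends, L)
      s2 <- c(s2, 1L); e2 <- c(e2, q_end - L)
    } else {
      starts <- c(starts, q_start); ends <- c(ends, q_end)
      s2 <- c(s2, NA_integer_); e2 <- c(e2, NA_integer_)
    }
  }
  ord <- order(starts)
  w <- data.frame(label = tolower(as.roman(seq_len(2L * k))),
                  start = starts[ord], end = ends[ord],
                  wrapped = !is.na(s2[ord]),
                  start2 = s2[ord], end2 = e2[ord],
                  stringsAsFactors = FALSE)
  structure(list(L = L, k = k, windows = w), class = "mito_windows")
}

#' @export
print.mito_windows <- function(x, ...) {
  w <- x$windows
  cat("Circular half-overlapping windows: L =", x$L, ", k =", x$k,
      "->", nrow(w), "windows\n")
  for (i in seq_len(nrow(w))) {
    cat(sprintf("  (%s) %d-%d%s\n", w$label[i], w$start[i], w$end[i],
                if (w$wrapped[i])
                  sprintf(" + %d-%d", w$start2[i], w$end2[i]) else ""))
  }
  invisible(x)
}

#' Column indices covered by one window
#'
#' @param ws a `mito_windows`.
#' @param i window number (row of `ws$windows`).
#' @return integer vector of column indices in window order (tail segment
#'   then head segment for the wrapped window).
#' @export
window_columns <- function(ws, i) {
  w <- ws$windows[i, ]
  cols <- seq.int(w$start, w$end)
  if (w$wrapped) cols <- c(cols, seq.int(w$start2, w$end2))
  cols
}

#' Slice an alignment by a window scheme
#'
#' @param aln a `mito_alignment` whose length equals `ws$L`.
#' @param ws a `mito_windows`.
#' @return named list of `mito_alignment` objects, one per window, named by
#'   window label.
#' @export
slice_windows <- function(aln, ws) {
  if (aln_length(aln) != ws$L) {
    stop("window scheme length ", ws$L, " does not match alignment length ",
         aln_length(aln), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(ws$windows)), function(i) {
    sub <- aln
    sub$matrix <- aln$matrix[, window_columns(ws, i), drop = FALSE]
    sub
  })
  names(out) <- ws$windows$label
  out
}

#' Write a window table as TSV
#'
#' @param ws a `mito_windows`.
#' @param path output path.
#' @export
write_window_table <- function(ws, path) {
  utils::write.table(ws$windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
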