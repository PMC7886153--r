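# Alignment construction, format I/O, partitions, and curation.

test_that("constructor normalizes case, '?' and 'U'", {
  aln <- alignment(c(a = "acg?u", b = "ACGTN"))
  expect_equal(unname(aln$matrix["a", ]), c("A", "C", "G", "N", "T"))
  expect_equal(aln_length(aln), 5L)
  expect_equal(aln_taxa(aln), c("a", "b"))
})

test_that("constructor rejects malformed input with labelled errors", {
  expect_error(alignment(c(a = "ACGT", b = "ACG")), "alignment error")
  m <- matrix("A", 2, 3)
  rownames(m) <- c("x", "x")
  expect_error(alignment(m), "identifier error")
  expect_error(alignment(c(a = "ACXT", b = "ACGT")), "alphabet error")
  expect_error(alignment(c(a = "ACXT", b = "ACGT")), "column 3")
  expect_error(alignment(c("ACGT", "ACGT")), "named")
})

test_that("species/family labels are validated and reordered", {
  aln <- alignment(c(a = "ACGT", b = "AC-T"),
                   species = c(b = "sp2", a = "sp1"))
  expect_equal(aln$species, c(a = "sp1", b = "sp2"))
  expect_error(alignment(c(a = "ACGT", b = "AC-T"),
                         species = c(a = "sp1")), "missing")
})

test_that("fasta, nexus and relaxed phylip round-trip", {
  aln <- alignment(c(tax_one = "ACGTAC-TNR", tax_two = "ACCTACGTAA"))
  for (fmt in c("fasta", "nexus", "phylip-relaxed")) {
    f <- tempfile(fileext = switch(fmt, fasta = ".fa", nexus = ".nex",
                                   `phylip-relaxed` = ".phy"))
    write_alignment(aln, f, format = fmt)
    back <- read_alignment(f)
    expect_equal(back$matrix, aln$matrix, info = fmt)
  }
})

test_that("relaxed phylip accepts long names and rejects bad headers", {
  f <- tempfile(fileext = ".phy")
  writeLines(c("2 6", "a_very_long_identifier ACG TAC",
               "b ACGTAA"), f)
  aln <- read_alignment(f)
  expect_equal(aln_taxa(aln), c("a_very_long_identifier", "b"))
  expect_equal(aln_length(aln), 6L)
  writeLines(c("not a header", "a ACGTAC"), f)
  expect_error(read_alignment(f), "malformed PHYLIP header")
})

test_that("partition tables are validated", {
  p <- data.frame(gene = c("g1", "g2"), start = c(1L, 10L),
                  end = c(9L, 15L), strand = c("+", "-"),
                  phase = c(1L, 1L), class = c("protein_coding", "tRNA"))
  f <- tempfile(fileext = ".tsv")
  write.table(p, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_partition(f), p)
  p2 <- p; p2$start[1] <- 0L
  expect_error(validate_partition(p2), "bounds error")
  p3 <- p; p3$strand[1] <- "x"
  expect_error(validate_partition(p3), "strand")
  expect_error(validate_partition(p, L = 12), "bounds error")
})

test_that("mask_regions unions intervals and maps columns", {
  aln <- alignment(c(a = "ACGTACGT", b = "ACGTACGT"))
  out <- mask_regions(aln, list(c(2, 4), c(3, 5)))
  expect_equal(aln_length(out), 4L)
  cmap <- attr(out, "column_map")
  expect_true(all(is.na(cmap[2:5])))
  expect_equal(cmap[c(1, 6, 7, 8)], 1:4)
  expect_error(mask_regions(aln, list(c(0, 2))), "bounds error")
  expect_error(mask_regions(aln, list(c(5, 2))), "bounds error")
})

test_that("indel events are keyed by gap-presence runs with polarity", {
  aln <- alignment(c(a = "AC--ACGTAC",
                     b = "ACGTACGT--",
                     c = "ACGTAC--AC",
                     d = "ACGTACGTAC"))
  ev <- find_indel_events(aln)
  expect_equal(nrow(ev), 3L)
  # each event has one gap carrier among 4 taxa -> deletion
  expect_true(all(ev$polarity == "deletion"))
  expect_equal(ev$carriers, c("a", "c", "b"))
  expect_equal(ev$start, c(3L, 7L, 9L))
  expect_equal(ev$end, c(4L, 8L, 10L))
})

test_that("insertion polarity: residue-bearing minority carries the event", {
  aln <- alignment(c(a = "ACGTAC", b = "AC--AC", c = "AC--AC", d = "AC--AC"))
  ev <- find_indel_events(aln)
  expect_equal(ev$polarity, "insertion")
  expect_equal(ev$carriers, "a")
  # 2 vs 2 tie counts as deletion
  tie <- alignment(c(a = "AC--AC", b = "AC--AC", c = "ACGTAC", d = "ACGTAC"))
  expect_equal(find_indel_events(tie)$polarity, "deletion")
})

test_that("singleton insertions are deleted, singleton deletions kept", {
  aln <- alignment(c(a = "ACGTTTAC", b = "AC----AC", c = "AC----AC",
                     d = "AC----AC", e = "ACGT--AC"))
  # columns 3-4: residues in a,e (2 carriers, not singleton)
  # columns 5-6: residues only in a -> singleton insertion, deleted
  cur <- remove_singleton_indels(aln)
  expect_equal(aln_length(cur$alignment), 6L)
  expect_equal(cur$report$action, "columns_deleted")
  expect_equal(unname(cur$alignment$matrix["a", ]),
               c("A", "C", "G", "T", "A", "C"))
  # all_singletons additionally recodes unique deletions to N
  del <- alignment(c(a = "AC--AC", b = "ACGTAC", c = "ACGTAC", d = "ACGTAC"))
  cur2 <- remove_singleton_indels(del, mode = "all_singletons")
  expect_equal(aln_length(cur2$alignment), 6L)
  expect_equal(unname(cur2$alignment$matrix["a", 3:4]), c("N", "N"))
})

test_that("transversion recoding applies the G->A / T->C mapping", {
  aln <- alignment(c(a = "AGRCTY", b = "SWKMBN"))
  out <- recode_transversions(aln)
  expect_equal(unname(out$matrix["a", ]),
               c("A", "A", "A", "C", "C", "C"))
  expect_equal(unname(out$matrix["b", ]), rep("N", 6))
  gap <- alignment(c(a = "A-GT", b = "ACG-"))
  expect_equal(unname(recode_transversions(gap)$matrix["a", ]),
               c("A", "-", "A", "C"))
})

test_that("transversion recoding is idempotent (property)", {
  for (s in 1:20) {
    aln <- random_alignment(4, 30, alphabet = DNA_ALPHABET, seed = s)
    once <- recode_transversions(aln)
    twice <- recode_transversions(once)
    expect_identical(twice$matrix, once$matrix)
    expect_true(all(once$matrix %in% c("A", "C", "N", "-")))
  }
})

test_that("extract_pcg keeps plus-strand protein genes with codon phases", {
  aln <- alignment(c(a = paste(rep("ACGT", 5), collapse = ""),
                     b = paste(rep("ACGT", 5), collapse = "")))
  parts <- data.frame(gene = c("g1", "nd6", "rrn"),
                      start = c(1L, 7L, 13L), end = c(6L, 12L, 20L),
                      strand = c("+", "-", "+"), phase = c(1L, 1L, 1L),
                      class = c("protein_coding", "protein_coding", "rRNA"))
  pcg <- extract_pcg(aln, parts)
  expect_equal(aln_length(pcg), 6L)
  expect_equal(attr(pcg, "codon_positions"), rep(1:3, 2))
  expect_equal(attr(pcg, "source_columns"), 1:6)
  # phase 2 starts mid-codon; non-multiple-of-3 warns
  parts2 <- data.frame(gene = "g", start = 1L, end = 5L, strand = "+",
                       phase = 2L, class = "protein_coding")
  expect_warning(pcg2 <- extract_pcg(aln, parts2), "multiple of 3")
  expect_equal(attr(pcg2, "codon_positions"), c(2L, 3L, 1L, 2L, 3L))
})
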