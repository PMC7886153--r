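# Splits, MRP construction, weighted Fitch, supertree search, SBP,
# classification and conflict detection.

test_that("split canonicalization pools a split with its complement", {
  taxa <- c("a", "b", "c", "d", "e")
  expect_equal(canonical_split(c("d", "e"), taxa), "d,e")
  expect_equal(canonical_split(c("a", "b", "c"), taxa), "d,e")  # complement
  expect_true(is.na(canonical_split("a", taxa)))                # trivial
  expect_true(is.na(canonical_split(c("b", "c", "d", "e"), taxa)))
})

test_that("split compatibility matches the four-intersection rule", {
  taxa <- c("a", "b", "c", "d")
  expect_false(splits_compatible("a,b", "a,c", taxa))  # ab|cd vs ac|bd
  expect_true(splits_compatible("a,b", "a,b", taxa))
  taxa6 <- c("a", "b", "c", "d", "e", "f")
  expect_true(splits_compatible("a,b", "a,b,c", taxa6))   # nested
  expect_true(splits_compatible("a,b", "e,f", taxa6))     # disjoint
  expect_false(splits_compatible("a,b,c", "c,d,e", taxa6))
})

test_that("bipartition frequencies pool complements and floor support", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((c,d),(a,b),e);")  # same splits, rewritten
  t3 <- ape::read.tree(text = "((a,c),(b,d),e);")
  ts <- tree_sample(list(t1, t2, t3), label = "w1")
  bf <- bipartition_frequencies(ts, floor = 0.05)
  expect_equal(bf$support[bf$bipartition == "c,d"], 2 / 3)
  expect_equal(bf$support[bf$bipartition == "b,d"], 1 / 3)
  expect_equal(unique(bf$window), "w1")
  hi <- bipartition_frequencies(ts, floor = 0.5)
  expect_false("b,d" %in% hi$bipartition)
})

test_that("MRP matrix codes ingroups, carries weights, skips trivia", {
  taxa <- c("a", "b", "c", "d", "e")
  lists <- list(data.frame(bipartition = c("a,b", "d,e"),
                           support = c(1, 0.6), window = "i"),
                data.frame(bipartition = "a,b", support = 0.9,
                           window = "ii"))
  mrp <- build_mrp(lists, taxa)
  expect_equal(ncol(mrp$X), 3L)
  expect_equal(mrp$weights, c(1, 0.6, 0.9))
  expect_equal(unname(mrp$X[, 1]), as.integer(taxa %in% c("a", "b")))
  expect_equal(mrp$provenance$window, c("i", "i", "ii"))
  expect_error(build_mrp(list(data.frame(bipartition = "a,z", support = 1,
                                         window = "i")), taxa),
               "unknown taxa")
  # a split trivial on the universe is skipped with a message
  expect_message(m2 <- build_mrp(list(data.frame(
    bipartition = "a,b,c,d", support = 1, window = "i")), taxa),
    "uninformative")
  expect_equal(ncol(m2$X), 0L)
})

test_that("MRP writers emit NEXUS with weights and TSV", {
  mrp <- random_mrp(5, 4, seed = 2)
  fn <- tempfile(fileext = ".nex")
  write_mrp(mrp, fn)
  txt <- readLines(fn)
  expect_true(any(grepl("NTAX=5 NCHAR=4", txt)))
  expect_true(any(grepl("WTSET", txt)))
  ft <- tempfile(fileext = ".tsv")
  write_mrp(mrp, ft, format = "tsv")
  back <- read.delim(ft)
  expect_equal(as.matrix(back[, -1]),
               matrix(mrp$X, 5, 4, dimnames = list(NULL, paste0("c", 1:4))),
               ignore_attr = TRUE)
})

test_that("weighted Fitch equals the independent parsimony oracle", {
  for (s in 1:15) {
    set.seed(s)
    n <- sample(4:8, 1)
    mrp <- random_mrp(n, sample(3:10, 1), seed = s + 100)
    if (s %% 3 == 0) mrp$X[sample(length(mrp$X), 3)] <- NA  # '?' cells
    tr <- ape::rtree(n, tip.label = sample(mrp$taxa), rooted = FALSE)
    expect_equal(parsimony_length(tr, mrp), phangorn_score(tr, mrp),
                 tolerance = 1e-10)
  }
})

test_that("extra tree leaves are pruned; absent leaves are an error", {
  mrp <- random_mrp(5, 3, seed = 9)
  big <- ape::rtree(7, tip.label = c(mrp$taxa, "x1", "x2"))
  expect_equal(parsimony_length(big, mrp),
               phangorn_score(ape::keep.tip(big, mrp$taxa), mrp))
  small <- ape::rtree(4, tip.label = mrp$taxa[1:4])
  expect_error(parsimony_length(small, mrp), "missing leaves")
})

test_that("exhaustive, branch-and-bound and brute force agree", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(5:7, 1)
    mrp <- random_mrp(n, sample(4:9, 1), seed = s + 500)
    ex <- mrp_supertree(mrp, search = "exhaustive")
    bb <- mrp_supertree(mrp, search = "branch_and_bound")
    oracle <- brute_force_optima(mrp)
    expect_equal(attr(ex, "score"), oracle$score, tolerance = 1e-9)
    expect_equal(attr(bb, "score"), oracle$score, tolerance = 1e-9)
    my_newicks <- sort(vapply(attr(ex, "optima"),
                              mitophylo:::canonical_newick, character(1)))
    expect_equal(my_newicks, oracle$newicks)
    bb_newicks <- sort(vapply(attr(bb, "optima"),
                              mitophylo:::canonical_newick, character(1)))
    expect_equal(bb_newicks, oracle$newicks)
  }
})

test_that("NNI hill-climbing finds the exhaustive optimum on easy input", {
  # congruent characters: the true tree's splits, thrice each
  tr <- ape::read.tree(text = "((a,b),(c,d),(e,f));")
  taxa <- sort(tr$tip.label)
  keys <- tree_splits(tr, taxa)
  lists <- lapply(1:3, function(i)
    data.frame(bipartition = keys, support = 1, window = as.character(i)))
  mrp <- build_mrp(lists, taxa)
  ex <- mrp_supertree(mrp, search = "exhaustive")
  nn <- mrp_supertree(mrp, search = "nni_hillclimb", seed = 4)
  expect_equal(attr(nn, "score"), attr(ex, "score"))
  expect_equal(ape::dist.topo(nn, tr), 0, ignore_attr = TRUE)
})

test_that("SBP is high for congruent matrices and bounded in [0,100]", {
  tr <- ape::read.tree(text = "((a,b),(c,d),(e,f));")
  taxa <- sort(tr$tip.label)
  keys <- tree_splits(tr, taxa)
  lists <- lapply(1:6, function(i)
    data.frame(bipartition = keys, support = 1, window = as.character(i)))
  mrp <- build_mrp(lists, taxa)
  boot <- supertri_bootstrap(mrp, n_reps = 100, seed = 5,
                             search = "exhaustive")
  expect_true(all(boot$sbp$sbp >= 0 & boot$sbp$sbp <= 100))
  for (k in keys) {
    expect_gte(boot$sbp$sbp[boot$sbp$bipartition == k], 95)
  }
  # splits of the majority consensus are mutually compatible
  cons_keys <- boot$sbp$bipartition[boot$sbp$sbp > 50]
  for (i in seq_along(cons_keys)) {
    for (j in seq_len(i - 1L)) {
      expect_true(splits_compatible(cons_keys[i], cons_keys[j], taxa))
    }
  }
  expect_equal(ape::dist.topo(boot$consensus, tr), 0, ignore_attr = TRUE)
})

test_that("consensus construction nests compatible splits laminarly", {
  taxa <- c("a", "b", "c", "d", "e", "f")
  tr <- mitophylo:::tree_from_splits(c("e,f", "c,d,e,f", "c,d"), taxa)
  expect_equal(sort(tree_splits(tr, taxa)), sort(c("c,d", "c,d,e,f", "e,f")))
  star <- mitophylo:::tree_from_splits(character(0), taxa)
  expect_equal(length(tree_splits(star, taxa)), 0L)
})

test_that("reproduction index counts windows containing the split", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((a,c),(b,d),e);")
  expect_equal(reproduction_index("c,d", list(t1, t2, t1)), 2L)
  expect_equal(reproduction_index("b,d", list(t1, t2, t1)), 1L)
  expect_equal(reproduction_index("a,e", list(t1, t2, t1)), 0L)
})

test_that("node classification follows the three-way rule", {
  expect_equal(classify_node(0.99, 98, 10), "signal_genome_wide")
  expect_equal(classify_node(0.96, 60, 3), "signal_weak_or_local")
  expect_equal(classify_node(0.99, 98, 3), "intermediate")
  expect_equal(classify_node(0.5, 98, 10), "intermediate")
  expect_equal(classify_node(0.96, 94.9, 5), "intermediate")
  # vectorized
  expect_equal(classify_node(c(0.99, 0.96), c(98, 60), c(10, 3)),
               c("signal_genome_wide", "signal_weak_or_local"))
})

test_that("robust main-vs-supertree incompatibility raises a conflict", {
  taxa <- c("a", "b", "c", "d")
  main <- data.frame(bipartition = "a,b", pp = 1.0)
  sup <- data.frame(bipartition = "a,c", sbp = 97)
  conf <- detect_conflicts(main, sup, taxa)
  expect_equal(nrow(conf), 1L)
  expect_equal(conf$main_bipartition, "a,b")
  expect_equal(conf$super_bipartition, "a,c")
  # below either threshold: no conflict
  expect_equal(nrow(detect_conflicts(
    data.frame(bipartition = "a,b", pp = 0.94), sup, taxa)), 0L)
  expect_equal(nrow(detect_conflicts(
    main, data.frame(bipartition = "a,c", sbp = 94), taxa)), 0L)
  # compatible pair: no conflict
  expect_equal(nrow(detect_conflicts(
    main, data.frame(bipartition = "a,b", sbp = 99), taxa)), 0L)
})

test_that("node support tables join pp, sbp, nrep and flag conflicts", {
  taxa <- c("a", "b", "c", "d", "e")
  # canonical split keys exclude the first taxon: {a,b} -> "c,d,e",
  # {a,c} -> "b,d,e"
  main <- data.frame(bipartition = c("c,d,e", "d,e"), pp = c(1.0, 0.97))
  sup <- data.frame(bipartition = c("c,d,e", "b,d,e"), sbp = c(99, 96))
  wt <- list(ape::read.tree(text = "((a,b),(d,e),c);"),
             ape::read.tree(text = "((a,b),(c,d),e);"))
  tab <- node_support_table(main, sup, wt, taxa, n_windows = 10)
  expect_equal(tab$sbp, c(99, 0))   # absent split gets 0
  expect_equal(tab$nrep, c(2L, 1L))
  expect_true(tab$conflict_suspect[tab$bipartition == "c,d,e"])
  conf <- attr(tab, "conflicts")
  expect_equal(conf$super_bipartition, "b,d,e")
})
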