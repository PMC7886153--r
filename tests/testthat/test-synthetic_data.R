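# Simulation and perturbation injectors.

test_that("sim_config validates its parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(base_freq = c(0.5, 0.5, 0.1, 0.1)), "sum")
  expect_error(sim_config(p_inv = 1), "p_inv")
  expect_error(sim_config(gamma_alpha = 0), "gamma_alpha")
})

test_that("Yule trees are ultrametric, sized and reproducible", {
  cfg <- sim_config(n_taxa = 9, seed = 4)
  t1 <- simulate_yule_tree(cfg)
  t2 <- simulate_yule_tree(cfg)
  expect_equal(length(t1$tip.label), 9L)
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("zero-length branches give identical sequences", {
  tr <- ape::read.tree(text = "(a:0,b:0,c:0);")
  cfg <- sim_config(n_taxa = 3, L = 500, seed = 2)
  aln <- simulate_sequences(tr, cfg)
  expect_equal(unname(aln$matrix["a", ]), unname(aln$matrix["b", ]))
  expect_equal(unname(aln$matrix["a", ]), unname(aln$matrix["c", ]))
})

test_that("two-taxon JC divergence matches the closed form", {
  # JC: equal rates and frequencies; rate homogeneity approximated by a
  # large gamma shape; expected p = (3/4)(1 - exp(-(4/3) t))
  tr <- ape::read.tree(text = "(a:0.05,b:0.05);")
  cfg <- sim_config(n_taxa = 2, L = 20000, gtr_rates = rep(1, 6),
                    base_freq = rep(0.25, 4), gamma_alpha = 1e6,
                    p_inv = 0, seed = 31)
  aln <- simulate_sequences(tr, cfg)
  p_obs <- p_distance_matrix(aln)$d["a", "b"]
  p_exp <- 0.75 * (1 - exp(-4 / 3 * 0.1))
  # Monte-Carlo tolerance: 4 binomial standard errors
  se <- sqrt(p_exp * (1 - p_exp) / 20000)
  expect_lt(abs(p_obs - p_exp), 4 * se)
})

test_that("long simulations approach the stationary frequencies", {
  tr <- ape::read.tree(text = "(a:0.4,b:0.4);")
  cfg <- sim_config(n_taxa = 2, L = 50000, p_inv = 0, seed = 13)
  aln <- simulate_sequences(tr, cfg)
  for (tax in c("a", "b")) {
    f <- table(factor(aln$matrix[tax, ], levels = c("A", "C", "G", "T")))
    f <- as.numeric(f) / sum(f)
    expect_true(all(abs(f - cfg$base_freq) < 0.01),
                info = paste("taxon", tax))
  }
})

test_that("sequence simulation is seed-deterministic", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.05,c:0.15);")
  cfg <- sim_config(n_taxa = 3, L = 300, seed = 8)
  expect_identical(simulate_sequences(tr, cfg)$matrix,
                   simulate_sequences(tr, cfg)$matrix)
  cfg2 <- sim_config(n_taxa = 3, L = 300, seed = 9)
  expect_false(identical(simulate_sequences(tr, cfg)$matrix,
                         simulate_sequences(tr, cfg2)$matrix))
})

test_that("clade shift displaces composition on a long stem", {
  # the shifted frequency vector itself
  bf <- c(0.31, 0.26, 0.13, 0.30)
  sh <- mitophylo:::shifted_bf(bf, "A", 0.5)
  expect_equal(unname(sh), c(0.81, 0.26, 0.13, 0.30) / 1.5)
  expect_equal(sum(sh), 1)
  expect_error(mitophylo:::shifted_bf(bf, "G", -0.2), "below 0")
  # within one simulated alignment, the shifted taxon (long terminal
  # branch) is A-enriched relative to every other lineage
  fx <- simulate_fixture(L = 6000, seed = 6,
                         clade_shift = list(taxa = "D3", base = "A",
                                            delta = 0.5))
  freq_A <- function(tax) mean(fx$alignment$matrix[tax, ] == "A")
  others <- setdiff(aln_taxa(fx$alignment), "D3")
  expect_gt(freq_A("D3"), mean(vapply(others, freq_A, 0)) + 0.01)
})

test_that("near-duplicate injection respects the distance ceiling", {
  fx <- simulate_fixture(L = 2000, seed = 5)
  aln <- inject_near_duplicates(fx$alignment, species = "B2", k = 2,
                                max_d = 0.005, seed = 3)
  expect_equal(aln_taxa(aln)[13:14], c("B2_dup1", "B2_dup2"))
  expect_equal(unname(aln$species[c("B2_dup1", "B2_dup2")]),
               rep(unname(fx$species["B2"]), 2))
  dm <- p_distance_matrix(aln)
  group <- c("B2", "B2_dup1", "B2_dup2")
  expect_true(all(dm$d[group, group] <= 0.005))
  # max_d = 0 means exact copies
  same <- inject_near_duplicates(fx$alignment, "B2", k = 1, max_d = 0)
  expect_equal(unname(same$matrix["B2_dup1", ]),
               unname(same$matrix["B2", ]))
  # seeded reproducibility
  a1 <- inject_near_duplicates(fx$alignment, "B2", k = 2, seed = 7)
  a2 <- inject_near_duplicates(fx$alignment, "B2", k = 2, seed = 7)
  expect_identical(a1$matrix, a2$matrix)
})

test_that("chimera injection replaces exactly the listed columns", {
  fx <- simulate_fixture(L = 1000, seed = 2)
  out <- inject_chimera(fx$alignment, host = "C1", donor = "A3",
                        intervals = list(c(101, 300), c(1, 50)))
  man <- attr(out, "chimera_manifest")
  expect_equal(man$host, "C1")
  expect_setequal(man$columns, c(1:50, 101:300))
  expect_equal(out$matrix["C1", man$columns],
               fx$alignment$matrix["A3", man$columns])
  untouched <- setdiff(seq_len(1000), man$columns)
  expect_equal(out$matrix["C1", untouched],
               fx$alignment$matrix["C1", untouched])
  # empty interval list is the identity
  id <- inject_chimera(fx$alignment, "C1", "A3", list())
  expect_identical(id$matrix, fx$alignment$matrix)
  # full-length interval turns the host into a duplicate
  dup <- inject_chimera(fx$alignment, "C1", "A3", list(c(1, 1000)))
  expect_equal(p_distance_matrix(dup)$d["C1", "A3"], 0)
  expect_error(inject_chimera(fx$alignment, "C1", "A3", list(c(0, 10))),
               "bounds error")
  expect_error(inject_chimera(fx$alignment, "C1", "C1", list(c(1, 5))))
})

test_that("singleton insertions add gap columns for all but the carrier", {
  fx <- simulate_fixture(L = 500, seed = 1)
  out <- inject_singleton_insertion(fx$alignment, "C2", position = 100,
                                    length = 9, seed = 2)
  expect_equal(aln_length(out), 509L)
  man <- attr(out, "insertion_manifest")
  expect_equal(man$columns, 101:109)
  expect_true(all(out$matrix["C2", 101:109] %in% c("A", "C", "G", "T")))
  others <- setdiff(aln_taxa(out), "C2")
  expect_true(all(out$matrix[others, 101:109] == "-"))
  # flanks preserved
  expect_equal(out$matrix[, 1:100], fx$alignment$matrix[, 1:100])
  expect_equal(out$matrix[, 110:509], fx$alignment$matrix[, 101:500])
  expect_identical(inject_singleton_insertion(fx$alignment, "C2", 100, 0),
                   fx$alignment)
  expect_error(inject_singleton_insertion(fx$alignment, "C2", 501, 3))
})

test_that("the standard fixture is labelled and reproducible", {
  fx <- simulate_fixture(L = 800, seed = 10)
  expect_equal(length(aln_taxa(fx$alignment)), 12L)
  expect_equal(sort(unique(unname(fx$family))), LETTERS[1:4])
  expect_equal(aln_length(fx$alignment), 800L)
  fx2 <- simulate_fixture(L = 800, seed = 10)
  expect_identical(fx$alignment$matrix, fx2$alignment$matrix)
})
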