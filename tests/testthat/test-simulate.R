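test_that("triple sampler matches the MSC closed form without introgression", {
  m <- msci_from_grid("GHOST", 0.3, 1.5, 0)   # gamma 0: plain species tree
  tr <- simulate_triples(m, 1e5, seed = 301)
  p_hat <- as.numeric(table(tr$topology)) / 1e5
  p <- unname(topology_probs(0, 1.5, 1.5))    # 1 - (2/3)e^-1.5 = 0.8512...
  expect_equal(p[1], 1 - 2 / 3 * exp(-1.5))
  se <- sqrt(p * (1 - p) / 1e5)
  expect_true(all(abs(p_hat - p) <= 3 * se))
  # ages respect the species tree support
  expect_true(all(tr$t1 >= m$tau_T - 1e-12))
  expect_true(all(tr$t2 >= m$tau_R - 1e-12))
  expect_true(all(tr$t1 <= tr$t2))
})

test_that("a fully introgressed ghost delays every a-coalescence past tau_G", {
  m <- msci_from_grid("GHOST", 0.3, 1.5, 1)   # gamma 1
  tr <- simulate_triples(m, 5000, seed = 302)
  t_ab <- ifelse(tr$topology == "ab|c", tr$t1, tr$t2)
  expect_true(min(t_ab) >= m$tau_G)
  tt <- simulate_gene_trees(m, sim_config(n_loci = 200, seed = 303))
  tri <- as_triples(tt)
  expect_true(min(ifelse(tri$topology == "ab|c", tri$t1, tri$t2)) >= m$tau_G)
})

test_that("event-driven and vectorized samplers agree with theory", {
  for (s in c("GHOST", "INFLOW", "OUTFLOW")) {
    m <- msci_from_grid(s, 0.3, 0.5, 0.3)
    cu <- coalescent_units(m)
    tri <- as_triples(simulate_gene_trees(m, sim_config(n_loci = 4000,
                                                        seed = 310 + nchar(s))))
    p <- unname(topology_probs(0.3, cu[["C_T"]], cu[["C_S"]]))
    p_hat <- as.numeric(table(tri$topology)) / 4000
    expect_true(all(abs(p_hat - p) <= 3.5 * sqrt(p * (1 - p) / 4000)))
    # pairwise ages against the analytic law (KS)
    d <- pairwise_density(m, "bc")
    age <- ifelse(tri$topology == "a|bc", tri$t1, tri$t2)
    ks <- suppressWarnings(stats::ks.test(age, function(q) mixture_cdf(d, q)))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("inflow and outflow are exchangeable at matched (C_T, C_S, gamma)", {
  # C_T = 0.5, C_S = 1.2 in both directions of gene flow
  mi <- msci_from_grid("INFLOW", 1.5 - 0.7, 0.5, 0.3)
  mo <- msci_from_grid("OUTFLOW", 1.5 - 1.2, 0.5, 0.3)
  expect_equal(coalescent_units(mi), coalescent_units(mo))
  p <- unname(topology_probs(0.3, 0.5, 1.2))
  for (m in list(mi, mo)) {
    tr <- simulate_triples(m, 4e4, seed = 320)
    p_hat <- as.numeric(table(tr$topology)) / 4e4
    expect_true(all(abs(p_hat - p) <= 3 * sqrt(p * (1 - p) / 4e4)))
  }
})

test_that("sequence evolution reproduces the JC69 distance law", {
  tr <- ape::read.tree(text = "(x:0.05,y:0.05);")
  cfg <- sim_config(n_loci = 1, sites = 4e4, model = "JC69", seed = 330)
  a <- simulate_alignments(c(tr), cfg)[[1]]
  p_diff <- mean(a["x", ] != a["y", ])
  p_exp <- 3 / 4 * (1 - exp(-4 * 0.1 / 3))
  expect_equal(p_diff, p_exp, tolerance = 0.05)
  # HKY with kappa 1 and equal frequencies reduces to JC69
  cfg2 <- sim_config(n_loci = 1, sites = 4e4, model = "HKY", kappa = 1,
                     seed = 331)
  b <- simulate_alignments(c(tr), cfg2)[[1]]
  expect_equal(mean(b["x", ] != b["y", ]), p_exp, tolerance = 0.05)
  # near-zero tree: identical sequences everywhere
  tr0 <- ape::read.tree(text = "((a:0,b:0):0,(c:0,o:0):1e-12);")
  z <- simulate_alignments(c(tr0), sim_config(n_loci = 1, sites = 200,
                                              seed = 332))[[1]]
  expect_true(all(apply(z, 2, function(col) length(unique(col)) == 1L)))
  # negative branch lengths are rejected
  trn <- ape::read.tree(text = "(x:-0.1,y:0.05);")
  expect_error(simulate_alignments(c(trn), cfg), "non-negative")
})

test_that("datasets round-trip losslessly and deterministically", {
  m <- msci_from_grid("INFLOW", 0.3, 0.5, 0.3)
  cfg <- sim_config(n_loci = 5, sites = 40, seed = 340)
  trees <- simulate_gene_trees(m, cfg)
  aln <- simulate_alignments(trees, cfg)
  out <- withr::local_tempdir()
  write_dataset(trees, aln, out, model = m, config = cfg)
  back <- read_dataset(out)
  expect_length(back$alignments, 5L)
  for (i in 1:5) {
    expect_identical(back$alignments[[i]][rownames(aln[[i]]), ], aln[[i]])
    expect_true(isTRUE(all.equal(back$trees[[i]], trees[[i]],
                                 use.edge.length = FALSE)))
    expect_equal(sort(ape::branching.times(back$trees[[i]])),
                 sort(ape::branching.times(trees[[i]])), tolerance = 1e-12)
  }
  expect_equal(back$manifest[["seed"]], "340")
  # the recorded seed reruns to identical trees
  trees2 <- simulate_gene_trees(m, sim_config(n_loci = 5, sites = 40,
                                              seed = 340))
  expect_equal(ape::write.tree(trees2), ape::write.tree(trees))
  # phylip round-trip and empty dataset
  out2 <- withr::local_tempdir()
  write_dataset(trees, aln, out2, format = "phylip")
  back2 <- read_dataset(out2)
  expect_identical(back2$alignments[[2]][rownames(aln[[2]]), ], aln[[2]])
  out3 <- withr::local_tempdir()
  write_dataset(NULL, NULL, out3, model = m)
  empty <- read_dataset(out3)
  expect_length(empty$alignments, 0L)
  expect_error(read_dataset(file.path(out3, "nope")), "manifest")
})

test_that("multiple sequences per species are simulated coherently", {
  m <- msci_from_grid("INFLOW", 0.3, 0.5, 0.5)
  cfg <- sim_config(n_loci = 50, seqs_per_species = 3, seed = 350)
  trees <- simulate_gene_trees(m, cfg)
  expect_setequal(trees[[1]]$tip.label,
                  c(paste0(rep(c("a", "b", "c"), each = 3), 1:3), "o"))
  # within-species pairs cannot coalesce before their species joins others
  bt <- ape::branching.times(trees[[7]])
  expect_true(all(bt > 0))
  expect_true(ape::is.ultrametric(trees[[3]], tol = 1e-8))
})
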