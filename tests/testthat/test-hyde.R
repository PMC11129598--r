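aln_from_strings <- function(a, b, c, o) {
  m <- rbind(a = strsplit(a, "")[[1]], b = strsplit(b, "")[[1]],
             c = strsplit(c, "")[[1]], o = strsplit(o, "")[[1]])
  m
}

test_that("site-pattern classification follows the outgroup-polarized rules", {
  # constant sites carry no pattern
  cnt <- count_site_patterns(aln_from_strings("aaaa", "aaaa", "aaaa", "aaaa"))
  expect_equal(unname(cnt$pooled), c(0L, 0L, 0L))
  # single informative site of each kind (uppercase is accepted)
  expect_equal(unname(count_site_patterns(
    aln_from_strings("G", "G", "A", "A"))$pooled), c(1L, 0L, 0L))
  cnt1 <- count_site_patterns(aln_from_strings("g", "g", "a", "a"))
  expect_equal(unname(cnt1$pooled), c(1L, 0L, 0L))
  cnt2 <- count_site_patterns(aln_from_strings("a", "g", "g", "a"))
  expect_equal(unname(cnt2$pooled), c(0L, 1L, 0L))
  cnt3 <- count_site_patterns(aln_from_strings("g", "a", "g", "a"))
  expect_equal(unname(cnt3$pooled), c(0L, 0L, 1L))
  # three-allele and triple-derived sites are excluded
  expect_equal(sum(count_site_patterns(
    aln_from_strings("g", "t", "a", "a"))$pooled), 0L)
  expect_equal(sum(count_site_patterns(
    aln_from_strings("g", "g", "g", "a"))$pooled), 0L)
  # two ingroup taxa share a state that the outgroup also carries: no pattern
  expect_equal(sum(count_site_patterns(
    aln_from_strings("a", "a", "g", "a"))$pooled), 0L)
  # malformed input is rejected loudly
  expect_error(count_site_patterns(aln_from_strings("gn", "gg", "aa", "aa")),
               "unknown characters")
  expect_error(count_site_patterns(list(list(a = c("g", "g"), b = "g",
                                             c = "a", o = "a"))),
               "unequal lengths")
  expect_error(count_site_patterns(aln_from_strings("g", "g", "a", "a"),
                                   taxon_map = c(A = "x", B = "b", C = "c",
                                                 O = "o")),
               "missing taxa")
  # the taxon map may come from a plain-text role = label file
  tm <- withr::local_tempfile()
  writeLines(c("A = a", "B = b", "C = c", "O = o"), tm)
  expect_equal(unname(count_site_patterns(aln_from_strings("g", "g", "a", "a"),
                                          taxon_map = tm)$pooled),
               c(1L, 0L, 0L))
})

test_that("pooled pattern frequencies track the infinite-sites expectation", {
  # small theta keeps multiple hits negligible (the closed form assumes an
  # infinite-sites model)
  m <- msci_from_grid("GHOST", 0.3, 1.5, 0.3, theta = 0.0036)
  cfg <- sim_config(n_loci = 600, sites = 1000, seed = 401)
  aln <- simulate_alignments(simulate_gene_trees(m, cfg), cfg)
  cnt <- count_site_patterns(aln)
  f_exp <- site_pattern_freqs(m) * cnt$total_sites
  for (p in names(f_exp)) {
    se <- sqrt(f_exp[[p]])
    expect_lt(abs(cnt$pooled[[p]] - f_exp[[p]]), 4 * se + 0.08 * f_exp[[p]])
  }
  expect_equal(unname(colSums(cnt$per_locus)), unname(cnt$pooled))
})

test_that("the jackknife test sits on its null boundary when patterns tie", {
  per <- matrix(rep(c(50L, 7L, 7L), each = 40), ncol = 3,
                dimnames = list(NULL, c("BBAA", "ABBA", "BABA")))
  cnt <- structure(list(per_locus = per, pooled = colSums(per),
                        total_sites = 40000L, n_blocks = 40L),
                   class = "site_pattern_counts")
  ht <- hyde_jackknife(cnt)
  expect_equal(ht$z, 0)
  expect_equal(ht$p.value, 1)     # direction-adjusted tail at the boundary
  expect_false(ht$significant)
  expect_error(hyde_jackknife(structure(list(per_locus = per[1, , drop = FALSE],
                                             pooled = per[1, ], total_sites = 10,
                                             n_blocks = 1L),
                                        class = "site_pattern_counts")),
               "at least 2 blocks")
})

test_that("hybrid attribution and gamma follow the rarest pattern", {
  mk <- function(bbaa, abba, baba, n = 50L) {
    per <- cbind(BBAA = stats::rmultinom(1, bbaa, rep(1, n))[, 1],
                 ABBA = stats::rmultinom(1, abba, rep(1, n))[, 1],
                 BABA = stats::rmultinom(1, baba, rep(1, n))[, 1])
    structure(list(per_locus = per, pooled = colSums(per),
                   total_sites = n * 1000L, n_blocks = n),
              class = "site_pattern_counts")
  }
  set.seed(402)
  # BABA rarest: B hybrid, parents A and C, gamma from the ABBA margin
  ht <- hyde_jackknife(mk(2000, 950, 130))
  expect_true(ht$significant)
  expect_equal(ht$hybrid, "B")
  expect_equal(sort(ht$parents), c("A", "C"))
  expect_equal(ht$gamma_hat, (950 - 130) / (950 + 2000 - 2 * 130))
  # ABBA rarest: A hybrid
  ht2 <- hyde_jackknife(mk(2000, 130, 950))
  expect_equal(ht2$hybrid, "A")
  # BBAA rarest: C hybrid
  ht3 <- hyde_jackknife(mk(130, 950, 2000))
  expect_equal(ht3$hybrid, "C")
})

test_that("simulated ghost introgression is mis-called as inflow into B", {
  m <- msci_from_grid("GHOST", 0.3, 1.5, 0.3)
  cfg <- sim_config(n_loci = 400, sites = 500, seed = 403)
  aln <- simulate_alignments(simulate_gene_trees(m, cfg), cfg)
  ht <- hyde_jackknife(count_site_patterns(aln))
  expect_true(ht$significant)
  expect_equal(ht$hybrid, "B")    # neither B nor C exchanged genes
})

test_that("Benjamini-Hochberg adjustment matches the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.007), 0.007)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  # independent hand implementation of the step-up rule as an oracle
  set.seed(404)
  for (i in 1:5) {
    p <- runif(7)
    o <- order(p)
    hand <- numeric(7)
    prev <- 1
    for (k in 7:1) {
      prev <- min(prev, p[o[k]] * 7 / k)
      hand[o[k]] <- prev
    }
    expect_equal(bh_adjust(p), hand)
  }
  # a list of test objects is re-flagged in place
  per <- cbind(BBAA = rpois(30, 50), ABBA = rpois(30, 12), BABA = rpois(30, 4))
  cnt <- structure(list(per_locus = per, pooled = colSums(per),
                        total_sites = 3e4, n_blocks = 30L),
                   class = "site_pattern_counts")
  hts <- bh_adjust(list(hyde_jackknife(cnt), hyde_jackknife(cnt)))
  expect_true(all(vapply(hts, `[[`, 0, "p.adjusted") >=
                  vapply(hts, `[[`, 0, "p.value")))
})
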