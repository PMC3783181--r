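test_that("sensitivity is the length-normalised L1 profile distance", {
  a <- fake_profile(c(1, 2, 3, 4, 5), condition = "c1")
  b <- fake_profile(c(2, 2, 2, 6, 5), condition = "c2")
  s <- profile_sensitivity(a, b)
  expect_equal(s$S, (1 + 0 + 1 + 2 + 0) / 5)
  expect_equal(s$l, 5L)
  expect_equal(profile_sensitivity(b, a)$S, s$S)   # symmetry
  expect_equal(profile_sensitivity(a, a)$S, 0)

  short <- fake_profile(c(1, 2), condition = "c2")
  expect_error(profile_sensitivity(a, short), "length mismatch")
  other <- fake_profile(1:5, gene = "other")
  expect_error(profile_sensitivity(a, other), "different genes")
})

test_that("sensitivity satisfies the metric axioms on random profiles", {
  set.seed(4)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    x <- fake_profile(runif(n, 0.1, 3), condition = "cx")
    y <- fake_profile(runif(n, 0.1, 3), condition = "cy")
    z <- fake_profile(runif(n, 0.1, 3), condition = "cz")
    sxy <- profile_sensitivity(x, y)$S
    syx <- profile_sensitivity(y, x)$S
    sxz <- profile_sensitivity(x, z)$S
    szy <- profile_sensitivity(z, y)$S
    expect_gte(sxy, 0)
    expect_equal(sxy, syx)
    expect_lte(sxy, sxz + szy + 1e-12)       # triangle inequality
  }
  # equivariance: scaling both profiles by k scales S by k
  x <- fake_profile(runif(30, 0.1, 3), condition = "cx")
  y <- fake_profile(runif(30, 0.1, 3), condition = "cy")
  xk <- fake_profile(x$smoothed_times * 3, condition = "cx")
  yk <- fake_profile(y$smoothed_times * 3, condition = "cy")
  expect_equal(profile_sensitivity(xk, yk)$S,
               3 * profile_sensitivity(x, y)$S)
})

test_that("sensitivity tables cover every gene under every shifted condition", {
  fx <- toy_fixture(61, perturbation = list(
    mode = "uniform", factors = c(c2 = 0.8, c3 = 0.5)))
  profs <- lapply(fx$conditions$pools,
                  function(p) profile_genes(fx$genes, codon_rates(p)))
  st <- sensitivity_table(profs, "c1")
  expect_equal(nrow(st), 2L * length(fx$genes))
  expect_setequal(unique(st$c2), c("c2", "c3"))
  expect_true(all(st$S > 0))
  # deeper uniform slowdown gives uniformly larger S
  s2 <- st$S[st$c2 == "c2"]
  s3 <- st$S[st$c2 == "c3"][match(st$gene[st$c2 == "c2"],
                                  st$gene[st$c2 == "c3"])]
  expect_true(all(s3 > s2))
})

test_that("ranking slices deterministic top and bottom fractions", {
  res <- data.frame(gene = sprintf("g%02d", 1:10), S = 10:1)
  rs <- rank_and_slice(res, fraction = 0.1)
  expect_equal(rs$most_sensitive, "g01")
  expect_equal(rs$least_sensitive, "g10")
  expect_equal(rs$ranked$rank, 1:10)

  # ties at the cut break lexicographically by gene id
  tied <- data.frame(gene = c("b", "a", "c"), S = c(1, 1, 1))
  rs2 <- rank_and_slice(tied, fraction = 1 / 3)
  expect_equal(rs2$most_sensitive, "a")
  expect_equal(rs2$least_sensitive, "c")

  # untranslated and pseudo genes are excluded before slicing
  cats <- c(g01 = "untranslated", g02 = "pseudo")
  rs3 <- rank_and_slice(res, fraction = 0.1, categories = cats)
  expect_equal(rs3$most_sensitive, "g03")
  expect_false(any(c("g01", "g02") %in% rs3$ranked$gene))

  expect_error(rank_and_slice(res, fraction = 0.6), "fraction")
})

test_that("group comparison detects stochastically larger sensitivities", {
  # clear separation: one-sided p must be tiny at n >= 20
  res <- data.frame(gene = c(sprintf("a%02d", 1:20), sprintf("b%02d", 1:20)),
                    S = c(seq(2, 3, length.out = 20),
                          seq(0.1, 1, length.out = 20)))
  g <- group_compare(res, sprintf("a%02d", 1:20), sprintf("b%02d", 1:20))
  expect_lte(g$p_value, 0.001)
  expect_equal(g$n_a, 20L)

  # singleton vs singleton stays defined
  g1 <- group_compare(res, "a01", "b01")
  expect_true(is.finite(g1$p_value))

  expect_error(group_compare(res, c("a01", "b01"), c("b01")), "disjoint")
  expect_error(group_compare(res, "zzz", "b01"), "genes present")
})

test_that("group test holds its size under the null", {
  set.seed(202)
  reps <- 400
  alpha <- 0.05
  p <- replicate(reps, {
    s <- data.frame(gene = sprintf("g%03d", 1:100),
                    S = rexp(100))
    group_compare(s, sprintf("g%03d", 1:50),
                  sprintf("g%03d", 51:100))$p_value
  })
  rej <- mean(p <= alpha)
  # binomial band around the nominal level
  expect_lt(abs(rej - alpha), 3 * sqrt(alpha * (1 - alpha) / reps) + 0.01)
})

test_that("genome bins tile the genome and average member genes", {
  glen <- 4639675
  # bin width matches an equal 200-way split of an E. coli-sized genome
  genes <- list(parse_cds("x", "ATGCTGCTG", strict = FALSE,
                          genome_start = 1))
  bins <- bin_genome(genes, glen, 200)
  expect_equal(bins$end[1] - bins$start[1] + 1, 23198)
  expect_equal(nrow(bins), 200L)
  expect_equal(bins$end[200], glen)        # last bin absorbs remainder
  expect_true(all(bins$start[-1] == bins$end[-200] + 1))

  # all genes in one bin: that bin carries the global mean, rest empty
  set.seed(8)
  fx <- toy_fixture(71)
  gs <- fx$genes[1:6]
  for (i in seq_along(gs)) gs[[i]]$genome_start <- 100 + i
  sens <- data.frame(gene = vapply(gs, `[[`, character(1), "id"),
                     c2 = "c2", S = runif(6))
  bins2 <- bin_genome(gs, 100000, 10, sensitivities = sens)
  expect_equal(bins2$n_genes, c(6L, rep(0L, 9)))
  expect_equal(bins2$mean_S_c2[1], mean(sens$S))
  expect_true(all(is.nan(bins2$mean_S_c2[-1]) | is.na(bins2$mean_S_c2[-1])))

  # per-bin means equal a brute-force recomputation
  for (i in seq_along(gs)) gs[[i]]$genome_start <- sample(1:100000, 1)
  bins3 <- bin_genome(gs, 100000, 10, sensitivities = sens)
  width <- 100000 %/% 10
  for (b in 1:10) {
    members <- vapply(gs, function(g)
      min((g$genome_start - 1) %/% width + 1, 10) == b, logical(1))
    if (any(members))
      expect_equal(bins3$mean_S_c2[b],
                   mean(sens$S[match(vapply(gs[members], `[[`,
                                            character(1), "id"),
                                     sens$gene)]))
  }

  bad <- gs[1]
  bad[[1]]$genome_start <- 200000
  expect_error(bin_genome(bad, 100000, 10), "outside")
})

test_that("CAI is the geometric mean of relative adaptiveness weights", {
  w <- c(CUG = 1, CUU = 0.5, CUA = 0.25, AUG = 1)
  g <- parse_cds("toy", "ATGCTGCTGCTG", strict = FALSE)
  expect_equal(cai(g, w), 1)               # only preferred codons
  g2 <- parse_cds("toy2", "CTGCTTCTA", strict = FALSE)
  expect_equal(cai(g2, w), (1 * 0.5 * 0.25)^(1 / 3))
  # codons of synonym-free amino acids carry weight 1: methionine-only
  # stretches leave the index at 1
  g3 <- parse_cds("toy3", "ATGATGCTG", strict = FALSE)
  expect_equal(cai(g3, w), 1)
  # zero weights are floored, not annihilating
  w0 <- c(CUG = 1, CUU = 0)
  g4 <- parse_cds("toy4", "CTGCTT", strict = FALSE)
  expect_equal(cai(g4, w0), sqrt(1 * 0.01))
  expect_error(cai(parse_cds("g", "GGGGGG", strict = FALSE), w),
               "missing")
})

test_that("rate-derived CAI weights give 1 to each family's preferred codon", {
  fx <- toy_fixture(81)
  w <- cai_weights_from_rates(codon_rates(fx$pool))
  expect_true(all(w >= 0 & w <= 1))
  aa <- vapply(names(w), function(cd)
    unname(Biostrings::GENETIC_CODE[chartr("U", "T", cd)]), character(1))
  for (a in unique(aa[w > 0]))
    expect_equal(max(w[aa == a]), 1)
})

test_that("rank correlation recovers sign and vanishes under the null", {
  x <- 1:50
  expect_equal(correlate_sensitivity(x, x)$rho, 1)
  expect_equal(correlate_sensitivity(x, -x)$rho, -1)
  expect_equal(correlate_sensitivity(x, x)$r_squared, 1)

  set.seed(5)
  n <- 1000
  r <- correlate_sensitivity(runif(n), runif(n))
  expect_lt(abs(r$rho), 0.1)

  expect_warning(cc <- correlate_sensitivity(rep(1, 10), runif(10)),
                 "constant")
  expect_true(is.na(cc$rho))
  expect_error(correlate_sensitivity(1:2, 1:2), "at least 3")
})
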