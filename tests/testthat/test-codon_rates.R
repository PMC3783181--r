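test_that("recognition map follows Crick wobble rules, hand-enumerated", {
  # C34 reads only codon-3' G
  m <- build_recognition_map(list(trna_species("LeuC", "L", "CAG")))
  expect_equal(m$CUG$species, "LeuC")
  expect_equal(m$CUG$pairing, "C34:G3")
  expect_equal(nrow(m$CUU), 0L)
  expect_equal(nrow(m$CUC), 0L)
  expect_equal(nrow(m$CUA), 0L)

  # U34 reads codon-3' A (Watson-Crick) and G (wobble)
  m <- build_recognition_map(list(trna_species("LeuU", "L", "UAA")))
  expect_equal(m$UUA$pairing, "U34:A3")
  expect_equal(m$UUG$pairing, "U34:G3")
  expect_equal(sum(vapply(m, nrow, integer(1))), 2L)

  # G34 reads codon-3' C and U
  m <- build_recognition_map(list(trna_species("Phe", "F", "GAA")))
  expect_equal(m$UUC$pairing, "G34:C3")
  expect_equal(m$UUU$pairing, "G34:U3")

  # A34 as inosine reads U, C and weakly A; as plain A only U
  m <- build_recognition_map(list(trna_species("Arg", "R", "ACG")))
  expect_equal(m$CGU$pairing, "A34:U3")
  expect_equal(m$CGC$pairing, "I34:C3")
  expect_equal(m$CGA$pairing, "I34:A3")
  m <- build_recognition_map(list(trna_species("Arg", "R", "ACG",
                                               inosine = FALSE)))
  expect_equal(m$CGU$pairing, "A34:U3")
  expect_equal(nrow(m$CGC), 0L)
  expect_equal(nrow(m$CGA), 0L)

  # empty species set: all codons unmatched, stop codons absent entirely
  m <- build_recognition_map(list())
  expect_true(all(vapply(m, nrow, integer(1)) == 0L))
  expect_false(any(c("UAA", "UAG", "UGA") %in% names(m)))
})

test_that("AUA and AUG are decoded only by lysidine-Ile and elongator Met", {
  ile2 <- trna_species("Ile2", "I", "CAU")   # lysidine by default
  met <- trna_species("Met", "M", "CAU")
  m <- build_recognition_map(list(ile2, met))
  expect_equal(m$AUA$species, "Ile2")
  expect_equal(m$AUA$pairing, "L34:A3")
  expect_equal(m$AUG$species, "Met")
  expect_equal(m$AUG$pairing, "C34:G3")
  # a hypothetical U34 Ile tRNA would generically hit AUA and AUG; both
  # are reserved for the modified readers
  m2 <- build_recognition_map(list(trna_species("IleX", "I", "UAU",
                                                lysidine = FALSE)))
  expect_equal(nrow(m2$AUA), 0L)
  expect_equal(nrow(m2$AUG), 0L)
})

test_that("adaptiveness is the (1-s)-discounted availability sum", {
  # single sole recognizer: W = (1-s) * conc
  pool <- trna_pool("c1", list(trna_species("Phe", "F", "GAA")),
                    c(Phe = 120))
  W <- adaptiveness(pool)
  expect_equal(W$W[["UUC"]], 120)            # G34:C3, s = 0
  expect_equal(W$W[["UUU"]], (1 - 0.41) * 120)
  expect_equal(sum(W$W > 0), 2L)

  # linearity: scaling the pool scales W
  pool2 <- trna_pool("c1", pool$species, pool$concentration * 3.5)
  expect_equal(adaptiveness(pool2)$W, W$W * 3.5)

  # two species over one codon box against a hand computation
  pool3 <- trna_pool("c1", list(trna_species("LeuC", "L", "CAG"),
                                trna_species("LeuU", "L", "UAG")),
                     c(LeuC = 100, LeuU = 40))
  W3 <- adaptiveness(pool3)$W
  expect_equal(W3[["CUG"]], 1 * 100 + (1 - 0.68) * 40)  # C34:G3 + U34:G3
  expect_equal(W3[["CUA"]], 1 * 40)                     # U34:A3
})

test_that("the CGA:ACG override replaces the generic inosine constraint", {
  pool <- trna_pool("c1", list(trna_species("Arg", "R", "ACG")),
                    c(Arg = 500))
  W <- adaptiveness(pool)$W
  expect_equal(W[["CGA"]], (1 - 0.9172) * 500)
  expect_equal(W[["CGC"]], (1 - 0.28) * 500)
  W_no <- adaptiveness(pool, rules = wobble_rules(overrides = NULL))$W
  expect_equal(W_no[["CGA"]], (1 - 0.9999) * 500)
})

test_that("bundled wobble config reproduces the default rules", {
  conf <- system.file("extdata", "wobble_defaults.conf",
                      package = "transens")
  expect_equal(read_wobble_config(conf), wobble_rules())
})

test_that("rates normalise to the total pool and scale homogeneously", {
  fx <- toy_fixture(5)
  rt <- codon_rates(fx$pool)
  expect_equal(sum(rt$r), sum(fx$pool$concentration),
               tolerance = 1e-12)
  pos <- rt$r > 0
  expect_equal(unname(rt$t[pos] * rt$r[pos]), rep(1, sum(pos)),
               tolerance = 1e-12)

  k <- 2.7
  scaled <- trna_pool("k", fx$pool$species, fx$pool$concentration * k)
  rtk <- codon_rates(scaled)
  expect_equal(rtk$r, rt$r * k, tolerance = 1e-12)
  pos <- rt$r > 0
  expect_equal(rtk$t[pos], rt$t[pos] / k, tolerance = 1e-12)

  # zero-W codons carry zero rate and infinite time
  expect_true(all(is.infinite(rt$t[rt$r == 0])))
  # all-zero adaptiveness is rejected
  empty_W <- structure(list(W = setNames(rep(0, 61), sense_codons()),
                            condition = "c1"),
                       class = "adaptiveness_table")
  expect_error(translation_rates(empty_W, fx$pool), "zero")
})

test_that("rate engine matches the literal brute-force oracle", {
  set.seed(101)
  for (i in 1:25) {
    pool <- random_test_pool(sample(3:10, 1))
    rt <- codon_rates(pool)
    orc <- oracle_rates(pool)
    expect_equal(rt$W, orc$W, tolerance = 1e-12)
    expect_equal(rt$r, orc$r, tolerance = 1e-12)
    expect_equal(sum(rt$r), sum(pool$concentration), tolerance = 1e-9)
  }
})

test_that("fully charged pools reproduce the concentration-only rates exactly", {
  fx <- toy_fixture(9)
  charged <- trna_pool(fx$pool$condition, fx$pool$species,
                       fx$pool$concentration,
                       charged_fraction = setNames(
                         rep(1, length(fx$pool$species)),
                         names(fx$pool$species)))
  eff <- effective_availability(charged, fx$pool)
  expect_identical(codon_rates(eff)$r, codon_rates(fx$pool)$r)
  expect_identical(codon_rates(eff)$t, codon_rates(fx$pool)$t)
})

test_that("fold changes are identity-1, homogeneous, and flag dead codons", {
  fx <- toy_fixture(13)
  rt <- codon_rates(fx$pool)
  fc <- fold_changes(rt, rt)
  expect_true(all(abs(fc - 1) < 1e-12))

  scaled <- codon_rates(trna_pool("s", fx$pool$species,
                                  fx$pool$concentration * 2))
  fc2 <- fold_changes(rt, scaled)
  expect_true(all(abs(fc2 - 2) < 1e-12))

  # halving one isoacceptor's availability lowers its exclusive codon
  conc <- fx$pool$concentration
  conc[["Leu2"]] <- conc[["Leu2"]] / 2       # sole reader of CUC/CUU
  half <- codon_rates(trna_pool("h", fx$pool$species, conc))
  fch <- fold_changes(rt, half)
  expect_lt(fch[["CUC"]], 1)
  expect_lt(fch[["CUU"]], 1)

  # codons unreadable under the toy pool are excluded, not ratioed
  expect_true("GGG" %in% attr(fc, "excluded"))
  expect_false("GGG" %in% names(fc))
})
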