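lociAB <- lociTable(c("A", "B"))
loci3 <- lociTable(c("ME2", "Lx", "Ly"))

test_that("pre-selection F2 frequencies follow Mendelian and gamete
          algebra", {
  j <- f2Frequencies(lociAB)
  expect_equal(sum(j), 1, tolerance = 1e-12)
  expect_equal(j["P1", "P1"], 1 / 16, tolerance = 1e-12)
  expect_equal(apply(j, 1, sum), c(P1 = 0.25, H = 0.5, P2 = 0.25))

  ## complete linkage: only the three coupling classes remain
  j0 <- f2Frequencies(lociTable(c("A", "B"), linkage_group = "lg",
                                recomb_fraction_to_prev = c(NA, 0)))
  expect_equal(sum(j0 > 0), 3)
  expect_equal(unname(diag(j0[, ])), c(0.25, 0.5, 0.25))

  ## r = 0.5 is indistinguishable from unlinked
  j5 <- f2Frequencies(lociTable(c("A", "B"), linkage_group = "lg",
                                recomb_fraction_to_prev = c(NA, 0.5)))
  expect_equal(max(abs(j5 - j)), 0, tolerance = 1e-12)

  expect_error(f2Frequencies(lociTable(c("A", "B"), linkage_group = "lg")),
               "invalid recombination fraction")
})

test_that("linked loci interleaved with unlinked ones keep their order", {
  loci <- lociTable(c("U1", "G1", "U2", "G2"),
                    linkage_group = c(NA, "lg", NA, "lg"),
                    recomb_fraction_to_prev = c(NA, NA, NA, 0.1))
  j <- f2Frequencies(loci)
  ## the linked pair is dims 2 and 4; unlinked dims marginalize to 1:2:1
  pair <- apply(j, c(2, 4), sum)
  direct <- f2Frequencies(lociTable(c("G1", "G2"), linkage_group = "lg",
                                    recomb_fraction_to_prev = c(NA, 0.1)))
  expect_equal(max(abs(pair - direct)), 0, tolerance = 1e-12)
  expect_equal(apply(j, 1, sum), c(P1 = 0.25, H = 0.5, P2 = 0.25))
})

test_that("named schemes build the documented clause sets", {
  sHH <- makeScheme("pairwise_hom_hom", "A", "B", w = 0)
  grid <- expand.grid(A = 0:2, B = 0:2)
  fHH <- fitnessOf(sHH, as.matrix(grid))
  expect_equal(sum(fHH == 0), 1)          # only the double derived hom
  expect_equal(fHH[grid$A == 2 & grid$B == 2], 0)

  sOW <- makeScheme("independent_one_way", "A", c("B", "C"), w = 0)
  g3 <- as.matrix(expand.grid(A = 0:2, B = 0:2, C = 0:2))
  fOW <- fitnessOf(sOW, g3)
  focalHom <- g3[, "A"] == 2
  survives <- fOW > 0
  expect_true(all(survives[focalHom] ==
                    (g3[focalHom, "B"] == 0 & g3[focalHom, "C"] == 0)))
  expect_true(all(survives[!focalHom]))

  sTW <- makeScheme("independent_two_way", "A", c("B", "C"), w = 0)
  fTW <- fitnessOf(sTW, g3)
  hetKilled <- g3[, "A"] == 1 & (g3[, "B"] == 2 | g3[, "C"] == 2)
  expect_true(all(fTW[hetKilled] == 0))

  expect_error(makeScheme("no_such_model", "A", "B"), "unknown model")
  expect_error(makeScheme("pairwise_hom_hom", "A", c("B", "C")),
               "exactly one partner")
  expect_error(makeScheme("complex_conspecific", "A", character()),
               "at least one partner")
})

test_that("selection predictions reproduce the exact analytic
          viabilities of the lethal models", {
  jAB <- f2Frequencies(lociAB)
  vOf <- function(pred, locus, cls) {
    v <- viabilities(pred)
    v$v[v$locus == locus & v$class == cls]
  }

  neutral <- applySelection(jAB, neutralScheme())
  expect_equal(viabilities(neutral)$v, rep(1, 4), tolerance = 1e-12)
  expect_equal(statistic(predictPairDeviation(neutral, "A", "B", 100)), 0,
               tolerance = 1e-9)

  pHH <- applySelection(jAB, makeScheme("pairwise_hom_hom", "A", "B", 0))
  expect_equal(vOf(pHH, "A", "P2_hom"), 0.75, tolerance = 1e-12)

  pOW <- applySelection(jAB, makeScheme("pairwise_one_way", "A", "B", 0))
  expect_equal(vOf(pOW, "A", "P2_hom"), 0.25, tolerance = 1e-12)

  j3 <- f2Frequencies(loci3)
  iOW <- applySelection(j3, makeScheme("independent_one_way", "ME2",
                                       c("Lx", "Ly"), 0))
  expect_equal(vOf(iOW, "ME2", "P2_hom"), 0.0625, tolerance = 1e-12)
  expect_equal(vOf(iOW, "Lx", "P2_hom"), 1, tolerance = 1e-12)
  expect_equal(vOf(iOW, "Lx", "P1_hom"), 13 / 12, tolerance = 1e-12)

  iTW <- applySelection(j3, makeScheme("independent_two_way", "ME2",
                                       c("Lx", "Ly"), 0))
  expect_equal(vOf(iTW, "ME2", "P2_hom"), 1 / 9, tolerance = 1e-12)
  expect_equal(vOf(iTW, "Lx", "P2_hom"), 0.4, tolerance = 1e-12)
  expect_equal(vOf(iTW, "Lx", "P1_hom"), 1.1, tolerance = 1e-12)

  cc <- applySelection(j3, makeScheme("complex_conspecific", "ME2",
                                      c("Lx", "Ly"), 0))
  expect_equal(vOf(cc, "ME2", "P2_hom"), 0.9375, tolerance = 1e-12)
})

test_that("selection respects normalization, label symmetry,
          monotonicity in w, and the one-partner limit", {
  j3 <- f2Frequencies(loci3)
  models <- list(
    c("pairwise_hom_hom", 1), c("pairwise_one_way", 1),
    c("complex_conspecific", 2), c("independent_one_way", 2),
    c("independent_two_way", 2))
  for (m in models) {
    partners <- c("Lx", "Ly")[seq_len(as.integer(m[2]))]
    vPrev <- -Inf
    for (w in c(0, 0.25, 0.5, 0.75, 1)) {
      pred <- applySelection(j3, makeScheme(m[1], "ME2", partners, w))
      expect_equal(sum(jointFreq(pred)), 1, tolerance = 1e-12)
      v <- viabilities(pred)
      vFocal <- v$v[v$locus == "ME2" & v$class == "P2_hom"]
      expect_gte(vFocal, vPrev - 1e-12)
      vPrev <- vFocal
    }
  }

  ## flipping every derived_parent mirrors the prediction
  lociFlip <- lociTable(loci3$name, derived_parent = "P1")
  pA <- applySelection(f2Frequencies(loci3),
                       makeScheme("independent_one_way", "ME2",
                                  c("Lx", "Ly"), 0))
  pB <- applySelection(f2Frequencies(lociFlip),
                       makeScheme("independent_one_way", "ME2",
                                  c("Lx", "Ly"), 0))
  expect_equal(marginalFreq(pB)[, c("P2", "H", "P1")],
               marginalFreq(pA)[, c("P1", "H", "P2")],
               ignore_attr = TRUE, tolerance = 1e-12)

  ## independent_one_way with one partner is exactly pairwise_one_way
  j2 <- f2Frequencies(lociAB)
  one <- applySelection(j2, makeScheme("independent_one_way", "A", "B", 0.3))
  pw <- applySelection(j2, makeScheme("pairwise_one_way", "A", "B", 0.3))
  expect_equal(jointFreq(one), jointFreq(pw), tolerance = 1e-14)
})

test_that("cytonuclear schemes act only on the foreign cytotype", {
  j <- f2Frequencies(lociTable("ME2"))
  sc <- makeScheme("cytonuclear", "ME2", w = 0)
  native <- applySelection(j, sc, cytotype = "native")
  expect_equal(viabilities(native)$v, c(1, 1), tolerance = 1e-12)
  foreign <- applySelection(j, sc, cytotype = "foreign")
  v <- viabilities(foreign)
  expect_equal(v$v[v$class == "P2_hom"], 0)
})

test_that("an all-lethal scheme is rejected", {
  j <- f2Frequencies(lociTable("A"))
  lethal <- new("FitnessScheme", model = "custom",
                clauses = list(list(dosage = list(A = 0:2),
                                    cytotype = NA_character_, w = 0)),
                episode = "nauplius_to_adult", loci = "A")
  expect_error(applySelection(j, lethal), "inviable")
})

test_that("fitness estimation recovers the truth and flags flat
          likelihoods", {
  loci <- lociAB
  pre <- f2Frequencies(loci)

  set.seed(31)
  pr0 <- applySelection(pre, makeScheme("pairwise_hom_hom", "A", "B", 0))
  o0 <- matrix(rmultinom(1, 10000, as.vector(jointFreq(pr0))), 3, 3)
  fit0 <- estimateFitness(twoLocusCounts(o0, c("A", "B")),
                          "pairwise_hom_hom", loci, "A", "B")
  expect_lt(fit0$w_hat, 0.05)

  oN <- matrix(rmultinom(1, 10000, as.vector(pre)), 3, 3)
  fitN <- estimateFitness(twoLocusCounts(oN, c("A", "B")),
                          "pairwise_hom_hom", loci, "A", "B")
  expect_gte(fitN$upper, 1 - 1e-6)
  expect_lte(fitN$lower, fitN$w_hat)

  ## single-locus marginal counts carry the signal too
  prM <- applySelection(pre, makeScheme("pairwise_one_way", "A", "B", 0.2))
  kM <- round(1e5 * marginalFreq(prM)["A", ])
  fitM <- estimateFitness(genotypeCounts(kM[1], kM[2], kM[3]),
                          "pairwise_one_way", loci, "A", "B")
  expect_equal(fitM$w_hat, 0.2, tolerance = 0.01)

  ## counts at a locus the scheme never touches: flat likelihood
  flat <- estimateFitness(genotypeCounts(25, 50, 25), "pairwise_hom_hom",
                          lociTable(c("A", "B", "C")), "B", "C",
                          focalLocus = "A")
  expect_false(flat$identifiable)
})

test_that("model specification files round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "loci:",
    "  - name: ME2",
    "    derived_parent: P2",
    "  - name: GOT2",
    "    derived_parent: P2",
    "    linkage_group: lg1",
    "  - name: RISP",
    "    linkage_group: lg1",
    "    recomb_fraction_to_prev: 0.05",
    "model: pairwise_one_way",
    "focal: ME2",
    "partners: [GOT2]",
    "w: 0.0"), path)
  spec <- readModelSpec(path)
  expect_equal(spec$loci$name, c("ME2", "GOT2", "RISP"))
  expect_equal(spec$loci$recomb_fraction_to_prev[3], 0.05)
  expect_equal(spec$scheme@model, "pairwise_one_way")
  pred <- applySelection(f2Frequencies(spec$loci), spec$scheme)
  v <- viabilities(pred)
  expect_equal(v$v[v$locus == "ME2" & v$class == "P2_hom"], 0.25,
               tolerance = 1e-12)

  out <- tempfile(fileext = ".tsv")
  writeModelPrediction(pred, out, pairs = list(c("ME2", "GOT2")), N = 200)
  tab <- read.delim(out)
  expect_equal(nrow(tab), 6)
  contrib <- read.delim(paste0(out, ".contrib.tsv"))
  expect_equal(nrow(contrib), 9)
})
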