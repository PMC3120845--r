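test_that("simulation output is fully determined by the seed", {
  cfg <- simConfig(lociTable(c("ME2", "GOT2")), nOffspring = 400,
                   sampleNauplii = 40, sampleAdults = 100, seed = 5)
  t1 <- simulateCohort(cfg)
  t2 <- simulateCohort(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  writeGenotypeTable(t1, f1); writeGenotypeTable(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("without selection genotype frequencies are Mendelian and sex
          is independent of genotype", {
  cfg <- simConfig(lociTable(c("A", "B")), nOffspring = 20000,
                   sampleAdults = 20000, seed = 6)
  tab <- simulateCohort(cfg)
  k <- counts(countGenotypes(tab, "A"))
  ## allele frequency 0.5 within binomial error (4 sd)
  pDerived <- (k[["P2"]] + k[["H"]] / 2) / sum(k)
  expect_lt(abs(pDerived - 0.5), 4 * sqrt(0.25 / (2 * 20000)))
  expect_equal(unname(k / sum(k)), c(0.25, 0.5, 0.25), tolerance = 0.03)
  ## genotype ratios homogeneous between the sexes
  km <- countGenotypes(tab, "A", sex = "male")
  kf <- countGenotypes(tab, "A", sex = "female")
  expect_gt(pvalue(sexHomogeneityTest(km, kf)), 1e-4)
})

test_that("the Mendelian test keeps nominal size on neutral cohorts", {
  loci <- lociTable("A")
  rej <- vapply(1:500, function(i) {
    cfg <- simConfig(loci, nOffspring = 1000, sampleAdults = 1000,
                     seed = 60000 + i)
    pvalue(mendelianChisq(countGenotypes(simulateCohort(cfg), "A"))) <= 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.025)
})

test_that("an adult-stage one-way lethal incompatibility distorts adults
          but not nauplii", {
  loci <- lociTable(c("ME2", "GOT2"))
  sch <- makeScheme("pairwise_one_way", "ME2", "GOT2", w = 0,
                    episode = "nauplius_to_adult")
  cfg <- simConfig(loci, list(nauplius_to_adult = sch),
                   nOffspring = 40000, sampleNauplii = 2000,
                   sampleAdults = 15000, seed = 61)
  tab <- simulateCohort(cfg)
  expect_gt(pvalue(mendelianChisq(
    countGenotypes(tab, "ME2", stage = "nauplius"))), 0.01)
  vAd <- haldaneViability(countGenotypes(tab, "ME2", stage = "adult"))
  expect_equal(vAd["P2_hom", "v"], 0.25, tolerance = 0.05)
})

test_that("physical linkage shows the joint nauplius-adult signature", {
  loci <- lociTable(c("GOT2", "RISP"), linkage_group = "lg1",
                    recomb_fraction_to_prev = c(NA, 0.1))
  cfg <- simConfig(loci, nOffspring = 6000, sampleNauplii = 1500,
                   sampleAdults = 3000, seed = 62)
  tab <- simulateCohort(cfg)
  rn <- independenceTest(crossTabulate(tab, "GOT2", "RISP",
                                       stage = "nauplius"))
  ra <- independenceTest(crossTabulate(tab, "GOT2", "RISP",
                                       stage = "adult"))
  expect_lt(pvalue(ra), 1e-6)
  expect_equal(classifyPair(rn, ra), "linkage_like")
})

test_that("the sex effect scales the magnitude but not the direction of
          distortion", {
  loci <- lociTable(c("ME2", "GOT2"))
  sch <- makeScheme("pairwise_one_way", "ME2", "GOT2", w = 0.5)
  cfg <- simConfig(loci, list(nauplius_to_adult = sch),
                   nOffspring = 60000, sampleAdults = 30000,
                   sexEffect = 1.5, seed = 63)
  tab <- simulateCohort(cfg)
  vm <- haldaneViability(countGenotypes(tab, "ME2", stage = "adult",
                                        sex = "male"))
  vf <- haldaneViability(countGenotypes(tab, "ME2", stage = "adult",
                                        sex = "female"))
  ## both sexes below 1 (same direction), females further below
  expect_lt(vm["P2_hom", "v"], 1)
  expect_lt(vf["P2_hom", "v"], vm["P2_hom", "v"])
})

test_that("cohorts can be sampled at the genotyped sizes of a real
          study design", {
  cfg <- simConfig(lociTable(c("ME1", "ME2", "GOT2")),
                   nOffspring = 3000, sampleNauplii = 174,
                   sampleAdults = c(male = 241, female = 411), seed = 64)
  tab <- simulateCohort(cfg)
  cd <- SummarizedExperiment::colData(tab)
  expect_equal(sum(cd$stage == "nauplius"), 174)
  expect_equal(sum(cd$sex == "male"), 241)
  expect_equal(sum(cd$sex == "female"), 411)
})

test_that("infeasible sample requests fail with an attrition report", {
  loci <- lociTable(c("ME2", "GOT2"))
  lethalish <- makeScheme("pairwise_one_way", "ME2", "GOT2", 0,
                          episode = "embryo_to_nauplius")
  cfg <- simConfig(loci, list(embryo_to_nauplius = lethalish),
                   nOffspring = 100, sampleNauplii = 95, seed = 65)
  expect_error(simulateCohort(cfg), "insufficient episode-1 survivors")
  cfg2 <- simConfig(loci, nOffspring = 100, sampleNauplii = 50,
                    sampleAdults = 60, seed = 65)
  expect_error(simulateCohort(cfg2), "insufficient adult survivors")
})

test_that("simulateStudy writes readable cohorts and a truthful
          manifest", {
  dir <- tempfile()
  loci <- lociTable(c("ME2", "GOT2"))
  configs <- lapply(1:5, function(i)
    simConfig(loci,
              list(nauplius_to_adult =
                     makeScheme("pairwise_one_way", "ME2", "GOT2",
                                w = 0.1 * i)),
              nOffspring = 300, sampleAdults = 100,
              crossLabel = sprintf("cross%d", i), seed = 70 + i))
  manifest <- simulateStudy(configs, dir)
  expect_equal(nrow(manifest), 5)
  expect_equal(manifest$w_ep2, 0.1 * (1:5))
  for (f in manifest$file) {
    tab <- readGenotypeTable(file.path(dir, f), loci)
    expect_equal(ncol(tab), 100)
  }
  onDisk <- read.delim(file.path(dir, "manifest.tsv"))
  expect_equal(onDisk$seed, 71:75)
})

test_that("simulation configurations round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "loci:",
    "  - name: ME2",
    "  - name: GOT2",
    "schemes:",
    "  nauplius_to_adult:",
    "    model: pairwise_one_way",
    "    focal: ME2",
    "    partners: [GOT2]",
    "    w: 0.25",
    "n_offspring: 500",
    "sample_nauplii: 50",
    "sample_adults: 120",
    "sex_effect: 0.5",
    "cross_label: ABf_x_SDm",
    "cytotype: AB",
    "seed: 99"), path)
  cfg <- readSimConfig(path)
  expect_s4_class(cfg, "SimConfig")
  expect_equal(cfg@nOffspring, 500L)
  expect_equal(cfg@schemes$nauplius_to_adult@model, "pairwise_one_way")
  expect_equal(cfg@sexEffect, 0.5)
  tab <- simulateCohort(cfg)
  expect_equal(ncol(tab), 170)
})
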