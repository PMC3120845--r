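## Forward simulator of F2 intercross cohorts.
##
## Zygotes are formed by random union of two coupling-phase F1 gametes
## (haplotypes follow the recombination fractions, no interference), sex
## is assigned with probability 1/2 independent of genotype, and two
## viability-selection episodes act: embryo-to-nauplius before the
## nauplius sample is taken, nauplius-to-adult before the adult sample.
## Nauplius sampling is destructive (sampled larvae do not continue to
## the adult episode). In females selection intensity is scaled as
## w^(1 + sexEffect), changing the magnitude but never the direction of
## genotypic deviations.
##
## RNG stream order per cohort (single seeded generator): gametes by
## linkage group (maternal then paternal, loci left to right), sex,
## episode-1 survival, nauplius sample, baseline larval mortality,
## episode-2 survival, adult sample.

#' Build a simulation configuration
#'
#' @param loci locus table from [lociTable()].
#' @param schemes named list of [FitnessScheme-class] (or `NULL`) for
#'   episodes `embryo_to_nauplius` and `nauplius_to_adult`; omitted
#'   episodes are neutral.
#' @param nOffspring number of F2 zygotes to generate.
#' @param sampleNauplii nauplii to genotype (drawn from episode-1
#'   survivors, destructively).
#' @param sampleAdults adults to genotype; either a single count or a
#'   named vector `c(male = ..., female = ...)`.
#' @param sexEffect non-negative scaling of selection intensity in
#'   females (`w^(1 + sexEffect)`); 0 = no sex difference.
#' @param crossLabel cross label recorded for every individual.
#' @param cytotype maternal-line cytotype label recorded for every
#'   individual and consulted by cytonuclear clauses (`"native"` or
#'   `"foreign"` semantics).
#' @param baselineMortality genotype-independent mortality between the
#'   nauplius and adult stages (nuisance attrition, default 0).
#' @param seed integer seed; the seed fully determines the output.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(loci, schemes = list(), nOffspring = 2000L,
                      sampleNauplii = 0L, sampleAdults = 0L,
                      sexEffect = 0, crossLabel = "P1f_x_P2m",
                      cytotype = "native", baselineMortality = 0,
                      seed = 1L) {
  unknown <- setdiff(names(schemes), .EPISODES)
  if (length(unknown))
    stop("unknown selection episode(s): ", paste(unknown, collapse = ", "))
  sa <- as.integer(sampleAdults)
  names(sa) <- names(sampleAdults)
  new("SimConfig", loci = loci, schemes = schemes,
      nOffspring = as.integer(nOffspring),
      sampleNauplii = as.integer(sampleNauplii),
      sampleAdults = sa,
      sexEffect = as.numeric(sexEffect),
      crossLabel = as.character(crossLabel),
      cytotype = as.character(cytotype),
      baselineMortality = as.numeric(baselineMortality),
      seed = as.integer(seed))
}

## One gamete per zygote for each linkage group: n x k allele matrix
## (0 = P1, 1 = P2), Markov chain over loci with flip probability r.
.drawGametes <- function(n, r) {
  k <- length(r) + 1L
  a <- matrix(0L, n, k)
  a[, 1L] <- stats::rbinom(n, 1L, 0.5)
  for (i in seq_along(r))
    a[, i + 1L] <- a[, i] != (stats::rbinom(n, 1L, r[i]) == 1L)
  a
}

.episodeSurvival <- function(dosage, scheme, cytotype, female, sexEffect) {
  if (is.null(scheme)) return(rep(TRUE, nrow(dosage)))
  w <- .fitnessVec(scheme, dosage, cytotype)
  w[female] <- w[female]^(1 + sexEffect)
  stats::runif(nrow(dosage)) < w
}

#' Simulate one F2 intercross cohort
#'
#' Runs the forward model described in [SimConfig-class]: gametogenesis
#' with linkage, sex assignment, stage-specific viability selection and
#' two-stage sampling, returning the genotyped individuals as an
#' [F2CrossTable-class]. Nauplii are reported with sex `"unknown"`
#' (larvae cannot be sexed), adults with their true sex.
#'
#' @param config a [SimConfig-class].
#' @return an [F2CrossTable-class] with `sampleNauplii` nauplius rows
#'   followed by the adult rows.
#' @examples
#' cfg <- simConfig(lociTable(c("ME2", "GOT2")), nOffspring = 500,
#'                  sampleNauplii = 50, sampleAdults = 100, seed = 42)
#' simulateCohort(cfg)
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  loci <- config@loci
  L <- nrow(loci)
  n <- config@nOffspring
  set.seed(config@seed)

  grp <- loci$linkage_group
  grp[is.na(grp)] <- paste0(".single", seq_len(L))[is.na(grp)]
  groups <- split(seq_len(L), factor(grp, levels = unique(grp)))
  geno <- matrix(0L, n, L)   # P2-allele dosage 0/1/2
  for (idx in groups) {
    r <- if (length(idx) > 1L) loci$recomb_fraction_to_prev[idx[-1L]]
         else numeric()
    if (any(is.na(r) | r < 0 | r > 0.5))
      stop("invalid recombination fraction for linked loci")
    geno[, idx] <- .drawGametes(n, r) + .drawGametes(n, r)
  }
  dosage <- geno
  flip <- loci$derived_parent == "P1"
  dosage[, flip] <- 2L - dosage[, flip, drop = FALSE]
  colnames(dosage) <- loci$name
  female <- stats::runif(n) < 0.5

  s1 <- .episodeSurvival(dosage, config@schemes[["embryo_to_nauplius"]],
                         config@cytotype, female, config@sexEffect)
  pool1 <- which(s1)
  nNaup <- config@sampleNauplii
  if (length(pool1) < nNaup)
    stop(sprintf(
      "insufficient episode-1 survivors: %d available, %d requested (attrition %.1f%%)",
      length(pool1), nNaup, 100 * (1 - length(pool1) / n)))
  naupIdx <- if (nNaup > 0) sample(pool1, nNaup) else integer()

  pool2 <- setdiff(pool1, naupIdx)
  if (config@baselineMortality > 0)
    pool2 <- pool2[stats::runif(length(pool2)) >= config@baselineMortality]
  s2 <- .episodeSurvival(dosage[pool2, , drop = FALSE],
                         config@schemes[["nauplius_to_adult"]],
                         config@cytotype, female[pool2], config@sexEffect)
  adults <- pool2[s2]

  want <- config@sampleAdults
  if (!is.null(names(want)) && all(c("male", "female") %in% names(want))) {
    males <- adults[!female[adults]]
    females <- adults[female[adults]]
    if (length(males) < want[["male"]] || length(females) < want[["female"]])
      stop(sprintf(
        "insufficient adult survivors: %d males / %d females available, %d / %d requested",
        length(males), length(females), want[["male"]], want[["female"]]))
    adultIdx <- c(if (want[["male"]] > 0) sample(males, want[["male"]])
                  else integer(),
                  if (want[["female"]] > 0) sample(females, want[["female"]])
                  else integer())
  } else {
    want <- sum(want)
    if (length(adults) < want)
      stop(sprintf(
        "insufficient adult survivors: %d available, %d requested (attrition %.1f%%)",
        length(adults), want, 100 * (1 - length(adults) / n)))
    adultIdx <- if (want > 0) sample(adults, want) else integer()
  }

  keep <- c(naupIdx, adultIdx)
  stage <- rep(c("nauplius", "adult"), c(length(naupIdx), length(adultIdx)))
  sex <- ifelse(stage == "nauplius", "unknown",
                ifelse(female[keep], "female", "male"))
  codes <- matrix(.GENO_CODES[geno[keep, , drop = FALSE] + 1L],
                  nrow = length(keep), dimnames = list(NULL, loci$name))
  ind <- data.frame(
    individual_id = sprintf("%s_%s%04d", config@crossLabel,
                            ifelse(stage == "nauplius", "n", "a"),
                            seq_along(keep)),
    cross = config@crossLabel, stage = stage, sex = sex,
    cytotype = config@cytotype, stringsAsFactors = FALSE)
  f2CrossTable(codes, ind, loci)
}

#' Simulate a multi-cross study to disk
#'
#' Simulates one cohort per configuration, writes each genotype table in
#' the canonical TSV format, and writes a `manifest.tsv` recording file,
#' cross label, seed and the true scheme parameters (model and `w` per
#' episode) so recovery harnesses can consume the truth.
#'
#' @param configs list of [SimConfig-class] objects.
#' @param dir output directory (created if needed).
#' @return the manifest `data.frame`, invisibly.
#' @export
simulateStudy <- function(configs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  schemeDesc <- function(s)
    if (is.null(s)) c("neutral", NA_real_)
    else c(s@model, if (length(s@clauses)) s@clauses[[1L]]$w else NA_real_)
  manifest <- do.call(rbind, lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    file <- sprintf("cohort_%02d_%s.tsv", i, cfg@crossLabel)
    writeGenotypeTable(simulateCohort(cfg), file.path(dir, file))
    d1 <- schemeDesc(cfg@schemes[["embryo_to_nauplius"]])
    d2 <- schemeDesc(cfg@schemes[["nauplius_to_adult"]])
    data.frame(file = file, cross = cfg@crossLabel, seed = cfg@seed,
               model_ep1 = d1[1L], w_ep1 = as.numeric(d1[2L]),
               model_ep2 = d2[1L], w_ep2 = as.numeric(d2[2L]),
               sex_effect = cfg@sexEffect, cytotype = cfg@cytotype,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a simulation configuration file
#'
#' YAML form of [simConfig()]: top-level keys mirror the constructor
#' arguments; `loci` is a list of locus entries as in [readModelSpec()]
#' and each entry of `schemes` is a model spec (`model`, `focal`,
#' `partners`, `w`) keyed by episode.
#'
#' @param path path to the YAML file.
#' @return a [SimConfig-class].
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(l, f, default)
    if (is.null(l[[f]])) default else l[[f]]
  loci <- lociTable(
    vapply(y$loci, `[[`, character(1), "name"),
    vapply(y$loci, function(l) pick(l, "derived_parent", "P2"),
           character(1)),
    vapply(y$loci, function(l) as.character(pick(l, "linkage_group", NA)),
           character(1)),
    vapply(y$loci, function(l)
      as.numeric(pick(l, "recomb_fraction_to_prev", NA)), numeric(1)))
  schemes <- lapply(y$schemes, function(s)
    makeScheme(s$model, s$focal, as.character(unlist(s$partners)),
               w = pick(s, "w", 0)))
  sa <- pick(y, "sample_adults", 0L)
  if (is.list(sa)) sa <- unlist(sa)
  simConfig(loci, schemes,
            nOffspring = pick(y, "n_offspring", 2000L),
            sampleNauplii = pick(y, "sample_nauplii", 0L),
            sampleAdults = sa,
            sexEffect = pick(y, "sex_effect", 0),
            crossLabel = pick(y, "cross_label", "P1f_x_P2m"),
            cytotype = pick(y, "cytotype", "native"),
            baselineMortality = pick(y, "baseline_mortality", 0),
            seed = pick(y, "seed", 1L))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d loci, %d zygotes, cross %s (cytotype %s), seed %d\n",
              nrow(object@loci), object@nOffspring, object@crossLabel,
              object@cytotype, object@seed))
  cat(sprintf("  samples: %d nauplii, %s adults; sexEffect = %g\n",
              object@sampleNauplii,
              paste(object@sampleAdults, collapse = "+"),
              object@sexEffect))
  for (ep in names(object@schemes))
    if (!is.null(object@schemes[[ep]]))
      cat(sprintf("  %s: scheme '%s'\n", ep, object@schemes[[ep]]@model))
})
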