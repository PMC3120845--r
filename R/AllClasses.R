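#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   colData rowData assayNames
NULL

## controlled vocabularies shared across the package
.GENO_CODES <- c("P1", "H", "P2")
.STAGES <- c("nauplius", "adult")
.SEXES <- c("male", "female", "unknown")
.PARENTS <- c("P1", "P2")
.EPISODES <- c("embryo_to_nauplius", "nauplius_to_adult")
.MODELS <- c("pairwise_hom_hom", "pairwise_one_way", "complex_conspecific",
             "independent_one_way", "independent_two_way", "cytonuclear")

#' F2 intercross genotype table
#'
#' An S4 container for per-individual marker genotypes of an F2 hybrid
#' cohort, extending [SummarizedExperiment::SummarizedExperiment]. Loci are
#' rows, individuals are columns. The `"genotype"` assay holds the codes
#' `"P1"` (homozygote for the population-1 allele), `"H"` (heterozygote),
#' `"P2"` (homozygote for the population-2 allele) or `NA` (not scored).
#' `colData` carries `cross`, `stage` (`nauplius`/`adult`), `sex`
#' (`male`/`female`/`unknown`) and `cytotype` (maternal-line population);
#' `rowData` carries the locus description (`derived_parent`,
#' `linkage_group`, `recomb_fraction_to_prev`).
#'
#' @seealso [readGenotypeTable()], [countGenotypes()], [crossTabulate()]
#' @export
setClass("F2CrossTable", contains = "SummarizedExperiment")

setValidity("F2CrossTable", function(object) {
  msg <- character()
  if (!"genotype" %in% assayNames(object))
    return("assay 'genotype' is required")
  g <- assay(object, "genotype")
  bad <- !is.na(g) & !(g %in% .GENO_CODES)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    msg <- c(msg, sprintf(
      "unknown genotype code '%s' at locus '%s', individual '%s'",
      g[bad][1L], rownames(g)[i[1L]], colnames(g)[i[2L]]))
  }
  cd <- colData(object)
  for (f in c("cross", "stage", "sex", "cytotype"))
    if (!f %in% colnames(cd)) msg <- c(msg, sprintf("colData lacks '%s'", f))
  if ("stage" %in% colnames(cd) && !all(cd$stage %in% .STAGES))
    msg <- c(msg, "stage values must be 'nauplius' or 'adult'")
  if ("sex" %in% colnames(cd) && !all(cd$sex %in% .SEXES))
    msg <- c(msg, "sex values must be 'male', 'female' or 'unknown'")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "individual ids (column names) must be unique")
  rd <- rowData(object)
  if ("derived_parent" %in% colnames(rd) &&
      !all(rd$derived_parent %in% .PARENTS))
    msg <- c(msg, "derived_parent must be 'P1' or 'P2'")
  if ("recomb_fraction_to_prev" %in% colnames(rd)) {
    r <- rd$recomb_fraction_to_prev
    if (any(!is.na(r) & (r < 0 | r > 0.5)))
      msg <- c(msg, "recomb_fraction_to_prev must lie in [0, 0.5]")
  }
  if (length(msg)) msg else TRUE
})

#' Genotype class counts at a single locus
#'
#' Counts of the three F2 genotype classes (`P1` homozygote, heterozygote,
#' `P2` homozygote) among non-missing individuals of some selection.
#'
#' @slot counts named integer vector of length 3 (`P1`, `H`, `P2`).
#' @seealso [countGenotypes()], [mendelianChisq()], [haldaneViability()]
#' @export
setClass("GenotypeCounts", representation(counts = "integer"))

setValidity("GenotypeCounts", function(object) {
  k <- object@counts
  if (length(k) != 3L || !identical(names(k), .GENO_CODES))
    return("counts must be a length-3 integer vector named P1, H, P2")
  if (any(is.na(k)) || any(k < 0L)) return("counts must be non-negative")
  TRUE
})

#' Two-locus genotype class counts
#'
#' A 3x3 grid of joint genotype-class counts for an ordered locus pair;
#' rows index the first locus's classes (`P1`, `H`, `P2`), columns the
#' second's. Built over the pairwise-complete subset (individuals missing
#' at either locus excluded), so the grid marginals reproduce the
#' single-locus counts of that same subset.
#'
#' @slot counts 3x3 numeric matrix (integer counts or model-scaled
#'   expected numbers).
#' @slot loci character vector of length 2 naming (rows, columns).
#' @seealso [crossTabulate()], [independenceTest()]
#' @export
setClass("TwoLocusCounts",
         representation(counts = "matrix", loci = "character"))

setValidity("TwoLocusCounts", function(object) {
  o <- object@counts
  if (!is.numeric(o) || !identical(dim(o), c(3L, 3L)))
    return("counts must be a 3x3 numeric matrix")
  if (any(is.na(o)) || any(o < 0)) return("counts must be non-negative")
  TRUE
})

#' Chi-square test result
#'
#' Result container for the package's Pearson chi-square tests: the
#' statistic, its degrees of freedom, the upper-tail p-value and, where
#' meaningful, signed per-cell contributions
#' (`sign(O - E) * (O - E)^2 / E`, so the statistic equals the sum of
#' their absolute values).
#'
#' @slot statistic non-negative chi-square statistic.
#' @slot df degrees of freedom.
#' @slot p.value upper-tail p-value.
#' @slot method short description of the test performed.
#' @slot cells signed per-cell contributions (vector or matrix), or `NULL`.
#' @slot note character vector of warnings attached to the computation
#'   (e.g. expected cells below 5).
#' @export
setClass("SegTestResult",
         representation(statistic = "numeric", df = "numeric",
                        p.value = "numeric", method = "character",
                        cells = "ANY", note = "character"))

#' Two-locus independence test result
#'
#' Extends [SegTestResult-class] with the observed and marginal-adjusted
#' expected 3x3 grids. Expected numbers are products of the observed
#' single-locus marginals, so single-locus distortion is removed from the
#' two-locus signal by construction and the expected grid conserves the
#' observed marginals exactly.
#'
#' @slot observed 3x3 observed count grid.
#' @slot expected 3x3 adjusted expected grid.
#' @slot loci locus pair (rows, columns).
#' @seealso [independenceTest()], [classifyPair()]
#' @export
setClass("TwoLocusResult", contains = "SegTestResult",
         representation(observed = "matrix", expected = "matrix",
                        loci = "character"))

#' Multi-locus viability scheme for Dobzhansky-Muller incompatibilities
#'
#' A fitness scheme maps each multi-locus F2 genotype (derived-allele
#' dosage 0/1/2 per locus, plus optionally the cytotype) to a viability in
#' \[0, 1\] for one selection episode. It is a set of clauses; a clause
#' assigns fitness `w` to genotypes satisfying a condition on per-locus
#' dosages (and cytotype), and fitness composes multiplicatively across
#' satisfied clauses. An empty clause set is the neutral scheme
#' (fitness 1 everywhere).
#'
#' @slot model name of the named model the scheme was built from, or
#'   `"custom"`.
#' @slot clauses list of clauses; each clause is a list with elements
#'   `dosage` (named list: locus -> allowed dosages), `cytotype`
#'   (`NA` or a required cytotype value) and `w`.
#' @slot episode selection episode the scheme applies to
#'   (`embryo_to_nauplius` or `nauplius_to_adult`).
#' @slot loci names of loci the clauses refer to.
#' @seealso [makeScheme()], [applySelection()], [fitnessOf()]
#' @export
setClass("FitnessScheme",
         representation(model = "character", clauses = "list",
                        episode = "character", loci = "character"))

setValidity("FitnessScheme", function(object) {
  for (cl in object@clauses) {
    if (!all(c("dosage", "cytotype", "w") %in% names(cl)))
      return("each clause needs 'dosage', 'cytotype' and 'w'")
    if (cl$w < 0 || cl$w > 1) return("clause fitness w must lie in [0, 1]")
    if (!all(unlist(cl$dosage) %in% 0:2))
      return("clause dosages must be subsets of {0, 1, 2}")
  }
  if (!object@episode %in% .EPISODES)
    return(sprintf("episode must be one of: %s",
                   paste(.EPISODES, collapse = ", ")))
  TRUE
})

#' Exact model prediction for an F2 cohort under selection
#'
#' Post-selection joint genotype-class frequencies from exact enumeration,
#' with per-locus marginals and Haldane relative viabilities derived from
#' them.
#'
#' @slot joint array of dimension `3^L` (one dimension per locus, classes
#'   `P1`, `H`, `P2`) holding post-selection frequencies summing to 1.
#' @slot loci locus description data frame (see [lociTable()]).
#' @slot marginals L x 3 matrix of per-locus class frequencies.
#' @slot viability data frame of per-locus Haldane viabilities for both
#'   homozygous classes (heterozygote = 1).
#' @slot scheme the [FitnessScheme-class] that was applied.
#' @seealso [applySelection()], [predictPairDeviation()]
#' @export
setClass("ModelPrediction",
         representation(joint = "array", loci = "data.frame",
                        marginals = "matrix", viability = "data.frame",
                        scheme = "FitnessScheme"))

setValidity("ModelPrediction", function(object) {
  if (abs(sum(object@joint) - 1) > 1e-12)
    return("joint frequencies must sum to 1 (within 1e-12)")
  TRUE
})

#' Forward-simulation configuration for an F2 cohort
#'
#' Parameters of one simulated F2 intercross cohort: loci (with linkage),
#' per-episode fitness schemes, cohort and sample sizes, a sex effect that
#' scales selection intensity in females, cross label, cytotype, baseline
#' genotype-independent larval mortality, and the seed that fully
#' determines the output.
#'
#' @seealso [simConfig()], [simulateCohort()]
#' @export
setClass("SimConfig",
         representation(loci = "data.frame", schemes = "list",
                        nOffspring = "integer", sampleNauplii = "integer",
                        sampleAdults = "integer", sexEffect = "numeric",
                        crossLabel = "character", cytotype = "character",
                        baselineMortality = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@nOffspring < 1L) return("nOffspring must be positive")
  if (any(object@sampleNauplii < 0L) || any(object@sampleAdults < 0L))
    return("sample sizes must be non-negative")
  if (object@sexEffect < 0) return("sexEffect must be >= 0")
  if (object@baselineMortality < 0 || object@baselineMortality >= 1)
    return("baselineMortality must lie in [0, 1)")
  bad <- !vapply(object@schemes, function(s)
    is.null(s) || is(s, "FitnessScheme"), logical(1))
  if (any(bad)) return("schemes must be FitnessScheme objects or NULL")
  TRUE
})

#' Full-screen analysis report
#'
#' Results of a Table-2/Table-3-style screen over one genotype table:
#' per-(cross, marker, subset) single-locus tests and viabilities,
#' per-(cross, pair, stage) two-locus independence tests with signed
#' contributions, and Holm (sequential Bonferroni) flags applied per
#' results table.
#'
#' @seealso [runScreen()], [writeScreenReport()]
#' @export
setClass("ScreenReport",
         representation(singleLocus = "data.frame", viability = "data.frame",
                        twoLocus = "data.frame", contributions = "data.frame",
                        alpha = "numeric"))
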