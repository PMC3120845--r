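#' Describe the loci of a study
#'
#' Builds the locus description table used throughout the package. Each
#' locus has a name, the parental population whose allele is treated as
#' "derived" for incompatibility-model semantics, and optionally a linkage
#' group plus the recombination fraction to the preceding locus of the
#' same group (`r = 0.5` is free recombination; loci without a linkage
#' group are unlinked).
#'
#' @param name character vector of unique locus names.
#' @param derived_parent `"P1"` or `"P2"` per locus (recycled).
#' @param linkage_group optional linkage-group labels (`NA` = unlinked).
#' @param recomb_fraction_to_prev recombination fraction in \[0, 0.5\] to
#'   the previous locus on the same linkage group; `NA` for the first
#'   locus of a group and for unlinked loci.
#' @return a `data.frame` with one row per locus.
#' @examples
#' lociTable(c("ME2", "GOT2"), derived_parent = "P2")
#' @export
lociTable <- function(name, derived_parent = "P2", linkage_group = NA,
                      recomb_fraction_to_prev = NA) {
  name <- as.character(name)
  if (anyDuplicated(name))
    stop("locus names must be unique within a study")
  n <- length(name)
  loci <- data.frame(
    name = name,
    derived_parent = rep_len(as.character(derived_parent), n),
    linkage_group = rep_len(as.character(linkage_group), n),
    recomb_fraction_to_prev = rep_len(as.numeric(recomb_fraction_to_prev), n),
    stringsAsFactors = FALSE)
  if (!all(loci$derived_parent %in% .PARENTS))
    stop("derived_parent must be 'P1' or 'P2'")
  r <- loci$recomb_fraction_to_prev
  if (any(!is.na(r) & (r < 0 | r > 0.5)))
    stop("recomb_fraction_to_prev must lie in [0, 0.5]")
  loci
}

#' Read a locus description file
#'
#' Reads a tab-separated locus table with columns `name`,
#' `derived_parent`, `linkage_group`, `recomb_fraction_to_prev`.
#'
#' @param path path to the TSV file.
#' @return a locus `data.frame`, as from [lociTable()].
#' @export
readLociTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("name", "derived_parent", "linkage_group",
            "recomb_fraction_to_prev")
  miss <- setdiff(need, colnames(d))
  if (length(miss))
    stop("locus file lacks column(s): ", paste(miss, collapse = ", "))
  lociTable(d$name, d$derived_parent, d$linkage_group,
            d$recomb_fraction_to_prev)
}

.fixedCols <- c("individual_id", "cross", "stage", "sex", "cytotype")

#' Construct an F2 genotype table
#'
#' @param genotype character matrix or data frame of genotype codes
#'   (`P1`/`H`/`P2`/`NA`) with one row per individual and one column per
#'   locus.
#' @param individuals data frame with columns `individual_id`, `cross`,
#'   `stage`, `sex`, `cytotype`, one row per individual.
#' @param loci locus description, as from [lociTable()]; defaults to
#'   unlinked loci named after the genotype columns.
#' @return an [F2CrossTable-class] object.
#' @examples
#' geno <- cbind(ME2 = c("P1", "H", "P2"), GOT2 = c("H", "H", NA))
#' ind <- data.frame(individual_id = c("i1", "i2", "i3"),
#'                   cross = "ABf_x_SDm", stage = "adult",
#'                   sex = c("male", "female", "male"), cytotype = "AB")
#' f2CrossTable(geno, ind)
#' @export
f2CrossTable <- function(genotype, individuals, loci = NULL) {
  g <- as.matrix(genotype)
  storage.mode(g) <- "character"
  if (is.null(loci)) loci <- lociTable(colnames(g))
  if (!identical(colnames(g), loci$name))
    stop("genotype columns must match loci$name (same order)")
  miss <- setdiff(.fixedCols, colnames(individuals))
  if (length(miss))
    stop("individuals lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(individuals$individual_id))
    stop("duplicate individual_id: ",
         individuals$individual_id[duplicated(individuals$individual_id)][1L])
  rownames(g) <- individuals$individual_id
  cd <- S4Vectors::DataFrame(
    cross = as.character(individuals$cross),
    stage = as.character(individuals$stage),
    sex = as.character(individuals$sex),
    cytotype = as.character(individuals$cytotype),
    row.names = individuals$individual_id)
  rd <- S4Vectors::DataFrame(loci[, setdiff(colnames(loci), "name")],
                             row.names = loci$name)
  se <- SummarizedExperiment(assays = list(genotype = t(g)),
                             colData = cd, rowData = rd)
  new("F2CrossTable", se)
}

#' Read an F2 genotype table from a delimited file
#'
#' The file must have a header with the fixed columns `individual_id`,
#' `cross`, `stage`, `sex`, `cytotype` followed by one column per locus,
#' cells coded `P1`/`H`/`P2`/`NA`. The delimiter is auto-detected between
#' tab and comma.
#'
#' @param path path to the file.
#' @param loci optional locus description, as from [lociTable()]; when
#'   given, its loci must all be columns of the file and are taken in the
#'   order of `loci`.
#' @return an [F2CrossTable-class] object.
#' @seealso [writeGenotypeTable()]
#' @export
readGenotypeTable <- function(path, loci = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  d <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE, na.strings = "NA",
                         colClasses = "character", check.names = FALSE)
  miss <- setdiff(.fixedCols, colnames(d))
  if (length(miss))
    stop("malformed header: missing column(s) ",
         paste(miss, collapse = ", "))
  locusCols <- setdiff(colnames(d), .fixedCols)
  if (!is.null(loci)) {
    absent <- setdiff(loci$name, locusCols)
    if (length(absent))
      stop("loci not present in file: ", paste(absent, collapse = ", "))
    locusCols <- loci$name
  } else {
    loci <- lociTable(locusCols)
  }
  g <- as.matrix(d[, locusCols, drop = FALSE])
  bad <- !is.na(g) & !(g %in% .GENO_CODES)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("unknown genotype code '%s' in row %d (individual '%s'), column '%s'",
                 g[bad][1L], i[1L], d$individual_id[i[1L]],
                 locusCols[i[2L]]))
  }
  if (anyDuplicated(d$individual_id))
    stop("duplicate individual_id: ",
         d$individual_id[duplicated(d$individual_id)][1L])
  f2CrossTable(g, d[, .fixedCols], loci)
}

#' Write an F2 genotype table to a delimited file
#'
#' Writes the canonical tab-separated genotype format; a table written and
#' re-read round-trips exactly.
#'
#' @param x an [F2CrossTable-class].
#' @param path output path.
#' @param sep field delimiter, tab by default.
#' @return `path`, invisibly.
#' @export
writeGenotypeTable <- function(x, path, sep = "\t") {
  d <- data.frame(individual_id = colnames(x),
                  cross = colData(x)$cross, stage = colData(x)$stage,
                  sex = colData(x)$sex, cytotype = colData(x)$cytotype,
                  t(assay(x, "genotype")), check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

## Validate a stage/sex/cross filter and return the logical column mask.
.individualMask <- function(x, cross = NULL, stage = NULL, sex = NULL) {
  cd <- colData(x)
  keep <- rep(TRUE, ncol(x))
  if (!is.null(stage)) {
    if (!all(stage %in% .STAGES))
      stop("unknown stage value: ", paste(setdiff(stage, .STAGES),
                                          collapse = ", "))
    keep <- keep & cd$stage %in% stage
  }
  if (!is.null(sex)) {
    if (!all(sex %in% .SEXES))
      stop("unknown sex value: ", paste(setdiff(sex, .SEXES),
                                        collapse = ", "))
    keep <- keep & cd$sex %in% sex
  }
  if (!is.null(cross)) keep <- keep & cd$cross %in% cross
  keep
}

#' Subset an F2 table by individual attributes
#'
#' @param x an [F2CrossTable-class].
#' @param cross,stage,sex optional values to keep (each `NULL` = no
#'   filtering on that field).
#' @return the filtered [F2CrossTable-class].
#' @export
subsetIndividuals <- function(x, cross = NULL, stage = NULL, sex = NULL) {
  x[, .individualMask(x, cross = cross, stage = stage, sex = sex)]
}

#' Build a GenotypeCounts object
#'
#' @param nP1,nHet,nP2 non-negative integer class counts.
#' @return a [GenotypeCounts-class].
#' @examples
#' genotypeCounts(25, 50, 25)
#' @export
genotypeCounts <- function(nP1, nHet, nP2) {
  k <- as.integer(c(nP1, nHet, nP2))
  names(k) <- .GENO_CODES
  new("GenotypeCounts", counts = k)
}

#' Count genotype classes at one locus
#'
#' Tallies `P1`/`H`/`P2` among the individuals passing the filter;
#' missing genotypes are excluded (so `nTotal()` is the number of scored
#' individuals in the selection).
#'
#' @param x an [F2CrossTable-class].
#' @param locus locus name.
#' @param cross,stage,sex optional filter values.
#' @return a [GenotypeCounts-class].
#' @export
countGenotypes <- function(x, locus, cross = NULL, stage = NULL, sex = NULL) {
  if (!locus %in% rownames(x)) stop("unknown locus: ", locus)
  g <- assay(x, "genotype")[locus,
                            .individualMask(x, cross, stage, sex)]
  tab <- table(factor(g, levels = .GENO_CODES))
  genotypeCounts(tab[["P1"]], tab[["H"]], tab[["P2"]])
}

#' Cross-tabulate genotype classes at a locus pair
#'
#' Builds the 3x3 joint count grid for an ordered locus pair over the
#' pairwise-complete subset: individuals missing at either locus are
#' excluded, so the grid marginals equal [countGenotypes()] on the
#' identical subset.
#'
#' @param x an [F2CrossTable-class].
#' @param locusA,locusB distinct locus names; `locusA` indexes rows.
#' @param cross,stage,sex optional filter values.
#' @return a [TwoLocusCounts-class].
#' @export
crossTabulate <- function(x, locusA, locusB, cross = NULL, stage = NULL,
                          sex = NULL) {
  if (identical(locusA, locusB))
    stop("locusA and locusB must differ")
  for (l in c(locusA, locusB))
    if (!l %in% rownames(x)) stop("unknown locus: ", l)
  keep <- .individualMask(x, cross, stage, sex)
  a <- assay(x, "genotype")[locusA, keep]
  b <- assay(x, "genotype")[locusB, keep]
  ok <- !is.na(a) & !is.na(b)
  o <- table(factor(a[ok], levels = .GENO_CODES),
             factor(b[ok], levels = .GENO_CODES))
  o <- matrix(as.numeric(o), 3, 3,
              dimnames = list(.GENO_CODES, .GENO_CODES))
  new("TwoLocusCounts", counts = o, loci = c(locusA, locusB))
}

## ---- accessors & show methods -------------------------------------------

#' @rdname accessors
#' @export
setMethod("genotypes", "F2CrossTable", function(x) assay(x, "genotype"))

#' @rdname accessors
#' @export
setMethod("lociInfo", "F2CrossTable", function(x) {
  rd <- rowData(x)
  cbind(data.frame(name = rownames(x), stringsAsFactors = FALSE),
        as.data.frame(rd))
})

#' @describeIn GenotypeCounts class counts as a named integer vector.
#' @param object a `GenotypeCounts`.
#' @export
setMethod("counts", "GenotypeCounts", function(object) object@counts)

#' @describeIn TwoLocusCounts the 3x3 count grid.
#' @param object a `TwoLocusCounts`.
#' @export
setMethod("counts", "TwoLocusCounts", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("nTotal", "GenotypeCounts", function(x) sum(x@counts))

#' @rdname accessors
#' @export
setMethod("nTotal", "TwoLocusCounts", function(x) sum(x@counts))

setMethod("show", "F2CrossTable", function(object) {
  cd <- colData(object)
  cat(sprintf("F2CrossTable: %d individuals x %d loci\n",
              ncol(object), nrow(object)))
  cat("  loci:", paste(rownames(object), collapse = ", "), "\n")
  cat("  crosses:", paste(unique(cd$cross), collapse = ", "), "\n")
  st <- table(factor(cd$stage, levels = .STAGES))
  sx <- table(factor(cd$sex, levels = .SEXES))
  cat(sprintf("  stages: %d nauplii, %d adults; sexes: %d male, %d female, %d unknown\n",
              st[["nauplius"]], st[["adult"]], sx[["male"]], sx[["female"]],
              sx[["unknown"]]))
})

setMethod("show", "GenotypeCounts", function(object) {
  k <- object@counts
  cat(sprintf("GenotypeCounts: P1=%d H=%d P2=%d (N=%d)\n",
              k[1L], k[2L], k[3L], sum(k)))
})

setMethod("show", "TwoLocusCounts", function(object) {
  cat(sprintf("TwoLocusCounts (%s x %s), N=%g\n", object@loci[1L],
              object@loci[2L], sum(object@counts)))
  print(object@counts)
})
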