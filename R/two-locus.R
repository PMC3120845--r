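## Two-locus deviation-from-independence machinery.
##
## The expected grid is the outer product of the observed single-locus
## marginals of the pairwise-complete subset, so each locus's own
## segregation distortion is removed from the two-locus signal by
## construction and the expected grid conserves the observed marginals
## exactly. The statistic is referred to chi-square on 4 df (9 cells - 1
## - 2 - 2 estimated marginal class frequencies).

#' Marginal-adjusted expected two-locus numbers
#'
#' `E[i, j] = row_i * col_j / N`, where `row`/`col` are the observed
#' single-locus class marginals of the grid itself.
#'
#' @param counts a [TwoLocusCounts-class] with `N > 0`.
#' @return a 3x3 numeric matrix whose marginals equal the observed ones.
#' @export
adjustedExpected <- function(counts) {
  o <- counts(counts)
  n <- sum(o)
  if (n == 0) stop("expected grid undefined: N = 0")
  outer(rowSums(o), colSums(o)) / n
}

#' Two-locus test for deviations from independence
#'
#' Pearson chi-square of the observed 3x3 two-locus grid against the
#' marginal-adjusted expectations of [adjustedExpected()], on 4 degrees
#' of freedom, with signed per-cell contributions
#' `sign(O - E) * (O - E)^2 / E`. Because the expectations absorb each
#' single locus's distortion, a significant result reflects
#' non-independence between the loci (linkage or epistatic viability
#' selection), not single-locus skew.
#'
#' @param counts a [TwoLocusCounts-class]; every marginal class must be
#'   non-empty. Expected cells below 1 attach a note but the test
#'   proceeds.
#' @return a [TwoLocusResult-class].
#' @examples
#' o <- matrix(c(4, 8, 4, 8, 16, 8, 4, 8, 0), 3, byrow = TRUE)
#' independenceTest(twoLocusCounts(o))  # chi-square = 3.75
#' @export
independenceTest <- function(counts) {
  o <- counts(counts)
  rs <- rowSums(o); cs <- colSums(o)
  if (any(rs == 0) || any(cs == 0)) {
    empty <- c(paste0(counts@loci[1L], ":", names(rs)[rs == 0]),
               paste0(counts@loci[2L], ":", names(cs)[cs == 0]))
    stop("test undefined on degenerate grid: empty marginal class ",
         paste(empty, collapse = ", "))
  }
  e <- adjustedExpected(counts)
  cells <- sign(o - e) * (o - e)^2 / e
  note <- if (any(e < 1)) "expected cell count below 1" else character()
  stat <- sum(abs(cells))
  new("TwoLocusResult", statistic = stat, df = 4,
      p.value = stats::pchisq(stat, 4, lower.tail = FALSE),
      method = "two-locus deviation from independence (marginal-adjusted)",
      cells = cells, note = note, observed = o, expected = e,
      loci = counts@loci)
}

#' Build a TwoLocusCounts object from a matrix
#'
#' @param O 3x3 non-negative count grid (rows = first locus classes
#'   `P1`, `H`, `P2`).
#' @param loci optional length-2 locus names.
#' @return a [TwoLocusCounts-class].
#' @export
twoLocusCounts <- function(O, loci = c("locusA", "locusB")) {
  o <- as.matrix(O)
  dimnames(o) <- list(.GENO_CODES, .GENO_CODES)
  new("TwoLocusCounts", counts = o, loci = as.character(loci))
}

#' Classify a locus pair as linkage-like or epistasis-like
#'
#' Heuristic codification of the stage-contrast reasoning used to read
#' two-locus results: physical linkage distorts the grid in nauplii and
#' adults alike, with the same recombinant-type (off-diagonal) cells
#' depleted at both stages, whereas an epistatic viability interaction
#' acting during development appears in adults but not nauplii.
#'
#' @param result_nauplii,result_adults [TwoLocusResult-class] objects for
#'   the same locus pair at the two stages.
#' @param alpha significance level applied to both stages (default 0.05;
#'   pass Holm-adjusted significance decisions upstream where a family of
#'   pairs is screened).
#' @return one of `"linkage_like"`, `"epistasis_like"`, `"none"`,
#'   `"ambiguous"`.
#' @export
classifyPair <- function(result_nauplii, result_adults, alpha = 0.05) {
  if (!identical(result_nauplii@loci, result_adults@loci))
    stop("the two results must concern the same locus pair")
  .classifyFromFlags(result_nauplii, result_adults,
                     pvalue(result_nauplii) <= alpha,
                     pvalue(result_adults) <= alpha)
}

## Decision rule with the per-stage significance decisions supplied
## (runScreen passes Holm-family decisions). Linkage is called when both
## stages are significant and the two most-depleted cells of each stage
## are recombinant-type (off-diagonal) cells, depleted at both stages.
.classifyFromFlags <- function(result_nauplii, result_adults, sigN, sigA) {
  if (!sigN && !sigA) return("none")
  if (sigA && !sigN) return("epistasis_like")
  if (sigN && sigA) {
    dep <- function(res) sort(order(contributions(res))[1:2])
    offDiag <- function(idx) {
      rc <- arrayInd(idx, c(3L, 3L))
      all(rc[, 1L] != rc[, 2L])
    }
    dn <- dep(result_nauplii); da <- dep(result_adults)
    both <- union(dn, da)
    if (offDiag(dn) && offDiag(da) &&
        all(contributions(result_nauplii)[both] < 0) &&
        all(contributions(result_adults)[both] < 0))
      return("linkage_like")
  }
  "ambiguous"
}

#' @rdname accessors
#' @export
setMethod("counts", "TwoLocusResult", function(object) object@observed)

#' Expected grid of a two-locus result
#'
#' @param x a [TwoLocusResult-class].
#' @return the 3x3 marginal-adjusted expected grid.
#' @export
expectedCounts <- function(x) x@expected

setMethod("show", "TwoLocusResult", function(object) {
  cat(sprintf("%s (%s x %s)\n  X-squared = %.4g, df = %g, p = %s\n",
              object@method, object@loci[1L], object@loci[2L],
              object@statistic, object@df, formatPValue(object@p.value)))
  for (n in object@note) cat("  note:", n, "\n")
})
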