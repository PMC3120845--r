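## Single-marker segregation-distortion statistics.
##
## All chi-square tests are uncorrected Pearson statistics (no continuity
## correction); a note is attached whenever an expected cell drops below 5.

.segResult <- function(statistic, df, cells, method, note = character()) {
  new("SegTestResult", statistic = statistic, df = df,
      p.value = stats::pchisq(statistic, df, lower.tail = FALSE),
      method = method, cells = cells, note = note)
}

#' Chi-square test against Mendelian 1:2:1 ratios
#'
#' Tests the genotype-class counts of one marker against the F2
#' expectation `N * (1/4, 1/2, 1/4)` with a Pearson chi-square on 2
#' degrees of freedom. Signed per-cell contributions
#' (`sign(O - E) * (O - E)^2 / E`) are attached.
#'
#' @param counts a [GenotypeCounts-class] with `N > 0`.
#' @return a [SegTestResult-class].
#' @examples
#' mendelianChisq(genotypeCounts(10, 50, 40))  # chi-square = 18, df = 2
#' @export
mendelianChisq <- function(counts) {
  o <- as.numeric(counts(counts))
  n <- sum(o)
  if (n == 0) stop("test undefined: no genotyped individuals (N = 0)")
  e <- n * c(0.25, 0.5, 0.25)
  cells <- sign(o - e) * (o - e)^2 / e
  names(cells) <- .GENO_CODES
  note <- if (any(e < 5)) "expected cell count below 5" else character()
  .segResult(sum(abs(cells)), 2, cells, "Mendelian 1:2:1 chi-square", note)
}

## Shared 2x3 contingency chi-square. Genotype classes empty in both rows
## are dropped with a matching reduction in df; an all-empty row is an error.
.contingencyChisq <- function(counts1, counts2, rowLabels, method) {
  o <- rbind(as.numeric(counts(counts1)), as.numeric(counts(counts2)))
  dimnames(o) <- list(rowLabels, .GENO_CODES)
  if (any(rowSums(o) == 0))
    stop(method, ": group '", rowLabels[rowSums(o) == 0][1L],
         "' has no genotyped individuals")
  keep <- colSums(o) > 0
  note <- character()
  if (!all(keep)) {
    note <- sprintf("genotype class(es) %s empty in both groups; df reduced",
                    paste(colnames(o)[!keep], collapse = ", "))
    o <- o[, keep, drop = FALSE]
  }
  if (ncol(o) < 2L)
    stop(method, ": fewer than two non-empty genotype classes")
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  cells <- sign(o - e) * (o - e)^2 / e
  if (any(e < 5)) note <- c(note, "expected cell count below 5")
  .segResult(sum(abs(cells)), ncol(o) - 1L, cells, method, note)
}

#' Sex-homogeneity contingency test
#'
#' Pearson chi-square for homogeneity of genotype-class ratios between
#' male and female F2 individuals at one marker (2x3 contingency table,
#' df = 2; a class empty in both sexes is dropped with the df reduced).
#'
#' @param counts_m,counts_f [GenotypeCounts-class] for males and females.
#' @return a [SegTestResult-class].
#' @export
sexHomogeneityTest <- function(counts_m, counts_f)
  .contingencyChisq(counts_m, counts_f, c("male", "female"),
                    "sex homogeneity contingency chi-square")

#' Reciprocal-cross contingency test
#'
#' Pearson chi-square comparing genotype-class ratios between the two
#' reciprocal crosses at one marker; identical machinery to
#' [sexHomogeneityTest()] with crosses as rows.
#'
#' @param counts_1,counts_2 [GenotypeCounts-class] for the two crosses.
#' @return a [SegTestResult-class].
#' @export
reciprocalCrossTest <- function(counts_1, counts_2)
  .contingencyChisq(counts_1, counts_2, c("cross1", "cross2"),
                    "reciprocal-cross contingency chi-square")

#' Haldane relative viabilities of the homozygous classes
#'
#' Quantifies segregation distortion as the deviation of each homozygous
#' class from the 1:2 ratio with heterozygotes expected under Mendelian
#' inheritance, taking heterozygote viability as 1:
#' `v = 2 * n_hom / n_het`. The standard error is the delta-method value
#' `v * sqrt(1/n_hom + 1/n_het)`; an empty homozygote class gives
#' `v = 0`, `se = 0` flagged via `zero_count`.
#'
#' @param counts a [GenotypeCounts-class] with `n_het > 0`.
#' @return a `data.frame` with rows `P1_hom` and `P2_hom` and columns
#'   `class`, `v`, `se`, `zero_count`.
#' @examples
#' haldaneViability(genotypeCounts(5, 50, 45))  # v = 0.2 and 1.8
#' @export
haldaneViability <- function(counts) {
  k <- counts(counts)
  nhet <- k[["H"]]
  if (nhet == 0)
    stop("viability scale undefined: no heterozygotes observed")
  hom <- c(P1_hom = k[["P1"]], P2_hom = k[["P2"]])
  v <- 2 * hom / nhet
  se <- ifelse(hom > 0, v * sqrt(1 / hom + 1 / nhet), 0)
  data.frame(class = names(hom), v = unname(v), se = unname(se),
             zero_count = unname(hom == 0), stringsAsFactors = FALSE,
             row.names = names(hom))
}

#' Holm (sequential Bonferroni) correction
#'
#' Step-down multiple-testing procedure: the i-th smallest p-value is
#' compared with `alpha / (m - i + 1)`; testing stops at the first
#' failure and all larger p-values are declared non-significant. Flags
#' and per-rank thresholds are returned in input order.
#'
#' @param p_values numeric vector of p-values in (0, 1\].
#' @param alpha family-wise error rate in (0, 1).
#' @return a `data.frame` in input order with columns `p`, `rank`,
#'   `threshold` and `significant`; zero rows for empty input.
#' @examples
#' holmCorrection(c(0.001, 0.04, 0.01), alpha = 0.05)
#' @export
holmCorrection <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L)
    return(data.frame(p = numeric(), rank = integer(),
                      threshold = numeric(), significant = logical()))
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  m <- length(p_values)
  ord <- order(p_values)
  thr <- alpha / (m - seq_len(m) + 1)
  pass <- p_values[ord] <= thr
  firstFail <- match(FALSE, pass, nomatch = m + 1L)
  sig <- seq_len(m) < firstFail
  out <- data.frame(p = p_values, rank = NA_integer_,
                    threshold = NA_real_, significant = NA)
  out$rank[ord] <- seq_len(m)
  out$threshold[ord] <- thr
  out$significant[ord] <- sig
  out
}

## ---- accessors & show ----------------------------------------------------

#' @rdname accessors
#' @export
setMethod("statistic", "SegTestResult", function(x) x@statistic)

#' @rdname accessors
#' @export
setMethod("dof", "SegTestResult", function(x) x@df)

#' @rdname accessors
#' @export
setMethod("pvalue", "SegTestResult", function(x) x@p.value)

#' @rdname accessors
#' @export
setMethod("contributions", "SegTestResult", function(x) x@cells)

#' Format a p-value for display
#'
#' Full precision is kept internally; formatted output truncates tiny
#' values to `"<0.00001"` the way published tables do.
#'
#' @param p numeric p-value(s).
#' @return character vector.
#' @export
formatPValue <- function(p)
  ifelse(p < 1e-5, "<0.00001", formatC(p, digits = 4, format = "g"))

setMethod("show", "SegTestResult", function(object) {
  cat(sprintf("%s\n  X-squared = %.4g, df = %g, p = %s\n", object@method,
              object@statistic, object@df, formatPValue(object@p.value)))
  for (n in object@note) cat("  note:", n, "\n")
})
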