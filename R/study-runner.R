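## Orchestration: full single- and two-locus screens over a genotype
## table, and simulation studies (test size, power, parameter recovery).

.tryTest <- function(expr, context) {
  tryCatch(expr, error = function(e)
    stop(context, ": ", conditionMessage(e), call. = FALSE))
}

#' Run a full segregation screen over a genotype table
#'
#' For every cross present in the table and every locus: the nauplius
#' Mendelian chi-square, the male/female homogeneity test among adults,
#' per-sex Mendelian chi-squares (reported only when the sexes are
#' heterogeneous at `alpha`, the convention of published single-locus
#' tables), the combined-adult chi-square, and Haldane viabilities per
#' stage. For every requested locus pair and stage: the
#' marginal-adjusted independence test with signed contributions, plus a
#' linkage-vs-epistasis classification when both stages are available.
#' Holm (sequential Bonferroni) flags are attached per results table,
#' with the family size taken from the table actually produced.
#'
#' @param x an [F2CrossTable-class] with at least one individual.
#' @param loci locus names to screen (default: all loci of `x`).
#' @param pairs list of length-2 character vectors of locus names
#'   (default: all pairs of `loci`).
#' @param alpha significance level for sex-heterogeneity reporting,
#'   Holm correction and pair classification.
#' @return a [ScreenReport-class].
#' @export
runScreen <- function(x, loci = rownames(x), pairs = NULL, alpha = 0.05) {
  if (ncol(x) == 0L) stop("genotype table has no individuals")
  if (is.null(pairs) && length(loci) > 1L) {
    cmb <- utils::combn(loci, 2L)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  crosses <- unique(colData(x)$cross)
  single <- list(); viab <- list()
  for (cr in crosses) for (loc in loci) {
    ctx <- sprintf("cross %s, marker %s", cr, loc)
    naup <- countGenotypes(x, loc, cross = cr, stage = "nauplius")
    addRow <- function(subset, res)
      data.frame(cross = cr, marker = loc, subset = subset,
                 statistic = statistic(res), df = dof(res),
                 p = pvalue(res), stringsAsFactors = FALSE)
    if (nTotal(naup) > 0)
      single[[length(single) + 1L]] <-
        .tryTest(addRow("nauplii", mendelianChisq(naup)), ctx)
    cm <- countGenotypes(x, loc, cross = cr, stage = "adult", sex = "male")
    cf <- countGenotypes(x, loc, cross = cr, stage = "adult",
                         sex = "female")
    sexHet <- FALSE
    if (nTotal(cm) > 0 && nTotal(cf) > 0) {
      mf <- .tryTest(sexHomogeneityTest(cm, cf), ctx)
      sexHet <- pvalue(mf) <= alpha
      single[[length(single) + 1L]] <- addRow("sex_MF", mf)
      if (sexHet) {
        single[[length(single) + 1L]] <-
          .tryTest(addRow("male", mendelianChisq(cm)), ctx)
        single[[length(single) + 1L]] <-
          .tryTest(addRow("female", mendelianChisq(cf)), ctx)
      }
    }
    ad <- countGenotypes(x, loc, cross = cr, stage = "adult")
    if (nTotal(ad) > 0)
      single[[length(single) + 1L]] <-
        .tryTest(addRow("adults", mendelianChisq(ad)), ctx)
    for (st in .STAGES) {
      k <- countGenotypes(x, loc, cross = cr, stage = st)
      if (counts(k)[["H"]] > 0) {
        hv <- haldaneViability(k)
        hv <- cbind(data.frame(cross = cr, marker = loc, stage = st,
                               stringsAsFactors = FALSE), hv)
        viab[[length(viab) + 1L]] <- hv
      }
    }
  }
  single <- do.call(rbind, single)
  if (nrow(single))
    single <- cbind(single,
                    holmCorrection(single$p, alpha)[c("threshold",
                                                      "significant")])
  viab <- if (length(viab)) do.call(rbind, viab) else
    data.frame(cross = character(), marker = character(),
               stage = character(), class = character(), v = numeric(),
               se = numeric(), zero_count = logical())
  rownames(viab) <- NULL

  two <- list(); contrib <- list(); results <- list()
  for (cr in crosses) for (pr in pairs) {
    key <- paste(cr, paste(pr, collapse = "/"))
    for (st in .STAGES) {
      tl <- crossTabulate(x, pr[1L], pr[2L], cross = cr, stage = st)
      if (nTotal(tl) == 0) next
      res <- tryCatch(independenceTest(tl), error = function(e) NULL)
      if (is.null(res)) next
      results[[paste(key, st)]] <- res
      two[[length(two) + 1L]] <-
        data.frame(cross = cr, pair = paste(pr, collapse = "/"),
                   stage = st, statistic = statistic(res), df = dof(res),
                   p = pvalue(res), stringsAsFactors = FALSE)
      cc <- contributions(res)
      contrib[[length(contrib) + 1L]] <-
        data.frame(cross = cr, pair = paste(pr, collapse = "/"),
                   stage = st, classA = rep(.GENO_CODES, 3),
                   classB = rep(.GENO_CODES, each = 3),
                   contribution = as.vector(cc), stringsAsFactors = FALSE)
    }
  }
  two <- if (length(two)) do.call(rbind, two) else
    data.frame(cross = character(), pair = character(), stage = character(),
               statistic = numeric(), df = numeric(), p = numeric())
  if (nrow(two)) {
    hc <- holmCorrection(two$p, alpha)
    two$threshold <- hc$threshold
    two$significant <- hc$significant
    two$classification <- NA_character_
    for (i in which(two$stage == "adult")) {
      key <- paste(two$cross[i], two$pair[i])
      rn <- results[[paste(key, "nauplius")]]
      ra <- results[[paste(key, "adult")]]
      if (!is.null(rn) && !is.null(ra)) {
        ## classify on Holm-corrected significance: a stage counts as
        ## significant only if its row survived the family correction
        sigOf <- function(st) {
          j <- which(two$cross == two$cross[i] & two$pair == two$pair[i] &
                       two$stage == st)
          length(j) > 0 && any(two$significant[j])
        }
        two$classification[i] <-
          .classifyFromFlags(rn, ra, sigOf("nauplius"), sigOf("adult"))
      }
    }
  }
  contrib <- if (length(contrib)) do.call(rbind, contrib) else
    data.frame(cross = character(), pair = character(), stage = character(),
               classA = character(), classB = character(),
               contribution = numeric())
  new("ScreenReport", singleLocus = single, viability = viab,
      twoLocus = two, contributions = contrib, alpha = alpha)
}

#' Write a screen report as TSV files
#'
#' Emits `single_locus.tsv`, `viability.tsv`, `two_locus.tsv` and
#' `contributions.tsv` (long-format signed per-cell contributions) into
#' a directory.
#'
#' @param report a [ScreenReport-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeScreenReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(d, f)
    utils::write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  w(report@singleLocus, "single_locus.tsv")
  w(report@viability, "viability.tsv")
  w(report@twoLocus, "two_locus.tsv")
  w(report@contributions, "contributions.tsv")
  invisible(dir)
}

#' Rejection-rate study over simulated scenarios
#'
#' Simulates `replicates` cohorts per scenario and records, for each
#' requested test, the fraction of replicates rejecting at `alpha`, with
#' its Monte-Carlo standard error. Replicate seeds are derived from
#' `seed` so every cell is independently reproducible.
#'
#' @param scenarios named list of [SimConfig-class] objects (names label
#'   the rows).
#' @param replicates replicates per scenario (at least 100).
#' @param alpha significance level.
#' @param seed integer base seed; replicate `i` of scenario `s` runs at
#'   `seed + 1000 * s + i`.
#' @param tests character subset of `"mendelian_adult"`,
#'   `"mendelian_nauplii"`, `"two_locus_adult"`.
#' @param locus focal locus for the Mendelian tests (default: first
#'   locus).
#' @param pair locus pair for the two-locus test (default: first two
#'   loci).
#' @return a `data.frame` with one row per (scenario, test):
#'   `rejection_rate`, `mc_se`, `replicates`.
#' @export
sizePowerStudy <- function(scenarios, replicates = 200, alpha = 0.05,
                           seed = 1L,
                           tests = c("mendelian_adult", "two_locus_adult"),
                           locus = NULL, pair = NULL) {
  if (replicates < 100) stop("at least 100 replicates are required")
  out <- list()
  for (s in seq_along(scenarios)) {
    cfg <- scenarios[[s]]
    lname <- if (is.null(locus)) cfg@loci$name[1L] else locus
    pnames <- if (is.null(pair)) cfg@loci$name[1:2] else pair
    rej <- matrix(NA, replicates, length(tests),
                  dimnames = list(NULL, tests))
    for (i in seq_len(replicates)) {
      cfg@seed <- as.integer(seed + 1000L * s + i)
      tab <- simulateCohort(cfg)
      for (tst in tests) {
        p <- switch(tst,
          mendelian_adult = pvalue(mendelianChisq(
            countGenotypes(tab, lname, stage = "adult"))),
          mendelian_nauplii = pvalue(mendelianChisq(
            countGenotypes(tab, lname, stage = "nauplius"))),
          two_locus_adult = pvalue(independenceTest(
            crossTabulate(tab, pnames[1L], pnames[2L], stage = "adult"))),
          stop("unknown test: ", tst))
        rej[i, tst] <- p <= alpha
      }
    }
    rate <- colMeans(rej)
    out[[s]] <- data.frame(
      scenario = if (is.null(names(scenarios))) as.character(s)
                 else names(scenarios)[s],
      test = tests, rejection_rate = unname(rate),
      mc_se = unname(sqrt(rate * (1 - rate) / replicates)),
      replicates = replicates, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

setMethod("show", "ScreenReport", function(object) {
  cat(sprintf("ScreenReport (alpha = %g)\n", object@alpha))
  cat(sprintf("  single-locus tests: %d (%d Holm-significant)\n",
              nrow(object@singleLocus),
              sum(object@singleLocus$significant)))
  cat(sprintf("  two-locus tests: %d (%d Holm-significant)\n",
              nrow(object@twoLocus), sum(object@twoLocus$significant)))
  cls <- object@twoLocus$classification
  cls <- cls[!is.na(cls)]
  if (length(cls)) {
    tb <- table(cls)
    cat("  pair classifications:",
        paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
})
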