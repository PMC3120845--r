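## Exact enumeration engine for multi-locus Dobzhansky-Muller (DM)
## incompatibility fitness models in F2 intercrosses.
##
## Genotype classes are indexed P1/H/P2 per locus; model semantics work on
## the derived-allele dosage d in {0, 1, 2}, where the "derived" allele is
## the one from `derived_parent`. F1 parents are heterozygous at every
## locus in coupling phase (all P1 alleles on one homolog), so gamete
## haplotype probabilities follow the recombination fractions directly,
## with independence across intervals (no interference).

## Gamete haplotype distribution for one linkage group of k loci.
## Rows of $hap are 0/1 (P1/P2 allele) per locus; $p are probabilities.
.gameteDist <- function(r) {
  k <- length(r) + 1L
  hap <- as.matrix(expand.grid(rep(list(0:1), k)))
  colnames(hap) <- NULL
  p <- rep(0.5, nrow(hap))
  for (i in seq_along(r)) {
    flip <- hap[, i] != hap[, i + 1L]
    p <- p * ifelse(flip, r[i], 1 - r[i])
  }
  list(hap = hap, p = p)
}

## Genotype-class joint array (dims 3^k) for one linkage group.
.groupJoint <- function(r) {
  g <- .gameteDist(r)
  k <- ncol(g$hap)
  joint <- array(0, dim = rep(3L, k))
  for (i in seq_along(g$p)) {
    for (j in seq_along(g$p)) {
      idx <- g$hap[i, ] + g$hap[j, ] + 1L   # P2-allele count + 1
      joint[matrix(idx, 1L)] <- joint[matrix(idx, 1L)] + g$p[i] * g$p[j]
    }
  }
  joint
}

#' Pre-selection F2 joint genotype frequencies
#'
#' Exact joint frequencies of all `3^L` genotype classes in an F2
#' intercross, from random union of coupling-phase F1 gametes. Unlinked
#' loci contribute independent (1/4, 1/2, 1/4) factors; loci sharing a
#' linkage group follow their recombination fractions with no
#' interference.
#'
#' @param loci locus description, as from [lociTable()]. Loci of one
#'   linkage group must carry `recomb_fraction_to_prev` (first locus of a
#'   group excepted).
#' @return an array of dimension `rep(3, L)` with dimnames
#'   `P1`/`H`/`P2` per locus, summing to 1; the locus table is attached
#'   as attribute `"loci"`.
#' @examples
#' j <- f2Frequencies(lociTable(c("A", "B")))
#' j["P1", "P1"]  # 1/16: both loci P1-homozygous, unlinked
#' @export
f2Frequencies <- function(loci) {
  L <- nrow(loci)
  grp <- loci$linkage_group
  grp[is.na(grp)] <- paste0(".single", seq_len(L))[is.na(grp)]
  groups <- split(seq_len(L), factor(grp, levels = unique(grp)))
  parts <- lapply(groups, function(idx) {
    if (length(idx) == 1L) return(c(0.25, 0.5, 0.25))
    r <- loci$recomb_fraction_to_prev[idx[-1L]]
    if (any(is.na(r) | r < 0 | r > 0.5))
      stop("invalid recombination fraction for linked loci: ",
           paste(loci$name[idx[-1L]][is.na(r) | r < 0 | r > 0.5],
                 collapse = ", "))
    .groupJoint(r)
  })
  joint <- parts[[1L]]
  if (length(parts) > 1L)
    for (i in 2L:length(parts)) joint <- outer(joint, parts[[i]])
  dim(joint) <- rep(3L, L)
  ## outer() orders dims by group; map back to the input locus order
  joint <- aperm(joint, order(unlist(groups)))
  dimnames(joint) <- rep(list(.GENO_CODES), L)
  names(dimnames(joint)) <- loci$name
  attr(joint, "loci") <- loci
  joint
}

#' Build a named DM-incompatibility fitness scheme
#'
#' Constructs the clause set of a named incompatibility model. All models
#' are recessive-style: lowered fitness requires the focal locus to carry
#' derived alleles, with partner conditions as follows (`d` = derived
#' dosage):
#' \describe{
#'   \item{`pairwise_hom_hom`}{`d_focal = 2` and `d_partner = 2` -> `w`.}
#'   \item{`pairwise_one_way`}{`d_focal = 2` and `d_partner >= 1` -> `w`.}
#'   \item{`complex_conspecific`}{all listed loci `d = 2` -> `w` (a single
#'     clause over focal plus partners).}
#'   \item{`independent_one_way`}{one `pairwise_one_way` clause per
#'     partner (independent incompatibilities sharing the focal locus).}
#'   \item{`independent_two_way`}{the `independent_one_way` clauses plus,
#'     per partner, `d_focal = 1` and `d_partner = 2` -> `w`.}
#'   \item{`cytonuclear`}{`d_focal = 2` and cytotype `"foreign"` -> `w`.}
#' }
#' Fitness composes multiplicatively across satisfied clauses.
#'
#' @param model model name (one of the above).
#' @param focal focal locus name.
#' @param partners character vector of partner locus names (empty for
#'   `cytonuclear`).
#' @param w fitness in \[0, 1\] of an incompatible combination; `w = 0`
#'   is complete inviability.
#' @param episode selection episode the scheme acts in.
#' @return a [FitnessScheme-class].
#' @examples
#' makeScheme("independent_one_way", "ME2", c("GOT2", "X3"), w = 0)
#' @export
makeScheme <- function(model, focal, partners = character(), w = 0,
                       episode = "nauplius_to_adult") {
  if (!model %in% .MODELS)
    stop("unknown model '", model, "'; known models: ",
         paste(.MODELS, collapse = ", "))
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  needPartners <- model != "cytonuclear"
  if (needPartners && length(partners) == 0L)
    stop("model '", model, "' requires at least one partner locus")
  if (startsWith(model, "pairwise") && length(partners) != 1L)
    stop("model '", model, "' takes exactly one partner locus")
  cl <- function(dosage, cyto = NA_character_)
    list(dosage = dosage, cytotype = cyto, w = w)
  clauses <- switch(model,
    pairwise_hom_hom = lapply(partners[1L], function(p)
      cl(stats::setNames(list(2L, 2L), c(focal, p)))),
    pairwise_one_way = lapply(partners[1L], function(p)
      cl(stats::setNames(list(2L, 1:2), c(focal, p)))),
    complex_conspecific = list(
      cl(stats::setNames(rep(list(2L), 1L + length(partners)),
                         c(focal, partners)))),
    independent_one_way = lapply(partners, function(p)
      cl(stats::setNames(list(2L, 1:2), c(focal, p)))),
    independent_two_way = c(
      lapply(partners, function(p)
        cl(stats::setNames(list(2L, 1:2), c(focal, p)))),
      lapply(partners, function(p)
        cl(stats::setNames(list(1L, 2L), c(focal, p))))),
    cytonuclear = list(
      cl(stats::setNames(list(2L), focal), cyto = "foreign")))
  new("FitnessScheme", model = model, clauses = clauses, episode = episode,
      loci = unique(c(focal, partners)))
}

#' Neutral fitness scheme
#'
#' The empty clause set: fitness 1 for every genotype.
#'
#' @param episode selection episode label.
#' @return a [FitnessScheme-class].
#' @export
neutralScheme <- function(episode = "nauplius_to_adult")
  new("FitnessScheme", model = "neutral", clauses = list(),
      episode = episode, loci = character())

## Vectorized fitness over a dosage matrix (rows = genotypes, named cols).
.fitnessVec <- function(scheme, dosage, cytotype) {
  w <- rep(1, nrow(dosage))
  for (cl in scheme@clauses) {
    if (!is.na(cl$cytotype) && !identical(cytotype, cl$cytotype)) next
    sat <- rep(TRUE, nrow(dosage))
    for (loc in names(cl$dosage)) {
      if (!loc %in% colnames(dosage))
        stop("scheme refers to unknown locus: ", loc)
      sat <- sat & dosage[, loc] %in% cl$dosage[[loc]]
    }
    w[sat] <- w[sat] * cl$w
  }
  w
}

#' Fitness of multi-locus genotypes under a scheme
#'
#' @param scheme a [FitnessScheme-class].
#' @param dosage named vector, or matrix with named columns, of
#'   derived-allele dosages in `{0, 1, 2}` per locus.
#' @param cytotype cytotype of the individuals, `"native"` or
#'   `"foreign"` (only consulted by cytonuclear clauses).
#' @return numeric fitness value(s) in \[0, 1\].
#' @export
fitnessOf <- function(scheme, dosage, cytotype = "native") {
  if (is.null(dim(dosage)))
    dosage <- matrix(dosage, 1L, dimnames = list(NULL, names(dosage)))
  .fitnessVec(scheme, dosage, cytotype)
}

## Class-index grid (3^L x L) and derived-dosage conversion.
.classGrid <- function(L) as.matrix(expand.grid(rep(list(1:3), L)))

.toDosage <- function(idx, loci) {
  d <- idx - 1L
  flip <- loci$derived_parent == "P1"
  d[, flip] <- 2L - d[, flip, drop = FALSE]
  colnames(d) <- loci$name
  d
}

#' Apply viability selection to a joint genotype table
#'
#' Reweights every genotype class by its scheme fitness and renormalizes,
#' returning the exact post-selection prediction with per-locus marginals
#' and Haldane relative viabilities (`v = 2 f(hom) / f(het)`).
#'
#' @param joint pre-selection joint frequency array from
#'   [f2Frequencies()] (or the `joint` of a previous prediction via
#'   [jointFreq()], to chain selection episodes).
#' @param scheme a [FitnessScheme-class].
#' @param cytotype cytotype of the cohort (a fixed, non-segregating
#'   factor set by the cross direction); must be given explicitly when
#'   the scheme has cytonuclear clauses.
#' @param loci locus table; defaults to the `"loci"` attribute of
#'   `joint`.
#' @return a [ModelPrediction-class].
#' @examples
#' loci <- lociTable(c("ME2", "GOT2"))
#' pred <- applySelection(f2Frequencies(loci),
#'                        makeScheme("pairwise_one_way", "ME2", "GOT2", 0))
#' viabilities(pred)  # ME2 derived homozygote: v = 0.25
#' @export
applySelection <- function(joint, scheme, cytotype = "native",
                           loci = attr(joint, "loci")) {
  if (is.null(loci)) stop("no locus table attached to 'joint'")
  hasCyto <- any(vapply(scheme@clauses,
                        function(cl) !is.na(cl$cytotype), logical(1)))
  if (hasCyto && !cytotype %in% c("native", "foreign"))
    stop("cytonuclear scheme needs cytotype 'native' or 'foreign'")
  L <- nrow(loci)
  idx <- .classGrid(L)
  w <- .fitnessVec(scheme, .toDosage(idx, loci), cytotype)
  post <- as.vector(joint) * w
  z <- sum(post)
  if (z == 0) stop("all genotype classes inviable under this scheme")
  post <- array(post / z, dim = rep(3L, L),
                dimnames = rep(list(.GENO_CODES), L))
  names(dimnames(post)) <- loci$name
  attr(post, "loci") <- loci
  marg <- t(vapply(seq_len(L), function(l) apply(post, l, sum),
                   numeric(3)))
  dimnames(marg) <- list(loci$name, .GENO_CODES)
  viab <- do.call(rbind, lapply(seq_len(L), function(l) {
    f <- marg[l, ]
    data.frame(locus = loci$name[l], class = c("P1_hom", "P2_hom"),
               v = 2 * c(f[["P1"]], f[["P2"]]) / f[["H"]],
               derived = c("P1", "P2") == loci$derived_parent[l],
               stringsAsFactors = FALSE)
  }))
  new("ModelPrediction", joint = post, loci = loci, marginals = marg,
      viability = viab, scheme = scheme)
}

#' Expected two-locus deviation pattern under a model
#'
#' Scales the post-selection joint frequencies of a locus pair to a
#' cohort of size `N` and runs the marginal-adjusted independence test on
#' the resulting (real-valued) grid, giving the signed per-cell deviation
#' pattern the model predicts.
#'
#' @param pred a [ModelPrediction-class].
#' @param locusA,locusB locus names (rows, columns).
#' @param N cohort size the pattern is stated at.
#' @return a [TwoLocusResult-class].
#' @export
predictPairDeviation <- function(pred, locusA, locusB, N = 100) {
  loci <- pred@loci$name
  ia <- match(locusA, loci); ib <- match(locusB, loci)
  if (is.na(ia) || is.na(ib)) stop("unknown locus in pair")
  if (ia == ib) stop("locusA and locusB must differ")
  grid <- apply(pred@joint, c(ia, ib), sum) * N
  independenceTest(twoLocusCounts(grid, c(locusA, locusB)))
}

#' Maximum-likelihood fitness of an incompatibility model
#'
#' Inverts the enumeration engine: finds the clause fitness `w` of a
#' single-parameter scheme family that maximizes the multinomial
#' likelihood of observed genotype-class counts, with a
#' profile-likelihood interval at the usual chi-square(1) cutoff of 1.92
#' log-likelihood units.
#'
#' @param counts a [GenotypeCounts-class] (classes at the focal locus) or
#'   [TwoLocusCounts-class] (grid whose `loci` name two of `loci`).
#' @param model scheme family name, as in [makeScheme()].
#' @param loci full locus table of the cross (partners included).
#' @param focal,partners locus roles passed to [makeScheme()].
#' @param focalLocus locus whose marginal the counts describe (defaults
#'   to `focal`; ignored for two-locus counts).
#' @param cytotype cohort cytotype.
#' @param episode selection episode label.
#' @return a one-row `data.frame` with `w_hat`, `lower`, `upper`,
#'   `logLik` and `identifiable`.
#' @export
estimateFitness <- function(counts, model, loci, focal, partners,
                            focalLocus = focal, cytotype = "native",
                            episode = "nauplius_to_adult") {
  pre <- f2Frequencies(loci)
  if (is(counts, "GenotypeCounts")) {
    o <- as.numeric(counts(counts))
    probFun <- function(pred)
      pred@marginals[focalLocus, ]
  } else if (is(counts, "TwoLocusCounts")) {
    o <- as.vector(counts(counts))
    pair <- counts@loci
    probFun <- function(pred) {
      ia <- match(pair[1L], loci$name); ib <- match(pair[2L], loci$name)
      as.vector(apply(pred@joint, c(ia, ib), sum))
    }
  } else stop("counts must be GenotypeCounts or TwoLocusCounts")
  if (sum(o) == 0) stop("counts total must be positive")
  ll <- function(w) {
    pred <- applySelection(pre, makeScheme(model, focal, partners, w,
                                           episode), cytotype)
    p <- probFun(pred)
    if (any(o > 0 & p <= 0)) return(-Inf)
    sum(o[o > 0] * log(p[o > 0]))
  }
  grid <- seq(0, 1, by = 0.05)
  llGrid <- vapply(grid, ll, numeric(1))
  identifiable <- diff(range(llGrid[is.finite(llGrid)])) > 1e-6
  if (!identifiable)
    return(data.frame(w_hat = NA_real_, lower = 0, upper = 1,
                      logLik = max(llGrid), identifiable = FALSE))
  opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, 0, 1)
  candLL <- c(opt$objective, llGrid[1L], llGrid[length(llGrid)])
  wHat <- cand[which.max(candLL)]
  llMax <- max(candLL)
  cut <- llMax - 1.92
  lower <- if (ll(0) >= cut) 0 else
    stats::uniroot(function(w) ll(w) - cut, c(0, wHat), tol = 1e-6)$root
  upper <- if (ll(1) >= cut) 1 else
    stats::uniroot(function(w) ll(w) - cut, c(wHat, 1), tol = 1e-6)$root
  data.frame(w_hat = wHat, lower = lower, upper = upper, logLik = llMax,
             identifiable = TRUE)
}

#' Read a model specification file
#'
#' YAML key-value specification of a cross and scheme: `loci` (list of
#' `name`, `derived_parent`, `linkage_group`,
#' `recomb_fraction_to_prev`), `model`, `focal`, `partners`, `w`,
#' `episode`.
#'
#' @param path path to the YAML file.
#' @return a list with elements `loci` (data frame) and `scheme`
#'   ([FitnessScheme-class]).
#' @export
readModelSpec <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(l, f, default = NA)
    if (is.null(l[[f]])) default else l[[f]]
  loci <- do.call(rbind, lapply(y$loci, function(l)
    data.frame(name = l$name,
               derived_parent = pick(l, "derived_parent", "P2"),
               linkage_group = as.character(pick(l, "linkage_group")),
               recomb_fraction_to_prev =
                 as.numeric(pick(l, "recomb_fraction_to_prev")),
               stringsAsFactors = FALSE)))
  scheme <- makeScheme(y$model, y$focal,
                       as.character(unlist(y$partners)),
                       w = pick(y, "w", 0),
                       episode = pick(y, "episode", "nauplius_to_adult"))
  list(loci = lociTable(loci$name, loci$derived_parent,
                        loci$linkage_group,
                        loci$recomb_fraction_to_prev),
       scheme = scheme)
}

#' Write a model prediction table
#'
#' Writes per-locus relative viabilities and, for each requested pair,
#' the expected signed per-cell contributions at cohort size `N`, as
#' tab-separated files.
#'
#' @param pred a [ModelPrediction-class].
#' @param path output path for the viability table.
#' @param pairs optional list of length-2 character vectors of locus
#'   names; contributions go to `<path>.contrib.tsv`.
#' @param N cohort size used to scale contribution patterns.
#' @return `path`, invisibly.
#' @export
writeModelPrediction <- function(pred, path, pairs = NULL, N = 100) {
  utils::write.table(viabilities(pred), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(pairs)) {
    rows <- do.call(rbind, lapply(pairs, function(pr) {
      res <- predictPairDeviation(pred, pr[1L], pr[2L], N)
      cc <- contributions(res)
      data.frame(pair = paste(pr, collapse = "/"),
                 classA = rep(.GENO_CODES, 3),
                 classB = rep(.GENO_CODES, each = 3),
                 contribution = as.vector(cc),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(rows, paste0(path, ".contrib.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

## ---- accessors & show ----------------------------------------------------

#' @rdname accessors
#' @export
setMethod("viabilities", "ModelPrediction", function(x) x@viability)

#' @rdname accessors
#' @export
setMethod("jointFreq", "ModelPrediction", function(x) x@joint)

#' @rdname accessors
#' @export
setMethod("marginalFreq", "ModelPrediction", function(x) x@marginals)

#' @rdname accessors
#' @export
setMethod("lociInfo", "ModelPrediction", function(x) x@loci)

setMethod("show", "FitnessScheme", function(object) {
  cat(sprintf("FitnessScheme '%s' (%s), %d clause(s)\n", object@model,
              object@episode, length(object@clauses)))
  for (cl in object@clauses) {
    cond <- paste(vapply(names(cl$dosage), function(l)
      sprintf("d[%s] in {%s}", l,
              paste(cl$dosage[[l]], collapse = ",")), character(1)),
      collapse = " & ")
    if (!is.na(cl$cytotype))
      cond <- paste0(cond, if (nzchar(cond)) " & " else "",
                     "cytotype = ", cl$cytotype)
    cat(sprintf("  %s -> w = %g\n", cond, cl$w))
  }
})

setMethod("show", "ModelPrediction", function(object) {
  cat(sprintf("ModelPrediction: %d loci, scheme '%s'\n",
              nrow(object@loci), object@scheme@model))
  cat("Relative viabilities (heterozygote = 1):\n")
  print(object@viability, row.names = FALSE)
})
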