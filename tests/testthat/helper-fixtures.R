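# Shared fixture builders: everything is generated in code at test time.

# A small hand-written genotype file (returns its path).
writeFixtureFile <- function(path = tempfile(fileext = ".tsv")) {
  lines <- c(
    "individual_id\tcross\tstage\tsex\tcytotype\tME1\tME2\tGOT2",
    "i1\tABf_x_SDm\tadult\tmale\tAB\tP1\tH\tP2",
    "i2\tABf_x_SDm\tadult\tfemale\tAB\tH\tH\tNA",
    "i3\tABf_x_SDm\tnauplius\tunknown\tAB\tP2\tP1\tH",
    "i4\tABf_x_SDm\tadult\tmale\tAB\tNA\tP2\tH")
  writeLines(lines, path)
  path
}

# Build an F2CrossTable directly from genotype vectors (one per locus).
makeTable <- function(..., stage = "adult", sex = NULL, cross = "c1",
                      cytotype = "native") {
  g <- cbind(...)
  n <- nrow(g)
  if (is.null(sex)) sex <- rep(c("male", "female"), length.out = n)
  ind <- data.frame(
    individual_id = sprintf("i%03d", seq_len(n)),
    cross = rep_len(cross, n), stage = rep_len(stage, n),
    sex = rep_len(sex, n), cytotype = rep_len(cytotype, n),
    stringsAsFactors = FALSE)
  f2CrossTable(g, ind)
}

# Random genotype table with missingness, for property tests.
randomTable <- function(n, nloci = 3, pNA = 0.1) {
  g <- matrix(sample(c("P1", "H", "P2"), n * nloci, replace = TRUE,
                     prob = c(0.25, 0.5, 0.25)),
              n, nloci, dimnames = list(NULL, paste0("L", seq_len(nloci))))
  g[runif(n * nloci) < pNA] <- NA
  ind <- data.frame(
    individual_id = sprintf("i%03d", seq_len(n)),
    cross = "c1",
    stage = sample(c("nauplius", "adult"), n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    cytotype = "native", stringsAsFactors = FALSE)
  f2CrossTable(g, ind)
}
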