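# Shared fixture builders. Everything is generated in code; no data files.

# small well-conditioned signature for fast deconvolution tests
tinySignature <- function(nGenes = 60, nCellTypes = 4, nTCellTypes = 2,
                          seed = 42) {
  makeSignature(nGenes = nGenes, nCellTypes = nCellTypes,
                nTCellTypes = nTCellTypes, seed = seed)
}

# named mixture vector from a signature and a fraction vector
mixFrom <- function(sig, f) {
  stats::setNames(as.vector(exprValues(sig) %*% f), geneIds(sig))
}

writeTempLines <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# NNLS oracle on the same globally standardized system the SVR stage uses,
# with a free intercept (+1/-1 columns) since global standardization does
# not zero the column means. Returns normalized non-negative fractions.
nnlsOracle <- function(mixture, sig) {
  S <- exprValues(sig)
  shared <- intersect(rownames(S), names(mixture))
  y <- as.numeric(mixture[shared])
  X <- S[shared, , drop = FALSE]
  ys <- (y - mean(y)) / stats::sd(y)
  Xs <- (X - mean(X)) / stats::sd(as.vector(X))
  A <- cbind(Xs, 1, -1)
  w <- pracma::lsqnonneg(A, ys)$x[seq_len(ncol(Xs))]
  w / sum(w)
}

# densities with cd8 <= cd3 guaranteed, iid continuous
randomDensities <- function(n, seed) {
  set.seed(seed)
  c3 <- runif(n)
  TCellDensities(sprintf("P%04d", seq_len(n)), cd3 = c3, cd8 = c3 * runif(n))
}

# whole-cohort mid-rank truth score used by threshold-recovery checks
truthScore <- function(dens) {
  pairPercentileScore(empiricalPercentile(cd3(dens), cd3(dens)),
                      empiricalPercentile(cd8(dens), cd8(dens)))
}

# independent mid-rank percentile oracle: naive counting loop
percentileOracle <- function(training, query) {
  vapply(query, function(q)
    100 * (sum(training < q) + 0.5 * sum(training == q)) / length(training),
    numeric(1))
}

# independent Youden oracle: scan every threshold interval (below the
# minimum, between every pair of consecutive distinct scores, above the
# maximum), smallest cut-off on ties
youdenOracle <- function(scores, labels) {
  ds <- sort(unique(scores))
  cands <- c(ds[1] - 1,
             if (length(ds) > 1) (ds[-1] + ds[-length(ds)]) / 2,
             ds[length(ds)] + 1)
  bestJ <- -Inf
  bestC <- NA_real_
  for (cc in cands) {
    tp <- sum(scores < cc & labels == 1)
    fn <- sum(scores >= cc & labels == 1)
    tn <- sum(scores >= cc & labels == 0)
    fp <- sum(scores < cc & labels == 0)
    J <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (J > bestJ + 1e-9) {
      bestJ <- J
      bestC <- cc
    }
  }
  list(cutoff = bestC, J = bestJ)
}

# independent Harrell C oracle: explicit double loop over ordered pairs
harrellCOracle <- function(time, event, score) {
  n <- length(time)
  num <- 0
  den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    comparable <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!comparable) next
    den <- den + 1
    if (score[j] > score[i]) num <- num + 1
    else if (score[j] == score[i]) num <- num + 0.5
  }
  num / den
}

# textbook two-group log-rank: sum(O - E) over event times, hypergeometric
# variance
logrankOracle <- function(time, event, group) {
  ts <- sort(unique(time[event == 1]))
  OmE <- 0
  V <- 0
  for (tt in ts) {
    atRisk <- time >= tt
    n1 <- sum(atRisk & group == 1)
    n0 <- sum(atRisk & group == 0)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == 1)
    n <- n1 + n0
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n0 / n) * (n - d) / (n - 1)
  }
  OmE^2 / V
}

# random censored survival instance for oracle comparisons
randomSurvivalInstance <- function(seed, nMax = 30) {
  set.seed(seed)
  n <- sample(3:nMax, 1)
  time <- sample(1:12, n, replace = TRUE)  # deliberate ties
  event <- rbinom(n, 1, 0.7)
  score <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
  list(time = time, event = event, score = score)
}
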