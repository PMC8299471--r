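# Small in-code fixtures shared across tests.

# genes x samples log-scale matrix with given values
logMatrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), ncol = length(samples),
         dimnames = list(genes, samples), byrow = TRUE)
}

# random valid program library for round-trip property tests
randomLibrary <- function(nPrograms, seed) {
  withr::with_seed(seed, {
    ProgramLibrary(lapply(seq_len(nPrograms), function(i) {
      nUp <- sample(1:6, 1)
      nDown <- sample(0:4, 1)
      genes <- sample(paste0("G", 1:50), nUp + nDown)
      GeneProgram(paste0("prog", i), up = genes[seq_len(nUp)],
                  down = if (nDown) genes[nUp + seq_len(nDown)] else
                    character(),
                  note = paste0("note", i))
    }), version = "test")
  })
}

# tiny deterministic cohort for integration-style unit tests
smallCohort <- function(seed = 42, nSamples = 120) {
  truth <- simulateTruth(nSamples = nSamples, seed = seed)
  expr <- simulateExpression(truth, nGenes = 300, seed = seed + 1)
  list(truth = truth, expr = expr, library = defaultPrograms())
}

# brute-force BH definition: q_i = min over p_j >= p_i of m * p_j / rank_j
bruteForceBH <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "min")
  vapply(seq_len(m), function(i) {
    min(1, min((m * p[p >= p[i]]) / r[p >= p[i]]))
  }, numeric(1))
}

# two-sided Fisher exact p by full hypergeometric enumeration over the
# support of table (a, b, c, d) with fixed margins
enumFisherP <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(k, m1)
  supp <- lo:hi
  pr <- dhyper(supp, m1, m2, k)
  pObs <- dhyper(a, m1, m2, k)
  sum(pr[pr <= pObs * (1 + 1e-7)])
}
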