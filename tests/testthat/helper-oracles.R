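# Independent oracles and fixture builders used across the test files.

# Literal, unoptimized NK fitness evaluator that walks the definition
# position by position: build locus i's sub-vector in neighbour-row order,
# read it as a binary number with the locus's own allele as the most
# significant bit, look up the contribution, and average.
naive_nk_fitness <- function(landscape, g) {
  n <- landscape$n
  k <- landscape$k
  total <- 0
  for (i in seq_len(n)) {
    sub <- g[landscape$neighbours[i, ]]
    state <- 0
    for (b in sub) state <- state * 2 + b
    total <- total + landscape$tables[i, state + 1]
  }
  total / n
}

# All 2^n genotypes as rows (n <= 20 or so).
enumerate_genotypes <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
}

# Hand-built landscape from explicit tables, bypassing generation.
manual_landscape <- function(neighbours, tables, seed = 0L) {
  structure(
    list(
      n = nrow(neighbours), k = ncol(neighbours) - 1L, seed = seed,
      neighbours = neighbours, tables = tables
    ),
    class = "nk_landscape"
  )
}

# K = 0 landscape whose optimum is a planted all-1 schema on `planted`
# loci (contribution 1 for allele 1, 0 for allele 0); all other loci are
# neutral at 0.5.
planted_landscape <- function(n, planted) {
  tables <- matrix(0.5, n, 2)
  tables[planted, ] <- rep(c(0, 1), each = length(planted))
  manual_landscape(matrix(seq_len(n), ncol = 1), tables)
}

# N-locus ring landscape (K = 1, neighbour = next locus) with two global
# peaks at all-0 and all-1: agreeing adjacent alleles score 1, disagreeing
# ones 0.2.
two_peak_landscape <- function(n) {
  neighbours <- cbind(seq_len(n), c(2:n, 1))
  tables <- matrix(rep(c(1, 0.2, 0.2, 1), each = n), nrow = n)
  manual_landscape(neighbours, tables)
}
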