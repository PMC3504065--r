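# NK landscape generation and the trait-weighted, threshold-modified
# fitness used throughout the package.
#
# An NK landscape assigns each of N binary loci a fitness contribution
# f_i read from a random lookup table indexed by the locus's own allele
# and the alleles of K epistatic partner loci; total fitness F is the
# mean contribution. The modified objective weights r "trait" loci:
# F_r is the mean contribution of the trait loci alone, and the trait
# fitness F' = F_r * F, set to 0 whenever F falls below a viability
# threshold f_th.

#' Generate an NK fitness landscape
#'
#' Builds the two tables that define an NK model: an epistasis map giving,
#' for each locus `i`, the `k` partner loci whose alleles co-determine its
#' contribution (locus `i` itself is always the first entry of its row),
#' and a fitness table of `2^(k+1)` contributions per locus drawn uniformly
#' on `[0, 1]`. Partner loci are sampled uniformly without replacement from
#' the remaining loci. Generation is fully determined by `(n, k, seed)`:
#' the master seed is split into independent child seeds for the epistasis
#' map and the fitness table, so either can be regenerated separately.
#'
#' @param n Number of loci (genome length), `n >= 1`.
#' @param k Epistasis order: each locus's contribution depends on its own
#'   allele plus `k` others; `0 <= k <= n - 1`. Larger `k` gives a more
#'   rugged landscape.
#' @param seed Integer master seed.
#' @return An object of class `nk_landscape`: a list with elements `n`, `k`,
#'   `seed`, `neighbours` (an `n` x `(k+1)` integer matrix of 1-based locus
#'   indices, row `i` starting with `i`) and `tables` (an `n` x `2^(k+1)`
#'   matrix of contributions in `[0, 1]`).
#' @examples
#' land <- generate_landscape(n = 10, k = 2, seed = 1)
#' nk_fitness(land, rep(1, 10))
#' @seealso [nk_fitness()], [trait_fitness()], [modified_fitness()]
#' @export
generate_landscape <- function(n, k, seed) {
  if (length(n) != 1 || is.na(n) || n < 1 || n != round(n)) {
    .stop_invalid("invalid parameter: n must be a positive integer")
  }
  if (length(k) != 1 || is.na(k) || k < 0 || k > n - 1 || k != round(k)) {
    .stop_invalid("invalid parameter: k must satisfy 0 <= k <= n - 1")
  }
  n <- as.integer(n)
  k <- as.integer(k)
  neighbours <- with_seed(derive_seed(seed, "epistasis"), {
    rows <- vapply(
      seq_len(n),
      function(i) {
        others <- if (k > 0) sample(seq_len(n)[-i], k) else integer(0)
        c(i, others)
      },
      integer(k + 1)
    )
    t(matrix(rows, nrow = k + 1)) # vapply drops to a vector when k = 0
  })
  tables <- with_seed(derive_seed(seed, "fitness_table"), {
    matrix(stats::runif(n * 2^(k + 1)), nrow = n, ncol = 2^(k + 1))
  })
  structure(
    list(n = n, k = k, seed = seed, neighbours = neighbours, tables = tables),
    class = "nk_landscape"
  )
}

#' @export
print.nk_landscape <- function(x, ...) {
  cat(
    "NK landscape: N =", x$n, ", K =", x$k, ", seed =", x$seed, "\n",
    "  lookup table:", x$n, "loci x", 2^(x$k + 1), "states\n"
  )
  invisible(x)
}

#' Trait configuration for the modified landscape
#'
#' Describes which loci carry the breeder's trait and the viability
#' threshold below which trait fitness collapses to zero. By default the
#' trait occupies the first `r` loci of the genome and the threshold is
#' 0.55, chosen so that only a modest fraction of a random starting
#' population is viable under the modified objective.
#'
#' @param r Number of trait loci, `1 <= r <= n`.
#' @param n Genome length (for validation); optional if `trait_loci` given.
#' @param trait_loci Integer vector of distinct 1-based trait locus indices;
#'   defaults to `1:r`.
#' @param f_th Viability threshold on the base fitness `F`, in `[0, 1]`.
#' @return An object of class `trait_config` with elements `trait_loci` and
#'   `f_th`.
#' @examples
#' trait_config(r = 10, n = 100)
#' @export
trait_config <- function(r = length(trait_loci), n = NULL,
                         trait_loci = seq_len(r), f_th = 0.55) {
  if (length(r) != 1 || is.na(r) || r < 1 || r != round(r)) {
    .stop_invalid("invalid parameter: r must be a positive integer")
  }
  trait_loci <- as.integer(trait_loci)
  if (anyDuplicated(trait_loci) || any(trait_loci < 1)) {
    .stop_invalid("invalid parameter: trait_loci must be distinct positive indices")
  }
  if (!is.null(n) && (r > n || any(trait_loci > n))) {
    .stop_invalid("invalid parameter: trait loci out of range for N = ", n)
  }
  if (length(f_th) != 1 || is.na(f_th) || f_th < 0 || f_th > 1) {
    .stop_invalid("invalid parameter: f_th must lie in [0, 1]")
  }
  structure(list(trait_loci = trait_loci, f_th = f_th), class = "trait_config")
}

#' @export
print.trait_config <- function(x, ...) {
  cat(
    "Trait config: r =", length(x$trait_loci), "loci (",
    paste(utils::head(x$trait_loci, 6), collapse = ", "),
    if (length(x$trait_loci) > 6) "..." else "", "), f_th =", x$f_th, "\n"
  )
  invisible(x)
}

# Per-locus realized contributions for one genotype or a population matrix
# (rows = individuals). Returns a matrix (individuals x loci).
#
# State indexing convention (frozen for reproducibility): the (K+1)-bit
# sub-vector is read in neighbour-row order with the locus's own allele
# (first entry) as the MOST significant bit; the resulting integer in
# [0, 2^(K+1) - 1] indexes the locus's table row (1-based offset of +1).
.contributions <- function(landscape, pop) {
  if (!is.matrix(pop)) pop <- matrix(pop, nrow = 1)
  .check_binary(pop, n = landscape$n)
  n <- landscape$n
  k <- landscape$k
  pow <- 2^(k:0)
  nb <- landscape$neighbours
  tab <- landscape$tables
  out <- matrix(0, nrow = nrow(pop), ncol = n)
  for (i in seq_len(n)) {
    state <- pop[, nb[i, ], drop = FALSE] %*% pow
    out[, i] <- tab[i, state + 1]
  }
  out
}

#' Base NK fitness F
#'
#' The mean of the per-locus realized fitness contributions: for genotype
#' `g`, `F = (1/N) * sum_i f_i(g restricted to locus i's epistatic
#' neighbourhood)`. Always lies in `[0, 1]`.
#'
#' @param landscape An [generate_landscape()] object.
#' @param g A binary vector of length `N`, or a matrix with one genotype
#'   per row.
#' @return A numeric fitness per genotype (scalar for a vector input).
#' @examples
#' land <- generate_landscape(8, 1, seed = 7)
#' nk_fitness(land, sample(0:1, 8, replace = TRUE))
#' @export
nk_fitness <- function(landscape, g) {
  rowMeans(.contributions(landscape, g))
}

#' Trait fitness F_r
#'
#' The mean realized contribution over the `r` trait loci only, i.e. the
#' trait loci's share of the overall fitness of the string. When the trait
#' covers the whole genome (`r = N`), `F_r` equals the base fitness `F`.
#'
#' @inheritParams nk_fitness
#' @param tc A [trait_config()].
#' @return Numeric trait fitness per genotype, in `[0, 1]`.
#' @export
trait_fitness <- function(landscape, tc, g) {
  if (any(tc$trait_loci > landscape$n)) {
    .stop_invalid("invalid parameter: trait locus out of range for N = ", landscape$n)
  }
  contrib <- .contributions(landscape, g)
  rowMeans(contrib[, tc$trait_loci, drop = FALSE])
}

#' Modified (thresholded) trait fitness F'
#'
#' The breeding objective: `F' = F_r * F` when the base fitness `F` clears
#' the viability threshold `f_th`, and `F' = 0` otherwise. The threshold
#' models the catastrophic loss of viability that can accompany optimising
#' a single trait at the expense of the whole organism.
#'
#' @inheritParams trait_fitness
#' @return Numeric modified fitness per genotype, in `[0, 1]`.
#' @examples
#' land <- generate_landscape(10, 1, seed = 3)
#' tc <- trait_config(r = 2, n = 10)
#' modified_fitness(land, tc, rep(1, 10))
#' @export
modified_fitness <- function(landscape, tc, g) {
  if (any(tc$trait_loci > landscape$n)) {
    .stop_invalid("invalid parameter: trait locus out of range for N = ", landscape$n)
  }
  contrib <- .contributions(landscape, g)
  f <- rowMeans(contrib)
  fr <- rowMeans(contrib[, tc$trait_loci, drop = FALSE])
  ifelse(f >= tc$f_th, fr * f, 0)
}

# Evaluate the active fitness mode for a population matrix.
.eval_fitness <- function(landscape, tc, pop, mode = c("global_F", "trait_F_prime")) {
  mode <- match.arg(mode)
  if (mode == "global_F") nk_fitness(landscape, pop) else modified_fitness(landscape, tc, pop)
}

#' Calibrate the viability threshold against a reference population
#'
#' Scans a grid `{0, grid_step, 2*grid_step, ...} <= 1` and returns the
#' largest threshold `t` for which at least `survivor_fraction` of the
#' population satisfies `F >= t` (i.e. would keep a non-zero modified
#' fitness). Grid values are rounded to 10 decimal places so that e.g.
#' `12 * 0.05` compares as exactly `0.6`. This is optional tooling; routine
#' runs use the fixed default threshold of 0.55.
#'
#' @param landscape An [generate_landscape()] object.
#' @param tc A [trait_config()] (carried for interface symmetry; the
#'   calibration depends only on base fitness).
#' @param pop Population matrix (rows = genotypes).
#' @param survivor_fraction Minimum fraction of the population that must
#'   remain viable, in `(0, 1]`. Default 0.01.
#' @param grid_step Threshold grid spacing in `(0, 1)`. Default 0.05.
#' @return The selected threshold; 0 (with a warning) if even a zero
#'   threshold leaves fewer survivors than requested (impossible for
#'   `survivor_fraction <= 1`, but kept as a guard for empty edge cases).
#' @export
calibrate_threshold <- function(landscape, tc, pop,
                                survivor_fraction = 0.01, grid_step = 0.05) {
  if (!is.matrix(pop) || nrow(pop) < 1) {
    .stop_invalid("invalid parameter: pop must be a non-empty genotype matrix")
  }
  if (survivor_fraction <= 0 || survivor_fraction > 1) {
    .stop_invalid("invalid parameter: survivor_fraction must be in (0, 1]")
  }
  if (grid_step <= 0 || grid_step >= 1) {
    .stop_invalid("invalid parameter: grid_step must be in (0, 1)")
  }
  f <- nk_fitness(landscape, pop)
  grid <- round(seq(0, 1, by = grid_step), 10)
  ok <- vapply(grid, function(t) mean(f >= t) >= survivor_fraction, logical(1))
  if (!any(ok)) {
    warning("no grid threshold leaves the requested survivor fraction; returning 0")
    return(0)
  }
  grid[max(which(ok))]
}
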