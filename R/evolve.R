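# Variation and selection operators, run-state plumbing, and the four
# non-rule-based algorithm steppers: Breeder (1+lambda), standard
# generational GA, local mating on a toroidal grid, and the niching GA
# with dynamic-radius genotypic fitness sharing.

#' Evolution parameters
#'
#' Collects the tunable parameters shared by all six algorithms. Defaults
#' are the settings used throughout the package's experiments:
#' `lam = 1000`, `p_m = 1/N` (resolved when the genome length is known),
#' `p_c = 0.7`, `t_size = 10`, and a target niche count `t_q = 5` for the
#' niching GA's dynamic radius.
#'
#' @param lam Population size (lambda), `>= 1`.
#' @param p_m Per-bit mutation rate in `[0, 1]`; `NULL` means `1/N`,
#'   resolved against the landscape at run time.
#' @param p_c Crossover (recombination) probability in `[0, 1]`.
#' @param t_size Tournament size, `>= 1`.
#' @param t_q Target number of niches for the niching GA.
#' @param grid_rows,grid_cols Local-mating grid dimensions; `NULL` selects
#'   the most-square factorisation of `lam` (e.g. 1000 -> 25 x 40).
#' @param niche_sample_size Individuals sampled when estimating the niche
#'   count `q` (the full population is never scanned for `q`).
#' @param beam_width,max_conditions,max_rules,l_tolerance Rule-induction
#'   controls for the EARL algorithms; see [induce_rules()].
#' @param top_fraction,bottom_fraction Fitness strata sizes used to train
#'   rules; see [extract_training_sets()].
#' @return An object of class `evolution_params`.
#' @examples
#' evolution_params(lam = 200)
#' @export
evolution_params <- function(lam = 1000, p_m = NULL, p_c = 0.7, t_size = 10,
                             t_q = 5, grid_rows = NULL, grid_cols = NULL,
                             niche_sample_size = 50, beam_width = 5,
                             max_conditions = 5, max_rules = 20,
                             l_tolerance = 0, top_fraction = 0.2,
                             bottom_fraction = 0.2) {
  if (lam < 1 || lam != round(lam)) {
    .stop_invalid("invalid parameter: lam must be a positive integer")
  }
  if (!is.null(p_m) && (p_m < 0 || p_m > 1)) {
    .stop_invalid("invalid parameter: p_m must lie in [0, 1]")
  }
  if (p_c < 0 || p_c > 1) {
    .stop_invalid("invalid parameter: p_c must lie in [0, 1]")
  }
  if (t_size < 1 || t_size != round(t_size)) {
    .stop_invalid("invalid parameter: t_size must be a positive integer")
  }
  if (!is.null(grid_rows) != !is.null(grid_cols)) {
    .stop_invalid("invalid parameter: give both grid_rows and grid_cols or neither")
  }
  if (!is.null(grid_rows) && grid_rows * grid_cols != lam) {
    .stop_invalid("invalid parameter: grid_rows * grid_cols must equal lam")
  }
  structure(
    list(
      lam = as.integer(lam), p_m = p_m, p_c = p_c, t_size = as.integer(t_size),
      t_q = t_q, grid_rows = grid_rows, grid_cols = grid_cols,
      niche_sample_size = niche_sample_size, beam_width = beam_width,
      max_conditions = max_conditions, max_rules = max_rules,
      l_tolerance = l_tolerance, top_fraction = top_fraction,
      bottom_fraction = bottom_fraction
    ),
    class = "evolution_params"
  )
}

# Most-square factorisation of lam: largest divisor <= sqrt(lam) as rows.
.grid_dims <- function(lam) {
  divs <- which(lam %% seq_len(floor(sqrt(lam))) == 0)
  r <- max(divs)
  c(r, lam %/% r)
}

#' Initialize a uniform random population
#'
#' @param n Genome length.
#' @param lam Population size.
#' @param seed Integer seed; the same seed always yields the same
#'   population.
#' @return An integer matrix with `lam` rows (individuals) and `n` columns
#'   (loci), entries drawn independently and uniformly from \{0, 1\}.
#' @examples
#' pop <- init_population(20, 50, seed = 1)
#' @export
init_population <- function(n, lam, seed) {
  if (n < 1 || lam < 1) {
    .stop_invalid("invalid parameter: n and lam must be positive")
  }
  with_seed(derive_seed(seed, "init_population"), {
    matrix(sample(c(0L, 1L), n * lam, replace = TRUE), nrow = lam, ncol = n)
  })
}

#' Per-bit mutation
#'
#' Flips each bit independently with probability `p_m`; the input is not
#' modified. Accepts a single genotype or a population matrix (one genotype
#' per row).
#'
#' @param g Binary vector or matrix.
#' @param p_m Per-bit mutation rate in `[0, 1]`.
#' @return Mutated copy of `g`, same shape.
#' @export
mutate_genotype <- function(g, p_m) {
  if (length(p_m) != 1 || is.na(p_m) || p_m < 0 || p_m > 1) {
    .stop_invalid("invalid parameter: p_m must lie in [0, 1]")
  }
  .check_binary(g)
  flip <- stats::runif(length(g)) < p_m
  out <- g
  out[flip] <- 1L - out[flip]
  out
}

#' Uniform crossover
#'
#' Each offspring locus is copied from the first or second parent with
#' probability 0.5, independently per locus.
#'
#' @param p1,p2 Parent genotypes (equal-length binary vectors).
#' @return One offspring genotype.
#' @export
uniform_crossover <- function(p1, p2) {
  if (length(p1) != length(p2)) {
    .stop_invalid("invalid parameter: parent genotypes must have equal length")
  }
  from1 <- stats::runif(length(p1)) < 0.5
  ifelse(from1, p1, p2)
}

# Row-wise uniform crossover for parent matrices of equal shape.
.crossover_rows <- function(P1, P2) {
  mask <- matrix(stats::runif(length(P1)) < 0.5, nrow = nrow(P1))
  out <- P2
  out[mask] <- P1[mask]
  out
}

#' Tournament selection
#'
#' Samples `t_size` indices with replacement from `pool` (all indices by
#' default) and returns the one with the highest fitness. Ties are broken
#' by the lowest index among the tied samples, so replays are
#' deterministic given the RNG state.
#'
#' @param fitnesses Numeric fitness vector for the whole population.
#' @param t_size Tournament size.
#' @param pool Optional integer vector of candidate indices.
#' @return The selected index (into `fitnesses`).
#' @export
tournament_select <- function(fitnesses, t_size, pool = seq_along(fitnesses)) {
  if (length(pool) == 0) {
    .stop_invalid("empty pool: tournament selection needs at least one candidate")
  }
  if (t_size < 1) {
    .stop_invalid("invalid parameter: t_size must be >= 1")
  }
  cand <- pool[sample.int(length(pool), t_size, replace = TRUE)]
  best <- cand[fitnesses[cand] == max(fitnesses[cand])]
  min(best)
}

# Vectorised tournaments: m independent tournaments over 1..n (or a pool),
# ties broken by lowest index. Returns integer vector of length m.
.tournament_many <- function(fitnesses, m, t_size, pool = NULL) {
  if (m == 0) return(integer(0))
  n <- if (is.null(pool)) length(fitnesses) else length(pool)
  idx <- matrix(sample.int(n, m * t_size, replace = TRUE), nrow = m)
  if (!is.null(pool)) idx <- matrix(pool[idx], nrow = m)
  fmat <- matrix(fitnesses[idx], nrow = m)
  .rowwise_argbest(fmat, idx)
}

# For each row, the entry of `idx` whose `fmat` value is maximal, ties
# resolved to the smallest index. Column-wise pmax/pmin keeps this O(m*t)
# without per-row apply.
.rowwise_argbest <- function(fmat, idx) {
  t_size <- ncol(fmat)
  rowmax <- fmat[, 1]
  if (t_size > 1) {
    for (j in 2:t_size) rowmax <- pmax(rowmax, fmat[, j])
  }
  winner <- ifelse(fmat[, 1] < rowmax, NA_integer_, idx[, 1])
  if (t_size > 1) {
    for (j in 2:t_size) {
      wj <- ifelse(fmat[, j] < rowmax, NA_integer_, idx[, j])
      winner <- pmin(winner, wj, na.rm = TRUE)
    }
  }
  as.integer(winner)
}

#' Construct a run state
#'
#' A run state bundles everything a stepper needs: the current population
#' and its cached fitness, the landscape and trait configuration, the
#' active fitness mode (`"global_F"` for burn-in on the unmodified
#' landscape, `"trait_F_prime"` for the breeding phase), the evolution
#' parameters, and per-algorithm bookkeeping (niche radius state, breeder
#' champion, local-mating grid).
#'
#' @param landscape An [generate_landscape()] object.
#' @param tc A [trait_config()].
#' @param pop Population matrix (`lam` rows).
#' @param params An [evolution_params()]; `lam` must match `nrow(pop)` and
#'   a `NULL` `p_m` resolves to `1/N`.
#' @param fitness_mode `"global_F"` or `"trait_F_prime"`.
#' @return An object of class `run_state`.
#' @export
run_state <- function(landscape, tc, pop, params,
                      fitness_mode = c("trait_F_prime", "global_F")) {
  fitness_mode <- match.arg(fitness_mode)
  if (nrow(pop) != params$lam) {
    .stop_invalid("invalid parameter: nrow(pop) must equal params$lam")
  }
  if (is.null(params$p_m)) params$p_m <- 1 / landscape$n
  structure(
    list(
      generation = 0L,
      pop = pop,
      fit = .eval_fitness(landscape, tc, pop, fitness_mode),
      landscape = landscape,
      tc = tc,
      params = params,
      fitness_mode = fitness_mode,
      niche_state = NULL,
      champion = NULL,
      grid_nb = NULL,
      ruleset = NULL
    ),
    class = "run_state"
  )
}

# Mutation applied to an offspring matrix, preserving integer storage.
.mutate_rows <- function(off, p_m) {
  flip <- matrix(stats::runif(length(off)) < p_m, nrow = nrow(off))
  off[flip] <- 1L - off[flip]
  off
}

# Shared generational-GA offspring production: tournament parents on
# `selfit` (which may be raw or shared fitness), uniform crossover with
# probability p_c, then mutation. Returns the offspring matrix.
.ga_offspring <- function(pop, selfit, params) {
  lam <- nrow(pop)
  recomb <- stats::runif(lam) < params$p_c
  par1 <- .tournament_many(selfit, lam, params$t_size)
  par2 <- .tournament_many(selfit, lam, params$t_size)
  off <- pop[par1, , drop = FALSE]
  if (any(recomb)) {
    off[recomb, ] <- .crossover_rows(
      pop[par1[recomb], , drop = FALSE],
      pop[par2[recomb], , drop = FALSE]
    )
  }
  .mutate_rows(off, params$p_m)
}

#' One generation of the Breeder (1+lambda) algorithm
#'
#' Strong truncation selection down to a single parent: the champion (the
#' fittest individual seen so far under the active fitness) is cloned
#' `lambda` times, each clone is mutated, and the champion is replaced
#' only if some offspring strictly beats it. The reported population is
#' the offspring (so diversity statistics reflect what a breeder would
#' measure on the new generation); the champion itself is retained
#' elitistically, so best-so-far fitness never decreases.
#'
#' @param state A [run_state()].
#' @return The updated state, `generation` incremented by 1.
#' @export
step_breeder <- function(state) {
  p <- state$params
  if (is.null(state$champion)) {
    b <- which.max(state$fit)
    state$champion <- list(geno = state$pop[b, ], fit = state$fit[b])
  }
  off <- matrix(
    rep(as.integer(state$champion$geno), each = p$lam),
    nrow = p$lam
  )
  off <- .mutate_rows(off, p$p_m)
  offfit <- .eval_fitness(state$landscape, state$tc, off, state$fitness_mode)
  b <- which.max(offfit)
  if (offfit[b] > state$champion$fit) {
    state$champion <- list(geno = off[b, ], fit = offfit[b])
  }
  state$pop <- off
  state$fit <- offfit
  state$generation <- state$generation + 1L
  state
}

#' One generation of the standard (generational, non-elitist) GA
#'
#' Each of the `lambda` offspring is produced independently: with
#' probability `p_c` by uniform crossover of two tournament-selected
#' parents, otherwise by cloning one tournament-selected parent; all
#' offspring are then mutated and entirely replace the parent generation,
#' even if less fit.
#'
#' @inheritParams step_breeder
#' @return The updated state.
#' @export
step_standard_ga <- function(state) {
  off <- .ga_offspring(state$pop, state$fit, state$params)
  state$pop <- off
  state$fit <- .eval_fitness(state$landscape, state$tc, off, state$fitness_mode)
  state$generation <- state$generation + 1L
  state
}

# Toroidal 24-cell (5x5 minus centre) neighbourhood index matrix for an
# r x c grid whose cells are numbered column-major 1..lam (R matrix order:
# cell (i, j) -> i + (j-1)*r).
.local_neighbourhood <- function(r, c) {
  offs <- expand.grid(dr = -2:2, dc = -2:2)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  lam <- r * c
  cell_row <- ((seq_len(lam) - 1) %% r)
  cell_col <- ((seq_len(lam) - 1) %/% r)
  nb <- matrix(0L, nrow = lam, ncol = 24)
  for (j in seq_len(24)) {
    rr <- (cell_row + offs$dr[j]) %% r
    cc <- (cell_col + offs$dc[j]) %% c
    nb[, j] <- as.integer(rr + cc * r + 1)
  }
  nb
}

#' One generation of the local-mating (spatially structured) GA
#'
#' Individuals occupy fixed cells on a toroidal two-dimensional grid and
#' mate only within their neighbourhood: for each cell, a tournament of
#' `t_size` samples drawn with replacement from the 24 cells of the 5x5
#' square around it picks a neighbour; with probability `p_c` the cell's
#' resident is recombined with that neighbour, otherwise the neighbour is
#' cloned. The (mutated) offspring replaces the resident in the next
#' generation, synchronously across the grid, so grid coordinates never
#' change. Restricting gene flow this way slows take-over by fit lineages
#' and preserves diversity.
#'
#' @inheritParams step_breeder
#' @return The updated state.
#' @export
step_local_mating <- function(state) {
  p <- state$params
  if (is.null(state$grid_nb)) {
    dims <- if (is.null(p$grid_rows)) .grid_dims(p$lam) else c(p$grid_rows, p$grid_cols)
    if (dims[1] * dims[2] != p$lam) {
      .stop_invalid("invalid parameter: grid dimensions must factor lam")
    }
    state$grid_nb <- .local_neighbourhood(dims[1], dims[2])
  }
  lam <- p$lam
  recomb <- stats::runif(lam) < p$p_c
  # Neighbourhood tournaments, one per cell, vectorised: sample positions
  # within each cell's 24-neighbour list, then rank by fitness with
  # lowest-global-index tie-breaks.
  pos <- matrix(sample.int(24, lam * p$t_size, replace = TRUE), nrow = lam)
  cand <- matrix(state$grid_nb[cbind(rep(seq_len(lam), p$t_size), as.vector(pos))],
    nrow = lam
  )
  fmat <- matrix(state$fit[cand], nrow = lam)
  winner <- .rowwise_argbest(fmat, cand)
  off <- state$pop[winner, , drop = FALSE] # clone path default
  if (any(recomb)) {
    off[recomb, ] <- .crossover_rows(
      state$pop[recomb, , drop = FALSE],
      state$pop[winner[recomb], , drop = FALSE]
    )
  }
  off <- .mutate_rows(off, p$p_m)
  state$pop <- off
  state$fit <- .eval_fitness(state$landscape, state$tc, off, state$fitness_mode)
  state$generation <- state$generation + 1L
  state
}

#' Genotypic fitness sharing
#'
#' `f_share = 10 f / (9 + n_c)` where `n_c` is the niche count: the number
#' of individuals (including the individual itself) within Hamming
#' distance `n_r`. The scaling makes an isolated individual keep its raw
#' fitness (`n_c = 1` gives `f_share = f`), while crowded genotypes are
#' penalised, preserving diversity.
#'
#' @param f Raw fitness (scalar or vector), `>= 0`.
#' @param n_c Niche count(s), `>= 1`.
#' @return Shared fitness values.
#' @export
shared_fitness <- function(f, n_c) {
  if (any(n_c < 1)) {
    .stop_invalid("invalid parameter: niche count must be >= 1 (self counts)")
  }
  10 * f / (9 + n_c)
}

# Pairwise Hamming distances between rows of two 0/1 matrices (or within
# one). Uses the inner-product identity d = |a| + |b| - 2 a.b.
.hamming_matrix <- function(A, B = A) {
  storage.mode(A) <- "double"
  storage.mode(B) <- "double"
  oa <- rowSums(A)
  ob <- rowSums(B)
  round(outer(oa, ob, "+") - 2 * tcrossprod(A, B))
}

#' Estimate the number of niches by sampled leader clustering
#'
#' Draws a random sample of individuals (without replacement) and runs
#' greedy leader clustering: each sampled genotype joins the first
#' existing leader within Hamming distance `n_r`, otherwise it founds a
#' new leader. The number of leaders estimates the niche count `q`
#' without an O(lambda^2) scan of the whole population.
#'
#' @param pop Population matrix.
#' @param n_r Niche radius (Hamming distance).
#' @param sample_size Number of individuals to sample (capped at the
#'   population size).
#' @return Integer estimate `q >= 1`.
#' @export
estimate_niche_count <- function(pop, n_r, sample_size = 50) {
  if (sample_size < 1) {
    .stop_invalid("invalid parameter: sample_size must be >= 1")
  }
  lam <- nrow(pop)
  take <- sample.int(lam, min(sample_size, lam))
  sampled <- pop[take, , drop = FALSE]
  leaders <- matrix(sampled[1, ], nrow = 1)
  for (i in seq_len(nrow(sampled))[-1]) {
    d <- .hamming_matrix(matrix(sampled[i, ], nrow = 1), leaders)
    if (all(d > n_r)) leaders <- rbind(leaders, sampled[i, ])
  }
  nrow(leaders)
}

#' Niche-radius state
#'
#' @param n_r Current niche radius (Hamming distance, loci).
#' @param n_max Maximum radius (genome length N).
#' @param q_estimate Last niche-count estimate.
#' @param sample_size Sample size used for estimation.
#' @return An object of class `niche_state`.
#' @export
niche_state <- function(n_r, n_max, q_estimate = NA_integer_, sample_size = 50) {
  n_r <- max(1L, min(as.integer(n_r), as.integer(n_max)))
  structure(
    list(
      n_r = n_r, n_max = as.integer(n_max),
      q_estimate = q_estimate, sample_size = sample_size
    ),
    class = "niche_state"
  )
}

#' Adjust the niche radius towards a target niche count
#'
#' Too many estimated niches means the radius is too small to merge
#' similar genotypes, so it grows by one locus; too few means it is too
#' coarse, so it shrinks by one. The radius is clamped to `[1, N]`.
#'
#' @param ns A [niche_state()] with a current `q_estimate`.
#' @param t_q Target number of niches.
#' @return The updated `niche_state`.
#' @export
update_niche_radius <- function(ns, t_q) {
  q <- ns$q_estimate
  if (!is.na(q)) {
    if (q > t_q) ns$n_r <- ns$n_r + 1L
    if (q < t_q) ns$n_r <- ns$n_r - 1L
    ns$n_r <- max(1L, min(ns$n_r, ns$n_max))
  }
  ns
}

#' One generation of the niching GA (genotypic fitness sharing)
#'
#' Follows the standard generational GA except that tournament selection
#' acts on shared fitness: each member's niche count `n_c` (itself plus
#' all others within Hamming distance `n_r`) is computed exactly over the
#' population, raw fitness is rescaled by [shared_fitness()], and
#' offspring are produced as in [step_standard_ga()]. After replacement,
#' the niche count `q` is re-estimated by [estimate_niche_count()] and the
#' radius nudged towards the target `t_q` by [update_niche_radius()].
#'
#' @inheritParams step_breeder
#' @return The updated state.
#' @export
step_niching <- function(state) {
  p <- state$params
  if (is.null(state$niche_state)) {
    state$niche_state <- niche_state(
      n_r = max(1L, floor(state$landscape$n / 10)),
      n_max = state$landscape$n,
      sample_size = p$niche_sample_size
    )
  }
  ns <- state$niche_state
  D <- .hamming_matrix(state$pop)
  n_c <- rowSums(D <= ns$n_r)
  fshare <- shared_fitness(state$fit, n_c)
  off <- .ga_offspring(state$pop, fshare, p)
  state$pop <- off
  state$fit <- .eval_fitness(state$landscape, state$tc, off, state$fitness_mode)
  ns$q_estimate <- estimate_niche_count(off, ns$n_r, ns$sample_size)
  state$niche_state <- update_niche_radius(ns, p$t_q)
  state$generation <- state$generation + 1L
  state
}
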