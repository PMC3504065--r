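# The comparison harness: diversity-preserving burn-in, matched replicate
# runs of the six algorithms, and the evaluation statistics (mean fitness,
# tie-adjusted mean ranks with standard errors, per-locus Shannon entropy).

#' Algorithm identifiers understood by the harness
#' @return Character vector of the six algorithm ids.
#' @export
algorithm_ids <- function() {
  c("breeder", "standard_ga", "local_mating", "niching", "earl1", "earl2")
}

.stepper_for <- function(algorithm) {
  switch(algorithm,
    breeder = step_breeder,
    standard_ga = step_standard_ga,
    local_mating = step_local_mating,
    niching = step_niching,
    earl1 = function(s) step_earl(s, variant = 1),
    earl2 = function(s) step_earl(s, variant = 2),
    .stop_invalid("invalid parameter: unknown algorithm id '", algorithm, "'")
  )
}

#' Per-locus Shannon entropy of a population
#'
#' For each locus, `H = -p0 log2 p0 - p1 log2 p1` with `p0`, `p1` the
#' allele frequencies (`0 log 0` taken as 0). For binary loci the entropy
#' is 0 bits when monomorphic and 1 bit at 50/50; its average over loci is
#' the package's population-diversity measure.
#'
#' @param pop Population matrix (rows = individuals).
#' @return Numeric vector of per-locus entropies in bits.
#' @examples
#' locus_entropy(init_population(10, 100, seed = 1))
#' @export
locus_entropy <- function(pop) {
  if (!is.matrix(pop) || nrow(pop) < 1) {
    .stop_invalid("invalid parameter: pop must be a non-empty genotype matrix")
  }
  p1 <- colMeans(pop)
  term <- function(p) ifelse(p > 0, -p * log2(p), 0)
  term(p1) + term(1 - p1)
}

#' Burn-in: warm-start a population with diversity-preserving evolution
#'
#' Real breeding stocks are moderately fit and genetically diverse, not
#' uniform random strings. The burn-in emulates this by running the
#' niching GA on the *unmodified* landscape (base fitness `F`, no trait
#' weighting or threshold) for a fixed number of generations, starting
#' from a uniform random population. A burn-in of 0 generations returns
#' the random population unchanged.
#'
#' @param landscape An [generate_landscape()] object.
#' @param generations Burn-in length (commonly 0, 20 or 50).
#' @param params An [evolution_params()].
#' @param seed Integer seed for initialization and burn-in evolution.
#' @return The burned-in population matrix.
#' @export
run_burn_in <- function(landscape, generations, params, seed) {
  pop <- init_population(landscape$n, params$lam, derive_seed(seed, "init"))
  if (generations < 1) {
    return(pop)
  }
  tc_dummy <- trait_config(r = 1, n = landscape$n) # unused in global_F mode
  state <- run_state(landscape, tc_dummy, pop, params, fitness_mode = "global_F")
  with_seed(derive_seed(seed, "burn_in"), {
    for (g in seq_len(generations)) state <- step_niching(state)
  })
  state$pop
}

#' Run one algorithm arm for a fixed number of generations
#'
#' Switches the objective to the modified trait fitness `F'` and steps the
#' named algorithm, recording one row per generation (including the
#' re-scored starting generation 0): mean and best fitness under the
#' active mode, and mean per-locus entropy.
#'
#' @param landscape An [generate_landscape()] object.
#' @param tc A [trait_config()].
#' @param start_pop Starting population (shared across arms for matched
#'   comparisons).
#' @param algorithm One of [algorithm_ids()].
#' @param params An [evolution_params()].
#' @param generations Number of generations to run.
#' @param seed Integer seed for this arm's RNG stream.
#' @return A data frame with columns `generation`, `fitness_mode`,
#'   `mean_fitness`, `best_fitness`, `mean_entropy`, plus the final
#'   population as attribute `"final_pop"`.
#' @export
run_replicate <- function(landscape, tc, start_pop, algorithm, params,
                          generations, seed) {
  stepper <- .stepper_for(algorithm)
  state <- run_state(landscape, tc, start_pop, params,
    fitness_mode = "trait_F_prime"
  )
  record <- function(s) {
    data.frame(
      generation = s$generation,
      fitness_mode = s$fitness_mode,
      mean_fitness = mean(s$fit),
      best_fitness = max(s$fit),
      mean_entropy = mean(locus_entropy(s$pop))
    )
  }
  rows <- vector("list", generations + 1)
  rows[[1]] <- record(state)
  with_seed(derive_seed(seed, "arm", algorithm), {
    for (g in seq_len(generations)) {
      state <- stepper(state)
      rows[[g + 1]] <- record(state)
    }
  })
  trace <- do.call(rbind, rows)
  attr(trace, "final_pop") <- state$pop
  trace
}

#' Specification of a full algorithm comparison
#'
#' @param n,k Landscape dimensions.
#' @param r Number of trait loci (the first `r` loci).
#' @param f_th Viability threshold.
#' @param algorithms Character vector of arm ids (default all six).
#' @param replicates Number of independent landscapes / matched runs.
#' @param burn_in Burn-in generations on the unmodified landscape.
#' @param generations Post-burn-in generations under trait fitness.
#' @param params An [evolution_params()].
#' @param master_seed Master seed; every other seed is derived from it.
#' @return An object of class `comparison_spec`.
#' @export
comparison_spec <- function(n = 100, k = 5, r = 10, f_th = 0.55,
                            algorithms = algorithm_ids(), replicates = 100,
                            burn_in = 20, generations = 70,
                            params = evolution_params(), master_seed = 1) {
  unknown <- setdiff(algorithms, algorithm_ids())
  if (length(unknown)) {
    .stop_invalid(
      "invalid parameter: unknown algorithm id(s): ",
      paste(unknown, collapse = ", ")
    )
  }
  if (length(algorithms) < 1) {
    .stop_invalid("invalid parameter: at least one algorithm required")
  }
  structure(
    list(
      n = n, k = k, r = r, f_th = f_th, algorithms = algorithms,
      replicates = replicates, burn_in = burn_in, generations = generations,
      params = params, master_seed = master_seed
    ),
    class = "comparison_spec"
  )
}

#' Run a matched comparison of algorithms over replicate landscapes
#'
#' For each replicate, a fresh landscape is drawn from a child seed, one
#' burn-in is run on its unmodified fitness, and the *identical*
#' burned-in population is handed to every algorithm arm (matched
#' starts). Each arm then evolves under the modified trait fitness for
#' the configured number of generations with its own independent RNG
#' stream. Traces, per-generation summaries (mean with +/- 1 standard
#' error = stdev/sqrt(n)), tie-adjusted fitness ranks and final-generation
#' entropy profiles are aggregated across replicates.
#'
#' @param spec A [comparison_spec()].
#' @param progress If `TRUE`, print one line per replicate.
#' @return An object of class `comparison_result`: list with
#'   * `traces`: data frame (algorithm, replicate, generation,
#'     fitness_mode, mean_fitness, best_fitness, mean_entropy);
#'   * `summary`: per algorithm x generation means of fitness/entropy with
#'     standard errors;
#'   * `final_fitness`: replicates x algorithms matrix of final-generation
#'     mean population fitness;
#'   * `rank_matrix`: tie-adjusted ranks of `final_fitness` rows
#'     (1 = lowest fitness);
#'   * `mean_ranks`: per-generation mean rank and standard error per
#'     algorithm;
#'   * `entropy_profiles`: algorithms x loci matrix of final-generation
#'     per-locus entropy averaged over replicates;
#'   * `spec`: the input specification.
#' @export
run_comparison <- function(spec, progress = FALSE) {
  algs <- spec$algorithms
  reps <- spec$replicates
  tc <- trait_config(r = spec$r, n = spec$n, f_th = spec$f_th)
  traces <- vector("list", reps * length(algs))
  profiles <- array(
    0, dim = c(length(algs), spec$n),
    dimnames = list(algs, NULL)
  )
  fit_cube <- array(
    NA_real_, dim = c(reps, length(algs), spec$generations + 1),
    dimnames = list(NULL, algs, NULL)
  )
  ti <- 1
  for (rep_i in seq_len(reps)) {
    land_seed <- derive_seed(spec$master_seed, "landscape", rep_i)
    landscape <- generate_landscape(spec$n, spec$k, land_seed)
    start_pop <- run_burn_in(
      landscape, spec$burn_in, spec$params,
      seed = derive_seed(spec$master_seed, "burnin", rep_i)
    )
    for (a in algs) {
      tr <- run_replicate(
        landscape, tc, start_pop, a, spec$params, spec$generations,
        seed = derive_seed(spec$master_seed, "replicate", rep_i, a)
      )
      profiles[a, ] <- profiles[a, ] +
        locus_entropy(attr(tr, "final_pop")) / reps
      fit_cube[rep_i, a, ] <- tr$mean_fitness
      tr_df <- as.data.frame(tr)
      tr_df$algorithm <- a
      tr_df$replicate <- rep_i
      traces[[ti]] <- tr_df
      ti <- ti + 1
    }
    if (progress) {
      message(sprintf("replicate %d/%d done", rep_i, reps))
    }
  }
  traces <- do.call(rbind, traces)
  traces <- traces[, c(
    "algorithm", "replicate", "generation", "fitness_mode",
    "mean_fitness", "best_fitness", "mean_entropy"
  )]

  gens <- sort(unique(traces$generation))
  summary_df <- do.call(rbind, lapply(algs, function(a) {
    sub <- traces[traces$algorithm == a, ]
    do.call(rbind, lapply(gens, function(g) {
      x <- sub[sub$generation == g, ]
      data.frame(
        algorithm = a, generation = g,
        mean_fitness = mean(x$mean_fitness),
        se_fitness = .stderr(x$mean_fitness),
        mean_entropy = mean(x$mean_entropy),
        se_entropy = .stderr(x$mean_entropy)
      )
    }))
  }))

  # Tie-adjusted ranks per generation; final-generation ranks are the
  # headline comparison.
  mean_ranks <- do.call(rbind, lapply(seq_len(spec$generations + 1), function(gi) {
    rk <- t(apply(fit_cube[, , gi, drop = FALSE][, , 1, drop = TRUE], 1, rank))
    if (length(algs) == 1) rk <- matrix(1, nrow = reps, ncol = 1)
    data.frame(
      generation = gi - 1, algorithm = algs,
      mean_rank = colMeans(rk),
      stderr = apply(rk, 2, .stderr),
      row.names = NULL
    )
  }))
  final_fitness <- fit_cube[, , spec$generations + 1, drop = FALSE][, , 1, drop = FALSE]
  final_fitness <- matrix(final_fitness,
    nrow = reps,
    dimnames = list(NULL, algs)
  )
  rank_matrix <- rank_matrix_of(final_fitness)
  structure(
    list(
      traces = traces,
      summary = summary_df,
      final_fitness = final_fitness,
      rank_matrix = rank_matrix,
      mean_ranks = mean_ranks,
      entropy_profiles = profiles,
      spec = spec
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  s <- x$spec
  cat(
    "Comparison over", s$replicates, "matched landscapes (N =", s$n,
    ", K =", s$k, ", r =", s$r, ")\n"
  )
  cat("Final mean fitness ranks (1 = worst, higher = better):\n")
  print(round(sort(rank_final_fitness(x$final_fitness)), 2))
  invisible(x)
}

#' Tie-adjusted rank matrix of final fitness
#'
#' @param fitness_table Matrix replicates x algorithms of fitness scores.
#' @return Matrix of the same shape: within each replicate row, rank 1 is
#'   the lowest fitness and C (the number of algorithms) the highest; tied
#'   scores receive the mean of the ranks they span.
#' @export
rank_matrix_of <- function(fitness_table) {
  t(apply(fitness_table, 1, rank))
}

#' Mean fitness rank per algorithm
#'
#' Ranks each replicate's algorithms by fitness (ascending, mean rank for
#' ties) and averages the ranks over replicates.
#'
#' @inheritParams rank_matrix_of
#' @return Named numeric vector of mean ranks (one per algorithm column).
#' @export
rank_final_fitness <- function(fitness_table) {
  if (ncol(fitness_table) < 2 || nrow(fitness_table) < 1) {
    .stop_invalid("invalid parameter: need >= 1 replicate and >= 2 algorithms")
  }
  colMeans(rank_matrix_of(fitness_table))
}

#' Size of a sequence search space, and the microarray area it would need
#'
#' Computes `alphabet_size^length` exactly as a mantissa and decimal
#' exponent via logarithms, and optionally the physical area of a
#' microarray carrying one spot per sequence, treating each spot of the
#' given diameter as occupying a square grid cell.
#'
#' @param alphabet_size Number of letters (4 for DNA, 2 for bits).
#' @param length Sequence length.
#' @param spot_side Optional spot diameter / grid-cell side in micrometres.
#' @return List with `mantissa`, `exponent` (cardinality =
#'   `mantissa x 10^exponent`), and, when `spot_side` is given,
#'   `area_km2` (total area, two significant figures).
#' @examples
#' search_space_report(4, 30, spot_side = 5)
#' @export
search_space_report <- function(alphabet_size, length, spot_side = NULL) {
  if (alphabet_size < 2 || length < 1) {
    .stop_invalid("invalid parameter: alphabet_size >= 2 and length >= 1 required")
  }
  log10_card <- length * log10(alphabet_size)
  exponent <- floor(log10_card)
  mantissa <- 10^(log10_card - exponent)
  out <- list(mantissa = mantissa, exponent = exponent)
  if (!is.null(spot_side)) {
    # spot_side in micrometres; one sequence per (spot_side)^2 cell.
    log10_area_m2 <- log10_card + 2 * log10(spot_side * 1e-6)
    area_km2 <- 10^(log10_area_m2 - 6)
    out$area_km2 <- signif(area_km2, 2)
  }
  out
}
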