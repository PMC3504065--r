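# Variation/selection operators and the four non-rule-based steppers.

make_state <- function(n = 20, k = 2, lam = 50, seed = 1, p_m = NULL,
                       p_c = 0.7, mode = "trait_F_prime", r = 5,
                       f_th = 0.55) {
  land <- generate_landscape(n, k, seed)
  tc <- trait_config(r = r, n = n, f_th = f_th)
  pop <- init_population(n, lam, seed + 1)
  params <- evolution_params(lam = lam, p_m = p_m, p_c = p_c)
  run_state(land, tc, pop, params, fitness_mode = mode)
}

test_that("population initialization has the right shape and uniform bits", {
  pop <- init_population(100, 1000, seed = 9)
  expect_equal(dim(pop), c(1000, 100))
  expect_true(all(pop %in% 0:1))
  big <- init_population(50, 10000, seed = 10)
  freq <- colMeans(big)
  expect_true(all(abs(freq - 0.5) < 0.02))
  expect_identical(init_population(30, 40, seed = 3), init_population(30, 40, seed = 3))
  expect_error(init_population(0, 10, 1), "invalid")
})

test_that("mutation respects its rate limits and expectation", {
  g <- rep(0L, 250)
  set.seed(1)
  expect_identical(mutate_genotype(g, 0), g)
  expect_identical(mutate_genotype(g, 1), rep(1L, 250))
  expect_error(mutate_genotype(g, 1.5), "invalid")
  # E[Hamming distance to parent] = N * p_m = 1 at p_m = 1/N.
  set.seed(2)
  flips <- replicate(10000, sum(mutate_genotype(g, 1 / 250)))
  expect_equal(mean(flips), 1.0, tolerance = 0.05)
})

test_that("uniform crossover copies every locus from one of the parents", {
  set.seed(3)
  p1 <- sample(0:1, 60, replace = TRUE)
  p2 <- sample(0:1, 60, replace = TRUE)
  off <- uniform_crossover(p1, p2)
  expect_true(all(off == p1 | off == p2))
  expect_identical(uniform_crossover(p1, p1), p1)
  expect_error(uniform_crossover(p1, p2[-1]), "invalid")
  # one-counts for all-0 x all-1 parents ~ Binomial(100, 0.5)
  ones <- replicate(10000, sum(uniform_crossover(rep(0, 100), rep(1, 100))))
  expect_equal(mean(ones), 50, tolerance = 1)
})

test_that("tournament selection matches its closed-form win probability", {
  fit <- (1:10) / 10
  set.seed(4)
  wins <- replicate(1e5, tournament_select(fit, 10)) == 10
  expect_equal(mean(wins), 1 - (9 / 10)^10, tolerance = 0.01)
  # single-sample tournaments are uniform
  set.seed(5)
  picks <- replicate(2e4, tournament_select(fit, 1))
  expect_true(all(abs(tabulate(picks, 10) / 2e4 - 0.1) < 0.01))
  # pool of one always wins; empty pool errors
  expect_equal(tournament_select(fit, 5, pool = 7), 7)
  expect_error(tournament_select(fit, 5, pool = integer(0)), "empty pool")
})

test_that("breeder offspring are mutated champion clones with elitist retention", {
  st <- make_state(lam = 40, p_m = 0)
  set.seed(6)
  st1 <- step_breeder(st)
  champ <- st$pop[which.max(st$fit), ]
  expect_true(all(apply(st1$pop, 1, identical, as.integer(champ))))
  expect_equal(st1$generation, 1L)
  # champion fitness is non-decreasing over a run
  st <- make_state(lam = 40)
  best <- max(st$fit)
  for (i in 1:25) {
    st <- step_breeder(st)
    expect_gte(st$champion$fit, best)
    best <- st$champion$fit
  }
})

test_that("a champion at the global optimum never changes", {
  land <- generate_landscape(8, 2, seed = 21)
  tc <- trait_config(r = 8, n = 8, f_th = 0)
  all_g <- enumerate_genotypes(8)
  opt <- all_g[which.max(modified_fitness(land, tc, all_g)), ]
  pop <- matrix(rep(as.integer(opt), each = 30), nrow = 30)
  st <- run_state(land, tc, pop, evolution_params(lam = 30, p_m = 1 / 8))
  set.seed(7)
  for (i in 1:50) st <- step_breeder(st)
  expect_identical(as.integer(st$champion$geno), as.integer(opt))
})

test_that("standard GA keeps population size and improves an easy landscape", {
  st <- make_state(n = 10, k = 0, lam = 100, mode = "global_F")
  set.seed(8)
  st1 <- step_standard_ga(st)
  expect_equal(dim(st1$pop), dim(st$pop))
  # p_c = 0, p_m = 0: every offspring is a copy of some parent
  st0 <- make_state(lam = 30, p_m = 0, p_c = 0)
  set.seed(9)
  st0b <- step_standard_ga(st0)
  parents <- apply(st0$pop, 1, paste, collapse = "")
  kids <- apply(st0b$pop, 1, paste, collapse = "")
  expect_true(all(kids %in% parents))
  # separable K=0 landscape: fitness rises by generation 20 almost surely
  improved <- 0
  for (s in 1:20) {
    land <- generate_landscape(10, 0, seed = 100 + s)
    tc <- trait_config(r = 10, n = 10, f_th = 0)
    pop <- init_population(10, 100, seed = s)
    st <- run_state(land, tc, pop, evolution_params(lam = 100, p_m = 0.1),
      fitness_mode = "global_F"
    )
    f0 <- mean(st$fit)
    set.seed(200 + s)
    for (i in 1:20) st <- step_standard_ga(st)
    improved <- improved + (mean(st$fit) > f0)
  }
  expect_gte(improved, 19)
})

test_that("steppers replay bit-identically from the same state and seed", {
  for (step_fn in list(step_breeder, step_standard_ga, step_local_mating, step_niching)) {
    st <- make_state(n = 30, lam = 40)
    a <- with_seed <- NULL
    set.seed(11)
    a <- step_fn(st)
    set.seed(11)
    b <- step_fn(st)
    expect_identical(a$pop, b$pop)
    expect_identical(a$fit, b$fit)
  }
})

test_that("local mating neighbourhoods are the 24 surrounding cells with wrap", {
  nb <- nkbreed:::.local_neighbourhood(5, 8)
  expect_equal(dim(nb), c(40, 24))
  for (i in c(1, 17, 40)) {
    expect_equal(anyDuplicated(nb[i, ]), 0)
    expect_false(i %in% nb[i, ]) # focal cell excluded
  }
  # cell 1 of a 5x8 torus: rows {3,4,0,1,2} x cols {6,7,0,1,2} minus itself
  rows_of <- function(cells) sort(unique((cells - 1) %% 5))
  cols_of <- function(cells) sort(unique((cells - 1) %/% 5))
  expect_equal(rows_of(c(nb[1, ], 1)), 0:4)
  expect_equal(cols_of(c(nb[1, ], 1)), c(0, 1, 2, 6, 7))
})

test_that("local mating replaces in place and gene flow stays local", {
  # p_m = 0 lineage audit on a 5x8 grid: offspring alleles must originate
  # in the focal cell's neighbourhood (clone of neighbour, or recombination
  # of the resident with a neighbour).
  st <- make_state(n = 25, lam = 40, p_m = 0)
  nb <- nkbreed:::.local_neighbourhood(5, 8)
  set.seed(12)
  st1 <- step_local_mating(st)
  expect_equal(dim(st1$pop), dim(st$pop))
  for (i in seq_len(40)) {
    sources <- c(i, nb[i, ])
    ok <- vapply(
      seq_len(25),
      function(loc) st1$pop[i, loc] %in% st$pop[sources, loc],
      logical(1)
    )
    expect_true(all(ok))
  }
})

test_that("fitness sharing follows the printed formula", {
  expect_equal(shared_fitness(0.7, 1), 0.7) # isolated individual keeps f
  expect_equal(shared_fitness(0.9, 11), 0.45)
  ncs <- 1:50
  fs <- shared_fitness(0.8, ncs)
  expect_true(all(diff(fs) < 0)) # strictly decreasing in crowding
  expect_error(shared_fitness(0.5, 0), "invalid")
})

test_that("niche count estimation clusters by Hamming distance", {
  base <- matrix(0L, 20, 60)
  expect_equal(estimate_niche_count(base, 0, 50), 1)
  expect_equal(estimate_niche_count(base, 60, 50), 1)
  # two tight clusters 50 apart
  far <- base
  far[11:20, 1:50] <- 1L
  set.seed(13)
  expect_equal(estimate_niche_count(far, 5, 20), 2)
})

test_that("the niche radius steps towards the target count and clamps", {
  ns <- niche_state(n_r = 10, n_max = 100, q_estimate = 20)
  expect_equal(update_niche_radius(ns, 5)$n_r, 11)
  ns$q_estimate <- 2
  expect_equal(update_niche_radius(ns, 5)$n_r, 9)
  ns$q_estimate <- 5
  expect_equal(update_niche_radius(ns, 5)$n_r, 10)
  low <- niche_state(n_r = 1, n_max = 100, q_estimate = 1)
  expect_equal(update_niche_radius(low, 5)$n_r, 1)
})

test_that("identical populations share fitness at the lambda-crowding limit", {
  land <- generate_landscape(12, 1, seed = 31)
  tc <- trait_config(r = 3, n = 12, f_th = 0)
  pop <- matrix(rep(c(0L, 1L), each = 30 * 6), nrow = 30)
  st <- run_state(land, tc, pop, evolution_params(lam = 30))
  st$niche_state <- niche_state(2, 12)
  D <- nkbreed:::.hamming_matrix(st$pop)
  n_c <- rowSums(D <= 2)
  expect_equal(n_c, rep(30, 30))
  expect_equal(shared_fitness(st$fit, n_c), 10 * st$fit / 39)
  set.seed(14)
  st1 <- step_niching(st)
  expect_equal(nrow(st1$pop), 30)
  expect_equal(st1$generation, 1L)
})

test_that("niching preserves two distant peaks longer than the standard GA", {
  land <- two_peak_landscape(30)
  tc <- trait_config(r = 30, n = 30, f_th = 0)
  params <- evolution_params(lam = 40, p_m = 1 / 30)
  persistence <- function(stepper, seed) {
    pop <- rbind(
      matrix(0L, 20, 30),
      matrix(1L, 20, 30)
    )
    st <- run_state(land, tc, pop, params, fitness_mode = "global_F")
    set.seed(seed)
    for (g in 1:30) {
      st <- stepper(st)
      both <- any(rowSums(st$pop) == 0) && any(rowSums(st$pop) == 30)
      if (!both) return(g)
    }
    31L
  }
  wins <- 0
  for (s in 1:15) {
    p_niche <- persistence(step_niching, 1000 + s)
    p_std <- persistence(step_standard_ga, 1000 + s)
    wins <- wins + (p_niche >= p_std)
  }
  expect_gte(wins, 12)
})

test_that("all steppers preserve lambda and genome length", {
  st <- make_state(n = 24, lam = 36)
  set.seed(15)
  for (step_fn in list(
    step_breeder, step_standard_ga, step_local_mating, step_niching,
    function(s) step_earl(s, 1), function(s) step_earl(s, 2)
  )) {
    out <- step_fn(st)
    expect_equal(dim(out$pop), c(36, 24))
    expect_equal(length(out$fit), 36)
  }
})
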