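# Attributional rule induction and the two rule-guided steppers (EARL1,
# EARL2). Rules are conjunctions of locus = allele conditions induced each
# generation to separate the high-fitness stratum (H set) of the current
# population from the low-fitness stratum (L set); they then restrict the
# mating pools from which parents are tournament-selected.

#' Fitness strata for rule training
#'
#' Orders the population by fitness (descending, ties broken by lower
#' index first) and takes the top and bottom fractions as the H (high) and
#' L (low) training sets. With the default 20% fractions the strata are
#' always disjoint. Under complete ties the H set is the first 20% of the
#' population by index and the L set the last 20%.
#'
#' @param pop Population matrix.
#' @param fitnesses Fitness vector, one value per row of `pop`.
#' @param top_fraction,bottom_fraction Stratum sizes as fractions of the
#'   population; each stratum holds `floor(fraction * lam)` members.
#' @return An object of class `training_strata`: list with genotype
#'   matrices `h_set` and `l_set` and the source row indices `h_idx`,
#'   `l_idx`.
#' @export
extract_training_sets <- function(pop, fitnesses,
                                  top_fraction = 0.2, bottom_fraction = 0.2) {
  lam <- nrow(pop)
  m_top <- floor(top_fraction * lam)
  m_bot <- floor(bottom_fraction * lam)
  if (m_top < 1 || m_bot < 1) {
    .stop_invalid(
      "invalid parameter: population too small for the requested strata (lam = ",
      lam, ")"
    )
  }
  ord <- order(-fitnesses, seq_len(lam))
  h_idx <- ord[seq_len(m_top)]
  l_idx <- ord[seq(lam - m_bot + 1, lam)]
  structure(
    list(
      h_set = pop[h_idx, , drop = FALSE],
      l_set = pop[l_idx, , drop = FALSE],
      h_idx = h_idx, l_idx = l_idx
    ),
    class = "training_strata"
  )
}

# Coverage of a condition set over a genotype matrix: number of rows
# matching every (locus, allele) condition.
.coverage_mask <- function(conds, mat) {
  ok <- rep(TRUE, nrow(mat))
  for (i in seq_len(nrow(conds))) {
    ok <- ok & (mat[, conds[i, 1]] == conds[i, 2])
  }
  ok
}

.new_rule <- function(conds, h_cov, l_cov) {
  structure(
    list(
      conditions = conds, # matrix: columns locus, allele
      h_coverage = h_cov,
      l_coverage = l_cov,
      top_abundance = NA_integer_
    ),
    class = "attributional_rule"
  )
}

#' @export
print.attributional_rule <- function(x, ...) {
  cat(
    paste(sprintf("locus%d=%d", x$conditions[, 1], x$conditions[, 2]),
      collapse = " & "
    ),
    sprintf(" [H:%d L:%d]\n", x$h_coverage, x$l_coverage)
  )
  invisible(x)
}

#' Induce attributional rules separating fitness strata
#'
#' A transparent AQ-family separate-and-conquer learner. It repeatedly
#' seeds on the first uncovered H genotype and beam-searches conjunctions
#' of `locus = seed-allele` conditions: starting from single conditions,
#' each beam step extends the best partial rules by one further seed
#' condition, scoring by (fewest L matches, then most H matches). A rule
#' is emitted as soon as its L coverage is within `l_tolerance` (default
#' 0: perfectly consistent rules only); its H matches are then marked
#' covered. Seeds that cannot be separated within `max_conditions`
#' conditions are skipped, so an empty rule set is a legal outcome (e.g.
#' when the strata are identical). Every emitted rule matches its own
#' seed, hence covers at least one H member.
#'
#' @param strata An [extract_training_sets()] result.
#' @param beam_width Number of partial rules kept per beam step.
#' @param max_conditions Maximum conditions per rule.
#' @param max_rules Cap on the number of emitted rules.
#' @param l_tolerance Maximum admissible L-set coverage of an emitted rule.
#' @return An object of class `rule_set`: list of `attributional_rule`s
#'   (possibly empty).
#' @export
induce_rules <- function(strata, beam_width = 5, max_conditions = 5,
                         max_rules = 20, l_tolerance = 0) {
  H <- strata$h_set
  L <- strata$l_set
  if (nrow(H) < 1 || nrow(L) < 1) {
    .stop_invalid("invalid parameter: both strata must be non-empty")
  }
  n <- ncol(H)
  rules <- list()
  uncovered <- rep(TRUE, nrow(H))
  while (any(uncovered) && length(rules) < max_rules) {
    seed <- H[which(uncovered)[1], ]
    best <- .beam_search_rule(
      seed, H, L,
      beam_width = beam_width, max_conditions = min(max_conditions, n)
    )
    if (is.null(best) || best$l_coverage > l_tolerance) {
      # No consistent rule for this seed: skip it (keeps the loop finite).
      uncovered[which(uncovered)[1]] <- FALSE
      next
    }
    rules[[length(rules) + 1]] <- best
    uncovered <- uncovered & !.coverage_mask(best$conditions, H)
  }
  structure(list(rules = rules), class = "rule_set")
}

# Beam search over conjunctions of (locus = seed allele) conditions.
# Scoring: primary minimise L coverage, secondary maximise H coverage.
# Candidate extensions are scored in bulk with column sums over the
# seed-agreement matrices, so cost per depth is O(beam * strata * N).
# Returns the best complete rule found (class attributional_rule) or NULL.
.beam_search_rule <- function(seed, H, L, beam_width, max_conditions) {
  n <- length(seed)
  Hs <- H == matrix(seed, nrow(H), n, byrow = TRUE) # row matches seed at locus
  Ls <- L == matrix(seed, nrow(L), n, byrow = TRUE)
  storage.mode(Hs) <- "double" # BLAS-ready for bulk coverage scoring
  storage.mode(Ls) <- "double"
  beam <- list(list(loci = integer(0), hm = rep(TRUE, nrow(H)), lm = rep(TRUE, nrow(L))))
  best <- NULL
  better <- function(a, b) {
    is.null(b) || a$l_coverage < b$l_coverage ||
      (a$l_coverage == b$l_coverage && a$h_coverage > b$h_coverage)
  }
  for (depth in seq_len(max_conditions)) {
    # Bulk-score every one-condition extension of every beam entry:
    # crossprod of the entries' coverage masks with the seed-agreement
    # matrices gives all H/L coverages in two BLAS calls.
    ne <- length(beam)
    Hm <- vapply(beam, function(e) as.double(e$hm), double(nrow(H)))
    Lm <- vapply(beam, function(e) as.double(e$lm), double(nrow(L)))
    hc <- crossprod(matrix(Hm, ncol = ne), Hs) # ne x n
    lc <- crossprod(matrix(Lm, ncol = ne), Ls)
    for (e in seq_len(ne)) hc[e, beam[[e]]$loci] <- -Inf # not extensions
    ord <- order(as.vector(lc), -as.vector(hc))
    new_beam <- list()
    seen <- character(0)
    for (o in ord) {
      if (length(new_beam) >= beam_width) break
      e <- (o - 1) %% ne + 1
      loc <- (o - 1) %/% ne + 1
      if (is.infinite(hc[e, loc])) next
      loci <- sort(c(beam[[e]]$loci, loc))
      key <- paste(loci, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      new_beam[[length(new_beam) + 1]] <- list(
        loci = loci,
        hm = beam[[e]]$hm & Hs[, loc],
        lm = beam[[e]]$lm & Ls[, loc]
      )
    }
    if (length(new_beam) == 0) break
    beam <- new_beam
    top <- beam[[1]]
    rule <- .new_rule(
      cbind(locus = top$loci, allele = as.integer(seed[top$loci])),
      h_cov = sum(top$hm), l_cov = sum(top$lm)
    )
    if (better(rule, best)) best <- rule
    if (rule$l_coverage == 0) break # consistent rule found; stop specialising
  }
  best
}

#' Does a genotype satisfy a rule?
#'
#' True iff the genotype carries the required allele at every condition
#' locus.
#'
#' @param rule An `attributional_rule`.
#' @param g Binary genotype vector.
#' @return Logical scalar.
#' @export
rule_matches <- function(rule, g) {
  conds <- rule$conditions
  if (any(conds[, 1] > length(g))) {
    .stop_invalid("invalid parameter: rule locus out of range for this genotype")
  }
  all(g[conds[, 1]] == conds[, 2])
}

# Match matrix: rules x individuals logical matrix.
.rule_match_matrix <- function(rs, pop) {
  t(vapply(
    rs$rules,
    function(r) .coverage_mask(r$conditions, pop),
    logical(nrow(pop))
  ))
}

#' Select a rule weighted by abundance in the top stratum
#'
#' Samples one rule from the set with probability proportional to the
#' number of top-stratum individuals that satisfy it; if no rule matches
#' any top member, sampling is uniform.
#'
#' @param rs A [induce_rules()] rule set (non-empty).
#' @param top_members Genotype matrix of the current top stratum.
#' @return The index of the selected rule within `rs$rules`.
#' @export
select_rule <- function(rs, top_members) {
  k <- length(rs$rules)
  if (k == 0) {
    .stop_invalid("empty rule set: caller should fall back to plain tournament")
  }
  ab <- rowSums(.rule_match_matrix(rs, top_members))
  w <- if (sum(ab) == 0) rep(1, k) else ab
  sample.int(k, 1, prob = w)
}

#' One generation of a rule-guided EARL algorithm
#'
#' Each generation the rule set is retrained on the current population's
#' fitness strata. For every offspring a rule `r_x` is selected (weighted
#' by its abundance in the top stratum) and the sub-population `s` of
#' individuals satisfying `r_x` becomes the mating pool: the first parent
#' is tournament-selected from `s` (both on the recombination and the
#' clone path). Under recombination (probability `p_c`) the second parent
#' comes from `s` for variant 1 — reinforcing the rule — or from the
#' complement of `s` for variant 2 — deliberately disrupting it to probe
#' beyond the rule's locus combination. Mutation and full generational
#' replacement follow the standard GA. Fallbacks: an empty rule set makes
#' the step identical to [step_standard_ga()]; an empty pool `s` reverts
#' that offspring to unrestricted tournaments; an empty complement in
#' variant 2 degrades that offspring to variant-1 behaviour.
#'
#' @param state A [run_state()].
#' @param variant 1 (second parent obeys the rule) or 2 (second parent
#'   drawn from the rule's complement).
#' @param audit If `TRUE`, attach a per-offspring data frame
#'   (`attr(state, "audit")`) recording the selected rule and parent rows,
#'   for lineage checks.
#' @return The updated state; `state$ruleset` holds the generation's rules.
#' @export
step_earl <- function(state, variant = 1, audit = FALSE) {
  if (!variant %in% c(1, 2)) {
    .stop_invalid("invalid parameter: variant must be 1 or 2")
  }
  p <- state$params
  strata <- extract_training_sets(
    state$pop, state$fit,
    top_fraction = p$top_fraction, bottom_fraction = p$bottom_fraction
  )
  rs <- induce_rules(
    strata,
    beam_width = p$beam_width, max_conditions = p$max_conditions,
    max_rules = p$max_rules, l_tolerance = p$l_tolerance
  )
  state$ruleset <- rs
  if (length(rs$rules) == 0) {
    out <- step_standard_ga(state)
    out$ruleset <- rs
    if (audit) attr(out, "audit") <- NULL
    return(out)
  }
  lam <- p$lam
  match_mat <- .rule_match_matrix(rs, state$pop)
  pools <- apply(match_mat, 1, which, simplify = FALSE)
  ab <- rowSums(.rule_match_matrix(rs, strata$h_set))
  w <- if (sum(ab) == 0) rep(1, length(rs$rules)) else ab
  rule_pick <- sample.int(length(rs$rules), lam, replace = TRUE, prob = w)
  recomb <- stats::runif(lam) < p$p_c
  all_idx <- seq_len(lam)
  p1 <- integer(lam)
  p2 <- rep(NA_integer_, lam)
  fb <- logical(lam)
  comp_empty <- logical(lam)
  # Offspring sharing a rule share its mating pool, so their tournaments
  # can be drawn in one vectorised batch per rule.
  for (g in unique(rule_pick)) {
    rows <- which(rule_pick == g)
    s <- pools[[g]]
    fallback <- length(s) == 0
    fb[rows] <- fallback
    pool1 <- if (fallback) all_idx else s
    p1[rows] <- .tournament_many(state$fit, length(rows), p$t_size, pool1)
    rr <- rows[recomb[rows]]
    if (length(rr)) {
      pool2 <- if (fallback) {
        all_idx
      } else if (variant == 1) {
        s
      } else {
        comp <- all_idx[!match_mat[g, ]]
        if (length(comp) == 0) {
          comp_empty[rr] <- TRUE
          s
        } else {
          comp
        }
      }
      p2[rr] <- .tournament_many(state$fit, length(rr), p$t_size, pool2)
    }
  }
  off <- state$pop[p1, , drop = FALSE]
  if (any(recomb)) {
    off[recomb, ] <- .crossover_rows(
      state$pop[p1[recomb], , drop = FALSE],
      state$pop[p2[recomb], , drop = FALSE]
    )
  }
  aud <- if (audit) {
    data.frame(
      rule = rule_pick, parent1 = p1, parent2 = p2,
      recombined = recomb, fallback = fb, complement_empty = comp_empty
    )
  }
  off <- .mutate_rows(off, p$p_m)
  state$pop <- off
  state$fit <- .eval_fitness(state$landscape, state$tc, off, state$fitness_mode)
  state$generation <- state$generation + 1L
  if (audit) attr(state, "audit") <- aud
  state
}
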