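---
title: "Models and methods behind nkbreed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nkbreed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nkbreed)
```

# The scientific problem

Experimental breeding programmes improve crops and livestock by choosing
which individuals to mate, generation after generation, under severe
constraints on population size and generation count. With cheap sequencing
it is now realistic to know the full genotype of every individual in a
breeding population, which raises a concrete question: do selection
strategies that exploit genotypes (G-algorithms) beat well-tuned strategies
that see only measured phenotypic fitness (F-algorithms)? `nkbreed` is an
in silico testbed for that question: it provides a biologically motivated
family of synthetic fitness landscapes, six breeding algorithms spanning
both camps, and a replicated, matched comparison harness.

# The landscape model

## Base NK fitness

A genome is a binary string of length $N$. Each locus $i$ contributes a
fitness $f_i$ that depends on its own allele and on the alleles of $K$
randomly chosen partner loci (epistasis). The $2^{K+1}$ possible states of
this sub-vector index a lookup table of contributions drawn i.i.d.
uniformly on $[0,1]$ when the landscape is generated. Total fitness is the
average contribution:

$$F(\alpha) = \frac{1}{N}\sum_{i=1}^{N} f_i\!\left(\alpha_{i,1},\dots,\alpha_{i,K+1}\right),
\qquad \alpha_{i,1} = \alpha_i .$$

$K$ tunes ruggedness: $K=0$ is separable with a trivially locatable
optimum, larger $K$ produces many local optima, mimicking the epistasis of
real biochemical networks.

**Indexing convention.** The $(K+1)$-bit state is read in neighbour-row
order with the locus's own allele as the most significant bit. Any fixed
convention defines the same model family; this one is frozen so that
landscapes regenerate bit-identically from `(n, k, seed)` across versions.

## Trait-weighted, thresholded fitness

A breeder does not optimise total fitness; they optimise a trait carried
disproportionately by particular genes, at some risk to the rest of the
organism. The modified objective weights the first $r$ loci (default
$r = 10$): their mean realized contribution is the trait fitness

$$F_r(\alpha) = \frac{1}{r}\sum_{i=1}^{r} f_i(\cdot),$$

and the breeding objective is $F' = F_r \times F$, collapsed to $0$
whenever $F < F_{th}$. The threshold (default $F_{th} = 0.55$) models the
catastrophic viability loss that can accompany single-minded trait
selection. The product form rewards genotypes that serve the trait without
wrecking the genetic background.

The exact functional form of $F_r$ is a design decision of this package:
we use the mean of the trait loci's realized contributions, which reduces
exactly to $F$ when $r = N$ and keeps $F' \in [0,1]$. Similarly the trait
occupies the *first* $r$ loci by convention, which makes entropy profiles
directly interpretable (the interesting loci are always positions
$1..r$). `calibrate_threshold()` is provided as optional tooling to pick
the largest grid threshold keeping a given fraction of a reference
population viable; routine runs use the fixed 0.55. Its grid is rounded to
10 decimals so that thresholds like $12 \times 0.05$ compare as exactly
$0.6$ rather than as a floating-point neighbour.

# The six algorithms

All six share the same variation operators: per-bit mutation at rate
$p_m$ (default $1/N$, roughly one new mutation per genome per
generation — the classic drift/selection balance point), uniform
crossover, and tournament selection of size $t_{size} = 10$. Populations
hold $\lambda$ individuals (default 1000) and are replaced generationally.

* **Breeder (1+λ)** — phenotype-only truncation selection taken to its
  extreme: every offspring is a mutated clone of the single fittest
  individual seen so far, and the champion is only replaced by a strictly
  better offspring. Elitist, greedy, and prone to premature convergence;
  diversity statistics are reported on the offspring population.
* **Standard GA** — non-elitist generational GA: each offspring arises by
  crossover of two tournament winners with probability $p_c = 0.7$, else
  by cloning one winner; all offspring replace all parents.
* **Local mating** — the standard GA on a toroidal grid (most-square
  factorisation of $\lambda$, e.g. $1000 = 25\times40$): each cell mates
  only with tournament winners drawn from the 24 cells of the surrounding
  $5\times5$ square, and offspring replace their cell synchronously.
  Restricted gene flow slows take-over and preserves diversity.
* **Niching GA** — genotype-aware fitness sharing: an individual's
  tournament fitness is $f_{share} = 10f/(9+n_c)$ where the niche count
  $n_c$ is the number of individuals (itself included, so an isolated
  genotype keeps $f_{share} = f$) within Hamming distance $n_r$. The
  radius is dynamic: each generation the niche count $q$ is estimated by
  greedy leader clustering of a 50-individual sample and $n_r$ moves one
  locus up (too many niches) or down (too few) towards the target
  $T_q = 5$, clamped to $[1, N]$; it starts at $\max(1, \lfloor N/10
  \rfloor)$. The exact $O(\lambda^2)$ niche count is used for sharing;
  sampling is reserved for the $q$ estimate.
* **EARL1 / EARL2** — rule-guided algorithms in the spirit of learnable
  evolution. Each generation the top and bottom 20% of the population by
  fitness become H and L training strata, and an AQ-family
  separate-and-conquer learner induces conjunctive `locus = allele` rules
  satisfied in H but not L. For each offspring a rule is drawn with
  probability proportional to its abundance in the top stratum; the
  sub-population $s$ matching the rule is the mating pool for the first
  parent (clone path included). Under crossover the second parent comes
  from $s$ (EARL1, reinforcing the rule) or from its complement (EARL2,
  deliberately disrupting it). With no rules, or an empty pool, selection
  falls back to plain tournaments — an empty rule set makes the step
  *identical* to the standard GA by construction.

## The rule learner

The original attributional-calculus learner behind this family of
algorithms is a large external system; `nkbreed` implements a transparent
AQ-style core that honours the same contract (strong H-not-L
regularities, possibly incomplete coverage): seed on the first uncovered H
genotype; beam-search (width 5) conjunctions of seed-allele conditions,
scored by fewest L matches then most H matches, up to 5 conditions;
emit a rule only when its L coverage is within `l_tolerance` (default 0,
i.e. perfectly consistent rules only); mark covered H members and repeat,
capping at 20 rules. Seeds that cannot be consistently separated are
skipped, so identical strata legitimately produce an empty rule set.
Candidate extensions are scored in bulk via crossproducts of coverage
masks, keeping induction cheap enough to retrain every generation. Rule
selection is drawn independently per offspring rather than once per
generation, so a generation can exploit several discovered regularities at
once.

# The comparison harness

**Burn-in.** Mutating a uniform random string yields beneficial mutations
far more often than mutating a real, long-evolved crop genome. To start
from something resembling a breeding stock — moderately fit but still
diverse — every run first evolves a random population with the *niching*
GA on the unmodified landscape (objective $F$) for a configurable number
of generations (default 20; 0 and 50 are also standard settings). The
resulting population is handed, bit-identically, to every algorithm arm:
starting populations are matched so that between-arm differences are pure
algorithm effects.

**Replication and seeds.** Each replicate draws a fresh landscape from a
child seed. A single master seed is split by a documented multiplicative
hash (`derive_seed()`) into independent child seeds per replicate, per
purpose (landscape, burn-in) and per algorithm arm, so the whole
comparison — traces, ranks, entropy profiles, exports — reproduces
byte-identically from one integer.

**Statistics.** Per generation and arm we record mean and best fitness
under the active objective ($F$ during burn-in, $F'$ afterwards; the mode
is stored per record so the discontinuity at the switch is explicit) and
mean per-locus Shannon entropy in bits,
$H = -p_0\log_2 p_0 - p_1\log_2 p_1$ (base 2 chosen so a 50/50 locus is
exactly 1 bit). Algorithms are compared by rank: within each replicate the
arms are ranked 1 (lowest final mean $F'$) to $C$ (highest), ties
receiving the mean rank, and ranks are averaged over replicates with
error bands of $\pm 1$ standard error ($\mathrm{sd}/\sqrt{n}$). Rank rows
always sum to $C(C+1)/2$. Final-generation entropy profiles (per-locus,
averaged over replicates) show *where* in the genome each algorithm
collapsed diversity — in particular whether the first $r$ trait loci were
singled out.

# What the synthetic landscapes do and do not capture

The generator reproduces the features that matter for comparing selection
strategies: tunable epistasis, a trait/viability trade-off, and
reproducible replication. It deliberately omits much of real genetics:
diploidy and dominance, linkage maps and position-dependent recombination
(uniform crossover is used throughout, a choice that favours thorough
search-space exploration over preserving long schemata), multi-allelic
loci, environmental variance on phenotypes, and epigenetics. Conclusions
drawn from this testbed therefore concern the relative behaviour of
selection strategies on rugged binary landscapes, not absolute genetic
gain in any particular crop.

# Numerical and degenerate-case choices

* Tournament ties break to the lowest index among the sampled candidates,
  making every stepper replayable bit-for-bit under a fixed RNG state.
* Thresholding is inclusive: $F \ge F_{th}$ survives.
* Fitness-stratum ties at the 20% boundaries break by population index
  (fully tied populations yield the first/last 20% by index), so rule
  training is deterministic.
* The local-mating grid is toroidal; the neighbourhood excludes the focal
  cell (exactly the 24 surrounding cells). Grids smaller than $5\times5$
  wrap onto themselves and are only used in toys.
* $0\log 0 = 0$ in entropy; monomorphic loci contribute exactly 0 bits.
* In the niching GA the niche count includes the individual itself: the
  scaling identity $f_{share}(n_c{=}1) = f$ requires it.
* An empty mating pool or empty rule set degrades gracefully to
  unrestricted tournament selection; in EARL2 an empty complement degrades
  that offspring to EARL1 behaviour. Both events are recorded when
  auditing is enabled.

# Problem sizes used in the shipped checks

The package's own test suite and the acceptance script run a scaled-down
profile of the full experiment: $N = 100$, $K = 5$, $r = 10$,
$\lambda = 200$, burn-in 20, 70 post-burn-in generations, 20 replicate
landscapes. This keeps a complete six-algorithm comparison within a few
minutes on one CPU while preserving the qualitative contrasts between
algorithms; the full-scale profile ($\lambda$ of 1000–10000, 100
replicates, $N$ up to 250) is supported through the same API and
configuration files. Statistical property tests (tournament win odds,
mutation load, stratified-rule convergence, two-peak niche persistence)
use reduced repetition counts sized to keep Monte-Carlo error well inside
the asserted bounds.

Two quantitative caveats of the scaled-down profile are worth knowing.
First, a mutated-clone population's per-locus entropy floor is
$\approx H(p_m)$; at $N = 100$, $p_m = 1/N = 0.01$ gives $\approx 0.08$
bits, so the breeder's "near zero" entropy plateau is noticeably higher
at $N = 100$ than at $N = 250$ ($\approx 0.04$ bits). Second, at
$\lambda = 200$ the niching GA's dynamic radius keeps the population far
from convergence over 70 generations, so its final trait fitness — and
hence its rank — sits well below the converging algorithms; at large
$\lambda$ the same scheme begins to converge within the horizon. Both
effects are properties of the stated parameters, not of the
implementation.

# Known limitations

* The rule learner is a deliberately simple AQ-style core: no internal
  disjunctions, numeric ranges, or exception handling; `l_tolerance`
  exposes the consistency trade-off instead of guessing a fuzziness level.
* Exact niche counting is $O(\lambda^2)$ per generation; for
  $\lambda \gtrsim 10^4$ the sampled estimator should be substituted for
  sharing as well (an optional mode on `estimate_niche_count()`'s
  machinery), at some cost in sharing accuracy.
* Fitness caching assumes the landscape is immutable during a run;
  mutating a landscape object invalidates any live `run_state`.
* The harness is single-threaded by design (replicable RNG streams);
  replicates are embarrassingly parallel and can be split across processes
  by running disjoint replicate ranges with the same master seed.
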