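# Stochastic meiosis simulator: synthetic-data generator and brute-force
# oracle for the exact probability engine.
#
# Chiasmata on the four-strand bundle are modelled as a stationary gamma
# renewal process along the chromosome (positions in Morgans) with shape
# `nu` and rate `2 * nu` per Morgan, so the chiasma density is 2 per
# Morgan for every `nu` and the crossover density on a sampled chromatid
# is 1 per Morgan after the customary independent 1/2-thinning (no
# chromatid interference). `nu = 1` recovers a Poisson process (no
# crossover interference, Haldane's map); larger `nu` spaces chiasmata
# more regularly, giving positive interference (coincidence below 1).

#' Lay a genetic map out in Morgans for simulation
#'
#' Converts each segment's recombination fraction into a Morgan length
#' under the chosen map function (Haldane by default, matching the
#' simulator's `nu = 1` crossover process exactly).
#'
#' @param map A [genetic_map()].
#' @param rule Inverse map function: `"haldane"`, `"kosambi"` or
#'   `"direct"` (Morgans = r).
#' @return List of groups, each with `loci` and cumulative `pos_morgans`.
#' @export
map_in_morgans <- function(map, rule = "haldane") {
  stopifnot(inherits(map, "genetic_map"))
  lapply(map$groups, function(g) {
    d <- map_function_inverse_morgans(g$r, rule)
    list(loci = g$loci, pos_morgans = cumsum(c(0, d)))
  })
}

# Crossover counts per segment for n gametes in one linkage group.
# Returns an n x (k-1) integer matrix. For nu = 1 the thinned chiasma
# process is exactly Poisson with rate 1/Morgan and independent
# increments, so counts are drawn directly; otherwise chiasma positions
# are simulated from the renewal process (with a burn-in to reach
# stationarity) and thinned per chiasma with probability 1/2.
segment_crossover_counts <- function(d, n, nu) {
  k1 <- length(d)
  if (nu == 1) {
    counts <- vapply(d, function(len) stats::rpois(n, len),
                     integer(n))
    return(matrix(counts, nrow = n, ncol = k1))
  }
  L <- sum(d)
  burn <- 5                       # Morgans; ~10 mean inter-chiasma gaps
  total <- burn + L
  # enough draws that the cumulative sum exceeds the window w.h.p.
  m <- ceiling(2 * total + 6 * sqrt(2 * total / nu) + 12)
  X <- matrix(stats::rgamma(n * m, shape = nu, rate = 2 * nu), nrow = n)
  for (j in 2:m) X[, j] <- X[, j - 1] + X[, j]
  bounds <- burn + cumsum(c(0, d))
  counts <- matrix(0L, nrow = n, ncol = k1)
  for (s in seq_len(k1)) {
    chiasma <- rowSums(X > bounds[s] & X <= bounds[s + 1])
    counts[, s] <- stats::rbinom(n, chiasma, 0.5)
  }
  counts
}

#' Simulate gametes from a parent by stochastic meiosis
#'
#' Draws crossover points from a stationary gamma renewal chiasma process
#' (shape `nu`, rate `2 * nu` per Morgan) thinned with probability 1/2,
#' then copies alleles switching parental strand at each retained
#' crossover. Every simulated allele comes from one of the two parental
#' haplotypes; nothing is invented.
#'
#' @param parent A [diplotype()].
#' @param n Number of gametes.
#' @param nu Gamma shape (`>= 0.25`); 1 = no interference (Poisson
#'   crossovers, Haldane's map function), larger values give positive
#'   interference.
#' @param rule Inverse map function used to convert the map's segment
#'   fractions to Morgans (default `"haldane"`, exact for `nu = 1`).
#' @param seed Optional integer seed for reproducibility.
#' @return Character matrix `n` x loci of gamete alleles, with the RNG
#'   seed used (if any) in `attr(, "seed")`.
#' @examples
#' m <- genetic_map(c("G", "R"), r = 0.078)
#' g <- simulate_gametes(diplotype("G +", "+ R", m), n = 1000, seed = 1)
#' mean(g[, "G"] == "G" & g[, "R"] == "R")  # ~ r/2 doubly recombinant
#' @export
simulate_gametes <- function(parent, n = 1, nu = 1, rule = "haldane",
                             seed = NULL) {
  stopifnot(inherits(parent, "diplotype"))
  if (nu < 0.25) stop_tl("nu must be at least 0.25")
  if (!is.null(seed)) set.seed(seed)
  groups <- map_in_morgans(parent$map, rule)
  loci <- parent$map$loci
  out <- matrix(NA_character_, nrow = n, ncol = length(loci),
                dimnames = list(NULL, loci))
  for (g in groups) {
    idx <- match(g$loci, loci)
    k <- length(g$loci)
    start <- stats::rbinom(n, 1, 0.5)
    if (k == 1L) {
      strand <- matrix(start, ncol = 1)
    } else {
      d <- diff(g$pos_morgans)
      counts <- segment_crossover_counts(d, n, nu)
      cum <- counts
      if (ncol(cum) > 1L) {
        for (j in 2:ncol(cum)) cum[, j] <- cum[, j - 1] + cum[, j]
      }
      strand <- cbind(start, (start + cum) %% 2)
    }
    h1 <- parent$h1[idx]; h2 <- parent$h2[idx]
    for (j in seq_len(k)) {
      out[, idx[j]] <- ifelse(strand[, j] == 0, h1[j], h2[j])
    }
  }
  attr(out, "seed") <- seed
  out
}

#' Empirical haplotype frequencies of a simulated gamete matrix
#'
#' @param gametes Matrix from [simulate_gametes()].
#' @return Named numeric vector of haplotype frequencies keyed like
#'   [gamete_distribution()].
#' @export
haplotype_frequencies <- function(gametes) {
  keys <- hap_key(gametes)
  tab <- table(keys)
  stats::setNames(as.numeric(tab) / nrow(gametes), names(tab))
}

#' Estimate the coefficient of coincidence from simulated gametes
#'
#' For a parent heterozygous at three informative loci, classifies each
#' gamete as recombinant or parental in the two segments and returns
#' `c_hat = P(double) / (r1_hat * r2_hat)` together with the component
#' estimates.
#'
#' @param gametes Matrix from [simulate_gametes()] over exactly 3 loci.
#' @param parent The [diplotype()] the gametes were simulated from; every
#'   locus must be heterozygous (distinct parental alleles).
#' @return List with `c_hat`, `r1_hat`, `r2_hat`, `double_freq`.
#' @export
estimate_coincidence <- function(gametes, parent) {
  loci <- colnames(gametes)
  if (length(loci) != 3L) stop_tl("coincidence estimation needs 3 loci")
  h1 <- parent$h1[loci]; h2 <- parent$h2[loci]
  if (any(h1 == h2)) stop_tl("all three loci must be heterozygous")
  strand <- vapply(seq_along(loci), function(j) {
    as.integer(gametes[, j] == h2[j])
  }, integer(nrow(gametes)))
  rec1 <- strand[, 1] != strand[, 2]
  rec2 <- strand[, 2] != strand[, 3]
  r1 <- mean(rec1); r2 <- mean(rec2); dbl <- mean(rec1 & rec2)
  list(c_hat = dbl / (r1 * r2), r1_hat = r1, r2_hat = r2,
       double_freq = dbl)
}

#' Simulate a seed population from a cross
#'
#' Draws one gamete from each parent per seed, assigns fluorescence
#' intensities by reporter dosage, applies adjacent-intensity
#' misclassification per channel, marks lethal genotypes dead, and labels
#' phenotypes. The observed class differs from the true class only when
#' `epsilon > 0`.
#'
#' @param cross A [cross_design()].
#' @param n_seeds Number of seeds.
#' @param model A [seed_class_model()].
#' @param lethal,phenotype As in [seed_class_distribution()].
#' @param nu,rule Interference model passed to [simulate_gametes()].
#' @param seed Optional integer RNG seed.
#' @return A data frame (`simulated_seeds`) with one row per seed:
#'   `genotype` (order-free diplotype key), true and observed intensities
#'   per channel, `viable`, `phenotype`; the seed used is in
#'   `attr(, "seed")`.
#' @export
simulate_cross <- function(cross, n_seeds, model = seed_class_model(),
                           lethal = list(), phenotype = NULL, nu = 1,
                           rule = "haldane", seed = NULL) {
  stopifnot(inherits(cross, "cross_design"))
  if (n_seeds < 1) stop_tl("n_seeds must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  g1 <- simulate_gametes(cross$parent1, n = n_seeds, nu = nu, rule = rule)
  g2 <- simulate_gametes(cross$parent2, n = n_seeds, nu = nu, rule = rule)
  loci <- cross$map$loci
  key1 <- hap_key(g1); key2 <- hap_key(g2)
  genotype <- diplo_key(key1, key2)
  dosage <- function(mat, locus) {
    as.integer(mat[, locus] != "+")
  }
  g_dose <- dosage(g1, model$green) + dosage(g2, model$green)
  r_dose <- dosage(g1, model$red) + dosage(g2, model$red)
  green_true <- INTENSITIES[g_dose + 1L]
  red_true <- INTENSITIES[r_dose + 1L]
  confuse <- function(true_int) {
    conf <- intensity_confusion(model$epsilon)
    out <- character(length(true_int))
    for (lvl in INTENSITIES) {
      idx <- which(true_int == lvl)
      if (length(idx)) {
        out[idx] <- sample(INTENSITIES, length(idx), replace = TRUE,
                           prob = conf[lvl, ])
      }
    }
    out
  }
  viable <- rep(TRUE, n_seeds)
  for (locus in names(lethal)) {
    pair_target <- sort(as.character(lethal[[locus]]))
    a1 <- g1[, locus]; a2 <- g2[, locus]
    viable <- viable & !(pmin(a1, a2) == pair_target[1] &
                           pmax(a1, a2) == pair_target[2])
  }
  labels <- if (is.null(phenotype)) rep("", n_seeds) else {
    vapply(seq_len(n_seeds), function(i) {
      phenotype(stats::setNames(g1[i, ], loci),
                stats::setNames(g2[i, ], loci))
    }, character(1))
  }
  out <- data.frame(
    genotype = genotype,
    green_true = green_true, red_true = red_true,
    green_obs = confuse(green_true), red_obs = confuse(red_true),
    viable = viable, phenotype = labels, stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  class(out) <- c("simulated_seeds", "data.frame")
  out
}

#' Simulate a testcross seed-class count table
#'
#' One multinomial draw of `N` seeds with class probabilities
#' `(1 - r)/2, (1 - r)/2, r/2, r/2` arranged by phase: in repulsion the
#' single-colour classes are parental; in coupling the both-colour and
#' nonfluorescent classes are.
#'
#' @param r True recombination fraction in `[0, 0.5]`.
#' @param N Number of seeds scored.
#' @param phase `"repulsion"` or `"coupling"`.
#' @param seed Optional integer RNG seed.
#' @return A [count_table()] with the matching phase.
#' @examples
#' simulate_testcross_counts(0.078, 423, seed = 1)
#' @export
simulate_testcross_counts <- function(r, N,
                                      phase = c("repulsion", "coupling"),
                                      seed = NULL) {
  phase <- match.arg(phase)
  if (r < 0 || r > 0.5) stop_tl("r must lie in [0, 0.5]")
  if (N < 1) stop_tl("N must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  if (phase == "repulsion") {
    probs <- c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2)
  } else {
    probs <- c(r / 2, r / 2, (1 - r) / 2, (1 - r) / 2)
  }
  x <- as.integer(stats::rmultinom(1, N, probs))
  count_table(x[1], x[2], x[3], x[4], phase = phase)
}
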