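test_that("two-point gamete distributions follow the repulsion design", {
  m <- genetic_map(c("G", "R"), r = 0.078)
  gd <- gamete_distribution(diplotype("G +", "+ R", m))
  expect_equal(sum(gd), 1, tolerance = 1e-12)
  expect_equal(gd[["G|+"]], 0.461)
  expect_equal(gd[["+|R"]], 0.461)
  expect_equal(gd[["G|R"]], 0.039)
  expect_equal(gd[["+|+"]], 0.039)

  # r = 0: only the two parental haplotypes, one half each
  m0 <- genetic_map(c("G", "M", "R"), r = c(0, 0), coincidence = 0.3)
  gd0 <- gamete_distribution(diplotype("G + R", "+ m +", m0))
  expect_equal(sort(names(gd0)), c("+|m|+", "G|+|R"))
  expect_equal(as.vector(gd0), c(0.5, 0.5), tolerance = 1e-15)
})

test_that("three-point distribution matches the coincidence closed form", {
  for (cfg in list(c(0.035, 0.035, 1), c(0.1, 0.2, 0.5),
                   c(0.05, 0.3, 0), c(0.12, 0.07, 0.8))) {
    r1 <- cfg[1]; r2 <- cfg[2]; cc <- cfg[3]
    m <- genetic_map(c("A", "B", "C"), r = c(r1, r2), coincidence = cc)
    gd <- gamete_distribution(diplotype(c("A1", "B1", "C1"),
                                        c("A2", "B2", "C2"), m))
    cls <- three_point_class_probs(r1, r2, cc)
    expect_equal(gd_prob(gd, "A1|B1|C1"), unname(cls["parental"]))
    expect_equal(gd_prob(gd, "A2|B1|C1"), unname(cls["single1"]))
    expect_equal(gd_prob(gd, "A1|B1|C2"), unname(cls["single2"]))
    expect_equal(gd_prob(gd, "A1|B2|C1"), unname(cls["double"]))
    expect_equal(sum(gd), 1, tolerance = 1e-12)
    expect_true(all(gd >= 0))
    # reciprocal haplotypes are equally frequent
    expect_equal(gd_prob(gd, "A2|B2|C2"), gd_prob(gd, "A1|B1|C1"))
    expect_equal(gd_prob(gd, "A2|B1|C2"), gd_prob(gd, "A1|B2|C1"))
  }
  # the worked double-recombinant haplotype value
  m <- genetic_map(c("G", "M", "R"), r = c(0.035, 0.035), coincidence = 1)
  gd <- gamete_distribution(diplotype("G + R", "+ m +", m))
  expect_equal(gd[["G|m|R"]], 0.0006125)
})

test_that("marginal recombination over a three-point map is r1+r2-2c r1 r2", {
  grid <- expand.grid(r1 = c(0.01, 0.035, 0.1, 0.3),
                      r2 = c(0.02, 0.15), cc = c(0, 0.5, 1))
  for (i in seq_len(nrow(grid))) {
    r1 <- grid$r1[i]; r2 <- grid$r2[i]; cc <- grid$cc[i]
    gd <- gamete_distribution(informative_parent3(r1, r2, cc))
    haps <- attr(gd, "haplotypes")
    rec_ac <- (haps[, "A"] == "A1") != (haps[, "C"] == "C1")
    expect_equal(sum(gd[rec_ac]), r1 + r2 - 2 * cc * r1 * r2,
                 tolerance = 1e-12)
  }
})

test_that("collapsing the interior locus at c = 1 gives the two-point law", {
  r1 <- 0.06; r2 <- 0.09
  r13 <- r1 + r2 - 2 * r1 * r2
  m3 <- genetic_map(c("G", "M", "R"), r = c(r1, r2))
  gd3 <- gamete_distribution(diplotype("G + R", "+ m +", m3))
  haps <- attr(gd3, "haplotypes")
  key2 <- paste(haps[, "G"], haps[, "R"], sep = "|")
  collapsed <- tapply(as.numeric(gd3), key2, sum)
  m2 <- genetic_map(c("G", "R"), r = r13)
  gd2 <- gamete_distribution(diplotype("G R", "+ +", m2))
  expect_equal(collapsed[names(gd2)], gd2[names(gd2)],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("four linked loci are exact under independence, refused otherwise", {
  m4 <- genetic_map(c("A", "B", "C", "D"), r = c(0.1, 0.05, 0.2))
  gd <- gamete_distribution(diplotype(c("A1", "B1", "C1", "D1"),
                                      c("A2", "B2", "C2", "D2"), m4))
  expect_equal(sum(gd), 1, tolerance = 1e-12)
  # single-crossover haplotype: crossover only in the middle segment
  expect_equal(gd[["A1|B1|C2|D2"]], 0.9 * 0.05 * 0.8 / 2)
  m4i <- genetic_map(c("A", "B", "C", "D"), r = c(0.1, 0.05, 0.2),
                     coincidence = 0.5)
  expect_error(gamete_distribution(
    diplotype(c("A1", "B1", "C1", "D1"), c("A2", "B2", "C2", "D2"), m4i)),
    "simulator")
})

test_that("double-recombinant frequency and balancer purity closed forms", {
  expect_equal(double_recombinant_freq(0.035, 0.035, 1), 0.001225)
  expect_equal(round(double_recombinant_freq(0.035, 0.035, 1), 3), 0.001)
  expect_equal(double_recombinant_freq(0.2, 0.3, 0), 0)
  # agreement with the double-class mass of the gamete distribution
  m <- genetic_map(c("A", "B", "C"), r = c(0.1, 0.2), coincidence = 0.5)
  gd <- gamete_distribution(diplotype(c("A1", "B1", "C1"),
                                      c("A2", "B2", "C2"), m))
  expect_equal(gd[["A1|B2|C1"]] + gd[["A2|B1|C2"]],
               double_recombinant_freq(0.1, 0.2, 0.5))

  bp <- balancer_purity(0.035, 0.035)
  expect_equal(bp$contamination, 0.001225 / (1 - 0.07 + 2 * 0.001225))
  expect_equal(bp$contamination, 0.001314, tolerance = 1e-3)
  expect_equal(bp$purity, 1 - bp$contamination)
  expect_equal(balancer_purity(0, 0.07)$contamination, 0)
  expect_error(balancer_purity(0.5, 0.5, coincidence = 0), "unmarked")
})

test_that("contamination peaks at the interval midpoint", {
  total <- 0.07
  r1 <- seq(0.005, 0.065, by = 0.005)
  contam <- vapply(r1, function(x) {
    balancer_purity(x, total - x)$contamination
  }, numeric(1))
  mid <- which.min(abs(r1 - total / 2))
  expect_equal(which.max(contam), mid)
  expect_true(all(diff(contam[1:mid]) > 0))
  expect_true(all(diff(contam[mid:length(contam)]) < 0))
})

test_that("offspring distributions are Mendelian where they should be", {
  m1 <- genetic_map("A", r = numeric(0))
  self <- cross_design(diplotype("A", "a", m1))
  off <- offspring_distribution(self)
  expect_equal(off[["A / A"]], 0.25)
  expect_equal(off[["A / a"]], 0.5)
  expect_equal(off[["a / a"]], 0.25)

  # testcross to a monomorphic parent reads out the gamete classes
  m2 <- genetic_map(c("G", "R"), r = 0.078)
  het <- diplotype("G +", "+ R", m2)
  col <- diplotype("+ +", "+ +", m2)
  off2 <- offspring_distribution(cross_design(het, col))
  gd <- gamete_distribution(het)
  for (key in names(gd)) {
    expect_equal(off2[[diplo_key_for_test(key, "+|+")]], gd[[key]])
  }

  m_other <- genetic_map(c("G", "X"), r = 0.1)
  expect_error(cross_design(het, diplotype("G +", "+ X", m_other)),
               "same genetic map")
})


test_that("seed classes of the lethal-rescue self match expectation", {
  # fie-11 in trans to the line, recombination neglected: strong-both 1/4,
  # moderate-both 1/2 (the balanced heterozygotes), nonfluorescent dead 1/4
  parent <- balancer_parent(0, 0, allele = "fie")
  dist <- seed_class_distribution(
    cross_design(parent), seed_class_model("G", "R"),
    lethal = list(LOC = c("fie", "fie")))
  cls <- dist$classes
  pick <- function(g, r) cls$prob[cls$green == g & cls$red == r]
  expect_equal(pick("strong", "strong"), 0.25)
  expect_equal(pick("moderate", "moderate"), 0.5)
  expect_equal(pick("none", "none"), 0.25)
  expect_false(cls$viable[cls$green == "none" & cls$red == "none"])
  fluor <- cls$green != "none" | cls$red != "none"
  expect_equal(sum(cls$prob[fluor]), 0.75)
  expect_equal(sum(cls$prob), 1, tolerance = 1e-12)
})

test_that("posterior inverts the class model exactly when epsilon is 0", {
  # r = 0: nonfluorescent seeds are certainly homozygous mutant
  parent <- balancer_parent(0, 0)
  post <- genotype_posterior(cross_design(parent), "nonfluorescent")
  expect_equal(nrow(post), 1L)
  expect_equal(post$prob, 1)
  expect_equal(post$genotype, "+|m|+ / +|m|+")

  # dosage classes separate the three genotypes of the genotyping scheme
  dist <- seed_class_distribution(cross_design(parent))
  strong <- genotype_posterior(dist, list(green = "strong", red = "strong"))
  expect_equal(strong$genotype, "G|+|R / G|+|R")
  expect_equal(strong$prob, 1)

  expect_error(genotype_posterior(dist, list(green = "strong",
                                             red = "none")),
               "zero probability")
})

test_that("posterior for an unlinked line leaves mutants at one quarter", {
  map <- genetic_map(list(c("G", "R"), "MUT"), r = list(0.2, numeric(0)))
  parent <- diplotype(c("G", "R", "+"), c("+", "+", "m"), map)
  post <- genotype_posterior(cross_design(parent), "fluorescent")
  mm <- vapply(strsplit(post$genotype, " / ", fixed = TRUE), function(h) {
    all(endsWith(h, "|m"))
  }, logical(1))
  expect_equal(sum(post$prob[mm]), 0.25, tolerance = 1e-12)
})

test_that("posterior at an interior locus matches the closed form", {
  for (cfg in list(c(0.042, 0.042, 1), c(0.02, 0.05, 0.6))) {
    r1 <- cfg[1]; r2 <- cfg[2]; cc <- cfg[3]
    parent <- balancer_parent(r1, r2, coincidence = cc)
    post <- genotype_posterior(cross_design(parent), "nonfluorescent")
    dbl <- cc * r1 * r2
    closed <- ((1 - r1 - r2 + dbl) / (1 - r1 - r2 + 2 * dbl))^2
    expect_equal(post$prob[post$genotype == "+|m|+ / +|m|+"], closed,
                 tolerance = 1e-12)
  }
})

test_that("misclassification moves posterior mass as the confusion model says", {
  # moderate-both seeds of the genotyping self: with per-channel adjacent
  # confusion, some homozygous seeds leak into the moderate class, so the
  # expected-genotype concordance drops below 1 (to roughly 97% here)
  eps <- 0.03
  parent <- balancer_parent(0.015, 0.015)
  dist <- seed_class_distribution(cross_design(parent),
                                  seed_class_model("G", "R", epsilon = eps))
  post <- genotype_posterior(dist, list(green = "moderate",
                                        red = "moderate"))
  het <- post$prob[post$genotype == "+|m|+ / G|+|R"]
  expect_gt(het, 0.9)
  expect_lt(het, 1)

  # Monte Carlo oracle over the same model within 3 binomial SE
  seeds <- simulate_cross(cross_design(parent), 2e5,
                          model = seed_class_model("G", "R", epsilon = eps),
                          seed = 101)
  mod <- seeds$green_obs == "moderate" & seeds$red_obs == "moderate"
  p_hat <- mean(seeds$genotype[mod] == "+|m|+ / G|+|R")
  se <- sqrt(het * (1 - het) / sum(mod))
  expect_lt(abs(p_hat - het), 3 * se)
})

test_that("separation scheme recovers the expected recombinant classes", {
  # symmetric limit: crossovers fall on either side of the mutation pair
  # with equal probability, so the two major classes are near one half
  sep <- separation_scheme(0.03, 1e-6, 0.03)
  expect_equal(unname(sep["both_mutations"]), 0.5, tolerance = 1e-3)
  expect_equal(unname(sep["neither_mutation"]), 0.5, tolerance = 1e-3)
  expect_lt(sep["first_only"] + sep["second_only"], 1e-4)
  expect_equal(unname(sep["not_single_recombinant"]), 0)
  expect_equal(sum(sep), 1, tolerance = 1e-12)

  # 0.6 Mb / 45 kb / 0.6 Mb at a uniform rate: the mixed classes take
  # about 45/1245 of the recombinant mass
  rate <- 0.056 / 1e6   # fractions proportional to physical length
  sep2 <- separation_scheme(6e5 * rate, 4.5e4 * rate, 6e5 * rate)
  mixed <- unname(sep2["first_only"] + sep2["second_only"])
  expect_equal(mixed, 45 / 1245, tolerance = 0.05)

  # the opposite selection class mirrors the classification
  sep3 <- separation_scheme(6e5 * rate, 4.5e4 * rate, 6e5 * rate,
                            selected = "strong_green_moderate_red")
  expect_equal(unname(sep3["both_mutations"]),
               unname(sep2["both_mutations"]), tolerance = 1e-10)

  # misclassified non-recombinants appear only when epsilon > 0
  sep4 <- separation_scheme(0.03, 0.002, 0.03, epsilon = 0.02)
  expect_gt(sep4["not_single_recombinant"], 0)
})

test_that("rescue scheme composes lethality, recombination and rescue", {
  base <- rescue_scheme(0, 0, tau = 0)
  expect_equal(unname(base["fluorescent_viable"]), 0.75)
  expect_equal(unname(base["nonfluorescent_dead"]), 0.25)
  expect_equal(sum(base), 1, tolerance = 1e-12)

  # tau = 0, r > 0: every nonfluorescent viable seed is a double-
  # recombination derived heterozygote
  r <- rescue_scheme(0.042, 0.042, tau = 0)
  expect_equal(unname(r["nonfluorescent_rescued_homozygote"]), 0)
  expect_gt(r["nonfluorescent_recombinant_heterozygote"], 0)

  # closed-form composition of the rescued vs recombinant split
  tau <- 0.01; r1 <- 0.042; r2 <- 0.042
  rr <- rescue_scheme(r1, r2, tau = tau)
  q_m <- (1 - r1 - r2 + r1 * r2) / 2   # unmarked parental gamete
  q_t <- r1 * r2 / 2                   # unmarked double-recombinant gamete
  expect_equal(unname(rr["nonfluorescent_rescued_homozygote"]),
               tau * q_m^2, tolerance = 1e-12)
  expect_equal(unname(rr["nonfluorescent_recombinant_heterozygote"]),
               2 * q_m * q_t + q_t^2, tolerance = 1e-12)
  expect_equal(sum(rr), 1, tolerance = 1e-12)
})

test_that("screen planning sample sizes solve the geometric bound", {
  expect_equal(required_sample_size(0.5, 0.95), 5L)
  expect_equal(required_sample_size(0.001, 0.95), 2995L)
  expect_equal(required_sample_size(1 - 1e-9, 0.95), 1L)
  expect_error(required_sample_size(0, 0.95), "positive")
  expect_error(required_sample_size(0.1, 1), "confidence")
  # the bound is tight: one fewer seed misses the confidence target
  n <- required_sample_size(0.03, 0.9)
  expect_gte(1 - (1 - 0.03)^n, 0.9)
  expect_lt(1 - (1 - 0.03)^(n - 1), 0.9)
})
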