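# Exact probability engine for traffic-line crossing schemes.
#
# A genetic map holds one or more linkage groups, each an ordered set of
# loci with per-segment recombination fractions and a scalar coefficient of
# coincidence c applied to adjacent-segment double crossovers. Marker loci
# use "+" for the absent-insertion allele; any other allele label counts as
# one reporter copy when seed fluorescence dosage is computed.

#' Construct a genetic map
#'
#' @param loci Character vector of locus names in map order (one linkage
#'   group), or a list of such vectors (several independently assorting
#'   groups).
#' @param r Numeric vector of per-segment recombination fractions
#'   (`length(loci) - 1`), or a list of such vectors matching `loci`.
#'   Each fraction must lie in `[0, 0.5]`.
#' @param coincidence Coefficient of coincidence in `[0, 1]` applied to
#'   adjacent-segment double crossovers (1 = no interference), recycled
#'   across groups.
#' @return A `genetic_map` object.
#' @examples
#' genetic_map(c("G", "FIE", "R"), r = c(0.042, 0.042))
#' @export
genetic_map <- function(loci, r = numeric(0), coincidence = 1) {
  if (!is.list(loci)) loci <- list(loci)
  if (!is.list(r)) r <- if (length(loci) == 1L) list(r) else
    stop_tl("r must be a list when loci has several groups")
  if (length(r) != length(loci)) stop_tl("loci and r group counts differ")
  coincidence <- rep_len(coincidence, length(loci))
  groups <- Map(function(l, rr, cc) {
    if (length(rr) != length(l) - 1L) {
      stop_tl("group with %d loci needs %d segment fractions, got %d",
              length(l), length(l) - 1L, length(rr))
    }
    if (any(rr < 0 | rr > 0.5)) {
      stop_tl("segment recombination fractions must lie in [0, 0.5]")
    }
    if (cc < 0 || cc > 1) stop_tl("coincidence must lie in [0, 1]")
    if (anyDuplicated(l)) stop_tl("duplicate locus names in a group")
    list(loci = l, r = rr, coincidence = cc)
  }, loci, r, as.list(coincidence))
  all_loci <- unlist(lapply(groups, `[[`, "loci"))
  if (anyDuplicated(all_loci)) stop_tl("locus names must be unique across groups")
  structure(list(groups = groups, loci = all_loci), class = "genetic_map")
}

parse_haplotype <- function(h, loci) {
  if (is.character(h) && length(h) == 1L && length(loci) > 1L) {
    h <- strsplit(trimws(h), "\\s+")[[1]]
  }
  if (length(h) != length(loci)) {
    stop_tl("haplotype has %d alleles but the map has %d loci",
            length(h), length(loci))
  }
  stats::setNames(as.character(h), loci)
}

#' Construct a diplotype (unordered pair of haplotypes)
#'
#' Haplotypes are given as character vectors of alleles in map order, or as
#' single space-separated strings (`"G + R"`). Marker presence is any
#' allele other than `"+"`.
#'
#' @param h1,h2 The two haplotypes.
#' @param map A [genetic_map()].
#' @return A `diplotype` object.
#' @examples
#' m <- genetic_map(c("G", "FIE", "R"), r = c(0.042, 0.042))
#' diplotype("G + R", "+ fie +", m)
#' @export
diplotype <- function(h1, h2, map) {
  stopifnot(inherits(map, "genetic_map"))
  structure(list(h1 = parse_haplotype(h1, map$loci),
                 h2 = parse_haplotype(h2, map$loci),
                 map = map), class = "diplotype")
}

# Gamete distribution for one linkage group: matrix of haplotypes (rows)
# with a prob vector. Closed three-point form carries the coincidence
# coefficient; for k segments with c = 1, crossovers in disjoint segments
# are independent and all 2^(k-1) crossover patterns are enumerated.
group_gamete_dist <- function(h1, h2, r, coincidence) {
  k <- length(h1)
  if (k == 1L) {
    haps <- rbind(h1, h2)
    probs <- c(0.5, 0.5)
  } else if (k == 3L && coincidence != 1) {
    r1 <- r[1]; r2 <- r[2]; cc <- coincidence
    dbl <- cc * r1 * r2
    classes <- list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE),
                    c(TRUE, TRUE))
    cls_prob <- c((1 - r1 - r2 + dbl) / 2, (r1 - dbl) / 2,
                  (r2 - dbl) / 2, dbl / 2)
    if (any(cls_prob < -1e-12)) stop_tl("invalid r/coincidence combination")
    haps <- NULL; probs <- numeric(0)
    for (start in 1:2) {
      for (j in seq_along(classes)) {
        strand <- cumsum(c(start - 1, classes[[j]])) %% 2
        hap <- ifelse(strand == 0, h1, h2)
        haps <- rbind(haps, hap)
        probs <- c(probs, cls_prob[j])
      }
    }
  } else {
    if (coincidence != 1 && k > 3L) {
      stop_tl(paste("maps with more than 3 linked loci support only",
                    "coincidence = 1 in the exact engine; use the meiosis",
                    "simulator (simulate_gametes) for interference"))
    }
    patterns <- as.matrix(expand.grid(rep(list(c(0, 1)), k - 1L)))
    pat_prob <- apply(patterns, 1, function(x) prod(ifelse(x == 1, r, 1 - r)))
    haps <- NULL; probs <- numeric(0)
    for (start in 1:2) {
      for (j in seq_len(nrow(patterns))) {
        strand <- cumsum(c(start - 1, patterns[j, ])) %% 2
        hap <- ifelse(strand == 0, h1, h2)
        haps <- rbind(haps, hap)
        probs <- c(probs, pat_prob[j] / 2)
      }
    }
  }
  rownames(haps) <- NULL
  list(haps = haps, probs = probs)
}

hap_key <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  do.call(paste, c(split(m, col(m)), sep = "|"))
}

#' Exact gamete haplotype distribution of a parent
#'
#' Two linked loci segregate as parental types `(1 - r)/2` each and
#' recombinant types `r/2` each. Three linked loci use the coincidence-
#' adjusted closed form: double crossovers `c r1 r2 / 2` per haplotype,
#' single-region types `(r_i - c r1 r2)/2`, parental types
#' `(1 - r1 - r2 + c r1 r2)/2`. Larger groups are enumerated under
#' independent segment crossovers (`c = 1` only; with interference, use the
#' meiosis simulator). Unlinked groups combine by independence.
#'
#' @param parent A [diplotype()].
#' @return A `gamete_distribution`: named numeric vector of probabilities
#'   keyed by `"allele|allele|..."` haplotype strings, with the allele
#'   matrix in `attr(, "haplotypes")` and locus names in `attr(, "loci")`.
#' @examples
#' m <- genetic_map(c("G", "R"), r = 0.078)
#' gamete_distribution(diplotype("G +", "+ R", m))
#' @export
gamete_distribution <- function(parent) {
  stopifnot(inherits(parent, "diplotype"))
  map <- parent$map
  dists <- lapply(map$groups, function(g) {
    idx <- match(g$loci, map$loci)
    group_gamete_dist(parent$h1[idx], parent$h2[idx], g$r, g$coincidence)
  })
  haps <- dists[[1]]$haps
  probs <- dists[[1]]$probs
  if (length(dists) > 1L) {
    for (d in dists[-1]) {
      i <- rep(seq_len(nrow(haps)), times = nrow(d$haps))
      j <- rep(seq_len(nrow(d$haps)), each = nrow(haps))
      haps <- cbind(haps[i, , drop = FALSE], d$haps[j, , drop = FALSE])
      probs <- probs[i] * d$probs[j]
    }
  }
  # restore map locus order
  ord <- match(map$loci, unlist(lapply(map$groups, `[[`, "loci")))
  haps <- haps[, ord, drop = FALSE]
  colnames(haps) <- map$loci
  keys <- hap_key(haps)
  agg <- rowsum(probs, keys)
  probs_out <- stats::setNames(agg[, 1], rownames(agg))
  probs_out <- probs_out[probs_out > 0]   # drop structurally absent types
  hap_out <- haps[match(names(probs_out), keys), , drop = FALSE]
  rownames(hap_out) <- names(probs_out)
  structure(probs_out, haplotypes = hap_out, loci = map$loci,
            class = "gamete_distribution")
}

#' Frequency of doubly recombinant gametes
#'
#' Total probability that a gamete carries an exchange in both segments
#' flanking an interior locus: `c * r1 * r2`. At the catalog's average
#' half-interval fractions (0.035 each side) and no interference this is
#' about one chromosome per thousand -- the rate at which a balancer's
#' unmarked product acquires the marked chromosome's interior allele.
#'
#' @param r1,r2 Segment recombination fractions in `[0, 0.5]`.
#' @param coincidence Coefficient of coincidence in `[0, 1]`.
#' @return The double-recombinant gamete frequency.
#' @examples
#' double_recombinant_freq(0.035, 0.035, 1)  # ~1/1000
#' @export
double_recombinant_freq <- function(r1, r2, coincidence = 1) {
  if (any(c(r1, r2) < 0 | c(r1, r2) > 0.5)) {
    stop_tl("r1 and r2 must lie in [0, 0.5]")
  }
  if (coincidence < 0 || coincidence > 1) stop_tl("coincidence must lie in [0, 1]")
  coincidence * r1 * r2
}

#' Balancer purity at an interior locus
#'
#' For a heterozygote carrying a doubly marked chromosome over an unmarked
#' one, a gamete showing neither marker is either the parental unmarked
#' chromosome or a double recombinant that has picked up the marked
#' chromosome's allele at the interior locus. The contamination probability
#' is `c r1 r2 / (1 - r1 - r2 + 2 c r1 r2)`; its complement is the purity.
#' Contamination is maximal when the locus sits at the genetic midpoint of
#' the interval and falls toward either marker.
#'
#' @param r1,r2 Recombination fractions between the locus and the two
#'   flanking markers; `r1 + r2` must be below 1.
#' @param coincidence Coefficient of coincidence in `[0, 1]`.
#' @return List with `contamination` (probability the unmarked gamete
#'   carries the marked chromosome's interior allele) and
#'   `purity = 1 - contamination`.
#' @examples
#' balancer_purity(0.035, 0.035)$contamination  # ~0.0013
#' @export
balancer_purity <- function(r1, r2, coincidence = 1) {
  if (any(c(r1, r2) < 0 | c(r1, r2) > 0.5)) {
    stop_tl("r1 and r2 must lie in [0, 0.5]")
  }
  dbl <- double_recombinant_freq(r1, r2, coincidence)
  denom <- 1 - r1 - r2 + 2 * dbl
  if (denom <= 0) stop_tl("degenerate map: no unmarked gametes exist")
  contamination <- dbl / denom
  list(contamination = contamination, purity = 1 - contamination)
}

#' Define a cross between two parents sharing a map
#'
#' @param parent1 A [diplotype()].
#' @param parent2 A [diplotype()]; defaults to `parent1` (selfing).
#' @return A `cross_design` object.
#' @export
cross_design <- function(parent1, parent2 = parent1) {
  stopifnot(inherits(parent1, "diplotype"), inherits(parent2, "diplotype"))
  if (!identical(parent1$map$loci, parent2$map$loci)) {
    stop_tl("parents must share the same genetic map")
  }
  structure(list(parent1 = parent1, parent2 = parent2,
                 map = parent1$map), class = "cross_design")
}

diplo_key <- function(k1, k2) {
  swap <- k2 < k1
  paste(ifelse(swap, k2, k1), ifelse(swap, k1, k2), sep = " / ")
}

#' Exact offspring diplotype distribution of a cross
#'
#' Convolves the two parental gamete distributions; selfing uses the same
#' parent twice. Diplotype keys are order-free (`"hap / hap"` with the
#' lexicographically smaller haplotype first).
#'
#' @param cross A [cross_design()].
#' @return An `offspring_distribution`: named probability vector over
#'   diplotype keys, with locus names in `attr(, "loci")`.
#' @export
offspring_distribution <- function(cross) {
  stopifnot(inherits(cross, "cross_design"))
  g1 <- gamete_distribution(cross$parent1)
  g2 <- gamete_distribution(cross$parent2)
  k1 <- names(g1); k2 <- names(g2)
  i <- rep(seq_along(k1), times = length(k2))
  j <- rep(seq_along(k2), each = length(k1))
  keys <- diplo_key(k1[i], k2[j])
  probs <- as.numeric(g1)[i] * as.numeric(g2)[j]
  agg <- rowsum(probs, keys)
  out <- stats::setNames(agg[, 1], rownames(agg))
  structure(out, loci = attr(g1, "loci"), class = "offspring_distribution")
}

split_diplo_key <- function(key) strsplit(key, " / ", fixed = TRUE)

diplo_alleles <- function(key, loci) {
  parts <- split_diplo_key(key)[[1]]
  lapply(parts, function(p) {
    stats::setNames(strsplit(p, "|", fixed = TRUE)[[1]], loci)
  })
}

#' Seed fluorescence dosage model
#'
#' Seed fluorescence intensity is dosage-coded on the diploid embryo: 0, 1
#' or 2 copies of a reporter give none / moderate / strong intensity in
#' that channel, which is what allows homozygotes and heterozygotes to be
#' told apart by eye. `epsilon` is a per-seed, per-channel probability of
#' misclassification to an adjacent intensity class (moderate splits its
#' epsilon evenly between none and strong), independent between channels.
#'
#' @param green,red Names of the GFP and DsRed marker loci on the map.
#' @param epsilon Adjacent-intensity misclassification probability in
#'   `[0, 0.5]`; default 0 (perfect scoring).
#' @return A `seed_class_model` object.
#' @export
seed_class_model <- function(green = "G", red = "R", epsilon = 0) {
  if (epsilon < 0 || epsilon > 0.5) stop_tl("epsilon must lie in [0, 0.5]")
  structure(list(green = green, red = red, epsilon = epsilon),
            class = "seed_class_model")
}

INTENSITIES <- c("none", "moderate", "strong")

# Row-stochastic confusion matrix over intensity classes for a given
# epsilon: mass epsilon moves to adjacent classes (split evenly when two).
intensity_confusion <- function(epsilon) {
  M <- diag(3) * (1 - epsilon)
  M[1, 2] <- epsilon
  M[3, 2] <- epsilon
  M[2, 1] <- epsilon / 2
  M[2, 3] <- epsilon / 2
  dimnames(M) <- list(true = INTENSITIES, observed = INTENSITIES)
  M
}

marker_dosage <- function(alleles_pair, locus) {
  sum(vapply(alleles_pair, function(a) a[[locus]] != "+", logical(1)))
}

genotype_is_lethal <- function(alleles_pair, lethal) {
  for (locus in names(lethal)) {
    pair <- sort(vapply(alleles_pair, function(a) a[[locus]], character(1)))
    if (identical(pair, sort(as.character(lethal[[locus]])))) return(TRUE)
  }
  FALSE
}

#' Joint seed-class distribution of a cross
#'
#' Maps every offspring diplotype to its (green intensity, red intensity,
#' viability, phenotype) class under the dosage model, applies the
#' adjacent-intensity misclassification independently per channel, and
#' aggregates. Lethality acts after genotype formation and before
#' observation: dead seeds remain observable (shrivelled seeds are still
#' scored for fluorescence).
#'
#' @param offspring An [offspring_distribution()] (or a [cross_design()],
#'   which is expanded first).
#' @param model A [seed_class_model()].
#' @param lethal Named list of lethal genotypes, e.g.
#'   `list(FIE = c("fie", "fie"))`: a seed is inviable when its unordered
#'   allele pair at the named locus matches.
#' @param phenotype Optional `function(a1, a2)` receiving the two named
#'   allele vectors of a diplotype and returning a phenotype label;
#'   default labels every seed `""`.
#' @return A `seed_class_distribution` list: `$classes`, a data frame over
#'   `(green, red, viable, phenotype)` with probabilities, and `$joint`,
#'   the underlying genotype-by-observed-class table used for posteriors.
#' @export
seed_class_distribution <- function(offspring, model = seed_class_model(),
                                    lethal = list(), phenotype = NULL) {
  if (inherits(offspring, "cross_design")) {
    offspring <- offspring_distribution(offspring)
  }
  stopifnot(inherits(offspring, "offspring_distribution"))
  loci <- attr(offspring, "loci")
  for (locus in c(model$green, model$red)) {
    if (!locus %in% loci) stop_tl("marker locus '%s' is not on the map", locus)
  }
  conf <- intensity_confusion(model$epsilon)
  keys <- names(offspring)
  joint <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    al <- diplo_alleles(keys[i], loci)
    g_true <- INTENSITIES[marker_dosage(al, model$green) + 1L]
    r_true <- INTENSITIES[marker_dosage(al, model$red) + 1L]
    viable <- !genotype_is_lethal(al, lethal)
    label <- if (is.null(phenotype)) "" else phenotype(al[[1]], al[[2]])
    g_obs <- rep(INTENSITIES, times = 3)
    r_obs <- rep(INTENSITIES, each = 3)
    p_obs <- conf[g_true, g_obs] * conf[r_true, r_obs]
    keep <- p_obs > 0
    joint[[i]] <- data.frame(
      genotype = keys[i], green = g_obs[keep], red = r_obs[keep],
      green_true = g_true, red_true = r_true,
      viable = viable, phenotype = label,
      prob = offspring[[i]] * p_obs[keep], stringsAsFactors = FALSE)
  }
  joint <- do.call(rbind, joint)
  # "#" sentinel keeps the phenotype field non-empty so strsplit is stable
  cls_key <- paste(joint$green, joint$red, joint$viable,
                   paste0("#", joint$phenotype), sep = "\r")
  agg <- rowsum(joint$prob, cls_key)
  parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  classes <- data.frame(green = parts[, 1], red = parts[, 2],
                        viable = parts[, 3] == "TRUE",
                        phenotype = sub("^#", "", parts[, 4]),
                        prob = agg[, 1], stringsAsFactors = FALSE)
  rownames(classes) <- NULL
  classes <- classes[order(-classes$prob), ]
  structure(list(classes = classes, joint = joint, model = model,
                 loci = loci),
            class = "seed_class_distribution")
}

# Resolve a class specification into a logical filter over rows of the
# joint table. Accepts "fluorescent"/"nonfluorescent", a list of observed
# intensities (green = ..., red = ..., viable = ...), or a predicate
# function over the joint data frame.
class_filter <- function(joint, class) {
  if (is.function(class)) return(class(joint))
  if (is.character(class) && length(class) == 1L) {
    fluor <- joint$green != "none" | joint$red != "none"
    return(switch(class,
      fluorescent = fluor,
      nonfluorescent = !fluor,
      stop_tl("unknown seed class '%s'", class)))
  }
  if (is.list(class)) {
    keep <- rep(TRUE, nrow(joint))
    for (field in names(class)) {
      if (!field %in% c("green", "red", "viable", "phenotype")) {
        stop_tl("unknown class field '%s'", field)
      }
      keep <- keep & joint[[field]] %in% class[[field]]
    }
    return(keep)
  }
  stop_tl("unsupported class specification")
}

#' Genotype posterior given an observed seed class
#'
#' Bayes inversion of [seed_class_distribution()]: the conditional
#' distribution over offspring genotypes given that a seed shows a
#' particular fluorescence class. This is the calculation behind reading a
#' genotype off a seed: e.g. the nonfluorescent seeds of a mutant/TL
#' heterozygote self are almost all homozygous mutant, failing only
#' through double recombination inside the marked interval.
#'
#' @param dist A [seed_class_distribution()] (or a [cross_design()], which
#'   is expanded with `model`, `lethal`, `phenotype`).
#' @param class Seed class to condition on: `"fluorescent"`,
#'   `"nonfluorescent"`, a list such as
#'   `list(green = "moderate", red = "moderate")`, or a predicate function
#'   over the joint table.
#' @param model,lethal,phenotype Passed to [seed_class_distribution()]
#'   when `dist` is a cross design.
#' @return A `genotype_posterior` data frame (`genotype`, `prob`), sorted
#'   by decreasing probability; the conditioning class probability is in
#'   `attr(, "class_prob")`.
#' @export
genotype_posterior <- function(dist, class, model = seed_class_model(),
                               lethal = list(), phenotype = NULL) {
  if (inherits(dist, "cross_design")) {
    dist <- seed_class_distribution(dist, model, lethal, phenotype)
  }
  stopifnot(inherits(dist, "seed_class_distribution"))
  joint <- dist$joint
  keep <- class_filter(joint, class)
  mass <- sum(joint$prob[keep])
  if (mass <= 0) stop_tl("conditioning seed class has zero probability")
  agg <- rowsum(joint$prob[keep], joint$genotype[keep])
  out <- data.frame(genotype = rownames(agg), prob = agg[, 1] / mass,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- out[order(-out$prob), ]
  structure(out, class_prob = mass,
            class = c("genotype_posterior", "data.frame"))
}

#' Recombinant-class distribution in the linked-mutation separation scheme
#'
#' To separate two tightly linked mutations held in trans to a traffic
#' line, F2 seeds are screened for a strong/moderate dosage asymmetry
#' between the channels: such a seed carries one fully marked chromosome
#' and one single-marker recombinant chromosome. Conditioning on the
#' selected class, this returns the distribution of the recombinant
#' chromosome's alleles at the two interior loci: with the mutations near
#' the middle of the interval, roughly equal numbers carry both mutations
#' or neither, and only crossovers falling between the two mutations give
#' single-mutation chromosomes.
#'
#' @param r_g1 Recombination fraction between the GFP marker and the first
#'   interior locus.
#' @param r_12 Fraction between the two interior loci.
#' @param r_2r Fraction between the second interior locus and the DsRed
#'   marker.
#' @param selected `"strong_red_moderate_green"` (recombinant carries the
#'   DsRed marker only) or `"strong_green_moderate_red"`.
#' @param epsilon Seed misclassification probability; with `epsilon > 0`
#'   some selected seeds are misclassified non-recombinants, reported in
#'   the `"not_single_recombinant"` category.
#' @param m1,m2 Allele labels of the two interior mutations (defaults
#'   `"m1"`, `"m2"`).
#' @return A named probability vector over
#'   `c("both_mutations", "neither_mutation", "first_only", "second_only",
#'   "not_single_recombinant")`, conditioned on the selected seed class;
#'   the selected-class probability is in `attr(, "class_prob")`.
#' @export
separation_scheme <- function(r_g1, r_12, r_2r,
                              selected = c("strong_red_moderate_green",
                                           "strong_green_moderate_red"),
                              epsilon = 0, m1 = "m1", m2 = "m2") {
  selected <- match.arg(selected)
  map <- genetic_map(c("G", "L1", "L2", "R"), r = c(r_g1, r_12, r_2r))
  parent <- diplotype(c("G", "+", "+", "R"), c("+", m1, m2, "+"), map)
  dist <- seed_class_distribution(cross_design(parent),
                                  seed_class_model("G", "R", epsilon))
  if (selected == "strong_red_moderate_green") {
    class <- list(red = "strong", green = "moderate")
    single_marker <- "R"; other_marker <- "G"
  } else {
    class <- list(green = "strong", red = "moderate")
    single_marker <- "G"; other_marker <- "R"
  }
  post <- genotype_posterior(dist, class)
  categories <- c("both_mutations", "neither_mutation", "first_only",
                  "second_only", "not_single_recombinant")
  out <- stats::setNames(numeric(length(categories)), categories)
  for (i in seq_len(nrow(post))) {
    al <- diplo_alleles(post$genotype[i], dist$loci)
    has_single <- vapply(al, function(a) {
      a[[single_marker]] != "+" && a[[other_marker]] == "+"
    }, logical(1))
    has_both <- vapply(al, function(a) {
      a[[single_marker]] != "+" && a[[other_marker]] != "+"
    }, logical(1))
    if (sum(has_single) == 1L && sum(has_both) == 1L) {
      rec <- al[[which(has_single)]]
      carries1 <- rec[["L1"]] == m1
      carries2 <- rec[["L2"]] == m2
      cat_name <- if (carries1 && carries2) "both_mutations"
        else if (!carries1 && !carries2) "neither_mutation"
        else if (carries1) "first_only" else "second_only"
    } else {
      cat_name <- "not_single_recombinant"
    }
    out[cat_name] <- out[cat_name] + post$prob[i]
  }
  structure(out, class_prob = attr(post, "class_prob"))
}

#' T1 seed-category distribution in the transgene rescue scheme
#'
#' A lethal allele is balanced in trans to a traffic line, the heterozygote
#' is transformed (each T1 seed independently transgenic with probability
#' `tau`; the transgene rescues homozygous lethality), and the plant is
#' selfed. Neglecting recombination, three quarters of the T1 seeds are
#' fluorescent and viable and one quarter are nonfluorescent homozygous
#' mutants that die unless transgenic. The only other source of
#' nonfluorescent viable seeds is double recombination within the marked
#' interval, which returns a wild-type allele to an unmarked chromosome.
#'
#' @param r1,r2 Recombination fractions between the lethal locus and the
#'   two flanking markers.
#' @param coincidence Coefficient of coincidence.
#' @param tau Transformation rate in `[0, 1]`.
#' @param lethal_allele Label of the lethal allele (default `"m"`).
#' @return Named probability vector over `c("fluorescent_viable",
#'   "fluorescent_dead", "nonfluorescent_dead",
#'   "nonfluorescent_rescued_homozygote",
#'   "nonfluorescent_recombinant_heterozygote")`; sums to 1. The last
#'   category contains the double-recombination-derived nonfluorescent
#'   seeds that carry at least one wild-type allele (almost all
#'   heterozygotes).
#' @examples
#' rescue_scheme(0, 0, tau = 0)  # 75% fluorescent, 25% nonfluorescent dead
#' @export
rescue_scheme <- function(r1, r2, coincidence = 1, tau = 0,
                          lethal_allele = "m") {
  if (tau < 0 || tau > 1) stop_tl("tau must lie in [0, 1]")
  map <- genetic_map(c("G", "LOC", "R"), r = c(r1, r2),
                     coincidence = coincidence)
  parent <- diplotype(c("G", "+", "R"), c("+", lethal_allele, "+"), map)
  dist <- seed_class_distribution(
    cross_design(parent), seed_class_model("G", "R", epsilon = 0),
    lethal = stats::setNames(list(c(lethal_allele, lethal_allele)), "LOC"))
  joint <- dist$joint
  fluor <- joint$green != "none" | joint$red != "none"
  homo <- !joint$viable    # lethal homozygote (pre-rescue viability)
  p <- function(keep) sum(joint$prob[keep])
  out <- c(
    fluorescent_viable = p(fluor & !homo) + tau * p(fluor & homo),
    fluorescent_dead = (1 - tau) * p(fluor & homo),
    nonfluorescent_dead = (1 - tau) * p(!fluor & homo),
    nonfluorescent_rescued_homozygote = tau * p(!fluor & homo),
    nonfluorescent_recombinant_heterozygote = p(!fluor & !homo)
  )
  out
}

#' Seeds needed to observe at least one seed of a class
#'
#' Smallest n with `1 - (1 - p)^n >= confidence`: the planning calculation
#' for screens targeting rare classes such as recombinants between tightly
#' linked loci.
#'
#' @param p_class Per-seed probability of the target class, in `(0, 1]`.
#' @param confidence Required probability of at least one hit, in `(0, 1)`.
#' @return Integer sample size.
#' @examples
#' required_sample_size(0.001, 0.95)  # 2995 seeds
#' @export
required_sample_size <- function(p_class, confidence = 0.95) {
  if (p_class <= 0) stop_tl("p_class must be positive (impossible event)")
  if (p_class > 1) stop_tl("p_class must be at most 1")
  if (confidence <= 0 || confidence >= 1) {
    stop_tl("confidence must lie in (0, 1)")
  }
  if (p_class >= 1) return(1L)
  n <- ceiling(log1p(-confidence) / log1p(-p_class))
  max(1L, as.integer(n))
}
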