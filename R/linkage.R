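# Linkage estimation from fluorescence-classed testcross seed counts.
#
# In a testcross of a doubly marked heterozygote to unmarked Col, the four
# seed fluorescence classes read the gamete haplotypes directly. With the
# markers in trans (repulsion) the single-colour classes are parental and
# the both-colour / nonfluorescent classes are recombinant; in coupling the
# roles swap. The recombination fraction is the pooled recombinant
# proportion, and the printed tables use the direct rule cM = 100 r.

#' Construct a seed-class count table
#'
#' @param n_red,n_green,n_both,n_none Non-negative counts of dsRed-only,
#'   GFP-only, doubly fluorescent and nonfluorescent seeds.
#' @param phase `"repulsion"` (markers in trans in the scored parent; the
#'   catalog testcross design) or `"coupling"` (markers in cis).
#' @return A `count_table` list.
#' @examples
#' count_table(196, 194, 21, 12)
#' @export
count_table <- function(n_red, n_green, n_both, n_none,
                        phase = c("repulsion", "coupling")) {
  phase <- match.arg(phase)
  counts <- c(n_red = n_red, n_green = n_green,
              n_both = n_both, n_none = n_none)
  if (any(counts < 0) || anyNA(counts)) {
    stop_tl("seed counts must be non-negative")
  }
  structure(list(n_red = n_red, n_green = n_green, n_both = n_both,
                 n_none = n_none, phase = phase, N = sum(counts)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("Seed-class counts (%s phase): dsRed %d, GFP %d, both %d, none %d (N = %d)\n",
              x$phase, x$n_red, x$n_green, x$n_both, x$n_none, x$N))
  invisible(x)
}

recombinant_count <- function(counts) {
  if (counts$phase == "repulsion") counts$n_both + counts$n_none
  else counts$n_red + counts$n_green
}

parental_count <- function(counts) counts$N - recombinant_count(counts)

# Wilson score interval for a binomial proportion; well behaved at the
# small recombinant counts typical of short intervals.
wilson_ci <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Estimate the recombination fraction from a seed-class count table
#'
#' Pools the two recombinant classes (phase-dependent), estimates the
#' fraction as `R / N` with `N` the class sum, attaches a Wilson score confidence
#' interval, and converts to cM by the direct rule (100 r, reported at one
#' decimal place, matching the printed catalog convention).
#'
#' An estimate above 0.5 is reported as computed but flagged
#' (`phase_suspect`), since it usually signals a mis-specified phase.
#'
#' @param counts A [count_table()].
#' @param level Confidence level for the Wilson interval (default 0.95).
#' @return A `recomb_estimate` list: `r_hat`, `cM` (1 dp), `se`, `ci`,
#'   `ci_method`, `level`, `N`, `R`, `phase`, `phase_suspect`.
#' @examples
#' estimate_r(count_table(196, 194, 21, 12))  # catalog line 1.30: 7.8 cM
#' @export
estimate_r <- function(counts, level = 0.95) {
  stopifnot(inherits(counts, "count_table"))
  if (counts$N < 1) stop_tl("count table is empty (N = 0)")
  R <- recombinant_count(counts)
  r_hat <- R / counts$N
  structure(list(
    r_hat = r_hat,
    cM = round_half_up(100 * r_hat, 1),
    se = sqrt(r_hat * (1 - r_hat) / counts$N),
    ci = wilson_ci(R, counts$N, level),
    ci_method = "wilson",
    level = level,
    N = counts$N,
    R = R,
    phase = counts$phase,
    phase_suspect = r_hat > 0.5
  ), class = "recomb_estimate")
}

#' @export
print.recomb_estimate <- function(x, ...) {
  cat(sprintf("r = %.4f (%d/%d), %.1f cM; %g%% Wilson CI [%.4f, %.4f]%s\n",
              x$r_hat, x$R, x$N, x$cM, 100 * x$level, x$ci["low"],
              x$ci["high"],
              if (x$phase_suspect) " [r > 0.5: phase suspect]" else ""))
  invisible(x)
}

#' Convert a recombination estimate to a cM/Mb rate
#'
#' The rate is the 1-dp cM value divided by the physical interval in Mb,
#' reported at one decimal place -- the convention of the printed catalog,
#' which divides the rounded cM, not the raw proportion.
#'
#' @param estimate A `recomb_estimate`.
#' @param interval_nt Physical interval between the markers in nucleotides.
#' @return A `rate_estimate` list: `cM_per_Mb` (1 dp), `cM_per_Mb_raw`,
#'   `interval_Mb`.
#' @examples
#' recomb_rate(estimate_r(count_table(196, 194, 21, 12)), 903452)  # 8.6
#' @export
recomb_rate <- function(estimate, interval_nt) {
  stopifnot(inherits(estimate, "recomb_estimate"))
  if (interval_nt <= 0) stop_tl("interval_nt must be positive")
  mb <- interval_nt / 1e6
  raw <- estimate$cM / mb
  structure(list(cM_per_Mb = round_half_up(raw, 1), cM_per_Mb_raw = raw,
                 interval_Mb = mb), class = "rate_estimate")
}

#' Map functions: recombination fraction to genetic distance
#'
#' `direct` is the printed-table convention (cM = 100 r, no interference
#' correction); `haldane` and `kosambi` are provided for calibrating the
#' meiosis simulator, whose crossover process is specified in Morgans.
#'
#' @param r Recombination fraction(s); in `[0, 1]` for `direct`, `[0, 0.5)`
#'   for `haldane`/`kosambi`.
#' @param rule One of `"direct"`, `"haldane"`, `"kosambi"`.
#' @return Genetic distance(s) in cM.
#' @export
map_function <- function(r, rule = c("direct", "haldane", "kosambi")) {
  rule <- match.arg(rule)
  if (any(r < 0)) stop_tl("r must be non-negative")
  if (rule == "direct") {
    if (any(r > 1)) stop_tl("r must be at most 1 under the direct rule")
    return(100 * r)
  }
  if (any(r >= 0.5)) {
    stop_tl("r must be below 0.5 under the %s map function", rule)
  }
  switch(rule,
    haldane = -50 * log(1 - 2 * r),
    kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r))
  )
}

# Inverse map functions, in Morgans, used when laying simulator loci out on
# a physical axis of genetic length.
map_function_inverse_morgans <- function(r, rule = c("haldane", "kosambi",
                                                     "direct")) {
  rule <- match.arg(rule)
  if (any(r < 0)) stop_tl("r must be non-negative")
  if (rule == "direct") return(r)
  if (any(r >= 0.5)) stop_tl("r must be below 0.5 under %s", rule)
  switch(rule,
    haldane = -0.5 * log(1 - 2 * r),
    kosambi = 0.25 * log((1 + 2 * r) / (1 - 2 * r))
  )
}

#' Compare recombinant fractions of two lines by an exact 2x2 test
#'
#' Fisher's exact test on the (recombinant, parental) counts of the two
#' lines; used to ask whether two lines spanning the same region recombine
#' at different rates (as observed for lines whose insertions suppress
#' local recombination).
#'
#' @param a,b [count_table()] objects.
#' @return List with `odds_ratio` (conditional MLE), `p_value` (two-sided),
#'   `method`, and the underlying 2x2 `table`.
#' @export
compare_lines <- function(a, b) {
  stopifnot(inherits(a, "count_table"), inherits(b, "count_table"))
  if (a$N < 1 || b$N < 1) stop_tl("both count tables must be non-empty")
  tab <- matrix(c(recombinant_count(a), parental_count(a),
                  recombinant_count(b), parental_count(b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(line = c("a", "b"),
                                class = c("recombinant", "parental")))
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
       method = "Fisher exact (two-sided)", table = tab)
}

#' Segregation-distortion diagnostics within class pairs
#'
#' Exact two-sided binomial tests of a 1:1 split within the parental pair
#' and within the recombinant pair. A lopsided recombinant split (e.g. 18
#' recombinants on one flank vs 6 on the other) can reveal an insertion-
#' associated rearrangement suppressing recombination on one side.
#'
#' @param counts A [count_table()].
#' @return List with `parental_1to1_p` and `recombinant_1to1_p`; a pair
#'   with zero total yields `NA` (test not applicable).
#' @export
distortion_tests <- function(counts) {
  stopifnot(inherits(counts, "count_table"))
  if (counts$N < 1) stop_tl("count table is empty (N = 0)")
  if (counts$phase == "repulsion") {
    par_pair <- c(counts$n_red, counts$n_green)
    rec_pair <- c(counts$n_both, counts$n_none)
  } else {
    par_pair <- c(counts$n_both, counts$n_none)
    rec_pair <- c(counts$n_red, counts$n_green)
  }
  one_to_one <- function(pair) {
    if (sum(pair) == 0) return(NA_real_)
    stats::binom.test(pair[1], sum(pair), p = 0.5)$p.value
  }
  list(parental_1to1_p = one_to_one(par_pair),
       recombinant_1to1_p = one_to_one(rec_pair))
}

#' Recompute genetic distances for every catalog row
#'
#' Applies [estimate_r()] and [recomb_rate()] to each row, using the class
#' sum as N, and tabulates the recomputed values next to the printed ones.
#'
#' @param catalog A `tl_catalog`.
#' @param level Confidence level for Wilson intervals.
#' @return Data frame with one row per line: `line_id`, `N`, `r_hat`,
#'   `cM`, `ci_low`, `ci_high`, `cM_per_Mb`, `printed_cM`, `printed_rate`,
#'   `cM_ok` / `rate_ok` agreement indicators at the integrity-check bands
#'   (0.1 cM, 0.2 cM/Mb).
#' @export
recompute_catalog <- function(catalog, level = 0.95) {
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    row <- catalog[i, ]
    est <- estimate_r(count_table(row$n_red, row$n_green, row$n_both,
                                  row$n_none), level = level)
    rate <- recomb_rate(est, row$interval_nt)
    data.frame(
      line_id = row$line_id, N = est$N, r_hat = est$r_hat, cM = est$cM,
      ci_low = est$ci[["low"]], ci_high = est$ci[["high"]],
      cM_per_Mb = rate$cM_per_Mb,
      printed_cM = row$printed_cM, printed_rate = row$printed_rate,
      cM_ok = abs(row$printed_cM - 100 * est$r_hat) <= 0.1 + 1e-9,
      rate_ok = abs(row$printed_rate - rate$cM_per_Mb_raw) <= 0.2 + 1e-9,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
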