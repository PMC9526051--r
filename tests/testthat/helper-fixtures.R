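# Shared builders for tests.

# Write a catalog TSV from a data frame of raw columns and load it back.
write_and_load_catalog <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  load_catalog(path)
}

# A self-consistent synthetic catalog row: printed values recomputed from
# the counts so it carries no integrity flags.
consistent_row <- function(line_id = "1.99", upper_pos = 1000,
                           lower_pos = 500000, counts = c(100, 100, 5, 5)) {
  N <- sum(counts)
  cM <- round_half_up(100 * (counts[3] + counts[4]) / N, 1)
  nt <- lower_pos - upper_pos
  data.frame(
    abrc_id = "CS00000", line_id = line_id,
    upper_marker = "CG1", upper_pos = upper_pos,
    lower_marker = "CR1", lower_pos = lower_pos,
    interval_nt = nt, n_red = counts[1], n_green = counts[2],
    n_both = counts[3], n_none = counts[4], printed_total = N,
    printed_cM = cM, printed_rate = round_half_up(cM / (nt / 1e6), 1),
    stringsAsFactors = FALSE)
}

# Three-point trans-configuration parent: markers on one strand, a mutant
# allele on the other, as in a TL/mutant heterozygote.
balancer_parent <- function(r1, r2, coincidence = 1, allele = "m") {
  map <- genetic_map(c("G", "LOC", "R"), r = c(r1, r2),
                     coincidence = coincidence)
  diplotype(c("G", "+", "R"), c("+", allele, "+"), map)
}

# Fully informative three-locus parent for simulator strand tracking.
informative_parent3 <- function(r1, r2, coincidence = 1) {
  map <- genetic_map(c("A", "B", "C"), r = c(r1, r2),
                     coincidence = coincidence)
  diplotype(c("A1", "B1", "C1"), c("A2", "B2", "C2"), map)
}

# Probability of a haplotype key in a gamete distribution; structurally
# absent haplotypes have probability zero.
gd_prob <- function(gd, key) {
  if (key %in% names(gd)) gd[[key]] else 0
}

diplo_key_for_test <- function(k1, k2) {
  paste(sort(c(k1, k2)), collapse = " / ")
}

cli_read_counts_for_test <- function(path) {
  trafficlines:::cli_read_counts(path)
}

# Independent closed-form three-point gamete class probabilities
# (parental, single in region 1, single in region 2, double), per
# haplotype within the class.
three_point_class_probs <- function(r1, r2, cc) {
  dbl <- cc * r1 * r2
  c(parental = (1 - r1 - r2 + dbl) / 2,
    single1 = (r1 - dbl) / 2,
    single2 = (r2 - dbl) / 2,
    double = dbl / 2)
}
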