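# Catalog of short-interval traffic lines: loading, validation, interval
# queries, coverage summaries and BED export.
#
# A traffic line (TL) is a stock carrying two linked seed-expressed
# fluorescent transgenes -- pNAP::eGFP ("CG" markers) and pNAP::DsRed
# ("CR" markers) -- in cis on one chromosome of the Col accession.
# Each catalog row records the two insertion positions, the physical
# interval between them, and the four fluorescence classes counted in the
# testcross used to measure the genetic distance between the markers.

CATALOG_COLUMNS <- c(
  "abrc_id", "line_id", "upper_marker", "upper_pos", "lower_marker",
  "lower_pos", "interval_nt", "n_red", "n_green", "n_both", "n_none",
  "printed_total", "printed_cM", "printed_rate"
)

marker_channel <- function(marker_id) {
  ifelse(startsWith(marker_id, "CG"), "green",
         ifelse(startsWith(marker_id, "CR"), "red", NA_character_))
}

#' Load a traffic-line catalog from TSV
#'
#' Reads a tab-separated catalog of traffic lines. Each row describes one
#' line: its ABRC stock ID, line ID (`<chromosome>.<serial>`), the upper and
#' lower marker insertions with 1-based positions on the Col reference, the
#' printed interval length, the four testcross seed-class counts
#' (dsRed-only, GFP-only, both, nonfluorescent), and the printed total, cM
#' and cM/Mb values. Numeric fields may contain comma thousands separators.
#'
#' The testcross behind the counts placed the two markers in trans
#' (repulsion), so the single-colour classes are parental and the
#' both-colour and nonfluorescent classes are recombinant.
#'
#' @param path Path to a catalog TSV with header
#'   `abrc_id line_id upper_marker upper_pos lower_marker lower_pos
#'   interval_nt n_red n_green n_both n_none printed_total printed_cM
#'   printed_rate`.
#' @return A `tl_catalog` data frame, one row per line in file order, with
#'   parsed numeric columns, a `chromosome` column taken from the integer
#'   part of `line_id`, and `upper_channel`/`lower_channel` columns.
#' @examples
#' cat <- load_catalog(tl_catalog_path())
#' nrow(cat)
#' @export
load_catalog <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(raw), CATALOG_COLUMNS)) {
    stop_tl("catalog header mismatch: expected columns %s",
            paste(CATALOG_COLUMNS, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    out <- empty_catalog()
    return(out)
  }
  num_cols <- c("upper_pos", "lower_pos", "interval_nt", "n_red", "n_green",
                "n_both", "n_none", "printed_total", "printed_cM",
                "printed_rate")
  out <- raw
  for (cc in num_cols) {
    v <- strip_commas(raw[[cc]])
    bad <- which(is.na(v))
    if (length(bad)) {
      stop_tl("malformed value in column '%s' for line %s", cc,
              raw$line_id[bad[1]])
    }
    out[[cc]] <- v
  }
  out$chromosome <- as.integer(sub("\\..*$", "", out$line_id))
  if (anyNA(out$chromosome)) {
    stop_tl("malformed line_id '%s': expected <chromosome>.<serial>",
            out$line_id[which(is.na(out$chromosome))[1]])
  }
  out$upper_channel <- marker_channel(out$upper_marker)
  out$lower_channel <- marker_channel(out$lower_marker)
  for (side in c("upper", "lower")) {
    bad <- which(is.na(out[[paste0(side, "_channel")]]))
    if (length(bad)) {
      stop_tl("unknown marker prefix '%s' for line %s (expected CG or CR)",
              out[[paste0(side, "_marker")]][bad[1]], out$line_id[bad[1]])
    }
  }
  counts <- as.matrix(out[, c("n_red", "n_green", "n_both", "n_none")])
  if (any(counts < 0)) {
    stop_tl("negative seed count for line %s",
            out$line_id[which(rowSums(counts < 0) > 0)[1]])
  }
  bad <- which(out$upper_pos >= out$lower_pos)
  if (length(bad)) {
    stop_tl("upper marker not above lower marker for line %s",
            out$line_id[bad[1]])
  }
  bad <- which(out$upper_channel == out$lower_channel)
  if (length(bad)) {
    stop_tl("line %s does not pair one green with one red marker",
            out$line_id[bad[1]])
  }
  class(out) <- c("tl_catalog", "data.frame")
  out
}

empty_catalog <- function() {
  out <- data.frame(matrix(nrow = 0, ncol = length(CATALOG_COLUMNS)))
  names(out) <- CATALOG_COLUMNS
  out$chromosome <- integer(0)
  out$upper_channel <- character(0)
  out$lower_channel <- character(0)
  class(out) <- c("tl_catalog", "data.frame")
  out
}

#' Path to the packaged traffic-line catalog
#'
#' The packaged TSV transcribes the published table of 162 short-interval
#' lines covering the five Arabidopsis chromosomes.
#'
#' @return File path of the installed catalog TSV.
#' @export
tl_catalog_path <- function() {
  system.file("extdata", "traffic_lines.tsv", package = "trafficlines",
              mustWork = TRUE)
}

#' Load the packaged traffic-line catalog
#'
#' @return A `tl_catalog` data frame with 162 rows.
#' @seealso [load_catalog()], [tl_catalog_path()]
#' @export
traffic_line_catalog <- function() {
  load_catalog(tl_catalog_path())
}

# Class-sum sample size: the four seed-class counts. The printed "Total"
# column is retained for flagging only -- several published rows (e.g. 1.70,
# 5.21) print totals that contradict the class sum while their cM is
# consistent with the class sum.
catalog_class_sum <- function(catalog) {
  catalog$n_red + catalog$n_green + catalog$n_both + catalog$n_none
}

#' Check a catalog for internal inconsistencies
#'
#' Recomputes every derivable quantity and flags rows where the printed
#' value disagrees:
#' \describe{
#'   \item{length_mismatch}{printed interval length differs from the marker
#'     position difference.}
#'   \item{total_mismatch}{printed total differs from the sum of the four
#'     seed-class counts.}
#'   \item{cM_mismatch}{printed cM differs by more than 0.1 from
#'     `100 * (n_both + n_none) / class sum`.}
#'   \item{rate_mismatch}{printed cM/Mb differs by more than 0.2 from the
#'     recomputed cM (rounded to 1 dp) divided by the interval in Mb.}
#'   \item{duplicate_counts}{two rows share an identical count vector.}
#' }
#' The tolerance bands absorb the mixed rounding conventions of the printed
#' table (some rows round half up, some truncate at 1 dp).
#'
#' @param catalog A `tl_catalog`.
#' @return Data frame with columns `line_id`, `flag_kind`, `detail`;
#'   zero rows when the catalog is internally consistent.
#' @examples
#' flags <- check_integrity(traffic_line_catalog())
#' subset(flags, line_id == "1.70")
#' @export
check_integrity <- function(catalog) {
  flags <- list()
  add <- function(line_id, kind, detail) {
    flags[[length(flags) + 1L]] <<- data.frame(
      line_id = line_id, flag_kind = kind, detail = detail,
      stringsAsFactors = FALSE)
  }
  if (nrow(catalog) == 0L) return(empty_flags())
  N <- catalog_class_sum(catalog)
  rc_cM <- 100 * (catalog$n_both + catalog$n_none) / N
  rc_rate <- round_half_up(rc_cM, 1) / (catalog$interval_nt / 1e6)
  eps <- 1e-9
  for (i in seq_len(nrow(catalog))) {
    row <- catalog[i, ]
    posdiff <- row$lower_pos - row$upper_pos
    if (row$interval_nt != posdiff) {
      add(row$line_id, "length_mismatch",
          sprintf("printed interval %s nt vs position difference %s nt",
                  format(row$interval_nt, big.mark = ""), posdiff))
    }
    if (row$printed_total != N[i]) {
      add(row$line_id, "total_mismatch",
          sprintf("printed total %d vs class sum %d",
                  row$printed_total, N[i]))
    }
    if (abs(row$printed_cM - rc_cM[i]) > 0.1 + eps) {
      add(row$line_id, "cM_mismatch",
          sprintf("printed %.1f cM vs recomputed %.4f cM",
                  row$printed_cM, rc_cM[i]))
    }
    if (abs(row$printed_rate - rc_rate[i]) > 0.2 + eps) {
      add(row$line_id, "rate_mismatch",
          sprintf("printed %.1f cM/Mb vs recomputed %.4f cM/Mb",
                  row$printed_rate, rc_rate[i]))
    }
  }
  key <- paste(catalog$n_red, catalog$n_green, catalog$n_both, catalog$n_none)
  dup <- key %in% key[duplicated(key)]
  for (i in which(dup)) {
    partners <- setdiff(catalog$line_id[key == key[i]], catalog$line_id[i])
    add(catalog$line_id[i], "duplicate_counts",
        sprintf("count vector (%s) shared with line(s) %s",
                key[i], paste(partners, collapse = ", ")))
  }
  if (length(flags) == 0L) return(empty_flags())
  do.call(rbind, flags)
}

empty_flags <- function() {
  data.frame(line_id = character(0), flag_kind = character(0),
             detail = character(0), stringsAsFactors = FALSE)
}

#' Find lines whose marked interval spans a genomic position
#'
#' Positions are 1-based; intervals are closed, so a position equal to a
#' marker insertion site is counted as spanned.
#'
#' @param catalog A `tl_catalog`.
#' @param chromosome Integer in 1..5.
#' @param position_bp 1-based position on the Col reference.
#' @return The spanning rows, sorted by interval length ascending (the
#'   tightest balancer for the locus first).
#' @examples
#' find_spanning(traffic_line_catalog(), 3, 7230000)$line_id
#' @export
find_spanning <- function(catalog, chromosome, position_bp) {
  if (length(chromosome) != 1L || is.na(chromosome) ||
      chromosome < 1 || chromosome > 5) {
    stop_tl("chromosome must be a single integer in 1..5")
  }
  hit <- catalog$chromosome == chromosome &
    catalog$upper_pos <= position_bp & catalog$lower_pos >= position_bp
  out <- catalog[hit, , drop = FALSE]
  out <- out[order(out$interval_nt), , drop = FALSE]
  class(out) <- c("tl_catalog", "data.frame")
  out
}

#' Summarise genome coverage of a catalog
#'
#' Reports the unweighted means of the printed interval lengths (in Mb) and
#' printed cM values, and lists the uncovered gaps between the unions of
#' marked intervals on each chromosome. Two candidate genome-average
#' recombination rates are reported -- the column mean of the printed cM/Mb
#' values and the ratio of mean cM to mean Mb -- because the two averaging
#' conventions disagree for this catalog; neither is privileged.
#'
#' @param catalog A non-empty `tl_catalog`.
#' @return A list with `mean_interval_Mb`, `mean_cM` (and `_1dp` rounded
#'   companions), `rate_column_mean`, `rate_ratio_of_means`, `rate_note`,
#'   and `gaps`, a data frame of uncovered regions (1-based closed
#'   coordinates) between consecutive covered blocks per chromosome.
#' @export
coverage_summary <- function(catalog) {
  if (nrow(catalog) == 0L) stop_tl("catalog is empty")
  mean_mb <- mean(catalog$interval_nt) / 1e6
  mean_cm <- mean(catalog$printed_cM)
  gaps <- lapply(sort(unique(catalog$chromosome)), function(ch) {
    rows <- catalog[catalog$chromosome == ch, ]
    ir <- IRanges::reduce(IRanges::IRanges(start = rows$upper_pos,
                                           end = rows$lower_pos))
    gp <- IRanges::gaps(ir)   # interior gaps between covered blocks
    if (length(gp) == 0L) return(NULL)
    data.frame(chromosome = ch, gap_start = IRanges::start(gp),
               gap_end = IRanges::end(gp),
               gap_nt = IRanges::width(gp))
  })
  gaps <- do.call(rbind, gaps)
  if (is.null(gaps)) {
    gaps <- data.frame(chromosome = integer(0), gap_start = integer(0),
                       gap_end = integer(0), gap_nt = integer(0))
  }
  list(
    mean_interval_Mb = mean_mb,
    mean_interval_Mb_1dp = round_half_up(mean_mb, 1),
    mean_cM = mean_cm,
    mean_cM_1dp = round_half_up(mean_cm, 1),
    rate_column_mean = mean(catalog$printed_rate),
    rate_ratio_of_means = mean_cm / mean_mb,
    rate_note = paste("genome-average cM/Mb depends on the averaging",
                      "convention; both candidates are reported"),
    gaps = gaps
  )
}

#' Export a catalog as BED intervals
#'
#' Writes one BED record per line: `Chr<K>`, 0-based half-open interval
#' covering the marked segment, the line ID as the name, and the printed cM
#' times ten (truncated to integer) as the score.
#'
#' @param catalog A `tl_catalog`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_bed <- function(catalog, path) {
  if (nrow(catalog) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(
    chrom = paste0("Chr", catalog$chromosome),
    start = catalog$upper_pos - 1,
    end = catalog$lower_pos,
    name = catalog$line_id,
    score = trunc(catalog$printed_cM * 10 + 1e-6)
  )
  # trailing epsilon guards binary-representation slip (5.9 * 10 -> 58.999...)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(bed) > 0L) {
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
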