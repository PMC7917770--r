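# Peak-centric analyses: promoter/non-promoter partition, peak-set overlap,
# genomic feature distribution and promoter-signal gene ranking. Interval
# tables use BED conventions throughout (0-based half-open); overlap means
# sharing >= 1 bp on the same chromosome, strand-agnostic.

# Validate an interval tibble and convert to GRanges (1-based closed).
# `levels` fixes the seqlevel universe so two sets can be compared without
# seqlevel mismatches.
intervals_to_gr <- function(tbl, what = "interval", levels = NULL) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(tbl))) {
    abort(sprintf("%s table needs columns %s", what, paste(need, collapse = ", ")))
  }
  bad <- which(!(tbl$start < tbl$end) | tbl$start < 0)
  if (length(bad) > 0) {
    lab <- if ("name" %in% names(tbl)) tbl$name[bad[1]] else sprintf("row %d", bad[1])
    abort(sprintf("malformed %s '%s': need 0 <= start < end (got [%s, %s))",
                  what, lab, format(tbl$start[bad[1]]), format(tbl$end[bad[1]])))
  }
  if (is.null(levels)) levels = unique(tbl$chrom)
  GenomicRanges::GRanges(factor(tbl$chrom, levels = levels),
                         IRanges::IRanges(start = tbl$start + 1, end = tbl$end))
}

# Convert two interval tables onto a shared seqlevel universe.
gr_pair <- function(a, b, what_a = "interval", what_b = "interval") {
  lv <- union(unique(a$chrom), unique(b$chrom))
  list(a = intervals_to_gr(a, what_a, levels = lv),
       b = intervals_to_gr(b, what_b, levels = lv))
}

#' Partition peaks into promoter and non-promoter peaks
#'
#' A peak is a promoter peak iff it shares at least one base pair with any
#' promoter interval on the same chromosome (strand-agnostic); all other
#' peaks are non-promoter peaks. The two sets are an exact partition of the
#' input.
#'
#' @param peaks Interval tibble (`chrom`, `start`, `end`, ...; 0-based
#'   half-open).
#' @param promoters Interval tibble of promoter regions.
#' @return A list of class `peak_classification` with tibbles
#'   `promoter_peaks` and `nonpromoter_peaks`.
#' @export
#' @examples
#' peaks <- tibble::tibble(chrom = "chr1", start = c(100, 500), end = c(200, 600))
#' proms <- tibble::tibble(chrom = "chr1", start = 150, end = 250)
#' classify_peaks(peaks, proms)
classify_peaks <- function(peaks, promoters) {
  gr <- gr_pair(peaks, promoters, "peak", "promoter")
  hit <- GenomicRanges::countOverlaps(gr$a, gr$b) > 0
  structure(list(promoter_peaks = as_tibble(peaks[hit, , drop = FALSE]),
                 nonpromoter_peaks = as_tibble(peaks[!hit, , drop = FALSE])),
            class = "peak_classification")
}

#' @export
print.peak_classification <- function(x, ...) {
  cat(sprintf("<peak_classification> %d promoter / %d non-promoter peaks\n",
              nrow(x$promoter_peaks), nrow(x$nonpromoter_peaks)))
  invisible(x)
}

#' Pairwise overlap summary of two peak sets
#'
#' Counts, from each set's own perspective, how many of its peaks overlap
#' (>= 1 bp) at least one peak of the other set. Because overlap is
#' many-to-many the two shared counts need not agree, so both are reported
#' rather than collapsed to a single Venn number.
#'
#' @param a,b Interval tibbles (0-based half-open).
#' @return A one-row tibble with `n_a`, `n_b`, `shared_a`, `only_a`,
#'   `shared_b`, `only_b`.
#' @export
overlap_peaksets <- function(a, b) {
  gr <- gr_pair(a, b, "peak", "peak")
  gra <- gr$a; grb <- gr$b
  shared_a <- sum(GenomicRanges::countOverlaps(gra, grb) > 0)
  shared_b <- sum(GenomicRanges::countOverlaps(grb, gra) > 0)
  tibble(n_a = nrow(a), n_b = nrow(b),
         shared_a = shared_a, only_a = nrow(a) - shared_a,
         shared_b = shared_b, only_b = nrow(b) - shared_b)
}

#' Genomic feature distribution of a peak set
#'
#' Assigns each peak to the highest-precedence annotation category it
#' overlaps (default precedence promoter > exon > intron > intergenic;
#' peaks overlapping nothing are intergenic) and compares the resulting
#' fractions with the genome background — the base-pair fraction each
#' category occupies under the same precedence.
#'
#' @param peaks Interval tibble.
#' @param annotation Interval tibble with a `category` column.
#' @param chrom_sizes Tibble with `chrom` and `length`.
#' @param precedence Category precedence, most specific first; must end with
#'   `"intergenic"`.
#' @return A tibble with `category`, `n_peaks`, `peak_fraction`,
#'   `genome_bp`, `genome_fraction`; both fraction columns sum to 1.
#' @export
genomic_distribution <- function(peaks, annotation, chrom_sizes,
                                 precedence = c("promoter", "exon", "intron", "intergenic")) {
  if (nrow(annotation) == 0) abort("empty annotation")
  stopifnot("category" %in% names(annotation),
            all(c("chrom", "length") %in% names(chrom_sizes)))
  extra <- setdiff(unique(annotation$category), precedence)
  if (length(extra) > 0) {
    abort(sprintf("annotation categories outside precedence: %s",
                  paste(extra, collapse = ", ")))
  }
  if (precedence[length(precedence)] != "intergenic") {
    abort("precedence must end with 'intergenic'")
  }
  lv <- Reduce(union, list(chrom_sizes$chrom, unique(peaks$chrom),
                           unique(annotation$chrom)))
  peak_gr <- intervals_to_gr(peaks, "peak", levels = lv)
  assigned <- rep("intergenic", length(peak_gr))
  unresolved <- rep(TRUE, length(peak_gr))
  covered <- GenomicRanges::GRanges()
  genome_bp <- setNames(numeric(length(precedence)), precedence)
  for (cat in setdiff(precedence, "intergenic")) {
    sub <- annotation[annotation$category == cat, , drop = FALSE]
    if (nrow(sub) == 0) next
    cat_gr <- GenomicRanges::reduce(intervals_to_gr(sub, "annotation", levels = lv))
    hit <- GenomicRanges::countOverlaps(peak_gr, cat_gr) > 0
    assigned[unresolved & hit] <- cat
    unresolved <- unresolved & !hit
    uniq <- GenomicRanges::setdiff(cat_gr, covered)
    genome_bp[cat] <- sum(GenomicRanges::width(uniq))
    covered <- GenomicRanges::reduce(c(covered, cat_gr))
  }
  total_bp <- sum(chrom_sizes$length)
  genome_bp["intergenic"] <- total_bp - sum(GenomicRanges::width(covered))
  counts <- table(factor(assigned, levels = precedence))
  tibble(
    category = precedence,
    n_peaks = as.integer(counts),
    peak_fraction = as.numeric(counts) / length(peak_gr),
    genome_bp = as.numeric(genome_bp),
    genome_fraction = as.numeric(genome_bp) / total_bp
  )
}

#' Rank genes by aggregated promoter peak signal
#'
#' For each gene, aggregates the `signal` of every peak overlapping any of
#' its promoters (`max` by default, `sum` optional), sorts genes by
#' descending signal with ties broken deterministically by `gene_id`, and
#' returns the `top_n` genes — e.g. the "top 200 genes with the highest
#' promoter binding" set fed to [gsea_preranked()].
#'
#' @param peaks Interval tibble with a numeric `signal` column.
#' @param promoters Interval tibble with a `gene_id` column.
#' @param top_n Number of genes to return (default 200). If fewer genes
#'   carry promoter signal, all of them are returned with a warning.
#' @param aggregate `"max"` (default) or `"sum"`.
#' @return A tibble with `gene_id`, `promoter_signal`, `rank`, sorted.
#' @export
promoter_signal_rank <- function(peaks, promoters, top_n = 200,
                                 aggregate = c("max", "sum")) {
  aggregate <- match.arg(aggregate)
  stopifnot("signal" %in% names(peaks), "gene_id" %in% names(promoters))
  if (any(peaks$signal < 0)) abort("peak signal must be >= 0")
  gr <- gr_pair(peaks, promoters, "peak", "promoter")
  ov <- GenomicRanges::findOverlaps(gr$a, gr$b)
  hits <- tibble(signal = peaks$signal[S4Vectors::queryHits(ov)],
                 gene_id = promoters$gene_id[S4Vectors::subjectHits(ov)])
  agg_fun <- if (aggregate == "max") max else sum
  ranked <- hits |>
    group_by(.data$gene_id) |>
    summarise(promoter_signal = agg_fun(.data$signal), .groups = "drop") |>
    arrange(desc(.data$promoter_signal), .data$gene_id) |>
    mutate(rank = row_number())
  if (top_n > nrow(ranked)) {
    warn(sprintf("top_n = %d exceeds the %d genes with promoter signal; returning all",
                 top_n, nrow(ranked)))
    top_n <- nrow(ranked)
  }
  ranked[seq_len(top_n), , drop = FALSE]
}
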