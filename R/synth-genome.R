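#' Generate a toy genome with promoters, gene-body annotation and peaks
#'
#' Lays out `n_genes` non-overlapping gene models across `n_chroms`
#' chromosomes. Each model is a promoter of `promoter_width` bp followed by
#' exon/intron/exon blocks; uncovered sequence is intergenic. Peaks of
#' `peak_width` bp are then placed so that an expected fraction
#' `promoter_fraction` falls fully inside a promoter and the rest avoid
#' promoters entirely (rejection sampling), each carrying a positive
#' log-normal signal. All coordinates are 0-based half-open, BED style.
#'
#' @param cfg A [sim_config()].
#' @return A list with tibbles `promoters` (`chrom`, `start`, `end`,
#'   `gene_id`, `score`, `strand`), `peaks` (`chrom`, `start`, `end`,
#'   `name`, `signal`, `strand`), `annotation` (`chrom`, `start`, `end`,
#'   `category` in promoter/exon/intron) and `chrom_sizes` (`chrom`,
#'   `length`).
#' @export
gen_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(cfg$seed, 5L))
  pw <- cfg$promoter_width
  if (cfg$peak_width > pw) abort("'peak_width' must not exceed 'promoter_width'")
  footprint <- 2 * pw           # promoter + gene body
  slot <- 3 * pw                # per-gene slot; slack becomes intergenic
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  needed <- per_chrom * slot + slot
  chrom_len <- if (is.null(cfg$chrom_length)) needed else cfg$chrom_length
  if (chrom_len < needed) {
    abort(sprintf("genome too small: chromosomes of %d bp cannot hold %d gene slots of %d bp",
                  chrom_len, per_chrom, slot))
  }
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  chrom_sizes <- tibble(chrom = chroms, length = chrom_len)

  gene_chrom <- chroms[((seq_len(cfg$n_genes) - 1L) %/% per_chrom) + 1L]
  slot_idx <- (seq_len(cfg$n_genes) - 1L) %% per_chrom
  offset <- floor(runif(cfg$n_genes, 0, slot - footprint + 1))
  p_start <- slot_idx * slot + offset
  promoters <- tibble(
    chrom = gene_chrom, start = p_start, end = p_start + pw,
    gene_id = cfg$gene_ids, score = 0, strand = "+"
  )
  body <- p_start + pw
  exon_w <- floor(pw / 4)
  annotation <- bind_rows(
    tibble(chrom = gene_chrom, start = p_start, end = p_start + pw, category = "promoter"),
    tibble(chrom = gene_chrom, start = body, end = body + exon_w, category = "exon"),
    tibble(chrom = gene_chrom, start = body + exon_w, end = body + pw - exon_w, category = "intron"),
    tibble(chrom = gene_chrom, start = body + pw - exon_w, end = body + pw, category = "exon")
  )

  n_peaks <- cfg$n_peaks
  wk <- cfg$peak_width
  in_prom <- runif(n_peaks) < cfg$promoter_fraction
  peak_chrom <- character(n_peaks)
  peak_start <- numeric(n_peaks)
  n_in <- sum(in_prom)
  if (n_in > 0) {
    pick <- sample.int(cfg$n_genes, n_in, replace = TRUE)
    peak_chrom[in_prom] <- promoters$chrom[pick]
    peak_start[in_prom] <- promoters$start[pick] +
      floor(runif(n_in, 0, pw - wk + 1))
  }
  n_out <- n_peaks - n_in
  if (n_out > 0) {
    placed <- place_avoiding(promoters, chrom_sizes, n_out, wk)
    peak_chrom[!in_prom] <- placed$chrom
    peak_start[!in_prom] <- placed$start
  }
  peaks <- tibble(
    chrom = peak_chrom, start = peak_start, end = peak_start + wk,
    name = sprintf("peak_%05d", seq_len(n_peaks)),
    signal = rlnorm(n_peaks, log(10), 1),
    strand = "."
  )
  list(promoters = promoters, peaks = peaks,
       annotation = annotation, chrom_sizes = chrom_sizes)
}

# Rejection-sample n interval starts of width w avoiding all `avoid` intervals.
place_avoiding <- function(avoid, chrom_sizes, n, w, max_tries = 200L) {
  chrom <- character(n); start <- numeric(n)
  done <- 0L
  avoid_gr <- intervals_to_gr(avoid, levels = chrom_sizes$chrom)
  for (try in seq_len(max_tries)) {
    m <- (n - done) * 2L
    ci <- sample.int(nrow(chrom_sizes), m, replace = TRUE)
    cand <- tibble(chrom = chrom_sizes$chrom[ci],
                   start = floor(runif(m, 0, chrom_sizes$length[ci] - w)))
    cand$end <- cand$start + w
    hit <- GenomicRanges::countOverlaps(
      intervals_to_gr(cand, levels = chrom_sizes$chrom), avoid_gr) > 0
    ok <- cand[!hit, , drop = FALSE]
    take <- min(nrow(ok), n - done)
    if (take > 0) {
      idx <- done + seq_len(take)
      chrom[idx] <- ok$chrom[seq_len(take)]
      start[idx] <- ok$start[seq_len(take)]
      done <- done + take
    }
    if (done == n) return(list(chrom = chrom, start = start))
  }
  abort("genome too small: could not place peaks outside promoters")
}
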