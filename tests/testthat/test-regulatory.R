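# Interval analyses: half-open overlap semantics, exact partition,
# all-pairs oracles, symmetry and distribution conservation.

test_that("promoter classification follows half-open overlap conventions", {
  proms <- tibble::tibble(chrom = "chr1", start = 150, end = 250, gene_id = "g1")
  pk <- function(s, e, chrom = "chr1") tibble::tibble(chrom = chrom, start = s, end = e)
  expect_equal(nrow(classify_peaks(pk(100, 200), proms)$promoter_peaks), 1)
  # abutting half-open intervals do not overlap
  expect_equal(nrow(classify_peaks(pk(250, 300), proms)$promoter_peaks), 0)
  expect_equal(nrow(classify_peaks(pk(100, 151), proms)$promoter_peaks), 1)
  expect_equal(nrow(classify_peaks(pk(100, 200, "chr2"), proms)$promoter_peaks), 0)
  expect_error(classify_peaks(pk(200, 100), proms), "malformed")
})

test_that("classification partitions the input and matches the all-pairs oracle", {
  set.seed(31)
  for (i in 1:3) {
    peaks <- rand_intervals(1000)
    proms <- rand_intervals(200)
    cl <- classify_peaks(peaks, proms)
    expect_equal(nrow(cl$promoter_peaks) + nrow(cl$nonpromoter_peaks), nrow(peaks))
    expect_equal(sort(c(cl$promoter_peaks$name, cl$nonpromoter_peaks$name)),
                 sort(peaks$name))
    hit <- oracle_classify(peaks, proms)
    expect_setequal(cl$promoter_peaks$name, peaks$name[hit])
  }
  # order invariance
  peaks <- rand_intervals(300)
  proms <- rand_intervals(60)
  a <- classify_peaks(peaks, proms)
  b <- classify_peaks(peaks[sample(nrow(peaks)), ], proms[sample(nrow(proms)), ])
  expect_setequal(a$promoter_peaks$name, b$promoter_peaks$name)
})

test_that("peak-set overlap counts match the oracle and are symmetric", {
  set.seed(37)
  a <- rand_intervals(400)
  b <- rand_intervals(300)
  ov <- overlap_peaksets(a, b)
  hit_a <- oracle_classify(a, b)
  hit_b <- oracle_classify(b, a)
  expect_equal(ov$shared_a, sum(hit_a))
  expect_equal(ov$shared_b, sum(hit_b))
  expect_equal(ov$only_a + ov$shared_a, nrow(a))
  expect_equal(ov$only_b + ov$shared_b, nrow(b))
  rev <- overlap_peaksets(b, a)
  expect_equal(rev$shared_a, ov$shared_b)
  expect_equal(rev$shared_b, ov$shared_a)
  # identity and disjoint chromosomes
  self <- overlap_peaksets(a, a)
  expect_equal(self$shared_a, nrow(a))
  expect_equal(self$only_a, 0)
  c1 <- dplyr::mutate(a, chrom = "chrX")
  c2 <- dplyr::mutate(b, chrom = "chrY")
  expect_equal(overlap_peaksets(c1, c2)$shared_a, 0)
})

test_that("genomic distribution conserves mass and respects precedence", {
  gn <- gen_genome(sim_config(seed = 12, n_genes = 80, n_peaks = 400,
                              promoter_fraction = 1))
  gd <- genomic_distribution(gn$peaks, gn$annotation, gn$chrom_sizes)
  expect_equal(gd$peak_fraction[gd$category == "promoter"], 1)
  expect_equal(sum(gd$peak_fraction), 1, tolerance = 1e-12)
  expect_equal(sum(gd$genome_fraction), 1, tolerance = 1e-12)

  # peaks placed uniformly at random converge to the genome background
  set.seed(99)
  len <- gn$chrom_sizes$length[1]
  n <- 4000
  unif <- tibble::tibble(chrom = sample(gn$chrom_sizes$chrom, n, replace = TRUE),
                         start = floor(runif(n, 0, len - 10)))
  unif$end <- unif$start + 1   # point-like, so category = the base's category
  gd2 <- genomic_distribution(unif, gn$annotation, gn$chrom_sizes)
  expect_true(all(abs(gd2$peak_fraction - gd2$genome_fraction) <
                    4 * sqrt(gd2$genome_fraction * (1 - gd2$genome_fraction) / n) + 0.01))
  expect_error(genomic_distribution(unif, gn$annotation[0, ], gn$chrom_sizes),
               "empty")
})

test_that("promoter signal ranking matches an aggregate-then-sort oracle", {
  set.seed(41)
  for (agg in c("max", "sum")) {
    peaks <- rand_intervals(500)
    proms <- rand_intervals(120)
    proms$gene_id <- sprintf("gene%03d", sample(1:60, 120, replace = TRUE))
    or <- oracle_promoter_signal(peaks, proms, aggregate = agg)
    got <- suppressWarnings(promoter_signal_rank(peaks, proms, top_n = 1000,
                                                 aggregate = agg))
    expect_equal(got$gene_id, or$gene_id)
    expect_equal(got$promoter_signal, or$signal, tolerance = 1e-12)
  }
})

test_that("promoter signal ranking: top gene, truncation and the top_n warning", {
  proms <- tibble::tibble(chrom = "chr1", start = c(0, 1000, 2000),
                          end = c(500, 1500, 2500),
                          gene_id = c("gA", "gB", "gC"))
  peaks <- tibble::tibble(chrom = "chr1",
                          start = c(100, 1100, 1200, 5000),
                          end = c(200, 1200, 1300, 5100),
                          signal = c(7, 99, 3, 1000))
  r <- promoter_signal_rank(peaks, proms, top_n = 2)
  expect_equal(r$gene_id, c("gB", "gA"))       # the intergenic monster peak is ignored
  expect_equal(r$promoter_signal, c(99, 7))
  expect_warning(promoter_signal_rank(peaks, proms, top_n = 10), "returning all")
  rsum <- suppressWarnings(promoter_signal_rank(peaks, proms, top_n = 5,
                                                aggregate = "sum"))
  expect_equal(rsum$promoter_signal[rsum$gene_id == "gB"], 102)
})
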