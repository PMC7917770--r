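# Generators: determinism, degenerate limits, planted-structure recovery
# and value-domain invariants.

test_that("identical configs give bit-identical outputs from every generator", {
  make_all <- function() {
    cfg <- sim_config(seed = 11, n_genes = 60, n_target_lines = 4,
                      n_other_lines = 10, n_tumor = 20, n_reference = 10,
                      n_samples_survival = 20, n_peaks = 80,
                      essential_genes = "g00003",
                      overexpressed_genes = "g00004",
                      prognostic_genes = "g00005",
                      de_genes = "g00006")
    ex <- gen_expression(cfg)
    list(dep = gen_dependency(cfg), ex = ex, sv = gen_survival(cfg, ex),
         ct = gen_counts(cfg), gn = gen_genome(cfg))
  }
  expect_identical(make_all(), make_all())
})

test_that("dependency generator plants exact shifts in the zero-noise limit", {
  cfg <- sim_config(seed = 3, n_genes = 10, n_target_lines = 3,
                    n_other_lines = 5, noise_sd = 0,
                    essential_genes = c("g00002", "g00007"),
                    essential_effect = -1)
  dep <- gen_dependency(cfg)
  m <- as.matrix(dep$scores[, -1])
  tgt <- dep$groups$group == "target"
  expect_equal(unname(rowMeans(m[c(2, 7), tgt])), c(-1, -1))
  expect_equal(unname(rowMeans(m[c(2, 7), !tgt])), c(0, 0))
  expect_true(all(m[-c(2, 7), ] == 0))
})

test_that("planted dependency effect is recovered within its sampling distribution", {
  # mean of 13 target lines with noise sd 0.1: |mean - effect| < 3 * 0.1/sqrt(13)
  tol <- 3 * 0.1 / sqrt(13)
  n_ok <- 0; n_tot <- 0
  for (s in 1:200) {
    cfg <- sim_config(seed = s, n_genes = 12, n_other_lines = 20,
                      noise_sd = 0.1, essential_effect = -0.8,
                      essential_genes = sprintf("g%05d", 1:5))
    dep <- gen_dependency(cfg)
    m <- as.matrix(dep$scores[, -1])
    tgt_means <- rowMeans(m[1:5, dep$groups$group == "target"])
    n_ok <- n_ok + sum(abs(tgt_means - (-0.8)) < tol)
    n_tot <- n_tot + 5
  }
  expect_gte(n_ok / n_tot, 0.99)
})

test_that("expression generator: null medians agree and degenerate fold is exact", {
  cfg0 <- sim_config(seed = 5, n_genes = 40, n_tumor = 150, n_reference = 150)
  ex0 <- gen_expression(cfg0)
  m <- as.matrix(ex0$tpm[, -1])
  tum <- ex0$samples$group == "tumor"
  med_t <- apply(m[, tum], 1, median)
  med_r <- apply(m[, !tum], 1, median)
  expect_true(all(m >= 0))
  expect_lt(median(abs(log(med_t / med_r))), 0.2)  # sampling error only

  cfg1 <- sim_config(seed = 5, n_genes = 10, tpm_sdlog_sample = 0,
                     overexpressed_genes = "g00001", overexpressed_fold = 8)
  ex1 <- gen_expression(cfg1)
  m1 <- as.matrix(ex1$tpm[, -1])
  tum1 <- ex1$samples$group == "tumor"
  expect_equal(mean(m1[1, tum1]) / mean(m1[1, !tum1]), 8)
})

test_that("planted expression fold is recovered under default sample noise", {
  hits <- 0; tot <- 0
  for (s in 1:100) {
    cfg <- sim_config(seed = s, n_genes = 30, n_tumor = 80, n_reference = 60,
                      overexpressed_genes = sprintf("g%05d", 1:5),
                      overexpressed_fold = 4)
    ex <- gen_expression(cfg)
    enr <- expression_enrichment(ex$tpm, ex$samples, pseudocount = 0)
    est <- enr$fold_change[match(sprintf("g%05d", 1:5), enr$gene_id)]
    hits <- hits + sum(est >= 3 & est <= 5)
    tot <- tot + 5
  }
  expect_gte(hits / tot, 0.95)
})

test_that("survival generator honours censoring, positivity and its planted hazard", {
  cfg <- sim_config(seed = 9, n_genes = 20, n_tumor = 60, n_reference = 10,
                    n_samples_survival = 50, censoring_rate = 0)
  ex <- gen_expression(cfg)
  sv <- gen_survival(cfg, ex)
  expect_true(all(sv$event == 1L))
  expect_true(all(sv$time > 0))
  expect_error(
    gen_survival(sim_config(seed = 9, n_genes = 20, n_tumor = 60,
                            n_reference = 10, n_samples_survival = 50,
                            prognostic_genes = "g00001"),
                 list(tpm = ex$tpm[-1, ], samples = ex$samples)),
    "prognostic"
  )
  # censoring rate approximately achieved without planted effects
  cfg2 <- sim_config(seed = 10, n_genes = 5, n_tumor = 400, n_reference = 10,
                     n_samples_survival = 400, censoring_rate = 0.3)
  sv2 <- gen_survival(cfg2, gen_expression(cfg2))
  expect_lt(abs(mean(1 - sv2$event) - 0.3), 0.08)
})

test_that("count generator limits: deterministic fold, Poisson mode, errors", {
  cfg <- sim_config(seed = 2, n_genes = 30, de_genes = sprintf("g%05d", 1:3),
                    de_fold = 4)
  exact <- gen_counts(cfg, noise = FALSE)
  m <- as.matrix(exact$counts[, -1])
  ko <- exact$conditions$condition == "knockout"
  expect_equal(unname(rowMeans(m[1:3, ko]) / rowMeans(m[1:3, !ko])), rep(4, 3))
  expect_true(all(m == floor(m) & m >= 0))

  pois <- gen_counts(sim_config(seed = 2, n_genes = 2000, nb_dispersion = 0))
  mp <- as.matrix(pois$counts[, -1])
  expect_true(all(mp == floor(mp) & mp >= 0))
  # per-gene condition means agree within Poisson error across the matrix
  d <- (rowMeans(mp[, 1:4]) - rowMeans(mp[, 5:8])) / sqrt(rowMeans(mp) / 2)
  expect_lt(abs(mean(d)), 0.1)
  expect_error(sim_config(seed = 1, nb_dispersion = -1), "dispersion")
})

test_that("toy genome respects the promoter-overlap fraction", {
  cfg1 <- sim_config(seed = 4, n_genes = 50, n_peaks = 100, promoter_fraction = 1)
  gn1 <- gen_genome(cfg1)
  cl1 <- classify_peaks(gn1$peaks, gn1$promoters)
  expect_equal(nrow(cl1$nonpromoter_peaks), 0)

  cfg0 <- sim_config(seed = 4, n_genes = 50, n_peaks = 100, promoter_fraction = 0)
  gn0 <- gen_genome(cfg0)
  cl0 <- classify_peaks(gn0$peaks, gn0$promoters)
  expect_equal(nrow(cl0$promoter_peaks), 0)

  cfg3 <- sim_config(seed = 4, n_genes = 100, n_peaks = 1000, promoter_fraction = 0.3)
  gn3 <- gen_genome(cfg3)
  n_prom <- nrow(classify_peaks(gn3$peaks, gn3$promoters)$promoter_peaks)
  halfw <- qnorm(0.995) * sqrt(1000 * 0.3 * 0.7)
  expect_gte(n_prom, 300 - halfw)
  expect_lte(n_prom, 300 + halfw)
  expect_true(all(gn3$peaks$signal > 0))
  expect_error(sim_config(seed = 4, n_genes = 50, chrom_length = 100) |> gen_genome(),
               "too small")
})

test_that("the truth sidecar records every planted set", {
  cfg <- sim_config(seed = 1, n_genes = 30, essential_genes = "g00001",
                    overexpressed_genes = "g00002", prognostic_genes = "g00003",
                    de_genes = "g00004")
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(cfg, path)
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(truth$essential$genes, "g00001")
  expect_equal(truth$overexpressed$genes, "g00002")
  expect_equal(truth$prognostic$hazard_ratio, 2.5)
  expect_equal(truth$differential$genes, "g00004")
})
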