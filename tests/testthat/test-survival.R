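# From-first-principles survival stack: stratification, product-limit
# estimator, log-rank test and Cox regression, validated against closed
# forms, hand calculations, an established survival library and
# simulation.

test_that("quantile stratification reproduces sort-and-slice behaviour", {
  d <- tibble::tibble(sample_id = letters[1:8], expr = 1:8)
  s <- stratify_by_quantile(d, expr, q = 0.25)
  expect_equal(d$sample_id[s$strat_group == "low"], c("a", "b"))
  expect_equal(d$sample_id[s$strat_group == "high"], c("g", "h"))

  s50 <- stratify_by_quantile(d, expr, q = 0.5)
  expect_false(any(s50$strat_group == "mid"))

  set.seed(13)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    x <- rnorm(n)
    q <- runif(1, 0.1, 0.45)
    grp <- stratify_by_quantile(tibble::tibble(v = x), v, q = q)$strat_group
    # oracle: sort and slice at the same quantile definition
    expect_equal(sum(grp == "low"), sum(x <= quantile(x, q)))
    expect_equal(sum(grp == "high"), sum(x >= quantile(x, 1 - q)))
  }
  expect_error(stratify_by_quantile(tibble::tibble(v = rep(1, 10)), v), "identical")
  expect_error(stratify_by_quantile(tibble::tibble(v = 1:10), v, q = 0.6), "q")
})

test_that("Kaplan-Meier estimate matches closed forms and a hand-computed curve", {
  km <- km_estimate(tibble::tibble(time = 1:3, event = 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  cens <- km_estimate(tibble::tibble(time = c(2, 3, 7), event = 0))
  expect_true(all(cens$survival == 1))

  # 10 samples, mixed censoring; product-limit values worked out by hand:
  # t=1 (d=1,n=10) S=9/10; t=2 (d=1,n=8) S=9/10*7/8; t=4 (d=2,n=6) S=...*4/6;
  # t=6 (d=1,n=2) after censors at 4 and 5: S=...*1/2
  d <- tibble::tibble(time = c(1, 1.5, 2, 3, 4, 4, 4, 5, 6, 7),
                      event = c(1, 0, 1, 0, 1, 1, 0, 0, 1, 0))
  km2 <- km_estimate(d)
  s_at <- function(t) km2$survival[max(which(km2$time <= t))]
  expect_equal(s_at(1), 0.9)
  expect_equal(s_at(2), 0.9 * 7 / 8)
  expect_equal(s_at(4), 0.9 * 7 / 8 * 4 / 6)
  expect_equal(s_at(6), 0.9 * 7 / 8 * 4 / 6 * 1 / 2)
  expect_true(all(diff(km2$survival) <= 0))

  # no censoring: equals the empirical survival function
  t3 <- c(3, 1, 4, 1, 5, 9, 2, 6)
  km3 <- km_estimate(tibble::tibble(time = t3, event = 1))
  expect_equal(km3$survival, 1 - ecdf(t3)(km3$time))
  expect_error(km_estimate(tibble::tibble(time = numeric(), event = numeric())),
               "empty")
})

test_that("log-rank test: identical groups give chi2 0, hand-tabulated toy agrees", {
  d <- tibble::tibble(time = rep(c(1, 2, 3, 5, 8, 13), 2),
                      event = rep(c(1, 1, 0, 1, 1, 0), 2),
                      grp = rep(c("A", "B"), each = 6))
  lr <- logrank_test(d, grp)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)

  # 6 + 6 toy data tabulated by hand per event time
  toy <- tibble::tibble(
    time = c(1, 3, 5, 7, 9, 11, 2, 4, 6, 8, 10, 12),
    event = c(1, 1, 1, 0, 1, 1, 1, 0, 1, 1, 0, 0),
    grp = rep(c("A", "B"), each = 6)
  )
  lr2 <- logrank_test(toy, grp)
  o_e <- 0; v <- 0
  for (u in sort(unique(toy$time[toy$event == 1]))) {
    at <- toy$time >= u
    n <- sum(at); n1 <- sum(at & toy$grp == "A")
    dt <- sum(toy$time == u & toy$event == 1)
    d1 <- sum(toy$time == u & toy$event == 1 & toy$grp == "A")
    o_e <- o_e + d1 - dt * n1 / n
    v <- v + dt * (n1 / n) * (1 - n1 / n) * (n - dt) / (n - 1)
  }
  expect_equal(lr2$statistic, o_e^2 / v, tolerance = 1e-12)
  expect_error(logrank_test(dplyr::mutate(toy, event = 0), grp), "events")
})

test_that("log-rank and Cox agree with the survival package on random data", {
  skip_if_not_installed("survival")
  set.seed(42)
  for (i in 1:20) {
    n <- sample(30:80, 1)
    d <- tibble::tibble(time = round(rexp(n, 0.1), 1) + 0.5,
                        event = rbinom(n, 1, 0.7),
                        x = rbinom(n, 1, 0.5))
    if (sum(d$event) < 2 || var(d$x) == 0) next
    fit <- cox_hr(d, x)
    or <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                          ties = "breslow")
    expect_equal(fit$log_hr, unname(coef(or)), tolerance = 1e-6)
    expect_equal(fit$se, sqrt(unname(vcov(or)[1, 1])), tolerance = 1e-6)
    fe <- cox_hr(d, x, ties = "efron")
    oe <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                          ties = "efron")
    expect_equal(fe$log_hr, unname(coef(oe)), tolerance = 1e-6)
    lr <- logrank_test(d, x)
    sd <- survival::survdiff(survival::Surv(time, event) ~ x, data = d)
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-6)
  }
})

test_that("swapping group labels negates the Cox log hazard ratio", {
  set.seed(3)
  d <- rand_survdata(120, hr = 2, censor_rate = 0.2)
  f1 <- cox_hr(d, x)
  f2 <- cox_hr(dplyr::mutate(d, x = 1L - x), x)
  expect_equal(f1$log_hr, -f2$log_hr, tolerance = 1e-10)
})

test_that("Cox estimates are centred on zero under the null", {
  set.seed(17)
  betas <- replicate(500, cox_hr(rand_survdata(500, hr = 1), x)$log_hr)
  expect_lt(abs(mean(betas)), 0.05)
})

test_that("complete separation is flagged, not thrown", {
  d <- tibble::tibble(time = c(1, 2, 3, 10, 11, 12),
                      event = c(1, 1, 1, 0, 0, 0),
                      x = c(1, 1, 1, 0, 0, 0))
  fit <- cox_hr(d, x)
  expect_false(fit$converged)
  expect_true(is.infinite(fit$ci_upper) || is.infinite(fit$se))
})

test_that("log-rank power: a hazard ratio of 3 is detected at n = 200", {
  set.seed(23)
  hits <- 0
  for (i in 1:100) {
    d <- rand_survdata(200, hr = 3, censor_rate = 0.2)
    if (logrank_test(d, x)$p_value < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("hazard screen flags constant genes, is order-invariant and ranks planted genes first", {
  cfg <- sim_config(seed = 6, n_genes = 40, n_tumor = 300, n_reference = 20,
                    n_samples_survival = 300,
                    prognostic_genes = "g00001", prognostic_hr = 2.5)
  ex <- gen_expression(cfg)
  sv <- gen_survival(cfg, ex)
  sv$flatgene <- 1
  hs <- hazard_screen(sv, genes = c(sprintf("g%05d", 1:10), "flatgene"))
  expect_equal(hs$note[hs$gene_id == "flatgene"], "constant_or_missing_expression")
  expect_true(is.na(hs$hr[hs$gene_id == "flatgene"]))

  perm_genes <- rev(sprintf("g%05d", 1:10))
  hs_perm <- hazard_screen(sv, genes = perm_genes)
  expect_equal(hs_perm[match(hs$gene_id[1:10], hs_perm$gene_id), ],
               hs[1:10, ])

  # planted prognostic gene outranks the nulls in nearly all seeds
  wins <- 0
  for (s in 1:50) {
    cfg2 <- sim_config(seed = s, n_genes = 20, n_tumor = 300, n_reference = 20,
                       n_samples_survival = 300,
                       prognostic_genes = "g00001", prognostic_hr = 2.5)
    ex2 <- gen_expression(cfg2)
    sv2 <- gen_survival(cfg2, ex2)
    hs2 <- hazard_screen(sv2)
    if (which.max(hs2$hr) == 1) wins <- wins + 1
  }
  expect_gte(wins / 50, 0.95)
})
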