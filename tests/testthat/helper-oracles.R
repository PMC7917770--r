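# Brute-force reference implementations, kept deliberately naive and
# independent of the package internals, plus small fixture builders.

oracle_group_means <- function(mat, labels) {
  out <- data.frame(gene_id = rownames(mat), mean_target = NA_real_,
                    mean_other = NA_real_)
  for (i in seq_len(nrow(mat))) {
    tv <- c(); ov <- c()
    for (j in seq_len(ncol(mat))) {
      v <- mat[i, j]
      if (is.na(v)) next
      if (labels[j] == "target") tv <- c(tv, v) else ov <- c(ov, v)
    }
    if (length(tv) > 0) out$mean_target[i] <- sum(tv) / length(tv)
    if (length(ov) > 0) out$mean_other[i] <- sum(ov) / length(ov)
  }
  out
}

oracle_fold <- function(mat, labels, pseudocount) {
  out <- data.frame(gene_id = rownames(mat), tumor = NA_real_,
                    reference = NA_real_, fold = NA_real_)
  for (i in seq_len(nrow(mat))) {
    tv <- mat[i, labels == "tumor"]
    rv <- mat[i, labels == "reference"]
    out$tumor[i] <- sum(tv) / length(tv)
    out$reference[i] <- sum(rv) / length(rv)
    out$fold[i] <- (out$tumor[i] + pseudocount) / (out$reference[i] + pseudocount)
  }
  out
}

# 0-based half-open overlap of two single intervals
bp_overlaps <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 && s1 < e2 && s2 < e1
}

oracle_classify <- function(peaks, promoters) {
  hit <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(promoters))) {
      if (bp_overlaps(peaks$chrom[i], peaks$start[i], peaks$end[i],
                      promoters$chrom[j], promoters$start[j], promoters$end[j])) {
        hit[i] <- TRUE
        break
      }
    }
  }
  hit
}

oracle_promoter_signal <- function(peaks, promoters, aggregate = "max") {
  sig <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(promoters))) {
      if (bp_overlaps(peaks$chrom[i], peaks$start[i], peaks$end[i],
                      promoters$chrom[j], promoters$start[j], promoters$end[j])) {
        g <- promoters$gene_id[j]
        sig[[g]] <- c(sig[[g]], peaks$signal[i])
      }
    }
  }
  if (length(sig) == 0) return(data.frame(gene_id = character(), signal = numeric()))
  agg <- vapply(sig, if (aggregate == "max") max else sum, numeric(1))
  out <- data.frame(gene_id = names(agg), signal = unname(agg))
  out[order(-out$signal, out$gene_id), , drop = FALSE]
}

oracle_size_factors <- function(mat) {
  keep <- apply(mat, 1, function(r) all(r > 0))
  sub <- mat[keep, , drop = FALSE]
  geo <- apply(sub, 1, function(r) exp(mean(log(r))))
  out <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) out[j] <- median(sub[, j] / geo)
  out
}

# Full running-sum walk, independently coded.
oracle_es <- function(metric_desc, is_hit, weight_p) {
  n <- length(metric_desc)
  k <- sum(is_hit)
  w <- abs(metric_desc)^weight_p
  denom <- sum(w[is_hit])
  rs <- 0; best_max <- 0; best_min <- 0
  for (i in seq_len(n)) {
    if (is_hit[i]) rs <- rs + w[i] / denom else rs <- rs - 1 / (n - k)
    if (rs > best_max) best_max <- rs
    if (rs < best_min) best_min <- rs
  }
  if (best_max >= -best_min) best_max else best_min
}

rand_intervals <- function(n, chroms = c("chrA", "chrB"), genome_len = 10000,
                           max_width = 300) {
  start <- floor(runif(n, 0, genome_len - max_width))
  width <- ceiling(runif(n, 1, max_width))
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start, end = start + width,
                 name = sprintf("iv%04d", seq_len(n)),
                 signal = round(runif(n, 0.5, 50), 3),
                 strand = ".")
}

# Two-group exponential survival data with true hazard ratio `hr`.
rand_survdata <- function(n, hr = 2, base_rate = 0.1, censor_rate = 0) {
  x <- rep(c(0L, 1L), length.out = n)
  t <- rexp(n, rate = base_rate * hr^x)
  ev <- rep(1L, n)
  if (censor_rate > 0) {
    cens <- rexp(n, rate = base_rate * censor_rate / (1 - censor_rate))
    ev <- as.integer(t <= cens)
    t <- pmin(t, cens)
  }
  tibble::tibble(time = t, event = ev, x = x)
}
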