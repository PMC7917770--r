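# From-scratch preranked gene-set enrichment: weighted running-sum
# statistic, gene-label permutation null, sign-stratified normalized
# enrichment score and nominal p-value.

# Order a (gene_id, metric) tibble descending by metric with ties kept in
# stable input order.
order_ranked <- function(ranked) {
  stopifnot(all(c("gene_id", "metric") %in% names(ranked)))
  if (anyDuplicated(ranked$gene_id)) abort("duplicate genes in ranked list")
  if (any(!is.finite(ranked$metric))) abort("ranking metrics must be finite")
  ranked[order(-ranked$metric), , drop = FALSE]
}

# Enrichment score from sorted hit positions. Hits increment the running
# sum by |metric|^p normalized over the in-set total; misses decrement by
# 1/(N - k). The ES is the running-sum value of maximal absolute deviation,
# signed. Evaluating the sum just before and just after every hit covers
# all candidate extrema.
es_from_positions <- function(pos, wts, n_total) {
  k <- length(pos)
  miss <- 1 / (n_total - k)
  total_w <- sum(wts)
  if (total_w == 0) {                    # all hit weights zero (e.g. metric 0)
    wts <- rep(1, k); total_w <- k
  }
  after <- cumsum(wts) / total_w - (pos - seq_len(k)) * miss
  before <- after - wts / total_w
  mx <- max(c(after, 0))
  mn <- min(c(before, 0))
  # extremum of larger magnitude; exact ties resolve to the positive side
  es <- unname(if (mx >= -mn) mx else mn)
  list(es = es, after = after, before = before)
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list from top to bottom: genes in the set ("hits")
#' increment the running sum by `|metric|^weight_p` normalized by the total
#' over hits, all other genes decrement it by `1/(N - N_hits)`. The
#' enrichment score (ES) is the signed value of maximal absolute deviation
#' from zero; positive ES means the set concentrates at the top of the
#' list, negative at the bottom. The leading edge is the set members at or
#' before (after, for negative ES) the extremum.
#'
#' @param ranked Tibble with `gene_id` and `metric`; sorted internally by
#'   descending metric, ties kept in input order.
#' @param gene_set Character vector of member gene ids. Members absent from
#'   the ranked list are dropped with a warning; the remaining members must
#'   be a non-empty proper subset of the list.
#' @param weight_p Weighting exponent (default 1; 0 gives the classic
#'   unweighted Kolmogorov-Smirnov statistic).
#' @return An object of class `enrichment_score`: `es`, `running_sum`
#'   (tibble with `position`, `gene_id`, `metric`, `hit`, `running_sum`),
#'   `leading_edge`, `n_hits`.
#' @export
#' @examples
#' ranked <- tibble::tibble(gene_id = letters[1:10], metric = 10:1)
#' enrichment_score(ranked, c("a", "b", "c"), weight_p = 0)$es
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  ranked <- order_ranked(ranked)
  gene_set <- unique(as.character(gene_set))
  n <- nrow(ranked)
  absent <- setdiff(gene_set, ranked$gene_id)
  if (length(absent) > 0) {
    warn(sprintf("%d set member(s) absent from the ranked list; dropped", length(absent)))
    gene_set <- setdiff(gene_set, absent)
  }
  if (length(gene_set) == 0) abort("gene set has no members in the ranked list")
  if (length(gene_set) >= n) {
    abort("gene set covers the whole ranked list; miss increment undefined")
  }
  hit <- ranked$gene_id %in% gene_set
  pos <- which(hit)
  wts <- abs(ranked$metric[pos])^weight_p
  parts <- es_from_positions(pos, wts, n)
  k <- length(pos)
  # full running sum for plotting
  step <- rep(-1 / (n - k), n)
  w <- if (sum(wts) == 0) rep(1, k) else wts
  step[pos] <- w / sum(w)
  rs <- cumsum(step)
  if (parts$es >= 0) {
    peak <- pos[which.max(parts$after)]
    le <- ranked$gene_id[pos[pos <= peak]]
  } else {
    trough <- pos[which.min(parts$before)]
    le <- rev(ranked$gene_id[pos[pos >= trough]])
  }
  structure(list(
    es = parts$es,
    running_sum = tibble(position = seq_len(n), gene_id = ranked$gene_id,
                         metric = ranked$metric, hit = hit, running_sum = rs),
    leading_edge = le,
    n_hits = k
  ), class = "enrichment_score")
}

#' @export
print.enrichment_score <- function(x, ...) {
  cat(sprintf("<enrichment_score> ES = %.4f (%d hits, %d-gene leading edge)\n",
              x$es, x$n_hits, length(x$leading_edge)))
  invisible(x)
}

#' Preranked gene-set enrichment with a permutation null
#'
#' For every gene set, computes the observed [enrichment_score()] and a
#' null distribution by gene-label permutation: set membership is assigned
#' to uniformly random positions of the ranked list, preserving set size.
#' The nominal p-value and the normalized enrichment score (NES) are
#' sign-stratified: with null ES values of the observed sign,
#' `p = (1 + #(|null| >= |observed|)) / (1 + #same-sign null)` and
#' `NES = es / mean(|same-sign null es|)`. If no null ES shares the
#' observed sign, `p` is reported at its resolution bound `1/(n_perm + 1)`
#' and flagged. Results are deterministic given `seed`.
#'
#' @param ranked Tibble with `gene_id` and `metric`.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]), or a single character vector.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param weight_p Weighting exponent passed to the score (default 1).
#' @param seed Integer seed for the permutation stream.
#' @return A tibble with one row per set: `set`, `size`, `es`, `nes`,
#'   `p_value`, `n_perm`, `flag`, and a `leading_edge` list column.
#' @export
gsea_preranked <- function(ranked, gene_sets, n_perm = 1000, weight_p = 1,
                           seed = NULL) {
  if (n_perm < 100) abort("'n_perm' must be >= 100")
  if (!is.list(gene_sets)) gene_sets <- list(set = gene_sets)
  if (is.null(names(gene_sets)) || any(names(gene_sets) == "")) {
    abort("'gene_sets' must be a named list")
  }
  ranked <- order_ranked(ranked)
  n <- nrow(ranked)
  if (!is.null(seed)) set.seed(as.integer(seed))
  w_all <- abs(ranked$metric)^weight_p
  rows <- map(names(gene_sets), function(nm) {
    obs <- enrichment_score(ranked, gene_sets[[nm]], weight_p = weight_p)
    k <- obs$n_hits
    null_es <- vapply(seq_len(n_perm), function(i) {
      p <- sort(sample.int(n, k))
      es_from_positions(p, w_all[p], n)$es
    }, numeric(1))
    same <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    if (length(same) == 0) {
      p_val <- 1 / (n_perm + 1)
      nes <- NA_real_
      flag <- "no_same_sign_null"
    } else {
      p_val <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
      nes <- obs$es / mean(abs(same))
      flag <- NA_character_
    }
    tibble(set = nm, size = k, es = obs$es, nes = nes, p_value = p_val,
           n_perm = n_perm, flag = flag,
           leading_edge = list(obs$leading_edge))
  })
  bind_rows(rows)
}
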