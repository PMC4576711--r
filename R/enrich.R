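#' Randomization enrichment test
#'
#' Tests whether a feature is over- or under-represented in a test set
#' relative to equal-sized random samples from a reference pool. Each of
#' `n_iter` draws samples `|test_set|` items from the pool without
#' replacement and counts feature-positive items; the observed count is
#' compared with the empirical null mean and standard deviation by a Z test
#' (two-sided normal p). The empirical two-sided tail proportion and the
#' exact hypergeometric moments and p value (the closed-form null for
#' without-replacement draws) are reported alongside as cross-checks.
#'
#' @param test_set Character vector of item ids; must be a subset of `pool`.
#' @param pool Character vector of all item ids.
#' @param feature Either a logical vector parallel to `pool` or a character
#'   vector of feature-positive item ids.
#' @param n_iter Number of random draws (default 10000).
#' @param seed Integer seed.
#' @param feature_id Label for the tested feature.
#' @return One-row `data.frame`: `feature_id`, `observed`, `n_test`,
#'   `n_pool`, `n_feature_pool`, `null_mean`, `null_sd`, `z`, `p_raw`,
#'   `p_emp`, `hyper_mean`, `hyper_sd`, `p_hyper`, `direction`, `n_iter`,
#'   `seed`.
#' @export
randomization_enrichment <- function(test_set, pool, feature, n_iter = 10000L,
                                     seed = 1L, feature_id = "feature") {
  if (anyDuplicated(pool)) stop("pool contains duplicate ids")
  if (!all(test_set %in% pool)) stop("test_set is not a subset of pool")
  if (!length(test_set)) stop("empty test set")
  fpos <- if (is.logical(feature)) {
    if (length(feature) != length(pool)) stop("logical feature must be parallel to pool")
    feature
  } else pool %in% feature
  N <- length(pool); K <- sum(fpos); n <- length(test_set)
  if (K == 0L || K == N)
    stop("pool must contain at least one feature-positive and one feature-negative item")
  observed <- sum(test_set %in% pool[fpos])
  draws <- with_seed(seed,
    vapply(seq_len(n_iter), function(i) sum(fpos[sample.int(N, n)]), 0L))
  null_mean <- mean(draws); null_sd <- sd(draws)
  if (null_sd == 0) {
    warning("degenerate null (sd = 0); z undefined, p taken from empirical tail")
    z <- NA_real_
    p_raw <- NA_real_
  } else {
    z <- (observed - null_mean) / null_sd
    p_raw <- 2 * pnorm(-abs(z))
  }
  p_emp <- min(1, 2 * min(mean(draws >= observed), mean(draws <= observed)))
  hyper_mean <- n * K / N
  hyper_sd <- sqrt(n * (K / N) * (1 - K / N) * (N - n) / (N - 1))
  p_hyper <- min(1, 2 * min(stats::phyper(observed, K, N - K, n),
                            stats::phyper(observed - 1, K, N - K, n,
                                          lower.tail = FALSE)))
  data.frame(feature_id = feature_id, observed = observed, n_test = n,
             n_pool = N, n_feature_pool = K,
             null_mean = null_mean, null_sd = null_sd, z = z,
             p_raw = if (is.na(p_raw)) p_emp else p_raw, p_emp = p_emp,
             hyper_mean = hyper_mean, hyper_sd = hyper_sd, p_hyper = p_hyper,
             direction = if (observed > null_mean) "enriched" else "depleted",
             n_iter = n_iter, seed = seed, stringsAsFactors = FALSE)
}

#' Event-type enrichment among ecotype-specific events
#'
#' For each ecotype and each of the five event types, tests whether the
#' ecotype-specific confirmed events are enriched or depleted for that type
#' relative to equal-sized samples from the pool of all confirmed events.
#' Bonferroni correction is applied over the full family (5 types x 2
#' ecotypes = 10 tests by default).
#'
#' @param labeled_events Confirmed events with a `specificity` column from
#'   [partition_specificity()].
#' @param ecotypes Length-2 character vector of ecotype labels.
#' @param n_iter Randomization draws per test.
#' @param seed Integer seed (one deterministic sub-seed per test).
#' @param family_m Bonferroni family size (default `5 * length(ecotypes)`).
#' @return `data.frame` with one row per (ecotype, type): the
#'   [randomization_enrichment()] columns plus `ecotype` and `p_adj`.
#' @export
event_type_enrichment <- function(labeled_events, ecotypes = c("head", "body"),
                                  n_iter = 10000L, seed = 1L,
                                  family_m = 5L * length(ecotypes)) {
  pool_ids <- paste0("ev", seq_len(nrow(labeled_events)))
  res <- list()
  for (ei in seq_along(ecotypes)) {
    eco <- ecotypes[ei]
    test_ids <- pool_ids[labeled_events$specificity == paste0(eco, "_only")]
    for (ti in seq_along(AS_TYPES)) {
      ty <- AS_TYPES[ti]
      fpos <- labeled_events$event_type == ty
      if (!length(test_ids) || !any(fpos) || all(fpos)) {
        # type absent from (or filling) the pool: no variation to test
        r <- data.frame(feature_id = ty,
                        observed = sum(fpos[match(test_ids, pool_ids)]),
                        n_test = length(test_ids), n_pool = length(pool_ids),
                        n_feature_pool = sum(fpos), null_mean = NA_real_,
                        null_sd = NA_real_, z = NA_real_, p_raw = NA_real_,
                        p_emp = NA_real_, hyper_mean = NA_real_,
                        hyper_sd = NA_real_, p_hyper = NA_real_,
                        direction = NA_character_, n_iter = n_iter,
                        seed = NA_integer_, stringsAsFactors = FALSE)
      } else {
        r <- randomization_enrichment(
          test_ids, pool_ids, fpos,
          n_iter = n_iter, seed = seed + 1000L * ((ei - 1L) * length(AS_TYPES) + ti),
          feature_id = ty)
      }
      r$ecotype <- eco
      res[[length(res) + 1L]] <- r
    }
  }
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p_raw)
  out$p_adj[ok] <- adjust_pvalues(out$p_raw[ok], method = "bonferroni",
                                  m = family_m)
  out
}

#' Two-proportion Z test (pooled variance)
#'
#' `z = (p1 - p2) / sqrt(p * (1 - p) * (1/n1 + 1/n2))` with
#' `p = (x1 + x2) / (n1 + n2)`, two-sided normal p value.
#'
#' @param x1,n1 Successes and trials in sample 1.
#' @param x2,n2 Successes and trials in sample 2.
#' @return List with `z`, `p`, `p1_hat`, `p2_hat`, `pooled_p`.
#' @export
two_prop_z <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2; pp <- (x1 + x2) / (n1 + n2)
  if (pp == 0 || pp == 1) {
    warning("pooled proportion is 0 or 1; no variance")
    return(list(z = 0, p = 1, p1_hat = p1, p2_hat = p2, pooled_p = pp))
  }
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * pnorm(-abs(z)), p1_hat = p1, p2_hat = p2, pooled_p = pp)
}

#' Multiple-testing adjustment with explicit family size
#'
#' Bonferroni (`min(1, p * m)`) or Benjamini-Hochberg step-up adjusted
#' values. The family size `m` may exceed the number of p values supplied
#' (e.g. when a family member is reported elsewhere).
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @param m Family size (default `length(p)`).
#' @return Adjusted p values, same order as the input.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh"), m = length(p)) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  p.adjust(p, method = if (method == "bh") "BH" else "bonferroni", n = m)
}

#' Gene-set (GO / curated list) enrichment by randomization
#'
#' Tests each gene set for over-representation in the test genes relative to
#' random equal-sized samples of the background. GO terms annotating fewer
#' than `min_term` background genes are pooled into one composite category
#' before testing (small-category grouping). BH adjustment is applied across
#' the tested categories.
#'
#' @param test_genes Character vector of genes (subset of
#'   `background_genes`).
#' @param background_genes Character vector; typically all alternatively
#'   spliced genes.
#' @param gene_sets Named list: category -> character vector of member
#'   genes.
#' @param n_iter Randomization draws per category.
#' @param seed Integer seed.
#' @param min_term Minimum background annotation count for a category to be
#'   tested on its own (default 100; smaller categories are grouped).
#' @return `data.frame`, one row per tested category (composite category
#'   labeled `"small_terms_grouped"`), with the
#'   [randomization_enrichment()] columns plus `n_background_annotated` and
#'   BH-adjusted `p_adj`.
#' @export
gene_set_enrichment <- function(test_genes, background_genes, gene_sets,
                                n_iter = 10000L, seed = 1L, min_term = 100L) {
  if (!length(background_genes)) stop("empty background gene set")
  if (!all(test_genes %in% background_genes))
    stop("test_genes is not a subset of background_genes")
  sets_bg <- lapply(gene_sets, intersect, background_genes)
  sizes <- vapply(sets_bg, length, 0L)
  small <- names(sets_bg)[sizes < min_term]
  kept <- sets_bg[sizes >= min_term]
  if (length(small))
    kept$small_terms_grouped <- unique(unlist(sets_bg[small], use.names = FALSE))
  kept <- kept[vapply(kept, function(g)
    length(g) > 0 && length(g) < length(background_genes), TRUE)]
  if (!length(kept)) stop("no testable category (all empty or background-wide)")
  res <- vector("list", length(kept))
  for (i in seq_along(kept)) {
    res[[i]] <- randomization_enrichment(
      test_genes, background_genes, kept[[i]],
      n_iter = n_iter, seed = seed + i, feature_id = names(kept)[i])
    res[[i]]$n_background_annotated <- length(kept[[i]])
  }
  out <- do.call(rbind, res)
  out$p_adj <- adjust_pvalues(out$p_raw, method = "bh", m = nrow(out))
  out
}
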