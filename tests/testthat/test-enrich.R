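test_that("null moments match exact hypergeometric moments", {
  pool <- paste0("i", 1:1000)
  feature <- pool[1:100]                      # 100 positives
  test_set <- c(pool[1:30], pool[101:120])    # 50 items, 30 positive
  r <- randomization_enrichment(test_set, pool, feature, n_iter = 10000, seed = 2)
  expect_equal(r$observed, 30L)
  # closed form: mean 5, sd sqrt(50 * 0.1 * 0.9 * 950/999)
  expect_equal(r$hyper_mean, 5)
  expect_equal(r$hyper_sd, sqrt(50 * 0.1 * 0.9 * 950 / 999))
  expect_lt(abs(r$null_mean - r$hyper_mean), 3 * r$hyper_sd / sqrt(10000))
  expect_lt(abs(r$null_sd - r$hyper_sd),
            3 * r$hyper_sd / sqrt(2 * (10000 - 1)))
  # z agrees with the closed form within Monte-Carlo tolerance
  z_exact <- (30 - 5) / sqrt(50 * 0.1 * 0.9 * 950 / 999)
  expect_lt(abs(r$z - z_exact) / z_exact, 0.05)
  expect_equal(r$direction, "enriched")
})

test_that("a test set equal to the pool is degenerate and non-significant", {
  pool <- paste0("i", 1:40)
  expect_warning(
    r <- randomization_enrichment(pool, pool, pool[1:10], n_iter = 200, seed = 1),
    "degenerate")
  expect_gt(r$p_emp, 0.99)
  expect_error(randomization_enrichment(c(pool, "zz"), pool, pool[1:10]),
               "subset")
  expect_error(randomization_enrichment(pool[1:5], pool, pool),
               "feature-positive")
})

test_that("enrichment is reproducible from the seed", {
  pool <- paste0("i", 1:200)
  r1 <- randomization_enrichment(pool[1:30], pool, pool[1:50],
                                 n_iter = 500, seed = 9)
  r2 <- randomization_enrichment(pool[1:30], pool, pool[1:50],
                                 n_iter = 500, seed = 9)
  expect_identical(r1, r2)
})

test_that("z and the empirical p agree in rank across result batches", {
  pool <- paste0("i", 1:400)
  feature <- pool[1:120]
  set.seed(77)
  rs <- do.call(rbind, lapply(1:8, function(i)
    randomization_enrichment(sample(pool, 60), pool, feature,
                             n_iter = 2000, seed = 100 + i)))
  expect_gt(stats::cor(abs(rs$z), -log(rs$p_emp + 1e-4), method = "spearman"),
            0.8)
  expect_equal(rs$direction == "enriched", rs$z > 0)
})

test_that("the two-proportion Z statistic matches hand evaluation", {
  expect_equal(two_prop_z(20, 100, 20, 100)$z, 0)
  expect_equal(two_prop_z(20, 100, 20, 100)$p, 1)
  r <- two_prop_z(30, 100, 20, 100)
  expect_equal(r$z, 0.1 / sqrt(0.25 * 0.75 * (1 / 100 + 1 / 100)))
  expect_equal(r$z, 1.63299, tolerance = 1e-5)
  # antisymmetry
  s <- two_prop_z(20, 100, 30, 100)
  expect_equal(s$z, -r$z)
  expect_equal(s$p, r$p)
  expect_warning(z0 <- two_prop_z(0, 10, 0, 20), "variance")
  expect_equal(z0$p, 1)
})

test_that("p-value adjustment follows Bonferroni and BH step-up arithmetic", {
  expect_equal(adjust_pvalues(0.03, "bonferroni", m = 1), 0.03)
  expect_equal(adjust_pvalues(0.3, "bonferroni", m = 10), 1)  # capped
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               c(0.04, 0.04, 0.04, 0.04))
  # BH is invariant to input order
  p <- c(0.002, 0.9, 0.04, 0.3, 0.011)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(adjust_pvalues(p, "bh")[perm], adjust_pvalues(p[perm], "bh"))
  expect_error(adjust_pvalues(c(0.5, 1.2), "bh"), "\\[0, 1\\]")
})

test_that("small GO categories are grouped before testing", {
  bg <- paste0("g", 1:300)
  sets <- list(big = bg[1:120], small1 = bg[1:40], small2 = bg[200:230])
  r <- gene_set_enrichment(bg[1:50], bg, sets, n_iter = 300, seed = 4,
                           min_term = 100)
  expect_setequal(r$feature_id, c("big", "small_terms_grouped"))
  expect_equal(r$n_background_annotated[r$feature_id == "small_terms_grouped"],
               length(union(bg[1:40], bg[200:230])))
  expect_error(gene_set_enrichment(bg[1:5], character(0), sets), "background")
})

test_that("event-type enrichment tests every (ecotype, type) with Bonferroni", {
  set.seed(15)
  n <- 400
  ev <- data.frame(
    gene_id = paste0("g", 1:n), event_type = sample(c("ES", "5S", "3S", "3S5S", "IR"),
                                                    n, replace = TRUE),
    chrom = "chr1", start = 1:n * 10L, end = 1:n * 10L + 5L,
    support_head = 1L, support_body = 1L, confirmed = TRUE,
    specificity = sample(c("shared", "head_only", "body_only"), n,
                         replace = TRUE, prob = c(0.6, 0.2, 0.2)),
    stringsAsFactors = FALSE)
  r <- event_type_enrichment(ev, n_iter = 400, seed = 5)
  expect_equal(nrow(r), 10L)
  expect_setequal(r$ecotype, c("head", "body"))
  ok <- !is.na(r$p_raw)
  expect_equal(r$p_adj[ok], pmin(1, r$p_raw[ok] * 10))
  # identical head and body specific sets give identical statistics
  ev2 <- ev
  ev2$specificity[ev2$specificity == "body_only"] <- "head_only"
  ev2$specificity[1:50] <- "body_only"
  ev3 <- ev2
  ev3$specificity[ev3$specificity == "head_only"] <- "x"
  ev3$specificity[ev3$specificity == "body_only"] <- "head_only"
  ev3$specificity[ev3$specificity == "x"] <- "body_only"
  r2 <- event_type_enrichment(ev2, n_iter = 400, seed = 5)
  r3 <- event_type_enrichment(ev3, n_iter = 400, seed = 5)
  expect_equal(r2$observed[r2$ecotype == "head"],
               r3$observed[r3$ecotype == "body"])
})
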