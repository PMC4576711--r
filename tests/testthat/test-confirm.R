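mk_events <- function(starts, ends, sup_head, sup_body, types = "ES",
                      gene = "g1") {
  n <- length(starts)
  data.frame(gene_id = rep_len(gene, n), event_type = rep_len(types, n),
             chrom = "chr1", start = as.integer(starts), end = as.integer(ends),
             support_head = as.integer(sup_head),
             support_body = as.integer(sup_body),
             confirmed = NA, stringsAsFactors = FALSE)
}

test_that("confirmation requires an exact junction-end match at a boundary", {
  # (200,300) vs junction (100,400): no boundary equals 200 or 300
  js1 <- junction_set(data.frame(chrom = "chr1", intron_start = 100L,
                                 intron_end = 400L, strand = "+",
                                 stringsAsFactors = FALSE))
  ev <- confirm_events(mk_events(c(200, 500), c(300, 600), 1, 1), js1)
  expect_equal(ev$confirmed, c(FALSE, FALSE))
  # (120,200) matches junction (120,200) at both ends; one suffices
  js2 <- junction_set(data.frame(chrom = "chr1", intron_start = 120L,
                                 intron_end = 200L, strand = ".",
                                 stringsAsFactors = FALSE))
  ev <- confirm_events(mk_events(c(120, 90), c(200, 120), 1, 1, types = "5S"), js2)
  expect_true(ev$confirmed[1])
  expect_true(ev$confirmed[2])  # end touches a junction donor: confirmed
  ev <- confirm_events(mk_events(130, 210, 1, 1), js2)
  expect_false(ev$confirmed[1])
})

test_that("engineered single-boundary matches are counted exactly", {
  # 8 events, 5 junctions, 3 events engineered to match exactly one boundary
  ev <- mk_events(seq(1000, 8000, by = 1000), seq(1000, 8000, by = 1000) + 100,
                  1, 0)
  js <- junction_set(data.frame(
    chrom = "chr1",
    intron_start = c(500L, 1100L, 3000L, 9000L, 9500L),
    intron_end = c(800L, 2050L, 5100L, 9300L, 9900L),
    strand = "+", stringsAsFactors = FALSE))
  # oracle: all-pairs boundary comparison
  jends <- c(500, 800, 1100, 2050, 3000, 5100, 9000, 9300, 9500, 9900)
  manual <- (ev$start %in% jends) | (ev$end %in% jends)
  ev <- confirm_events(ev, js)
  expect_equal(ev$confirmed, manual)
  expect_equal(sum(ev$confirmed), 3L)
})

test_that("confirmation is monotone and distributes over junction-set union", {
  set.seed(3)
  ev <- mk_events(sample(0:500, 30) * 10, sample(501:1000, 30) * 10, 1, 1)
  mk_js <- function(n, seed) {
    set.seed(seed)
    s <- sample(c(ev$start, sample(0:10000, n)), n)
    junction_set(data.frame(chrom = "chr1", intron_start = s,
                            intron_end = s + 50L, strand = "+",
                            stringsAsFactors = FALSE))
  }
  j1 <- mk_js(20, 11); j2 <- mk_js(20, 12)
  j12 <- junction_set(rbind(j1$junctions, j2$junctions))
  c1 <- confirm_events(ev, j1)$confirmed
  c2 <- confirm_events(ev, j2)$confirmed
  c12 <- confirm_events(ev, j12)$confirmed
  expect_true(all(c12 >= c1))           # adding junctions never unconfirms
  expect_equal(c12, c1 | c2)            # union = union of confirmed sets
})

test_that("specificity partition reproduces inclusion-exclusion identities", {
  # disjoint support: nothing shared
  p <- partition_specificity(mk_events(c(100, 200), c(150, 250),
                                       c(1, 0), c(0, 2), gene = c("g1", "g2")))
  expect_equal(p$counts$shared, 0L)
  expect_equal(p$events$specificity, c("head_only", "body_only"))

  # identical support: everything shared
  p <- partition_specificity(mk_events(c(100, 200), c(150, 250),
                                       c(2, 1), c(1, 3)))
  expect_equal(p$counts$shared, 2L)
  expect_equal(p$counts$specific_A + p$counts$specific_B, 0L)

  # zero-support events are rejected
  expect_error(partition_specificity(mk_events(100, 150, 0, 0)),
               "zero total support")
})

test_that("partition is symmetric under swapping ecotype labels", {
  set.seed(5)
  ev <- mk_events(1:40 * 100, 1:40 * 100 + 50,
                  rbinom(40, 3, 0.6), rbinom(40, 3, 0.6))
  ev <- ev[ev$support_head + ev$support_body > 0, ]
  p <- partition_specificity(ev, ecotypes = c("head", "body"))
  q <- partition_specificity(ev, ecotypes = c("body", "head"))
  expect_equal(p$counts$specific_A, q$counts$specific_B)
  expect_equal(p$counts$specific_B, q$counts$specific_A)
  expect_equal(p$counts$shared, q$counts$shared)
})

test_that("gene specificity sets match brute-force recomputation", {
  set.seed(9)
  n <- 60
  ev <- mk_events(1:n * 100, 1:n * 100 + 50,
                  rbinom(n, 2, 0.5), rbinom(n, 2, 0.5),
                  gene = paste0("g", sample(1:20, n, replace = TRUE)))
  ev <- ev[ev$support_head + ev$support_body > 0, ]
  p <- partition_specificity(ev)
  gs <- gene_specificity_sets(p$events)
  # brute force row-by-row
  a <- character(0); b <- character(0)
  for (i in seq_len(nrow(p$events))) {
    if (p$events$specificity[i] == "head_only") a <- union(a, p$events$gene_id[i])
    if (p$events$specificity[i] == "body_only") b <- union(b, p$events$gene_id[i])
  }
  expect_setequal(gs$genes_specific_A, a)
  expect_setequal(gs$genes_specific_B, b)
  expect_setequal(gs$genes_both, intersect(a, b))
  expect_equal(length(gs$genes_union),
               length(gs$genes_specific_A) + length(gs$genes_specific_B) -
                 length(gs$genes_both))
})

test_that("one gene with one A-only event populates only the A set", {
  p <- partition_specificity(mk_events(100, 150, 1, 0))
  gs <- gene_specificity_sets(p$events)
  expect_equal(gs$genes_specific_A, "g1")
  expect_equal(length(gs$genes_specific_B), 0L)
  expect_equal(length(gs$genes_both), 0L)
})
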