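# Classification of single transcripts against a fixed template.

test_that("exon skipping, retention, and splice-site shifts are classified", {
  tpl <- mk_template(c(0, 100, 200, 300, 400, 500))

  # intron (100,400) skips the middle exon
  ev <- detect_events(mk_aln(c(0, 100, 400, 500)), tpl)
  expect_equal(ev$event_type, "ES")
  expect_equal(c(ev$start, ev$end), c(200L, 300L))

  # a block covering intron (100,200) retains it
  ev <- detect_events(mk_aln(c(0, 300)), tpl)
  expect_equal(ev$event_type, "IR")
  expect_equal(c(ev$start, ev$end), c(100L, 200L))

  # a template-concordant transcript emits nothing
  expect_equal(nrow(detect_events(mk_aln(c(0, 100, 200, 300, 400, 500)), tpl)), 0L)

  # an intron skipping two exons yields two ES events
  ev <- detect_events(mk_aln(c(0, 100, 600, 700)),
                      mk_template(c(0, 100, 200, 300, 400, 500, 600, 700)))
  expect_equal(ev$event_type, c("ES", "ES"))
  expect_equal(ev$start, c(200L, 400L))
})

test_that("donor/acceptor shifts are strand-aware (5S on + mirrors 3S on -)", {
  for (st in c("+", "-")) {
    tpl <- mk_template(c(0, 100, 200, 300), strand = st)
    ev <- detect_events(mk_aln(c(0, 120, 200, 300), strand = st), tpl)
    # intron (120,200): start moved, end shared with template intron (100,200)
    expect_equal(ev$event_type, if (st == "+") "5S" else "3S")
    expect_equal(c(ev$start, ev$end), c(120L, 200L))
    ev <- detect_events(mk_aln(c(0, 100, 180, 300), strand = st), tpl)
    expect_equal(ev$event_type, if (st == "+") "3S" else "5S")
  }
})

test_that("a doubly-shifted intron without a skipped exon is 3S5S", {
  tpl <- mk_template(c(0, 100, 200, 300))
  ev <- detect_events(mk_aln(c(0, 90, 210, 300)), tpl)
  expect_equal(ev$event_type, "3S5S")
  expect_equal(c(ev$start, ev$end), c(90L, 210L))
})

test_that("retention is detected against observed introns absorbed by the union", {
  # one transcript retains the intron, two splice it; the union template has a
  # single merged exon, but the observed intron keeps retention detectable
  txs <- list(mk_aln(c(0, 300), id = "retainer", eco = "body"),
              mk_aln(c(0, 100, 200, 300), id = "s1"),
              mk_aln(c(0, 100, 200, 300), id = "s2"))
  raw <- detect_gene_events("g1", txs)
  expect_equal(raw$event_type, "IR")
  expect_equal(raw$transcript_id, "retainer")
  ev <- deduplicate_events(raw)
  expect_equal(ev$support_body, 1L)
  expect_equal(ev$support_head, 0L)  # splicers do not support the event
})

test_that("an intron that both skips an exon and shifts a boundary emits both", {
  tpl <- mk_template(c(0, 100, 200, 300, 400, 500))
  # intron (80,400): skips the middle exon and moves the donor (5'-side)
  ev <- detect_events(mk_aln(c(0, 80, 400, 500)), tpl)
  expect_setequal(ev$event_type, c("ES", "5S"))
  expect_equal(nrow(detect_events(mk_aln(c(0, 80, 400, 500)), tpl,
                                  emit_side_with_es = FALSE)), 1L)
})

test_that("a single deviating intron yields exactly one classification family", {
  # exclusivity: an ES set (possibly with its one side event) or exactly one
  # of 5S/3S/3S5S, never two different site-shift types for the same intron
  tpl <- mk_template(c(0, 100, 200, 300, 400, 500))
  gap_key <- paste(tpl$introns[, 1], tpl$introns[, 2])
  for (blocks in enumerate_edits(tpl$exons)) {
    a <- mk_aln(t(blocks))
    ii <- alignment_introns(a)
    if (sum(!paste(ii[, 1], ii[, 2]) %in% gap_key) != 1) next
    ev <- detect_events(a, tpl)
    site <- ev$event_type[ev$event_type %in% c("5S", "3S", "3S5S")]
    expect_lte(length(site), 1L)
    if (!any(ev$event_type == "ES") && nrow(ev[ev$event_type != "IR", ]) > 0)
      expect_equal(nrow(ev[ev$event_type != "IR", ]), 1L)
    expect_false(any(duplicated(paste(ev$event_type, ev$start, ev$end))))
  }
})

test_that("classifier agrees with the brute-force definitional oracle", {
  set.seed(11)
  shapes <- list(c(0, 100, 200, 300),
                 c(0, 100, 200, 300, 400, 500),
                 c(0, 150, 200, 300, 350, 500, 550, 650))
  for (shape in shapes) for (st in c("+", "-")) {
    tpl <- mk_template(shape, strand = st)
    for (blocks in enumerate_edits(tpl$exons)) {
      a <- mk_aln(t(blocks), strand = st)
      expect_identical(event_keys(detect_events(a, tpl)),
                       event_keys(oracle_detect(a, tpl)))
    }
  }
})

test_that("strand antisymmetry: a strand flip swaps 5S and 3S, a mirror-and-flip preserves them", {
  M <- 1000L
  tpl_p <- mk_template(c(0, 100, 200, 300, 400, 500), strand = "+")
  tpl_n <- mk_template(c(0, 100, 200, 300, 400, 500), strand = "-")
  tpl_m <- mk_template(M - c(500, 400, 300, 200, 100, 0), strand = "-")
  mirror_blocks <- function(b) M - b[rev(seq_len(nrow(b))), c(2, 1), drop = FALSE]
  swap <- c(ES = "ES", `5S` = "3S", `3S` = "5S", `3S5S` = "3S5S", IR = "IR")
  for (blocks in enumerate_edits(tpl_p$exons)) {
    a_p <- mk_aln(t(blocks), strand = "+")
    ev_p <- detect_events(a_p, tpl_p)
    # same geometry read on the opposite strand: donor/acceptor roles swap
    a_n <- mk_aln(t(blocks), strand = "-")
    expect_identical(sort(unname(swap[detect_events(a_p, tpl_p)$event_type])),
                     sort(detect_events(a_n, tpl_n)$event_type))
    # reflecting the locus and flipping strand leaves transcript-relative
    # geometry (hence every event type) unchanged
    a_m <- spliced_alignment("t1", "head", "chr1", "-",
                             mirror_blocks(a_p$blocks), min_intron = 1L)
    expect_identical(sort(ev_p$event_type),
                     sort(detect_events(a_m, tpl_m)$event_type))
  }
})

test_that("duplicate transcripts add support but never new distinct events", {
  txs <- list(mk_aln(c(0, 100, 400, 500), id = "a", eco = "head"),
              mk_aln(c(0, 100, 200, 300, 400, 500), id = "full"))
  base <- deduplicate_events(detect_gene_events("g1", txs))
  more <- deduplicate_events(detect_gene_events("g1", c(txs, list(
    mk_aln(c(0, 100, 400, 500), id = "b", eco = "head"),
    mk_aln(c(0, 100, 400, 500), id = "c", eco = "body")))))
  expect_equal(more[, c("gene_id", "event_type", "start", "end")],
               base[, c("gene_id", "event_type", "start", "end")])
  expect_equal(more$support_head, 2L)
  expect_equal(more$support_body, 1L)
})

test_that("deduplication merges on the identity tuple and sums support", {
  raw <- data.frame(
    gene_id = "g1", event_type = "ES", chrom = "chr1",
    start = c(200L, 200L, 200L, 200L, 200L, 201L),
    end = 300L,
    ecotype = c("head", "head", "head", "body", "body", "head"),
    transcript_id = paste0("t", 1:6), stringsAsFactors = FALSE)
  ev <- deduplicate_events(raw)
  expect_equal(nrow(ev), 2L)  # 1-bp difference keeps events distinct
  exact <- ev[ev$start == 200L, ]
  expect_equal(exact$support_head, 3L)
  expect_equal(exact$support_body, 2L)
  # fixture with identity duplicates: 10 raw rows collapse to 6 distinct
  raw10 <- data.frame(
    gene_id = "g1", event_type = c(rep("ES", 5), "IR", "IR", "5S", "3S", "3S5S"),
    chrom = "chr1",
    start = c(10L, 10L, 10L, 50L, 50L, 80L, 80L, 120L, 150L, 180L),
    end = c(20L, 20L, 20L, 60L, 60L, 90L, 90L, 130L, 160L, 190L),
    ecotype = "head", transcript_id = paste0("t", 1:10),
    stringsAsFactors = FALSE)
  expect_equal(nrow(deduplicate_events(raw10)), 6L)
  expect_equal(nrow(deduplicate_events(raw10[0, ])), 0L)
})
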