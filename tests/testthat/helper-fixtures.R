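# Small constructors used across the unit tests.

# A spliced alignment from a 2-column block matrix (0-based half-open).
mk_aln <- function(blocks, id = "t1", eco = "head", chrom = "chr1",
                   strand = "+", min_intron = 1L) {
  spliced_alignment(id, eco, chrom, strand, matrix(blocks, ncol = 2, byrow = TRUE),
                    min_intron = min_intron)
}

# A gene template constructed directly from an exon matrix; gap introns are
# derived, observed introns default to the gaps.
mk_template <- function(exons, strand = "+", gene_id = "g1", chrom = "chr1",
                        observed = NULL) {
  exons <- matrix(as.integer(exons), ncol = 2, byrow = TRUE,
                  dimnames = list(NULL, c("start", "end")))
  n <- nrow(exons)
  introns <- if (n > 1) cbind(start = exons[-n, 2], end = exons[-1, 1]) else
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  if (is.null(observed)) observed <- introns
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, introns = introns, observed_introns = observed),
            class = "gene_template")
}

# A catalog data.frame.
mk_catalog <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r[[1]], chrom = r[[2]], strand = r[[3]],
               start = as.integer(r[[4]]), end = as.integer(r[[5]]),
               stringsAsFactors = FALSE)))
}

# Enumerate edited transcripts of a template for oracle-sweep tests:
# identity, internal-exon skips, single/double boundary shifts on each
# intron, and intron retentions. Returns a list of block matrices.
enumerate_edits <- function(exons, shift = 25L) {
  n <- nrow(exons)
  out <- list(exons)
  if (n >= 3) for (j in 2:(n - 1)) out <- c(out, list(exons[-j, , drop = FALSE]))
  for (j in seq_len(n - 1)) {
    for (dl in c(-shift, 0L, shift)) for (dr in c(-shift, 0L, shift)) {
      if (dl == 0L && dr == 0L) next
      ex <- exons
      ex[j, 2] <- ex[j, 2] + dl      # intron start moves by dl
      ex[j + 1, 1] <- ex[j + 1, 1] + dr
      if (ex[j, 1] >= ex[j, 2] || ex[j + 1, 1] >= ex[j + 1, 2]) next
      if (ex[j + 1, 1] - ex[j, 2] < 1) next  # intron must keep >= 1 bp
      out <- c(out, list(ex))
    }
    # retention of intron j
    ex <- exons
    ex[j, 2] <- ex[j + 1, 1]
    out <- c(out, list(merge_rows(ex)))
  }
  # skip + shifted outer boundary (combined event) where possible
  if (n >= 3) {
    ex <- exons[-2, , drop = FALSE]
    ex[1, 2] <- ex[1, 2] - shift
    if (ex[1, 1] < ex[1, 2]) out <- c(out, list(ex))
  }
  out
}

merge_rows <- function(ex) {
  keep <- c(TRUE, ex[-1, 1] > ex[-nrow(ex), 2])
  grp <- cumsum(keep)
  cbind(start = as.integer(tapply(ex[, 1], grp, min)),
        end = as.integer(tapply(ex[, 2], grp, max)))
}
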