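#' Read gene annotations from GFF3
#'
#' Parses the `gene`-typed features of a GFF3 file into a gene catalog.
#' GFF3's 1-based inclusive coordinates are converted to the package's
#' internal 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (0-based half-open), one row per gene.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  validate_gff3_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  ids <- S4Vectors::mcols(gr)$ID
  if (length(gr) && (is.null(ids) || anyNA(ids)))
    stop("GFF3 gene feature without an ID attribute")
  if (anyDuplicated(ids))
    stop("duplicate gene_id in annotation: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cat_df <- data.frame(
    gene_id = as.character(ids %||% character(0)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (nrow(cat_df) && any(!cat_df$strand %in% c("+", "-")))
    stop("gene feature without a +/- strand")
  if (any(cat_df$start >= cat_df$end)) stop("gene with start >= end")
  cat_df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Structural pre-scan so a malformed GFF3 body line is reported with its
# line number (rtracklayer's own errors do not carry one).
validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != 9)
      stop("malformed GFF3 at line ", i, ": expected 9 tab-separated fields, got ", nf)
  }
  invisible(TRUE)
}

#' Construct a spliced alignment
#'
#' Builds one transcript alignment from exon blocks, merging inter-block gaps
#' shorter than `min_intron` (treated as alignment indels, not introns).
#'
#' @param transcript_id,ecotype,chrom,strand Scalars describing the transcript.
#' @param blocks Two-column matrix of 0-based half-open exon intervals,
#'   sorted, non-overlapping.
#' @param min_intron Minimum gap length (bp) retained as an intron.
#' @return A list of class `spliced_alignment` with fields `transcript_id`,
#'   `ecotype`, `chrom`, `strand`, and `blocks` (after gap merging).
#' @export
spliced_alignment <- function(transcript_id, ecotype, chrom, strand, blocks,
                              min_intron = 40L) {
  blocks <- matrix(as.integer(blocks), ncol = 2)
  if (any(blocks[, 1] >= blocks[, 2]))
    stop("alignment block with start >= end in ", transcript_id)
  if (nrow(blocks) > 1) {
    if (any(diff(blocks[, 1]) <= 0) || any(blocks[-nrow(blocks), 2] > blocks[-1, 1]))
      stop("blocks out of order or overlapping in ", transcript_id)
    gaps <- blocks[-1, 1] - blocks[-nrow(blocks), 2]
    keep <- gaps >= min_intron
    # merge runs of blocks whose separating gaps are below threshold
    grp <- cumsum(c(TRUE, keep))
    blocks <- cbind(tapply(blocks[, 1], grp, min), tapply(blocks[, 2], grp, max))
    blocks <- matrix(as.integer(blocks), ncol = 2)
  }
  colnames(blocks) <- c("start", "end")
  structure(list(transcript_id = as.character(transcript_id),
                 ecotype = as.character(ecotype),
                 chrom = as.character(chrom), strand = as.character(strand),
                 blocks = blocks),
            class = "spliced_alignment")
}

#' Introns implied by a spliced alignment
#'
#' @param aln A `spliced_alignment`.
#' @return Two-column matrix of 0-based half-open intron intervals (gaps
#'   between consecutive blocks); zero rows for single-block alignments.
#' @export
alignment_introns <- function(aln) {
  b <- aln$blocks
  if (nrow(b) < 2) return(matrix(integer(0), ncol = 2,
                                 dimnames = list(NULL, c("start", "end"))))
  m <- cbind(start = b[-nrow(b), 2], end = b[-1, 1])
  m
}

#' Read spliced transcript alignments from BED12
#'
#' One BED12 record per transcript; blocks are the aligned exons. Inter-block
#' gaps shorter than `min_intron` are merged into a single block at read time.
#'
#' @param path Path to a BED12 file.
#' @param ecotype Ecotype label attached to every alignment (free string;
#'   `"head"` and `"body"` are the conventional values).
#' @param min_intron Minimum gap length (bp) retained as an intron.
#' @return List of `spliced_alignment` objects.
#' @export
read_spliced_alignments <- function(path, ecotype, min_intron = 40L) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bed <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 12) stop("expected BED12 (12 columns), got ", ncol(bed))
  out <- vector("list", nrow(bed))
  for (i in seq_len(nrow(bed))) {
    sizes <- as.integer(strsplit(bed[i, 11], ",", fixed = TRUE)[[1]])
    starts <- as.integer(strsplit(bed[i, 12], ",", fixed = TRUE)[[1]])
    n <- as.integer(bed[i, 10])
    if (length(sizes) != n || length(starts) != n)
      stop("BED12 record ", bed[i, 4], ": blockCount ", n,
           " disagrees with blockSizes/blockStarts lengths")
    abs_start <- as.integer(bed[i, 2]) + starts
    blocks <- cbind(abs_start, abs_start + sizes)
    if (n > 1 && any(diff(abs_start) <= 0))
      stop("BED12 record ", bed[i, 4], ": blocks out of order")
    if (blocks[n, 2] != as.integer(bed[i, 3]))
      stop("BED12 record ", bed[i, 4], ": blocks do not end at chromEnd")
    out[[i]] <- spliced_alignment(bed[i, 4], ecotype, bed[i, 1], bed[i, 6],
                                  blocks, min_intron = min_intron)
  }
  out
}

#' Read short-read splice junctions
#'
#' Reads a junction table (columns `chrom`, `intron_start`, `intron_end`,
#' `strand`; 0-based half-open intron interval) into a deduplicated junction
#' set supporting exact lookup of either intron end.
#'
#' @param path Path to a tab-separated junction file with a header line.
#' @return A list of class `junction_set` with the deduplicated `junctions`
#'   data.frame and an internal position index.
#' @export
read_junctions <- function(path) {
  if (!file.exists(path)) stop("junction file not found: ", path)
  j <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "intron_start", "intron_end", "strand")
  miss <- setdiff(need, names(j))
  if (length(miss)) stop("junction file missing column(s): ", paste(miss, collapse = ", "))
  junction_set(j)
}

#' Build a junction set from a data.frame
#'
#' @param j `data.frame` with columns `chrom`, `intron_start`, `intron_end`,
#'   `strand` (`+`, `-`, or `.` for unknown).
#' @return A `junction_set`.
#' @export
junction_set <- function(j) {
  if (nrow(j) && any(j$intron_start >= j$intron_end))
    stop("junction with intron_start >= intron_end")
  j <- unique(j[, c("chrom", "intron_start", "intron_end", "strand")])
  rownames(j) <- NULL
  keys <- unique(c(paste0(j$chrom, ":", j$intron_start),
                   paste0(j$chrom, ":", j$intron_end)))
  structure(list(junctions = j, position_keys = keys), class = "junction_set")
}

#' Exact splice-site lookup in a junction set
#'
#' @param jset A `junction_set`.
#' @param chrom Chromosome name(s).
#' @param pos Genomic position(s), 0-based.
#' @return Logical: is any junction's donor or acceptor end exactly at the
#'   position? Vectorized over `chrom`/`pos`.
#' @export
junction_site_lookup <- function(jset, chrom, pos) {
  paste0(chrom, ":", pos) %in% jset$position_keys
}

#' Read a GO annotation map
#'
#' Reads a tab-separated `gene_id`, `term_id`, `term_name` map, drops rows
#' whose gene is absent from the catalog, and returns the term-to-genes
#' mapping.
#'
#' @param path Path to the GO map TSV (with header).
#' @param catalog Gene catalog from [read_gene_annotation()].
#' @return List with `gene_terms` (gene -> character vector of term ids),
#'   `term_genes` (term -> character vector of genes), `term_names` (named
#'   character), and `n_dropped` (annotation rows referencing unknown genes).
#' @export
read_go_map <- function(path, catalog) {
  if (!file.exists(path)) stop("GO map file not found: ", path)
  go <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "term_id")
  miss <- setdiff(need, names(go))
  if (length(miss)) stop("GO map missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(go)) stop("GO map file is empty: ", path)
  known <- go$gene_id %in% catalog$gene_id
  n_dropped <- sum(!known)
  if (n_dropped) message(n_dropped, " GO annotation row(s) dropped (gene not in catalog)")
  go <- go[known, , drop = FALSE]
  term_names <- if ("term_name" %in% names(go))
    vapply(split(go$term_name, go$term_id), `[`, "", 1) else
    setNames(unique(go$term_id), unique(go$term_id))
  list(gene_terms = lapply(split(go$term_id, go$gene_id), unique),
       term_genes = lapply(split(go$gene_id, go$term_id), unique),
       term_names = term_names,
       n_dropped = n_dropped)
}

#' Read a curated gene list
#'
#' One gene ID per line; IDs not present in the catalog are dropped with a
#' message. An empty file is an error (misconfiguration, not an empty set).
#'
#' @param path Path to the list file.
#' @param catalog Gene catalog from [read_gene_annotation()].
#' @return List with `genes` (character vector) and `n_dropped`.
#' @export
read_gene_list <- function(path, catalog) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  ids <- readLines(path, warn = FALSE)
  ids <- ids[nzchar(trimws(ids))]
  if (!length(ids)) stop("gene list file is empty: ", path)
  ids <- trimws(ids)
  known <- ids %in% catalog$gene_id
  if (any(!known)) message(sum(!known), " gene list ID(s) dropped (not in catalog)")
  list(genes = unique(ids[known]), n_dropped = sum(!known))
}

#' Write / read the distinct-events table
#'
#' Tab-separated, one row per distinct event: `gene_id`, `event_type`,
#' `chrom`, `start`, `end`, one `support_<ecotype>` column per ecotype, and
#' `confirmed`. Round-trips field-for-field.
#'
#' @param events Events `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly (writer); the events `data.frame` (reader).
#' @export
write_events_tsv <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "event_type", "chrom", "start", "end")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("events table missing column(s): ", paste(miss, collapse = ", "))
  if ("confirmed" %in% names(ev)) ev$confirmed <- as.logical(ev$confirmed)
  ev
}
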