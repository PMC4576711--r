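#' Simulation configuration
#'
#' Parameters of the synthetic two-ecotype transcriptome generator. Defaults
#' describe a desk-scale dataset whose statistical structure mirrors the
#' two-pool study design the analysis assumes: a common gene catalog, two
#' ecotype transcript pools, a planted fraction of alternatively spliced
#' genes (~30%, the prevalence scale observed in arthropods), a partition of
#' planted events into shared / A-specific / B-specific categories at the
#' proportions observed for confirmed louse events (57% / 17% / 26%), a
#' B-specific event-type mixture shifted from intron retention toward exon
#' skipping (the qualitative body-louse pattern) while leaving the other
#' three types at background frequency, junction confirmation at 76.5%, and
#' a 3-fold GO-term bias plus a 2-fold reproductive-list bias among genes
#' with B-specific events.
#'
#' @param n_genes Number of genes.
#' @param n_chroms Number of chromosomes genes are laid out on.
#' @param exons_per_gene,exon_len,intron_len,intergenic_len Inclusive ranges
#'   `c(lo, hi)` in counts/bp.
#' @param transcripts_per_gene Range of transcripts per gene per ecotype.
#' @param ecotypes Length-2 character vector; element 1 is ecotype "A".
#' @param frac_genes_with_events Fraction of genes carrying planted events.
#' @param events_per_gene Range of planted events per event-carrying gene.
#' @param frac_shared,frac_A_specific,frac_B_specific Event-category
#'   proportions (must sum to 1).
#' @param event_mixture Named list `shared`/`A_specific`/`B_specific`, each a
#'   probability vector over the five event types.
#' @param carrier_frac Expected fraction of an ecotype's transcripts
#'   exhibiting a planted event (at least one, never all).
#' @param boundary_shift Range (bp) of alternative splice-site displacement.
#' @param junction_confirm_prob Probability a planted event's boundary is
#'   covered by an emitted junction.
#' @param noise_junction_rate Spurious junctions per kb of genome, placed at
#'   least 2 bp away from every true event boundary.
#' @param n_go_terms,go_term_size GO catalog size and term-size range.
#' @param planted_go_bias List `(term, ecotype, fold)`: sampling weight
#'   multiplier for genes with events specific to `ecotype` when drawing the
#'   members of `term`.
#' @param gene_lists Named list of curated-list specs `(size, fold,
#'   ecotype)`; `fold = 1` means unbiased.
#' @param seed Integer seed; identical configs and seeds yield byte-identical
#'   output files.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_genes = 1000L, n_chroms = 5L,
    exons_per_gene = c(4L, 8L), exon_len = c(80L, 300L),
    intron_len = c(60L, 400L), intergenic_len = c(500L, 2000L),
    transcripts_per_gene = c(15L, 25L),
    ecotypes = c("head", "body"),
    frac_genes_with_events = 0.30,
    events_per_gene = c(1L, 2L),
    frac_shared = 0.57, frac_A_specific = 0.17, frac_B_specific = 0.26,
    event_mixture = list(
      shared     = c(ES = 0.30, `5S` = 0.10, `3S` = 0.15, `3S5S` = 0.05, IR = 0.40),
      A_specific = c(ES = 0.50, `5S` = 0.10, `3S` = 0.15, `3S5S` = 0.05, IR = 0.20),
      B_specific = c(ES = 0.60, `5S` = 0.10, `3S` = 0.15, `3S5S` = 0.05, IR = 0.10)),
    carrier_frac = 0.4,
    boundary_shift = c(8L, 30L),
    junction_confirm_prob = 0.7649,
    noise_junction_rate = 0.05,
    n_go_terms = 8L, go_term_size = c(100L, 220L),
    planted_go_bias = list(term = "GO:B1", ecotype = "body", fold = 3),
    gene_lists = list(
      immune_response       = list(size = 100L, fold = 1, ecotype = NULL),
      phagocytosis_proteome = list(size = 90L,  fold = 1, ecotype = NULL),
      phagocytosis_rnai     = list(size = 110L, fold = 1, ecotype = NULL),
      reproductive          = list(size = 120L, fold = 2, ecotype = "body")),
    seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(frac_shared, frac_A_specific, frac_B_specific)
  if (abs(sum(fr) - 1) > 1e-9) stop("event-category fractions must sum to 1")
  for (nm in names(event_mixture)) {
    mx <- event_mixture[[nm]]
    if (!setequal(names(mx), AS_TYPES) || abs(sum(mx) - 1) > 1e-9)
      stop("event_mixture$", nm, " must be a probability vector over ",
           paste(AS_TYPES, collapse = "/"))
  }
  if (length(ecotypes) != 2) stop("exactly two ecotypes are supported")
  if (exons_per_gene[1] < 4) stop("genes need >= 4 exons to host every event type")
  if (junction_confirm_prob < 0 || junction_confirm_prob > 1)
    stop("junction_confirm_prob must be a probability")
  structure(cfg, class = "simulation_config")
}

# Geometry of one planted event within a gene's exon matrix.
# Returns list(interval = c(start, end), edit) where edit describes how a
# carrier transcript deviates from the full isoform.
plan_event <- function(type, slot, exons, strand, shift_rng) {
  E <- nrow(exons)
  gap <- function(j) c(exons[j, 2], exons[j + 1, 1])  # intron j
  if (type == "ES") {
    j <- slot + 1L  # skipped exon (slot is its upstream intron)
    list(interval = c(exons[j, 1], exons[j, 2]),
         edit = list(op = "skip_exon", exon = j))
  } else if (type == "IR") {
    list(interval = gap(slot),
         edit = list(op = "retain_intron", intron = slot))
  } else if (type %in% c("5S", "3S")) {
    d <- sample_range(shift_rng)
    # donor side is the intron start on +, the intron end on -
    left <- (type == "5S") == (strand == "+")
    g <- gap(slot)
    iv <- if (left) c(g[1] - d, g[2]) else c(g[1], g[2] + d)
    list(interval = iv,
         edit = list(op = "shift", intron = slot,
                     d_left = if (left) d else 0L,
                     d_right = if (left) 0L else d))
  } else {  # 3S5S: both boundaries moved
    d1 <- sample_range(shift_rng); d2 <- sample_range(shift_rng)
    g <- gap(slot)
    list(interval = c(g[1] - d1, g[2] + d2),
         edit = list(op = "shift", intron = slot, d_left = d1, d_right = d2))
  }
}

# Apply a set of event edits to the full-isoform exon matrix.
apply_edits <- function(exons, edits) {
  drop_exon <- rep(FALSE, nrow(exons))
  merge_next <- rep(FALSE, nrow(exons))  # merge exon j with j+1 (retention)
  for (ed in edits) {
    if (ed$op == "skip_exon") drop_exon[ed$exon] <- TRUE
    else if (ed$op == "retain_intron") merge_next[ed$intron] <- TRUE
    else {  # shift: truncate exon j end and/or exon j+1 start
      exons[ed$intron, 2] <- exons[ed$intron, 2] - ed$d_left
      exons[ed$intron + 1L, 1] <- exons[ed$intron + 1L, 1] + ed$d_right
    }
  }
  # close retained-intron gaps, then merge the bookended blocks
  for (j in which(merge_next)) exons[j, 2] <- exons[j + 1L, 1]
  merge_intervals(exons[!drop_exon, , drop = FALSE])
}

#' Generate a synthetic two-ecotype dataset with a ground-truth manifest
#'
#' Writes a GFF3 gene annotation, one BED12 transcript file per ecotype, a
#' junction TSV, a GO map TSV, curated gene-list files, and a manifest JSON
#' recording every planted event (type, interval, category, confirmability),
#' GO/list memberships, and the expected partition counts. Transcripts are
#' exon-subset / boundary-edit derivatives of each gene's full isoform, so
#' every planted event corresponds to an exact geometric edit matching one
#' of the five event definitions. Spurious junctions are kept at least 2 bp
#' from every true event boundary so they can never accidentally confirm an
#' event.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `files` (named paths) and `manifest`.
#' @export
simulate_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  with_seed(config$seed, simulate_dataset_impl(config, outdir))
}

simulate_dataset_impl <- function(cfg, outdir) {
  eco_a <- cfg$ecotypes[1]; eco_b <- cfg$ecotypes[2]
  n <- cfg$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))
  chrom_of <- sprintf("chr%d", 1L + (seq_len(n) - 1L) %% cfg$n_chroms)
  strand_of <- sample(c("+", "-"), n, replace = TRUE)

  # gene structures: sequential layout per chromosome
  cursor <- setNames(rep(0L, cfg$n_chroms), sprintf("chr%d", seq_len(cfg$n_chroms)))
  gene_exons <- vector("list", n)
  gene_start <- integer(n); gene_end <- integer(n)
  for (i in seq_len(n)) {
    E <- sample_range(cfg$exons_per_gene)
    elen <- sample_range(cfg$exon_len, E)
    ilen <- sample_range(cfg$intron_len, E - 1L)
    g0 <- cursor[chrom_of[i]] + sample_range(cfg$intergenic_len)
    starts <- g0 + cumsum(c(0L, elen[-E] + ilen))
    ex <- cbind(start = as.integer(starts), end = as.integer(starts + elen))
    gene_exons[[i]] <- ex
    gene_start[i] <- ex[1, 1]; gene_end[i] <- ex[E, 2]
    cursor[chrom_of[i]] <- gene_end[i]
  }

  # planted events
  n_ev_genes <- round(cfg$frac_genes_with_events * n)
  ev_genes <- sort(sample.int(n, n_ev_genes))
  cat_levels <- c("shared", "A_specific", "B_specific")
  cat_prob <- c(cfg$frac_shared, cfg$frac_A_specific, cfg$frac_B_specific)
  events <- list()
  gene_events <- vector("list", n)  # per gene: list of (event index, edit, categories)
  for (i in ev_genes) {
    ex <- gene_exons[[i]]; E <- nrow(ex)
    n_ev <- sample_range(cfg$events_per_gene)
    occupied <- logical(E - 1L)  # intron slots
    for (k in seq_len(n_ev)) {
      category <- sample(cat_levels, 1, prob = cat_prob)
      type <- sample(AS_TYPES, 1, prob = cfg$event_mixture[[category]])
      # ES occupies the two introns flanking the skipped internal exon
      feasible <- if (type == "ES") {
        which(!occupied[-(E - 1L)] & !occupied[-1L])  # slot j: introns j, j+1 free
      } else which(!occupied)
      if (!length(feasible)) next
      slot <- feasible[sample.int(length(feasible), 1)]
      if (type == "ES") occupied[c(slot, slot + 1L)] <- TRUE else occupied[slot] <- TRUE
      pl <- plan_event(type, slot, ex, strand_of[i], cfg$boundary_shift)
      rec <- data.frame(gene_id = gene_ids[i], event_type = type,
                        chrom = chrom_of[i],
                        start = pl$interval[1], end = pl$interval[2],
                        category = category,
                        confirmable = runif(1) < cfg$junction_confirm_prob,
                        stringsAsFactors = FALSE)
      events[[length(events) + 1L]] <- rec
      gene_events[[i]] <- c(gene_events[[i]],
                            list(list(rec = rec, edit = pl$edit, slot = slot)))
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(gene_id = character(0), event_type = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               category = character(0), confirmable = logical(0))

  # transcript pools
  bed_lines <- setNames(list(character(0), character(0)), cfg$ecotypes)
  for (i in seq_len(n)) {
    ex <- gene_exons[[i]]
    for (eco in cfg$ecotypes) {
      n_tx <- sample_range(cfg$transcripts_per_gene)
      applicable <- Filter(function(ev) {
        ev$rec$category == "shared" ||
          (ev$rec$category == "A_specific" && eco == eco_a) ||
          (ev$rec$category == "B_specific" && eco == eco_b)
      }, gene_events[[i]] %||% list())
      carrier_of <- matrix(FALSE, nrow = n_tx, ncol = length(applicable))
      for (k in seq_along(applicable)) {
        n_car <- max(1L, min(n_tx - 1L, rbinom(1, n_tx, cfg$carrier_frac)))
        carrier_of[sample.int(n_tx, n_car), k] <- TRUE
      }
      for (t in seq_len(n_tx)) {
        edits <- lapply(applicable[carrier_of[t, ]], `[[`, "edit")
        blocks <- apply_edits(ex, edits)
        tid <- sprintf("%s_%s_t%02d", gene_ids[i], eco, t)
        sizes <- blocks[, 2] - blocks[, 1]
        rel <- blocks[, 1] - blocks[1, 1]
        bed_lines[[eco]] <- c(bed_lines[[eco]], paste(
          chrom_of[i], blocks[1, 1], blocks[nrow(blocks), 2], tid, 0L,
          strand_of[i], blocks[1, 1], blocks[nrow(blocks), 2], 0L,
          nrow(blocks), paste(sizes, collapse = ","),
          paste(rel, collapse = ","), sep = "\t"))
      }
    }
  }

  # junctions: one boundary-matching junction per confirmable event, plus noise
  jrows <- list()
  for (i in seq_len(n)) {
    for (ev in gene_events[[i]] %||% list()) {
      if (!ev$rec$confirmable) next
      ex <- gene_exons[[i]]
      iv <- if (ev$rec$event_type == "ES") {
        j <- ev$edit$exon
        c(ex[j - 1L, 2], ex[j, 1])  # upstream constitutive intron; acceptor = event start
      } else c(ev$rec$start, ev$rec$end)
      jrows[[length(jrows) + 1L]] <-
        data.frame(chrom = ev$rec$chrom, intron_start = iv[1], intron_end = iv[2],
                   strand = strand_of[i], stringsAsFactors = FALSE)
    }
  }
  # spurious junctions, kept >= 2 bp away from every true event boundary
  forbidden <- split(c(events$start, events$end), rep(events$chrom, 2))
  genome_kb <- sum(cursor) / 1000
  n_noise <- round(cfg$noise_junction_rate * genome_kb)
  chrs <- names(cursor)
  while (n_noise > 0) {
    ch <- sample(chrs, 1, prob = cursor / sum(cursor))
    s <- sample.int(max(cursor[ch] - 500L, 1L), 1)
    e <- s + sample_range(cfg$intron_len)
    bad <- forbidden[[ch]]
    if (!is.null(bad) && length(bad) &&
        any(abs(outer(c(s, e), bad, "-")) < 2)) next
    jrows[[length(jrows) + 1L]] <-
      data.frame(chrom = ch, intron_start = s, intron_end = e,
                 strand = sample(c("+", "-", "."), 1), stringsAsFactors = FALSE)
    n_noise <- n_noise - 1L
  }
  junctions <- if (length(jrows)) unique(do.call(rbind, jrows)) else
    data.frame(chrom = character(0), intron_start = integer(0),
               intron_end = integer(0), strand = character(0))

  # GO map and curated lists, with planted biases
  spec_b_genes <- unique(events$gene_id[events$category == "B_specific"])
  spec_a_genes <- unique(events$gene_id[events$category == "A_specific"])
  biased_genes <- function(eco) {
    if (is.null(eco)) character(0)
    else if (eco == eco_b) spec_b_genes else spec_a_genes
  }
  weighted_sample <- function(size, fold, eco) {
    w <- rep(1, n)
    w[gene_ids %in% biased_genes(eco)] <- fold
    gene_ids[sample.int(n, min(size, n), prob = w)]
  }
  go_rows <- list()
  go_terms <- sprintf("GO:B%d", seq_len(cfg$n_go_terms))
  for (tt in go_terms) {
    sz <- sample_range(cfg$go_term_size)
    memb <- if (tt == cfg$planted_go_bias$term)
      weighted_sample(sz, cfg$planted_go_bias$fold, cfg$planted_go_bias$ecotype)
    else weighted_sample(sz, 1, NULL)
    go_rows[[tt]] <- data.frame(gene_id = sort(memb), term_id = tt,
                                term_name = paste0("synthetic process ", tt),
                                stringsAsFactors = FALSE)
  }
  go_map <- do.call(rbind, go_rows)
  list_members <- lapply(cfg$gene_lists, function(sp)
    sort(weighted_sample(sp$size, sp$fold, sp$ecotype)))

  # expected partition counts, computed two independent ways
  conf <- events[events$confirmable, , drop = FALSE]
  by_category <- list(
    total_confirmed = nrow(conf),
    shared = sum(conf$category == "shared"),
    specific_A = sum(conf$category == "A_specific"),
    specific_B = sum(conf$category == "B_specific"))
  in_a <- conf$category %in% c("shared", "A_specific")
  in_b <- conf$category %in% c("shared", "B_specific")
  by_support <- partition_counts(sum(in_a), sum(in_b), nrow(conf))
  stopifnot(by_category$shared == by_support$shared,
            by_category$specific_A == by_support$specific_A,
            by_category$specific_B == by_support$specific_B)

  # write files
  f <- function(name) file.path(outdir, name)
  gff <- c("##gff-version 3",
           paste(chrom_of, "sim", "gene", gene_start + 1L, gene_end, ".",
                 strand_of, ".", paste0("ID=", gene_ids), sep = "\t"))
  writeLines(gff, f("genes.gff3"))
  for (eco in cfg$ecotypes)
    writeLines(bed_lines[[eco]], f(paste0("transcripts_", eco, ".bed")))
  write.table(junctions, f("junctions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(go_map, f("go_map.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  for (lname in names(list_members))
    writeLines(list_members[[lname]], f(paste0("list_", lname, ".txt")))

  manifest <- list(
    seed = cfg$seed,
    ecotypes = cfg$ecotypes,
    n_genes = n,
    genes = gene_ids,
    events = events,
    expected_partition = c(by_support["observed_A"], by_support["observed_B"],
                           by_category),
    expected_gene_sets = list(
      genes_specific_A = sort(unique(conf$gene_id[conf$category == "A_specific"])),
      genes_specific_B = sort(unique(conf$gene_id[conf$category == "B_specific"]))),
    go_members = lapply(go_rows, `[[`, "gene_id"),
    list_members = list_members,
    planted_go_bias = cfg$planted_go_bias)
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  files <- c(annotation = f("genes.gff3"),
             setNames(file.path(outdir, paste0("transcripts_", cfg$ecotypes, ".bed")),
                      cfg$ecotypes),
             junctions = f("junctions.tsv"), go_map = f("go_map.tsv"),
             setNames(file.path(outdir, paste0("list_", names(list_members), ".txt")),
                      names(list_members)),
             manifest = f("manifest.json"))
  invisible(list(files = files, manifest = manifest))
}

#' Compare pipeline output with the simulation ground truth
#'
#' Matches detected distinct events against the manifest's planted events by
#' identity tuple and reports per-type recall (planted events detected),
#' confirmed recall (confirmable planted events detected and confirmed),
#' precision (detected events that were planted), and the difference between
#' the pipeline's partition counts and the manifest's expectation.
#'
#' @param manifest Manifest from [simulate_dataset()] (or read back from
#'   `manifest.json`).
#' @param events Distinct events `data.frame` with `confirmed` filled in.
#' @param counts Optional partition counts from [partition_specificity()].
#' @return List with `by_type` (`data.frame`: type, planted, detected,
#'   recall, confirmable, confirmed_recall), `precision`, and
#'   `partition_delta` (when `counts` supplied).
#' @export
end_to_end_recovery_report <- function(manifest, events, counts = NULL) {
  planted <- as.data.frame(manifest$events)
  if (!all(events$gene_id %in% unlist(manifest$genes)))
    stop("events do not match manifest (different simulation run?)")
  pkey <- paste(planted$gene_id, planted$event_type, planted$start, planted$end)
  dkey <- paste(events$gene_id, events$event_type, events$start, events$end)
  planted$detected <- pkey %in% dkey
  planted$confirmed <- pkey %in% dkey[!is.na(events$confirmed) & events$confirmed]
  by_type <- do.call(rbind, lapply(AS_TYPES, function(ty) {
    p <- planted[planted$event_type == ty, , drop = FALSE]
    conf <- p[p$confirmable, , drop = FALSE]
    data.frame(event_type = ty, planted = nrow(p), detected = sum(p$detected),
               recall = if (nrow(p)) mean(p$detected) else NA_real_,
               confirmable = nrow(conf),
               confirmed_recall = if (nrow(conf)) mean(conf$confirmed) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- list(by_type = by_type,
              precision = if (length(dkey)) mean(dkey %in% pkey) else NA_real_)
  if (!is.null(counts)) {
    exp <- manifest$expected_partition
    out$partition_delta <- c(
      shared = counts$shared - exp$shared,
      specific_A = counts$specific_A - exp$specific_A,
      specific_B = counts$specific_B - exp$specific_B,
      total_confirmed = counts$total_confirmed - exp$total_confirmed)
  }
  out
}
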