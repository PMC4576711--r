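#' Run the full comparative-splicing analysis
#'
#' Orchestrates the stages in order — read inputs, assign transcripts,
#' detect and deduplicate events, confirm against junctions, partition by
#' ecotype specificity, compute the per-ecotype coverage-corrected AS index,
#' and run the enrichment analyses — writing one TSV per result table and a
#' machine-readable run summary JSON. GO and curated-list stages are
#' optional and marked `"not run"` in the summary when their inputs are
#' absent. Identical inputs, config, and seeds reproduce identical outputs.
#'
#' @param config Either a named list or a path to a YAML/JSON config file.
#'   Recognised keys: `annotation` (GFF3), `alignments` (named list,
#'   ecotype -> BED12 path), `junctions` (TSV), optional `go_map`, optional
#'   `gene_lists` (named list of files), `outdir`, and the thresholds
#'   `min_intron` (40), `k` (10), `n_samples` (100), `n_iter` (10000),
#'   `min_term` (100), `family_m` (10), `seed_index` (1), `seed_enrich` (1).
#' @return The run summary, invisibly (also written to
#'   `<outdir>/run_summary.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  ecotypes <- names(cfg$alignments)
  f <- function(name) file.path(cfg$outdir, name)

  catalog <- read_gene_annotation(cfg$annotation)
  alignments <- list()
  for (eco in ecotypes)
    alignments <- c(alignments,
                    read_spliced_alignments(cfg$alignments[[eco]], eco,
                                            min_intron = cfg$min_intron))
  asg <- assign_transcripts(alignments, catalog)
  raw <- do.call(rbind, lapply(names(asg$assigned), function(g)
    detect_gene_events(g, asg$assigned[[g]])))
  events <- deduplicate_events(raw, ecotypes = ecotypes)

  jset <- read_junctions(cfg$junctions)
  events <- confirm_events(events, jset)
  write_events_tsv(events, f("events.tsv"))

  conf <- confirmed_only(events)
  part <- partition_specificity(conf, ecotypes = ecotypes)
  write_events_tsv(part$events, f("events_confirmed_partitioned.tsv"))
  gsets <- gene_specificity_sets(part$events, ecotypes = ecotypes)

  index <- list()
  for (eco in ecotypes) {
    per_gene <- lapply(asg$assigned, function(txs)
      Filter(function(a) a$ecotype == eco, txs))
    per_gene <- per_gene[vapply(per_gene, length, 0L) > 0]
    res <- corrected_as_index(per_gene, k = cfg$k, n_samples = cfg$n_samples,
                              seed = cfg$seed_index)
    write.table(res, f(paste0("as_index_", eco, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    index[[eco]] <- res
  }

  type_enr <- event_type_enrichment(part$events, ecotypes = ecotypes,
                                    n_iter = cfg$n_iter, seed = cfg$seed_enrich,
                                    family_m = cfg$family_m)
  write.table(type_enr, f("enrichment_types.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  as_genes <- sort(unique(conf$gene_id))
  go_enr <- NULL; list_enr <- NULL
  if (!is.null(cfg$go_map)) {
    go <- read_go_map(cfg$go_map, catalog)
    go_enr <- list()
    for (eco in ecotypes) {
      spec_genes <- if (eco == ecotypes[1]) gsets$genes_specific_A else
        gsets$genes_specific_B
      r <- tryCatch(
        gene_set_enrichment(spec_genes, as_genes, go$term_genes,
                            n_iter = cfg$n_iter, seed = cfg$seed_enrich,
                            min_term = cfg$min_term),
        error = function(e) { warning("GO enrichment (", eco, ") skipped: ",
                                      conditionMessage(e)); NULL })
      if (!is.null(r)) { r$ecotype <- eco; go_enr[[eco]] <- r }
    }
    go_enr <- if (length(go_enr)) do.call(rbind, go_enr) else NULL
    if (!is.null(go_enr))
      write.table(go_enr, f("enrichment_go.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
  }
  if (!is.null(cfg$gene_lists)) {
    lists <- lapply(cfg$gene_lists, function(p) read_gene_list(p, catalog)$genes)
    list_enr <- list()
    for (eco in ecotypes) {
      spec_genes <- if (eco == ecotypes[1]) gsets$genes_specific_A else
        gsets$genes_specific_B
      r <- tryCatch(
        gene_set_enrichment(spec_genes, as_genes, lists,
                            n_iter = cfg$n_iter, seed = cfg$seed_enrich,
                            min_term = 1L),  # curated lists are tested as-is
        error = function(e) { warning("list enrichment (", eco, ") skipped: ",
                                      conditionMessage(e)); NULL })
      if (!is.null(r)) { r$ecotype <- eco; list_enr[[eco]] <- r }
    }
    list_enr <- if (length(list_enr)) do.call(rbind, list_enr) else NULL
    if (!is.null(list_enr))
      write.table(list_enr, f("enrichment_lists.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
  }

  summary <- list(
    config = cfg[setdiff(names(cfg), "outdir")],
    ecotypes = ecotypes,
    n_transcripts_read = length(alignments),
    n_assigned = sum(vapply(asg$assigned, length, 0L)),
    n_discarded = nrow(asg$discarded),
    discard_reasons = as.list(table(asg$discarded$reason)),
    n_raw_events = if (is.null(raw)) 0L else nrow(raw),
    n_distinct_events = nrow(events),
    n_confirmed_events = nrow(conf),
    confirmation_rate_pct = if (nrow(events))
      confirmation_rate(nrow(conf), nrow(events)) else NA,
    partition = part$counts,
    gene_sets = list(n_specific_A = length(gsets$genes_specific_A),
                     n_specific_B = length(gsets$genes_specific_B),
                     n_both = length(gsets$genes_both),
                     n_union = length(gsets$genes_union)),
    prevalence = lapply(index, function(r) as_prevalence(r)),
    go_enrichment = if (is.null(go_enr)) "not run" else "enrichment_go.tsv",
    list_enrichment = if (is.null(list_enr)) "not run" else "enrichment_lists.tsv",
    seeds = list(index = cfg$seed_index, enrich = cfg$seed_enrich))
  stopifnot(summary$n_transcripts_read ==
              summary$n_assigned + summary$n_discarded)
  jsonlite::write_json(summary, f("run_summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(list(summary = summary, events = events, partition = part,
                 gene_sets = gsets, index = index, type_enrichment = type_enr,
                 go_enrichment = go_enr, list_enrichment = list_enr))
}

load_config <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (grepl("\\.json$", config)) jsonlite::fromJSON(config) else
      yaml::read_yaml(config)
  } else config
  for (key in c("annotation", "alignments", "junctions", "outdir"))
    if (is.null(cfg[[key]])) stop("config is missing required key: ", key)
  defaults <- list(min_intron = 40L, k = 10L, n_samples = 100L,
                   n_iter = 10000L, min_term = 100L, family_m = 10L,
                   seed_index = 1L, seed_enrich = 1L)
  for (key in names(defaults)) cfg[[key]] <- cfg[[key]] %||% defaults[[key]]
  for (p in c(cfg$annotation, unlist(cfg$alignments), cfg$junctions,
              cfg$go_map, unlist(cfg$gene_lists)))
    if (!file.exists(p)) stop("input file not found: ", p)
  cfg
}
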