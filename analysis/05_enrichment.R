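#!/usr/bin/env Rscript
# Stage 5 — randomization enrichment: event types among ecotype-specific
# events (Bonferroni over 10 tests), the body-vs-head two-proportion
# comparison, and GO / curated-list enrichment among genes with
# ecotype-specific events (BH across categories).

suppressMessages(library(ecosplice))

part_events <- read_events_tsv("results/events_confirmed_partitioned.tsv")
catalog <- read_gene_annotation("results/sim/genes.gff3")

te <- event_type_enrichment(part_events, n_iter = 10000L, seed = 21L)
write.table(te, "results/enrichment_types.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- te[!is.na(te$p_adj) & te$p_adj < 0.05, ]
cat("Event types deviating from the pool (Bonferroni p < 0.05):\n")
print(sig[, c("ecotype", "feature_id", "observed", "null_mean", "z", "p_adj",
              "direction")])

sh <- part_events[part_events$specificity == "head_only", ]
sb <- part_events[part_events$specificity == "body_only", ]
for (ty in c("ES", "IR")) {
  z <- two_prop_z(sum(sb$event_type == ty), nrow(sb),
                  sum(sh$event_type == ty), nrow(sh))
  cat(sprintf("2-prop Z, %s share body vs head: z = %.3f, p = %.4f\n",
              ty, z$z, z$p))
}

part <- partition_specificity(part_events)
gs <- gene_specificity_sets(part$events)
bg <- sort(unique(part_events$gene_id))
go <- read_go_map("results/sim/go_map.tsv", catalog)
for (eco in c("head", "body")) {
  spec <- if (eco == "head") gs$genes_specific_A else gs$genes_specific_B
  r <- gene_set_enrichment(spec, bg, go$term_genes, n_iter = 10000L,
                           seed = 31L, min_term = 30L)
  r$ecotype <- eco
  write.table(r, sprintf("results/enrichment_go_%s.tsv", eco), sep = "\t",
              quote = FALSE, row.names = FALSE)
  hits <- r[r$p_adj < 0.05, ]
  cat(eco, "GO categories at BH p < 0.05:",
      if (nrow(hits)) paste(hits$feature_id, paste0("(", hits$direction, ")"),
                            collapse = ", ") else "none", "\n")
}

lists <- list(
  immune_response = read_gene_list("results/sim/list_immune_response.txt", catalog)$genes,
  phagocytosis_proteome = read_gene_list("results/sim/list_phagocytosis_proteome.txt", catalog)$genes,
  phagocytosis_rnai = read_gene_list("results/sim/list_phagocytosis_rnai.txt", catalog)$genes,
  reproductive = read_gene_list("results/sim/list_reproductive.txt", catalog)$genes)
for (eco in c("head", "body")) {
  spec <- if (eco == "head") gs$genes_specific_A else gs$genes_specific_B
  r <- gene_set_enrichment(spec, bg, lists, n_iter = 10000L, seed = 41L,
                           min_term = 1L)
  r$ecotype <- eco
  write.table(r, sprintf("results/enrichment_lists_%s.tsv", eco), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(eco, "curated lists: ")
  cat(paste(sprintf("%s p_adj=%.3f", r$feature_id, r$p_adj), collapse = "; "),
      "\n")
}
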