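# End-to-end pipeline over the synthetic experiment, with per-stage
# artifacts, a manifest, and a deterministic heatmap ordering.

#' Run the full synthetic small RNA analysis pipeline
#'
#' Stages, in order: reference generation, count-level truth, per-library
#' read simulation, seven-rule QC, annotation summary and rRNA gate, known
#' miRNA quantification and TPM, differential expression and DE-type
#' classification, novel miRNA calling, target prediction, conjoint
#' analysis, enrichment, and qPCR round-trip. Outputs are a pure function of
#' (config, seed): re-running with the same config reproduces identical
#' tables.
#'
#' @param config [sim_config()] object (or a path to a YAML file of
#'   `sim_config()` arguments).
#' @param out_dir optional output directory; when given, every stage table
#'   is written as TSV alongside reference FASTA/GFF3 files, a YAML config
#'   echo and a JSON `manifest.json` with per-stage row counts.
#' @param min_novel_reads minimum read support for a locus to seed a novel
#'   miRNA candidate window (default 10).
#' @param write_fastq also write the simulated FASTQ libraries (off by
#'   default: they dominate the output size).
#' @return list of class `mirdef_run` with every stage result and the
#'   ground truth.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         min_novel_reads = 10, write_fastq = FALSE) {
  if (is.character(config)) {
    config <- do.call(sim_config, yaml::read_yaml(config))
  }
  refs <- generate_reference_set(config)
  sim <- simulate_count_libraries(config, refs)
  truth <- sim$truth

  qc_reports <- list()
  clean_all <- list()
  fates_all <- list()
  for (lib in names(config$library_sizes)) {
    rl <- simulate_read_library(config, refs, truth, lib)
    qc <- filter_reads(rl$reads, config$adapter_3p, config$adapter_5p)
    qc_reports[[lib]] <- qc$report
    clean_all[[lib]] <- mutate(qc$clean, library = lib)
    fates_all[[lib]] <- mutate(
      left_join(rl$fates, qc$fates, by = "id", suffix = c("_planted", "_observed")),
      library = lib)
    if (!is.null(out_dir) && write_fastq) {
      dir.create(file.path(out_dir, "fastq"), recursive = TRUE, showWarnings = FALSE)
      write_fastq(rl$reads, file.path(out_dir, "fastq", paste0(lib, ".fastq")))
    }
  }
  qc_report <- bind_rows(qc_reports, .id = "library")
  clean <- bind_rows(clean_all)
  fates <- bind_rows(fates_all)
  qc_totals <- select(qc_report, "library", "total_reads")

  summary <- annotation_summary(clean, refs$index, qc_totals)
  gate <- rrna_qc_gate(summary)

  counts <- quantify_known(clean, refs$index$mirna_catalog)
  clean_totals <- qc_report %>% select("library", n = "clean_reads")
  expr <- tpm_normalize(counts, clean_totals)
  conservation <- grade_conservation(refs$index$mirna_catalog)

  de <- call_de(counts, library_totals = clean_totals)
  de_types <- classify_de_types(de)

  # novel miRNA discovery from well-supported unannotated mapped loci
  uniq <- clean %>% count(.data$sequence, name = "count")
  uniq <- annotate_priority(uniq, refs$index)
  unann <- uniq %>%
    filter(.data$annotation == "unannotated", .data$count >= min_novel_reads)
  unann <- map_to_genome(unann, refs$index) %>% filter(.data$mapped)
  cands <- extract_precursor_candidates(unann, refs$index$genome)
  novel <- call_novel(cands)

  pairs <- simulate_expression_pairs(config, refs, truth)
  de_mirnas <- de %>% filter(.data$call != "ns") %>% distinct(.data$mirna)
  target_in <- refs$index$mirna_catalog %>%
    filter(.data$mature_id %in% de_mirnas$mirna) %>%
    select(id = "mature_id", "sequence")
  targets <- if (nrow(target_in)) {
    predict_targets(target_in, pairs$transcripts)
  } else {
    tibble(mirna = character(), transcript = character())
  }
  conjoint <- conjoint_negative_pairs(de, pairs$mrna_de, targets)
  conjoint_summary <- summarize_conjoint(conjoint)

  enrich <- if (nrow(conjoint)) {
    hypergeom_enrich(unique(conjoint$transcript), pairs$annotation_map,
                     universe = pairs$transcripts$id)
  } else {
    NULL
  }

  ct <- simulate_qpcr(config, truth)
  qpcr <- purrr::map(setNames(nm = default_comparisons()), function(cmp) {
    cond <- strsplit(cmp, "/")[[1]]
    rq <- delta_delta_ct(ct, treat = cond[1], control = cond[2])
    conc <- concordance_check(
      rq, filter(de, .data$comparison == cmp, .data$call != "ns"))
    list(rq = rq, concordance = conc)
  })

  heat <- cluster_order(
    de %>% filter(.data$mirna %in% de_mirnas$mirna) %>%
      select("mirna", "comparison", "log2fc")
  )

  run <- structure(
    list(config = config, refs = refs, truth = truth, qc_report = qc_report,
         fates = fates, annotation_summary = summary, rrna_gate = gate,
         expression = expr, conservation = conservation, de = de,
         de_types = de_types, novel = novel, targets = targets,
         mrna = pairs, conjoint = conjoint,
         conjoint_summary = conjoint_summary, enrichment = enrich,
         ct = ct, qpcr = qpcr, heatmap = heat),
    class = "mirdef_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_gff3 <- function(gene_model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(gene_model)) {
    writeLines(sprintf("%s\tmirdefense\t%s\t%d\t%d\t.\t+\t.\tID=%s",
                       gene_model$contig, gene_model$feature, gene_model$start,
                       gene_model$end, gene_model$gene_id), con)
  }
  invisible(path)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_tsv(x, file.path(out_dir, paste0(name, ".tsv")))
    nrow(x)
  }
  cfg <- run$config
  yaml::write_yaml(
    lapply(unclass(cfg), function(v) if (is.numeric(v)) unname(v) else v),
    file.path(out_dir, "config.yaml")
  )
  write_fasta(run$refs$index$genome %>% rename(id = "contig"),
              file.path(out_dir, "genome.fasta"))
  write_gff3(run$refs$index$gene_model, file.path(out_dir, "gene_model.gff3"))
  counts <- c(
    qc_report = w(run$qc_report, "qc_report"),
    annotation_summary = w(as_tibble(run$annotation_summary), "annotation_summary"),
    rrna_gate = w(run$rrna_gate, "rrna_gate"),
    expression = w(run$expression, "expression_matrix"),
    conservation = w(run$conservation, "conservation_grades"),
    de = w(as_tibble(run$de), "differential_expression"),
    de_types = w(tidy(run$de_types), "de_types"),
    novel = w(run$novel$calls, "novel_mirna_calls"),
    targets = w(as_tibble(run$targets), "target_sites"),
    conjoint = w(as_tibble(run$conjoint), "conjoint_pairs"),
    enrichment = if (!is.null(run$enrichment)) w(as_tibble(run$enrichment), "enrichment") else 0L,
    ground_truth_de = w(run$truth$de_planted, "ground_truth_de"),
    read_fates = w(run$fates, "read_fates")
  )
  manifest <- list(
    package = "mirdefense",
    version = as.character(utils::packageVersion("mirdefense")),
    seed = cfg$seed,
    libraries = as.list(cfg$library_sizes),
    rows = as.list(counts)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Deterministic hierarchical ordering of a DE fold-change matrix
#'
#' Average-linkage hierarchical clustering on Euclidean distances of the
#' miRNA x comparison log2 fold-change matrix (missing cells imputed to 0),
#' as used for DE heatmaps; the comparison (column) dendrogram is also cut
#' at k = 2 to report the two-module split.
#'
#' @param lfc long tibble `mirna`, `comparison`, `log2fc`.
#' @return list of class `mirdef_cluster`: `matrix`, `row_order` (miRNA
#'   ids), `col_order` (comparison labels), `col_modules` (named k = 2
#'   membership).
#' @export
cluster_order <- function(lfc) {
  wide <- lfc %>%
    distinct(.data$mirna, .data$comparison, .keep_all = TRUE) %>%
    tidyr::pivot_wider(names_from = "comparison", values_from = "log2fc")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$mirna
  mat[is.na(mat)] <- 0
  row_order <- if (nrow(mat) > 1) {
    rownames(mat)[hclust(dist(mat), method = "average")$order]
  } else {
    rownames(mat)
  }
  if (ncol(mat) > 1) {
    col_hc <- hclust(dist(t(mat)), method = "average")
    col_order <- colnames(mat)[col_hc$order]
    col_modules <- cutree(col_hc, k = 2)
  } else {
    col_order <- colnames(mat)
    col_modules <- setNames(rep(1L, ncol(mat)), colnames(mat))
  }
  structure(
    list(matrix = mat, row_order = row_order, col_order = col_order,
         col_modules = col_modules),
    class = "mirdef_cluster"
  )
}

#' @export
print.mirdef_run <- function(x, ...) {
  cat(sprintf(
    "<mirdef_run> seed %d: %d clean reads, %d miRNAs quantified, %d DE calls, %d novel accepted, %d conjoint pairs\n",
    x$config$seed, sum(x$qc_report$clean_reads),
    dplyr::n_distinct(x$expression$mirna), sum(x$de$call != "ns"),
    nrow(x$novel$accepted), nrow(x$conjoint)))
  invisible(x)
}
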