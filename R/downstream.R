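# Hypergeometric enrichment and stem-loop qRT-PCR quantification.

#' Hypergeometric GO/KEGG enrichment of a gene set
#'
#' Upper-tail hypergeometric test per term: with a universe of `N` genes of
#' which `K` carry the term, and a query set of `n` genes of which `k` carry
#' it, `p = P(X >= k)`. q-values are BH-adjusted within each namespace; a
#' term is called significant at `p <= alpha` (raw-p gating, the q-gated
#' column is emitted alongside).
#'
#' @param gene_set character vector of query gene ids (must lie in the
#'   universe).
#' @param annotation tibble `term_id`, `namespace`, `term_name`, `gene_id`
#'   (one row per term-gene link; no empty terms).
#' @param universe character vector of background gene ids; defaults to all
#'   genes in the annotation map.
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @return tibble of class `mirdef_enrich`: `term_id`, `namespace`,
#'   `term_name`, `k`, `K`, `n`, `N`, `p`, `q`, `significant`,
#'   `significant_q`.
#' @export
hypergeom_enrich <- function(gene_set, annotation, universe = NULL,
                             alpha = 0.05) {
  if (is.null(universe)) universe <- unique(annotation$gene_id)
  if (!length(universe)) abort("empty gene universe")
  stray <- setdiff(gene_set, universe)
  if (length(stray))
    abort(paste0("query genes outside the universe: ",
                 paste(head(stray, 3), collapse = ", ")))
  gene_set <- unique(gene_set)
  ann <- filter(annotation, .data$gene_id %in% universe)
  N <- length(universe)
  n <- length(gene_set)
  out <- ann %>%
    group_by(.data$term_id, .data$namespace, .data$term_name) %>%
    summarise(K = dplyr::n_distinct(.data$gene_id),
              k = dplyr::n_distinct(intersect(.data$gene_id, gene_set)),
              .groups = "drop") %>%
    mutate(n = n, N = N,
           p = phyper(.data$k - 1, .data$K, .data$N - .data$K, .data$n,
                      lower.tail = FALSE)) %>%
    group_by(.data$namespace) %>%
    mutate(q = qvalue_adjust(.data$p)) %>%
    ungroup() %>%
    mutate(significant = .data$p <= alpha,
           significant_q = .data$q <= alpha) %>%
    arrange(.data$p, .data$term_id)
  structure(out, class = c("mirdef_enrich", class(out)))
}

#' Relative quantification from stem-loop qRT-PCR Ct values (2^-ddCt)
#'
#' Per miRNA: `dCt = mean Ct(miRNA) - mean Ct(reference)` within each sample,
#' `ddCt = dCt(treat) - dCt(control)`, `RQ = 2^-ddCt`. The p-value is a
#' two-sided two-sample t-test on per-replicate dCt values (replicates paired
#' with the reference by replicate index).
#'
#' @param ct tibble `mirna`, `sample`, `rep`, `ct` (Ct > 0, at least three
#'   replicates per miRNA and sample).
#' @param treat,control sample labels to contrast.
#' @param reference reference miRNA id (default `"mir1520d"`); must be
#'   present in both samples.
#' @param alpha significance threshold (default 0.05).
#' @return tibble of class `mirdef_rq`: `mirna`, `dct_treat`, `dct_control`,
#'   `ddct`, `rq`, `p`, `significant`.
#' @export
delta_delta_ct <- function(ct, treat, control, reference = "mir1520d",
                           alpha = 0.05) {
  ct <- filter(ct, .data$sample %in% c(treat, control))
  if (any(ct$ct <= 0)) abort("Ct values must be positive")
  ref <- filter(ct, .data$mirna == reference)
  if (!all(c(treat, control) %in% ref$sample))
    abort(paste0("reference gene '", reference, "' missing from a sample"))
  nrep <- ct %>% count(.data$mirna, .data$sample)
  if (any(nrep$n < 3)) abort("at least three replicates are required per (miRNA, sample)")
  dct <- ct %>%
    filter(.data$mirna != reference) %>%
    inner_join(ref %>% select("sample", "rep", ref_ct = "ct"),
               by = c("sample", "rep")) %>%
    mutate(dct = .data$ct - .data$ref_ct)
  out <- dct %>%
    group_by(.data$mirna) %>%
    summarise(
      dct_treat = mean(.data$dct[.data$sample == treat]),
      dct_control = mean(.data$dct[.data$sample == control]),
      p = safe_t_test(.data$dct[.data$sample == treat],
                      .data$dct[.data$sample == control]),
      .groups = "drop"
    ) %>%
    mutate(ddct = .data$dct_treat - .data$dct_control,
           rq = 2^-.data$ddct,
           significant = .data$p <= alpha) %>%
    select("mirna", "dct_treat", "dct_control", "ddct", "rq", "p",
           "significant")
  structure(out, class = c("mirdef_rq", class(out)))
}

# t.test errors on zero-variance input (the noiseless simulation limit);
# degenerate comparisons collapse to 1 (equal means) or 0 (different).
safe_t_test <- function(x, y) {
  tryCatch(t.test(x, y)$p.value,
           error = function(e) if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
}

#' Concordance between qRT-PCR and sequencing fold changes
#'
#' A miRNA agrees when the sign of `log2(RQ)` matches the sign of its
#' sequencing `log2fc`.
#'
#' @param rq_table output of [delta_delta_ct()] (or tibble `mirna`, `rq`).
#' @param de_table tibble `mirna`, `log2fc` (e.g. one comparison of a
#'   `mirdef_de` table).
#' @return list with `per_mirna` (tibble `mirna`, `rq_log2`, `log2fc`,
#'   `agree`) and `agreement_fraction`.
#' @export
concordance_check <- function(rq_table, de_table) {
  per <- rq_table %>%
    inner_join(select(de_table, "mirna", "log2fc"), by = "mirna") %>%
    transmute(.data$mirna, rq_log2 = log2(.data$rq), .data$log2fc,
              agree = sign(.data$rq_log2) == sign(.data$log2fc))
  list(per_mirna = per,
       agreement_fraction = if (nrow(per)) mean(per$agree) else NA_real_)
}
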