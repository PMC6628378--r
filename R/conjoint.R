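# miRNA/mRNA negative-regulation conjoint analysis.
#
# Plant miRNAs act by transcript cleavage, so regulation is assumed
# negative: within each comparison, a differentially expressed miRNA is
# paired with its predicted target transcripts that are differentially
# expressed in the opposite direction.

#' Pair DE miRNAs with opposite-direction DE predicted targets
#'
#' @param de_mirnas tibble with columns `mirna`, `comparison`, `log2fc`,
#'   `call` (only `"up"`/`"down"` rows are used).
#' @param de_mrnas tibble with columns `transcript`, `comparison`, `log2fc`,
#'   `call`, optionally `description`.
#' @param targets predicted target table with columns `mirna`, `transcript`.
#' @param lfc_min minimum |log2fc| on both sides (default 1).
#' @return tibble of class `mirdef_conjoint`: `comparison`, `mirna`,
#'   `mirna_log2fc`, `transcript`, `mrna_log2fc`, `description`.
#' @export
conjoint_negative_pairs <- function(de_mirnas, de_mrnas, targets, lfc_min = 1) {
  extra <- setdiff(unique(de_mrnas$comparison), unique(de_mirnas$comparison))
  if (length(extra))
    abort(paste0("comparison labels missing from the miRNA table: ",
                 paste(extra, collapse = ", ")))
  if (!"description" %in% names(de_mrnas)) de_mrnas$description <- NA_character_
  mi <- de_mirnas %>%
    filter(.data$call %in% c("up", "down"), abs(.data$log2fc) >= lfc_min) %>%
    select("comparison", "mirna", mirna_log2fc = "log2fc")
  mr <- de_mrnas %>%
    filter(.data$call %in% c("up", "down"), abs(.data$log2fc) >= lfc_min) %>%
    select("comparison", "transcript", mrna_log2fc = "log2fc", "description")
  out <- mi %>%
    inner_join(distinct(targets, .data$mirna, .data$transcript),
               by = "mirna", relationship = "many-to-many") %>%
    inner_join(mr, by = c("comparison", "transcript"),
               relationship = "many-to-many") %>%
    filter(sign(.data$mirna_log2fc) * sign(.data$mrna_log2fc) == -1) %>%
    distinct(.data$comparison, .data$mirna, .data$transcript, .keep_all = TRUE) %>%
    arrange(.data$comparison, .data$mirna, .data$transcript)
  structure(out, class = c("mirdef_conjoint", class(out)))
}

#' Summarize a conjoint pair table
#'
#' @param pairs conjoint pair table from [conjoint_negative_pairs()].
#' @return list of class `mirdef_conjoint_summary`: `n_pairs`,
#'   `n_unique_mirnas`, `n_unique_transcripts`, `per_comparison` (distinct
#'   miRNA/transcript/pair counts), `targets_per_mirna` (distinct targets per
#'   miRNA over the whole table), and `shared_targets` (transcripts hit by
#'   more than one miRNA, with the miRNA set).
#' @export
summarize_conjoint <- function(pairs) {
  per_comparison <- pairs %>%
    group_by(.data$comparison) %>%
    summarise(n_mirnas = dplyr::n_distinct(.data$mirna),
              n_transcripts = dplyr::n_distinct(.data$transcript),
              n_pairs = n(), .groups = "drop")
  targets_per_mirna <- pairs %>%
    group_by(.data$mirna) %>%
    summarise(n_targets = dplyr::n_distinct(.data$transcript), .groups = "drop") %>%
    arrange(desc(.data$n_targets), .data$mirna)
  shared_targets <- pairs %>%
    distinct(.data$transcript, .data$mirna) %>%
    group_by(.data$transcript) %>%
    summarise(n_mirnas = dplyr::n_distinct(.data$mirna),
              mirnas = list(sort(unique(.data$mirna))), .groups = "drop") %>%
    filter(.data$n_mirnas > 1) %>%
    arrange(desc(.data$n_mirnas), .data$transcript)
  structure(
    list(
      n_pairs = nrow(pairs),
      n_unique_mirnas = dplyr::n_distinct(pairs$mirna),
      n_unique_transcripts = dplyr::n_distinct(pairs$transcript),
      per_comparison = per_comparison,
      targets_per_mirna = targets_per_mirna,
      shared_targets = shared_targets
    ),
    class = "mirdef_conjoint_summary"
  )
}

#' @export
print.mirdef_conjoint_summary <- function(x, ...) {
  cat(sprintf(
    "<mirdef_conjoint_summary> %d pairs: %d miRNAs negatively correlated with %d target transcripts\n",
    x$n_pairs, x$n_unique_mirnas, x$n_unique_transcripts))
  invisible(x)
}
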