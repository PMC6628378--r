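# Packaged worked-example fixtures: the per-library sequencing statistics
# table and the printed miRNA/mRNA conjoint pair table, transcribed from the
# motivating study's published tables (one stray space inside a gene id was
# normalized during transcription).

#' Load the packaged library-statistics fixture
#'
#' The published per-library sequencing report: raw/clean/mapped totals and
#' annotation-class counts with the printed percentages, in tidy long form.
#'
#' @return tibble `type`, `library`, `count`, `printed_pct` (NA for the
#'   total row, which prints no percentage).
#' @export
read_table1_fixture <- function() {
  path <- system.file("extdata", "table1_library_stats.tsv",
                      package = "mirdefense", mustWork = TRUE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  raw %>%
    tidyr::pivot_longer(-"type", names_to = "library", values_to = "cell") %>%
    mutate(
      count = as.numeric(sub("\\(.*", "", .data$cell)),
      printed_pct = ifelse(
        grepl("\\(", .data$cell),
        as.numeric(sub(".*\\(([0-9.]+)%\\)", "\\1", .data$cell)),
        NA_real_
      )
    ) %>%
    select("type", "library", "count", "printed_pct")
}

#' Load the packaged conjoint-pair fixture
#'
#' The printed negative-regulation pairs: per comparison, each DE miRNA with
#' its opposite-direction DE target transcript and fold changes.
#'
#' @return tibble `comparison`, `mirna`, `mirna_log2fc`, `transcript`,
#'   `mrna_log2fc`, `description`.
#' @export
read_table3_fixture <- function() {
  path <- system.file("extdata", "table3_conjoint_pairs.tsv",
                      package = "mirdefense", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    comparison = "c", mirna = "c", mirna_log2fc = "d", transcript = "c",
    mrna_log2fc = "d", description = "c"
  ))
}

#' Recast the conjoint fixture as DE tables plus an implied target map
#'
#' Every printed pair is taken as a predicted target relation; the two fold
#'-change columns become miRNA and mRNA DE tables with up/down calls by
#' sign. Feeding these into [conjoint_negative_pairs()] must reproduce the
#' printed rows exactly.
#'
#' @return list `de_mirnas`, `de_mrnas`, `target_map`.
#' @export
table3_as_inputs <- function() {
  t3 <- read_table3_fixture()
  list(
    de_mirnas = t3 %>%
      distinct(.data$comparison, .data$mirna, .data$mirna_log2fc) %>%
      transmute(.data$mirna, .data$comparison, log2fc = .data$mirna_log2fc,
                call = if_else(.data$mirna_log2fc > 0, "up", "down")),
    de_mrnas = t3 %>%
      distinct(.data$comparison, .data$transcript, .data$mrna_log2fc,
               .data$description) %>%
      transmute(.data$transcript, .data$comparison, log2fc = .data$mrna_log2fc,
                call = if_else(.data$mrna_log2fc > 0, "up", "down"),
                .data$description),
    target_map = distinct(t3, .data$mirna, .data$transcript)
  )
}
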