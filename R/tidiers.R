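# broom-style tidiers for the package's result objects.

#' Tidy a QC result
#'
#' One row per read fate (clean plus the seven removal rules) with counts
#' and fractions.
#'
#' @param x `mirdef_qc` object.
#' @param ... unused.
#' @return tibble `fate`, `count`, `fraction`.
#' @export
tidy.mirdef_qc <- function(x, ...) {
  r <- x$report
  tibble(
    fate = c("clean", names(RULE_LABELS)),
    count = c(r$clean_reads, unlist(r[names(RULE_LABELS)], use.names = FALSE)),
  ) %>%
    mutate(fraction = if (r$total_reads > 0) .data$count / r$total_reads else NA_real_)
}

#' @rdname tidy.mirdef_qc
#' @export
glance.mirdef_qc <- function(x, ...) x$report

#' Tidy a DE result table
#'
#' @param x `mirdef_de` object.
#' @param ... unused.
#' @return the underlying tibble.
#' @export
tidy.mirdef_de <- function(x, ...) as_tibble(x)

#' @rdname tidy.mirdef_de
#' @export
glance.mirdef_de <- function(x, ...) {
  as_tibble(x) %>%
    group_by(.data$comparison) %>%
    summarise(n_tested = n(),
              n_up = sum(.data$call == "up"),
              n_down = sum(.data$call == "down"),
              n_de = sum(.data$call != "ns"),
              n_specific = sum(!is.na(.data$specific)),
              .groups = "drop")
}

#' Tidy a DE-type partition
#'
#' @param x `mirdef_de_types` object.
#' @param ... unused.
#' @return long tibble `type`, `mirna`, `subcategory`.
#' @export
tidy.mirdef_de_types <- function(x, ...) {
  bind_rows(purrr::imap(x, ~mutate(.x, type = .y))) %>%
    select("type", "mirna", "subcategory")
}

#' @rdname tidy.mirdef_de_types
#' @export
glance.mirdef_de_types <- function(x, ...) {
  tibble(type1 = nrow(x$type1), type2 = nrow(x$type2), type3 = nrow(x$type3))
}

#' Tidy a novel-miRNA call set
#'
#' @param x `mirdef_novel` object.
#' @param ... unused.
#' @return the per-candidate call tibble.
#' @export
tidy.mirdef_novel <- function(x, ...) as_tibble(x$calls)

#' @rdname tidy.mirdef_novel
#' @export
glance.mirdef_novel <- function(x, ...) {
  tibble(n_candidates = nrow(x$calls), n_accepted = nrow(x$accepted),
         first_base_u_fraction = x$first_base_u_fraction)
}

#' Tidy a conjoint summary
#'
#' @param x `mirdef_conjoint_summary` object.
#' @param ... unused.
#' @return the per-comparison count tibble.
#' @export
tidy.mirdef_conjoint_summary <- function(x, ...) x$per_comparison

#' @rdname tidy.mirdef_conjoint_summary
#' @export
glance.mirdef_conjoint_summary <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, n_unique_mirnas = x$n_unique_mirnas,
         n_unique_transcripts = x$n_unique_transcripts)
}
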