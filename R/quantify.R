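# Known-miRNA quantification, TPM normalization, conservation grading.

#' Count clean reads per known mature miRNA and library
#'
#' A read is assigned to a mature miRNA when both start at the same 5' base
#' and one is a prefix of the other with a length difference of at most
#' `trail_tolerance` nucleotides (3' trailing tolerance); internal mismatches
#' are never tolerated. Exact matches take precedence over trailing variants;
#' among trailing variants the longest shared prefix wins.
#'
#' @param clean tibble of clean reads with columns `library`, `sequence`.
#' @param catalog miRNA catalog tibble (`mature_id`, `sequence`, ...);
#'   duplicate mature ids are an error.
#' @param trail_tolerance maximum 3' length difference (default 2).
#' @return long count tibble `mirna`, `library`, `count`, complete over the
#'   catalog x library grid.
#' @export
quantify_known <- function(clean, catalog, trail_tolerance = 2) {
  if (!nrow(catalog)) abort("miRNA catalog is empty")
  if (anyDuplicated(catalog$mature_id)) abort("duplicate mature ids in catalog")
  exact <- setNames(catalog$mature_id, catalog$sequence)
  keys <- clean$sequence
  assign <- unname(exact[keys])
  todo <- which(is.na(assign))
  if (length(todo) && trail_tolerance > 0) {
    # read longer than mature: truncate read; read shorter: look the read up
    # in the mature-prefix dictionaries (longest prefix first)
    for (d in seq_len(trail_tolerance)) {
      trunc <- substr(keys[todo], 1, pmax(nchar(keys[todo]) - d, 1))
      cand <- unname(exact[trunc])
      assign[todo[!is.na(cand)]] <- cand[!is.na(cand)]
      todo <- which(is.na(assign))
      if (!length(todo)) break
    }
    if (length(todo)) {
      for (d in seq_len(trail_tolerance)) {
        pref <- substr(catalog$sequence, 1, pmax(nchar(catalog$sequence) - d, 1))
        dict <- setNames(catalog$mature_id, pref)[!duplicated(pref)]
        cand <- unname(dict[keys[todo]])
        assign[todo[!is.na(cand)]] <- cand[!is.na(cand)]
        todo <- which(is.na(assign))
        if (!length(todo)) break
      }
    }
  }
  hits <- tibble(library = clean$library, mirna = assign) %>%
    filter(!is.na(.data$mirna)) %>%
    count(.data$mirna, .data$library, name = "count")
  tidyr::expand_grid(mirna = catalog$mature_id,
                     library = sort(unique(clean$library))) %>%
    left_join(hits, by = c("mirna", "library")) %>%
    mutate(count = dplyr::coalesce(.data$count, 0L))
}

#' TPM-normalize a count table
#'
#' Tags per million: `tpm = count * 1e6 / N`, where `N` is the per-library
#' total. By default `N` is the column sum of the table itself (so TPM sums
#' to 1e6 per library); in the pipeline `N` is each library's clean read
#' count, matching the convention of the standard sequencing report.
#'
#' @param counts long tibble `mirna`, `library`, `count`.
#' @param library_totals optional tibble `library`, `n` (or named numeric) of
#'   per-library totals N; any zero total is an error naming the library.
#' @return input with a `tpm` column appended.
#' @export
tpm_normalize <- function(counts, library_totals = NULL) {
  if (is.null(library_totals)) {
    library_totals <- counts %>%
      group_by(.data$library) %>%
      summarise(n = sum(.data$count), .groups = "drop")
  } else if (!is.data.frame(library_totals)) {
    library_totals <- tibble(library = names(library_totals),
                             n = as.numeric(library_totals))
  }
  zero <- library_totals$library[library_totals$n <= 0]
  if (length(zero))
    abort(paste0("library total N is zero for: ", paste(zero, collapse = ", ")))
  missing <- setdiff(unique(counts$library), library_totals$library)
  if (length(missing))
    abort(paste0("no library total for: ", paste(missing, collapse = ", ")))
  counts %>%
    left_join(library_totals, by = "library") %>%
    mutate(tpm = .data$count * 1e6 / .data$n) %>%
    select(-"n")
}

#' Grade miRNA family conservation by plant-species occurrence
#'
#' Families found in more than 10 plant species are highly conserved, in 5-9
#' moderately, in 2-4 lowly, and in a single species non-conserved. The
#' published rule leaves exactly 10 species unspecified; that gap defaults to
#' moderately conserved (the nearest stated band) and is reported.
#'
#' @param catalog tibble with `family_id` and `n_species` (>= 1; occurrence 0
#'   is an error).
#' @return tibble `family_id`, `n_species`, `grade` (one row per family;
#'   `n_species` must be constant within family).
#' @export
grade_conservation <- function(catalog) {
  fam <- distinct(catalog, .data$family_id, .data$n_species)
  if (anyDuplicated(fam$family_id))
    abort("inconsistent n_species within a family")
  if (any(fam$n_species < 1 | fam$n_species != floor(fam$n_species)))
    abort("species occurrence must be an integer >= 1")
  if (any(fam$n_species == 10))
    rlang::inform(
      "occurrence of exactly 10 species falls in the unspecified gap of the grading rule; graded moderately conserved",
      .frequency = "once", .frequency_id = "mirdef_grade_gap"
    )
  fam %>%
    mutate(grade = dplyr::case_when(
      .data$n_species > 10 ~ "highly",
      .data$n_species >= 5 ~ "moderately", # includes the documented gap at 10
      .data$n_species >= 2 ~ "lowly",
      TRUE ~ "non-conserved"
    )) %>%
    arrange(.data$family_id)
}
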