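# MA-plot binomial differential expression.
#
# Two-library model: each condition's summed count C is assumed to be a
# binomial draw from its library total N. On the MA plane, M = log2 C1 -
# log2 C2 is approximately normal given A; under the null hypothesis of a
# common sampling proportion p = (C1+C2)/(N1+N2), M has mean log2(N1/N2) and
# delta-method variance (1-p)/ln(2)^2 * (1/(N1 p) + 1/(N2 p)). An exact
# conditional binomial test serves as the small-count oracle.

#' MA-plot statistics
#'
#' `M = log2 C1 - log2 C2`, `A = (log2 C1 + log2 C2)/2`.
#'
#' @param c1,c2 positive counts (vectorised). Nonpositive counts are an
#'   error: zero-count rows are handled by the specificity logic of
#'   [call_de()], not here.
#' @return tibble `M`, `A`.
#' @export
ma_stats <- function(c1, c2) {
  if (any(c1 <= 0) || any(c2 <= 0))
    abort("ma_stats requires positive counts; zeros are routed to specificity handling")
  tibble(M = log2(c1) - log2(c2), A = (log2(c1) + log2(c2)) / 2)
}

#' Normal-approximation MA-plot test
#'
#' Two-sided p-value for the null hypothesis that both counts arise from a
#' common sampling proportion. Zero counts enter the M statistic with a
#' half-count continuity floor so the statistic stays finite; rows with
#' `c1 + c2 == 0` get p = 1 with a warning.
#'
#' @param c1,c2 condition counts (vectorised).
#' @param n1,n2 library totals (> 0).
#' @return numeric p-values in (0, 1].
#' @export
ma_plot_test <- function(c1, c2, n1, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) abort("library totals must be positive")
  k <- c1 + c2
  if (any(k == 0)) warn("rows with zero total count: p set to 1")
  phat <- ifelse(k > 0, k / (n1 + n2), NA_real_)
  m <- log2(pmax(c1, 0.5)) - log2(pmax(c2, 0.5))
  mu <- log2(n1 / n2)
  v <- (1 - phat) / log(2)^2 * (1 / (n1 * phat) + 1 / (n2 * phat))
  z <- (m - mu) / sqrt(v)
  p <- 2 * pnorm(-abs(z))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  ifelse(k == 0, 1, p)
}

#' Exact conditional binomial test
#'
#' Conditional on the total `k = c1 + c2`, `c1` is Binomial(k, n1/(n1+n2))
#' under the null; the two-sided p-value sums the probabilities of all
#' outcomes no more probable than the observed one (ties included).
#'
#' @inheritParams ma_plot_test
#' @return numeric p-values in (0, 1].
#' @export
exact_conditional_test <- function(c1, c2, n1, n2) {
  df <- tibble(c1 = c1, c2 = c2, n1 = n1, n2 = n2)
  if (any(df$c1 + df$c2 < 1)) abort("exact test requires c1 + c2 >= 1")
  purrr::pmap_dbl(df, function(c1, c2, n1, n2) {
    k <- c1 + c2
    pr <- n1 / (n1 + n2)
    d <- dbinom(0:k, k, pr)
    min(1, sum(d[d <= d[c1 + 1] * (1 + 1e-9)]))
  })
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment with monotonicity enforcement; order-preserving.
#'
#' @param p p-values in \[0, 1\].
#' @return q-values, same order as the input.
#' @export
qvalue_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

default_comparisons <- function() {
  c("HRK48/HRK0", "HSK48/HSK0", "HRK0/HSK0", "HRK48/HSK48")
}

#' Call differentially expressed miRNAs across labelled comparisons
#'
#' Replicate counts are summed per condition (the two-library model has no
#' replicate term), tested with [ma_plot_test()], BH-adjusted per comparison,
#' and called up/down when `|log2fc| >= lfc_min` and `q <= alpha`. The fold
#' change is computed on mean TPM with a small floor so genotype-specific
#' expression ("almost no expression" in one condition) stays finite; such
#' rows additionally carry a specificity flag when one condition is zero in
#' every replicate and the other reaches `specificity_floor` summed counts.
#'
#' @param counts long count tibble `mirna`, `library`, `count`.
#' @param library_totals per-library totals N for TPM and for the binomial
#'   test (tibble `library`, `n` or named vector); defaults to the column
#'   sums of `counts`.
#' @param comparisons character vector of `"COND1/COND2"` labels; conditions
#'   are the library labels with a trailing `-<replicate>` stripped.
#' @param alpha,lfc_min call thresholds (defaults: q <= 0.001, |log2fc| >= 1).
#' @param tpm_floor TPM floor used in the fold change (default 0.01).
#' @param specificity_floor minimum summed count in the expressed condition
#'   for the genotype/condition-specificity flag (default 10).
#' @param min_total rows with `C1 + C2 < min_total` are dropped (default 1).
#' @param min_replicates required libraries per tested condition (default 2,
#'   the two-biological-replicate design); fewer is an error.
#' @return tibble of class `mirdef_de`: `mirna`, `comparison`, `C1`, `C2`,
#'   `N1`, `N2`, `M`, `A`, `log2fc`, `p`, `q`, `call`, `specific`.
#' @export
call_de <- function(counts, library_totals = NULL,
                    comparisons = default_comparisons(),
                    alpha = 0.001, lfc_min = 1, tpm_floor = 0.01,
                    specificity_floor = 10, min_total = 1,
                    min_replicates = 2) {
  counts <- mutate(counts, condition = sub("-[0-9]+$", "", .data$library))
  if (is.null(library_totals)) {
    library_totals <- counts %>%
      group_by(.data$library) %>%
      summarise(n = sum(.data$count), .groups = "drop")
  } else if (!is.data.frame(library_totals)) {
    library_totals <- tibble(library = names(library_totals),
                             n = as.numeric(library_totals))
  }
  tpm <- tpm_normalize(select(counts, "mirna", "library", "count"),
                       library_totals) %>%
    mutate(condition = sub("-[0-9]+$", "", .data$library))
  lib_cond <- distinct(counts, .data$library, .data$condition)
  totals <- lib_cond %>%
    left_join(library_totals, by = "library") %>%
    group_by(.data$condition) %>%
    summarise(N = sum(.data$n), .groups = "drop")
  per_cond <- counts %>%
    group_by(.data$mirna, .data$condition) %>%
    summarise(C = sum(.data$count), all_zero = all(.data$count == 0),
              .groups = "drop")
  mean_tpm <- tpm %>%
    group_by(.data$mirna, .data$condition) %>%
    summarise(mtpm = mean(.data$tpm), .groups = "drop")

  res <- purrr::map_dfr(comparisons, function(cmp) {
    cond <- strsplit(cmp, "/", fixed = TRUE)[[1]]
    if (length(cond) != 2) abort(paste0("malformed comparison label: ", cmp))
    missing <- setdiff(cond, per_cond$condition)
    if (length(missing))
      abort(paste0("missing libraries for condition: ", paste(missing, collapse = ", ")))
    nrep <- table(lib_cond$condition)[cond]
    if (any(nrep < min_replicates))
      abort(paste0("missing library: condition ",
                   paste(cond[nrep < min_replicates], collapse = ", "),
                   " has fewer than ", min_replicates, " replicate libraries"))
    a <- filter(per_cond, .data$condition == cond[1])
    b <- filter(per_cond, .data$condition == cond[2])
    ta <- filter(mean_tpm, .data$condition == cond[1])
    tb <- filter(mean_tpm, .data$condition == cond[2])
    d <- tibble(mirna = a$mirna, C1 = a$C, zero1 = a$all_zero) %>%
      inner_join(tibble(mirna = b$mirna, C2 = b$C, zero2 = b$all_zero), by = "mirna") %>%
      inner_join(tibble(mirna = ta$mirna, tpm1 = ta$mtpm), by = "mirna") %>%
      inner_join(tibble(mirna = tb$mirna, tpm2 = tb$mtpm), by = "mirna") %>%
      filter(.data$C1 + .data$C2 >= min_total)
    N1 <- totals$N[totals$condition == cond[1]]
    N2 <- totals$N[totals$condition == cond[2]]
    d %>%
      mutate(
        comparison = cmp,
        N1 = N1, N2 = N2,
        M = log2(pmax(.data$C1, 0.5)) - log2(pmax(.data$C2, 0.5)),
        A = (log2(pmax(.data$C1, 0.5)) + log2(pmax(.data$C2, 0.5))) / 2,
        log2fc = log2(pmax(.data$tpm1, tpm_floor) / pmax(.data$tpm2, tpm_floor)),
        p = ma_plot_test(.data$C1, .data$C2, N1, N2),
        q = qvalue_adjust(.data$p),
        call = dplyr::case_when(
          .data$q <= alpha & .data$log2fc >= lfc_min ~ "up",
          .data$q <= alpha & .data$log2fc <= -lfc_min ~ "down",
          TRUE ~ "ns"
        ),
        specific = dplyr::case_when(
          .data$zero2 & .data$C1 >= specificity_floor ~ paste0("only_", cond[1]),
          .data$zero1 & .data$C2 >= specificity_floor ~ paste0("only_", cond[2]),
          TRUE ~ NA_character_
        )
      ) %>%
      select("mirna", "comparison", "C1", "C2", "N1", "N2", "M", "A",
             "log2fc", "p", "q", "call", "specific")
  })
  structure(res, class = c("mirdef_de", class(res)))
}

#' Classify differentially expressed miRNAs into the three design types
#'
#' Type 1 ("genotype-constitutive"): DE between genotypes before feeding
#' (HRK0/HSK0), subclassified by its joint direction at 48 h. Type 2
#' ("induced in both genotypes"): DE in both induced comparisons
#' (HRK48/HRK0 and HSK48/HSK0), subclassified by direction concordance.
#' Type 3 ("induced, genotype-specific"): DE in exactly one induced
#' comparison, split by genotype.
#'
#' @param de `mirdef_de` table holding all four standard comparisons.
#' @return list of class `mirdef_de_types` with tibbles `type1`, `type2`,
#'   `type3` (`mirna`, `subcategory`).
#' @export
classify_de_types <- function(de) {
  need <- default_comparisons()
  if (!all(need %in% de$comparison))
    abort("all four standard comparisons are required")
  dir_of <- function(cmp) {
    de %>%
      filter(.data$comparison == cmp, .data$call != "ns") %>%
      select("mirna", dir = "call")
  }
  d0 <- dir_of("HRK0/HSK0")
  d48 <- dir_of("HRK48/HSK48")
  dr <- dir_of("HRK48/HRK0")
  ds <- dir_of("HSK48/HSK0")

  type1 <- d0 %>%
    left_join(d48, by = "mirna", suffix = c("_0h", "_48h")) %>%
    mutate(subcategory = dplyr::case_when(
      .data$dir_0h == "up" & .data$dir_48h %in% "up" ~ "always_up",
      .data$dir_0h == "down" & .data$dir_48h %in% "down" ~ "always_down",
      .data$dir_0h == "up" & .data$dir_48h %in% "down" ~ "up_then_down",
      .data$dir_0h == "down" & .data$dir_48h %in% "up" ~ "down_then_up",
      TRUE ~ "no_difference_48h"
    )) %>%
    select("mirna", "subcategory")
  type2 <- inner_join(dr, ds, by = "mirna", suffix = c("_r", "_s")) %>%
    mutate(subcategory = dplyr::case_when(
      .data$dir_r == "up" & .data$dir_s == "up" ~ "up_both",
      .data$dir_r == "down" & .data$dir_s == "down" ~ "down_both",
      .data$dir_r == "down" & .data$dir_s == "up" ~ "down_resistant_up_susceptible",
      TRUE ~ "up_resistant_down_susceptible"
    )) %>%
    select("mirna", "subcategory")
  type3 <- bind_rows(
    anti_join(dr, ds, by = "mirna") %>%
      mutate(subcategory = "resistant_genotype"),
    anti_join(ds, dr, by = "mirna") %>%
      mutate(subcategory = "susceptible_genotype")
  ) %>% select("mirna", "subcategory")
  structure(list(type1 = type1, type2 = type2, type3 = type3),
            class = "mirdef_de_types")
}

#' @export
print.mirdef_de_types <- function(x, ...) {
  cat(sprintf("<mirdef_de_types> type1: %d, type2: %d, type3: %d miRNAs\n",
              nrow(x$type1), nrow(x$type2), nrow(x$type3)))
  invisible(x)
}
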