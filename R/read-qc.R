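# Seven-rule raw-read filter and length accounting.
#
# Raw small RNA reads are screened in a fixed, printed order; every read is
# attributed to exactly one fate (clean, or the first rule it violates):
#   rule 1  low sequencing quality (> max_low_qual_frac of bases below
#           min_base_phred on the raw read)
#   rule 2  N proportion above 10% (evaluated on the 3'-trimmed insert; the
#           whole read when no 3' adapter is present)
#   rule 3  5' adapter contamination (insert contains a 5'-adapter prefix)
#   rule 4  3' adapter not found
#   rule 5  no insert (adapter dimer: trimmed insert length 0)
#   rule 6  polyA insert (>= 70% A or a >= 10 nt A homopolymer)
#   rule 7  insert shorter than 18 nt
# Surviving reads are emitted as their 3'-trimmed inserts.

qc_default_thresholds <- function() {
  list(
    min_base_phred = 13, max_low_qual_frac = 0.20,
    max_n_frac = 0.10,
    polya_frac = 0.70, polya_run = 10,
    min_insert = 18,
    adapter_match_len = 10, adapter_min_overlap = 6, adapter_max_mismatch = 1,
    adapter5_probe_len = 12
  )
}

RULE_LABELS <- c(
  rule1_low_quality = "low sequencing quality",
  rule2_high_n = "N proportion > 10%",
  rule3_adapter5 = "5' adapter contamination",
  rule4_no_adapter3 = "no 3' adapter",
  rule5_no_insert = "no insert fragment",
  rule6_polya = "polyA insert",
  rule7_short = "insert < 18 nt"
)

# leftmost start of the 3' adapter in each read; NA when absent.
# Exact search on a fixed-length adapter prefix first; reads without an exact
# internal hit are rescued by an exact tail overlap (>= min_overlap) or a
# single-mismatch scan.
locate_adapter3 <- function(seqs, adapter3, th) {
  probe <- substr(adapter3, 1, th$adapter_match_len)
  pos <- stringi::stri_locate_first_fixed(seqs, probe)[, 1]
  todo <- which(is.na(pos) & nchar(seqs) >= th$adapter_min_overlap)
  if (length(todo)) {
    sub <- seqs[todo]
    L <- nchar(sub)
    found <- rep(NA_integer_, length(sub))
    # exact tail overlap, longest first
    hi <- min(th$adapter_match_len - 1, max(L))
    for (ov in if (hi >= th$adapter_min_overlap) seq(hi, th$adapter_min_overlap) else integer()) {
      hit <- is.na(found) & L >= ov &
        substr(sub, nchar(sub) - ov + 1, nchar(sub)) == substr(adapter3, 1, ov)
      found[hit] <- L[hit] - ov + 1L
    }
    if (th$adapter_max_mismatch >= 1 && any(is.na(found))) {
      rem <- which(is.na(found))
      pl <- nchar(probe)
      pr <- strsplit(probe, "")[[1]]
      for (p in seq_len(max(L[rem]) - th$adapter_min_overlap + 1)) {
        cand <- rem[L[rem] - p + 1 >= pl & is.na(found[rem])]
        if (!length(cand)) next
        win <- substr(sub[cand], p, p + pl - 1)
        mm <- vapply(strsplit(win, ""), function(w) sum(w != pr), integer(1))
        ok <- mm <= th$adapter_max_mismatch
        found[cand[ok & is.na(found[cand])]] <- p
      }
    }
    pos[todo] <- found
  }
  as.integer(pos)
}

#' Filter raw small RNA reads with the seven-rule screen
#'
#' Applies the seven removal rules in their printed order (low quality, high
#' N, 5' adapter contamination, missing 3' adapter, no insert, polyA, length
#' below 18 nt) and returns the surviving 3'-trimmed inserts together with a
#' library-accounting report. A read violating several rules is attributed to
#' the first one, so the per-rule removals plus the clean reads always sum to
#' the input total.
#'
#' @param reads tibble with columns `id`, `sequence`, `quality` (Phred+33
#'   string, same length as the sequence).
#' @param adapter3,adapter5 adapter sequences; `adapter3` is located (exact
#'   prefix match with up to one mismatch, minimum overlap
#'   `thresholds$adapter_min_overlap`) and trimmed; a read whose insert still
#'   contains the first `thresholds$adapter5_probe_len` nt of `adapter5` is
#'   removed as 5'-contaminated.
#' @param thresholds list of rule parameters, see `qc_default_thresholds()`.
#' @return list of class `mirdef_qc` with elements `clean` (tibble `id`,
#'   `sequence`, `quality` of trimmed inserts), `report` (one-row tibble with
#'   totals, per-rule removal counts and `clean_fraction`), `fates` (tibble
#'   `id`, `fate`) and `length_histogram`.
#' @export
filter_reads <- function(reads, adapter3, adapter5 = "",
                         thresholds = qc_default_thresholds()) {
  th <- utils::modifyList(qc_default_thresholds(), thresholds)
  if (!nchar(adapter3)) abort("`adapter3` must be a nonempty sequence")
  if (!nrow(reads)) {
    return(new_qc_result(reads[0, ], tibble(id = character(), fate = character()), 0L))
  }
  bad_len <- which(nchar(reads$sequence) != nchar(reads$quality))
  if (length(bad_len))
    abort(paste0("malformed read record (sequence/quality length mismatch): ",
                 reads$id[bad_len[1]]))
  bad_ab <- which(stringr::str_detect(reads$sequence, "[^ACGTN]"))
  if (length(bad_ab))
    abort(paste0("malformed read record (alphabet): ", reads$id[bad_ab[1]]))

  seqs <- reads$sequence
  n <- length(seqs)
  pos <- locate_adapter3(seqs, adapter3, th)
  has_ad <- !is.na(pos)
  insert <- ifelse(has_ad, substr(seqs, 1, pos - 1), seqs)
  ins_len <- ifelse(has_ad, pos - 1L, nchar(seqs))

  # rule predicates (evaluated for all reads; attribution is first-failing)
  low_q <- stringi::stri_count_regex(
    reads$quality, sprintf("[\\x21-\\x%02x]", 33 + th$min_base_phred - 1)
  ) / pmax(nchar(reads$quality), 1) > th$max_low_qual_frac
  n_frac <- stringi::stri_count_fixed(insert, "N") / pmax(ins_len, 1)
  high_n <- n_frac > th$max_n_frac
  probe5 <- substr(adapter5, 1, th$adapter5_probe_len)
  contam5 <- nchar(probe5) > 0 & ins_len > 0 &
    stringi::stri_detect_fixed(insert, probe5)
  no_ad <- !has_ad
  no_ins <- has_ad & ins_len == 0
  a_frac <- stringi::stri_count_fixed(insert, "A") / pmax(ins_len, 1)
  polya <- ins_len > 0 &
    (a_frac >= th$polya_frac | stringi::stri_detect_regex(insert, paste0("A{", th$polya_run, ",}")))
  short <- ins_len < th$min_insert

  fate <- rep("clean", n)
  rules <- list(rule1_low_quality = low_q, rule2_high_n = high_n,
                rule3_adapter5 = contam5, rule4_no_adapter3 = no_ad,
                rule5_no_insert = no_ins, rule6_polya = polya,
                rule7_short = short)
  for (r in rev(names(rules))) fate[rules[[r]]] <- r

  keep <- fate == "clean"
  clean <- tibble(
    id = reads$id[keep],
    sequence = insert[keep],
    quality = substr(reads$quality[keep], 1, ins_len[keep])
  )
  new_qc_result(clean, tibble(id = reads$id, fate = fate), n)
}

new_qc_result <- function(clean, fates, total) {
  removals <- setNames(integer(length(RULE_LABELS)), names(RULE_LABELS))
  tb <- table(fates$fate)
  removals[intersect(names(tb), names(removals))] <-
    as.integer(tb[intersect(names(tb), names(removals))])
  report <- tibble(
    total_reads = as.integer(total),
    clean_reads = nrow(clean),
    !!!as.list(removals),
    clean_fraction = if (total > 0) nrow(clean) / total else NA_real_
  )
  structure(
    list(clean = clean, report = report, fates = fates,
         length_histogram = length_distribution(clean)),
    class = "mirdef_qc"
  )
}

#' Length distribution of clean reads
#'
#' @param clean tibble of clean reads (column `sequence`).
#' @return tibble `length`, `count`, sorted by length; empty for empty input.
#' @export
length_distribution <- function(clean) {
  if (!nrow(clean)) return(tibble(length = integer(), count = integer()))
  clean %>%
    count(length = nchar(.data$sequence), name = "count") %>%
    arrange(.data$length)
}

#' @export
print.mirdef_qc <- function(x, ...) {
  r <- x$report
  cat(sprintf("<mirdef_qc> %d reads: %d clean (%.2f%%), %d removed\n",
              r$total_reads, r$clean_reads, 100 * r$clean_fraction,
              r$total_reads - r$clean_reads))
  invisible(x)
}
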