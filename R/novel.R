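# Novel miRNA calling from hairpin secondary structure.
#
# Unannotated mapped small RNAs seed candidate precursor windows; each window
# is folded, the stem-loop enclosing the seeding mature is extracted and the
# hairpin criteria applied: a single stem-loop, the mature on one arm with at
# least 16 bases paired to the star arm, |MFE|/length above 0.2 kcal/mol/nt,
# |MFEI| above 0.85, precursor length 69-910 nt, mature length 19-30 nt, and
# a 2 nt 3' overhang consistent with dicer processing.

#' Novel miRNA acceptance criteria
#'
#' @return list of tunable thresholds: `min_mfe_per_nt` (|MFE|/length, in
#'   kcal/mol/nt), `min_abs_mfei`, `precursor_len` and `mature_len` ranges,
#'   `min_mature_paired` (mature bases paired to the star arm),
#'   `merge_dist` (locus clustering distance) and `flank` (window extension),
#'   `overhang` (dicer 3' overhang, nt), `max_spans` (enclosing stems tried
#'   per window).
#' @export
novel_criteria <- function() {
  list(
    min_mfe_per_nt = 0.2, min_abs_mfei = 0.85,
    precursor_len = c(69L, 910L), mature_len = c(19L, 30L),
    min_mature_paired = 16L, merge_dist = 10L, flank = 150L,
    overhang = 2L, max_spans = 12L, min_stem_depth = 4L
  )
}

#' Extract candidate precursor windows around unannotated small RNA loci
#'
#' Mapped loci on the same contig and strand are merged when closer than
#' `merge_dist`; each cluster yields one window: the cluster span extended by
#' `flank` on both sides, clipped at contig ends. The cluster's most abundant
#' read (ties: leftmost) seeds the candidate mature.
#'
#' @param srnas tibble of unannotated mapped sRNAs: `sequence`, `contig`,
#'   `start`, `end`, `strand`, optionally `count` (defaults to 1).
#' @param genome tibble `contig`, `sequence`.
#' @param flank window extension per side (nt).
#' @param merge_dist cluster merge distance (nt).
#' @return tibble: `candidate_id`, `contig`, `strand`, `window_start`,
#'   `window_end` (genome coordinates of the window on the plus strand),
#'   `window_seq` (strand-oriented), `mature_seq`, `mature_offset` (1-based
#'   within `window_seq`).
#' @export
extract_precursor_candidates <- function(srnas, genome, flank = 150L,
                                         merge_dist = 10L) {
  if (!nrow(srnas)) {
    return(tibble(candidate_id = character(), contig = character(),
                  strand = character(), window_start = integer(),
                  window_end = integer(), window_seq = character(),
                  mature_seq = character(), mature_offset = integer()))
  }
  if (!"count" %in% names(srnas)) srnas$count <- 1L
  lens <- setNames(nchar(genome$sequence), genome$contig)
  srnas %>%
    group_by(.data$contig, .data$strand) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(cluster = cumsum(
      c(TRUE, .data$start[-1] > head(cummax(.data$end), -1) + merge_dist)
    )) %>%
    group_by(.data$contig, .data$strand, .data$cluster) %>%
    summarise(
      span_start = min(.data$start), span_end = max(.data$end),
      seed = which.max(.data$count),
      mature_seq = .data$sequence[seed],
      mature_genome_start = .data$start[seed],
      mature_genome_end = .data$end[seed],
      .groups = "drop"
    ) %>%
    mutate(
      window_start = pmax(.data$span_start - flank, 1L),
      window_end = pmin(.data$span_end + flank, lens[.data$contig]),
      window_seq = {
        fwd <- substr(genome$sequence[match(.data$contig, genome$contig)],
                      .data$window_start, .data$window_end)
        if_else(.data$strand == "-", revcomp(fwd), fwd)
      },
      mature_offset = if_else(
        .data$strand == "-",
        .data$window_end - .data$mature_genome_end + 1L,
        .data$mature_genome_start - .data$window_start + 1L
      ),
      candidate_id = sprintf("cand_%s_%d_%s", .data$contig,
                             .data$window_start, .data$strand)
    ) %>%
    select("candidate_id", "contig", "strand", "window_start", "window_end",
           "window_seq", "mature_seq", "mature_offset")
}

# evaluate all hairpin criteria for a precursor sequence with the mature at
# [ms, me]; returns list(ok=, reason=, ...) with fold metrics
evaluate_precursor <- function(prec_seq, ms, me, criteria, model) {
  L <- nchar(prec_seq)
  if (L < criteria$precursor_len[1] || L > criteria$precursor_len[2])
    return(list(ok = FALSE, reason = "precursor_length"))
  ml <- me - ms + 1
  if (ml < criteria$mature_len[1] || ml > criteria$mature_len[2])
    return(list(ok = FALSE, reason = "mature_length"))
  f <- fold_mfe(prec_seq, model)
  partner <- pair_table(f$structure)
  loops <- dominant_hairpin_loops(f$structure, criteria$min_stem_depth)
  if (nrow(loops) != 1)
    return(list(ok = FALSE, reason = "not_single_stem_loop", fold = f))
  in_5p_arm <- me <= loops$start[1]
  in_3p_arm <- ms >= loops$end[1]
  if (!in_5p_arm && !in_3p_arm)
    return(list(ok = FALSE, reason = "mature_straddles_loop", fold = f))
  mp <- partner[ms:me]
  n_paired <- sum(mp > 0)
  if (n_paired < criteria$min_mature_paired)
    return(list(ok = FALSE, reason = "mature_underpaired", fold = f))
  star <- range(mp[mp > 0])
  # dicer consistency: the star (shifted by the 2 nt 3' overhang) must stay
  # inside the precursor and itself keep clear of the loop
  star_len <- star[2] - star[1] + 1
  if (star_len > (me - ms + 1) + 4)
    return(list(ok = FALSE, reason = "star_geometry", fold = f))
  star_3p_end <- if (in_5p_arm) star[2] + criteria$overhang else star[2]
  star_5p_start <- if (in_3p_arm) star[1] - criteria$overhang else star[1]
  if (star_5p_start < 1 || star_3p_end > L)
    return(list(ok = FALSE, reason = "overhang_outside_precursor", fold = f))
  if (abs(f$mfe) / L <= criteria$min_mfe_per_nt)
    return(list(ok = FALSE, reason = "mfe_per_nt", fold = f))
  ix <- compute_mfei(f$mfe, prec_seq)
  if (ix$abs_mfei <= criteria$min_abs_mfei)
    return(list(ok = FALSE, reason = "mfei", fold = f, mfei = ix))
  list(ok = TRUE, reason = "pass", fold = f, mfei = ix,
       star_start = star[1], star_end = star[2])
}

#' Call novel miRNAs from candidate precursor windows
#'
#' Each window is folded; among the base pairs enclosing the seeding mature
#' (widest first, up to `criteria$max_spans`), the first enclosed
#' subsequence that satisfies every hairpin criterion is accepted as the
#' precursor. Accepted matures' first-base composition (the U fraction) is
#' reported.
#'
#' @param candidates tibble from [extract_precursor_candidates()].
#' @param criteria list from [novel_criteria()].
#' @param model energy model for [fold_mfe()].
#' @return list of class `mirdef_novel`: `calls` (one row per candidate:
#'   metrics, `accepted`, `reason`), `accepted` (accepted subset with
#'   precursor sequence/fold/mfe/amfe/mfei, mature placement, `first_base`)
#'   and `first_base_u_fraction`.
#' @export
call_novel <- function(candidates, criteria = novel_criteria(),
                       model = fold_energy_model()) {
  rows <- purrr::map_dfr(seq_len(nrow(candidates)), function(k) {
    cand <- candidates[k, ]
    ms <- cand$mature_offset
    me <- ms + nchar(cand$mature_seq) - 1L
    base <- tibble(candidate_id = cand$candidate_id, accepted = FALSE,
                   reason = NA_character_, precursor_seq = NA_character_,
                   precursor_start = NA_integer_, fold = NA_character_,
                   mfe = NA_real_, amfe = NA_real_, mfei = NA_real_,
                   mature_start = NA_integer_, mature_end = NA_integer_,
                   first_base = substr(chartr("T", "U", cand$mature_seq), 1, 1))
    if (me > nchar(cand$window_seq)) {
      base$reason <- "mature_outside_window"
      return(base)
    }
    w <- fold_mfe(cand$window_seq, model)
    partner <- pair_table(w$structure)
    enclosing <- which(partner > seq_along(partner)) # 5' members of pairs
    enclosing <- enclosing[enclosing <= ms & partner[enclosing] >= me]
    if (!length(enclosing)) {
      base$reason <- "no_enclosing_stem"
      return(base)
    }
    # innermost first: short spans fail the length range cheaply, and the
    # first span wide enough to cover the full stem is the precursor;
    # outermost spans (flank sequences pairing around the hairpin) would
    # refold into multibranch structures and waste the span budget
    spans <- tibble(i = enclosing, j = partner[enclosing]) %>%
      arrange(desc(.data$i)) %>%
      filter(.data$j - .data$i + 1 >= criteria$precursor_len[1]) %>%
      head(criteria$max_spans)
    reason <- "no_qualifying_span"
    for (r in seq_len(nrow(spans))) {
      i <- spans$i[r]; j <- spans$j[r]
      ev <- evaluate_precursor(substr(cand$window_seq, i, j),
                               ms - i + 1L, me - i + 1L, criteria, model)
      reason <- ev$reason
      if (ev$ok) {
        base$accepted <- TRUE
        base$reason <- "pass"
        base$precursor_seq <- substr(cand$window_seq, i, j)
        base$precursor_start <- i
        base$fold <- ev$fold$structure
        base$mfe <- ev$fold$mfe
        base$amfe <- ev$mfei$amfe
        base$mfei <- ev$mfei$mfei
        base$mature_start <- ms - i + 1L
        base$mature_end <- me - i + 1L
        return(base)
      }
    }
    base$reason <- reason
    base
  })
  acc <- filter(rows, .data$accepted)
  structure(
    list(calls = rows, accepted = acc,
         first_base_u_fraction = if (nrow(acc)) mean(acc$first_base == "U") else NA_real_),
    class = "mirdef_novel"
  )
}

#' Independently re-validate an accepted hairpin call
#'
#' Re-checks every acceptance criterion from the stored precursor sequence,
#' dot-bracket fold and mature placement, without reusing the caller's
#' intermediate state: balanced fold of matching length, single hairpin
#' loop, mature inside one arm, pairing count, length ranges, MFE/MFEI
#' thresholds (MFE recomputed from the sequence).
#'
#' @param call one row of the `accepted` table of [call_novel()].
#' @param criteria list from [novel_criteria()].
#' @param model energy model.
#' @return TRUE when every criterion holds, otherwise FALSE (with the failed
#'   criterion as an attribute `"reason"`).
#' @export
validate_hairpin_call <- function(call, criteria = novel_criteria(),
                                  model = fold_energy_model()) {
  fail <- function(why) structure(FALSE, reason = why)
  L <- nchar(call$precursor_seq)
  if (nchar(call$fold) != L) return(fail("fold_length"))
  partner <- pair_table(call$fold) # aborts if unbalanced
  if (L < criteria$precursor_len[1] || L > criteria$precursor_len[2])
    return(fail("precursor_length"))
  ml <- call$mature_end - call$mature_start + 1
  if (ml < criteria$mature_len[1] || ml > criteria$mature_len[2])
    return(fail("mature_length"))
  loops <- dominant_hairpin_loops(call$fold, criteria$min_stem_depth)
  if (nrow(loops) != 1) return(fail("hairpin_count"))
  if (!(call$mature_end <= loops$start[1] || call$mature_start >= loops$end[1]))
    return(fail("mature_straddles_loop"))
  mp <- partner[call$mature_start:call$mature_end]
  if (sum(mp > 0) < criteria$min_mature_paired) return(fail("mature_pairing"))
  f <- fold_mfe(call$precursor_seq, model)
  if (abs(f$mfe - call$mfe) > 1e-6) return(fail("mfe_mismatch"))
  if (abs(f$mfe) / L <= criteria$min_mfe_per_nt) return(fail("mfe_per_nt"))
  ix <- compute_mfei(f$mfe, call$precursor_seq)
  if (ix$abs_mfei <= criteria$min_abs_mfei) return(fail("mfei"))
  TRUE
}
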