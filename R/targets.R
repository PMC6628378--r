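# Plant miRNA target-site penalty scoring.
#
# Classic plant-target scheme: penalty = mismatches x1 + G:U wobbles x0.5 +
# gaps x2, all doubled inside the 5' weight region (miRNA positions 2-13).
# Two modes are run and their union taken: a lenient mode (weighted penalty
# <= 4, at most one gap) and a strict mode (un-doubled raw penalty <= 8,
# minimum complementary stretch 17, at most one gap).

target_modes <- function() {
  list(
    lenient = list(cutoff = 4.0, max_gap = 1L),
    strict = list(max_raw_penalty = 8.0, min_stretch = 17L, max_gap = 1L)
  )
}

# penalty of one aligned column: miRNA base a vs revcomp(site) base b,
# integer codes A=0 C=1 G=2 U=3; equality = Watson-Crick pairing
col_penalty <- function(a, b) {
  if (a == b) 0 else if ((a == 2 && b == 0) || (a == 3 && b == 1)) 0.5 else 1
}

#' Score a miRNA binding site
#'
#' Optimal gapped alignment (at most `max_gap` gaps) of the miRNA (5'->3')
#' against the reverse complement of the site, minimizing the weighted
#' penalty: mismatch 1, G:U wobble 0.5, gap 2, each doubled at miRNA
#' positions `weight_region` (counted from the 5' end; a bulged site base
#' takes the weight of the miRNA position it interrupts). Ties are broken
#' deterministically (pairing preferred over a miRNA bulge over a site
#' bulge).
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param site target site on the transcript plus strand, 5'->3'; its length
#'   may differ from the miRNA's by at most `max_gap`.
#' @param weight_region integer pair, 5'-weighted positions (default 2-13).
#' @param max_gap gap allowance (default 1).
#' @param weighted set `FALSE` to optimize the un-doubled raw penalty (the
#'   strict mode's objective).
#' @return one-row tibble: `penalty` (optimized objective), `raw_penalty` and
#'   `weighted_penalty` of the reported alignment, `mismatches`, `gu`,
#'   `gaps`, `stretch` (longest run of consecutively paired columns), and the
#'   alignment strings `mirna_align`, `pairing`, `site_align` (site shown
#'   reverse-complemented, aligned 5'->3' of the miRNA).
#' @export
score_target_site <- function(mirna, site, weight_region = c(2L, 13L),
                              max_gap = 1L, weighted = TRUE) {
  m <- encode_dna(mirna)
  s <- encode_dna(revcomp(site))
  L <- length(m); Ls <- length(s)
  if (abs(L - Ls) > max_gap)
    abort("site length incompatible with miRNA length under the gap limit")
  wt <- function(pos) {
    if (weighted && pos >= weight_region[1] && pos <= weight_region[2]) 2 else 1
  }
  INF <- 1e18
  dp <- array(INF, dim = c(max_gap + 1, L + 1, Ls + 1))
  dp[, 1, 1] <- 0
  # moves: 1 diagonal, 2 miRNA bulge, 3 site bulge
  from <- array(0L, dim = c(max_gap + 1, L + 1, Ls + 1))
  for (g in seq_len(max_gap + 1)) {
    for (i in 0:L) {
      for (j in 0:Ls) {
        cur <- dp[g, i + 1, j + 1]
        if (cur >= INF) next
        w <- wt(i + 1)
        if (i < L && j < Ls) {
          pen <- col_penalty(m[i + 1], s[j + 1]) * w
          if (cur + pen < dp[g, i + 2, j + 2]) {
            dp[g, i + 2, j + 2] <- cur + pen
            from[g, i + 2, j + 2] <- 1L
          }
        }
        if (g <= max_gap) {
          if (i < L && cur + 2 * w < dp[g + 1, i + 2, j + 1]) {
            dp[g + 1, i + 2, j + 1] <- cur + 2 * w
            from[g + 1, i + 2, j + 1] <- 2L
          }
          if (j < Ls && cur + 2 * w < dp[g + 1, i + 1, j + 2]) {
            dp[g + 1, i + 1, j + 2] <- cur + 2 * w
            from[g + 1, i + 1, j + 2] <- 3L
          }
        }
      }
    }
  }
  ends <- dp[, L + 1, Ls + 1]
  g_best <- which.min(ends)
  if (ends[g_best] >= INF) abort("no admissible alignment")
  # traceback
  g <- g_best; i <- L; j <- Ls
  cols <- list()
  letters4 <- c("A", "C", "G", "U")
  while (i > 0 || j > 0) {
    mv <- from[g, i + 1, j + 1]
    if (mv == 1L) {
      a <- m[i]; b <- s[j]
      sym <- if (a == b) "|" else if ((a == 2 && b == 0) || (a == 3 && b == 1)) "o" else " "
      cols[[length(cols) + 1]] <- c(letters4[a + 1], sym, letters4[b + 1], i)
      i <- i - 1; j <- j - 1
    } else if (mv == 2L) {
      cols[[length(cols) + 1]] <- c(letters4[m[i] + 1], " ", "-", i)
      i <- i - 1; g <- g - 1
    } else {
      cols[[length(cols) + 1]] <- c("-", " ", letters4[s[j] + 1], i + 1)
      j <- j - 1; g <- g - 1
    }
  }
  cols <- rev(cols)
  al <- do.call(rbind, cols)
  pair_sym <- al[, 2]
  is_gap <- al[, 1] == "-" | al[, 3] == "-"
  mism <- sum(pair_sym == " " & !is_gap)
  gu <- sum(pair_sym == "o")
  gaps <- sum(is_gap)
  paired <- pair_sym %in% c("|", "o")
  stretch <- if (any(paired)) max(rle(paired)$lengths[rle(paired)$values]) else 0L
  wcol <- function(pos) ifelse(pos >= weight_region[1] & pos <= weight_region[2], 2, 1)
  pos_w <- wcol(as.integer(al[, 4]))
  colpen_raw <- ifelse(is_gap, 2, ifelse(pair_sym == "o", 0.5,
                                         ifelse(pair_sym == " ", 1, 0)))
  raw_pen <- sum(colpen_raw)
  weighted_pen <- sum(colpen_raw * pos_w)
  tibble(
    penalty = unname(ends[g_best]),
    raw_penalty = raw_pen, weighted_penalty = weighted_pen,
    mismatches = mism, gu = gu, gaps = gaps, stretch = as.integer(stretch),
    mirna_align = paste(al[, 1], collapse = ""),
    pairing = paste(pair_sym, collapse = ""),
    site_align = paste(al[, 3], collapse = "")
  )
}

#' Predict miRNA target sites on transcripts (lenient/strict union)
#'
#' Scans every miRNA against every transcript at all start positions and site
#' lengths within one gap of the miRNA length. A window is reported when it
#' passes the lenient mode (weighted penalty <= 4) or the strict mode (raw
#' penalty <= 8 and complementary stretch >= 17); the union is deduplicated
#' by (miRNA, transcript, interval).
#'
#' @param mirnas tibble `id`, `sequence` of mature miRNAs.
#' @param transcripts tibble `id`, `sequence`.
#' @param modes mode parameters, see `target_modes()`.
#' @param weight_region 5'-weighted miRNA positions (default 2-13).
#' @return tibble of class `mirdef_targets`: `mirna`, `transcript`, `start`,
#'   `end` (1-based inclusive, transcript plus strand), `score`, `mode`
#'   (`"lenient"`, `"strict"` or `"both"`), `mismatches`, `gu`, `gaps`,
#'   `stretch`.
#' @export
predict_targets <- function(mirnas, transcripts, modes = target_modes(),
                            weight_region = c(2L, 13L)) {
  if (!nrow(mirnas) || !nrow(transcripts))
    abort("both miRNA and transcript sets must be nonempty")
  max_gap <- max(modes$lenient$max_gap, modes$strict$max_gap)
  out <- purrr::map_dfr(seq_len(nrow(mirnas)), function(mi) {
    m <- encode_dna(mirnas$sequence[mi])
    purrr::map_dfr(seq_len(nrow(transcripts)), function(ti) {
      tx <- encode_dna(transcripts$sequence[ti])
      tx_comp <- 3L - tx # per-base complement in integer coding
      cand <- scan_targets_cpp(m, tx_comp, weight_region[1], weight_region[2],
                               max_gap, modes$lenient$cutoff,
                               modes$strict$max_raw_penalty)
      if (!nrow(cand)) return(NULL)
      cand <- as_tibble(cand) %>%
        mutate(end = .data$start + .data$site_len - 1L)
      details <- purrr::map_dfr(seq_len(nrow(cand)), function(k) {
        site <- substr(transcripts$sequence[ti], cand$start[k], cand$end[k])
        det <- score_target_site(mirnas$sequence[mi], site,
                                 weight_region = weight_region,
                                 max_gap = max_gap,
                                 weighted = cand$weighted[k] > modes$lenient$cutoff)
        mutate(det, start = cand$start[k], end = cand$end[k],
               weighted_opt = cand$weighted[k], raw_opt = cand$raw[k])
      })
      details %>%
        mutate(
          lenient = .data$weighted_opt <= modes$lenient$cutoff,
          strict = .data$raw_opt <= modes$strict$max_raw_penalty &
            .data$stretch >= modes$strict$min_stretch,
          mirna = mirnas$id[mi], transcript = transcripts$id[ti]
        ) %>%
        filter(.data$lenient | .data$strict) %>%
        mutate(
          mode = dplyr::case_when(
            .data$lenient & .data$strict ~ "both",
            .data$lenient ~ "lenient",
            TRUE ~ "strict"
          ),
          score = if_else(.data$lenient, .data$weighted_opt, .data$raw_opt)
        ) %>%
        select("mirna", "transcript", "start", "end", "score", "mode",
               "mismatches", "gu", "gaps", "stretch")
    })
  })
  out <- distinct(out, .data$mirna, .data$transcript, .data$start, .data$end,
                  .keep_all = TRUE) %>%
    arrange(.data$mirna, .data$transcript, .data$start)
  structure(out, class = c("mirdef_targets", class(out)))
}
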