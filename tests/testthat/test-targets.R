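mir21 <- "TGACAGAAGAGAGTGAGCACA" # 21 nt

test_that("a perfect complement scores zero penalty", {
  s <- score_target_site(mir21, revcomp(mir21))
  expect_equal(s$penalty, 0)
  expect_equal(s$mismatches + s$gu + s$gaps, 0L)
  expect_equal(s$stretch, nchar(mir21))
})

test_that("mismatch penalties double inside miRNA positions 2-13", {
  flip <- function(site_rc_pos) {
    # mutate the site base pairing miRNA position `site_rc_pos`
    s <- revcomp(mir21)
    # site position pairing miRNA position i is nchar - i + 1 on the site;
    # easier: mutate revcomp(site) directly and rebuild the site
    rc <- s
    rc_chars <- strsplit(mir21, "")[[1]] # revcomp(site) == mirna when perfect
    old <- rc_chars[site_rc_pos]
    rc_chars[site_rc_pos] <- setdiff(c("A", "C"), old)[1] # break the pair
    if (old == "G") rc_chars[site_rc_pos] <- "C" # avoid G:U wobble cases
    revcomp(paste(rc_chars, collapse = ""))
  }
  s15 <- score_target_site(mir21, flip(15))
  s5 <- score_target_site(mir21, flip(5))
  expect_equal(s15$penalty, 1)
  expect_equal(s5$penalty, 2)
})

test_that("G:U wobble costs half a mismatch", {
  # miRNA G pairing site T is a wobble: set site base to T where miRNA has G
  m <- "TTGGCCAAGGTTCCAAGGTTC"
  g_pos <- 20 # outside the weighted region
  rc <- strsplit(m, "")[[1]]
  stopifnot(rc[g_pos] == "T") # miRNA U pairing site G wobble: rc base C
  rc[g_pos] <- "C"
  s <- score_target_site(m, revcomp(paste(rc, collapse = "")))
  expect_equal(s$penalty, 0.5)
  expect_equal(s$gu, 1L)
})

test_that("optimal score equals brute-force enumeration over <= 1-gap alignments", {
  withr::with_seed(41, {
    for (rep in 1:40) {
      L <- sample(19:21, 1)
      m <- random_seq(L)
      # sites near-complementary with random edits, lengths L-1, L, L+1
      base <- revcomp(m)
      site <- base
      n_ed <- sample(0:3, 1)
      for (e in seq_len(n_ed)) {
        at <- sample(nchar(site), 1)
        substr(site, at, at) <- sample(c("A", "C", "G", "T"), 1)
      }
      dl <- sample(c(-1L, 0L, 1L), 1)
      if (dl == -1L) site <- substr(site, 1, nchar(site) - 1)
      if (dl == 1L) site <- paste0(site, sample(c("A", "C", "G", "T"), 1))
      got <- score_target_site(m, site)$penalty
      want <- oracle_align_penalty(m, site)
      expect_equal(got, want, info = paste(m, site))
      # the C++ scanner core agrees with the R scorer
      cpp <- mirdefense:::align_penalty_cpp(
        mirdefense:::encode_dna(m),
        mirdefense:::encode_dna(revcomp(site)), 2L, 13L, 1L)
      expect_equal(cpp, want, info = paste(m, site))
    }
  })
})

test_that("prediction finds embedded complements once, via the mode union", {
  withr::with_seed(6, {
    tx_body <- random_seq(300)
    tx <- paste0(substr(tx_body, 1, 150), revcomp(mir21),
                 substr(tx_body, 151, 300))
    mirnas <- tibble::tibble(id = "mir", sequence = mir21)
    txs <- tibble::tibble(id = c("t_hit", "t_decoy"),
                          sequence = c(tx, random_seq(320)))
    hits <- predict_targets(mirnas, txs)
    perfect <- dplyr::filter(as_tibble(hits), transcript == "t_hit",
                             score == 0)
    expect_equal(nrow(perfect), 1L) # deduplicated across modes
    expect_equal(perfect$mode, "both")
    expect_equal(perfect$start, 151L)
    expect_equal(perfect$end, 151L + nchar(mir21) - 1L)
    expect_equal(nrow(dplyr::filter(as_tibble(hits),
                                    transcript == "t_decoy")), 0L)
    # invariant to transcript input order
    hits2 <- predict_targets(mirnas, txs[c(2, 1), ])
    expect_equal(as_tibble(hits), as_tibble(hits2))
  })
})

test_that("one miRNA may hit several transcripts and vice versa", {
  withr::with_seed(9, {
    m2 <- random_seq(21)
    t1 <- paste0(random_seq(60), revcomp(mir21), random_seq(40),
                 revcomp(m2), random_seq(60))
    t2 <- paste0(random_seq(50), revcomp(mir21), random_seq(50))
    hits <- predict_targets(
      tibble::tibble(id = c("mirA", "mirB"), sequence = c(mir21, m2)),
      tibble::tibble(id = c("t1", "t2"), sequence = c(t1, t2))
    )
    h <- dplyr::distinct(as_tibble(hits), mirna, transcript)
    expect_true(all(c("t1", "t2") %in% h$transcript[h$mirna == "mirA"]))
    expect_true(all(c("mirA", "mirB") %in% h$mirna[h$transcript == "t1"]))
  })
})

test_that("every reported site satisfies its mode's cutoffs", {
  cfg <- small_config(seed = 2)
  refs <- generate_reference_set(cfg)
  sim <- simulate_count_libraries(cfg, refs)
  pairs <- simulate_expression_pairs(cfg, refs, sim$truth)
  ids <- unique(pairs$target_map$mirna)[1:4]
  mi <- refs$index$mirna_catalog %>%
    dplyr::filter(mature_id %in% ids) %>%
    dplyr::select(id = mature_id, sequence)
  tg <- as_tibble(predict_targets(mi, pairs$transcripts))
  modes <- mirdefense:::target_modes()
  lenient <- dplyr::filter(tg, mode %in% c("lenient", "both"))
  strict <- dplyr::filter(tg, mode %in% c("strict", "both"))
  expect_true(all(lenient$score <= modes$lenient$cutoff | lenient$mode == "both"))
  expect_true(all(strict$stretch >= modes$strict$min_stretch))
  expect_true(all(tg$gaps <= 1))
})
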