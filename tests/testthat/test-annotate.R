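# a tiny fully handcrafted index used throughout this file
tiny_index <- function() {
  withr::with_seed(11, {
    g1 <- random_seq(3000)
    g2 <- random_seq(2000)
    mature <- "TGACAGAAGAGAGTGAGCACA"
    rrna <- random_seq(150)
    # embed features at known positions
    substr(g1, 101, 100 + nchar(mature)) <- mature
    substr(g2, 501, 500 + nchar(rrna)) <- rrna
    genome <- tibble::tibble(contig = c("c1", "c2"), sequence = c(g1, g2))
    gene_model <- tibble::tibble(
      contig = "c1", gene_id = "geneA",
      feature = c("exon", "intron", "exon"),
      start = c(1001L, 1201L, 1401L), end = c(1200L, 1400L, 1600L)
    )
    catalog <- tibble::tibble(mature_id = "mirX", family_id = "MIRX",
                              precursor_id = "mirX_prec", n_species = 12,
                              sequence = mature)
    refs <- list(
      miRNA = tibble::tibble(id = "mirX", sequence = mature),
      piRNA = tibble::tibble(id = character(), sequence = character()),
      snoRNA = tibble::tibble(id = "sno1", sequence = random_seq(90)),
      rRNA = tibble::tibble(id = "rrn1", sequence = rrna),
      tRNA = tibble::tibble(id = "trn1", sequence = random_seq(75)),
      sncRNA = tibble::tibble(id = "snc1", sequence = random_seq(100)),
      precursor = tibble::tibble(id = character(), sequence = character())
    )
    list(index = annotation_index(genome, gene_model, refs, catalog),
         genome1 = g1, genome2 = g2, mature = mature, rrna = rrna)
  })
}

test_that("genome mapping finds embedded sequences and misses foreign ones", {
  tx <- tiny_index()
  srnas <- tibble::tibble(sequence = c(
    tx$mature,                          # embedded at c1:101
    substr(tx$genome1, 1050, 1070),     # exonic window
    substr(tx$genome1, 1250, 1272),     # intronic window
    substr(tx$genome2, 300, 320),       # intergenic on c2
    "GGGGGGGGGGGGGGGGGGGG"              # absent
  ))
  m <- map_to_genome(srnas, tx$index)
  expect_equal(m$mapped, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(m$start[1], 101L)
  expect_equal(m$locus_class[2:4], c("exon", "intron", "intergenic"))
  # brute-force substring oracle agrees on mapped/unmapped
  withr::with_seed(5, {
    rand <- tibble::tibble(sequence = vapply(1:30, function(i) random_seq(20),
                                             character(1)))
    m2 <- map_to_genome(rand, tx$index)
    oracle <- vapply(rand$sequence, function(s) {
      grepl(s, tx$genome1, fixed = TRUE) || grepl(s, tx$genome2, fixed = TRUE) ||
        grepl(revcomp(s), tx$genome1, fixed = TRUE) ||
        grepl(revcomp(s), tx$genome2, fixed = TRUE)
    }, logical(1))
    expect_equal(m2$mapped, unname(oracle))
  })
})

test_that("exon wins over intron at a boundary-overlapping read", {
  tx <- tiny_index()
  straddle <- tibble::tibble(sequence = substr(tx$genome1, 1190, 1210))
  m <- map_to_genome(straddle, tx$index)
  expect_equal(m$locus_class, "exon")
})

test_that("priority annotation gives one label, highest priority first", {
  tx <- tiny_index()
  # a sequence present in both the miRNA and rRNA references must be miRNA
  shared <- substr(tx$mature, 1, 19)
  idx2 <- tx$index
  idx2$class_refs$rRNA <- dplyr::bind_rows(
    idx2$class_refs$rRNA,
    tibble::tibble(id = "rrn_shared", sequence = paste0(shared, random_seq(40)))
  )
  ann <- annotate_priority(
    tibble::tibble(sequence = c(shared, strrep("ACGT", 5))), idx2)
  expect_equal(ann$annotation, c("miRNA", "unannotated"))
})

test_that("priority annotation equals the first-match oracle on random input", {
  tx <- tiny_index()
  withr::with_seed(21, {
    pool <- c(
      vapply(1:40, function(i) random_seq(sample(18:24, 1)), character(1)),
      vapply(1:30, function(i) { # fragments of random reference classes
        cls <- sample(c("snoRNA", "rRNA", "tRNA", "sncRNA", "miRNA"), 1)
        ref <- tx$index$class_refs[[cls]]
        s <- ref$sequence[sample(nrow(ref), 1)]
        a <- sample(nchar(s) - 18, 1)
        substr(s, a, a + sample(17:20, 1))
      }, character(1))
    )
    srnas <- tibble::tibble(sequence = pool)
    got <- annotate_priority(srnas, tx$index)$annotation
    want <- vapply(pool, oracle_priority_annotation, character(1),
                   class_refs = tx$index$class_refs)
    expect_equal(got, unname(want))
    # single-label property: exactly one annotation per sequence
    expect_length(got, length(pool))
  })
})

test_that("rRNA gate passes below 60% and fails at the boundary", {
  s <- tibble::tibble(library = c("L1", "L2", "L3", "L4"),
                      type = "rRNA",
                      fraction = c(0.0126, 0.60, 0.59, 0.999))
  g <- rrna_qc_gate(s)
  expect_equal(g$pass, c(TRUE, FALSE, TRUE, FALSE))
  # a library with no rRNA row at all passes with fraction 0
  s2 <- tibble::tibble(library = c("L1", "L2"),
                       type = c("rRNA", "miRNA"), fraction = c(0.01, 0.05))
  expect_true(all(rrna_qc_gate(s2)$pass))
})

test_that("per-library summary accounts mapped + unmapped = clean", {
  cfg <- small_config(seed = 13, reads = 3000L)
  refs <- generate_reference_set(cfg)
  sim <- simulate_count_libraries(cfg, refs)
  rl <- simulate_read_library(cfg, refs, sim$truth, "HRK0-1")
  qc <- filter_reads(rl$reads, cfg$adapter_3p, cfg$adapter_5p)
  summ <- annotation_summary(mutate(qc$clean, library = "HRK0-1"), refs$index)
  totals <- summ %>%
    dplyr::group_by(library) %>%
    dplyr::summarise(n = sum(count), clean = dplyr::first(clean_reads))
  expect_equal(totals$n, totals$clean)
  rrna <- summ$fraction[summ$type == "rRNA"]
  expect_gt(rrna, 0.005)
  expect_lt(rrna, 0.05)
})
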