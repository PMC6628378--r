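test_that("configuration invariants are enforced", {
  expect_error(sim_config(de_log2fc_range = c(0.5, 2)), "bounded below")
  expect_error(sim_config(contamination_rates = c(
    rule1_low_quality = 0.5, rule2_high_n = 0.6, rule3_adapter5 = 0,
    rule4_no_adapter3 = 0, rule5_no_insert = 0, rule6_polya = 0,
    rule7_short = 0)), "jointly")
  expect_error(sim_config(rrna_target_fraction = 1.2), "\\[0, 1\\)")
})

test_that("identical config and seed give byte-identical artifacts", {
  cfg <- small_config(seed = 42, reads = 2000L)
  r1 <- generate_reference_set(cfg)
  r2 <- generate_reference_set(cfg)
  expect_identical(r1$index$genome, r2$index$genome)
  expect_identical(r1$index$mirna_catalog, r2$index$mirna_catalog)
  expect_identical(r1$novel_truth, r2$novel_truth)
  s1 <- simulate_count_libraries(cfg, r1)
  s2 <- simulate_count_libraries(cfg, r2)
  expect_identical(s1$counts, s2$counts)
  l1 <- simulate_read_library(cfg, r1, s1$truth, "HSK48-2")
  l2 <- simulate_read_library(cfg, r2, s2$truth, "HSK48-2")
  expect_identical(l1$reads, l2$reads)
  expect_error(simulate_read_library(cfg, r1, s1$truth, "nope"), "unknown")
})

test_that("reference construction embeds matures in precursors and genome", {
  cfg <- small_config(seed = 8, n_known_mirnas = 50L)
  refs <- generate_reference_set(cfg)
  cat <- refs$index$mirna_catalog
  expect_equal(nrow(cat), 50L)
  prec <- refs$index$class_refs$precursor
  for (i in seq_len(nrow(cat))) {
    p <- prec$sequence[prec$id == cat$precursor_id[i]]
    expect_true(grepl(cat$sequence[i], p, fixed = TRUE) ||
                  grepl(revcomp(cat$sequence[i]), p, fixed = TRUE))
  }
  # every precursor is a verbatim genome substring
  gg <- paste(refs$index$genome$sequence, collapse = strrep("N", 5))
  expect_true(all(vapply(prec$sequence, grepl, logical(1), x = gg,
                         fixed = TRUE)))
  expect_error(generate_reference_set(small_config(genome_length = 5000L)),
               "feature overflow")
})

test_that("simulated mature lengths stay within the observed 19-30 nt range", {
  cfg <- sim_config(seed = 77, n_known_mirnas = 500L, genome_length = 900000L)
  refs <- generate_reference_set(cfg)
  lens <- nchar(refs$index$mirna_catalog$sequence)
  expect_true(all(lens >= 19 & lens <= 30))
  plens <- nchar(refs$index$class_refs$precursor$sequence)
  expect_true(all(plens >= 69 & plens <= 910))
})

test_that("zero contamination means a fully clean library", {
  cfg <- small_config(seed = 9, reads = 2000L,
                      contamination_rates = setNames(
                        rep(0, 7),
                        c("rule1_low_quality", "rule2_high_n", "rule3_adapter5",
                          "rule4_no_adapter3", "rule5_no_insert", "rule6_polya",
                          "rule7_short")))
  refs <- generate_reference_set(cfg)
  sim <- simulate_count_libraries(cfg, refs)
  rl <- simulate_read_library(cfg, refs, sim$truth, "HRK0-1")
  qc <- filter_reads(rl$reads, cfg$adapter_3p, cfg$adapter_5p)
  expect_equal(qc$report$clean_fraction, 1)
})

test_that("planted contamination yields the expected clean fraction", {
  rates <- setNames(rep(0, 7),
                    c("rule1_low_quality", "rule2_high_n", "rule3_adapter5",
                      "rule4_no_adapter3", "rule5_no_insert", "rule6_polya",
                      "rule7_short"))
  rates["rule7_short"] <- 0.10
  cfg <- small_config(seed = 10, reads = 8000L, contamination_rates = rates)
  refs <- generate_reference_set(cfg)
  sim <- simulate_count_libraries(cfg, refs)
  rl <- simulate_read_library(cfg, refs, sim$truth, "HRK48-1")
  qc <- filter_reads(rl$reads, cfg$adapter_3p, cfg$adapter_5p)
  # binomial band around 0.90 at n = 8000 (about 5 sd)
  expect_gt(qc$report$clean_fraction, 0.90 - 5 * sqrt(0.1 * 0.9 / 8000))
  expect_lt(qc$report$clean_fraction, 0.90 + 5 * sqrt(0.1 * 0.9 / 8000))
  # conservation: fate classes sum to the library size
  expect_equal(nrow(rl$fates), 8000L)
  expect_equal(sum(table(rl$fates$fate)), 8000L)
})

test_that("count simulation plants fold changes and genotype specificity", {
  cfg <- small_config(seed = 2)
  refs <- generate_reference_set(cfg)
  # no DE planted: every true fold change is zero
  cfg0 <- small_config(seed = 2, de_fraction = 0, n_genotype_specific = 0L)
  sim0 <- simulate_count_libraries(cfg0, generate_reference_set(cfg0))
  expect_equal(nrow(sim0$truth$de_planted), 0L)
  expect_true(all(abs(sim0$truth$true_lfc$true_log2fc) < 1e-12))
  # planted fold change is realized in the true proportions, up to the
  # small compositional shift that renormalization imposes on everyone
  sim <- simulate_count_libraries(cfg, refs)
  de <- sim$truth$de_planted
  j <- dplyr::inner_join(de, sim$truth$true_lfc, by = c("mirna", "comparison"))
  expect_true(all(abs(j$log2fc - j$true_log2fc) < 0.1))
  # genotype-specific miRNAs have zero counts in every HSK replicate
  sp <- sim$truth$specific
  expect_length(sp, cfg$n_genotype_specific)
  hsk <- sim$counts %>%
    dplyr::filter(mirna %in% sp, grepl("^HSK", library))
  expect_true(all(hsk$count == 0))
})

test_that("the overdispersion knob perturbs replicates but keeps structure", {
  cfg <- small_config(seed = 6, reads = 3000L)
  refs <- generate_reference_set(cfg)
  s <- simulate_count_libraries(cfg, refs, overdispersion = 0.05)
  expect_equal(nrow(s$counts), cfg$n_known_mirnas * 8)
  expect_true(all(s$counts$count >= 0))
  hsk <- s$counts %>%
    dplyr::filter(mirna %in% s$truth$specific, grepl("^HSK", library))
  expect_true(all(hsk$count == 0)) # zero proportions stay zero
})

test_that("a planted log2fc of 2 yields a TPM ratio near 4", {
  cfg <- small_config(seed = 4, reads = 60000L, de_log2fc_range = c(2, 2))
  refs <- generate_reference_set(cfg)
  sim <- simulate_count_libraries(cfg, refs)
  tpm <- tpm_normalize(sim$counts)
  de <- sim$truth$de_planted
  j <- tpm %>%
    mutate(condition = sub("-[0-9]+$", "", library)) %>%
    dplyr::inner_join(de, by = "mirna") %>%
    dplyr::group_by(mirna, comparison, condition) %>%
    dplyr::summarise(m = mean(tpm), .groups = "drop")
  for (r in seq_len(nrow(de))) {
    cond <- strsplit(de$comparison[r], "/")[[1]]
    m1 <- j$m[j$mirna == de$mirna[r] & j$condition == cond[1] &
                j$comparison == de$comparison[r]]
    m2 <- j$m[j$mirna == de$mirna[r] & j$condition == cond[2] &
                j$comparison == de$comparison[r]]
    ratio <- if (de$log2fc[r] > 0) m1 / m2 else m2 / m1
    expect_equal(unname(log2(ratio)), 2, tolerance = 0.45)
  }
})

test_that("expression pairs plant opposite-direction targets only for DE miRNAs", {
  cfg <- small_config(seed = 2)
  refs <- generate_reference_set(cfg)
  sim <- simulate_count_libraries(cfg, refs)
  pairs <- simulate_expression_pairs(cfg, refs, sim$truth)
  de <- sim$truth$de_planted
  planted <- pairs$mrna_de %>% dplyr::filter(call != "ns")
  j <- pairs$target_map %>%
    dplyr::inner_join(de, by = "mirna") %>%
    dplyr::inner_join(planted, by = c("transcript", "comparison"),
                      suffix = c("_mi", "_mr"))
  expect_equal(nrow(j), nrow(pairs$target_map))
  expect_true(all(sign(j$log2fc_mi) * sign(j$log2fc_mr) == -1))
  expect_true(all(abs(j$log2fc_mr) >= 1))
  # no DE: nothing planted
  cfg0 <- small_config(seed = 2, de_fraction = 0, n_genotype_specific = 0L)
  refs0 <- generate_reference_set(cfg0)
  sim0 <- simulate_count_libraries(cfg0, refs0)
  p0 <- simulate_expression_pairs(cfg0, refs0, sim0$truth)
  expect_equal(nrow(p0$target_map), 0L)
  expect_true(all(p0$mrna_de$call == "ns"))
})
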