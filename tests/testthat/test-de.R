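test_that("MA statistics follow their definitions", {
  expect_equal(ma_stats(8, 2), tibble::tibble(M = 2, A = 2))
  expect_equal(ma_stats(100, 100)$M, 0)
  expect_equal(ma_stats(929540, 607305)$M, 0.6140957, tolerance = 1e-6)
  expect_error(ma_stats(0, 5), "positive")
})

test_that("the normal MA test is centred and matches the exact test closely", {
  # equal proportions, equal totals: the statistic sits at its null mean
  expect_equal(ma_plot_test(100, 100, 1e6, 1e6), 1)
  # centred under unequal totals too
  expect_equal(ma_plot_test(200, 100, 2e6, 1e6), 1)
  # moderate-significance pair: within a factor of 1.5 of the exact p
  pa <- ma_plot_test(130, 100, 1e6, 1e6)
  pe <- exact_conditional_test(130, 100, 1e6, 1e6)
  expect_lt(max(pa / pe, pe / pa), 1.5)
  # deep-tail pair: both tests agree decisively in the call; the raw tail
  # probabilities themselves diverge multiplicatively out there
  expect_lt(ma_plot_test(200, 100, 1e6, 1e6), 1e-6)
  expect_lt(exact_conditional_test(200, 100, 1e6, 1e6), 1e-6)
  expect_warning(p0 <- ma_plot_test(0, 0, 1e6, 1e6), "zero")
  expect_equal(p0, 1)
})

test_that("swapping condition labels negates M and preserves p", {
  withr::with_seed(8, {
    c1 <- rpois(20, 80) + 1
    c2 <- rpois(20, 120) + 1
    d1 <- ma_stats(c1, c2)
    d2 <- ma_stats(c2, c1)
    expect_equal(d1$M, -d2$M)
    expect_equal(ma_plot_test(c1, c2, 1e6, 2e6),
                 ma_plot_test(c2, c1, 2e6, 1e6))
  })
})

test_that("exact conditional test gives closed-form values and is super-uniform", {
  expect_equal(exact_conditional_test(10, 0, 1e6, 1e6), 2 * 0.5^10)
  expect_equal(exact_conditional_test(5, 5, 1e6, 1e6), 1)
  # exhaustive super-uniformity for all outcomes, a range of k
  for (k in c(1, 3, 7, 15, 30)) {
    for (ratio in c(1, 2.5)) {
      pr <- ratio / (1 + ratio)
      d <- dbinom(0:k, k, pr)
      pv <- vapply(0:k, function(c1)
        exact_conditional_test(c1, k - c1, ratio * 1e6, 1e6), numeric(1))
      for (a in unique(pv)) {
        expect_lte(sum(d[pv <= a]), a + 1e-12)
      }
    }
  }
})

test_that("BH adjustment matches hand arithmetic and is order-equivariant", {
  expect_equal(qvalue_adjust(0.01), 0.01)
  expect_equal(qvalue_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  withr::with_seed(4, {
    p <- runif(50)
    perm <- sample(50)
    expect_equal(qvalue_adjust(p)[perm], qvalue_adjust(p[perm]))
    expect_true(all(qvalue_adjust(p) >= p))
  })
})

de_fixture_counts <- function() {
  # 4 miRNAs x 8 libraries with known structure
  libs <- lib_names
  counts <- tidyr::expand_grid(mirna = c("flat", "bigup", "hskonly", "hrkonly"),
                               library = libs) %>%
    mutate(condition = sub("-[0-9]+$", "", library),
           count = dplyr::case_when(
             mirna == "flat" ~ 500L,
             mirna == "bigup" & condition == "HRK48" ~ 800L,
             mirna == "bigup" ~ 100L,
             mirna == "hrkonly" & condition %in% c("HRK0", "HRK48") ~ 50L,
             mirna == "hrkonly" ~ 0L,
             mirna == "hskonly" & condition %in% c("HSK0", "HSK48") ~ 60L,
             TRUE ~ 0L
           )) %>%
    dplyr::select(mirna, library, count)
  counts
}

test_that("call_de flags genotype-specific expression and calls planted DE", {
  de <- call_de(de_fixture_counts(),
                library_totals = setNames(rep(1e5, 8), lib_names))
  d <- as_tibble(de)
  hrk <- d %>% dplyr::filter(mirna == "hrkonly", comparison == "HRK0/HSK0")
  expect_equal(hrk$specific, "only_HRK0")
  expect_equal(hrk$call, "up")
  up <- d %>% dplyr::filter(mirna == "bigup", comparison == "HRK48/HRK0")
  expect_equal(up$call, "up")
  expect_gt(up$log2fc, 1)
  flat <- d %>% dplyr::filter(mirna == "flat")
  expect_true(all(flat$call == "ns"))
  expect_error(call_de(de_fixture_counts() %>%
                         dplyr::filter(library != "HSK48-2")),
               "missing")
})

test_that("DE type partition equals a set-algebra oracle on constructed calls", {
  cmp <- c("HRK48/HRK0", "HSK48/HSK0", "HRK0/HSK0", "HRK48/HSK48")
  withr::with_seed(12, {
    mirnas <- paste0("m", 1:40)
    tab <- tidyr::expand_grid(mirna = mirnas, comparison = cmp) %>%
      mutate(call = sample(c("up", "down", "ns"), dplyr::n(), replace = TRUE,
                           prob = c(0.25, 0.25, 0.5)),
             log2fc = ifelse(call == "up", 2, ifelse(call == "down", -2, 0)),
             C1 = 10, C2 = 10, N1 = 1e5, N2 = 1e5, M = 0, A = 0, p = 1, q = 1,
             specific = NA_character_)
    de <- structure(tab, class = c("mirdef_de", class(tab)))
    part <- classify_de_types(de)
    call_of <- function(m, cc) tab$call[tab$mirna == m & tab$comparison == cc]
    # oracle by direct set algebra
    t1 <- mirnas[vapply(mirnas, function(m) call_of(m, "HRK0/HSK0") != "ns", TRUE)]
    t2 <- mirnas[vapply(mirnas, function(m)
      call_of(m, "HRK48/HRK0") != "ns" && call_of(m, "HSK48/HSK0") != "ns", TRUE)]
    t3 <- mirnas[vapply(mirnas, function(m)
      xor(call_of(m, "HRK48/HRK0") != "ns", call_of(m, "HSK48/HSK0") != "ns"), TRUE)]
    expect_setequal(part$type1$mirna, t1)
    expect_setequal(part$type2$mirna, t2)
    expect_setequal(part$type3$mirna, t3)
    # subcategory counts sum to their set sizes
    expect_equal(sum(table(part$type1$subcategory)), length(t1))
    expect_equal(sum(table(part$type2$subcategory)), length(t2))
    expect_equal(sum(table(part$type3$subcategory)), length(t3))
    # spot-check: always-up means up at both 0 h and 48 h between genotypes
    au <- part$type1$mirna[part$type1$subcategory == "always_up"]
    for (m in au) {
      expect_equal(call_of(m, "HRK0/HSK0"), "up")
      expect_equal(call_of(m, "HRK48/HSK48"), "up")
    }
  })
})
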