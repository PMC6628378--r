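# Synthetic data generator: references, read libraries, count matrices,
# paired mRNA differential expression and qPCR tables, each with a
# ground-truth ledger for parameter-recovery tests.

SIM_CONDITIONS <- c("HRK0", "HRK48", "HSK0", "HSK48")

# --- reference construction -------------------------------------------------

# palindromic stem-loop around a mature sequence: lower stem `d` nt per side,
# loop `loop_len` nt, mature on the chosen arm
make_hairpin <- function(mature, d, loop_len, arm = c("5p", "3p")) {
  arm <- match.arg(arm)
  upper5 <- if (arm == "5p") mature else revcomp(mature)
  # a GC clamp next to an all-A loop makes the terminal structure uniquely
  # optimal under the per-pair energy model: loop bases have no admissible
  # partner nearby and undoing a clamp pair always loses energy, so the
  # planted fold is a single unambiguous stem-loop
  clamp <- "GGGG"
  arm5 <- paste0(random_dna(1, d), upper5, clamp)
  prec <- paste0(arm5, strrep("A", loop_len), revcomp(arm5))
  lm <- nchar(mature)
  nc <- nchar(clamp)
  if (arm == "5p") {
    ms <- d + 1L
  } else {
    ms <- d + lm + nc + loop_len + nc + 1L
  }
  list(precursor = prec, mature_start = as.integer(ms),
       mature_end = as.integer(ms + lm - 1L), arm = arm)
}

place_features <- function(contig_lens, widths, max_try = 500) {
  occ <- lapply(contig_lens, function(...) IRanges::IRanges())
  out <- tibble(contig = character(length(widths)), start = integer(length(widths)))
  ord <- order(widths, decreasing = TRUE) # large features first
  for (k in ord) {
    w <- widths[k]
    placed <- FALSE
    for (t in seq_len(max_try)) {
      ci <- sample(length(contig_lens), 1, prob = contig_lens)
      if (contig_lens[ci] < w + 2) next
      s <- sample.int(contig_lens[ci] - w - 1L, 1) + 1L
      cand <- IRanges::IRanges(s, s + w - 1L)
      if (!IRanges::overlapsAny(cand, occ[[ci]])) {
        occ[[ci]] <- c(occ[[ci]], cand)
        out$contig[k] <- names(contig_lens)[ci]
        out$start[k] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed) abort("feature overflow: features cannot be placed without overlap")
  }
  out
}

#' Generate the synthetic reference set
#'
#' Builds a genome (4 contigs), a gene model, per-class reference sequence
#' sets and a known-miRNA catalog. Known and novel miRNA precursors are
#' palindromic stem-loops embedded verbatim in the genome (precursor lengths
#' fall inside the observed 69-910 nt range, mature lengths inside
#' 19-30 nt); rRNA/tRNA/snoRNA/snRNA genes are also embedded so their read
#' fragments map. Novel precursors are deliberately absent from the
#' reference classes so that their reads stay unannotated.
#'
#' @param config [sim_config()] object.
#' @return list of class `mirdef_refs`: `index` (a `mirdef_index`),
#'   `novel_truth` (planted hairpins with genomic loci and mature
#'   placement), and `footprints` (embedded feature intervals).
#' @export
generate_reference_set <- function(config) {
  with_stage_seed(config$seed, "refs", {
    n <- config$n_known_mirnas
    mature_lens <- sample(19:24, n, replace = TRUE,
                          prob = c(.05, .15, .40, .10, .05, .25))
    matures <- vapply(mature_lens, function(l) random_dna(1, l), character(1))
    # family structure: roughly a third of families have several members
    n_fam <- max(1L, round(n * 0.65))
    fam_of <- sort(c(seq_len(n_fam), sample(n_fam, n - n_fam, replace = TRUE)))
    n_species <- sample(c(1:9, 10:15), n_fam, replace = TRUE,
                        prob = c(rep(.09, 9), rep(.19 / 6, 6)))
    hp <- purrr::map(seq_len(n), function(i) {
      make_hairpin(matures[i], d = sample(12:35, 1), loop_len = sample(5:9, 1),
                   arm = sample(c("5p", "3p"), 1))
    })
    catalog <- tibble(
      mature_id = sprintf("syn-miR%03d%s", fam_of,
                          ave(fam_of, fam_of, FUN = function(z) seq_along(z)) |>
                            (\(k) ifelse(k > 1, letters[pmin(k, 26)], ""))()),
      family_id = sprintf("SYN-MIR%03d", fam_of),
      precursor_id = sprintf("syn-MIR%03d_prec%d", fam_of, seq_len(n)),
      n_species = n_species[fam_of],
      sequence = matures
    )
    novel <- purrr::map(seq_len(config$n_novel_hairpins), function(i) {
      lm <- sample(20:22, 1)
      mat <- paste0("T", random_dna(1, lm - 1)) # novel matures start with U
      c(make_hairpin(mat, d = sample(14:30, 1), loop_len = sample(5:9, 1),
                     arm = sample(c("5p", "3p"), 1)),
        list(mature_seq = mat, id = sprintf("novel-hp%02d", i)))
    })
    refclass <- purrr::imap(config$n_other_ncrna, function(cnt, cls) {
      lens <- switch(cls, rRNA = 120:200, tRNA = 70:90, snoRNA = 70:150,
                     snRNA = 80:160)
      tibble(id = sprintf("%s_%02d", cls, seq_len(cnt)),
             sequence = vapply(sample(lens, cnt, replace = TRUE),
                               function(l) random_dna(1, l), character(1)))
    })
    # genome: embed every feature verbatim
    feats <- tibble(
      id = c(catalog$precursor_id, vapply(novel, `[[`, character(1), "id"),
             unlist(purrr::map(refclass, "id"))),
      class = c(rep("precursor", n), rep("novel", length(novel)),
                rep(names(refclass), vapply(refclass, nrow, integer(1)))),
      sequence = c(vapply(hp, `[[`, character(1), "precursor"),
                   vapply(novel, `[[`, character(1), "precursor"),
                   unlist(purrr::map(refclass, "sequence")))
    )
    feat_len <- sum(nchar(feats$sequence))
    if (config$genome_length < 10 * feat_len)
      abort("feature overflow: genome_length must be >= 10x the embedded feature length")
    contig_lens <- setNames(
      diff(round(seq(0, config$genome_length, length.out = 5))),
      paste0("ctg", 1:4)
    )
    genome_seq <- vapply(contig_lens, function(l) random_dna(1, l), character(1))
    pos <- place_features(contig_lens, nchar(feats$sequence))
    feats <- bind_cols(feats, pos) %>%
      mutate(end = .data$start + nchar(.data$sequence) - 1L)
    for (k in seq_len(nrow(feats))) {
      ci <- feats$contig[k]
      substr(genome_seq[ci], feats$start[k], feats$end[k]) <- feats$sequence[k]
    }
    genome <- tibble(contig = names(contig_lens), sequence = unname(genome_seq))
    # gene model in the remaining space
    gene_rows <- list()
    occupied <- feats %>% select("contig", "start", "end")
    for (g in seq_len(config$n_genes)) {
      n_ex <- sample(2:4, 1)
      ex_len <- sample(150:400, n_ex, replace = TRUE)
      in_len <- sample(100:300, n_ex - 1, replace = TRUE)
      gl <- sum(ex_len) + sum(in_len)
      p <- tryCatch(place_gene(contig_lens, occupied, gl), error = function(e) NULL)
      if (is.null(p)) next
      occupied <- bind_rows(occupied,
                            tibble(contig = p$contig, start = p$start,
                                   end = p$start + gl - 1L))
      at <- p$start
      gid <- sprintf("gene%03d", g)
      for (e in seq_len(n_ex)) {
        gene_rows[[length(gene_rows) + 1]] <-
          tibble(contig = p$contig, gene_id = gid, feature = "exon",
                 start = at, end = at + ex_len[e] - 1L)
        at <- at + ex_len[e]
        if (e < n_ex) {
          gene_rows[[length(gene_rows) + 1]] <-
            tibble(contig = p$contig, gene_id = gid, feature = "intron",
                   start = at, end = at + in_len[e] - 1L)
          at <- at + in_len[e]
        }
      }
    }
    gene_model <- bind_rows(gene_rows)
    class_refs <- list(
      miRNA = tibble(id = catalog$mature_id, sequence = catalog$sequence),
      piRNA = tibble(id = character(), sequence = character()),
      snoRNA = refclass$snoRNA,
      rRNA = refclass$rRNA,
      tRNA = refclass$tRNA,
      sncRNA = refclass$snRNA,
      precursor = tibble(id = catalog$precursor_id,
                         sequence = vapply(hp, `[[`, character(1), "precursor"))
    )
    index <- annotation_index(genome, gene_model, class_refs, catalog)
    nv <- feats %>% filter(.data$class == "novel")
    novel_truth <- tibble(
      id = vapply(novel, `[[`, character(1), "id"),
      mature_seq = vapply(novel, `[[`, character(1), "mature_seq"),
      precursor_seq = vapply(novel, `[[`, character(1), "precursor"),
      mature_start = vapply(novel, `[[`, integer(1), "mature_start"),
      mature_end = vapply(novel, `[[`, integer(1), "mature_end"),
      arm = vapply(novel, `[[`, character(1), "arm")
    ) %>%
      left_join(select(nv, "id", "contig", "start", "end"), by = "id")
    structure(list(index = index, novel_truth = novel_truth,
                   footprints = select(feats, "id", "class", "contig", "start", "end")),
              class = "mirdef_refs")
  })
}

place_gene <- function(contig_lens, occupied, width, max_try = 300) {
  for (t in seq_len(max_try)) {
    ci <- sample(length(contig_lens), 1, prob = contig_lens)
    if (contig_lens[ci] < width + 2) next
    s <- sample.int(contig_lens[ci] - width - 1L, 1) + 1L
    occ <- occupied[occupied$contig == names(contig_lens)[ci], ]
    if (!nrow(occ) ||
        !IRanges::overlapsAny(IRanges::IRanges(s, s + width - 1L),
                              IRanges::IRanges(occ$start, occ$end))) {
      return(list(contig = names(contig_lens)[ci], start = s))
    }
  }
  abort("feature overflow: gene cannot be placed")
}

# --- count-level truth ------------------------------------------------------

#' Simulate the eight-library known-miRNA count matrix with planted DE
#'
#' Baseline abundances are lognormal; a `de_fraction` of miRNAs is planted
#' differentially expressed in one of the four standard comparisons with a
#' signed log2 fold change drawn from `de_log2fc_range` (directions
#' balanced); `n_genotype_specific` miRNAs are expressed only in the
#' resistant genotype. Replicate counts are multinomial draws from the
#' condition's proportions (no extra overdispersion: the DE model assumes
#' binomial sampling); an optional Dirichlet-multinomial knob
#' (`overdispersion > 0`) perturbs each replicate's proportions for
#' robustness tests.
#'
#' @param config [sim_config()] object.
#' @param refs reference set from [generate_reference_set()].
#' @param overdispersion Dirichlet concentration is `1/overdispersion`; 0
#'   (default) reproduces pure multinomial replicates.
#' @return list with `counts` (long tibble `mirna`, `library`, `count`) and
#'   `truth` (list: `de_planted`, `true_lfc` for all four comparisons,
#'   `specific`, `proportions` per condition, `mirna_sizes` of the drawn
#'   libraries).
#' @export
simulate_count_libraries <- function(config, refs, overdispersion = 0) {
  with_stage_seed(config$seed, "counts", {
    catalog <- refs$index$mirna_catalog
    n <- nrow(catalog)
    lambda <- rlnorm(n, meanlog = log(60), sdlog = 1.1)
    lam <- purrr::map(SIM_CONDITIONS, ~lambda) %>% setNames(SIM_CONDITIONS)
    # planted effects live on sub-median-abundance miRNAs and are applied as
    # reductions of the opposite condition (below), so the per-condition
    # totals -- and with them the null miRNAs' proportions -- stay nearly
    # constant across conditions
    sub_median <- catalog$mature_id[lambda <= stats::quantile(lambda, 0.85)]
    specific <- character(0)
    if (config$n_genotype_specific > 0) {
      specific <- sample(sub_median, config$n_genotype_specific)
      sp <- match(specific, catalog$mature_id)
      lam$HSK0[sp] <- 0
      lam$HSK48[sp] <- 0
      lam$HRK0[sp] <- pmax(lam$HRK0[sp], 40) # clearly expressed on the HRK side
      lam$HRK48[sp] <- pmax(lam$HRK48[sp], 40)
    }
    n_de <- round(config$de_fraction * n)
    de_pool <- setdiff(sub_median, specific)
    de_ids <- sample(de_pool, min(n_de, length(de_pool)))
    de_planted <- tibble(
      mirna = de_ids,
      comparison = sample(default_comparisons(), length(de_ids), replace = TRUE),
      direction = rep_len(c("up", "down"), length(de_ids)),
      log2fc = runif(length(de_ids), config$de_log2fc_range[1],
                     config$de_log2fc_range[2]) *
        ifelse(rep_len(c(TRUE, FALSE), length(de_ids)), 1, -1)
    ) %>%
      mutate(direction = if_else(.data$log2fc > 0, "up", "down"))
    for (r in seq_len(nrow(de_planted))) {
      cond <- strsplit(de_planted$comparison[r], "/")[[1]]
      i <- match(de_planted$mirna[r], catalog$mature_id)
      f <- de_planted$log2fc[r]
      # realize the ratio 2^f by shrinking the lower side only
      if (f > 0) {
        lam[[cond[2]]][i] <- lam[[cond[2]]][i] * 2^(-f)
      } else {
        lam[[cond[1]]][i] <- lam[[cond[1]]][i] * 2^f
      }
    }
    props <- purrr::map(lam, ~ setNames(.x / sum(.x), catalog$mature_id))
    true_lfc <- purrr::map_dfr(default_comparisons(), function(cmp) {
      cond <- strsplit(cmp, "/")[[1]]
      tibble(mirna = catalog$mature_id, comparison = cmp,
             true_log2fc = unname(log2(props[[cond[1]]] / props[[cond[2]]])))
    })
    clean_rate <- 1 - sum(config$contamination_rates)
    sizes <- round(config$library_sizes * clean_rate *
                     config$class_fractions[["mirna"]])
    counts <- purrr::imap_dfr(sizes, function(sz, lib) {
      cond <- sub("-[0-9]+$", "", lib)
      p <- props[[cond]]
      if (overdispersion > 0) {
        a <- p / overdispersion
        g <- rgamma(length(p), shape = pmax(a, 1e-12))
        p <- if (sum(g) > 0) g / sum(g) else p
        if (any(props[[cond]] == 0)) p[props[[cond]] == 0] <- 0
        p <- p / sum(p)
      }
      tibble(mirna = catalog$mature_id, library = lib,
             count = as.integer(rmultinom(1, sz, p)[, 1]))
    })
    list(counts = counts,
         truth = list(de_planted = de_planted, true_lfc = true_lfc,
                      specific = specific, proportions = props,
                      mirna_sizes = sizes))
  })
}

# --- read-level simulation --------------------------------------------------

sample_free_positions <- function(n, lens, genome, footprints) {
  # positions avoiding embedded feature footprints (genes are allowed)
  out_ci <- integer(0); out_pos <- integer(0); out_len <- integer(0)
  clens <- nchar(genome$sequence)
  while (length(out_ci) < n) {
    need <- n - length(out_ci)
    ci <- sample(nrow(genome), need, replace = TRUE, prob = clens)
    ln <- if (length(lens) == 1) rep(lens, need) else sample(lens, need, replace = TRUE)
    pos <- floor(runif(need, 1, clens[ci] - ln)) + 1L
    ok <- rep(TRUE, need)
    for (c2 in unique(ci)) {
      fp <- footprints[footprints$contig == genome$contig[c2], ]
      idx <- which(ci == c2)
      if (nrow(fp)) {
        q <- IRanges::IRanges(pos[idx], pos[idx] + ln[idx] - 1L)
        ok[idx] <- !IRanges::overlapsAny(q, IRanges::IRanges(fp$start, fp$end))
      }
    }
    out_ci <- c(out_ci, ci[ok]); out_pos <- c(out_pos, pos[ok])
    out_len <- c(out_len, ln[ok])
  }
  tibble(ci = out_ci[seq_len(n)], pos = out_pos[seq_len(n)],
         len = out_len[seq_len(n)])
}

quality_pool <- function(n, read_length, mean_phred, low = FALSE) {
  vapply(seq_len(n), function(i) {
    ph <- round(rnorm(read_length, mean_phred, 3))
    if (low) {
      bad <- sample(read_length, ceiling(0.4 * read_length))
      ph[bad] <- round(rnorm(length(bad), 8, 2))
    }
    intToUtf8(pmin(pmax(ph, 2), 40) + 33)
  }, character(1))
}

#' Simulate one raw small RNA read library
#'
#' Reads are adapter-flanked inserts sampled from the reference classes at
#' the configured proportions: known matures drawn from the library
#' condition's true proportions, planted novel matures, ncRNA fragments,
#' genomic background (outside embedded features) and unmappable sequences.
#' Insert lengths follow the configured 18-32 nt mixture peaking at 20, 21
#' and 24 nt. A configured fraction of reads violates exactly one of the
#' seven filter rules; every read's expected fate is recorded.
#'
#' @param config [sim_config()] object.
#' @param refs reference set from [generate_reference_set()].
#' @param truth ground truth from [simulate_count_libraries()].
#' @param library_id one of the eight library labels.
#' @return list with `reads` (tibble `id`, `sequence`, `quality`) and
#'   `fates` (tibble `id`, `fate`, `class`, `source`).
#' @export
simulate_read_library <- function(config, refs, truth, library_id) {
  if (!library_id %in% names(config$library_sizes))
    abort(paste0("unknown library id: ", library_id))
  with_stage_seed(config$seed, paste0("lib_", library_id), {
    n <- config$library_sizes[[library_id]]
    cond <- sub("-[0-9]+$", "", library_id)
    genome <- refs$index$genome
    catalog <- refs$index$mirna_catalog
    rates <- config$contamination_rates
    fate_n <- as.integer(rmultinom(1, n, c(1 - sum(rates), rates))[, 1])
    names(fate_n) <- c("clean", names(rates))

    cf <- config$class_fractions
    class_p <- c(mirna = cf[["mirna"]], novel = cf[["novel"]],
                 rRNA = config$rrna_target_fraction, tRNA = cf[["trna"]],
                 snoRNA = cf[["snorna"]], sncRNA = cf[["snrna"]],
                 precursor = cf[["precursor"]], unmapped = cf[["unmapped"]])
    class_p <- c(class_p, genomic = 1 - sum(class_p))
    cls_n <- as.integer(rmultinom(1, fate_n[["clean"]], class_p)[, 1])
    names(cls_n) <- names(class_p)

    ins <- character(0); cls <- character(0); src <- character(0)
    add <- function(seqs, class, source) {
      ins <<- c(ins, seqs); cls <<- c(cls, rep(class, length(seqs)))
      src <<- c(src, rep_len(source, length(seqs)))
    }
    # known matures from condition proportions, with 3' trailing variants
    if (cls_n[["mirna"]] > 0) {
      idx <- sample.int(nrow(catalog), cls_n[["mirna"]], replace = TRUE,
                        prob = truth$proportions[[cond]])
      seqs <- catalog$sequence[idx]
      kind <- sample(1:3, length(idx), replace = TRUE, prob = c(.85, .075, .075))
      seqs[kind == 2] <- substr(seqs[kind == 2], 1, nchar(seqs[kind == 2]) - 1)
      ext <- which(kind == 3)
      if (length(ext)) {
        prec <- refs$index$class_refs$precursor$sequence[
          match(catalog$precursor_id[idx[ext]], refs$index$class_refs$precursor$id)]
        at <- stringi::stri_locate_first_fixed(prec, catalog$sequence[idx[ext]])[, 2]
        nxt <- substr(prec, at + 1, at + 1)
        grow <- !is.na(nxt) & nxt != ""
        seqs[ext[grow]] <- paste0(seqs[ext[grow]], nxt[grow])
      }
      add(seqs, "miRNA", catalog$mature_id[idx])
    }
    if (cls_n[["novel"]] > 0 && nrow(refs$novel_truth)) {
      idx <- sample.int(nrow(refs$novel_truth), cls_n[["novel"]], replace = TRUE)
      add(refs$novel_truth$mature_seq[idx], "novel", refs$novel_truth$id[idx])
    }
    frag_from_refs <- function(k, ref_tbl, class) {
      if (k == 0 || !nrow(ref_tbl)) return(invisible(NULL))
      idx <- sample.int(nrow(ref_tbl), k, replace = TRUE)
      rl <- nchar(ref_tbl$sequence[idx])
      ln <- pmin(sample(18:32, k, replace = TRUE, prob = config$insert_len_probs), rl)
      st <- floor(runif(k, 1, rl - ln + 1))
      add(substring(ref_tbl$sequence[idx], st, st + ln - 1), class,
          ref_tbl$id[idx])
    }
    frag_from_refs(cls_n[["rRNA"]], refs$index$class_refs$rRNA, "rRNA")
    frag_from_refs(cls_n[["tRNA"]], refs$index$class_refs$tRNA, "tRNA")
    frag_from_refs(cls_n[["snoRNA"]], refs$index$class_refs$snoRNA, "snoRNA")
    frag_from_refs(cls_n[["sncRNA"]], refs$index$class_refs$sncRNA, "sncRNA")
    frag_from_refs(cls_n[["precursor"]], refs$index$class_refs$precursor,
                   "precursor")
    if (cls_n[["genomic"]] > 0) {
      gp <- sample_free_positions(cls_n[["genomic"]],
                                  sample(18:32, cls_n[["genomic"]],
                                         replace = TRUE,
                                         prob = config$insert_len_probs),
                                  genome, refs$footprints)
      add(substring(genome$sequence[gp$ci], gp$pos, gp$pos + gp$len - 1),
          "genomic", paste0(genome$contig[gp$ci], ":", gp$pos))
    }
    if (cls_n[["unmapped"]] > 0) {
      ln <- sample(18:32, cls_n[["unmapped"]], replace = TRUE,
                   prob = config$insert_len_probs)
      add(vapply(ln, function(l) random_dna(1, l), character(1)),
          "unmapped", "random")
    }
    clean_fates <- tibble(insert = ins, class = cls, source = src,
                          fate = "clean")

    # planted violations (each violating exactly its own rule)
    viol <- list()
    mk_genomic <- function(k, lens) {
      gp <- sample_free_positions(k, lens, genome, refs$footprints)
      substring(genome$sequence[gp$ci], gp$pos, gp$pos + gp$len - 1)
    }
    if (fate_n[["rule1_low_quality"]] > 0)
      viol$rule1_low_quality <- mk_genomic(fate_n[["rule1_low_quality"]], 20:24)
    if (fate_n[["rule2_high_n"]] > 0) {
      s <- mk_genomic(fate_n[["rule2_high_n"]], 20:24)
      s <- vapply(s, function(x) {
        nn <- ceiling(0.2 * nchar(x))
        at <- sample(nchar(x), nn)
        for (a in at) substr(x, a, a) <- "N"
        x
      }, character(1), USE.NAMES = FALSE)
      viol$rule2_high_n <- s
    }
    if (fate_n[["rule3_adapter5"]] > 0)
      viol$rule3_adapter5 <- paste0(substr(config$adapter_5p, 1, 12),
                                    mk_genomic(fate_n[["rule3_adapter5"]], 12))
    if (fate_n[["rule4_no_adapter3"]] > 0) {
      # guarantee the planted fate: resample any draw in which the filter's
      # tolerant adapter search would still find a spurious 3' adapter match
      s <- mk_genomic(fate_n[["rule4_no_adapter3"]], config$read_length)
      th <- qc_default_thresholds()
      for (tries in 1:20) {
        spurious <- which(!is.na(locate_adapter3(s, config$adapter_3p, th)))
        if (!length(spurious)) break
        s[spurious] <- mk_genomic(length(spurious), config$read_length)
      }
      viol$rule4_no_adapter3 <- s
    }
    if (fate_n[["rule5_no_insert"]] > 0)
      viol$rule5_no_insert <- rep("", fate_n[["rule5_no_insert"]])
    if (fate_n[["rule6_polya"]] > 0)
      viol$rule6_polya <- rep(strrep("A", 22), fate_n[["rule6_polya"]])
    if (fate_n[["rule7_short"]] > 0)
      viol$rule7_short <- mk_genomic(fate_n[["rule7_short"]], 12:17)
    viol_fates <- purrr::imap_dfr(viol, function(s, rule) {
      tibble(insert = s, class = NA_character_, source = NA_character_,
             fate = rule)
    })

    all_rows <- bind_rows(clean_fates, viol_fates)
    all_rows <- all_rows[sample.int(nrow(all_rows)), ]
    # assemble raw reads: insert + 3' adapter fill, fixed read length
    fill <- strrep(config$adapter_3p,
                   ceiling(config$read_length / nchar(config$adapter_3p)) + 1)
    raw <- substr(paste0(all_rows$insert, fill), 1, config$read_length)
    no_ad <- all_rows$fate == "rule4_no_adapter3"
    raw[no_ad] <- substr(all_rows$insert[no_ad], 1, config$read_length)
    good_pool <- quality_pool(200, config$read_length, config$mean_phred)
    low_pool <- quality_pool(50, config$read_length, config$mean_phred, low = TRUE)
    qual <- good_pool[sample.int(length(good_pool), nrow(all_rows), replace = TRUE)]
    lowq <- all_rows$fate == "rule1_low_quality"
    qual[lowq] <- low_pool[sample.int(length(low_pool), sum(lowq), replace = TRUE)]
    qual <- substr(qual, 1, nchar(raw))
    ids <- sprintf("%s_%07d", library_id, seq_len(nrow(all_rows)))
    list(
      reads = tibble(id = ids, sequence = raw, quality = qual),
      fates = tibble(id = ids, fate = all_rows$fate, class = all_rows$class,
                     source = all_rows$source)
    )
  })
}

# --- paired mRNA differential expression ------------------------------------

#' Simulate target transcripts and the paired mRNA DE table
#'
#' For every planted DE miRNA, `mrna_targets_per_de_mirna` target transcripts
#' are created carrying a perfect complementary binding site; in the miRNA's
#' comparison each target receives an opposite-direction log2 fold change
#' with magnitude at least 1. Decoy transcripts carry no planted site and
#' null fold changes. A small GO/KEGG-style annotation map over all
#' transcript parent genes is included for the enrichment stage.
#'
#' @param config [sim_config()] object.
#' @param refs reference set.
#' @param truth ground truth from [simulate_count_libraries()].
#' @return list: `transcripts` (tibble `id`, `sequence`), `mrna_de` (tibble
#'   `transcript`, `comparison`, `log2fc`, `call`, `description`),
#'   `target_map` (tibble `mirna`, `transcript`), `annotation_map` (tibble
#'   `term_id`, `namespace`, `term_name`, `gene_id`).
#' @export
simulate_expression_pairs <- function(config, refs, truth) {
  with_stage_seed(config$seed, "mrna", {
    de <- truth$de_planted
    catalog <- refs$index$mirna_catalog
    tx <- list(); map <- list(); de_rows <- list()
    k <- 0L
    for (r in seq_len(nrow(de))) {
      mat <- catalog$sequence[match(de$mirna[r], catalog$mature_id)]
      for (j in seq_len(config$mrna_targets_per_de_mirna)) {
        k <- k + 1L
        txid <- sprintf("SynGene.%03d.1", k)
        body <- random_dna(1, sample(300:500, 1))
        at <- sample(50:(nchar(body) - 50), 1)
        seq <- paste0(substr(body, 1, at - 1), revcomp(mat),
                      substr(body, at, nchar(body)))
        tx[[k]] <- tibble(id = txid, sequence = seq)
        map[[k]] <- tibble(mirna = de$mirna[r], transcript = txid)
        de_rows[[k]] <- tibble(
          transcript = txid, comparison = de$comparison[r],
          log2fc = -sign(de$log2fc[r]) * runif(1, 1.5, 8),
          call = if_else(de$log2fc[r] > 0, "down", "up"),
          description = sprintf("synthetic target of %s", de$mirna[r])
        )
      }
    }
    n_dec <- config$n_decoy_genes
    decoys <- tibble(
      id = sprintf("SynDecoy.%03d.1", seq_len(n_dec)),
      sequence = vapply(sample(300:500, n_dec, replace = TRUE),
                        function(l) random_dna(1, l), character(1))
    )
    decoy_de <- tidyr::expand_grid(transcript = decoys$id,
                                   comparison = default_comparisons()) %>%
      mutate(log2fc = rnorm(n(), 0, 0.3), call = "ns",
             description = "synthetic decoy")
    transcripts <- bind_rows(bind_rows(tx), decoys)
    mrna_de <- bind_rows(bind_rows(de_rows), decoy_de)
    genes <- transcripts$id
    terms <- tibble(
      term_id = c(sprintf("GO:%07d", 1:8), sprintf("ko%05d", 1:4)),
      namespace = c(rep(c("GO-BP", "GO-CC", "GO-MF"), c(3, 2, 3)),
                    rep("KEGG", 4)),
      term_name = c(sprintf("synthetic biological process %d", 1:3),
                    sprintf("synthetic cellular component %d", 1:2),
                    sprintf("synthetic molecular function %d", 1:3),
                    sprintf("synthetic pathway %d", 1:4))
    )
    ann <- purrr::map_dfr(seq_len(nrow(terms)), function(i) {
      g <- sample(genes, sample(5:15, 1))
      tibble(terms[i, ], gene_id = g)
    })
    # concentrate planted targets in the first term of each namespace so the
    # enrichment stage has signal to find
    tgt <- unique(unlist(purrr::map(map, "transcript")))
    if (length(tgt)) {
      extra <- purrr::map_dfr(c("GO:0000001", "ko00001"), function(tid) {
        tibble(terms[terms$term_id == tid, ],
               gene_id = sample(tgt, max(1, round(length(tgt) * 0.7))))
      })
      ann <- distinct(bind_rows(ann, extra))
    }
    list(transcripts = transcripts, mrna_de = mrna_de,
         target_map = bind_rows(map), annotation_map = ann)
  })
}

# --- qPCR simulation --------------------------------------------------------

#' Simulate a stem-loop qRT-PCR Ct table consistent with the ground truth
#'
#' Ct values encode each miRNA's true per-condition abundance
#' (`Ct = 30 - log2(1e6 x proportion)`) plus Gaussian cycle noise, so the
#' 2^-ddCt of any condition pair recovers the true fold change up to noise.
#' The reference gene (`mir1520d`) has constant expected Ct across
#' conditions.
#'
#' @param config [sim_config()] object.
#' @param truth ground truth from [simulate_count_libraries()].
#' @param mirnas miRNA ids to assay (default: the planted DE set, skipping
#'   any with zero abundance in a condition).
#' @param n_replicates parallel reactions per (miRNA, sample); at least 3.
#' @param noise_sd Ct noise (cycles); defaults to `config$qpcr_noise_sd`.
#' @return tibble `mirna`, `sample`, `rep`, `ct` of class `mirdef_ct`, with
#'   the reference gene included in every sample.
#' @export
simulate_qpcr <- function(config, truth, mirnas = NULL, n_replicates = 3,
                          noise_sd = config$qpcr_noise_sd) {
  if (n_replicates < 3) abort("at least three parallel reactions are required")
  with_stage_seed(config$seed, "qpcr", {
    props <- truth$proportions
    if (is.null(mirnas)) mirnas <- truth$de_planted$mirna
    keep <- vapply(mirnas, function(m) {
      i <- match(m, names(props[[1]]))
      all(vapply(props, function(p) p[i] > 0, logical(1)))
    }, logical(1))
    mirnas <- mirnas[keep]
    grid <- tidyr::expand_grid(mirna = c(mirnas, "mir1520d"),
                               sample = SIM_CONDITIONS,
                               rep = seq_len(n_replicates))
    ct <- purrr::pmap_dbl(grid, function(mirna, sample, rep) {
      base <- if (mirna == "mir1520d") 20 else {
        30 - log2(1e6 * props[[sample]][match(mirna, names(props[[sample]]))])
      }
      base + if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
    })
    structure(mutate(grid, ct = ct), class = c("mirdef_ct", "tbl_df", "tbl",
                                               "data.frame"))
  })
}
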