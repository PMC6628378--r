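# Genome mapping, priority annotation and per-library accounting.
#
# The annotation index bundles the genome, a gene model and priority-ordered
# reference classes. Each unique small RNA receives exactly one annotation:
# the highest-priority class whose reference set contains it as a substring
# (miRNA > piRNA > snoRNA > Rfam classes rRNA/tRNA/sncRNA > precursor);
# anything else is "unannotated" and is classified by genomic location
# (exon > intron > intergenic) when it maps.

#' Build an annotation index
#'
#' @param genome tibble `contig`, `sequence`.
#' @param gene_model tibble `contig`, `gene_id`, `feature` (`"exon"` or
#'   `"intron"`), `start`, `end` (1-based, inclusive).
#' @param class_refs named list of tibbles (`id`, `sequence`), in annotation
#'   priority order; conventionally `miRNA`, `piRNA`, `snoRNA`, `rRNA`,
#'   `tRNA`, `sncRNA`, `precursor`. Empty sets are allowed (the plant piRNA
#'   slot is typically empty but the priority position is kept).
#' @param mirna_catalog tibble `mature_id`, `family_id`, `precursor_id`,
#'   `n_species`, `sequence`.
#' @return list of class `mirdef_index`.
#' @export
annotation_index <- function(genome, gene_model, class_refs, mirna_catalog) {
  stopifnot(all(c("contig", "sequence") %in% names(genome)))
  if (nrow(gene_model)) {
    lens <- setNames(nchar(genome$sequence), genome$contig)
    bad <- gene_model$start < 1 | gene_model$end > lens[gene_model$contig] |
      gene_model$start > gene_model$end
    if (any(bad)) abort("gene model intervals outside contig bounds")
  }
  if (anyDuplicated(mirna_catalog$mature_id))
    abort("duplicate mature ids in miRNA catalog")
  if (nrow(mirna_catalog) && any(is.na(mirna_catalog$family_id)))
    abort("every mature id needs a family")
  structure(list(genome = genome, gene_model = gene_model,
                 class_refs = class_refs, mirna_catalog = mirna_catalog),
            class = "mirdef_index")
}

# which of `seqs` occur as an exact substring of any sequence in `refs`
# (both strands are not considered: references are stranded small RNA sets)
seqs_in_refs <- function(seqs, refs) {
  if (!length(refs) || !length(seqs)) return(rep(FALSE, length(seqs)))
  hit <- rep(FALSE, length(seqs))
  ok <- !stringr::str_detect(seqs, "N")
  subject <- Biostrings::DNAString(paste(refs, collapse = strrep("N", 40)))
  for (w in unique(nchar(seqs[ok]))) {
    idx <- which(ok & nchar(seqs) == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[idx]))
    hit[idx] <- Biostrings::countPDict(pd, subject) > 0
  }
  hit
}

# one N-spaced subject per reference class, shared across width groups
concat_subject <- function(seqs) {
  Biostrings::DNAString(paste(seqs, collapse = strrep("N", 40)))
}

#' Map unique small RNAs to the genome and classify their loci
#'
#' Exact (or single-mismatch) search of each unique small RNA against both
#' strands of the genome. Multi-mapping sequences are assigned their first
#' hit (contig order, then leftmost position, plus strand preferred); the
#' locus class is `exon` when the hit overlaps any exon (exon wins over
#' intron at a boundary), `intron` for intron-only overlap, otherwise
#' `intergenic`.
#'
#' @param srnas tibble with a `sequence` column of unique small RNAs.
#' @param index `mirdef_index` from [annotation_index()].
#' @param max_mismatch 0 (default, fast dictionary search) or 1.
#' @return the input tibble with columns `mapped`, `contig`, `start`, `end`,
#'   `strand`, `locus_class` appended.
#' @export
map_to_genome <- function(srnas, index, max_mismatch = 0) {
  if (!max_mismatch %in% c(0, 1)) abort("`max_mismatch` must be 0 or 1")
  seqs <- srnas$sequence
  n <- length(seqs)
  hit <- tibble(contig = rep(NA_character_, n), start = NA_integer_,
                end = NA_integer_, strand = NA_character_)
  if (max_mismatch == 0) {
    # single N-spaced subject over all contigs; leftmost hit = first contig,
    # smallest position; plus strand takes precedence
    clens <- nchar(index$genome$sequence)
    offsets <- cumsum(c(0L, head(clens + 40L, -1)))
    subject <- concat_subject(index$genome$sequence)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") seqs else revcomp(seqs)
      todo <- which(is.na(hit$contig) & !stringr::str_detect(pat, "N"))
      if (!length(todo)) next
      for (w in unique(nchar(pat[todo]))) {
        idx <- todo[nchar(pat[todo]) == w]
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(pat[idx]))
        m <- Biostrings::matchPDict(pd, subject)
        nh <- S4Vectors::elementNROWS(m)
        got <- which(nh > 0)
        if (!length(got)) next
        gstart <- vapply(Biostrings::startIndex(m)[got], min, integer(1))
        ci <- findInterval(gstart, offsets + 1L)
        rows <- idx[got]
        hit$contig[rows] <- index$genome$contig[ci]
        hit$start[rows] <- gstart - offsets[ci]
        hit$end[rows] <- hit$start[rows] + w - 1L
        hit$strand[rows] <- strand
      }
    }
  } else {
    for (i in seq_len(n)) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") seqs[i] else revcomp(seqs[i])
        for (ci in seq_len(nrow(index$genome))) {
          m <- Biostrings::matchPattern(
            pat, Biostrings::DNAString(index$genome$sequence[ci]),
            max.mismatch = max_mismatch
          )
          if (length(m)) {
            hit$contig[i] <- index$genome$contig[ci]
            hit$start[i] <- min(IRanges::start(m))
            hit$end[i] <- hit$start[i] + nchar(pat) - 1L
            hit$strand[i] <- strand
            break
          }
        }
        if (!is.na(hit$contig[i])) break
      }
      if (!is.na(hit$contig[i])) next
    }
  }
  out <- bind_cols(srnas, hit) %>% mutate(mapped = !is.na(.data$contig))
  out$locus_class <- classify_locus(out, index$gene_model)
  out
}

classify_locus <- function(hits, gene_model) {
  cls <- rep(NA_character_, nrow(hits))
  mapped <- which(hits$mapped)
  if (!length(mapped)) return(cls)
  cls[mapped] <- "intergenic"
  if (!nrow(gene_model)) return(cls)
  for (feat in c("intron", "exon")) { # exon assigned last: wins at boundaries
    gm <- gene_model[gene_model$feature == feat, ]
    if (!nrow(gm)) next
    for (ctg in unique(gm$contig)) {
      rows <- mapped[hits$contig[mapped] == ctg]
      if (!length(rows)) next
      q <- IRanges::IRanges(hits$start[rows], hits$end[rows])
      s <- IRanges::IRanges(gm$start[gm$contig == ctg], gm$end[gm$contig == ctg])
      ov <- IRanges::overlapsAny(q, s)
      cls[rows[ov]] <- feat
    }
  }
  cls
}

#' Assign each unique small RNA a single annotation class by priority
#'
#' Walks the index's reference classes in order and labels each sequence with
#' the first class containing it as an exact substring; sequences matching no
#' class are labelled `"unannotated"`.
#'
#' @param srnas tibble with a `sequence` column.
#' @param index `mirdef_index`.
#' @return input tibble with an `annotation` column appended.
#' @export
annotate_priority <- function(srnas, index) {
  ann <- rep("unannotated", nrow(srnas))
  seqs <- srnas$sequence
  classes <- names(index$class_refs)
  subjects <- purrr::map(index$class_refs, function(r) {
    if (nrow(r)) concat_subject(r$sequence) else NULL
  })
  ok <- !stringr::str_detect(seqs, "N")
  for (w in unique(nchar(seqs[ok]))) {
    idx <- which(ok & nchar(seqs) == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[idx]))
    undecided <- rep(TRUE, length(idx))
    for (cls in classes) {
      if (is.null(subjects[[cls]]) || !any(undecided)) next
      hit <- Biostrings::countPDict(pd, subjects[[cls]]) > 0
      take <- undecided & hit
      ann[idx[take]] <- cls
      undecided[take] <- FALSE
    }
  }
  mutate(srnas, annotation = ann)
}

#' Per-library annotation accounting
#'
#' Combines genome mapping and priority annotation of the unique clean
#' sequences into a per-library table mirroring the standard sequencing
#' report rows: total, clean, mapped, location classes of unannotated mapped
#' reads, annotation classes, and unmapped.
#'
#' @param clean tibble of clean reads with columns `library`, `sequence`.
#' @param index `mirdef_index`.
#' @param qc_totals optional tibble `library`, `total_reads` to carry raw
#'   totals into the report.
#' @param max_mismatch passed to [map_to_genome()].
#' @return tibble with one row per (library, type) holding `count` and
#'   `fraction` (of clean reads; of total reads for the clean row itself),
#'   plus a `unique_count` column counting distinct sequences.
#' @export
annotation_summary <- function(clean, index, qc_totals = NULL, max_mismatch = 0) {
  uniq <- distinct(clean, .data$sequence)
  uniq <- map_to_genome(uniq, index, max_mismatch = max_mismatch)
  uniq <- annotate_priority(uniq, index)
  uniq <- uniq %>%
    mutate(type = dplyr::case_when(
      !.data$mapped ~ "unmap",
      .data$annotation != "unannotated" ~ .data$annotation,
      TRUE ~ .data$locus_class
    ))
  per_read <- clean %>%
    inner_join(select(uniq, "sequence", "type"), by = "sequence") %>%
    count(.data$library, .data$type, name = "count")
  uniq_counts <- clean %>%
    distinct(.data$library, .data$sequence) %>%
    inner_join(select(uniq, "sequence", "type"), by = "sequence") %>%
    count(.data$library, .data$type, name = "unique_count")
  clean_tot <- count(clean, .data$library, name = "clean_reads")
  mapped_tot <- per_read %>%
    filter(.data$type != "unmap") %>%
    group_by(.data$library) %>%
    summarise(mapped = sum(.data$count), .groups = "drop")
  out <- per_read %>%
    left_join(uniq_counts, by = c("library", "type")) %>%
    left_join(clean_tot, by = "library") %>%
    left_join(mapped_tot, by = "library") %>%
    mutate(fraction = .data$count / .data$clean_reads)
  if (!is.null(qc_totals)) out <- left_join(out, qc_totals, by = "library")
  structure(out, class = c("mirdef_annotation_summary", class(out)))
}

#' rRNA quality-control gate
#'
#' A library passes when its rRNA fraction of clean reads is strictly below
#' the threshold (default 60%).
#'
#' @param summary annotation summary (from [annotation_summary()]) or any
#'   tibble with columns `library`, `type`, `fraction`.
#' @param threshold maximum tolerated rRNA fraction.
#' @return tibble `library`, `rrna_fraction`, `pass`.
#' @export
rrna_qc_gate <- function(summary, threshold = 0.60) {
  libs <- distinct(summary, .data$library)
  summary %>%
    filter(.data$type == "rRNA") %>%
    select("library", rrna_fraction = "fraction") %>%
    right_join(libs, by = "library") %>%
    mutate(rrna_fraction = dplyr::coalesce(.data$rrna_fraction, 0),
           pass = .data$rrna_fraction < threshold) %>%
    arrange(.data$library)
}
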