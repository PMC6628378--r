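# RNA secondary structure folding under a simple per-pair energy model.

#' Default pair-energy model
#'
#' Per-pair energies in kcal/mol (GC -3, AU -2, GU -1), minimum hairpin loop
#' of 3 unpaired bases, no stacking terms. Deliberately simple so that an
#' exhaustive dynamic-programming oracle over all nested structures stays
#' feasible; a thermodynamic folder can be plugged in via the `folder`
#' argument of [fold_mfe()].
#'
#' @return list with `gc`, `au`, `gu`, `min_loop`.
#' @export
fold_energy_model <- function() {
  list(gc = -3, au = -2, gu = -1, min_loop = 3L)
}

#' Fold an RNA sequence to its minimum-energy nested structure
#'
#' Interval dynamic programming over all pseudoknot-free structures under the
#' configured per-pair energy model; deterministic given sequence and model.
#' T is read as U; any other non-ACGU character is an error.
#'
#' @param sequence nucleotide sequence (a single string).
#' @param model energy model, see [fold_energy_model()].
#' @param folder optional plug-in: a `function(sequence)` returning
#'   `list(structure=, mfe=)` from an external thermodynamic model; when
#'   given it replaces the internal fold.
#' @return list with `structure` (dot-bracket string) and `mfe` (kcal/mol,
#'   <= 0).
#' @export
fold_mfe <- function(sequence, model = fold_energy_model(), folder = NULL) {
  if (length(sequence) != 1) abort("fold_mfe folds a single sequence")
  if (!is.null(folder)) return(folder(sequence))
  fold_mfe_cpp(sequence, model$gc, model$au, model$gu, model$min_loop)
}

#' Adjusted MFE and MFE index of a hairpin candidate
#'
#' `amfe = mfe / length * 100` (kcal/mol per 100 nt) and `mfei = amfe / GC%`
#' with GC% on the 0-100 scale. Both signed values and the magnitude of the
#' index (the quantity thresholded by the novel-miRNA criteria) are returned.
#'
#' @param mfe minimum folding free energy (kcal/mol, <= 0).
#' @param sequence the folded sequence (for length and GC content; GC content
#'   of zero is an error).
#' @return one-row tibble `amfe`, `mfei`, `abs_mfei`, `gc_pct`.
#' @export
compute_mfei <- function(mfe, sequence) {
  gc_pct <- 100 * gc_fraction(sequence)
  if (gc_pct == 0) abort("GC content is zero; MFEI undefined")
  amfe <- mfe / nchar(sequence) * 100
  mfei <- amfe / gc_pct
  tibble(amfe = amfe, mfei = mfei, abs_mfei = abs(mfei), gc_pct = gc_pct)
}

# partner vector from a dot-bracket string (0 = unpaired)
pair_table <- function(db) {
  ch <- strsplit(db, "")[[1]]
  n <- length(ch)
  partner <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) abort("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack)) abort("unbalanced dot-bracket string")
  partner
}

# number of hairpin loops = innermost '(' ... ')' groups
count_hairpin_loops <- function(db) {
  stringr::str_count(db, "\\(\\.*\\)")
}

# innermost loops whose closing helix has a contiguous stacked run of at
# least `min_stem` pairs; shallow incidental hairpins (tie-broken pairings
# of a terminal loop) are not counted as structure
dominant_hairpin_loops <- function(db, min_stem = 4L) {
  partner <- pair_table(db)
  loc <- stringr::str_locate_all(db, "\\(\\.*\\)")[[1]]
  if (!nrow(loc)) return(tibble(start = integer(), end = integer(), depth = integer()))
  depth <- vapply(seq_len(nrow(loc)), function(k) {
    a <- loc[k, 1]; b <- loc[k, 2]
    d <- 0L
    while (a >= 1 && b <= length(partner) && partner[a] == b) {
      d <- d + 1L
      a <- a - 1L
      b <- b + 1L
    }
    d
  }, integer(1))
  tibble(start = loc[, 1], end = loc[, 2], depth = depth) %>%
    filter(.data$depth >= min_stem)
}
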