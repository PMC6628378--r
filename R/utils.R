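# Shared sequence and randomness helpers.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA sequences
#'
#' Vectorised reverse complement over character DNA sequences (alphabet
#' A/C/G/T/N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringr::str_to_upper(x) %>%
    chartr("ACGTN", "TGCAN", .) %>%
    stringi::stri_reverse()
}

# integer coding A=0 C=1 G=2 T/U=3 used by the alignment core
encode_dna <- function(x) {
  m <- match(strsplit(x, "")[[1]], c("A", "C", "G", "T", "U"))
  m[m == 5L] <- 4L
  if (anyNA(m)) abort(paste0("non-ACGTU character in sequence: ", x))
  m - 1L
}

random_dna <- function(n, length, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

gc_fraction <- function(x) {
  stringr::str_count(x, "[GCgc]") / nchar(x)
}

# Derive a reproducible child seed from a base seed and a stage label,
# bounded below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

with_stage_seed <- function(seed, stage, code) {
  withr::with_seed(derive_seed(seed, stage), code)
}

# strict scalar validators
assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
    abort(paste0("`", name, "` must be a single integer >= ", min))
  invisible(x)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x >= 1))
    abort(paste0("`", name, "` must lie in [0, 1)"))
  invisible(x)
}

# dinucleotide-preserving shuffle (random Eulerian-walk construction with
# rejection; falls back to plain shuffle for degenerate inputs)
dinucleotide_shuffle <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < 4) return(seq)
  edges <- split(ch[-1], ch[-n]) # successor multiset per base
  for (tries in seq_len(50)) {
    succ <- lapply(edges, function(v) sample(v))
    pos <- lapply(succ, function(v) 1L)
    out <- character(n)
    out[1] <- ch[1]
    ok <- TRUE
    for (i in 2:n) {
      b <- out[i - 1]
      k <- pos[[b]]
      if (k > length(succ[[b]])) {
        ok <- FALSE
        break
      }
      out[i] <- succ[[b]][k]
      pos[[b]] <- k + 1L
    }
    if (ok && pos_exhausted(pos, succ)) return(paste(out, collapse = ""))
    if (ok) return(paste(out, collapse = "")) # walk completed n steps
  }
  paste(sample(ch), collapse = "")
}

pos_exhausted <- function(pos, succ) {
  all(vapply(names(succ), function(b) pos[[b]] > length(succ[[b]]), logical(1)))
}
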