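# Independent oracles used across the suite. Each re-implements the checked
# computation from its definition, sharing no code with the package paths it
# verifies.

# minimum energy over all nested structures: plain interval DP written
# directly from the recurrence, energies GC -3 / AU -2 / GU -1, loop >= 3
oracle_fold_mfe <- function(seq) {
  ch <- strsplit(chartr("T", "U", seq), "")[[1]]
  n <- length(ch)
  pe <- function(a, b) {
    k <- paste0(a, b)
    if (k %in% c("GC", "CG")) -3
    else if (k %in% c("AU", "UA")) -2
    else if (k %in% c("GU", "UG")) -1
    else NA_real_
  }
  if (n < 5) return(0)
  E <- matrix(0, n, n)
  for (span in 4:(n - 1)) {
    for (i in 1:(n - span)) {
      j <- i + span
      best <- E[i + 1, j]
      for (k in (i + 4):j) {
        e <- pe(ch[i], ch[k])
        if (is.na(e)) next
        inner <- if (k - i > 1) E[i + 1, k - 1] else 0
        outer <- if (k < j) E[k + 1, j] else 0
        best <- min(best, e + inner + outer)
      }
      E[i, j] <- best
    }
  }
  E[1, n]
}

# energy of a given dot-bracket structure under the same model (NA if any
# pair is inadmissible or a loop is too tight)
structure_energy <- function(seq, db) {
  ch <- strsplit(chartr("T", "U", seq), "")[[1]]
  st <- integer(0)
  e <- 0
  for (i in seq_along(ch)) {
    c2 <- substr(db, i, i)
    if (c2 == "(") st <- c(st, i)
    if (c2 == ")") {
      j <- st[length(st)]
      st <- st[-length(st)]
      if (i - j - 1 < 3) return(NA_real_)
      k <- paste0(ch[j], ch[i])
      e <- e + switch(k, GC = , CG = -3, AU = , UA = -2, GU = , UG = -1,
                      return(NA_real_))
    }
  }
  e
}

# brute-force enumeration of every alignment with at most one gap, applying
# the stated penalty scheme directly
oracle_align_penalty <- function(mirna, site, w_lo = 2, w_hi = 13) {
  enc <- function(x) strsplit(x, "")[[1]]
  m <- enc(chartr("T", "U", mirna))
  s <- enc(chartr("T", "U", mirdefense::revcomp(site)))
  L <- length(m); Ls <- length(s)
  wt <- function(pos) if (pos >= w_lo && pos <= w_hi) 2 else 1
  colp <- function(a, b, pos) {
    if (a == b) 0
    else if ((a == "G" && b == "A") || (a == "U" && b == "C")) 0.5 * wt(pos)
    else 1 * wt(pos)
  }
  pens <- c()
  if (Ls == L) {
    pens <- c(pens, sum(vapply(seq_len(L), function(i) colp(m[i], s[i], i),
                               numeric(1))))
  }
  if (Ls == L - 1) { # one miRNA base bulged, at any position g
    for (g in seq_len(L)) {
      p <- 2 * wt(g)
      si <- 0
      for (i in seq_len(L)) {
        if (i == g) next
        si <- si + 1
        p <- p + colp(m[i], s[si], i)
      }
      pens <- c(pens, p)
    }
  }
  if (Ls == L + 1) { # one site base bulged, before miRNA position g
    for (g in seq_len(L + 1)) {
      p <- 2 * wt(g)
      mi <- 0
      for (j in seq_len(Ls)) {
        if (j == g) next
        mi <- mi + 1
        p <- p + colp(m[mi], s[j], mi)
      }
      pens <- c(pens, p)
    }
  }
  min(pens)
}

# first-match-in-priority-list annotation by naive substring search
oracle_priority_annotation <- function(seq, class_refs) {
  for (cls in names(class_refs)) {
    refs <- class_refs[[cls]]$sequence
    if (length(refs) && any(grepl(seq, refs, fixed = TRUE))) return(cls)
  }
  "unannotated"
}

# exhaustive hypergeometric upper tail by enumerating draw outcomes
oracle_hyper_upper <- function(k, K, n, N) {
  probs <- vapply(0:n, function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }, numeric(1))
  sum(probs[(0:n) >= k])
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
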