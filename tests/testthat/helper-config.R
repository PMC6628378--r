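# Shared small-scale configurations; generation is seeded so every test run
# sees identical data.

lib_names <- c("HRK0-1", "HRK0-2", "HRK48-1", "HRK48-2",
               "HSK0-1", "HSK0-2", "HSK48-1", "HSK48-2")

small_config <- function(seed = 101, reads = 5000L, ...) {
  sim_config(seed = seed,
             library_sizes = setNames(rep(as.integer(reads), 8), lib_names),
             ...)
}

# one handcrafted raw read: insert + 3' adapter, padded to 50 nt
make_read <- function(id, insert, adapter3, qual_char = "I", len = 50,
                      with_adapter = TRUE) {
  seq <- if (with_adapter) paste0(insert, strrep(adapter3, 4)) else insert
  seq <- substr(seq, 1, len)
  tibble::tibble(id = id, sequence = seq,
                 quality = strrep(qual_char, nchar(seq)))
}
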