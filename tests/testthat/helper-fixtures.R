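# fixtures are generated in code; each helper takes an explicit seed

random_reads <- function(n, len = 20, seed = 1, alphabet = c("A", "C", "G", "U"),
                         quality = 38L) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    paste0(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
  tibble::tibble(
    id = sprintf("r%04d", seq_len(n)),
    seq = seqs,
    qual = strrep(intToUtf8(quality + 33L), len)
  )
}

# exhaustively enumerate every nested pair set of a short sequence (no
# memoization, no dynamic programming) and return the maximum pair count:
# an independent oracle for the DP folder, feasible for length <= 12
brute_force_max_pairs <- function(seq, min_loop = 3,
                                  pairs = c("AU", "UA", "GC", "CG", "GU", "UG")) {
  chars <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(chars)
  enumerate <- function(idx) {
    if (length(idx) == 0) return(0L)
    i <- idx[1]
    best <- enumerate(idx[-1])          # i unpaired
    for (q in idx[-1]) {
      if (q - i > min_loop && paste0(chars[i], chars[q]) %in% pairs) {
        inside  <- idx[idx > i & idx < q]
        outside <- idx[idx > q]
        best <- max(best, 1L + enumerate(inside) + enumerate(outside))
      }
    }
    best
  }
  if (n < min_loop + 2) return(0L)
  enumerate(seq_len(n))
}
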