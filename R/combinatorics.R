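# Pool combinatorics with exact integer arithmetic. Sequence-space sizes
# like 4^60 overflow doubles, so an exact little-endian base-10^4 integer
# representation is used internally (no big-integer package is required).

big_from_num <- function(x) {
  stopifnot(x >= 0, x == floor(x), x < 2^53)
  digits <- integer(0)
  x <- as.double(x)
  if (x == 0) return(0L)
  while (x > 0) {
    digits <- c(digits, as.integer(x %% 10000))
    x <- floor(x / 10000)
  }
  digits
}

big_mul <- function(a, b) {
  res <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    res[i:(i + length(b) - 1L)] <- res[i:(i + length(b) - 1L)] + a[i] * b
  }
  carry <- 0
  for (i in seq_along(res)) {
    v <- res[i] + carry
    res[i] <- v %% 10000
    carry <- floor(v / 10000)
  }
  while (carry > 0) {
    res <- c(res, carry %% 10000)
    carry <- floor(carry / 10000)
  }
  while (length(res) > 1 && res[length(res)] == 0) res <- res[-length(res)]
  as.integer(res)
}

big_pow <- function(base, exp) {
  stopifnot(exp >= 0, exp == floor(exp))
  out <- big_from_num(1)
  b <- big_from_num(base)
  for (i in seq_len(exp)) out <- big_mul(out, b)
  out
}

big_to_string <- function(x) {
  n <- length(x)
  paste0(x[n], paste0(sprintf("%04d", rev(x[-n])), collapse = ""))
}

big_to_double <- function(x) sum(as.double(x) * 10000^(seq_along(x) - 1))

#' Combinatorial book-keeping of a random oligomer pool
#'
#' For a pool of `n_molecules` random `length`-mers over an
#' `alphabet_size`-letter alphabet, computes the sequence-space size
#' (diversity), the per-sequence redundancy, the molar amount, and the
#' number of potential binary interactions. Diversity and binary pairs are
#' computed with exact integer arithmetic (valid for `length` up to 60 and
#' beyond); e.g. a 10^15-member eicosamer pool holds 909 copies of each
#' possible 20-mer in about 1.7 nmol, with >10^24 potential binary pairs.
#'
#' @param n_molecules number of molecules in the pool.
#' @param length oligomer length in nucleotides.
#' @param alphabet_size number of letters in the code (4 for RNA).
#' @param avogadro Avogadro constant (1/mol).
#' @return one-row tibble: `diversity` / `binary_pairs` (doubles),
#'   `diversity_exact` / `binary_pairs_exact` (exact digit strings),
#'   `redundancy` (copies per unique sequence, floored) and `amount_nmol`.
#' @export
pool_combinatorics <- function(n_molecules, length, alphabet_size = 4L,
                               avogadro = 6.02214076e23) {
  stopifnot(n_molecules > 0, length > 0, alphabet_size > 1, avogadro > 0)
  diversity_big <- big_pow(alphabet_size, length)
  pairs_big <- big_mul(diversity_big, diversity_big)
  diversity <- big_to_double(diversity_big)
  tibble(
    diversity = diversity,
    diversity_exact = big_to_string(diversity_big),
    redundancy = floor(n_molecules / diversity),
    amount_nmol = n_molecules / avogadro * 1e9,
    binary_pairs = big_to_double(pairs_big),
    binary_pairs_exact = big_to_string(pairs_big)
  )
}
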