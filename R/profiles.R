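# Position-specific nucleotide frequencies, RGB signature transformation,
# and matched-frequency synthetic pool generation.

#' Position-specific nucleotide frequency profile
#'
#' @param records tibble with `seq` (and optionally `count`) columns, or a
#'   character vector of equal-length sequences.
#' @param weighted if `TRUE`, weight each record by its `count` column
#'   (collapsed records); otherwise each record counts once.
#' @param alphabet alphabet (column order of the result).
#' @return a `freq_profile` tibble: `position` plus one frequency column per
#'   alphabet letter; every row sums to 1.
#' @export
frequency_profile <- function(records, weighted = FALSE, alphabet = NULL) {
  seqs <- if (is.character(records)) records else records$seq
  if (length(seqs) == 0) abort("no sequences given")
  if (length(unique(nchar(seqs))) != 1L) {
    abort("sequences have mixed lengths; bucket them with split_by_length() first")
  }
  w <- if (weighted && !is.character(records) && !is.null(records[["count"]])) {
    as.numeric(records[["count"]])
  } else {
    rep(1, length(seqs))
  }
  m <- seq_matrix(seqs)
  alphabet <- alphabet %||% infer_alphabet(unique(as.vector(m)))
  check_alphabet(seqs, alphabet)
  counts <- vapply(alphabet, function(b) colSums((m == b) * w), numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1, dimnames = list(NULL, alphabet))
  freqs <- counts / sum(w)
  out <- as_tibble(freqs)
  out <- tibble(position = seq_len(nrow(out))) |> dplyr::bind_cols(out)
  attr(out, "alphabet") <- alphabet
  attr(out, "n") <- sum(w)
  class(out) <- c("freq_profile", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.freq_profile <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"position",
                      names_to = "base", values_to = "freq")
}

profile_matrix <- function(profile) {
  alphabet <- attr(profile, "alphabet") %||% setdiff(names(profile), "position")
  m <- as.matrix(as_tibble(profile)[, alphabet, drop = FALSE])
  rownames(m) <- profile$position
  m
}

#' RGB signature of a nucleotide frequency profile
#'
#' Converts per-position frequencies into the RGB colour code used for
#' nucleotide signature strips: R = 255(1 - fC - fA), G = 255(1 - fC - fU),
#' B = 255(1 - fA - fG - fU), so pure C is blue (0,0,255), pure U red
#' (255,0,0), pure A green (0,255,0) and pure G yellow (255,255,0). Values
#' are kept as reals (clipped to \[0, 255\]); `hex` rounds half-up for
#' display.
#'
#' @param profile a 4-letter [frequency_profile()] over C, A, U/T, G.
#' @return tibble with `position`, `red`, `green`, `blue`, `hex`.
#' @export
rgb_signature <- function(profile) {
  cols <- setdiff(names(profile), "position")
  cols_u <- toupper(cols)
  if (length(cols) != 4 || !setequal(chartr("T", "U", cols_u), c("A", "C", "G", "U"))) {
    abort("rgb_signature requires a 4-letter profile over A, C, G, U/T")
  }
  get <- function(base) {
    nm <- cols[chartr("T", "U", cols_u) == base]
    profile[[nm]]
  }
  fC <- get("C"); fA <- get("A"); fU <- get("U"); fG <- get("G")
  clip <- function(x) pmin(pmax(x, 0), 255)
  r <- clip(255 - fC * 255 - fA * 255)
  g <- clip(255 - fC * 255 - fU * 255)
  b <- clip(255 - fA * 255 - fG * 255 - fU * 255)
  half_up <- function(x) floor(x + 0.5)
  tibble(
    position = profile$position,
    red = r, green = g, blue = b,
    hex = grDevices::rgb(half_up(r), half_up(g), half_up(b), maxColorValue = 255)
  )
}

#' Generate a synthetic pool matched to a frequency profile
#'
#' Samples every position independently from the profile's per-position
#' frequencies (the construction used for in-silico comparison pools of
#' 3 x 300,000 sequences).
#'
#' @param profile a [frequency_profile()].
#' @param n number of sequences to generate.
#' @param seed integer seed.
#' @return character vector of `n` sequences.
#' @export
generate_matched_pool <- function(profile, n, seed = 1L) {
  stopifnot(n >= 1)
  m <- profile_matrix(profile)
  alphabet <- colnames(m)
  with_seed(seed, {
    cols <- lapply(seq_len(nrow(m)), function(i) {
      sample(alphabet, n, replace = TRUE, prob = m[i, ])
    })
  })
  do.call(paste0, cols)
}
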