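# Ligation-junction dinucleotide fingerprints: the (N-1, N+1) composition
# flanking the ligation bond, compared against an input-pool background.

#' Junction dinucleotide fingerprint of a product set
#'
#' Tabulates the dinucleotide (N-1, N+1) flanking the ligation junction
#' over a set of aligned same-length products and compares it with the
#' expectation from a background profile under independence. The background
#' is ideally the unligated input-pool profile; with no background a
#' uniform expectation is used.
#'
#' @param products tibble with `seq` (and optionally `count`) or character
#'   vector of equal-length sequences.
#' @param junction_index 1-based bond index: the junction lies between
#'   positions `junction_index` and `junction_index + 1`.
#' @param background optional [frequency_profile()] covering positions
#'   `junction_index` and `junction_index + 1`.
#' @param alphabet alphabet over which dinucleotides are enumerated.
#' @return a `junction_fingerprint` tibble over all dinucleotides:
#'   `n_minus1`, `n_plus1`, `observed` (frequencies summing to 1),
#'   `expected`, `log2_enrichment` (`Inf` flagged where the background
#'   expectation is 0 but the dinucleotide was observed) and `difference`
#'   (observed - expected).
#' @export
junction_fingerprint <- function(products, junction_index, background = NULL,
                                 alphabet = RNA_ALPHABET) {
  seqs <- if (is.character(products)) products else products$seq
  if (length(seqs) == 0) abort("no products given")
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L) abort("products must be aligned to one length; use split_by_length()")
  if (junction_index < 1 || junction_index >= lens) {
    abort(sprintf("junction_index must be an interior bond in 1..%d", lens - 1L))
  }
  w <- if (!is.character(products) && !is.null(products[["count"]])) {
    as.numeric(products[["count"]])
  } else {
    rep(1, length(seqs))
  }
  a <- substr(seqs, junction_index, junction_index)
  b <- substr(seqs, junction_index + 1L, junction_index + 1L)
  grid <- tidyr::expand_grid(n_minus1 = alphabet, n_plus1 = alphabet)
  obs <- rowsum(w, group = paste0(a, b))
  key <- paste0(grid$n_minus1, grid$n_plus1)
  observed <- as.numeric(obs[match(key, rownames(obs))])
  observed[is.na(observed)] <- 0
  observed <- observed / sum(w)

  if (is.null(background)) {
    expected <- rep(1 / nrow(grid), nrow(grid))
  } else {
    bm <- profile_matrix(background)
    if (nrow(bm) < junction_index + 1L) {
      abort("background profile does not cover the junction positions")
    }
    pa <- bm[junction_index, match(grid$n_minus1, colnames(bm))]
    pb <- bm[junction_index + 1L, match(grid$n_plus1, colnames(bm))]
    expected <- as.numeric(pa * pb)
  }
  enr <- ifelse(expected > 0, log2(observed / expected),
                ifelse(observed > 0, Inf, NA_real_))
  out <- grid |>
    mutate(observed = observed, expected = expected,
           log2_enrichment = enr, difference = observed - expected)
  attr(out, "junction_index") <- junction_index
  attr(out, "n_products") <- sum(w)
  class(out) <- c("junction_fingerprint", class(out))
  out
}

#' Marginal base frequencies on each side of the junction
#'
#' @param fingerprint a [junction_fingerprint()].
#' @return tibble with `side` (`"minus1"`/`"plus1"`), `base`, `observed`,
#'   `expected` and `log2_enrichment`.
#' @export
junction_marginals <- function(fingerprint) {
  m1 <- fingerprint |>
    group_by(base = .data$n_minus1) |>
    summarise(observed = sum(.data$observed), expected = sum(.data$expected)) |>
    mutate(side = "minus1")
  p1 <- fingerprint |>
    group_by(base = .data$n_plus1) |>
    summarise(observed = sum(.data$observed), expected = sum(.data$expected)) |>
    mutate(side = "plus1")
  bind_rows(m1, p1) |>
    mutate(log2_enrichment = ifelse(.data$expected > 0,
                                    log2(.data$observed / .data$expected), NA_real_)) |>
    select("side", "base", "observed", "expected", "log2_enrichment")
}

#' @exportS3Method generics::tidy
tidy.junction_fingerprint <- function(x, ...) as_tibble(x)
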