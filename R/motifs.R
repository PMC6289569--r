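# Junction-proximal secondary-structure submotif matching, per-bond
# ligation-site profiles, and consensus extraction (pseudocounted PWM with
# per-column information content).

#' Parametric catalogue of junction-proximal structure motifs
#'
#' Generates element-string patterns over `(`, `)`, `.`: internal-loop
#' strands (a run of unpaired bases flanked by helical runs, in both
#' opening and closing orientation) and hairpins. The J and H motifs (a
#' 4-nt unpaired loop flanked by 3-nt helical regions, opening and closing
#' orientation respectively) are predefined entries.
#'
#' @param loop_sizes unpaired run lengths for internal-loop strands.
#' @param helix_sizes helical flank lengths.
#' @param hairpin_loops loop lengths for hairpin patterns (>= 3).
#' @return tibble catalogue: `id`, `kind`, `pattern`.
#' @export
submotif_catalogue <- function(loop_sizes = 0:6, helix_sizes = 1:4,
                               hairpin_loops = 3:6) {
  il <- tidyr::expand_grid(h = helix_sizes, a = loop_sizes)
  open_str  <- paste0(strrep("(", il$h), strrep(".", il$a), strrep("(", il$h))
  close_str <- paste0(strrep(")", il$h), strrep(".", il$a), strrep(")", il$h))
  hp <- tidyr::expand_grid(h = helix_sizes, a = hairpin_loops)
  hp_str <- paste0(strrep("(", hp$h), strrep(".", hp$a), strrep(")", hp$h))
  out <- bind_rows(
    tibble(id = "J", kind = "internal_loop_open", pattern = "(((....((("),
    tibble(id = "H", kind = "internal_loop_close", pattern = ")))....)))"),
    tibble(id = sprintf("ILo_h%d_a%d", il$h, il$a), kind = "internal_loop_open",
           pattern = open_str),
    tibble(id = sprintf("ILc_h%d_a%d", il$h, il$a), kind = "internal_loop_close",
           pattern = close_str),
    tibble(id = sprintf("HP_h%d_a%d", hp$h, hp$a), kind = "hairpin",
           pattern = hp_str)
  )
  dplyr::distinct(out, .data$pattern, .keep_all = TRUE)
}

#' Match structure submotifs around a ligation junction
#'
#' Finds all catalogue patterns that occur in a dot-bracket structure such
#' that the junction bond (between positions `junction_index` and
#' `junction_index + 1`) lies on an internal bond of the motif, with the
#' motif contained in a `window` around the junction.
#'
#' @param structure a dot-bracket string or [parse_dotbracket()] result.
#' @param junction_index 1-based junction bond index.
#' @param catalogue tibble from [submotif_catalogue()] (columns `id`,
#'   `pattern`).
#' @param window number of nucleotides either side of the junction searched.
#' @return tibble of matches: `motif_id`, `start` (1-based match position),
#'   `junction_bond` (which intra-motif bond, 1..len-1, holds the junction).
#' @export
match_submotifs <- function(structure, junction_index, catalogue, window = 10L) {
  s <- if (inherits(structure, "dotbracket")) structure$structure else structure
  L <- nchar(s)
  if (junction_index < 1 || junction_index >= L) {
    abort("junction_index must be an interior bond")
  }
  if (nrow(catalogue) == 0) {
    return(tibble(motif_id = character(), start = integer(), junction_bond = integer()))
  }
  res <- pmap(list(catalogue$id, catalogue$pattern), function(id, pat) {
    m <- nchar(pat)
    lo <- max(1L, junction_index - m + 2L, junction_index + 1L - window)
    hi <- min(L - m + 1L, junction_index, junction_index + window - m + 1L)
    if (lo > hi) return(NULL)
    starts <- lo:hi
    hit <- substring(s, starts, starts + m - 1L) == pat
    if (!any(hit)) return(NULL)
    tibble(motif_id = id, start = starts[hit],
           junction_bond = junction_index - starts[hit] + 1L)
  })
  bind_rows(res)
}

#' Per-bond ligation-site profile of matched motifs
#'
#' Normalizes junction counts over the internal bonds of each motif and
#' flags bonds whose frequency exceeds `enrichment_threshold` times the
#' motif's unpaired-region baseline (the mean frequency over bonds joining
#' two unpaired positions).
#'
#' @param matches tibble of matches across many products (from
#'   [match_submotifs()], row-bound).
#' @param catalogue the catalogue used for matching.
#' @param enrichment_threshold fold over the unpaired-bond baseline above
#'   which a bond is flagged.
#' @return a `motif_ligation_profile` tibble: `motif_id`, `bond`,
#'   `count`, `freq` (sums to 1 within each motif), `in_loop`, `baseline`,
#'   `enriched`.
#' @export
motif_ligation_profile <- function(matches, catalogue, enrichment_threshold = 2) {
  if (nrow(matches) == 0) abort("no matches to profile")
  pats <- setNames(catalogue$pattern, catalogue$id)
  seen <- unique(matches$motif_id)
  grid <- bind_rows(lapply(seen, function(id) {
    tibble(motif_id = id, bond = seq_len(nchar(pats[[id]]) - 1L))
  }))
  tallies <- matches |>
    count(.data$motif_id, bond = .data$junction_bond, name = "count")
  out <- grid |>
    left_join(tallies, by = c("motif_id", "bond")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    group_by(.data$motif_id) |>
    mutate(freq = .data$count / sum(.data$count)) |>
    ungroup()
  pat_of <- pats[out$motif_id]
  out$in_loop <- substr(pat_of, out$bond, out$bond) == "." &
    substr(pat_of, out$bond + 1L, out$bond + 1L) == "."
  out <- out |>
    group_by(.data$motif_id) |>
    mutate(baseline = ifelse(any(.data$in_loop),
                             mean(.data$freq[.data$in_loop]), NA_real_)) |>
    ungroup() |>
    mutate(enriched = .data$in_loop & !is.na(.data$baseline) & .data$baseline > 0 &
             .data$freq > enrichment_threshold * .data$baseline)
  class(out) <- c("motif_ligation_profile", class(out))
  out
}

#' Position weight matrix and information content of aligned members
#'
#' Builds a pseudocounted PWM from equal-length sequences anchored at a
#' motif match, with per-column information content IC = log2(|alphabet|) -
#' H(column) bits (2 - H for the 4-letter code).
#'
#' @param member_sequences character vector of equal-length sequences.
#' @param pseudocount added to every cell before normalization.
#' @param alphabet alphabet (columns of the PWM).
#' @return a `consensus_matrix` list: `pwm` (positions x alphabet matrix,
#'   rows sum to 1), `ic` (bits per column), `n` (members), `consensus`
#'   (majority-letter string).
#' @export
consensus_matrix <- function(member_sequences, pseudocount = 0.5,
                             alphabet = RNA_ALPHABET) {
  if (length(member_sequences) == 0) abort("no member sequences given")
  check_alphabet(member_sequences, alphabet)
  m <- seq_matrix(member_sequences)
  counts <- vapply(alphabet, function(b) colSums(m == b), numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1, dimnames = list(NULL, alphabet))
  pwm <- (counts + pseudocount) / (length(member_sequences) + pseudocount * length(alphabet))
  h <- apply(pwm, 1, function(p) -sum(p[p > 0] * log2(p[p > 0])))
  ic <- log2(length(alphabet)) - h
  out <- list(pwm = pwm, ic = ic, n = length(member_sequences),
              consensus = paste0(alphabet[apply(pwm, 1, which.max)], collapse = ""))
  class(out) <- "consensus_matrix"
  out
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat(sprintf("<consensus_matrix> %d members, %d positions, consensus %s\n",
              x$n, nrow(x$pwm), x$consensus))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.consensus_matrix <- function(x, ...) {
  as_tibble(x$pwm) |>
    mutate(position = dplyr::row_number(), ic = x$ic) |>
    tidyr::pivot_longer(cols = colnames(x$pwm), names_to = "base",
                        values_to = "prob") |>
    select("position", "base", "prob", "ic")
}

#' Write a PWM in MEME minimal motif format
#'
#' @param x a [consensus_matrix()].
#' @param path output path.
#' @param name motif name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(x, path, name = "motif1") {
  alph <- colnames(x$pwm)
  lines <- c(
    "MEME version 4", "",
    sprintf("ALPHABET= %s", paste(alph, collapse = "")), "",
    sprintf("MOTIF %s", name),
    sprintf("letter-probability matrix: alength= %d w= %d nsites= %d E= 0",
            length(alph), nrow(x$pwm), x$n),
    apply(x$pwm, 1, function(p) paste(sprintf("%.6f", p), collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}
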