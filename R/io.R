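# Read I/O and preprocessing: FASTA/FASTQ via Biostrings, quality filtering,
# duplicate collapsing, anchored adapter trimming, and length splitting.
# Reads are plain tibbles (id, seq, qual) so every step chains with the pipe.

#' Read a FASTA file into a tibble of reads
#'
#' @param path path to a FASTA file.
#' @param normalize one of `"none"`, `"rna"` (T -> U) or `"dna"` (U -> T).
#'   Sequences are always upper-cased.
#' @return a tibble with columns `id`, `seq` and `qual` (all `NA` for FASTA).
#' @export
read_fasta <- function(path, normalize = c("none", "rna", "dna")) {
  normalize <- match.arg(normalize)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) abort(sprintf("malformed FASTA in %s: %s", path, conditionMessage(e)))
  )
  tibble(
    id   = names(set) %||% as.character(seq_along(set)),
    seq  = normalize_seq(unname(as.character(set)), normalize),
    qual = NA_character_
  )
}

#' Read a FASTQ file (Phred+33) into a tibble of reads
#'
#' Only Phred+33 encoding is supported (modern Illumina output).
#'
#' @inheritParams read_fasta
#' @return a tibble with columns `id`, `seq`, `qual` (Phred+33 strings).
#' @export
read_fastq <- function(path, normalize = c("none", "rna", "dna")) {
  normalize <- match.arg(normalize)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  validate_fastq_lines(path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) abort(sprintf("malformed FASTQ in %s: %s", path, conditionMessage(e)))
  )
  qual <- as.character(S4Vectors::mcols(set)$qualities)
  out <- tibble(
    id   = names(set) %||% as.character(seq_along(set)),
    seq  = normalize_seq(unname(as.character(set)), normalize),
    qual = qual
  )
  bad <- which(nchar(out$qual) != nchar(out$seq))
  if (length(bad) > 0) {
    abort(sprintf("FASTQ record %d (line %d of %s): quality length %d != sequence length %d",
                  bad[1], (bad[1] - 1L) * 4L + 4L, path,
                  nchar(out$qual[bad[1]]), nchar(out$seq[bad[1]])))
  }
  out
}

# structural pre-check so malformed records fail with a line number rather
# than an opaque parser error
validate_fastq_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) > length(lines) - 1 & lines == "")]
  if (length(lines) %% 4 != 0) {
    abort(sprintf("truncated FASTQ %s: %d lines is not a multiple of 4", path, length(lines)))
  }
  heads <- lines[seq(1, length(lines), by = 4)]
  plus  <- lines[seq(3, length(lines), by = 4)]
  bad_h <- which(!startsWith(heads, "@"))
  if (length(bad_h) > 0) {
    abort(sprintf("malformed FASTQ %s: line %d does not start with '@'", path, (bad_h[1] - 1L) * 4L + 1L))
  }
  bad_p <- which(!startsWith(plus, "+"))
  if (length(bad_p) > 0) {
    abort(sprintf("malformed FASTQ %s: line %d does not start with '+'", path, (bad_p[1] - 1L) * 4L + 3L))
  }
  seq_len_ok <- nchar(lines[seq(2, length(lines), by = 4)]) ==
    nchar(lines[seq(4, length(lines), by = 4)])
  if (!all(seq_len_ok)) {
    rec <- which(!seq_len_ok)[1]
    abort(sprintf("FASTQ record %d (line %d of %s): quality length != sequence length",
                  rec, (rec - 1L) * 4L + 4L, path))
  }
  invisible(TRUE)
}

normalize_seq <- function(seqs, normalize) {
  seqs <- toupper(seqs)
  switch(normalize,
    none = seqs,
    rna  = chartr("T", "U", seqs),
    dna  = chartr("U", "T", seqs)
  )
}

#' Write reads or collapsed records to FASTA
#'
#' @param records tibble with `seq` and optionally `id` / `count` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  ids <- record_ids(records)
  set <- Biostrings::BStringSet(setNames(records$seq, ids))
  Biostrings::writeXStringSet(set, path, format = "fasta", width = 20000L)
  invisible(path)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads tibble with `id`, `seq`, `qual` columns; `qual` must be present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (any(is.na(reads$qual))) abort("cannot write FASTQ: some reads have no quality string")
  lines <- as.vector(rbind(paste0("@", record_ids(reads)), reads$seq, "+", reads$qual))
  writeLines(lines, path)
  invisible(path)
}

record_ids <- function(records) {
  if (!is.null(records[["id"]]) && !anyNA(records[["id"]])) return(records[["id"]])
  paste0("rec", seq_len(nrow(records)))
}

#' Filter reads by the fraction of high-quality bases
#'
#' Keeps a read iff the fraction of bases with Phred quality at least
#' `min_q` is at least `min_fraction` (a ">=" comparison at the boundary, so
#' 9/10 bases at Q >= 20 passes the 90% / Q20 filter).
#'
#' @param reads tibble of reads with a `qual` column (Phred+33 strings).
#' @param min_q minimum per-base Phred score counted as high quality.
#' @param min_fraction minimum fraction of high-quality bases, in \[0, 1\].
#' @return the surviving subset of `reads`.
#' @export
quality_filter <- function(reads, min_q = 20L, min_fraction = 0.9) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  if (nrow(reads) == 0) return(reads)
  if (is.null(reads[["qual"]]) || anyNA(reads$qual)) {
    abort("quality_filter is undefined for reads without quality scores")
  }
  frac <- vapply(phred_decode(reads$qual),
                 function(q) mean(q >= min_q), numeric(1))
  reads[frac >= min_fraction, , drop = FALSE]
}

#' Collapse reads into unique sequences with copy counts
#'
#' @param reads tibble with a `seq` column.
#' @return tibble with columns `seq` and `count`, ordered by descending
#'   count, then lexicographically by sequence. Counts sum to `nrow(reads)`.
#' @export
collapse_reads <- function(reads) {
  if (nrow(reads) == 0) return(tibble(seq = character(), count = integer()))
  reads |>
    count(.data$seq, name = "count") |>
    arrange(desc(.data$count), .data$seq)
}

#' Trim constant flanking sequences from read termini
#'
#' Terminus-anchored trimming: a 5' (3') adapter is removed iff the read
#' starts (ends) with it within `max_mismatch` Hamming substitutions. No
#' indels are considered, matching fixed-length constant regions.
#'
#' @param reads tibble of reads.
#' @param adapter5,adapter3 adapter sequences (`NULL` to skip a side).
#' @param max_mismatch maximum Hamming distance tolerated (default 0).
#' @return `reads` with trimmed `seq`/`qual` and logical columns
#'   `trimmed5`, `trimmed3`.
#' @export
trim_constant <- function(reads, adapter5 = NULL, adapter3 = NULL, max_mismatch = 0L) {
  stopifnot(max_mismatch >= 0)
  out <- reads
  out$trimmed5 <- FALSE
  out$trimmed3 <- FALSE
  if (nrow(out) == 0) return(out)
  if (!is.null(adapter5)) {
    k <- nchar(adapter5)
    pre <- substr(out$seq, 1L, k)
    hit <- nchar(out$seq) >= k & hamming_to(pre, adapter5) <= max_mismatch
    out$seq[hit] <- substr(out$seq[hit], k + 1L, nchar(out$seq[hit]))
    has_q <- hit & !is.na(out$qual)
    out$qual[has_q] <- substr(out$qual[has_q], k + 1L, nchar(out$qual[has_q]))
    out$trimmed5 <- hit
  }
  if (!is.null(adapter3)) {
    k <- nchar(adapter3)
    len <- nchar(out$seq)
    suf <- substr(out$seq, len - k + 1L, len)
    hit <- len >= k & hamming_to(suf, adapter3) <= max_mismatch
    out$seq[hit] <- substr(out$seq[hit], 1L, nchar(out$seq[hit]) - k)
    has_q <- hit & !is.na(out$qual)
    out$qual[has_q] <- substr(out$qual[has_q], 1L, nchar(out$qual[has_q]) - k)
    out$trimmed3 <- hit
  }
  out
}

# Hamming distance between each string in x (same length as ref or shorter)
# and a single reference; unequal lengths count as Inf
hamming_to <- function(x, ref) {
  ref_int <- utf8ToInt(ref)
  vapply(x, function(s) {
    if (is.na(s) || nchar(s) != length(ref_int)) return(Inf)
    sum(utf8ToInt(s) != ref_int)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Split records into same-length buckets with a length histogram
#'
#' @param records tibble with `seq` (and optionally `count`) columns.
#' @return a nested tibble with one row per observed length: `length`,
#'   `n_records` (distinct records), `n_molecules` (count-weighted), and a
#'   `data` list-column holding each bucket. Buckets partition the input.
#' @export
split_by_length <- function(records) {
  if (nrow(records) == 0) {
    return(tibble(length = integer(), n_records = integer(),
                  n_molecules = integer(), data = list()))
  }
  cnt <- if (is.null(records[["count"]])) rep(1L, nrow(records)) else records[["count"]]
  records |>
    mutate(length = nchar(.data$seq), .count = cnt) |>
    tidyr::nest(data = -"length") |>
    mutate(
      n_records   = map_int(.data$data, nrow),
      n_molecules = map_int(.data$data, ~ sum(.x$.count)),
      data        = map(.data$data, ~ select(.x, -".count"))
    ) |>
    arrange(.data$length) |>
    select("length", "n_records", "n_molecules", "data")
}
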