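# shared helpers: alphabets, Phred codecs, seed splitting

RNA_ALPHABET <- c("A", "C", "G", "U")
DNA_ALPHABET <- c("A", "C", "G", "T")

#' Decode a Phred+33 quality string to integer scores
#'
#' @param qual character vector of Phred+33 encoded quality strings.
#' @return list of integer vectors, one per input string.
#' @export
phred_decode <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q)) return(NA_integer_)
    utf8ToInt(q) - 33L
  })
}

#' Encode integer Phred scores as a Phred+33 string
#'
#' @param scores integer vector of Phred scores (0-93).
#' @return single character string.
#' @export
phred_encode <- function(scores) {
  stopifnot(all(scores >= 0), all(scores <= 93))
  intToUtf8(as.integer(scores) + 33L)
}

# Deterministic per-stage seed derivation from one master seed. Stages are
# named so adding a stage never perturbs another stage's stream. Kept below
# 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(master_seed, stage, index = 0L) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  val <- (as.double(master_seed) * 48271 + h * 1299721 + as.double(index) * 69427) %%
    2147483629
  as.integer(val)
}

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- NULL
  } else {
    old <- get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# split vector of sequences into a character matrix (rows = seqs); all equal length
seq_matrix <- function(seqs) {
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L) {
    abort("sequences have mixed lengths; use split_by_length() first")
  }
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = lens, byrow = TRUE)
}

# default to the full nucleotide alphabet when the observed letters are a
# subset (a pure-C pool is still a 4-letter pool)
infer_alphabet <- function(letters_seen) {
  if (all(letters_seen %in% RNA_ALPHABET)) return(RNA_ALPHABET)
  if (all(letters_seen %in% DNA_ALPHABET)) return(DNA_ALPHABET)
  sort(letters_seen)
}

check_alphabet <- function(seqs, alphabet) {
  ok <- grepl(paste0("^[", paste(alphabet, collapse = ""), "]*$"), seqs)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    abort(sprintf("sequence %d contains characters outside alphabet {%s}",
                  bad, paste(alphabet, collapse = ",")))
  }
  invisible(TRUE)
}
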