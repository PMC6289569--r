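# Dot-bracket handling, an exact base-pair-maximization folder (internal
# oracle), an adapter for an external MFE folding backend, and per-position
# structure element profiles.

#' Parse a dot-bracket string into a pair map
#'
#' @param s string over `(`, `)`, `.` (nested structures only).
#' @param energy optional energy annotation to carry along.
#' @return a `dotbracket` list: `structure`, `pairs` (integer vector,
#'   1-based partner index or `NA` when unpaired) and `energy`.
#' @export
parse_dotbracket <- function(s, energy = NA_real_) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad) > 0) {
    abort(sprintf("invalid dot-bracket character '%s' at position %d", chars[bad[1]], bad[1]))
  }
  pairs <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0) {
        abort(sprintf("unbalanced dot-bracket: unmatched ')' at position %d", i))
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[j] <- i
      pairs[i] <- j
    }
  }
  if (length(stack) > 0) {
    abort(sprintf("unbalanced dot-bracket: '(' at position %d never closed (end of string reached)",
                  stack[1]))
  }
  structure(list(structure = s, pairs = pairs, energy = energy),
            class = "dotbracket")
}

#' Number of base pairs in a dot-bracket structure
#'
#' @param x a `dotbracket` or dot-bracket string.
#' @return integer pair count.
#' @export
pair_count <- function(x) {
  s <- if (inherits(x, "dotbracket")) x$structure else x
  sum(strsplit(s, "", fixed = TRUE)[[1]] == "(")
}

default_pair_set <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Fold a sequence by exact base-pair maximization (Nussinov)
#'
#' Dynamic-programming maximization of the number of nested base pairs
#' subject to a minimum hairpin loop. This is a deterministic internal
#' folder used as an oracle and an energy-free proxy; it does not model
#' nearest-neighbour thermodynamics. Traceback tie-break: position i pairs
#' with the smallest admissible j, and pairing is preferred over leaving i
#' unpaired when both attain the optimum.
#'
#' @param seq RNA sequence (A/C/G/U; T is treated as U).
#' @param min_loop minimum number of unpaired bases in a hairpin loop.
#' @param pairs allowed pair set as 2-character strings (default canonical
#'   Watson-Crick plus GU wobble).
#' @return a `dotbracket` with `energy` set to `-pair_count` (proxy).
#' @export
nussinov_fold <- function(seq, min_loop = 3L, pairs = default_pair_set) {
  s <- chartr("T", "U", toupper(seq))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  can_pair <- function(i, j) paste0(chars[i], chars[j]) %in% pairs
  if (n == 0) return(parse_dotbracket(""))
  M <- matrix(0L, n, n)
  for (len in (min_loop + 2L):n) {
    if (len > n) break
    for (i in 1L:(n - len + 1L)) {
      j <- i + len - 1L
      best <- M[i + 1L, j]
      for (k in (i + min_loop + 1L):j) {
        if (can_pair(i, k)) {
          inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
          outer <- if (k + 1L <= j) M[k + 1L, j] else 0L
          cand <- 1L + inner + outer
          if (cand > best) best <- cand
        }
      }
      M[i, j] <- best
    }
  }
  db <- rep(".", n)
  trace <- function(i, j) {
    while (i < j) {
      if (j - i <= min_loop) return(invisible())
      paired <- FALSE
      for (k in (i + min_loop + 1L):j) {
        if (can_pair(i, k)) {
          inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
          outer <- if (k + 1L <= j) M[k + 1L, j] else 0L
          if (1L + inner + outer == M[i, j]) {
            db[i] <<- "("; db[k] <<- ")"
            if (k + 1L <= j) trace(k + 1L, j)
            i <- i + 1L; j <- k - 1L
            paired <- TRUE
            break
          }
        }
      }
      if (!paired) i <- i + 1L
    }
    invisible()
  }
  if (n >= 2) trace(1L, n)
  out <- parse_dotbracket(paste0(db, collapse = ""))
  out$energy <- -pair_count(out)
  out
}

#' Fold sequences with an external MFE backend
#'
#' Runs an external folding program (e.g. `RNAfold`) through a command
#' template and parses its plain-text output (sequence line followed by a
#' dot-bracket line with a trailing `(energy)` annotation). If no backend
#' is configured, a capability error is raised; all downstream profile
#' operations equally accept precomputed dot-bracket files read with
#' [read_dotbracket()].
#'
#' @param seqs character vector of sequences.
#' @param backend_command command line to run, e.g. `"RNAfold --noPS"`.
#' @return tibble with `seq`, `structure`, `energy`.
#' @export
external_fold <- function(seqs, backend_command = NULL) {
  if (is.null(backend_command) || !nzchar(backend_command)) {
    abort(paste("no external folding backend configured;",
                "set `backend_command` (e.g. \"RNAfold --noPS\")",
                "or supply precomputed structures via read_dotbracket()"))
  }
  parts <- strsplit(backend_command, "[[:space:]]+")[[1]]
  exe <- parts[1]
  if (Sys.which(exe) == "" && !file.exists(exe)) {
    abort(sprintf("external folding backend '%s' not found on PATH (config key: backend_command)", exe))
  }
  out <- suppressWarnings(
    system2(exe, args = parts[-1], input = seqs, stdout = TRUE, stderr = TRUE)
  )
  status <- attr(out, "status") %||% 0L
  if (status != 0) {
    abort(sprintf("backend '%s' exited with status %d: %s",
                  backend_command, status, paste(out, collapse = " | ")))
  }
  struct_re <- "^([().]+)(\\s+\\(\\s*(-?[0-9.]+)\\s*\\))?\\s*$"
  hits <- grepl(struct_re, out) & nzchar(out)
  structs <- out[hits]
  if (length(structs) < length(seqs)) {
    abort(sprintf("backend output unparseable: expected %d structures, found %d (output: %s)",
                  length(seqs), length(structs), paste(head(out, 5), collapse = " | ")))
  }
  structs <- structs[seq_along(seqs)]
  m <- regmatches(structs, regexec(struct_re, structs))
  tibble(
    seq = seqs,
    structure = map_chr(m, 2),
    energy = map_dbl(m, ~ ifelse(nzchar(.x[4]), as.numeric(.x[4]), NA_real_))
  )
}

#' Read a plain-text dot-bracket file
#'
#' Expects records of a sequence line followed by a structure line with an
#' optional trailing `(energy)` (the common RNAfold text output layout).
#'
#' @param path file path.
#' @return tibble with `seq`, `structure`, `energy`.
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, ">")]
  if (length(lines) %% 2 != 0) abort(sprintf("odd number of content lines in %s", path))
  seqs <- lines[seq(1, length(lines), by = 2)]
  st <- lines[seq(2, length(lines), by = 2)]
  struct_re <- "^([().]+)(\\s+\\(\\s*(-?[0-9.]+)\\s*\\))?\\s*$"
  m <- regmatches(st, regexec(struct_re, st))
  bad <- which(vapply(m, length, integer(1)) == 0)
  if (length(bad) > 0) abort(sprintf("unparseable structure line %d in %s", bad[1] * 2L, path))
  tibble(
    seq = seqs,
    structure = map_chr(m, 2),
    energy = map_dbl(m, ~ ifelse(nzchar(.x[4]), as.numeric(.x[4]), NA_real_))
  )
}

#' Per-position structure element frequencies
#'
#' Frequencies of opening pairs (`obp`, "("), closing pairs (`cbp`, ")")
#' and unpaired bases (`unp`, ".") at every position of a set of
#' equal-length dot-bracket structures.
#'
#' @param structures character vector of dot-bracket strings (or a tibble
#'   with a `structure` column).
#' @return a `structure_profile` tibble: `position`, `obp`, `cbp`, `unp`
#'   (rows sum to 1).
#' @export
structure_profile <- function(structures) {
  st <- if (is.character(structures)) structures else structures$structure
  if (length(st) == 0) abort("no structures given")
  if (length(unique(nchar(st))) != 1L) abort("structures have mixed lengths")
  m <- matrix(unlist(strsplit(st, "", fixed = TRUE), use.names = FALSE),
              nrow = length(st), byrow = TRUE)
  out <- tibble(
    position = seq_len(ncol(m)),
    obp = colMeans(m == "("),
    cbp = colMeans(m == ")"),
    unp = colMeans(m == ".")
  )
  class(out) <- c("structure_profile", class(out))
  out
}

#' Compare an experimental structure profile against synthetic replicates
#'
#' @param experimental a [structure_profile()].
#' @param synthetic_replicates list of [structure_profile()]s (>= 1) from
#'   matched synthetic pools.
#' @return tibble with `position`, `element`, `experimental`,
#'   `synthetic_mean`, `difference` (experimental - mean synthetic) and
#'   `sd` (across replicates).
#' @export
compare_structure_profiles <- function(experimental, synthetic_replicates) {
  if (inherits(synthetic_replicates, "structure_profile")) {
    synthetic_replicates <- list(synthetic_replicates)
  }
  stopifnot(length(synthetic_replicates) >= 1)
  same_len <- vapply(synthetic_replicates, nrow, integer(1)) == nrow(experimental)
  if (!all(same_len)) abort("synthetic replicate profile length does not match the experimental profile")
  long <- function(p, id) {
    tidyr::pivot_longer(as_tibble(p), c("obp", "cbp", "unp"),
                        names_to = "element", values_to = "freq") |>
      mutate(rep = id)
  }
  synth <- bind_rows(imap(synthetic_replicates, ~ long(.x, .y))) |>
    group_by(.data$position, .data$element) |>
    summarise(synthetic_mean = mean(.data$freq), sd = sd(.data$freq), .groups = "drop")
  synth$sd[is.na(synth$sd)] <- 0
  long(experimental, 0) |>
    select("position", "element", experimental = "freq") |>
    left_join(synth, by = c("position", "element")) |>
    mutate(difference = .data$experimental - .data$synthetic_mean) |>
    select("position", "element", "experimental", "synthetic_mean", "difference", "sd")
}

#' Summarise a distribution of MFE energies (or pair-count proxies)
#'
#' @param x numeric vector of energies, or a named list of numeric vectors
#'   to summarise side by side (e.g. experimental vs matched pools).
#' @param binwidth histogram bin width (default 1 energy unit).
#' @return tibble with `set`, `n`, `mean`, `sd`, `median` and a `histogram`
#'   list-column of (`bin`, `count`) tibbles.
#' @export
mfe_distribution <- function(x, binwidth = 1) {
  sets <- if (is.numeric(x)) list(energies = x) else x
  stopifnot(length(sets) >= 1, all(vapply(sets, is.numeric, logical(1))))
  imap(sets, function(v, nm) {
    bins <- floor(v / binwidth) * binwidth
    tb <- table(bins)
    tibble(
      set = as.character(nm), n = length(v), mean = mean(v), sd = sd(v),
      median = median(v),
      histogram = list(tibble(bin = as.numeric(names(tb)), count = as.integer(tb)))
    )
  }) |> bind_rows()
}
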