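# Synthetic pools and ligation/recombination products with truth labels.
# The generator emulates the experimental design: semi-random oligomers with
# a random core (default an eicosamer, N20), optional constant flanks
# (primer binding sites C1/C2), optional homopolymer tails (A10), and
# bait-prey concatenation products with a tunable junction dinucleotide bias
# and a bait 3'-truncation ladder.

#' Specify a (semi-)random oligonucleotide pool
#'
#' @param length length of the random core in nucleotides (default 20, the
#'   eicosamer used throughout).
#' @param alphabet ordered character vector; 4-letter RNA by default, use a
#'   2-letter subset for reduced code complexity.
#' @param n_unique number of distinct random cores.
#' @param redundancy copies per unique sequence.
#' @param constant5,constant3 optional fixed flanking sequences.
#' @param tail optional homopolymer tail, e.g. `list(base = "A", length = 10)`.
#' @param blocked5 logical; a 5'-blocked pool (e.g. 5'-FAM labelled) cannot
#'   act as the prey (downstream) segment of a product.
#' @return a `pool_spec` object.
#' @export
pool_spec <- function(length = 20L, alphabet = RNA_ALPHABET, n_unique = 1000L,
                      redundancy = 100L, constant5 = NULL, constant3 = NULL,
                      tail = NULL, blocked5 = FALSE) {
  stopifnot(length >= 1, n_unique >= 1, redundancy >= 1, length(alphabet) >= 2)
  if (log(n_unique) > length * log(base::length(alphabet))) {
    abort("n_unique exceeds the sequence space |alphabet|^length")
  }
  if (!is.null(tail)) stopifnot(is.list(tail), !is.null(tail$base), tail$length >= 1)
  structure(
    list(length = as.integer(length), alphabet = alphabet,
         n_unique = as.integer(n_unique), redundancy = as.integer(redundancy),
         constant5 = constant5, constant3 = constant3, tail = tail,
         blocked5 = isTRUE(blocked5)),
    class = "pool_spec"
  )
}

#' Generate a sequence pool from a specification
#'
#' Samples `n_unique` distinct random cores uniformly without replacement,
#' each present at `redundancy` copies, then appends flanks/tails verbatim.
#'
#' @param spec a [pool_spec()].
#' @param seed integer seed; the same seed reproduces the same pool.
#' @return a tibble (`sequence_pool`) with columns `id`, `core`, `seq`,
#'   `count`. Total molecules = `n_unique * redundancy`.
#' @export
make_pool <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "pool_spec"))
  with_seed(seed, {
    cores <- character(0)
    while (length(cores) < spec$n_unique) {
      need <- spec$n_unique - length(cores)
      m <- matrix(sample(spec$alphabet, need * spec$length, replace = TRUE),
                  nrow = need)
      cores <- unique(c(cores, apply(m, 1, paste0, collapse = "")))
    }
    cores <- cores[seq_len(spec$n_unique)]
  })
  tail_str <- if (is.null(spec$tail)) "" else
    strrep(spec$tail$base, spec$tail$length)
  seqs <- paste0(spec$constant5 %||% "", cores, spec$constant3 %||% "", tail_str)
  out <- tibble(
    id    = sprintf("u%06d", seq_along(cores)),
    core  = cores,
    seq   = seqs,
    count = rep(spec$redundancy, length(cores))
  )
  attr(out, "pool_spec") <- spec
  class(out) <- c("sequence_pool", class(out))
  out
}

#' Specify how synthetic ligation/recombination products are formed
#'
#' Products are (possibly 3'-truncated) bait prefixes joined to full-length
#' prey. The junction dinucleotide (N-1, N+1) is biased by reweighting the
#' candidate truncation points of each bait; the prey 5' base is fixed, so
#' the bias acts through the bait cut base.
#'
#' @param junction_bias named numeric weights over junction dinucleotides.
#'   Names are 2-character strings; `"N"` is a wildcard (e.g.
#'   `c(CN = 8)` enriches any C|N junction 8-fold over baseline 1).
#' @param truncation_dist distribution over bait 3'-truncation lengths:
#'   `list(family = "geometric", prob = p)` (default, matching progressive
#'   truncation ladders) or `list(family = "fixed", value = t)`.
#' @param product_mix named proportions over classes `"B-P"`, `"P-P"`,
#'   `"B-B"`; must sum to 1.
#' @param n_products number of products to generate.
#' @return a `product_spec` object.
#' @export
product_spec <- function(junction_bias = NULL,
                         truncation_dist = list(family = "geometric", prob = 0.25),
                         product_mix = c("B-P" = 1),
                         n_products = 1000L) {
  if (!is.null(junction_bias)) {
    stopifnot(all(junction_bias >= 0), any(junction_bias > 0),
              all(nchar(names(junction_bias)) == 2L))
  }
  stopifnot(abs(sum(product_mix) - 1) < 1e-9,
            all(names(product_mix) %in% c("B-P", "P-P", "B-B")),
            n_products >= 1)
  stopifnot(truncation_dist$family %in% c("geometric", "fixed"))
  structure(
    list(junction_bias = junction_bias, truncation_dist = truncation_dist,
         product_mix = product_mix, n_products = as.integer(n_products)),
    class = "product_spec"
  )
}

# expand wildcard dinucleotide weights to a full 16-entry lookup over alphabet
expand_junction_bias <- function(bias, alphabet) {
  all_din <- as.vector(outer(alphabet, alphabet, paste0))
  w <- setNames(rep(1, length(all_din)), all_din)
  if (is.null(bias)) return(w)
  for (nm in names(bias)) {
    a <- substr(nm, 1, 1); b <- substr(nm, 2, 2)
    aa <- if (a == "N") alphabet else a
    bb <- if (b == "N") alphabet else b
    for (x in aa) for (y in bb) w[paste0(x, y)] <- bias[[nm]]
  }
  w
}

#' Generate bait-prey concatenation products with truth labels
#'
#' @param bait_pool,prey_pool `sequence_pool` tibbles from [make_pool()].
#' @param spec a [product_spec()].
#' @param seed integer seed.
#' @return tibble of products: `product_id`, `seq`, `class`, `bait_id`,
#'   `prey_id`, `truncation` (nt removed from the bait 3' end) and
#'   `junction` (1-based bond index: the junction lies between positions
#'   `junction` and `junction + 1`). Prey segment length is always preserved.
#' @export
make_products <- function(bait_pool, prey_pool, spec, seed = 1L) {
  stopifnot(inherits(spec, "product_spec"), nrow(bait_pool) > 0, nrow(prey_pool) > 0)
  bait_spec <- attr(bait_pool, "pool_spec")
  prey_spec <- attr(prey_pool, "pool_spec")
  # the downstream (second) segment of each class acts as prey and needs a
  # free 5' end
  downstream_pool <- c("B-P" = "prey", "P-P" = "prey", "B-B" = "bait")
  for (cls in names(spec$product_mix)) {
    if (spec$product_mix[[cls]] <= 0) next
    blocked <- if (downstream_pool[[cls]] == "prey") isTRUE(prey_spec$blocked5)
               else isTRUE(bait_spec$blocked5)
    if (blocked) {
      abort(sprintf("class %s requires a free 5' end on its downstream segment, but that pool is 5'-blocked", cls))
    }
  }
  alphabet <- bait_spec$alphabet %||% RNA_ALPHABET
  w_lookup <- expand_junction_bias(spec$junction_bias, alphabet)
  n <- spec$n_products

  with_seed(seed, {
    classes <- sample(names(spec$product_mix), n, replace = TRUE,
                      prob = spec$product_mix)
    up_pool_of   <- c("B-P" = "bait", "P-P" = "prey", "B-B" = "bait")
    pools <- list(bait = bait_pool, prey = prey_pool)
    specs <- list(bait = bait_spec, prey = prey_spec)
    up_idx <- integer(n); down_idx <- integer(n); trunc <- integer(n)
    for (p in c("bait", "prey")) {
      sel_d <- downstream_pool[classes] == p
      if (any(sel_d)) down_idx[sel_d] <- sample.int(nrow(pools[[p]]), sum(sel_d),
                                                    replace = TRUE, prob = pools[[p]]$count)
    }
    down_seq <- ifelse(downstream_pool[classes] == "bait",
                       bait_pool$seq[down_idx], prey_pool$seq[down_idx])
    down_base <- substr(down_seq, 1L, 1L)

    # The upstream molecule and its 3'-truncation are drawn jointly: over all
    # (molecule, truncation) candidates, weight = copy count x truncation
    # prior x junction-dinucleotide bias. Pool-wide, cut bases are near
    # uniform, so the realized junction dinucleotide frequencies converge to
    # the bias weights as the pool grows.
    for (p in c("bait", "prey")) {
      sel <- which(up_pool_of[classes] == p)
      if (length(sel) == 0) next
      up_pool <- pools[[p]]
      L <- nchar(up_pool$seq[1])
      tmax <- min(specs[[p]]$length, L - 1L)
      ts <- 0:tmax
      prior <- switch(spec$truncation_dist$family,
        geometric = stats::dgeom(ts, prob = spec$truncation_dist$prob),
        fixed     = as.numeric(ts == spec$truncation_dist$value)
      )
      # cut_base[i, t+1] = last base retained when molecule i loses t nt
      cut_base <- vapply(ts, function(t) substr(up_pool$seq, L - t, L - t),
                         character(nrow(up_pool)))
      if (nrow(up_pool) == 1L) cut_base <- matrix(cut_base, nrow = 1)
      base_w <- outer(as.numeric(up_pool$count), prior)
      for (b in unique(down_base[sel])) {
        idx <- sel[down_base[sel] == b]
        wt <- base_w * matrix(w_lookup[paste0(cut_base, b)], nrow = nrow(up_pool))
        if (sum(wt) <= 0) {
          abort("no candidate truncation point satisfies the junction bias support")
        }
        draw <- sample.int(length(wt), length(idx), replace = TRUE,
                           prob = as.vector(wt))
        up_idx[idx] <- (draw - 1L) %% nrow(up_pool) + 1L
        trunc[idx] <- ts[(draw - 1L) %/% nrow(up_pool) + 1L]
      }
    }
    up_seq <- ifelse(up_pool_of[classes] == "bait",
                     bait_pool$seq[up_idx], prey_pool$seq[up_idx])
  })
  up_trunc <- substr(up_seq, 1L, nchar(up_seq) - trunc)
  out <- tibble(
    product_id = sprintf("p%06d", seq_len(n)),
    seq        = paste0(up_trunc, down_seq),
    class      = classes,
    bait_id    = ifelse(up_pool_of[classes] == "bait",
                        bait_pool$id[up_idx], prey_pool$id[up_idx]),
    prey_id    = ifelse(downstream_pool[classes] == "bait",
                        bait_pool$id[down_idx], prey_pool$id[down_idx]),
    truncation = trunc,
    junction   = nchar(up_trunc)
  )
  attr(out, "product_spec") <- spec
  class(out) <- c("product_set", class(out))
  out
}

#' Specify a sequencing error/quality profile
#'
#' @param sub_rate per-base substitution rate in \[0, 1\].
#' @param quality Phred score assigned to ordinary bases.
#' @param tail_frac fraction of reads receiving an injected low-quality 3'
#'   tail (for exercising quality filters).
#' @param tail_len length of the injected tail in nt.
#' @param tail_quality Phred score inside the injected tail.
#' @return an `error_profile` object.
#' @export
error_profile <- function(sub_rate = 0, quality = 40L, tail_frac = 0,
                          tail_len = 0L, tail_quality = 2L) {
  stopifnot(sub_rate >= 0, sub_rate <= 1, tail_frac >= 0, tail_frac <= 1)
  structure(list(sub_rate = sub_rate, quality = as.integer(quality),
                 tail_frac = tail_frac, tail_len = as.integer(tail_len),
                 tail_quality = as.integer(tail_quality)),
            class = "error_profile")
}

#' Attach sequencing errors and quality strings to products
#'
#' @param products tibble with `seq` (e.g. from [make_products()]).
#' @param profile an [error_profile()].
#' @param seed integer seed.
#' @param alphabet alphabet for substitution sampling.
#' @return FASTQ-ready tibble: `id`, `seq`, `qual`, plus truth columns
#'   `n_errors` (injected substitutions) and `low_tail` (whether a
#'   low-quality tail was injected).
#' @export
attach_quality <- function(products, profile = error_profile(), seed = 1L,
                           alphabet = RNA_ALPHABET) {
  stopifnot(inherits(profile, "error_profile"))
  n <- nrow(products)
  ids <- products[["product_id"]] %||% products[["id"]] %||% sprintf("r%06d", seq_len(n))
  with_seed(seed, {
    seqs <- products$seq
    n_err <- integer(n)
    if (profile$sub_rate > 0) {
      for (i in seq_len(n)) {
        chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        hit <- which(runif(length(chars)) < profile$sub_rate)
        for (j in hit) {
          chars[j] <- sample(setdiff(alphabet, chars[j]), 1L)
        }
        n_err[i] <- length(hit)
        if (length(hit) > 0) seqs[i] <- paste0(chars, collapse = "")
      }
    }
    low_tail <- runif(n) < profile$tail_frac
    qual <- vapply(seq_len(n), function(i) {
      L <- nchar(seqs[i])
      q <- rep(profile$quality, L)
      if (low_tail[i] && profile$tail_len > 0) {
        k <- min(profile$tail_len, L)
        q[(L - k + 1L):L] <- profile$tail_quality
      }
      phred_encode(q)
    }, character(1))
  })
  tibble(id = ids, seq = seqs, qual = qual, n_errors = n_err, low_tail = low_tail)
}
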