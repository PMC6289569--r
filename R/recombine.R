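# Population-level recombination simulator: stochastic mid-point hydrolysis
# followed by size-weighted random ligation, with Shannon-diversity
# accounting before and after (delta-D landscapes over rate grids).

#' Shannon diversity index of a sequence population (bits)
#'
#' D = -sum_i n_i log2(n_i) where n_i is the proportion of molecules
#' belonging to the i-th unique sequence. D is 0 when all molecules are
#' identical and log2(N) when N unique sequences are uniformly represented.
#'
#' @param pool either a tibble with `seq` and (optionally) `count` columns,
#'   a character vector of molecules, or a bare numeric vector of counts.
#' @return diversity in bits.
#' @export
shannon_index <- function(pool) {
  counts <- pool_counts(pool)
  if (length(counts) == 0 || sum(counts) == 0) abort("shannon_index of an empty pool is undefined")
  p <- counts / sum(counts)
  # "+ 0" normalizes IEEE negative zero for the monomorphic case
  -sum(p * log2(p)) + 0
}

pool_counts <- function(pool) {
  if (is.numeric(pool)) return(pool[pool > 0])
  if (is.character(pool)) {
    # hash-based counting; much faster than table() on large pools
    return(tabulate(match(pool, unique(pool))))
  }
  if (is.data.frame(pool)) {
    if (!is.null(pool[["count"]])) {
      agg <- rowsum(as.numeric(pool[["count"]]), group = pool$seq)
      return(as.numeric(agg))
    }
    return(tabulate(match(pool$seq, unique(pool$seq))))
  }
  abort("pool must be a counts vector, character vector, or tibble with seq/count")
}

#' Expand a counted pool tibble into one element per molecule
#'
#' @param pool tibble with `seq`/`count` columns, or a character vector
#'   (returned unchanged).
#' @return character vector with each sequence repeated `count` times.
#' @export
expand_pool <- function(pool) {
  if (is.character(pool)) return(pool)
  cnt <- if (is.null(pool[["count"]])) rep(1L, nrow(pool)) else pool[["count"]]
  rep(pool$seq, times = cnt)
}

#' Simulation parameters for one recombination round
#'
#' @param hydrolysis_rate probability in \[0, 1\] that a molecule is cleaved.
#' @param ligation_rate probability in \[0, 1\] that an eligible fragment
#'   initiates a ligation.
#' @param sigma standard deviation (nt) of the normal breakpoint
#'   distribution centred on the molecule midpoint. `NULL` (default) uses
#'   L/6 per molecule, keeping ~95% of breakpoints well inside the strand.
#' @param min_ligatable_length fragments shorter than this cannot ligate
#'   (default 3: only fragments longer than two nucleotides react).
#' @return a `sim_params` object.
#' @export
sim_params <- function(hydrolysis_rate, ligation_rate, sigma = NULL,
                       min_ligatable_length = 3L) {
  stopifnot(hydrolysis_rate >= 0, hydrolysis_rate <= 1,
            ligation_rate >= 0, ligation_rate <= 1,
            is.null(sigma) || sigma > 0, min_ligatable_length >= 3)
  structure(list(hydrolysis_rate = hydrolysis_rate,
                 ligation_rate = ligation_rate, sigma = sigma,
                 min_ligatable_length = as.integer(min_ligatable_length)),
            class = "sim_params")
}

#' Hydrolyze a pool of molecules at near-midpoint breakpoints
#'
#' Each molecule of length >= 2 is independently cleaved with probability
#' `hydrolysis_rate`; the breakpoint (a bond index in 1..L-1) is drawn from
#' Normal(L/2, sigma), rounded, and clipped to the valid range. Nucleotide
#' mass is conserved: every cleaved molecule is replaced by its two
#' fragments.
#'
#' @param molecules character vector of molecules (use [expand_pool()] on a
#'   counted pool).
#' @param params a [sim_params()].
#' @return list with `fragments` (cleavage products) and `survivors`
#'   (uncleaved molecules), both character vectors.
#' @export
hydrolyze <- function(molecules, params) {
  n <- length(molecules)
  if (n == 0) return(list(fragments = character(0), survivors = character(0)))
  L <- nchar(molecules)
  cut <- runif(n) < params$hydrolysis_rate & L >= 2L
  if (!any(cut)) return(list(fragments = character(0), survivors = molecules))
  Lc <- L[cut]
  sigma <- params$sigma %||% (Lc / 6)
  b <- round(rnorm(sum(cut), mean = Lc / 2, sd = sigma))
  b <- pmin(pmax(b, 1L), Lc - 1L)
  mc <- molecules[cut]
  list(
    fragments = c(substr(mc, 1L, b), substr(mc, b + 1L, Lc)),
    survivors = molecules[!cut]
  )
}

#' Ligate hydrolysis fragments with each other or with intact molecules
#'
#' Each eligible fragment (length >= `min_ligatable_length`), visited in
#' random order, initiates a ligation with probability `ligation_rate`. Its
#' partner is drawn from the union of the other eligible fragments and the
#' intact survivors, with class probability proportional to each
#' population's current size and uniformly within class. Partners are
#' consumed (sampling without replacement) and joined 3' of the initiator;
#' ligation is single-pass (products do not react again this round).
#'
#' @param fragments,survivors character vectors from [hydrolyze()].
#' @param params a [sim_params()].
#' @return character vector of molecules after ligation (ligated products,
#'   unreacted fragments, unreacted survivors). Total nucleotide mass equals
#'   the input mass.
#' @export
ligate <- function(fragments, survivors, params) {
  elig <- which(nchar(fragments) >= params$min_ligatable_length)
  inel <- fragments[nchar(fragments) < params$min_ligatable_length]
  nS <- length(survivors)
  if (length(elig) == 0 || params$ligation_rate == 0) {
    return(c(fragments, survivors))
  }
  pairs <- ligation_matching(length(fragments), as.integer(elig), nS,
                             params$ligation_rate)
  if (nrow(pairs) == 0) return(c(fragments, survivors))
  from_frag <- pairs[, 2] > 0L
  partner_seq <- ifelse(from_frag, fragments[pmax(pairs[, 2], 1L)],
                        survivors[pmax(pairs[, 3], 1L)])
  products <- paste0(fragments[pairs[, 1]], partner_seq)
  used_f <- logical(length(fragments))
  used_f[pairs[, 1]] <- TRUE
  used_f[pairs[from_frag, 2]] <- TRUE
  used_s <- logical(nS)
  used_s[pairs[!from_frag, 3]] <- TRUE
  c(products, inel, fragments[elig][!used_f[elig]], survivors[!used_s])
}

#' Simulate one recombination round and its diversity change
#'
#' Runs hydrolysis then ligation on a pool and reports the Shannon index
#' before (`D_before`) and after (`D_after`), their difference `delta_D`,
#' and fragment-length histograms.
#'
#' @param pool a counted pool tibble (e.g. from [make_pool()]) or character
#'   vector of molecules.
#' @param params a [sim_params()].
#' @param seed integer seed; the outcome is deterministic given the seed.
#' @param rounds number of hydrolysis+ligation rounds (default 1).
#' @return a `sim_outcome` list: `pool_before`, `pool_after` (tibbles of
#'   seq/count), `D_before`, `D_after`, `delta_D` (bits), `length_before`,
#'   `length_after` (length histograms), and `params`.
#' @export
simulate_recombination <- function(pool, params, seed = 1L, rounds = 1L) {
  mols <- expand_pool(pool)
  if (length(mols) == 0) abort("cannot simulate an empty pool")
  D0 <- shannon_index(mols)
  after <- mols
  with_seed(seed, {
    for (r in seq_len(rounds)) {
      hy <- hydrolyze(after, params)
      after <- ligate(hy$fragments, hy$survivors, params)
    }
  })
  D1 <- shannon_index(after)
  out <- list(
    pool_before = counted_tibble(mols),
    pool_after = counted_tibble(after),
    D_before = D0, D_after = D1, delta_D = D1 - D0,
    length_before = length_histogram(mols),
    length_after = length_histogram(after),
    params = params
  )
  class(out) <- "sim_outcome"
  out
}

counted_tibble <- function(mols) {
  u <- unique(mols)
  tibble(seq = u, count = tabulate(match(mols, u))) |>
    arrange(desc(.data$count), .data$seq)
}

length_histogram <- function(mols) {
  tb <- tabulate(nchar(mols))
  keep <- which(tb > 0)
  tibble(length = keep, n = tb[keep])
}

#' Total nucleotide mass of a pool (for conservation checks)
#'
#' @param pool counted tibble or character vector.
#' @return total number of nucleotides across all molecules.
#' @export
nucleotide_mass <- function(pool) {
  if (is.character(pool)) return(sum(nchar(pool)))
  cnt <- if (is.null(pool[["count"]])) rep(1L, nrow(pool)) else pool[["count"]]
  sum(nchar(pool$seq) * as.numeric(cnt))
}

#' @export
print.sim_outcome <- function(x, ...) {
  cat("<sim_outcome>\n")
  cat(sprintf("  molecules: %d -> %d\n",
              sum(x$pool_before$count), sum(x$pool_after$count)))
  cat(sprintf("  D_before = %.4f bits, D_after = %.4f bits, delta_D = %+.4f bits\n",
              x$D_before, x$D_after, x$delta_D))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.sim_outcome <- function(x, ...) {
  tibble(
    n_before = sum(x$pool_before$count), n_after = sum(x$pool_after$count),
    unique_before = nrow(x$pool_before), unique_after = nrow(x$pool_after),
    D_before = x$D_before, D_after = x$D_after, delta_D = x$delta_D,
    mass = nucleotide_mass(x$pool_after)
  )
}

# one round, diversity change only (no bookkeeping tibbles) — the hot path
# of grid sweeps
delta_D_once <- function(mols, params, seed) {
  D0 <- shannon_index(mols)
  with_seed(seed, {
    hy <- hydrolyze(mols, params)
    after <- ligate(hy$fragments, hy$survivors, params)
  })
  shannon_index(after) - D0
}

#' Mean delta-D landscape over a hydrolysis x ligation rate grid
#'
#' For every rate pair, simulates `replicates` independent recombination
#' rounds on fresh pools and averages the Shannon-diversity change.
#'
#' @param base_pool_spec a [pool_spec()] describing the pools to regenerate
#'   per replicate.
#' @param hydrolysis_rates,ligation_rates numeric vectors of rates in \[0, 1\].
#' @param replicates replicate simulations per cell (fresh pool each).
#' @param seed master seed; per-cell/replicate seeds are derived
#'   deterministically from it.
#' @param sigma,min_ligatable_length passed to [sim_params()].
#' @return a `delta_d_grid` tibble: `hydrolysis_rate`, `ligation_rate`,
#'   `mean_delta_D`, `sd_delta_D`, `replicates`.
#' @export
delta_D_grid <- function(base_pool_spec, hydrolysis_rates, ligation_rates,
                         replicates = 10L, seed = 1L, sigma = NULL,
                         min_ligatable_length = 3L) {
  stopifnot(length(hydrolysis_rates) >= 1, length(ligation_rates) >= 1,
            replicates >= 1)
  cells <- tidyr::expand_grid(hydrolysis_rate = hydrolysis_rates,
                              ligation_rate = ligation_rates)
  res <- pmap(list(cells$hydrolysis_rate, cells$ligation_rate,
                   seq_len(nrow(cells))),
    function(h, l, ci) {
      pr <- sim_params(h, l, sigma = sigma,
                       min_ligatable_length = min_ligatable_length)
      dd <- vapply(seq_len(replicates), function(r) {
        pool <- make_pool(base_pool_spec,
                          seed = derive_seed(seed, "grid_pool", ci * 1000L + r))
        delta_D_once(expand_pool(pool), pr,
                     seed = derive_seed(seed, "grid_sim", ci * 1000L + r))
      }, numeric(1))
      c(mean(dd), sd(dd))
    })
  out <- cells |>
    mutate(mean_delta_D = map_dbl(res, 1),
           sd_delta_D = map_dbl(res, 2),
           replicates = replicates)
  class(out) <- c("delta_d_grid", class(out))
  attr(out, "pool_spec") <- base_pool_spec
  out
}

#' @exportS3Method generics::tidy
tidy.delta_d_grid <- function(x, ...) {
  as_tibble(x)
}
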