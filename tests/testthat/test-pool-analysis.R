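test_that("frequency profiles are unit vectors for constant input and sum to 1", {
  prof <- frequency_profile(c("ACGU", "ACGU"))
  m <- as.matrix(tibble::as_tibble(prof)[, c("A", "C", "G", "U")])
  expect_equal(m, diag(4), ignore_attr = TRUE)
  expect_error(frequency_profile(c("AC", "ACG")), "mixed lengths")

  # weighted profiles use collapse counts
  rec <- tibble::tibble(seq = c("AA", "CC"), count = c(3L, 1L))
  prof_w <- frequency_profile(rec, weighted = TRUE)
  expect_equal(prof_w$A, c(0.75, 0.75))
  expect_equal(rowSums(as.matrix(tibble::as_tibble(prof_w)[, c("A", "C", "G", "U")])),
               c(1, 1))
})

test_that("uniform random pools give near-uniform profiles", {
  pool <- generate_matched_pool(
    frequency_profile(strrep("A", 40), alphabet = c("A", "C", "G", "U")) |>
      dplyr::mutate(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
    n = 50000, seed = 13)
  prof <- frequency_profile(pool)
  m <- as.matrix(tibble::as_tibble(prof)[, c("A", "C", "G", "U")])
  tol <- 3 * sqrt(0.25 * 0.75 / 50000)
  expect_true(all(abs(m - 0.25) < tol))
})

test_that("RGB transformation maps pure bases to the legend colors", {
  pure <- function(base) frequency_profile(strrep(base, 3))
  expect_equal(unlist(rgb_signature(pure("C"))[1, c("red", "green", "blue")]),
               c(red = 0, green = 0, blue = 255))
  expect_equal(unlist(rgb_signature(pure("U"))[1, c("red", "green", "blue")]),
               c(red = 255, green = 0, blue = 0))
  expect_equal(unlist(rgb_signature(pure("A"))[1, c("red", "green", "blue")]),
               c(red = 0, green = 255, blue = 0))
  expect_equal(unlist(rgb_signature(pure("G"))[1, c("red", "green", "blue")]),
               c(red = 255, green = 255, blue = 0))
})

test_that("RGB values stay real before export and idempotent on a fixed profile", {
  prof <- frequency_profile(c("ACGU", "CAGU", "GUCA", "UGAC"))
  prof[, c("A", "C", "G", "U")] <- 0.25
  sig <- rgb_signature(prof)
  expect_equal(sig$red, rep(127.5, 4))
  expect_equal(sig$green, rep(127.5, 4))
  expect_equal(sig$blue, rep(63.75, 4))
  expect_identical(sig, rgb_signature(prof))
})

test_that("junction fingerprint concentrates on the constructed dinucleotide", {
  prods <- rep("AACGAA", 5)   # junction bond 3: C|G
  fp <- junction_fingerprint(prods, 3)
  expect_equal(fp$observed[fp$n_minus1 == "C" & fp$n_plus1 == "G"], 1)
  expect_equal(sum(fp$observed), 1)
  expect_error(junction_fingerprint(prods, 6), "interior")
})

test_that("junction fingerprint recovers an injected CpN bias fold", {
  bait <- make_pool(pool_spec(length = 20, n_unique = 2000, redundancy = 1), seed = 41)
  prey <- make_pool(pool_spec(length = 20, n_unique = 2000, redundancy = 1), seed = 42)
  pr <- make_products(bait, prey, product_spec(
    junction_bias = c(CN = 8),
    truncation_dist = list(family = "fixed", value = 0),
    n_products = 10000), seed = 43)
  background <- dplyr::bind_rows(frequency_profile(bait$seq), frequency_profile(prey$seq)) |>
    dplyr::mutate(position = 1:40)
  fp <- junction_fingerprint(pr$seq, 20, background = background)
  marg <- junction_marginals(fp) |> dplyr::filter(side == "minus1")
  expect_equal(marg$base[which.max(marg$observed)], "C")
  # composition-free fold estimate: odds of C vs non-C enrichment ratios
  obs_c <- marg$observed[marg$base == "C"]; exp_c <- marg$expected[marg$base == "C"]
  fold <- (obs_c / exp_c) / ((1 - obs_c) / (1 - exp_c))
  se3 <- 3 * fold / (obs_c * (1 - obs_c)) * sqrt(obs_c * (1 - obs_c) / 10000)
  expect_lt(abs(fold - 8), se3)
})

test_that("an unbiased fixture shows no significant junction enrichment", {
  pool <- make_pool(pool_spec(length = 20, n_unique = 3000, redundancy = 1), seed = 44)
  pr <- make_products(pool, pool, product_spec(
    truncation_dist = list(family = "fixed", value = 0),
    n_products = 8000), seed = 45)
  background <- dplyr::bind_rows(frequency_profile(pool$seq), frequency_profile(pool$seq)) |>
    dplyr::mutate(position = 1:40)
  fp <- junction_fingerprint(pr$seq, 20, background = background)
  # each dinucleotide frequency within 4 sigma of its background expectation
  tol <- 4 * sqrt(fp$expected * (1 - fp$expected) / 8000)
  expect_true(all(abs(fp$difference) < tol + 2e-3))
})

test_that("fingerprints mix by product-count weighting", {
  fp_a <- junction_fingerprint(rep("CG", 3), 1)
  fp_b <- junction_fingerprint(rep("AU", 1), 1)
  fp_mix <- junction_fingerprint(c(rep("CG", 3), rep("AU", 1)), 1)
  expect_equal(fp_mix$observed, (3 * fp_a$observed + 1 * fp_b$observed) / 4)
})

test_that("matched pools reproduce the input profile within binomial error", {
  prof <- frequency_profile(strrep("C", 10))
  expect_equal(generate_matched_pool(prof, 5, seed = 1), rep(strrep("C", 10), 5))

  base <- make_pool(pool_spec(length = 15, n_unique = 300, redundancy = 1), seed = 51)
  prof <- frequency_profile(base$seq)
  synth <- generate_matched_pool(prof, 100000, seed = 52)
  rec <- frequency_profile(synth)
  pm <- as.matrix(tibble::as_tibble(prof)[, c("A", "C", "G", "U")])
  rm_ <- as.matrix(tibble::as_tibble(rec)[, c("A", "C", "G", "U")])
  tol <- 3 * sqrt(pmax(pm * (1 - pm), 1e-12) / 100000) + 1e-9
  expect_true(all(abs(rm_ - pm) < tol | pm %in% c(0, 1)))
  expect_identical(synth, generate_matched_pool(prof, 100000, seed = 52))
})

test_that("pool combinatorics reproduces the printed eicosamer numbers", {
  out <- pool_combinatorics(1e15, 20, 4)
  expect_equal(out$redundancy, 909)
  expect_equal(signif(out$amount_nmol, 2), 1.7)
  expect_equal(out$diversity_exact, "1099511627776")   # 4^20
  expect_gte(out$diversity, 1e12)
  expect_gte(out$binary_pairs, 1e24)
  expect_equal(out$binary_pairs_exact, "1208925819614629174706176")  # 4^40
})

test_that("big-integer powers are exact far beyond double precision", {
  # cross-checked against independent arbitrary-precision arithmetic
  expect_equal(pool_combinatorics(1, 60, 4)$diversity_exact,
               "1329227995784915872903807060280344576")  # 4^60 = 2^120
  # agrees with double arithmetic where doubles are exact
  for (len in c(5, 13, 26)) {
    expect_equal(pool_combinatorics(1, len, 4)$diversity, 4^len)
  }
})

test_that("kinetics fit inverts noiseless data exactly and flags degenerate input", {
  t <- c(0, 1, 2, 4, 8, 16, 32, 64)
  y <- 0.5 * (1 - exp(-0.1 * t))
  fit <- fit_ligation_kinetics(t, y)
  expect_equal(fit$k_obs, 0.1, tolerance = 1e-6)
  expect_equal(fit$plateau, 0.5, tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-8)

  flat <- fit_ligation_kinetics(t, rep(0, 8))
  expect_equal(flat$plateau, 0)
  expect_true(is.na(flat$k_obs))
  expect_match(flat$flag, "indeterminate")
  expect_error(fit_ligation_kinetics(c(0, 1), c(0, 1)), "3 timepoints")
  expect_error(fit_ligation_kinetics(t, y + 1), "fractions")
})

test_that("kinetics fit recovers k within 20% (median) under 5% noise", {
  # 8 timepoints spanning the rise and the plateau of k = 0.1/day kinetics
  t <- c(0, 2, 5, 10, 15, 20, 30, 60)
  rel_err <- vapply(1:100, function(s) {
    set.seed(s)
    y <- pmin(pmax(0.5 * (1 - exp(-0.1 * t)) + rnorm(8, 0, 0.05), 0), 1)
    fit <- fit_ligation_kinetics(t, y)
    abs(fit$k_obs - 0.1) / 0.1
  }, numeric(1))
  expect_lt(median(rel_err), 0.2)
})
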