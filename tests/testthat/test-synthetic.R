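test_that("make_pool builds n_unique distinct cores at the set redundancy", {
  pool <- make_pool(pool_spec(length = 20, n_unique = 1000, redundancy = 100), seed = 1)
  expect_equal(nrow(pool), 1000)
  expect_equal(length(unique(pool$core)), 1000)
  expect_true(all(pool$count == 100))
  expect_equal(sum(pool$count), 100000)
  expect_true(all(nchar(pool$seq) == 20))

  # flanks and tails appended verbatim
  p2 <- make_pool(pool_spec(length = 5, n_unique = 10, redundancy = 1,
                            constant5 = "GGG", constant3 = "CC",
                            tail = list(base = "A", length = 10)), seed = 2)
  expect_true(all(startsWith(p2$seq, "GGG")))
  expect_true(all(endsWith(p2$seq, paste0("CC", strrep("A", 10)))))
  expect_true(all(nchar(p2$seq) == 3 + 5 + 2 + 10))
})

test_that("a redundancy-1 monomer pool enumerates the alphabet", {
  pool <- make_pool(pool_spec(length = 1, alphabet = c("A", "C", "G", "U"),
                              n_unique = 4, redundancy = 1), seed = 5)
  expect_setequal(pool$seq, c("A", "C", "G", "U"))
  expect_error(pool_spec(length = 1, n_unique = 5),
               "exceeds the sequence space")
})

test_that("pool and product generation are deterministic under a seed", {
  s <- pool_spec(n_unique = 50, redundancy = 2)
  expect_identical(make_pool(s, seed = 9), make_pool(s, seed = 9))
  a <- make_products(make_pool(s, 1), make_pool(s, 2),
                     product_spec(n_products = 100), seed = 3)
  b <- make_products(make_pool(s, 1), make_pool(s, 2),
                     product_spec(n_products = 100), seed = 3)
  expect_identical(a, b)
  expect_false(identical(make_pool(s, seed = 9), make_pool(s, seed = 10)))
})

test_that("zero truncation with uniform bias yields full-length concatemers", {
  bait <- make_pool(pool_spec(length = 20, n_unique = 50, redundancy = 1), seed = 1)
  prey <- make_pool(pool_spec(length = 20, n_unique = 50, redundancy = 1), seed = 2)
  pr <- make_products(bait, prey, product_spec(
    truncation_dist = list(family = "fixed", value = 0), n_products = 300), seed = 3)
  expect_true(all(nchar(pr$seq) == 40))
  expect_true(all(pr$truncation == 0))
  expect_true(all(pr$junction == 20))
  expect_equal(pr$seq, paste0(bait$seq[match(pr$bait_id, bait$id)],
                              prey$seq[match(pr$prey_id, prey$id)]))
})

test_that("products preserve prey length and truncate only bait", {
  bait <- make_pool(pool_spec(length = 20, n_unique = 100, redundancy = 1), seed = 4)
  prey <- make_pool(pool_spec(length = 20, n_unique = 100, redundancy = 1,
                              constant3 = "GGGG"), seed = 5)
  pr <- make_products(bait, prey, product_spec(n_products = 500), seed = 6)
  # downstream segment is the full prey sequence
  expect_equal(substr(pr$seq, pr$junction + 1, nchar(pr$seq)),
               prey$seq[match(pr$prey_id, prey$id)])
  expect_equal(nchar(pr$seq), 40L + 4L - pr$truncation)
})

test_that("a 5'-blocked pool cannot provide the downstream (prey) segment", {
  blocked <- make_pool(pool_spec(length = 10, n_unique = 20, redundancy = 1,
                                 blocked5 = TRUE), seed = 1)
  free <- make_pool(pool_spec(length = 10, n_unique = 20, redundancy = 1), seed = 2)
  expect_error(
    make_products(blocked, free, product_spec(product_mix = c("B-B" = 1),
                                              n_products = 10), seed = 1),
    "5'-blocked")
  # bait-prey products are fine: the blocked pool acts only upstream
  expect_silent(make_products(blocked, free,
                              product_spec(n_products = 10), seed = 1))
})

test_that("empirical junction dinucleotide frequencies track the bias weights", {
  pool <- make_pool(pool_spec(length = 20, n_unique = 500, redundancy = 1), seed = 7)
  pr <- make_products(pool, pool, product_spec(
    junction_bias = c(CN = 8),
    truncation_dist = list(family = "fixed", value = 0),
    n_products = 4000), seed = 8)
  minus1 <- substr(pr$seq, pr$junction, pr$junction)
  frac_c <- mean(minus1 == "C")
  # expected C share folds the pool's realized composition at the cut
  # position into the 8x reweighting (generator bookkeeping)
  f_c <- mean(substr(pool$seq, 20, 20) == "C")
  p_exp <- 8 * f_c / (8 * f_c + (1 - f_c))
  expect_gt(frac_c, p_exp - 3 * sqrt(p_exp * (1 - p_exp) / 4000))
  expect_lt(frac_c, p_exp + 3 * sqrt(p_exp * (1 - p_exp) / 4000))
})

test_that("attach_quality with zero error leaves sequences intact at Q40", {
  pool <- make_pool(pool_spec(length = 10, n_unique = 20, redundancy = 1), seed = 1)
  pr <- make_products(pool, pool, product_spec(n_products = 50), seed = 2)
  reads <- attach_quality(pr, error_profile(), seed = 3)
  expect_equal(reads$seq, pr$seq)
  expect_true(all(reads$n_errors == 0))
  expect_true(all(vapply(phred_decode(reads$qual), function(q) all(q == 40), logical(1))))
})

test_that("substitution counts follow the binomial expectation", {
  pool <- make_pool(pool_spec(length = 20, n_unique = 1000, redundancy = 1), seed = 1)
  pr <- make_products(pool, pool, product_spec(
    truncation_dist = list(family = "fixed", value = 0),
    n_products = 10000), seed = 2)
  reads <- attach_quality(pr, error_profile(sub_rate = 0.01), seed = 3)
  total <- sum(reads$n_errors)
  expected <- 10000 * 40 * 0.01
  sd3 <- 3 * sqrt(10000 * 40 * 0.01 * 0.99)
  expect_gt(total, expected - sd3)
  expect_lt(total, expected + sd3)
  # injected errors really differ from the originals
  expect_equal(sum(mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)),
                          reads$seq, pr$seq)), total)
})
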