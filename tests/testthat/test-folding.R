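test_that("dot-bracket parsing builds the pair map and flags imbalance", {
  db <- parse_dotbracket("((..))")
  expect_equal(db$pairs, c(6L, 5L, NA, NA, 2L, 1L))
  expect_equal(parse_dotbracket(".....")$pairs, rep(NA_integer_, 5))
  expect_error(parse_dotbracket("(()"), "position 1.*end of string")
  expect_error(parse_dotbracket("())."), "position 3")
  expect_error(parse_dotbracket("(x)"), "invalid")
})

test_that("base-pair maximization handles canonical small cases", {
  expect_equal(nussinov_fold("AAAA")$structure, "....")
  f <- nussinov_fold("GGGAAACCC")
  expect_equal(pair_count(f), 3)
  expect_equal(f$structure, "(((...)))")
  # deterministic traceback
  expect_identical(nussinov_fold("GCAUCGGCAUCG")$structure,
                   nussinov_fold("GCAUCGGCAUCG")$structure)
})

test_that("DP pair counts equal exhaustive enumeration on random 12-mers", {
  set.seed(61)
  for (i in 1:60) {
    len <- sample(4:12, 1)
    s <- paste0(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
    folded <- nussinov_fold(s)
    expect_equal(pair_count(folded), brute_force_max_pairs(s), label = s)
    # and the reported structure is valid and consistent
    expect_silent(parse_dotbracket(folded$structure))
  }
})

test_that("the minimum loop constraint is respected", {
  set.seed(62)
  for (i in 1:25) {
    s <- paste0(sample(c("A", "C", "G", "U"), 12, replace = TRUE), collapse = "")
    db <- parse_dotbracket(nussinov_fold(s, min_loop = 3)$structure)
    gaps <- abs(db$pairs - seq_along(db$pairs))
    expect_true(all(gaps[!is.na(gaps)] > 3))
  }
})

test_that("external folding requires a configured, present backend", {
  expect_error(external_fold("ACGU", NULL), "backend_command")
  expect_error(external_fold("ACGU", "definitely-not-a-folder-xyz"),
               "not found on PATH")
})

test_that("a mock backend round-trips structures and energies", {
  mock <- withr::local_tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh",
               "cat > /dev/null",
               "echo 'GGGAAACCC'",
               "echo '(((...))) ( -4.20)'",
               "echo 'AAAA'",
               "echo '.... ( 0.00)'"), mock)
  Sys.chmod(mock, "0755")
  out <- external_fold(c("GGGAAACCC", "AAAA"), mock)
  expect_equal(out$structure, c("(((...)))", "...."))
  expect_equal(out$energy[1], -4.2)

  bad <- withr::local_tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "echo garbage-output; exit 0"), bad)
  Sys.chmod(bad, "0755")
  expect_error(external_fold("ACGU", bad), "unparseable")
})

test_that("dot-bracket files round-trip through read_dotbracket", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("GGGAAACCC", "(((...))) (-4.20)", "ACGU", "...."), f)
  out <- read_dotbracket(f)
  expect_equal(out$seq, c("GGGAAACCC", "ACGU"))
  expect_equal(out$structure, c("(((...)))", "...."))
  expect_equal(out$energy, c(-4.2, NA))
})

test_that("structure profiles tabulate obp/cbp/unp and sum to one", {
  p <- structure_profile("((..))")
  expect_equal(p$obp, c(1, 1, 0, 0, 0, 0))
  expect_equal(p$cbp, c(0, 0, 0, 0, 1, 1))
  expect_equal(p$unp, c(0, 0, 1, 1, 0, 0))

  p2 <- structure_profile(c("()....", "....()"))
  expect_equal(p2$obp[1], 0.5)

  set.seed(63)
  sts <- vapply(1:200, function(i) {
    nussinov_fold(paste0(sample(c("A", "C", "G", "U"), 15, replace = TRUE),
                         collapse = ""))$structure
  }, character(1))
  p3 <- structure_profile(sts)
  expect_equal(p3$obp + p3$cbp + p3$unp, rep(1, 15))
  expect_error(structure_profile(c("..", "...")), "mixed lengths")
})

test_that("profile comparison recovers constructed offsets and is zero on self", {
  p <- structure_profile(c("((....))", "(......)"))
  self <- compare_structure_profiles(p, list(p, p))
  expect_true(all(self$difference == 0))
  expect_true(all(self$sd == 0))

  shifted <- p
  shifted$obp[3] <- shifted$obp[3] + 0.1
  shifted$unp[3] <- shifted$unp[3] - 0.1
  cmp <- compare_structure_profiles(p, list(shifted))
  expect_equal(cmp$difference[cmp$position == 3 & cmp$element == "obp"], -0.1)
  expect_equal(cmp$difference[cmp$position == 3 & cmp$element == "unp"], 0.1)
  expect_error(compare_structure_profiles(p, list(structure_profile("..."))),
               "length")
})

test_that("energy distributions summarise and shift exactly", {
  x <- c(-5, -3, -2, -8)
  a <- mfe_distribution(x)
  b <- mfe_distribution(list(shifted = x - 1))
  expect_equal(b$mean, a$mean - 1)
  expect_equal(b$sd, a$sd)
  expect_equal(mfe_distribution(x), mfe_distribution(x))
})

test_that("ligated complements fold better than shuffled controls (pair-count proxy)", {
  set.seed(64)
  rc <- function(s) chartr("ACGU", "UGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  halves <- vapply(1:40, function(i) {
    paste0(sample(c("A", "C", "G", "U"), 10, replace = TRUE), collapse = "")
  }, character(1))
  ligated <- paste0(halves, vapply(halves, rc, character(1)))
  shuffled <- vapply(ligated, function(s) {
    paste0(sample(strsplit(s, "")[[1]]), collapse = "")
  }, character(1))
  pc <- function(seqs) mean(vapply(seqs, function(s) pair_count(nussinov_fold(s)),
                                   numeric(1)))
  expect_gt(pc(ligated), pc(shuffled))
})
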