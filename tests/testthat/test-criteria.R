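# Each case constructs a hairpin at one criterion's inclusive boundary and a
# twin one unit past it, verifying that exactly that criterion flips.

check_boundary <- function(hp_pass, hp_fail, which_c, mature_pass, mature_fail,
                           energy = c(-60, -60)) {
  rp <- evaluate_criteria(hp_pass$seq, hp_pass$structure, energy[1],
                          mature_pass[1], mature_pass[2])
  rf <- evaluate_criteria(hp_fail$seq, hp_fail$structure, energy[2],
                          mature_fail[1], mature_fail[2])
  flags_p <- unlist(rp[paste0("c", 1:11)])
  flags_f <- unlist(rf[paste0("c", 1:11)])
  expect_true(rp$pass, label = paste0(which_c, " boundary should pass"))
  expect_false(rf$pass, label = paste0(which_c, " past boundary should fail"))
  expect_false(flags_f[[which_c]])
  expect_true(all(flags_f[setdiff(names(flags_f), which_c)]),
              label = paste0(which_c, ": only ", which_c, " flips"))
  list(pass = rp, fail = rf)
}

test_that("stem bulge size boundary (12 vs 13 nt) gates criterion 1", {
  hp <- function(l, r) build_hairpin(list(list(p = 10), list(b = c(l, r)),
                                          list(p = 20)), loop = 8)
  check_boundary(hp(6, 6), hp(7, 6), "c1",
                 mature_pass = c(10 + 6 + 1, 20), mature_fail = c(10 + 7 + 1, 20))
})

test_that("stem pair count boundary (16 vs 15) gates criterion 2", {
  hp <- function(p) build_hairpin(list(list(p = p)), loop = 20)
  check_boundary(hp(16), hp(15), "c2",
                 mature_pass = c(1, 18), mature_fail = c(1, 18))
})

test_that("energy boundary (-15 vs -14) gates criterion 3", {
  hp <- build_hairpin(list(list(p = 30)), loop = 8)
  check_boundary(hp, hp, "c3", c(1, 22), c(1, 22), energy = c(-15, -14))
})

test_that("hairpin length boundary (50 vs 49 nt) gates criterion 4", {
  hp <- function(loop) build_hairpin(list(list(p = 16)), loop = loop)
  check_boundary(hp(18), hp(17), "c4", c(1, 18), c(1, 18))
})

test_that("terminal loop boundary (20 vs 21 nt) gates criterion 5", {
  hp <- function(loop) build_hairpin(list(list(p = 20)), loop = loop)
  check_boundary(hp(20), hp(21), "c5", c(1, 20), c(1, 20))
})

test_that("mature bulge size boundary (8 vs 9 nt) gates criterion 6", {
  hp <- function(l, r) build_hairpin(list(list(p = 6), list(b = c(l, r)),
                                          list(p = 14)), loop = 8)
  check_boundary(hp(4, 4), hp(4, 5), "c6", c(1, 22), c(1, 22))
})

test_that("biased-error boundary (4 vs 5) gates criterion 7", {
  hp <- function(l) build_hairpin(list(list(p = 6), list(b = c(l, 0)),
                                       list(p = 14)), loop = 8)
  check_boundary(hp(4), hp(5), "c7", c(1, 22), c(1, 23))
})

test_that("biased-bulge count boundary (2 vs 3) gates criterion 8", {
  hp2 <- build_hairpin(list(list(p = 6), list(b = c(1, 0)), list(p = 6),
                            list(b = c(1, 0)), list(p = 10)), loop = 8)
  hp3 <- build_hairpin(list(list(p = 6), list(b = c(1, 0)), list(p = 6),
                            list(b = c(1, 0)), list(p = 6), list(b = c(1, 0)),
                            list(p = 6)), loop = 8)
  check_boundary(hp2, hp3, "c8", c(1, 24), c(1, 27))
})

test_that("mature error boundary (7 vs 8) gates criterion 9", {
  hp <- function(b2) build_hairpin(list(list(p = 6), list(b = c(4, 4)),
                                        list(p = 4), list(b = c(b2, b2)),
                                        list(p = 8)), loop = 8)
  check_boundary(hp(3), hp(4), "c9", c(1, 25), c(1, 26))
})

test_that("mature pair boundary (12 vs 11) gates criterion 10", {
  hp <- build_hairpin(list(list(p = 6), list(b = c(3, 3)), list(p = 6),
                           list(b = c(3, 3)), list(p = 6)), loop = 8)
  res <- check_boundary(hp, hp, "c10", c(1, 15), c(1, 14))
  expect_equal(res$pass$mature_pairs, 12L)
  expect_equal(res$fail$mature_pairs, 11L)
})

test_that("mature-in-stem percentage boundary (80 vs < 80) gates criterion 11", {
  hp <- function(f) build_hairpin(list(list(p = 30)), loop = 8, flank = c(f, 0))
  res <- check_boundary(hp(5), hp(6), "c11", c(1, 25), c(1, 25))
  expect_equal(res$pass$mature_stem_pct, 80)
  expect_lt(res$fail$mature_stem_pct, 80)
})

test_that("multi-branched structures are rejected as not a hairpin", {
  s <- "((..((...))..((...))..))"
  r <- evaluate_criteria(strrep("A", nchar(s)), s, -60, 1, 10)
  expect_false(r$pass)
  expect_equal(r$reason, "not_a_hairpin")

  r0 <- evaluate_criteria(strrep("A", 30), strrep(".", 30), -60, 1, 20)
  expect_false(r0$pass)
  expect_equal(r0$reason, "no_pairs")
})

test_that("evaluate_criteria is pure and validates the mature interval", {
  hp <- build_hairpin(list(list(p = 30)), loop = 8)
  a <- evaluate_criteria(hp$seq, hp$structure, -60, 1, 22)
  b <- evaluate_criteria(hp$seq, hp$structure, -60, 1, 22)
  expect_identical(a, b)
  expect_error(evaluate_criteria(hp$seq, hp$structure, -60, 60, 22), "outside")
  expect_error(evaluate_criteria(hp$seq, substr(hp$structure, 1, 10), -60, 1, 5),
               "lengths differ")
})

test_that("a textbook compliant hairpin passes every criterion", {
  # perfect 30-bp stem, 8 nt loop, 22 nt mature fully on the 5' arm
  hp <- build_hairpin(list(list(p = 30)), loop = 8)
  r <- evaluate_criteria(hp$seq, hp$structure, -60, 1, 22)
  expect_true(r$pass)
  expect_equal(r$stem_pairs, 30L)
  expect_equal(r$mature_pairs, 22L)
  expect_equal(r$mature_stem_pct, 100)
  expect_equal(r$loop_len, 8L)
  expect_equal(r$hairpin_len, 68L)
})
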