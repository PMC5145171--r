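test_that("repetition-free pattern enumeration has the permutation count", {
  p2 <- norepeat_patterns(2)
  expect_length(p2, 56L)            # 8 * 7
  expect_identical(p2, sort(p2))    # lexicographic
  expect_length(norepeat_patterns(1), 8L)
  expect_length(norepeat_patterns(8), 40320L) # 8!
  expect_true(all(vapply(strsplit(norepeat_patterns(3), ""),
                         function(d) !anyDuplicated(d), logical(1))))
  expect_error(norepeat_patterns(9), class = "chemotif_domain_error")
  expect_error(norepeat_patterns(0), class = "chemotif_domain_error")
})

test_that("common patterns are exactly the shared L-mers of the encodings", {
  d <- tibble::tibble(seq_id = c("a", "b"), residues = c("DRS", "ADRS"))
  res <- common_patterns(d, 3)
  expect_identical(res$patterns, "127")
  expect_identical(res$hits$position, c(1L, 2L))
  expect_identical(unique(res$hits$residue_block), "DRS")

  rep4 <- common_patterns(tibble::tibble(seq_id = c("a", "b"),
                                         residues = c("DDRD", "ADDRD")),
                          4, mode = "repeat")
  expect_identical(rep4$patterns, "1121")
  expect_identical(rep4$hits$position, c(1L, 2L))

  none <- tibble::tibble(seq_id = c("a", "b"), residues = c("DR", "RD"))
  expect_length(common_patterns(none, 2)$patterns, 0L)
  expect_length(common_patterns(none, 2, mode = "repeat")$patterns, 0L)

  # L beyond the shortest sequence: empty result, not an error
  expect_length(common_patterns(d, 10, mode = "repeat")$patterns, 0L)
})

test_that("both search strategies equal the brute-force oracle", {
  withr::local_seed(301)
  for (rep in 1:6) {
    n <- sample(2:10, 1)
    seqs <- random_seq_table(n, c(20, 200))
    enc <- encode_sequences(seqs)
    for (L in sample(2:6, 2)) {
      for (mode in c("norepeat", "repeat")) {
        expected <- oracle_common(enc$digits, L, norepeat = mode == "norepeat")
        got_i <- common_patterns(seqs, L, mode = mode, method = "intersect")
        got_g <- common_patterns(seqs, L, mode = mode, method = "grow")
        expect_identical(got_i$patterns, expected)
        expect_identical(got_g$patterns, expected)
      }
    }
  }
})

test_that("tetramer growth handles quotient and remainder lengths", {
  withr::local_seed(302)
  # short sequences keep the common sets non-trivial at larger L
  seqs <- random_seq_table(3, c(15, 25))
  enc <- encode_sequences(seqs)
  for (L in c(4L, 5L, 7L, 8L, 9L, 13L)) {
    expected <- oracle_common(enc$digits, L)
    expect_identical(common_patterns(seqs, L, mode = "repeat",
                                     method = "grow")$patterns,
                     expected)
  }
})

test_that("common patterns shrink and nest as length grows", {
  withr::local_seed(303)
  seqs <- random_seq_table(4, c(30, 60))
  enc <- encode_sequences(seqs)
  for (L in 2:5) {
    longer <- common_patterns(seqs, L + 1L, mode = "repeat")$patterns
    shorter <- common_patterns(seqs, L, mode = "repeat")$patterns
    # prefix and suffix of every common (L+1)-mer are common L-mers
    expect_true(all(substr(longer, 1, L) %in% shorter))
    expect_true(all(substr(longer, 2, L + 1L) %in% shorter))
    # repetition-free patterns are a subset of the unconstrained ones
    expect_true(all(common_patterns(seqs, L)$patterns %in% shorter))
  }
})

test_that("maximal search returns the longest non-empty common set", {
  one <- tibble::tibble(seq_id = "s", residues = "DRSMYI")
  mx <- maximal_common_patterns(one)
  expect_identical(mx$L, 6L)
  expect_identical(mx$patterns, "127634") # its own repetition-free encoding

  withr::local_seed(304)
  seqs <- random_seq_table(4, c(30, 60))
  for (mode in c("norepeat", "repeat")) {
    mx <- maximal_common_patterns(seqs, mode = mode)
    expect_gt(length(mx$patterns), 0L)
    expect_identical(sort(mx$patterns),
                     common_patterns(seqs, mx$L, mode = mode)$patterns)
    # all longer lengths are empty (monotonicity)
    if (!(mode == "norepeat" && mx$L >= 8L)) {
      expect_length(common_patterns(seqs, mx$L + 1L, mode = mode,
                                    method = "intersect")$patterns, 0L)
    }
  }
})

test_that("a planted chemical motif is always recovered", {
  withr::local_seed(305)
  for (pat in c("352471", "84268444", "12345678")) {
    fx <- simulate_sequences(n_sequences = 6, length_range = c(120, 160),
                             planted = pat, seed = sample.int(10000, 1))
    found <- common_patterns(fx$sequences, nchar(pat), mode = "repeat")
    expect_true(pat %in% found$patterns)
    # every manifest position is among the located hits
    hits <- locate_pattern(fx$sequences, pat)
    man <- fx$manifest
    expect_true(all(paste(man$seq_id, man$position) %in%
                      paste(hits$seq_id, hits$position)))
  }
})

test_that("maximal repeat-mode length is at least a planted pattern's", {
  fx <- simulate_sequences(n_sequences = 5, length_range = c(150, 180),
                           planted = "34842742818772342342", seed = 7)
  mx <- maximal_common_patterns(fx$sequences, mode = "repeat")
  expect_gte(mx$L, 20L)
  mn <- maximal_common_patterns(fx$sequences, mode = "norepeat")
  expect_lte(mn$L, 8L) # pigeonhole cap
})

test_that("locate_pattern reports every overlapping occurrence 1-based", {
  d <- tibble::tibble(seq_id = "s", residues = "ADRSDRS") # 4127127
  hits <- locate_pattern(d, "127")
  expect_identical(hits$position, c(2L, 5L))
  expect_identical(hits$residue_block, c("DRS", "DRS"))

  over <- locate_pattern(tibble::tibble(seq_id = "s", residues = "DDD"), "11")
  expect_identical(over$position, c(1L, 2L)) # overlaps included

  expect_identical(nrow(locate_pattern(d, "88")), 0L)
  expect_error(locate_pattern(d, ""), class = "chemotif_domain_error")
  expect_error(locate_pattern(d, "9"), class = "chemotif_domain_error")
})

test_that("classification splits patterns by subgroup commonality", {
  d <- tibble::tibble(seq_id = c("a1", "a2", "b1"),
                      residues = c("DRS", "ADRS", "RSD")) # 127, 4127, 271
  cls <- classify_patterns(d, ids_a = c("a1", "a2"), ids_b = "b1", L = 2)
  expect_identical(cls$pattern[cls$set == "common"], "27")
  expect_identical(cls$pattern[cls$set == "a_only"], "12")
  expect_identical(cls$pattern[cls$set == "b_only"], "71")
  # the three sets are pairwise disjoint
  expect_identical(anyDuplicated(cls$pattern), 0L)

  expect_error(classify_patterns(d, c("a1", "a2"), c("a2", "b1"), 2),
               class = "chemotif_domain_error")
  expect_error(classify_patterns(d, c("a1", "a2"), character(0), 2),
               class = "chemotif_domain_error")
  expect_error(classify_patterns(d, "a1", "b1", 2), # a2 unassigned
               class = "chemotif_domain_error")
})

test_that("pattern results tidy, glance and print coherently", {
  d <- tibble::tibble(seq_id = c("a", "b"), residues = c("DRS", "ADRS"))
  res <- common_patterns(d, 3)
  td <- tidy(res)
  expect_identical(names(td),
                   c("pattern", "L", "mode", "seq_id", "position",
                     "residue_block"))
  expect_identical(nrow(td), nrow(res$hits))
  gl <- glance(res)
  expect_identical(gl$n_patterns, 1L)
  expect_identical(gl$n_sequences, 2L)
  expect_output(print(res), "127")
  expect_s3_class(autoplot(res), "ggplot")
})
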