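# Folding engines, the rescue-count statistic and the dinucleotide shuffle.

test_that("folding basics: open rule, N masking, balanced structures", {
  f <- fold("AAAAAAAAAA")
  expect_true(f$open)
  expect_equal(f$structure, strrep(".", 10))
  # the designed 8-bp stem folds fully under the fallback engine
  f2 <- fold("CCCCCUGUAAAUAAAAAUAUUUACACCCCC")
  expect_equal(f2$energy, -8)
  expect_equal(sum(f2$paired), 16)
  # masked positions are never paired
  f3 <- fold("CCCCCUGUANNNNNNNUAUUUACACCCCC")
  n_pos <- which(strsplit("CCCCCUGUANNNNNNNUAUUUACACCCCC", "")[[1]] == "N")
  expect_true(all(!f3$paired[n_pos]))
  # a single-pair fallback structure is treated as fully open
  f4 <- fold("ACGUACG")  # exactly 1 pair possible under min loop 3
  expect_true(f4$open)
  expect_equal(f4$structure, ".......")
  expect_error(fold(""), "empty")
  # balanced brackets
  s <- strsplit(f2$structure, "")[[1]]
  expect_equal(sum(s == "("), sum(s == ")"))
})

test_that("fallback engine equals exhaustive max-pairing enumeration to 14 nt", {
  set.seed(61)
  for (rep in 1:60) {
    n <- sample(5:14, 1)
    seq <- random_rna(n, c("A", "C", "G", "U", "N"))
    got <- fold(seq, open_energy = Inf)
    expect_equal(-got$energy, brute_max_pairs(seq),
                 info = seq)
    # compiled and pure-R engines agree
    expect_equal(got$structure,
                 utrcoop:::fold_nussinov_r(seq)$structure)
  }
})

test_that("vienna engine parses RNAfold output when available", {
  skip_if(!has_rnafold(), "RNAfold not on PATH")
  f <- fold("GGGGGAAAACCCCC", engine = "vienna")
  expect_equal(nchar(f$structure), 14L)
  expect_lt(f$energy, -1)
  expect_true(any(f$paired))
  f2 <- fold("AAAAAAAAAA", engine = "vienna")
  expect_true(f2$open)
})

test_that("pair windows are extracted with 5-nt flanks and clamping", {
  seq <- strrep("A", 200)
  w <- extract_pair_window(seq, list(start = 100, end = 108),
                           list(start = 120, end = 127))
  expect_equal(w$window_start, 95L)
  expect_equal(nchar(w$seq), 132 - 95)
  expect_equal(w$rbp, c(5, 13))
  expect_equal(w$mirna, c(25, 32))
  # clamping at the UTR start
  w2 <- extract_pair_window(seq, list(start = 2, end = 10),
                            list(start = 20, end = 27))
  expect_equal(w2$window_start, 0L)
  expect_equal(w2$rbp, c(2, 10))
  # order independence
  w3 <- extract_pair_window(seq, list(start = 120, end = 128),
                            list(start = 100, end = 107))
  expect_equal(w3$window_start, 95L)
})

test_that("rescue counts match the worked scheme on a designed hairpin", {
  # PUM site (N instantiated as G) paired to the reverse complement of its
  # first 7 nt across a C-loop: the stem is the seed site's only partner
  win <- "CUGUAGAUACCCCAUCUACAC"
  rbp_iv <- c(1L, 9L)
  mir_iv <- c(13L, 20L)
  # oracle: max pairing of the window is exactly the 7-bp stem, and after
  # masking only one internal U-A pair remains (which the open rule clears)
  expect_equal(brute_max_pairs(win), 7L)
  masked <- paste0(strrep("N", 10), substr(win, 11, 21))
  expect_equal(brute_max_pairs(masked), 1L)
  rc <- rescue_count(win, rbp_iv, mir_iv)
  expect_equal(rc$c1, 7L)
  expect_equal(rc$c2, 0L)
  expect_equal(rc$c, 7L)
  # poly-A window: nothing pairs
  polyA <- strrep("A", 40)
  rc0 <- rescue_count(polyA, c(5L, 13L), c(20L, 27L))
  expect_equal(c(rc0$c1, rc0$c2, rc0$c), c(0L, 0L, 0L))
  # overlapping mask and miRNA site is an error
  expect_error(rescue_count(win, c(1L, 9L), c(9L, 16L)), "overlaps")
})

test_that("dinucleotide shuffle preserves mono and dinucleotide counts exactly", {
  set.seed(71)
  for (rep in 1:1000) {
    seq <- random_rna(60)
    out <- dinucleotide_shuffle(seq)
    expect_equal(nchar(out), 60L)
    expect_equal(dinuc_counts(out), dinuc_counts(seq))
    expect_equal(sort(strsplit(out, "")[[1]]), sort(strsplit(seq, "")[[1]]))
  }
  # endpoints preserved; homopolymer is its own shuffle; determinism
  expect_equal(dinucleotide_shuffle("AAAA"), "AAAA")
  s <- "ACGUACGUAAGGCCUU"
  expect_equal(substr(dinucleotide_shuffle(s, seed = 2), 1, 1), "A")
  expect_equal(dinucleotide_shuffle(s, seed = 9),
               dinucleotide_shuffle(s, seed = 9))
  out <- dinucleotide_shuffle("AAUU")
  d <- dinuc_counts(out)
  expect_equal(as.integer(d[c("AA", "AU", "UU")]), c(1L, 1L, 1L))
})

test_that("the shuffle background conserves pair totals and is seed-stable", {
  set.seed(81)
  wins <- lapply(1:12, function(i) {
    rbp <- "UGUAAAUA"
    mir <- "UAUUUACA"
    list(seq = paste0(random_rna(5), rbp, random_rna(10), mir,
                      random_rna(5)),
         rbp = c(5L, 13L), mirna = c(23L, 31L))
  })
  bg <- rescue_background(wins, n = 4L, seed = 3L)
  expect_equal(sum(bg$real_count), 12)
  expect_equal(sum(bg$bg_mean), 12)
  bg2 <- rescue_background(wins, n = 4L, seed = 3L)
  expect_identical(bg, bg2)
  # all-A windows shuffle to themselves: background identical, sd 0
  winsA <- list(list(seq = strrep("A", 40), rbp = c(5L, 13L),
                     mirna = c(20L, 27L)))
  bgA <- rescue_background(winsA, n = 3L, seed = 1L)
  expect_equal(bgA$real_count, bgA$bg_mean)
  expect_equal(bgA$bg_sd, 0)
})

test_that("rank-sum comparison of rescue distributions has the exact tail", {
  res <- compare_rescue_distributions(c(5, 6, 7), c(0, 0, 1))
  expect_equal(res$p_greater, 1 / choose(6, 3))
  res2 <- compare_rescue_distributions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res2$p_two_sided, 1)
  # swapping inputs flips the one-sided direction
  res3 <- compare_rescue_distributions(c(0, 0, 1), c(5, 6, 7))
  expect_equal(res3$p_greater, 1)
})
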