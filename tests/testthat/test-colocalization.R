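# Pair windows, permutation nulls, empirical p, FDR, interacting calls.

site <- function(tx, start, end, fam = NULL, seed_type = "m8",
                 pattern = "ACGUACG") {
  df <- data.frame(transcript_id = tx, start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  if (!is.null(fam)) {
    df$family_id <- fam
    df$seed_type <- seed_type
    df$pattern <- pattern
  }
  df
}

test_that("gap and window follow the 50-nt bucket convention", {
  r <- site("t", 100, 108)
  expect_equal(pair_gap_and_window(r, site("t", 120, 127)),
               list(gap = 12L, window = 0L))
  expect_equal(pair_gap_and_window(r, site("t", 200, 207)),
               list(gap = 92L, window = 1L))
  expect_equal(pair_gap_and_window(r, site("t", 20, 27)),
               list(gap = 73L, window = -2L))
  # overlap -> gap 0
  expect_equal(pair_gap_and_window(r, site("t", 104, 111))$gap, 0L)
  expect_error(pair_gap_and_window(r, site("u", 120, 127)), "different")
})

test_that("pair enumeration counts every pair once per window", {
  rbp <- site("t", 100, 108)
  mir <- rbind(site("t", 120, 127, "X"), site("t", 160, 167, "X"))
  pairs <- colocalization_pairs(rbp, mir)
  cnt <- count_colocalized(pairs, "X")
  expect_equal(cnt["X", "0"], 1L)
  expect_equal(cnt["X", "1"], 1L)
  # no shared transcripts -> all zero
  expect_equal(sum(count_colocalized(
    colocalization_pairs(site("a", 1, 9), site("b", 1, 8, "X")), "X")), 0L)
  # two RBP sites flanking one miRNA site -> 2 pairs (enumerated by hand)
  rbp2 <- rbind(site("t", 100, 108), site("t", 140, 148))
  mir2 <- site("t", 113, 120, "X")
  expect_equal(sum(count_colocalized(colocalization_pairs(rbp2, mir2),
                                     "X")), 2L)
  # gap >= 500 is out of range
  far <- site("t", 700, 707, "X")
  expect_equal(sum(count_colocalized(colocalization_pairs(rbp, far),
                                     "X")), 0L)
})

test_that("permutation strata implement the three shuffling schemes", {
  mir <- rbind(site("t1", 50, 57, "A", pattern = "AAUUAAU"),
               site("t1", 950, 957, "B", pattern = "ACGUCGA"),
               site("t2", 120, 127, "C", pattern = "GCGCGCG"))
  lens <- c(t1 = 1000L, t2 = 1000L)
  expect_equal(utrcoop:::permutation_strata(mir, "plain", lens),
               rep("all", 3))
  expect_equal(utrcoop:::permutation_strata(mir, "plain", lens,
                                            chrom = c("c1", "c1", "c2")),
               c("c1", "c1", "c2"))
  expect_equal(utrcoop:::permutation_strata(mir, "by_decile", lens),
               c("0", "9", "1"))
  expect_equal(utrcoop:::permutation_strata(mir, "by_au_category", lens),
               c("1", "2", "3"))
  expect_error(utrcoop:::permutation_strata(mir, "bogus", lens), "unknown")
  # null replicates preserve per-stratum family multisets: total pair mass
  # per stratum is conserved, so a one-family stratum is fixed
  one <- rbind(site("t1", 10, 17, "A", pattern = "GCGCGCG"),
               site("t1", 100, 107, "B", pattern = "AAUUAAU"),
               site("t1", 140, 147, "B", pattern = "AUUAAUU"))
  rbp <- site("t1", 30, 38)
  pairs <- colocalization_pairs(rbp, one)
  nul <- colocalization_null(pairs, one, c("A", "B"), "by_au_category",
                             n = 25L, seed = 4L)
  # A is alone in its AU stratum: its null always equals the observed
  expect_true(all(nul$sum["A", ] / 25 == nul$observed["A", ] + 0))
})

test_that("AU categories split seeds at 6-7 / 3-5 / 0-2 A+U", {
  expect_equal(utrcoop:::seed_au_category(c("AAUUAAU", "ACGUCGA",
                                            "GCGCGCG", "AUAUAUC")),
               c(1L, 2L, 3L, 1L))
})

test_that("empirical p-values follow the tail-proportion definition", {
  expect_equal(empirical_pvalue(5, c(5, 3, 2, 7)), 0.5)
  expect_equal(empirical_pvalue(10, c(1, 2, 3)), 0)
  expect_equal(empirical_pvalue(0, c(0, 1, 2)), 1)
  expect_equal(empirical_pvalue(10, c(1, 2, 3), add_one = TRUE), 1 / 4)
})

test_that("BH q-values match the hand step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.07), 0.07)
})

test_that("sampled empirical p matches full permutation enumeration on a toy", {
  # 5 sites, 2 families, one stratum; exact null by enumerating all 120
  # label permutations
  mir <- rbind(site("t", 10, 17, "A"), site("t", 60, 67, "A"),
               site("t", 200, 207, "B"), site("t", 260, 267, "B"),
               site("t", 400, 407, "B"))
  rbp <- rbind(site("t", 30, 38), site("t", 230, 238))
  lens <- c(t = 1000L)
  pairs <- colocalization_pairs(rbp, mir)
  obs <- count_colocalized(pairs, c("A", "B"))
  perms <- all_strata_perms(mir$family_id, rep("all", 5))
  wi <- pairs$window
  exact_p <- function(fam, w) {
    cnt <- vapply(perms, function(lab)
      sum(lab[pairs$mirna_idx] == fam & wi == w), numeric(1))
    mean(cnt >= obs[fam, as.character(w)])
  }
  nul <- colocalization_null(pairs, mir, c("A", "B"), "plain",
                             n = 4000L, seed = 2L)
  for (fam in c("A", "B")) {
    for (w in c(-1L, 0L)) {
      p_exact <- exact_p(fam, w)
      p_mc <- nul$ge_obs[fam, as.character(w)] / nul$n
      se <- sqrt(p_exact * (1 - p_exact) / 4000)
      expect_lt(abs(p_mc - p_exact), 3 * se + 1e-9)
    }
  }
})

test_that("a single family's null equals the observed counts", {
  mir <- rbind(site("t", 10, 17, "A"), site("t", 60, 67, "A"))
  rbp <- site("t", 30, 38)
  pairs <- colocalization_pairs(rbp, mir)
  nul <- colocalization_null(pairs, mir, "A", "plain", n = 50L, seed = 1L)
  expect_true(all(nul$ge_obs == 50L))
  expect_equal(nul$sum / 50, nul$observed + 0)
})

test_that("window enrichment ratio takes the minimum over schemes", {
  it <- data.frame(
    family_id = "X", seed_type = "m8", window = 0L,
    scheme = c("plain", "by_decile", "by_au_category"),
    observed = 8, null_mean = c(4, 5, 4.5), null_sd = 1,
    p = 0.01, q = 0.02)
  attr(it, "n_perm") <- 100L
  m <- window_enrichment_matrix(it)
  expect_equal(m["X", "0"], 8 / 5)
  # observed 0 with null mean 0 -> ratio 1
  it0 <- it
  it0$observed <- 0
  it0$null_mean <- 0
  expect_equal(window_enrichment_matrix(it0)["X", "0"], 1)
})

test_that("RBP-shuffle enrichment normalizes by the overall ratio", {
  real <- data.frame(transcript_id = "t",
                     mirna_idx = 1L, family_id = "X",
                     gap = c(rep(10L, 20), rep(80L, 80)),
                     window = c(rep(0L, 20), rep(1L, 80)))
  ctrl <- data.frame(transcript_id = "t",
                     mirna_idx = 1L, family_id = "X",
                     gap = c(rep(10L, 10), rep(80L, 90)),
                     window = c(rep(0L, 10), rep(1L, 90)))
  m <- rbp_shuffle_enrichment(real, ctrl, "X")
  expect_equal(m["X", "0"], 2.0)
  # identical tables -> 1 everywhere with pairs
  m2 <- rbp_shuffle_enrichment(real, real, "X")
  expect_true(all(m2[is.finite(m2)] == 1))
  # zero control pairs in a window -> missing
  expect_true(is.na(m["X", "5"]))
})

test_that("proximal fraction counts sites with an RBP neighbor within 50 nt", {
  mir <- do.call(rbind, lapply(0:49, function(i)
    site("t", 20 * i, 20 * i + 7, "X")))
  rbp <- rbind(site("t", 9, 17), site("t", 30, 38))
  # starts 0,20,40,60 are within gap 50 of the site at [9,17): 4/50 = 8%
  expect_equal(proximal_fraction(mir, rbp[1, ]), 8)
  expect_equal(proximal_fraction(mir, rbp[0, , drop = FALSE]), 0)
  expect_error(proximal_fraction(mir[0, ], rbp), "no sites")
  # all sites proximal
  near <- rbind(site("t", 50, 57, "X"), site("t", 70, 77, "X"))
  expect_equal(proximal_fraction(near, site("t", 30, 38)), 100)
})

test_that("planted interacting families are called and off-window enrichment is not", {
  sim <- simulate_dataset(sim_config(seed = 404L, n_utrs = 150L,
                                     n_families = 15L,
                                     sites_per_family = 120L,
                                     planted_interacting_families = 2L))
  ref_seqs <- utr_ref_seqs(sim$utrs)
  rbp_sites <- scan_utr_sites(ref_seqs, sim$rbp_motif)
  mir_sites <- scan_family_sites(ref_seqs, sim$families)
  it <- colocalization_test(rbp_sites, mir_sites, nchar(ref_seqs),
                            n_perm = 500L, seed = 9L)
  calls <- call_interacting_mirnas(it)
  planted <- sim$truth$planted_families
  expect_gte(length(intersect(calls, planted)), 1L)
  expect_lte(length(setdiff(calls, planted)), 1L)
  # q >= p within every scheme/window batch
  expect_true(all(it$q >= it$p - 1e-12))
  # intersection rule: flooring one scheme's q above the threshold
  # removes the family
  it2 <- it
  sel <- it2$family_id == calls[1] & it2$scheme == "by_au_category"
  it2$q[sel] <- 1
  expect_false(calls[1] %in% call_interacting_mirnas(it2))
})
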