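# Branch length scores, conserved-species detection, shuffled-motif
# controls, precision curves and the gating rule.

test_that("branch length score matches hand-enumerated subtrees", {
  tr <- tree4()
  expect_equal(branch_length_score(tr, c("Ref", "S1")), 2 / 6)
  expect_equal(branch_length_score(tr, "Ref"), 0)
  expect_equal(branch_length_score(tr, tr$tip.label), 1)
  expect_error(branch_length_score(tr, character(0)), "empty")
  expect_error(branch_length_score(tr, c("Ref", "nope")), "not in tree")
})

test_that("BLS equals brute-force spanning-subtree enumeration on all subsets", {
  set.seed(31)
  for (rep in 1:4) {
    tr <- ape::rcoal(6, tip.label = paste0("s", 1:6))
    tips <- tr$tip.label
    for (k in 2:6) {
      subsets <- utils::combn(tips, k, simplify = FALSE)
      for (ss in subsets) {
        expect_equal(branch_length_score(tr, ss), brute_bls(tr, ss),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("BLS is monotone under adding species", {
  set.seed(5)
  tr <- ape::rcoal(8, tip.label = paste0("s", 1:8))
  for (rep in 1:20) {
    ss <- sample(tr$tip.label, sample(1:7, 1))
    extra <- sample(setdiff(tr$tip.label, ss), 1)
    expect_gte(branch_length_score(tr, c(ss, extra)),
               branch_length_score(tr, ss))
  }
})

test_that("conserved species are found within the +/-10 nt window", {
  pum <- parse_motif_consensus("UGUANAUA", "PUM")
  bg <- function(n) strrep("C", n)
  site <- "UGUAAAUA"
  # reference hit at 20; S1 shifted +3; S2 shifted +15; S3 no hit
  mk_row <- function(offset, has = TRUE) {
    paste0(bg(20 + offset), if (has) site else bg(8), bg(32 - offset))
  }
  block <- make_block(c(Ref = mk_row(0), S1 = mk_row(3),
                        S2 = mk_row(15), S3 = mk_row(0, has = FALSE)))
  got <- conserved_species_for_hit(block, 20L, pum, tree4())
  expect_setequal(got, c("Ref", "S1"))
  # shifting beyond the window drops the species
  block2 <- make_block(c(Ref = mk_row(0), S1 = mk_row(15),
                         S2 = mk_row(15, has = FALSE),
                         S3 = mk_row(0, has = FALSE)))
  expect_setequal(conserved_species_for_hit(block2, 20L, pum, tree4()),
                  "Ref")
  expect_error(conserved_species_for_hit(
    make_block(c(Ref = mk_row(0), SX = mk_row(0))), 20L, pum, tree4()),
    "absent from tree")
})

test_that("a lone distant hit is pruned by the gap/distance rule", {
  pum <- parse_motif_consensus("UGUANAUA", "PUM")
  # caterpillar tree: S3 is much farther from Ref than S1/S2
  tr <- ape::read.tree(text = "(((Ref:0.1,S1:0.1):0.1,S2:0.2):1.8,S3:2);")
  bg <- function(n) strrep("C", n)
  site <- "UGUAAAUA"
  row_hit <- paste0(bg(20), site, bg(32))
  row_no <- bg(60)
  # only the farthest species S3 shares the hit; S1 and S2 (2 of 4 aligned
  # genomes, more than one-third) lack it; d(S3) > 2 * d(second = Ref-only)
  block <- make_block(c(Ref = row_hit, S1 = row_no, S2 = row_no,
                        S3 = row_hit))
  expect_setequal(conserved_species_for_hit(block, 20L, pum, tr), "Ref")
  # with an intermediate conserved species the distance ratio fails and the
  # far species is kept
  block2 <- make_block(c(Ref = row_hit, S1 = row_no, S2 = row_hit,
                         S3 = row_hit))
  expect_true("S3" %in% conserved_species_for_hit(block2, 20L, pum, tr))
})

test_that("planted conservation subsets are recovered exactly", {
  cfg <- sim_config(seed = 77L, n_utrs = 10L, n_families = 3L,
                    sites_per_family = 2L,
                    planted_interacting_families = 0L,
                    rbp_rate = 0, utr_meanlog = log(400),
                    planted_conservation = list(
                      list(pattern = "UGCAUGU", n = 6L,
                           species = c("sp2", "sp3"))))
  sim <- simulate_dataset(cfg)
  fox <- parse_motif_consensus("UGCAUGU", "Fox")
  cons <- sim$truth$conservation_sites
  expect_equal(nrow(cons), 6L)
  for (i in seq_len(nrow(cons))) {
    got <- conserved_species_for_hit(sim$utrs[[cons$transcript_id[i]]],
                                     cons$start[i], fox, sim$tree)
    expect_setequal(got, c("ref", "sp2", "sp3"))
    expect_equal(
      branch_length_score(sim$tree, got),
      branch_length_score(sim$tree, c("ref", "sp2", "sp3")))
  }
})

test_that("motif similarity is symmetric, self-maximal and 0 for disjoint", {
  m1 <- parse_motif_consensus("UGUA")
  expect_equal(motif_similarity(m1, m1), 1.0)
  m2 <- parse_motif_consensus("AAAA")
  m3 <- parse_motif_consensus("CCCC")
  expect_equal(motif_similarity(m2, m3), 0.0)
  set.seed(9)
  for (rep in 1:10) {
    a <- parse_motif_consensus(random_rna(8))
    b <- parse_motif_consensus(random_rna(8))
    expect_equal(motif_similarity(a, b), motif_similarity(b, a))
    expect_lte(motif_similarity(a, b), motif_similarity(a, a) + 1e-12)
  }
})

test_that("control motifs are anagrams, deterministic, and homopolymers are ineligible", {
  pum <- parse_motif_consensus("UGUANAUA", "PUM")
  c1 <- generate_control_motifs(pum, seed = 3L)
  expect_true(c1$eligible)
  expect_gte(length(c1$motifs), 3L)
  canon_sorted <- paste(sort(strsplit(pum$pattern, "")[[1]]),
                        collapse = "")
  for (m in c1$motifs) {
    expect_equal(paste(sort(strsplit(m$pattern, "")[[1]]), collapse = ""),
                 canon_sorted)
    expect_false(m$pattern == pum$pattern)
  }
  c2 <- generate_control_motifs(pum, seed = 3L)
  expect_identical(vapply(c1$motifs, `[[`, character(1), "pattern"),
                   vapply(c2$motifs, `[[`, character(1), "pattern"))
  u7 <- parse_motif_consensus("UUUUUUU", "polyU")
  expect_false(generate_control_motifs(u7, seed = 1L)$eligible)
})

test_that("precision formula and gating behave as specified", {
  # canonical 100 hits at BLS >= 0, shuffled mean 40 -> precision 0.6
  canon <- rep(0, 100)
  shuf <- list(rep(0, 40), rep(0, 40))
  pc <- precision_curve(canon, shuf)
  expect_equal(pc$precision[1], 0.6)
  expect_equal(precision_curve(canon, list(numeric(0)))$precision[1], 1.0)
  expect_equal(precision_curve(canon, list(rep(0, 100)))$precision[1], 0.0)
  # canonical counts are non-increasing in threshold
  set.seed(2)
  pc2 <- precision_curve(runif(200), list(runif(80), runif(90)))
  expect_true(all(diff(pc2$canonical_count) <= 0))
  # gate: needs precision >= 0.6 with more than 10 hits at some threshold
  expect_true(gate_rbp_motif(precision_curve(rep(0.5, 50),
                                             list(rep(0, 10)))))
  expect_false(gate_rbp_motif(precision_curve(rep(0.5, 50),
                                              list(rep(0.5, 30)))))
  # high precision but too few hits fails
  expect_false(gate_rbp_motif(precision_curve(rep(0.9, 8),
                                              list(numeric(0)))))
})

test_that("hits conserved only in the reference score 0 but count at threshold 0", {
  pc <- precision_curve(c(0, 0, 0.5), list(c(0, 0.2)))
  expect_equal(pc$canonical_count[1], 3L)
  expect_equal(pc$canonical_count[52], 0L)  # threshold 0.51
})

test_that("precision of a motif against its own shuffles is near 0 on random sequence", {
  set.seed(123)
  # 200 kb of uniform random sequence; shuffles preserve composition so
  # expected hit counts are identical and precision should be ~0
  utr <- setNames(vapply(1:200, function(i) random_rna(1000),
                         character(1)), paste0("t", 1:200))
  m <- parse_motif_consensus("WWCGWW", "test")
  ctrl <- generate_control_motifs(m, utr, seed = 4L)
  expect_gte(length(ctrl$motifs), 5L)
  canon_hits <- nrow(scan_utr_sites(utr, m))
  shuf_hits <- vapply(ctrl$motifs, function(cm)
    nrow(scan_utr_sites(utr, cm)), numeric(1))
  prec <- 1 - mean(shuf_hits) / canon_hits
  expect_lt(abs(prec), 0.1)
})
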