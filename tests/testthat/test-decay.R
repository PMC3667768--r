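# Transcript grouping, expression filtering and group comparisons.

dsite <- function(tx, start, end, fam = NULL) {
  df <- data.frame(transcript_id = tx, start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  if (!is.null(fam)) df$family_id <- fam
  df
}

test_that("the expression filter keeps the top quartile with ties", {
  tab <- data.frame(family_id = c("A", "B", "C", "D"),
                    reads = c(100L, 10L, 1L, 0L))
  expect_equal(filter_expressed_mirnas(tab), "A")
  tab2 <- data.frame(family_id = letters[1:4], reads = rep(5L, 4))
  expect_setequal(filter_expressed_mirnas(tab2), letters[1:4])
  tab3 <- data.frame(family_id = letters[1:8], reads = 8:1)
  expect_setequal(filter_expressed_mirnas(tab3), c("a", "b"))
  expect_error(filter_expressed_mirnas(tab3[0, ]), "nrow")
})

test_that("transcripts are classified with interacting/proximal precedence", {
  rbp <- dsite("t1", 100, 108)
  mir <- rbind(dsite("t1", 130, 137, "int"),    # gap 22 -> proximal
               dsite("t1", 500, 507, "non"))
  cls <- function(mirs, inter = "int") {
    classify_transcripts_by_pairing(rbp, mirs, inter,
                                    c("int", "non"), "t1")$group
  }
  expect_equal(as.character(cls(mir)), "Int-proximal")
  # interacting site distant only
  mir2 <- rbind(dsite("t1", 300, 307, "int"), dsite("t1", 120, 127, "non"))
  expect_equal(as.character(cls(mir2)), "Int-distant")
  # only a non-interacting site, proximal
  mir3 <- dsite("t1", 130, 137, "non")
  expect_equal(as.character(cls(mir3)), "Nonint-proximal")
  mir4 <- dsite("t1", 400, 407, "non")
  expect_equal(as.character(cls(mir4)), "Nonint-distant")
  # no RBP site, or unexpressed family -> unclassified
  norbp <- classify_transcripts_by_pairing(rbp[0, ], mir, "int",
                                           c("int", "non"), "t1")
  expect_equal(as.character(norbp$group), "unclassified")
  unexpr <- classify_transcripts_by_pairing(rbp, mir, "int",
                                            character(0), "t1")
  expect_equal(as.character(unexpr$group), "unclassified")
})

test_that("group comparisons report box statistics and exact rank-sum p", {
  res <- compare_group_values(list("Int-proximal" = c(1, 2),
                                   "Int-distant" = c(3, 4),
                                   "Nonint-proximal" = c(1, 2)),
                              pairings = list(
                                c("Int-proximal", "Int-distant"),
                                c("Int-proximal", "Nonint-proximal")))
  # {1,2} vs {3,4}: 2 of 6 rank splits are as extreme two-sided -> 1/3
  expect_equal(res$tests$p[1], 1 / 3)
  expect_equal(res$tests$p[2], 1)
  med <- res$summary$median[res$summary$group == "Int-distant"]
  expect_equal(med, 3.5)
  # groups with < 2 values are skipped and flagged
  res2 <- compare_group_values(list(A = 1, B = c(2, 3)),
                               pairings = list(c("A", "B")))
  expect_true(res2$tests$skipped[1])
  expect_true(is.na(res2$tests$p[1]))
})

test_that("summary quantiles and whiskers match brute-force values", {
  set.seed(8)
  v <- rlnorm(101, 2, 0.7)
  s <- compare_group_values(list(g = v), pairings = list())$summary
  expect_equal(s$median, median(v))
  expect_equal(s$q25, quantile(v, 0.25, names = FALSE))
  iqr <- s$q75 - s$q25
  expect_true(all(v[v >= s$q25 - 1.5 * iqr] >= s$whisker_lo))
  expect_equal(s$whisker_hi, max(v[v <= s$q75 + 1.5 * iqr]))
})

test_that("AU-control groups are re-derivable from their site tables", {
  rbp <- dsite("t1", 100, 108)
  int_mir <- dsite("t1", 130, 137, "int")
  ctrl_rbp <- dsite("t2", 50, 58)
  ctrl_mir <- rbind(dsite("t1", 600, 607), dsite("t3", 10, 17))
  g <- au_control_decay_groups(rbp, int_mir, ctrl_rbp, ctrl_mir)
  expect_equal(g$Real, "t1")
  expect_equal(g$miR_control, character(0))  # control sites are distant
  expect_equal(g$RBP_control, character(0))
  ctrl_mir2 <- dsite("t1", 120, 127)
  g2 <- au_control_decay_groups(rbp, int_mir, ctrl_rbp, ctrl_mir2)
  expect_equal(g2$miR_control, "t1")
})

test_that("site-level conservation buckets partition the RBP sites", {
  rbp <- rbind(dsite("t1", 100, 108), dsite("t1", 600, 608),
               dsite("t2", 10, 18))
  rbp$bls <- c(0.8, 0.3, 0.5)
  mir <- rbind(dsite("t1", 130, 137, "int"), dsite("t2", 500, 507, "non"))
  res <- site_conservation_by_group(rbp, mir, "int", c("int", "non"))
  grp <- as.character(res$assignments$group)
  expect_equal(grp, c("Int-proximal", "Int-distant", "Nonint-distant"))
  expect_equal(sum(lengths(res$bls_by_group)), nrow(rbp))
  expect_equal(res$bls_by_group[["Int-proximal"]], 0.8)
})

test_that("planted high-conservation proximal sites give a higher median bucket", {
  # sites proximal to an interacting family planted at BLS 0.8, distant at 0.3
  set.seed(21)
  n <- 30L
  rbp <- do.call(rbind, lapply(seq_len(2 * n), function(i)
    dsite(paste0("t", i), 100, 108)))
  rbp$bls <- c(rep(0.8, n) + rnorm(n, 0, 0.02),
               rep(0.3, n) + rnorm(n, 0, 0.02))
  mir <- do.call(rbind, lapply(seq_len(2 * n), function(i) {
    if (i <= n) dsite(paste0("t", i), 130, 137, "int")
    else dsite(paste0("t", i), 400, 407, "int")
  }))
  res <- site_conservation_by_group(rbp, mir, "int", "int")
  cmp <- compare_group_values(res$bls_by_group,
                              pairings = list(c("Int-proximal",
                                                "Int-distant")))
  med <- setNames(cmp$summary$median, cmp$summary$group)
  expect_gt(med["Int-proximal"], med["Int-distant"])
  expect_lt(cmp$tests$p[1], 1e-6)
})

test_that("a planted 0.7x half-life effect is detected between proximity groups", {
  set.seed(12)
  hl_prox <- rlnorm(90, log(8 * 0.7), 0.5)
  hl_dist <- rlnorm(90, log(8), 0.5)
  cmp <- compare_group_values(list("Int-proximal" = hl_prox,
                                   "Int-distant" = hl_dist),
                              pairings = list(c("Int-proximal",
                                                "Int-distant")))
  expect_lt(cmp$tests$p[1], 0.05)
})

test_that("null group comparisons reject at about the nominal 5% rate", {
  set.seed(44)
  rejections <- vapply(1:60, function(i) {
    a <- rlnorm(40, log(8), 0.5)
    b <- rlnorm(40, log(8), 0.5)
    compare_group_values(list(x = a, y = b),
                         pairings = list(c("x", "y")))$tests$p[1] < 0.05
  }, logical(1))
  rate <- mean(rejections)
  se <- sqrt(0.05 * 0.95 / 60)
  expect_lte(rate, 0.05 + 3 * se)
})
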