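# Four-group transcript classification by RBP/miRNA site pairing, expression
# filtering, and half-life / decay-rate / site-conservation comparisons.

GROUP_LEVELS <- c("Int-proximal", "Int-distant", "Nonint-proximal",
                  "Nonint-distant", "unclassified")

#' Filter miRNA families by expression
#'
#' Families in the top `quantile` fraction by read count are "expressed".
#' The rank cutoff is `ceiling(quantile * n)` and ties at the cutoff count
#' are all included.
#'
#' @param expression data.frame with columns `family_id` and `reads` (or any
#'   second numeric column).
#' @param quantile Fraction of families kept (default 0.25).
#' @return Character vector of expressed family ids.
#' @export
filter_expressed_mirnas <- function(expression, quantile = 0.25) {
  stopifnot(nrow(expression) > 0L)
  counts <- if ("reads" %in% names(expression)) expression$reads
            else expression[[2]]
  stopifnot(all(counts >= 0))
  k <- max(1L, ceiling(quantile * nrow(expression)))
  cutoff <- sort(counts, decreasing = TRUE)[k]
  sort(expression$family_id[counts >= cutoff])
}

# Minimum gap between any RBP site and any miRNA site on one transcript.
min_pair_gap <- function(rbp_sub, mir_sub) {
  if (nrow(rbp_sub) == 0L || nrow(mir_sub) == 0L) return(Inf)
  g <- Inf
  for (i in seq_len(nrow(rbp_sub))) {
    gw <- gap_window_vec(rbp_sub$start[i], rbp_sub$end[i],
                         mir_sub$start, mir_sub$end)
    g <- min(g, gw$gap)
  }
  g
}

#' Classify transcripts by RBP/miRNA site pairing
#'
#' Four categories per transcript: `Int-proximal` (an RBP site and an
#' expressed interacting-family site within `max_gap`), `Int-distant` (both
#' present but never within `max_gap`), `Nonint-proximal` / `Nonint-distant`
#' (same with non-interacting expressed families, for transcripts without
#' expressed interacting sites), `unclassified` (no RBP site or no expressed
#' miRNA site).  Interacting status takes precedence over non-interacting,
#' proximal over distant.
#'
#' @param rbp_sites Site table for the RBP.
#' @param mirna_sites Site table with `family_id`.
#' @param interacting_families Families called interacting for this RBP.
#' @param expressed_families Families passing the expression filter.
#' @param transcripts All transcript ids to classify.
#' @param max_gap Proximity threshold (default 50 nt).
#' @return data.frame: `transcript_id`, `group` (factor with the five
#'   levels).
#' @export
classify_transcripts_by_pairing <- function(rbp_sites, mirna_sites,
                                            interacting_families,
                                            expressed_families,
                                            transcripts, max_gap = 50L) {
  mir <- mirna_sites[mirna_sites$family_id %in% expressed_families, ,
                     drop = FALSE]
  int_mir <- mir[mir$family_id %in% interacting_families, , drop = FALSE]
  non_mir <- mir[!(mir$family_id %in% interacting_families), , drop = FALSE]
  rbp_by_tx <- split(rbp_sites, rbp_sites$transcript_id)
  int_by_tx <- split(int_mir, int_mir$transcript_id)
  non_by_tx <- split(non_mir, non_mir$transcript_id)
  group <- vapply(transcripts, function(tx) {
    r <- rbp_by_tx[[tx]]
    if (is.null(r)) return("unclassified")
    im <- int_by_tx[[tx]]
    nm <- non_by_tx[[tx]]
    if (!is.null(im)) {
      if (min_pair_gap(r, im) <= max_gap) return("Int-proximal")
      return("Int-distant")
    }
    if (!is.null(nm)) {
      if (min_pair_gap(r, nm) <= max_gap) return("Nonint-proximal")
      return("Nonint-distant")
    }
    "unclassified"
  }, character(1))
  data.frame(transcript_id = transcripts,
             group = factor(group, levels = GROUP_LEVELS),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Exact two-sided mid-rank permutation p-value for a rank-sum comparison
# (used for small samples where ties make the distribution-based test
# approximate).
ranksum_perm_p <- function(x, y, alternative = "two.sided") {
  all_v <- c(x, y)
  r <- rank(all_v)
  nx <- length(x)
  obs <- sum(r[seq_len(nx)])
  idx <- utils::combn(length(all_v), nx)
  sums <- colSums(matrix(r[idx], nrow = nx))
  mu <- nx * (length(all_v) + 1) / 2
  switch(alternative,
         two.sided = mean(abs(sums - mu) >= abs(obs - mu) - 1e-9),
         greater = mean(sums >= obs - 1e-9),
         less = mean(sums <= obs + 1e-9))
}

# Rank-sum p with exact enumeration for small samples, otherwise
# stats::wilcox.test.
ranksum_p <- function(x, y, alternative = "two.sided", exact_max = 12L) {
  if (length(x) + length(y) <= exact_max) {
    return(ranksum_perm_p(x, y, alternative))
  }
  suppressWarnings(stats::wilcox.test(x, y,
                                      alternative = alternative)$p.value)
}

#' Compare value distributions across transcript groups
#'
#' Box-plot summaries (median, quartiles, 1.5 x IQR whisker bounds) per
#' group and two-sided rank-sum p-values for the requested pairings on the
#' full data.  Groups with fewer than 2 values are summarized but their
#' comparisons are skipped (p = NA, flagged).
#'
#' @param values_by_group Named list of numeric vectors.
#' @param pairings List of 2-element character vectors; defaults to the two
#'   headline contrasts Int-proximal vs Nonint-proximal and Int-proximal vs
#'   Int-distant.
#' @return List with `summary` (data.frame per group) and `tests`
#'   (data.frame per pairing: `group1`, `group2`, `p`, `skipped`).
#' @export
compare_group_values <- function(values_by_group,
                                 pairings = list(
                                   c("Int-proximal", "Nonint-proximal"),
                                   c("Int-proximal", "Int-distant"))) {
  summ <- do.call(rbind, lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    if (length(v) == 0L) {
      return(data.frame(group = g, n = 0L, median = NA_real_,
                        q25 = NA_real_, q75 = NA_real_,
                        whisker_lo = NA_real_, whisker_hi = NA_real_))
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lo <- min(v[v >= q[1] - 1.5 * iqr])
    hi <- max(v[v <= q[3] + 1.5 * iqr])
    data.frame(group = g, n = length(v), median = q[2], q25 = q[1],
               q75 = q[3], whisker_lo = lo, whisker_hi = hi)
  }))
  tests <- do.call(rbind, lapply(pairings, function(pr) {
    x <- values_by_group[[pr[1]]]
    y <- values_by_group[[pr[2]]]
    skipped <- is.null(x) || is.null(y) || length(x) < 2L || length(y) < 2L
    p <- if (skipped) NA_real_ else ranksum_p(x, y)
    data.frame(group1 = pr[1], group2 = pr[2], p = p, skipped = skipped)
  }))
  list(summary = summ, tests = tests)
}

#' AU-content control groups for the decay comparison
#'
#' Three transcript groups built from real and composition-matched shuffled
#' motif sites: `Real` (real RBP site + real interacting-family site within
#' `max_gap`), `miR_control` (real RBP site + shuffled-miRNA-motif site),
#' and `RBP_control` (shuffled-RBP-motif site + real interacting site).
#'
#' @param rbp_sites Real RBP site table.
#' @param int_mirna_sites Real interacting-family site table.
#' @param ctrl_rbp_sites Sites of shuffled RBP motifs.
#' @param ctrl_mirna_sites Sites of shuffled interacting-miRNA motifs.
#' @param max_gap Proximity threshold.
#' @return Named list of transcript-id character vectors
#'   (`Real`, `miR_control`, `RBP_control`).
#' @export
au_control_decay_groups <- function(rbp_sites, int_mirna_sites,
                                    ctrl_rbp_sites, ctrl_mirna_sites,
                                    max_gap = 50L) {
  proximal_tx <- function(a_sites, b_sites) {
    tx <- intersect(unique(a_sites$transcript_id),
                    unique(b_sites$transcript_id))
    a_by <- split(a_sites, a_sites$transcript_id)
    b_by <- split(b_sites, b_sites$transcript_id)
    tx[vapply(tx, function(t)
      min_pair_gap(a_by[[t]], b_by[[t]]) <= max_gap, logical(1))]
  }
  list(Real = proximal_tx(rbp_sites, int_mirna_sites),
       miR_control = proximal_tx(rbp_sites, ctrl_mirna_sites),
       RBP_control = proximal_tx(ctrl_rbp_sites, int_mirna_sites))
}

#' Site-level conservation by miRNA proximity class
#'
#' Classifies individual RBP sites (not transcripts) by whether an expressed
#' interacting-family or non-interacting-family site lies within `max_gap`,
#' using the same precedence as the transcript classification, and returns
#' the BLS values per class.
#'
#' @param rbp_sites RBP site table with a `bls` column.
#' @param mirna_sites miRNA site table with `family_id`.
#' @param interacting_families,expressed_families Family sets.
#' @param max_gap Proximity threshold.
#' @return List with `assignments` (rbp_sites plus `group`) and
#'   `bls_by_group` (named list of numeric vectors).
#' @export
site_conservation_by_group <- function(rbp_sites, mirna_sites,
                                       interacting_families,
                                       expressed_families, max_gap = 50L) {
  stopifnot("bls" %in% names(rbp_sites))
  mir <- mirna_sites[mirna_sites$family_id %in% expressed_families, ,
                     drop = FALSE]
  int_mir <- mir[mir$family_id %in% interacting_families, , drop = FALSE]
  non_mir <- mir[!(mir$family_id %in% interacting_families), , drop = FALSE]
  int_by_tx <- split(int_mir, int_mir$transcript_id)
  non_by_tx <- split(non_mir, non_mir$transcript_id)
  group <- vapply(seq_len(nrow(rbp_sites)), function(i) {
    site <- rbp_sites[i, , drop = FALSE]
    im <- int_by_tx[[site$transcript_id]]
    nm <- non_by_tx[[site$transcript_id]]
    if (!is.null(im)) {
      if (min_pair_gap(site, im) <= max_gap) return("Int-proximal")
      return("Int-distant")
    }
    if (!is.null(nm)) {
      if (min_pair_gap(site, nm) <= max_gap) return("Nonint-proximal")
      return("Nonint-distant")
    }
    "unclassified"
  }, character(1))
  out <- rbp_sites
  out$group <- factor(group, levels = GROUP_LEVELS)
  list(assignments = out,
       bls_by_group = split(out$bls, out$group))
}
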