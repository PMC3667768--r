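# Permutation-based co-localization of RBP and miRNA seed-match sites:
# proximal-pair counting, three identity-shuffling null schemes, empirical
# p-values, BH FDR and interacting-miRNA calls.

N_WINDOWS_PER_SIDE <- 10L
WINDOW_NT <- 50L

#' Gap and signed window of an RBP/miRNA site pair
#'
#' Edge-to-edge gap in nucleotides (overlapping sites get gap 0) and the
#' signed 50-nt window index: window `w >= 0` (miRNA downstream of the RBP
#' site) covers gaps `[50w, 50(w+1))`; window `w < 0` (miRNA upstream)
#' covers gaps `[50(|w|-1), 50|w|)`.  A pair is "proximal" when its gap is
#' at most 50 nt.
#'
#' @param rbp_site,mirna_site Lists or one-row data.frames with
#'   `transcript_id`, `start`, `end`.
#' @return List with `gap` and `window`.
#' @export
pair_gap_and_window <- function(rbp_site, mirna_site) {
  if (!identical(as.character(rbp_site$transcript_id),
                 as.character(mirna_site$transcript_id))) {
    stop("sites are on different transcripts")
  }
  gw <- gap_window_vec(rbp_site$start, rbp_site$end,
                       mirna_site$start, mirna_site$end)
  list(gap = gw$gap, window = gw$window)
}

# Vectorized gap/window computation.
gap_window_vec <- function(rbp_start, rbp_end, mir_start, mir_end) {
  downstream <- mir_start >= rbp_start
  gap <- ifelse(downstream,
                pmax(0L, mir_start - rbp_end),
                pmax(0L, rbp_start - mir_end))
  w <- gap %/% WINDOW_NT
  window <- ifelse(downstream, w, -(w + 1L))
  list(gap = as.integer(gap), window = as.integer(window))
}

#' Enumerate proximal-pair records between RBP and miRNA site tables
#'
#' Every (RBP site, miRNA site) pair on a shared transcript with gap below
#' `max_gap` (ten 50-nt windows per side) contributes one record; pairs are
#' never deduplicated.
#'
#' @param rbp_sites Site-call data.frame for one RBP motif.
#' @param mirna_sites Site-call data.frame with additional columns
#'   `family_id` (and typically `seed_type`); row order defines the site
#'   index used by the permutation null.
#' @param max_gap Maximum gap considered (default 500 nt).
#' @return data.frame: `transcript_id`, `mirna_idx` (row of `mirna_sites`),
#'   `family_id`, `gap`, `window`.
#' @export
colocalization_pairs <- function(rbp_sites, mirna_sites, max_gap = 500L) {
  empty <- data.frame(transcript_id = character(0), mirna_idx = integer(0),
                      family_id = character(0), gap = integer(0),
                      window = integer(0), stringsAsFactors = FALSE)
  if (nrow(rbp_sites) == 0L || nrow(mirna_sites) == 0L) return(empty)
  mir_by_tx <- split(seq_len(nrow(mirna_sites)), mirna_sites$transcript_id)
  out <- vector("list", nrow(rbp_sites))
  for (i in seq_len(nrow(rbp_sites))) {
    mi <- mir_by_tx[[rbp_sites$transcript_id[i]]]
    if (is.null(mi)) next
    gw <- gap_window_vec(rbp_sites$start[i], rbp_sites$end[i],
                         mirna_sites$start[mi], mirna_sites$end[mi])
    keep <- gw$gap < max_gap
    if (!any(keep)) next
    out[[i]] <- data.frame(
      transcript_id = rbp_sites$transcript_id[i],
      mirna_idx = mi[keep],
      family_id = mirna_sites$family_id[mi[keep]],
      gap = gw$gap[keep], window = gw$window[keep],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res
}

#' Observed co-localization counts per (family, window)
#'
#' @param pairs Pair records from [colocalization_pairs()].
#' @param families Character vector of all family ids (fixes the table
#'   layout even for families with zero pairs).
#' @return Integer matrix, families x 20 windows (-10..-1, 0..9).
#' @export
count_colocalized <- function(pairs, families) {
  windows <- c(-N_WINDOWS_PER_SIDE:-1L, 0:(N_WINDOWS_PER_SIDE - 1L))
  m <- matrix(0L, nrow = length(families), ncol = length(windows),
              dimnames = list(families, as.character(windows)))
  if (nrow(pairs) > 0L) {
    fi <- match(pairs$family_id, families)
    wi <- match(pairs$window, windows)
    ok <- !is.na(fi) & !is.na(wi)
    t <- table(factor(fi[ok], levels = seq_along(families)),
               factor(wi[ok], levels = seq_along(windows)))
    m[] <- as.integer(t)
  }
  m
}

# AU category of a 7-nt seed pattern by its A/U count: 1 = high (6-7),
# 2 = medium (3-5), 3 = low (0-2).
seed_au_category <- function(pattern) {
  au <- vapply(strsplit(toupper(pattern), ""), function(l)
    sum(l %in% c("A", "U", "W")), numeric(1))
  ifelse(au >= 6, 1L, ifelse(au >= 3, 2L, 3L))
}

# Stratum labels for identity permutation under the three schemes.
permutation_strata <- function(mirna_sites, scheme, utr_lengths = NULL,
                               chrom = NULL) {
  n <- nrow(mirna_sites)
  switch(scheme,
    plain = {
      if (is.null(chrom)) rep("all", n) else as.character(chrom)
    },
    by_decile = {
      stopifnot(!is.null(utr_lengths))
      L <- utr_lengths[mirna_sites$transcript_id]
      as.character(pmin(9L, as.integer(floor(10 * mirna_sites$start / L))))
    },
    by_au_category = {
      pat <- if ("pattern" %in% names(mirna_sites)) {
        mirna_sites$pattern
      } else {
        stop("by_au_category scheme needs a 'pattern' column on mirna_sites")
      }
      as.character(seed_au_category(substr(pat, 1L, 7L)))
    },
    stop("unknown permutation scheme: ", scheme)
  )
}

#' Null co-localization counts under miRNA identity permutation
#'
#' Keeps every site position fixed and permutes family identities within
#' strata: `plain` permutes within chromosome (or one global stratum),
#' `by_decile` within the 3'UTR decile of the site, and `by_au_category`
#' within AU-content categories of the 7-nt seed (6-7, 3-5, 0-2 A/U
#' nucleotides).  Per-stratum family label multisets are preserved in every
#' replicate.
#'
#' @param pairs Pair records from [colocalization_pairs()] computed on the
#'   real labels.
#' @param mirna_sites The site table the pairs index into.
#' @param families All family ids.
#' @param scheme One of `"plain"`, `"by_decile"`, `"by_au_category"`.
#' @param n Number of permutation replicates.
#' @param seed Integer seed.
#' @param utr_lengths Named lengths (needed for `by_decile`).
#' @param chrom Optional per-site chromosome/batch labels for `plain`.
#' @return List: `ge_obs` (matrix of counts of replicates with null >=
#'   observed), `sum`, `sumsq` (per-cell accumulators), `n`, `observed`.
#' @export
colocalization_null <- function(pairs, mirna_sites, families, scheme,
                                n = 10000L, seed = 1L, utr_lengths = NULL,
                                chrom = NULL) {
  observed <- count_colocalized(pairs, families)
  strata <- permutation_strata(mirna_sites, scheme, utr_lengths, chrom)
  fam_idx <- match(mirna_sites$family_id, families)
  windows <- as.integer(colnames(observed))
  wi <- match(pairs$window, windows)
  si <- pairs$mirna_idx
  nf <- length(families); nw <- length(windows)
  ge <- matrix(0L, nf, nw, dimnames = dimnames(observed))
  s1 <- matrix(0, nf, nw, dimnames = dimnames(observed))
  s2 <- matrix(0, nf, nw, dimnames = dimnames(observed))
  strata_idx <- split(seq_len(nrow(mirna_sites)), strata)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  obs_vec <- as.vector(observed)
  cell <- (wi - 1L) * nf  # add fam index for the flat cell id
  for (r in seq_len(n)) {
    lab <- fam_idx
    for (idx in strata_idx) {
      if (length(idx) > 1L) lab[idx] <- lab[idx][sample.int(length(idx))]
    }
    cnt <- tabulate(cell + lab[si], nbins = nf * nw)
    ge <- ge + (cnt >= obs_vec)
    s1 <- s1 + cnt
    s2 <- s2 + cnt^2
  }
  list(ge_obs = ge, sum = s1, sumsq = s2, n = n, observed = observed,
       scheme = scheme)
}

#' Empirical p-value from null counts
#'
#' Default is the raw proportion of null replicates with a count at least
#' as large as the observed one; `add_one = TRUE` uses the (k+1)/(n+1)
#' smoothed estimator (raw zeros make BH degenerate).
#'
#' @param observed Observed count (scalar).
#' @param null_counts Numeric vector of null replicate counts.
#' @param add_one Use add-one smoothing.
#' @return p-value in \[0, 1\].
#' @export
empirical_pvalue <- function(observed, null_counts, add_one = FALSE) {
  stopifnot(length(null_counts) >= 1L)
  k <- sum(null_counts >= observed)
  if (add_one) (k + 1) / (length(null_counts) + 1) else k / length(null_counts)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up q-values (monotone in sorted order).
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return q-values, same order as input.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Full co-localization test for one RBP
#'
#' Runs the observed pair counting and all three permutation null schemes
#' for each seed type, computes empirical p-values and BH q-values (across
#' families, within each scheme x seed type x window batch), and per-cell
#' enrichment ratios.
#'
#' @param rbp_sites Site table for the RBP motif.
#' @param mirna_sites Site table with `family_id`, `seed_type`
#'   (`"m8"`/`"1a"`) and `pattern` columns.
#' @param utr_lengths Named reference UTR lengths.
#' @param n_perm Permutation replicates per scheme.
#' @param seed Integer seed (scheme r uses `seed + r`).
#' @param schemes Null schemes to run.
#' @param chrom Optional per-site stratum labels for the plain scheme.
#' @param add_one Use add-one smoothing in empirical p-values.
#' @return data.frame of class `interaction_table` with one row per
#'   (family, seed_type, window, scheme): `observed`, `null_mean`,
#'   `null_sd`, `p`, `q`.
#' @export
colocalization_test <- function(rbp_sites, mirna_sites, utr_lengths,
                                n_perm = 10000L, seed = 1L,
                                schemes = c("plain", "by_decile",
                                            "by_au_category"),
                                chrom = NULL, add_one = FALSE) {
  stopifnot(all(c("family_id", "seed_type") %in% names(mirna_sites)))
  families <- sort(unique(mirna_sites$family_id))
  rows <- list()
  for (st in sort(unique(mirna_sites$seed_type))) {
    sites_st <- mirna_sites[mirna_sites$seed_type == st, , drop = FALSE]
    chrom_st <- if (!is.null(chrom)) chrom[mirna_sites$seed_type == st]
    pairs <- colocalization_pairs(rbp_sites, sites_st)
    for (k in seq_along(schemes)) {
      nul <- colocalization_null(pairs, sites_st, families, schemes[k],
                                 n = n_perm, seed = seed + k,
                                 utr_lengths = utr_lengths,
                                 chrom = chrom_st)
      p <- nul$ge_obs / nul$n
      if (add_one) p <- (nul$ge_obs + 1) / (nul$n + 1)
      nm <- nul$sum / nul$n
      nsd <- nm
      nsd[] <- sqrt(pmax(0, as.vector(nul$sumsq / nul$n) -
                           as.vector(nm)^2))
      for (w in colnames(nul$observed)) {
        rows[[length(rows) + 1L]] <- data.frame(
          family_id = families, seed_type = st, window = as.integer(w),
          scheme = schemes[k],
          observed = nul$observed[, w],
          null_mean = nm[, w], null_sd = nsd[, w],
          p = p[, w], q = bh_fdr(p[, w]),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "n_perm") <- n_perm
  class(res) <- c("interaction_table", "data.frame")
  res
}

#' Call interacting miRNA families
#'
#' A family is interacting with the RBP when, in the first 50-nt window
#' (downstream window 0 or upstream window -1, evaluated separately), both
#' seed types have q at or below `fdr` under every null scheme.
#'
#' @param interaction_table From [colocalization_test()].
#' @param fdr FDR threshold (default 0.05).
#' @return Character vector of interacting family ids.
#' @export
call_interacting_mirnas <- function(interaction_table, fdr = 0.05) {
  it <- interaction_table[interaction_table$window %in% c(-1L, 0L), ,
                          drop = FALSE]
  schemes <- unique(it$scheme)
  seed_types <- unique(it$seed_type)
  called <- character(0)
  for (fam in unique(it$family_id)) {
    for (w in c(0L, -1L)) {
      sub <- it[it$family_id == fam & it$window == w, , drop = FALSE]
      # every scheme x seed type cell must pass
      pass <- nrow(sub) == length(schemes) * length(seed_types) &&
        all(sub$q <= fdr)
      if (pass) {
        called <- c(called, fam)
        break
      }
    }
  }
  sort(called)
}

#' Window enrichment matrix (heatmap layout)
#'
#' Per (family, window) enrichment ratio: the minimum over null schemes of
#' observed / null mean, with both seed types' counts pooled.  A cell with
#' null mean 0 and observed 0 gets ratio 1; with observed > 0 the ratio is
#' capped at `observed * n_perm`.
#'
#' @param interaction_table From [colocalization_test()].
#' @return Numeric matrix families x 20 windows.
#' @export
window_enrichment_matrix <- function(interaction_table) {
  it <- interaction_table
  n_perm <- attr(it, "n_perm")
  if (is.null(n_perm)) n_perm <- 10000L
  agg <- stats::aggregate(cbind(observed, null_mean) ~
                            family_id + window + scheme, data = it, FUN = sum)
  families <- sort(unique(agg$family_id))
  windows <- sort(unique(agg$window))
  m <- matrix(NA_real_, length(families), length(windows),
              dimnames = list(families, as.character(windows)))
  for (i in seq_len(nrow(agg))) {
    obs <- agg$observed[i]; nm <- agg$null_mean[i]
    ratio <- if (nm > 0) obs / nm else if (obs == 0) 1 else obs * n_perm
    fi <- match(agg$family_id[i], families)
    wi <- match(as.character(agg$window[i]), colnames(m))
    m[fi, wi] <- min(m[fi, wi], ratio, na.rm = TRUE)
  }
  m
}

#' AU-controlled enrichment using shuffled RBP motifs
#'
#' Ratio of real-RBP to shuffled-RBP pair counts per (family, window),
#' normalized by the same ratio over all windows, testing whether
#' co-localization survives an AU-composition-matched RBP control.
#'
#' @param real_pairs Pair records for the canonical RBP motif.
#' @param control_pairs Pair records pooled over shuffled RBP motifs.
#' @param families All family ids.
#' @return Numeric matrix families x 20 windows (NA where a control count
#'   is zero).
#' @export
rbp_shuffle_enrichment <- function(real_pairs, control_pairs, families) {
  real <- count_colocalized(real_pairs, families)
  ctrl <- count_colocalized(control_pairs, families)
  overall <- rowSums(real) / rowSums(ctrl)
  m <- (real / ctrl) / overall
  m[!is.finite(m)] <- NA_real_
  m
}

#' Percentage of a family's sites proximal to an RBP site
#'
#' @param mirna_sites Site table of one family (or filtered to it).
#' @param rbp_sites Site table of the RBP.
#' @param max_gap Proximity threshold (default 50 nt).
#' @return Percentage in \[0, 100\]; errors when the family has no sites.
#' @export
proximal_fraction <- function(mirna_sites, rbp_sites, max_gap = 50L) {
  if (nrow(mirna_sites) == 0L) stop("family has no sites")
  if (nrow(rbp_sites) == 0L) return(0)
  rbp_by_tx <- split(seq_len(nrow(rbp_sites)), rbp_sites$transcript_id)
  prox <- vapply(seq_len(nrow(mirna_sites)), function(i) {
    ri <- rbp_by_tx[[mirna_sites$transcript_id[i]]]
    if (is.null(ri)) return(FALSE)
    gw <- gap_window_vec(rbp_sites$start[ri], rbp_sites$end[ri],
                         mirna_sites$start[i], mirna_sites$end[i])
    any(gw$gap <= max_gap)
  }, logical(1))
  100 * mean(prox)
}
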