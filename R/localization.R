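# Positional distribution of motif sites along 3'UTRs.

UTR_LENGTH_CLASSES <- c("<500", "500-2000", ">=2000")

#' Assign UTRs to length classes
#' @param lengths Named integer vector of UTR lengths.
#' @param length_class One of `"<500"`, `"500-2000"`, `">=2000"`.
#' @return Names of UTRs in that class.
#' @export
utrs_in_length_class <- function(lengths, length_class) {
  length_class <- match.arg(length_class, UTR_LENGTH_CLASSES)
  keep <- switch(length_class,
                 "<500" = lengths < 500,
                 "500-2000" = lengths >= 500 & lengths < 2000,
                 ">=2000" = lengths >= 2000)
  names(lengths)[keep]
}

#' Decile positional profile of sites
#'
#' Divides each 3'UTR into 10 equal parts and reports the percentage of
#' sites whose start falls in each decile (decile index
#' `floor(10 * start / length)`, clamped to 9).
#'
#' @param sites Site-call data.frame.
#' @param utr_lengths Named integer vector of UTR reference lengths.
#' @param length_class UTR length class to profile.
#' @return data.frame of class `positional_profile`: `length_class`, `bin`
#'   (0-9), `count`, `percent` (sums to 100), plus attribute `total`.
#' @export
decile_site_fractions <- function(sites, utr_lengths,
                                  length_class = "500-2000") {
  tx <- utrs_in_length_class(utr_lengths, length_class)
  if (length(tx) == 0L) stop("no UTRs in length class ", length_class)
  s <- sites[sites$transcript_id %in% tx, , drop = FALSE]
  dec <- pmin(9L, as.integer(floor(10 * s$start /
                                     utr_lengths[s$transcript_id])))
  counts <- tabulate(dec + 1L, nbins = 10L)
  total <- sum(counts)
  if (total == 0L) stop("no sites on UTRs of class ", length_class)
  structure(data.frame(length_class = length_class, bin = 0:9,
                       count = counts, percent = 100 * counts / total),
            class = c("positional_profile", "data.frame"),
            total = total, mode = "decile")
}

#' End-anchored 100-nt window profiles for long UTRs
#'
#' For UTRs of length at least 2000 nt, counts sites in ten 100-nt windows
#' anchored at the 5' start (`[100w, 100(w+1))`, by site start) and ten
#' anchored at the 3' end (`[L - 100(w+1), L - 100w)`, by the site's most-3'
#' base so end-touching sites land in window 0).
#'
#' @param sites Site-call data.frame.
#' @param utr_lengths Named integer vector of UTR lengths.
#' @return List with `five_prime` and `three_prime` profiles
#'   (window 0-9, `count`, `percent`; percentages are of all sites falling
#'   in that profile's ten windows).
#' @export
end_window_fractions <- function(sites, utr_lengths) {
  tx <- utrs_in_length_class(utr_lengths, ">=2000")
  s <- sites[sites$transcript_id %in% tx, , drop = FALSE]
  L <- utr_lengths[s$transcript_id]
  w5 <- ifelse(s$start < 1000, s$start %/% 100L, NA_integer_)
  last <- s$end - 1L
  w3 <- ifelse(last >= L - 1000, (L - 1L - last) %/% 100L, NA_integer_)
  mk <- function(w, mode) {
    counts <- tabulate(w[!is.na(w)] + 1L, nbins = 10L)
    total <- sum(counts)
    pct <- if (total > 0) 100 * counts / total else rep(NA_real_, 10)
    structure(data.frame(length_class = ">=2000", bin = 0:9,
                         count = counts, percent = pct),
              class = c("positional_profile", "data.frame"),
              total = total, mode = mode)
  }
  list(five_prime = mk(w5, "end_window_5p"),
       three_prime = mk(w3, "end_window_3p"))
}

#' Per-bin positional enrichment test against control motifs
#'
#' For each bin, an exact binomial upper-tail test of the real site count
#' against the mean control-motif bin fraction, Bonferroni-corrected for the
#' 10 bins.  Control profiles should come from base-composition-matched
#' shuffled motifs (see [generate_control_motifs()]) so that AU content is
#' controlled.
#'
#' @param real_profile A `positional_profile` of the canonical motif.
#' @param control_profiles List of `positional_profile`s, one per control
#'   motif.
#' @return data.frame: `bin`, `real_count`, `real_percent`,
#'   `control_percent`, `p_raw`, `p_bonferroni`.
#' @export
positional_enrichment_test <- function(real_profile, control_profiles) {
  stopifnot(length(control_profiles) >= 1L)
  n <- attr(real_profile, "total")
  ctrl_frac <- rowMeans(sapply(control_profiles,
                               function(p) p$percent / 100))
  ctrl_total <- sum(vapply(control_profiles, function(p)
    attr(p, "total"), numeric(1)))
  p_raw <- vapply(seq_len(10L), function(b) {
    k <- real_profile$count[b]
    if (k == 0L) return(1)
    p0 <- ctrl_frac[b]
    if (p0 == 0) p0 <- 1 / (ctrl_total + 1)  # floor proportion
    stats::pbinom(k - 1L, n, p0, lower.tail = FALSE)
  }, numeric(1))
  data.frame(bin = real_profile$bin,
             real_count = real_profile$count,
             real_percent = real_profile$percent,
             control_percent = 100 * ctrl_frac,
             p_raw = p_raw,
             p_bonferroni = pmin(1, p_raw * 10))
}

#' AU-content decile profile of UTRs
#'
#' Mean AU fraction of each UTR decile across a set of UTR sequences
#' (the AU gradient along 3'UTRs).
#'
#' @param utr_seqs Named character vector of UTR sequences.
#' @return data.frame: `bin` (0-9), `mean_au`, `sd_au`.
#' @export
au_decile_profile <- function(utr_seqs) {
  per_utr <- sapply(utr_seqs, function(s) {
    L <- nchar(s)
    vapply(0:9, function(b) {
      from <- floor(L * b / 10) + 1L
      to <- floor(L * (b + 1) / 10)
      if (to < from) return(NA_real_)
      compute_au_fraction(substr(s, from, to))
    }, numeric(1))
  })
  per_utr <- matrix(per_utr, nrow = 10)
  data.frame(bin = 0:9,
             mean_au = rowMeans(per_utr, na.rm = TRUE),
             sd_au = apply(per_utr, 1, stats::sd, na.rm = TRUE))
}
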