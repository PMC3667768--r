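# Local-alignment scoring of miRNA seed hybridization to the reversed RBP
# recognition motif.

# A seed base "matches" a (possibly degenerate) motif letter when any
# expansion of the letter can form a canonical or wobble pair with it
# (A-U, G-C, G-U, either orientation).  Every base has at least one
# partner, so a pattern N matches any seed base.
hyb_match <- function(seed_base, motif_letter) {
  exp <- IUPAC_RNA[[motif_letter]]
  if (is.null(exp) || !(seed_base %in% c("A", "C", "G", "U"))) return(FALSE)
  any(RNA_PAIRS[seed_base, exp])
}

#' Hybridization score between a miRNA seed and a reversed RBP motif
#'
#' Smith-Waterman local alignment with hybridization-pairing matches
#' scored `match` (default 2), mismatches `mismatch` (default 0) and
#' insertions/deletions `gap` (default -1).  The seed is conventionally the
#' 8-mer site (7mer-m8 followed by the 1A adenosine).  Ties are broken
#' toward the shortest, then most 5', alignment so output is deterministic.
#'
#' @param seed Seed (site) sequence, e.g. an 8-mer.
#' @param reversed_motif A `motif_consensus` (typically from
#'   [reverse_consensus()]) or plain IUPAC string.
#' @param match,mismatch,gap Scoring parameters.
#' @return Object of class `hybridization_score`: `score`, `seed_aln`,
#'   `motif_aln` (aligned strings with `-` gaps), `seed_range`,
#'   `motif_range` (1-based inclusive).
#' @export
hybridization_score <- function(seed, reversed_motif, match = 2,
                                mismatch = 0, gap = -1) {
  if (inherits(reversed_motif, "motif_consensus")) {
    motif_pat <- reversed_motif$pattern
  } else {
    motif_pat <- parse_motif_consensus(reversed_motif, "motif")$pattern
  }
  s <- strsplit(chartr("T", "U", toupper(seed)), "")[[1]]
  m <- strsplit(motif_pat, "")[[1]]
  if (length(s) == 0L || length(m) == 0L) stop("empty input sequence")
  ns <- length(s); nm <- length(m)
  H <- matrix(0, ns + 1L, nm + 1L)
  # move: 0 = stop, 1 = diagonal, 2 = up (gap in motif), 3 = left
  mv <- matrix(0L, ns + 1L, nm + 1L)
  for (i in seq_len(ns)) {
    for (j in seq_len(nm)) {
      sub <- if (hyb_match(s[i], m[j])) match else mismatch
      cand <- c(H[i, j] + sub, H[i, j + 1L] + gap, H[i + 1L, j] + gap)
      best <- max(0, cand)
      H[i + 1L, j + 1L] <- best
      # prefer diagonal, then up, then left, so tied tracebacks stay short
      mv[i + 1L, j + 1L] <- if (best == 0) 0L else which(cand == best)[1]
    }
  }
  smax <- max(H)
  ends <- which(H == smax, arr.ind = TRUE)
  # shortest then most 5': smallest i+j endpoint, then smallest row
  ends <- ends[order(ends[, 1] + ends[, 2], ends[, 1]), , drop = FALSE]
  i <- ends[1, 1]; j <- ends[1, 2]
  seed_aln <- motif_aln <- character(0)
  end_i <- i - 1L; end_j <- j - 1L
  while (i > 1L && j > 1L && H[i, j] > 0) {
    step <- mv[i, j]
    if (step == 1L) {
      seed_aln <- c(s[i - 1L], seed_aln)
      motif_aln <- c(m[j - 1L], motif_aln)
      i <- i - 1L; j <- j - 1L
    } else if (step == 2L) {
      seed_aln <- c(s[i - 1L], seed_aln)
      motif_aln <- c("-", motif_aln)
      i <- i - 1L
    } else if (step == 3L) {
      seed_aln <- c("-", seed_aln)
      motif_aln <- c(m[j - 1L], motif_aln)
      j <- j - 1L
    } else break
  }
  structure(list(score = smax,
                 seed_aln = paste(seed_aln, collapse = ""),
                 motif_aln = paste(motif_aln, collapse = ""),
                 seed_range = c(i, end_i), motif_range = c(j, end_j)),
            class = "hybridization_score")
}

#' @export
print.hybridization_score <- function(x, ...) {
  cat(sprintf("<hybridization_score> %g\n  seed:  %s\n  motif: %s\n",
              x$score, x$seed_aln, x$motif_aln))
  invisible(x)
}

#' 8-mer seed site of a family (7mer-m8 plus the 1A adenosine)
#'
#' @param family One row of a [build_seed_families()] table (or a list with
#'   `m8_pattern`).
#' @return Character 8-mer.
#' @export
seed_8mer <- function(family) {
  paste0(family$m8_pattern, "A")
}

#' Hybridization scores for all families against an RBP motif
#'
#' Scores each family's 8-mer seed site against the reversed RBP motif and
#' compares interacting vs non-interacting score distributions with a
#' two-sided rank-sum test.  When control (shuffled) RBP motifs are given,
#' per-score histograms of real vs control scores are also returned
#' (mean and sd across controls).
#'
#' @param families [build_seed_families()] table.
#' @param rbp_motif Canonical RBP `motif_consensus`.
#' @param interacting_set Family ids called interacting.
#' @param control_motifs Optional list of shuffled RBP `motif_consensus`.
#' @return List: `scores` (data.frame `family_id`, `score`, `seed_aln`,
#'   `motif_aln`, `interacting`), `p_two_sided`, `histogram` (or NULL).
#' @export
score_groups <- function(families, rbp_motif, interacting_set,
                         control_motifs = NULL) {
  rev_motif <- reverse_consensus(rbp_motif)
  hs <- lapply(seq_len(nrow(families)), function(i)
    hybridization_score(seed_8mer(families[i, ]), rev_motif))
  scores <- data.frame(
    family_id = families$family_id,
    score = vapply(hs, `[[`, numeric(1), "score"),
    seed_aln = vapply(hs, `[[`, character(1), "seed_aln"),
    motif_aln = vapply(hs, `[[`, character(1), "motif_aln"),
    interacting = families$family_id %in% interacting_set,
    stringsAsFactors = FALSE)
  int <- scores$score[scores$interacting]
  non <- scores$score[!scores$interacting]
  if (length(int) == 0L || length(non) == 0L) {
    stop("both interacting and non-interacting groups must be non-empty")
  }
  p <- ranksum_p(int, non, "two.sided")
  hist_df <- NULL
  if (!is.null(control_motifs) && length(control_motifs) > 0L) {
    bins <- 0:(2L * (nchar(rbp_motif$pattern) + 1L))
    real_h <- vapply(bins, function(b) sum(scores$score == b), numeric(1))
    ctrl_h <- sapply(control_motifs, function(cm) {
      cs <- vapply(seq_len(nrow(families)), function(i)
        hybridization_score(seed_8mer(families[i, ]),
                            reverse_consensus(cm))$score, numeric(1))
      vapply(bins, function(b) sum(cs == b), numeric(1))
    })
    ctrl_h <- matrix(ctrl_h, nrow = length(bins))
    hist_df <- data.frame(score = bins, real_count = real_h,
                          control_mean = rowMeans(ctrl_h),
                          control_sd = apply(ctrl_h, 1, stats::sd))
  }
  list(scores = scores, p_two_sided = p, histogram = hist_df)
}
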