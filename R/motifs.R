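#' @useDynLib utrcoop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# IUPAC degenerate nucleotide codes over the RNA alphabet.
IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

#' Parse an IUPAC consensus motif
#'
#' Validates a degenerate nucleotide pattern and stores it as a motif
#' consensus object.  DNA-style `T` is accepted and mapped to `U`; all other
#' letters must be IUPAC nucleotide codes.
#'
#' @param pattern Character scalar, IUPAC pattern (e.g. `"UGUANAUA"`).
#' @param name Motif name (e.g. the RBP it belongs to).
#' @param kind One of `"rbp"`, `"mirna_m8"`, `"mirna_1a"`.
#' @return An object of class `motif_consensus` with fields `name`,
#'   `pattern` and `kind`.
#' @examples
#' pum <- parse_motif_consensus("UGUANAUA", "PUM")
#' scan_motif_sites("AAUGUAAAUAGG", pum)
#' @export
parse_motif_consensus <- function(pattern, name = pattern,
                                  kind = c("rbp", "mirna_m8", "mirna_1a")) {
  kind <- match.arg(kind)
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  pattern <- chartr("t", "u", toupper(pattern))
  pattern <- chartr("T", "U", pattern)
  letters_ <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- setdiff(letters_, names(IUPAC_RNA))
  if (length(bad) > 0L) {
    stop("invalid IUPAC letter(s) in motif pattern: ",
         paste(unique(bad), collapse = ", "))
  }
  structure(list(name = name, pattern = pattern, kind = kind),
            class = "motif_consensus")
}

#' @export
print.motif_consensus <- function(x, ...) {
  cat(sprintf("<motif_consensus> %s: %s (%s, %d nt)\n",
              x$name, x$pattern, x$kind, nchar(x$pattern)))
  invisible(x)
}

#' @export
length.motif_consensus <- function(x) nchar(x$pattern)

# Regular expression for a consensus; subject N never matches because the
# character classes only ever contain A/C/G/U (masked bases cannot seed sites).
motif_regex <- function(motif) {
  letters_ <- strsplit(motif$pattern, "", fixed = TRUE)[[1]]
  paste(vapply(letters_, function(l) {
    exp <- IUPAC_RNA[[l]]
    if (length(exp) == 1L) exp else paste0("[", paste(exp, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Scan a sequence for motif occurrences
#'
#' Reports every (possibly overlapping) start position at which the sequence
#' matches the consensus.  Coordinates are 0-based, half-open on the input
#' sequence.  `N` in the subject matches nothing, including a pattern `N`.
#'
#' @param seq RNA sequence (character scalar over `A,C,G,U,N`; `T` tolerated).
#' @param motif A `motif_consensus`.
#' @param transcript_id Optional id copied into the result.
#' @return A data.frame of site calls with columns `transcript_id`,
#'   `motif_name`, `start`, `end` (0-based half-open), sorted by `start`.
#' @export
scan_motif_sites <- function(seq, motif, transcript_id = NA_character_) {
  stopifnot(inherits(motif, "motif_consensus"))
  seq <- chartr("Tt", "Uu", toupper(seq))
  rx <- paste0("(?=", motif_regex(motif), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  starts <- if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  data.frame(transcript_id = rep(transcript_id, length(starts)),
             motif_name = rep(motif$name, length(starts)),
             start = starts,
             end = starts + nchar(motif$pattern),
             stringsAsFactors = FALSE)
}

#' Scan a set of UTR sequences for one or more motifs
#'
#' @param seqs Named character vector of reference UTR sequences.
#' @param motifs A `motif_consensus` or list of them.
#' @return Combined site-call data.frame (see [scan_motif_sites()]).
#' @export
scan_utr_sites <- function(seqs, motifs) {
  if (inherits(motifs, "motif_consensus")) motifs <- list(motifs)
  seqs_u <- chartr("Tt", "Uu", toupper(unlist(seqs)))
  ids <- names(seqs)
  out <- vector("list", length(motifs))
  for (k in seq_along(motifs)) {
    m <- motifs[[k]]
    rx <- paste0("(?=", motif_regex(m), ")")
    hits <- gregexpr(rx, seqs_u, perl = TRUE)
    starts <- lapply(hits, function(h)
      if (h[1] == -1L) integer(0) else as.integer(h) - 1L)
    n_per <- lengths(starts)
    st <- unlist(starts, use.names = FALSE)
    out[[k]] <- data.frame(
      transcript_id = rep(ids, n_per),
      motif_name = rep(m$name, sum(n_per)),
      start = st, end = st + nchar(m$pattern),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A", N = "N")

reverse_complement_rna <- function(seq) {
  letters_ <- rev(strsplit(chartr("T", "U", toupper(seq)), "")[[1]])
  paste(RNA_COMPLEMENT[letters_], collapse = "")
}

#' Derive miRNA seed-match site motifs from a mature miRNA sequence
#'
#' Builds the two canonical TargetScan-style site types for a mature miRNA:
#' the 7mer-m8 site (reverse complement of miRNA nucleotides 2-8) and the
#' 7mer-1A site (reverse complement of nucleotides 2-7 followed by an `A`
#' opposite miRNA position 1).  With `orientation = "complement"` the literal
#' (unreversed) complement is used instead.
#'
#' @param mature_seq Mature miRNA sequence, at least 8 nt, 5'->3'.
#' @param family_id Name used for the derived motifs.
#' @param orientation `"reverse_complement"` (default, standard site
#'   orientation) or `"complement"`.
#' @return List with `m8_site` and `a1_site`, both `motif_consensus` (7 nt).
#' @examples
#' derive_seed_site_motifs("UAGCAGCACGUAAAUAUUGGCG", "miR-15")
#' @export
derive_seed_site_motifs <- function(mature_seq, family_id = "miRNA",
                                    orientation = c("reverse_complement",
                                                    "complement")) {
  orientation <- match.arg(orientation)
  mature_seq <- chartr("T", "U", toupper(mature_seq))
  if (nchar(mature_seq) < 8L) {
    stop("mature miRNA sequence must be at least 8 nt, got ",
         nchar(mature_seq))
  }
  seed28 <- substr(mature_seq, 2L, 8L)
  seed27 <- substr(mature_seq, 2L, 7L)
  if (orientation == "reverse_complement") {
    m8 <- reverse_complement_rna(seed28)
    a1 <- paste0(reverse_complement_rna(seed27), "A")
  } else {
    comp <- function(s) paste(RNA_COMPLEMENT[strsplit(s, "")[[1]]],
                              collapse = "")
    m8 <- comp(seed28)
    a1 <- paste0(comp(seed27), "A")
  }
  list(m8_site = parse_motif_consensus(m8, family_id, "mirna_m8"),
       a1_site = parse_motif_consensus(a1, family_id, "mirna_1a"))
}

#' Build seed families from mature miRNA sequences
#'
#' Families whose 7mer-m8 site patterns are identical are collapsed into one
#' family whose id concatenates the member names (as in miR-221/222).
#'
#' @param mirnas data.frame with columns `family_id` and `mature_seq`.
#' @param orientation Passed to [derive_seed_site_motifs()].
#' @return data.frame with columns `family_id`, `mature_seq`, `m8_pattern`,
#'   `a1_pattern`, `members`.
#' @export
build_seed_families <- function(mirnas,
                                orientation = "reverse_complement") {
  stopifnot(all(c("family_id", "mature_seq") %in% names(mirnas)))
  sites <- lapply(seq_len(nrow(mirnas)), function(i)
    derive_seed_site_motifs(mirnas$mature_seq[i], mirnas$family_id[i],
                            orientation))
  m8 <- vapply(sites, function(s) s$m8_site$pattern, character(1))
  a1 <- vapply(sites, function(s) s$a1_site$pattern, character(1))
  grp <- split(seq_len(nrow(mirnas)), m8)
  out <- lapply(grp, function(idx) {
    data.frame(
      family_id = paste(sort(unique(mirnas$family_id[idx])), collapse = "/"),
      mature_seq = mirnas$mature_seq[idx[1]],
      m8_pattern = m8[idx[1]],
      a1_pattern = a1[idx[1]],
      members = paste(mirnas$family_id[idx], collapse = ","),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$family_id), , drop = FALSE]
}

#' AU fraction of a sequence
#'
#' Fraction of non-N bases that are A or U.  `N` is excluded from the
#' denominator; an all-N (or empty) sequence has no defined AU content and
#' raises an error.
#'
#' @param seq RNA sequence.
#' @return Numeric in \[0, 1\].
#' @export
compute_au_fraction <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  letters_ <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n_acgu <- sum(letters_ %in% c("A", "C", "G", "U"))
  if (n_acgu == 0L) stop("AU fraction undefined: no non-N bases in sequence")
  sum(letters_ %in% c("A", "U")) / n_acgu
}

#' Restrict site calls to a set of regions
#'
#' Keeps sites that are fully contained in some region on the same
#' transcript (Par-CLIP-style interval restriction).
#'
#' @param sites Site-call data.frame (`transcript_id`, `start`, `end`).
#' @param regions data.frame with `transcript_id`, `start`, `end`.
#' @return The contained subset of `sites`.
#' @export
restrict_sites_to_regions <- function(sites, regions) {
  if (nrow(sites) == 0L || nrow(regions) == 0L) {
    return(sites[0, , drop = FALSE])
  }
  keep <- vapply(seq_len(nrow(sites)), function(i) {
    r <- regions[regions$transcript_id == sites$transcript_id[i], ,
                 drop = FALSE]
    any(r$start <= sites$start[i] & sites$end[i] <= r$end)
  }, logical(1))
  sites[keep, , drop = FALSE]
}

#' Reverse a consensus motif
#'
#' Reverses the letter order, keeping degenerate letters intact (used when
#' scoring seed hybridization against the reversed RBP motif).
#'
#' @param motif A `motif_consensus`.
#' @return A `motif_consensus` with reversed pattern.
#' @export
reverse_consensus <- function(motif) {
  stopifnot(inherits(motif, "motif_consensus"))
  rev_pat <- paste(rev(strsplit(motif$pattern, "")[[1]]), collapse = "")
  parse_motif_consensus(rev_pat, paste0(motif$name, "_rev"), motif$kind)
}
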