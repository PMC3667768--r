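# Branch length score (BLS) conservation of motif instances, shuffled-motif
# controls, precision curves and the motif gating rule.

#' Branch length score of a conserved species set
#'
#' Total branch length of the minimal phylogenetic subtree connecting the
#' given species, as a fraction of the whole tree's branch length.  A set
#' containing only one species spans no edges and scores 0.
#'
#' @param tree ape `phylo` with branch lengths.
#' @param species_set Character vector of leaf names (must include the
#'   reference species of the analysis).
#' @return Numeric in \[0, 1\].
#' @examples
#' tr <- ape::read.tree(text = "((Ref:1,S1:1):1,(S2:1,S3:1):1);")
#' branch_length_score(tr, c("Ref", "S1"))  # 2/6
#' @export
branch_length_score <- function(tree, species_set) {
  species_set <- unique(species_set)
  if (length(species_set) == 0L) stop("empty species set")
  missing_sp <- setdiff(species_set, tree$tip.label)
  if (length(missing_sp) > 0L) {
    stop("species not in tree: ", paste(missing_sp, collapse = ", "))
  }
  total <- sum(tree$edge.length)
  if (!is.finite(total) || total <= 0) stop("tree has no positive total length")
  if (length(species_set) == 1L) return(0)
  sub <- ape::keep.tip(tree, species_set)
  sum(sub$edge.length) / total
}

# Path distances from the reference leaf to every other leaf, in
# substitutions/site (tree path length, not rank).
ref_leaf_distances <- function(tree, ref_species) {
  d <- ape::cophenetic.phylo(tree)[ref_species, ]
  d
}

#' Species in which a motif hit is conserved
#'
#' A species is conserved for a reference hit if its (ungapped) aligned row
#' contains a motif match whose start maps within +/- `window` reference-
#' anchored nucleotides of the hit start.  To prevent BLS inflation by a
#' single distant hit, the most distant conserved species is removed when
#' (a) the species ranked between it and the next-nearest conserved species
#' (by tree distance to the reference) that lack the motif number more than
#' one-third of the aligned genomes, and (b) its distance to the reference
#' is more than twice the distance of the second-most-distant conserved
#' species.
#'
#' @param autr An `aligned_utr`.
#' @param hit_start 0-based start of the hit on the reference sequence.
#' @param motif A `motif_consensus`.
#' @param tree ape `phylo` covering all species of the block.
#' @param window Conservation window in nt (default 10).
#' @return Character vector of conserved species (always contains the
#'   reference).
#' @export
conserved_species_for_hit <- function(autr, hit_start, motif, tree,
                                      window = 10L) {
  species <- names(autr$rows)
  missing_sp <- setdiff(species, tree$tip.label)
  if (length(missing_sp) > 0L) {
    stop("species in block absent from tree: ",
         paste(missing_sp, collapse = ", "))
  }
  ref <- autr$ref_species
  others <- setdiff(species, ref)
  conserved <- ref
  for (sp in others) {
    row <- autr$rows[[sp]]
    ung <- gsub("-", "", row, fixed = TRUE)
    if (nchar(ung) < nchar(motif$pattern)) next
    hits <- scan_motif_sites(ung, motif)
    if (nrow(hits) == 0L) next
    cols_sp <- which(strsplit(row, "")[[1]] != "-")
    # alignment column of each species-hit start, mapped to a reference-
    # anchored coordinate
    hit_cols <- cols_sp[hits$start + 1L]
    ref_pos <- column_to_ref_pos(autr, hit_cols)
    if (any(abs(ref_pos - hit_start) <= window)) {
      conserved <- c(conserved, sp)
    }
  }
  prune_distant_hit(conserved, species, ref, tree)
}

# Distant-hit exclusion rule applied to a conserved species set.
prune_distant_hit <- function(conserved, aligned_species, ref, tree) {
  non_ref <- setdiff(conserved, ref)
  if (length(non_ref) == 0L) return(conserved)
  d <- ref_leaf_distances(tree, ref)
  ord <- non_ref[order(d[non_ref], decreasing = TRUE)]
  farthest <- ord[1]
  d1 <- d[[farthest]]
  if (length(ord) >= 2L) {
    second <- ord[2]
    d2 <- d[[second]]
  } else {
    second <- ref
    d2 <- 0
  }
  between <- setdiff(aligned_species, c(conserved, ref))
  n_between_missing <- sum(d[between] > d2 & d[between] < d1)
  n_aligned <- length(aligned_species)
  cond_gap <- n_between_missing > n_aligned / 3
  cond_dist <- d1 > 2 * d2
  if (cond_gap && cond_dist) conserved <- setdiff(conserved, farthest)
  conserved
}

#' BLS-annotate a table of reference motif hits
#'
#' For each site call, determines the conserved species set in its aligned
#' UTR block and attaches the branch length score.  Hits conserved only in
#' the reference get BLS 0 (and still count at threshold 0).
#'
#' @param sites Site-call data.frame (from [scan_utr_sites()]).
#' @param utrs Named list of `aligned_utr`.
#' @param motif The `motif_consensus` that produced the sites.
#' @param tree ape `phylo`.
#' @param window Conservation window in nt.
#' @return `sites` with a `bls` column.
#' @export
bls_annotate_sites <- function(sites, utrs, motif, tree, window = 10L) {
  if (nrow(sites) == 0L) {
    sites$bls <- numeric(0)
    return(sites)
  }
  sites$bls <- vapply(seq_len(nrow(sites)), function(i) {
    u <- utrs[[sites$transcript_id[i]]]
    if (is.null(u)) stop("no aligned UTR for ", sites$transcript_id[i])
    cs <- conserved_species_for_hit(u, sites$start[i], motif, tree, window)
    branch_length_score(tree, cs)
  }, numeric(1))
  sites
}

#' Similarity between two consensus motifs
#'
#' Ungapped sliding-offset similarity: each consensus column is represented
#' as a probability vector uniform over its IUPAC expansion, per-column
#' overlap is the Sandelin-Wasserman-style score `1 - sum((p - q)^2) / 2`
#' (1 for identical columns, 0 for disjoint single-base columns), and the
#' motif similarity is the maximum over all offsets with overlap of at
#' least `min_overlap` of the mean per-column score.  Symmetric; a motif is
#' maximally similar to itself.
#'
#' @param m1,m2 `motif_consensus` objects.
#' @param min_overlap Minimum overlapping columns per offset.
#' @return Numeric in \[0, 1\].
#' @export
motif_similarity <- function(m1, m2, min_overlap = 4L) {
  similarity_from_profiles(consensus_profile(m1), consensus_profile(m2),
                           min_overlap)
}

similarity_from_profiles <- function(p1, p2, min_overlap = 4L) {
  n1 <- ncol(p1); n2 <- ncol(p2)
  min_overlap <- min(min_overlap, n1, n2)
  best <- 0
  for (off in seq(-(n2 - min_overlap), n1 - min_overlap)) {
    i1 <- max(1L, 1L + off):min(n1, n2 + off)
    i2 <- i1 - off
    d <- p1[, i1, drop = FALSE] - p2[, i2, drop = FALSE]
    sc <- mean(1 - colSums(d * d) / 2)
    if (sc > best) best <- sc
  }
  best
}

# 4 x L probability-profile matrix of a consensus (uniform over each
# letter's IUPAC expansion); cached per pattern within a session.
consensus_profile <- local({
  cache <- new.env(parent = emptyenv())
  function(motif) {
    pat <- if (inherits(motif, "motif_consensus")) motif$pattern else motif
    hit <- cache[[pat]]
    if (!is.null(hit)) return(hit)
    letters_ <- strsplit(pat, "")[[1]]
    p <- sapply(letters_, function(l) {
      v <- stats::setNames(numeric(4), c("A", "C", "G", "U"))
      exp <- IUPAC_RNA[[l]]
      v[exp] <- 1 / length(exp)
      v
    })
    p <- matrix(p, nrow = 4, dimnames = list(c("A", "C", "G", "U"), NULL))
    cache[[pat]] <- p
    p
  }
})

#' Generate shuffled control motifs
#'
#' Candidate controls are random permutations of the motif letters.  Pairwise
#' similarity ([motif_similarity()]) is profiled among the canonical and all
#' candidates, and candidates in the top `similarity_cut` fraction of
#' similarity to the canonical or any already-retained control are discarded
#' as redundant.  Among survivors, up to `max_keep` controls are selected,
#' preferring those whose genome hit count is within `hit_tolerance` of the
#' canonical motif's; arbitrary survivors fill remaining slots.  Motifs with
#' fewer than `min_keep` distinct shuffles (e.g. homopolymers) are flagged
#' ineligible.
#'
#' @param motif Canonical `motif_consensus`.
#' @param utr_seqs Named character vector of reference UTR sequences used for
#'   hit counting (may be empty, in which case the hit preference is skipped).
#' @param n_raw Number of raw shuffles to draw.
#' @param similarity_cut Upper-quantile similarity fraction to discard.
#' @param hit_tolerance Relative hit-count tolerance.
#' @param max_keep,min_keep Maximum controls kept / minimum required.
#' @param seed Integer seed (controls are deterministic given the seed).
#' @return List of class `control_motifs`: `motifs` (list of
#'   `motif_consensus`), `eligible` (flag), `canonical_hits`, `hits`.
#' @export
generate_control_motifs <- function(motif, utr_seqs = character(0),
                                    n_raw = 200L, similarity_cut = 0.10,
                                    hit_tolerance = 0.20, max_keep = 10L,
                                    min_keep = 3L, seed = 1L) {
  letters_ <- strsplit(motif$pattern, "")[[1]]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  raw <- vapply(seq_len(n_raw), function(i)
    paste(sample(letters_), collapse = ""), character(1))
  cand <- setdiff(unique(raw), motif$pattern)
  if (length(cand) < min_keep) {
    return(structure(list(motifs = list(), eligible = FALSE,
                          canonical_hits = NA_integer_, hits = integer(0)),
                     class = "control_motifs"))
  }
  cand_motifs <- lapply(cand, function(p)
    parse_motif_consensus(p, paste0(motif$name, "_shuf"), motif$kind))
  # similarity of every candidate to the canonical and to each other
  all_m <- c(list(motif), cand_motifs)
  nm <- length(all_m)
  profiles <- lapply(all_m, consensus_profile)
  sim <- matrix(0, nm, nm)
  for (i in seq_len(nm - 1L)) {
    for (j in (i + 1L):nm) {
      sim[i, j] <- sim[j, i] <- similarity_from_profiles(profiles[[i]],
                                                         profiles[[j]])
    }
  }
  cut <- stats::quantile(sim[upper.tri(sim)], 1 - similarity_cut,
                         names = FALSE)
  # greedy pruning: drop candidates too similar to the canonical or to a
  # previously retained control
  retained <- integer(0)
  for (j in seq_along(cand_motifs)) {
    jj <- j + 1L
    if (sim[1, jj] >= cut) next
    if (length(retained) > 0L && any(sim[retained + 1L, jj] >= cut)) next
    retained <- c(retained, j)
  }
  if (length(retained) < min_keep) {
    # redundancy pruning left too few distinct shuffles
    return(structure(list(motifs = list(), eligible = FALSE,
                          canonical_hits = NA_integer_, hits = integer(0)),
                     class = "control_motifs"))
  }
  survivors <- cand_motifs[retained]
  canonical_hits <- NA_integer_
  hits <- rep(NA_integer_, length(survivors))
  if (length(utr_seqs) > 0L) {
    canonical_hits <- nrow(scan_utr_sites(utr_seqs, motif))
    hits <- vapply(survivors, function(m)
      nrow(scan_utr_sites(utr_seqs, m)), integer(1))
    in_tol <- abs(hits - canonical_hits) <= hit_tolerance * canonical_hits
    ord <- order(!in_tol, abs(hits - canonical_hits))
    survivors <- survivors[ord]
    hits <- hits[ord]
  }
  keep <- seq_len(min(max_keep, length(survivors)))
  structure(list(motifs = survivors[keep], eligible = TRUE,
                 canonical_hits = canonical_hits, hits = hits[keep]),
            class = "control_motifs")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Precision curve over BLS thresholds
#'
#' For the 101-threshold grid 0.00-1.00 (step 0.01), counts canonical and
#' shuffled-motif hits with BLS at or above each threshold and computes the
#' conservation precision `1 - shuffled_mean / canonical_count` (undefined
#' where the canonical count is 0).
#'
#' @param canonical_bls Numeric vector of BLS values of canonical hits.
#' @param shuffled_bls List of numeric vectors, one per control motif.
#' @return data.frame of class `precision_curve`: `threshold`,
#'   `canonical_count`, `shuffled_mean`, `shuffled_sd`, `precision`.
#' @export
precision_curve <- function(canonical_bls, shuffled_bls) {
  stopifnot(is.list(shuffled_bls), length(shuffled_bls) >= 1L)
  thresholds <- seq(0, 1, by = 0.01)
  eps <- 1e-12
  count_ge <- function(x, t) sum(x >= t - eps)
  canonical <- vapply(thresholds, function(t) count_ge(canonical_bls, t),
                      numeric(1))
  shuf <- sapply(shuffled_bls, function(b)
    vapply(thresholds, function(t) count_ge(b, t), numeric(1)))
  shuf <- matrix(shuf, nrow = length(thresholds))
  sm <- rowMeans(shuf)
  ssd <- apply(shuf, 1, stats::sd)
  precision <- ifelse(canonical > 0, 1 - sm / canonical, NA_real_)
  structure(data.frame(threshold = thresholds,
                       canonical_count = as.integer(canonical),
                       shuffled_mean = sm, shuffled_sd = ssd,
                       precision = precision),
            class = c("precision_curve", "data.frame"))
}

#' Conservation gate for an RBP motif
#'
#' A motif passes when some BLS threshold has precision of at least
#' `precision_min` with more than `min_hits` canonical hits remaining.
#'
#' @param curve A `precision_curve`.
#' @param precision_min Precision threshold (default 0.6).
#' @param min_hits Hit-count threshold (default 10; strictly more required).
#' @return Logical flag.
#' @export
gate_rbp_motif <- function(curve, precision_min = 0.6, min_hits = 10L) {
  ok <- !is.na(curve$precision) & curve$precision >= precision_min &
    curve$canonical_count > min_hits
  any(ok)
}
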