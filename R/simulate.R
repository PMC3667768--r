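# Synthetic dataset generation: a phylogeny, aligned 3'UTRs with an AU
# gradient and planted conserved motifs, planted proximal RBP/miRNA site
# pairs, half-lives with a multiplicative proximal-pair effect, and skewed
# miRNA expression counts.  Everything is deterministic given the seed, and
# planted-site ground truth is returned alongside the data.

#' Simulation configuration
#'
#' Collects all knobs of the synthetic-data generator with defaults chosen
#' to emulate a mammalian 3'UTR compendium at desk scale: log-normal UTR
#' lengths around 1.2 kb, an AU fraction rising toward the 3' end, one RBP
#' motif (the PUM consensus), 50 miRNA seed families with Zipf-skewed read
#' counts, 5 families planted with 3-fold excess proximal co-occurrence,
#' and a 0.7x half-life multiplier on transcripts carrying a planted
#' proximal pair.
#'
#' @param seed Integer master seed.
#' @param n_species Number of species in the phylogeny (reference first).
#' @param n_utrs Number of 3'UTRs.
#' @param utr_meanlog,utr_sdlog Log-normal UTR length parameters (nt).
#' @param utr_min Minimum UTR length (nt).
#' @param au_gradient Length-2 numeric: AU fraction at the 5' start and 3'
#'   end of each UTR (linear interpolation along the UTR).
#' @param rbp_name,rbp_pattern The planted RBP motif.
#' @param rbp_rate Expected RBP sites per UTR (Poisson).
#' @param positional_bias Optional length-10 decile weight vector for
#'   non-proximal site placement (default uniform).
#' @param n_families Number of miRNA seed families.
#' @param sites_per_family Planted sites per family and seed type.
#' @param planted_interacting_families Number of families planted with
#'   excess proximal co-occurrence.
#' @param colocalization_excess Target fold excess of the planted families'
#'   proximal fraction over the chance baseline.
#' @param halflife_effect Half-life multiplier for transcripts with a
#'   planted proximal pair.
#' @param halflife_meanlog,halflife_sdlog Log-normal base half-life (hours).
#' @param expression_skew Zipf exponent for family read counts.
#' @param mut_scale Per-unit-branch-length substitution probability scale
#'   for non-reference rows.
#' @param tree_total_length Total branch length the phylogeny is rescaled
#'   to (substitutions/site).
#' @param conservation_depth_range Range (integer, in species count) of the
#'   nested conservation subsets drawn per planted site.
#' @param planted_conservation Optional list of lists
#'   `(pattern, species, n)` planting `n` extra instances of `pattern`
#'   conserved in exactly `species`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 20130530L,
                       n_species = 8L,
                       n_utrs = 400L,
                       utr_meanlog = log(1200), utr_sdlog = 0.5,
                       utr_min = 80L,
                       au_gradient = c(0.45, 0.65),
                       rbp_name = "PUM", rbp_pattern = "UGUANAUA",
                       rbp_rate = 1.2,
                       positional_bias = NULL,
                       n_families = 50L,
                       sites_per_family = 200L,
                       planted_interacting_families = 5L,
                       colocalization_excess = 3,
                       halflife_effect = 0.7,
                       halflife_meanlog = log(8), halflife_sdlog = 0.5,
                       expression_skew = 1.1,
                       mut_scale = 0.25,
                       tree_total_length = 4,
                       conservation_depth_range = c(1L, NA_integer_),
                       planted_conservation = NULL) {
  stopifnot(n_species >= 2L, n_utrs >= 1L,
            all(au_gradient >= 0 & au_gradient <= 1),
            colocalization_excess > 0, halflife_effect > 0,
            planted_interacting_families <= n_families)
  if (!is.null(positional_bias)) {
    stopifnot(length(positional_bias) == 10L,
              abs(sum(positional_bias) - 1) < 1e-8)
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a random coalescent-style phylogeny
#'
#' The reference species is the first leaf (`ref`); branch lengths are
#' rescaled to the requested total.
#'
#' @param n_species Number of leaves (>= 2).
#' @param seed Integer seed.
#' @param total_length Total branch length after rescaling.
#' @return ape `phylo`.
#' @export
generate_phylogeny <- function(n_species, seed = 1L, total_length = 4) {
  if (n_species < 2L) stop("need at least 2 species")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  labels <- c("ref", paste0("sp", seq_len(n_species)[-1]))
  tree <- ape::rcoal(n_species, tip.label = sample(labels))
  # put the labels in a canonical order regardless of rcoal's internals
  tree$tip.label <- labels[match(tree$tip.label, labels)]
  tree$edge.length <- tree$edge.length * total_length /
    sum(tree$edge.length)
  tree
}

# One random background sequence with a linear AU gradient.
random_utr_seq <- function(len, au_start, au_end) {
  au <- au_start + (au_end - au_start) * (seq_len(len) - 1) / max(1, len - 1)
  is_au <- stats::runif(len) < au
  pick <- stats::runif(len) < 0.5
  base <- ifelse(is_au, ifelse(pick, "A", "U"), ifelse(pick, "C", "G"))
  paste(base, collapse = "")
}

# Realize a degenerate pattern as a concrete sequence.
instantiate_pattern <- function(pattern) {
  letters_ <- strsplit(pattern, "")[[1]]
  paste(vapply(letters_, function(l) {
    exp <- IUPAC_RNA[[l]]
    if (length(exp) == 1L) exp else sample(exp, 1L)
  }, character(1)), collapse = "")
}

# Sample a start position given optional decile weights.
sample_start <- function(len, site_len, decile_weights = NULL) {
  max_start <- len - site_len
  if (is.null(decile_weights)) return(sample.int(max_start + 1L, 1L) - 1L)
  d <- sample.int(10L, 1L, prob = decile_weights) - 1L
  lo <- as.integer(ceiling(len * d / 10))
  hi <- min(max_start, as.integer(ceiling(len * (d + 1) / 10)) - 1L)
  if (hi < lo) return(sample.int(max_start + 1L, 1L) - 1L)
  if (hi == lo) return(lo)
  sample(lo:hi, 1L)
}

#' Generate a full synthetic dataset
#'
#' Builds the phylogeny, reference UTRs, planted RBP and miRNA-family
#' sites, per-species alignment rows with site-level conservation subsets,
#' half-life and expression tables, and the ground-truth bookkeeping needed
#' by the planted-signal tests.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_dataset`: `tree`, `utrs` (aligned_utr list),
#'   `rbp_motif`, `families`, `mirnas`, `halflife`, `expression`, `truth`
#'   (list with `rbp_sites`, `mirna_sites`, `planted_families`,
#'   `int_proximal_tx`, `conservation_sites`), `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  tree <- generate_phylogeny(config$n_species, seed = config$seed + 1L,
                             total_length = config$tree_total_length)
  species <- tree$tip.label
  ref <- "ref"
  dist_ref <- ref_leaf_distances(tree, ref)
  sp_by_dist <- names(sort(dist_ref[setdiff(species, ref)]))

  # reference sequences
  lens <- pmax(config$utr_min,
               as.integer(round(stats::rlnorm(config$n_utrs,
                                              config$utr_meanlog,
                                              config$utr_sdlog))))
  tx_ids <- sprintf("tx%04d", seq_len(config$n_utrs))
  names(lens) <- tx_ids
  ref_seqs <- stats::setNames(vapply(lens, function(L)
    random_utr_seq(L, config$au_gradient[1], config$au_gradient[2]),
    character(1)), tx_ids)

  plant <- function(seqs, tx, start, site_seq) {
    s <- seqs[[tx]]
    substr(s, start + 1L, start + nchar(site_seq)) <- site_seq
    seqs[[tx]] <- s
    seqs
  }

  # --- RBP sites ---
  rbp_motif <- parse_motif_consensus(config$rbp_pattern, config$rbp_name,
                                     "rbp")
  rbp_len <- nchar(config$rbp_pattern)
  rbp_truth <- list()
  placed <- lapply(stats::setNames(nm = tx_ids), function(x) NULL)
  for (tx in tx_ids) {
    k <- stats::rpois(1L, config$rbp_rate)
    if (k == 0L) next
    for (s in seq_len(k)) {
      st <- sample_start(lens[[tx]], rbp_len, config$positional_bias)
      # RBP truth sites must not overwrite each other
      tries <- 0L
      while (tries < 10L && !is.null(placed[[tx]]) &&
             any(placed[[tx]]$start < st + rbp_len &
                   st < placed[[tx]]$end)) {
        st <- sample_start(lens[[tx]], rbp_len, config$positional_bias)
        tries <- tries + 1L
      }
      if (tries == 10L) next
      placed[[tx]] <- rbind(placed[[tx]],
                            data.frame(start = st, end = st + rbp_len))
      site_seq <- instantiate_pattern(config$rbp_pattern)
      ref_seqs <- plant(ref_seqs, tx, st, site_seq)
      rbp_truth[[length(rbp_truth) + 1L]] <- data.frame(
        transcript_id = tx, motif_name = config$rbp_name,
        start = st, end = st + rbp_len, stringsAsFactors = FALSE)
    }
  }
  rbp_truth <- do.call(rbind, rbp_truth)
  if (is.null(rbp_truth)) {
    rbp_truth <- data.frame(transcript_id = character(0),
                            motif_name = character(0),
                            start = integer(0), end = integer(0),
                            stringsAsFactors = FALSE)
  }

  # chance baseline: fraction of start positions within a <= 50 nt gap of
  # an RBP site, averaged over UTRs (drives the planted proximal rate)
  cover <- vapply(tx_ids, function(tx) {
    r <- rbp_truth[rbp_truth$transcript_id == tx, , drop = FALSE]
    if (nrow(r) == 0L) return(0)
    covered <- rep(FALSE, lens[[tx]])
    for (i in seq_len(nrow(r))) {
      lo <- max(1L, r$start[i] - 50L - 7L + 1L)
      hi <- min(lens[[tx]], r$end[i] + 50L + 7L)
      covered[lo:hi] <- TRUE
    }
    mean(covered)
  }, numeric(1))
  chance_prox <- mean(cover)
  # deliberate proximal placement rate solving
  # p + chance*(1-p) = excess * chance  for p
  p_extra <- min(0.9, (config$colocalization_excess - 1) * chance_prox /
                   max(1e-9, 1 - chance_prox))

  # --- miRNA families ---
  # Seed-region AU composition is prescribed so that the AU-category
  # permutation strata are all well-populated: planted families get 4 A/U
  # nucleotides in the 7-nt seed match (medium category, like the AU-rich
  # PUM-interacting seeds), other families cycle over 2..6.
  n_planted <- config$planted_interacting_families
  au_counts <- integer(config$n_families)
  au_counts[seq_len(n_planted)] <- 4L
  if (config$n_families > n_planted) {
    au_counts[(n_planted + 1L):config$n_families] <-
      rep(2:6, length.out = config$n_families - n_planted)
  }
  mature <- vapply(seq_len(config$n_families), function(i) {
    seed28 <- character(7L)
    au_pos <- sample.int(7L, au_counts[i])
    seed28[au_pos] <- sample(c("A", "U"), au_counts[i], replace = TRUE)
    seed28[-au_pos] <- sample(c("C", "G"), 7L - au_counts[i],
                              replace = TRUE)
    paste(c(sample(c("A", "C", "G", "U"), 1L), seed28,
            sample(c("A", "C", "G", "U"), 14L, replace = TRUE)),
          collapse = "")
  }, character(1))
  mirnas <- data.frame(family_id = sprintf("fam%03d",
                                           seq_len(config$n_families)),
                       mature_seq = mature, stringsAsFactors = FALSE)
  families <- build_seed_families(mirnas)
  planted_families <- families$family_id[
    seq_len(config$planted_interacting_families)]

  rbp_by_tx <- split(rbp_truth, rbp_truth$transcript_id)
  tx_with_rbp <- names(rbp_by_tx)
  # planted miRNA sites must not destroy planted RBP sites
  overlaps_rbp <- function(tx, st, en) {
    r <- rbp_by_tx[[tx]]
    if (is.null(r)) return(FALSE)
    any(r$start < en & st < r$end)
  }
  mir_truth <- vector("list", nrow(families) * 2L * config$sites_per_family)
  mt <- 0L
  for (fi in seq_len(nrow(families))) {
    fam <- families$family_id[fi]
    planted_fam <- fam %in% planted_families
    for (st_type in c("m8", "1a")) {
      pat <- if (st_type == "m8") families$m8_pattern[fi]
             else families$a1_pattern[fi]
      for (s in seq_len(config$sites_per_family)) {
        proximal <- planted_fam && stats::runif(1) < p_extra
        if (proximal && length(tx_with_rbp) > 0L) {
          ok <- FALSE
          for (try in 1:10) {
            tx <- sample(tx_with_rbp, 1L)
            r <- rbp_by_tx[[tx]]
            r <- r[sample.int(nrow(r), 1L), ]
            gap <- sample.int(51L, 1L) - 1L
            downstream <- stats::runif(1) < 0.5
            st <- if (downstream) r$end + gap else r$start - gap - 7L
            if (st >= 0L && st + 7L <= lens[[tx]] &&
                !overlaps_rbp(tx, st, st + 7L)) {
              ok <- TRUE
              break
            }
          }
          if (!ok) {
            st <- sample_start(lens[[tx]], 7L, NULL)
            proximal <- FALSE
          }
        } else {
          proximal <- FALSE
          tx <- sample(tx_ids, 1L)
          st <- sample_start(lens[[tx]], 7L, config$positional_bias)
        }
        if (!proximal) {
          # re-draw a few times rather than overwrite a planted RBP site
          tries <- 0L
          while (overlaps_rbp(tx, st, st + 7L) && tries < 5L) {
            tx <- sample(tx_ids, 1L)
            st <- sample_start(lens[[tx]], 7L, config$positional_bias)
            tries <- tries + 1L
          }
        }
        ref_seqs <- plant(ref_seqs, tx, st, pat)
        mt <- mt + 1L
        mir_truth[[mt]] <- data.frame(
          transcript_id = tx, family_id = fam, seed_type = st_type,
          start = st, end = st + 7L, planted_proximal = proximal,
          stringsAsFactors = FALSE)
      }
    }
  }
  mir_truth <- do.call(rbind, mir_truth[seq_len(mt)])

  # --- per-species rows with site-level conservation subsets ---
  p_mut <- config$mut_scale * dist_ref[setdiff(species, ref)]
  p_mut <- stats::setNames(pmin(0.6, p_mut), names(p_mut))
  rows_by_tx <- lapply(tx_ids, function(tx) {
    refs <- ref_seqs[[tx]]
    chars <- strsplit(refs, "")[[1]]
    rows <- c(stats::setNames(list(refs), ref),
              lapply(stats::setNames(nm = setdiff(species, ref)),
                     function(sp) {
      mut <- stats::runif(length(chars)) < p_mut[[sp]]
      ch <- chars
      if (any(mut)) {
        # substitute with one of the three other bases, vectorized
        alt <- rbind(A = c("C", "G", "U"), C = c("A", "G", "U"),
                     G = c("A", "C", "U"), U = c("A", "C", "G"))
        ch[mut] <- alt[cbind(match(ch[mut], rownames(alt)),
                             sample.int(3L, sum(mut), replace = TRUE))]
      }
      paste(ch, collapse = "")
    }))
    unlist(rows)
  })
  names(rows_by_tx) <- tx_ids

  depth_max <- config$conservation_depth_range[2]
  if (is.na(depth_max)) depth_max <- config$n_species - 1L
  depth_min <- config$conservation_depth_range[1]
  copy_site <- function(tx, start, end, n_deep) {
    if (n_deep < 1L) return(invisible())
    site_seq <- substr(rows_by_tx[[tx]][[ref]], start + 1L, end)
    for (sp in sp_by_dist[seq_len(n_deep)]) {
      row <- rows_by_tx[[tx]][[sp]]
      substr(row, start + 1L, end) <- site_seq
      rows_by_tx[[tx]][[sp]] <<- row
    }
    invisible()
  }
  all_truth_sites <- rbind(
    rbp_truth[, c("transcript_id", "start", "end")],
    mir_truth[, c("transcript_id", "start", "end")])
  depths <- sample(seq(depth_min, depth_max),
                   nrow(all_truth_sites), replace = TRUE)
  for (i in seq_len(nrow(all_truth_sites))) {
    copy_site(all_truth_sites$transcript_id[i], all_truth_sites$start[i],
              all_truth_sites$end[i], depths[i])
  }

  # explicitly configured conservation plantings (exact species subsets)
  cons_truth <- NULL
  if (!is.null(config$planted_conservation)) {
    recs <- list()
    for (pc in config$planted_conservation) {
      for (k in seq_len(pc$n)) {
        tx <- sample(tx_ids, 1L)
        site_seq <- instantiate_pattern(pc$pattern)
        st <- sample_start(lens[[tx]], nchar(site_seq), NULL)
        for (sp in species) {
          row <- rows_by_tx[[tx]][[sp]]
          repl <- if (sp == ref || sp %in% pc$species) site_seq
                  else random_utr_seq(nchar(site_seq), 0.5, 0.5)
          substr(row, st + 1L, st + nchar(site_seq)) <- repl
          rows_by_tx[[tx]][[sp]] <- row
        }
        recs[[length(recs) + 1L]] <- data.frame(
          transcript_id = tx, pattern = pc$pattern, start = st,
          end = st + nchar(site_seq),
          species = paste(pc$species, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    cons_truth <- do.call(rbind, recs)
  }

  utrs <- lapply(tx_ids, function(tx) aligned_utr(tx, ref, rows_by_tx[[tx]]))
  names(utrs) <- tx_ids

  # --- half-lives with planted proximal-pair effect ---
  # The decay effect acts on realized proximity as an analysis would see
  # it: the reference sequences are re-scanned (so background occurrences
  # of the planted patterns are part of the truth bookkeeping), and every
  # transcript with a planted-family site within 50 nt of an RBP site gets
  # the multiplier.
  int_prox_tx <- character(0)
  if (length(planted_families) > 0L) {
    ref_seqs_final <- vapply(tx_ids, function(tx) rows_by_tx[[tx]][[ref]],
                             character(1))
    rbp_scan <- scan_utr_sites(ref_seqs_final, rbp_motif)
    planted_rows <- match(planted_families, families$family_id)
    pat_motifs <- lapply(planted_rows, function(i) list(
      parse_motif_consensus(families$m8_pattern[i],
                            families$family_id[i], "mirna_m8"),
      parse_motif_consensus(families$a1_pattern[i],
                            families$family_id[i], "mirna_1a")))
    pl_scan <- scan_utr_sites(ref_seqs_final, unlist(pat_motifs,
                                                     recursive = FALSE))
    if (nrow(pl_scan) > 0L && nrow(rbp_scan) > 0L) {
      rbp_scan_by_tx <- split(rbp_scan, rbp_scan$transcript_id)
      is_prox <- vapply(seq_len(nrow(pl_scan)), function(i) {
        r <- rbp_scan_by_tx[[pl_scan$transcript_id[i]]]
        if (is.null(r)) return(FALSE)
        gw <- gap_window_vec(r$start, r$end, pl_scan$start[i],
                             pl_scan$end[i])
        any(gw$gap <= 50L)
      }, logical(1))
      int_prox_tx <- sort(unique(pl_scan$transcript_id[is_prox]))
    }
  }
  hl <- stats::rlnorm(config$n_utrs, config$halflife_meanlog,
                      config$halflife_sdlog)
  names(hl) <- tx_ids
  hl[int_prox_tx] <- hl[int_prox_tx] * config$halflife_effect
  halflife <- data.frame(transcript_id = tx_ids,
                         halflife_h = as.numeric(hl),
                         stringsAsFactors = FALSE)

  # --- expression: Zipf-skewed reads; planted families get top ranks so the
  # planted decay effect acts through expressed miRNAs ---
  nf <- nrow(families)
  ranks <- integer(nf)
  planted_idx <- match(planted_families, families$family_id)
  if (length(planted_idx) > 0L) {
    ranks[planted_idx] <- sample(seq_along(planted_idx))
    ranks[-planted_idx] <- sample(seq(length(planted_idx) + 1L, nf))
  } else {
    ranks <- sample(nf)
  }
  reads <- as.integer(round(1e5 / ranks^config$expression_skew))
  expression <- data.frame(family_id = families$family_id,
                           reads = reads, stringsAsFactors = FALSE)

  structure(list(tree = tree, utrs = utrs, rbp_motif = rbp_motif,
                 families = families, mirnas = mirnas,
                 halflife = halflife, expression = expression,
                 truth = list(rbp_sites = rbp_truth,
                              mirna_sites = mir_truth,
                              planted_families = planted_families,
                              int_proximal_tx = int_prox_tx,
                              conservation_sites = cons_truth,
                              chance_prox = chance_prox,
                              p_extra = p_extra),
                 config = config),
            class = "sim_dataset")
}

#' Write a synthetic dataset in the standard input formats
#'
#' Emits the exact formats [load_dataset()] reads -- newick, MAF, motif
#' definitions, miRNA TSV, half-life TSV, read-count TSV -- plus a
#' `truth_sites.tsv` with the planted-site bookkeeping.  Byte-identical
#' given the same dataset.
#'
#' @param sim A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             maf = file.path(dir, "utrs.maf"),
             motifs = file.path(dir, "rbp_motifs.txt"),
             mirnas = file.path(dir, "mirnas.tsv"),
             halflife = file.path(dir, "halflife.tsv"),
             expression = file.path(dir, "mirna_reads.tsv"),
             truth = file.path(dir, "truth_sites.tsv"))
  ape::write.tree(sim$tree, paths["tree"])
  write_maf(sim$utrs, paths["maf"])
  writeLines(sprintf("%s\t%s", sim$rbp_motif$name, sim$rbp_motif$pattern),
             paths["motifs"])
  write_tsv_table(sim$mirnas, paths["mirnas"])
  write_tsv_table(sim$halflife, paths["halflife"])
  write_tsv_table(sim$expression, paths["expression"])
  truth <- rbind(
    cbind(sim$truth$rbp_sites[, c("transcript_id", "start", "end")],
          name = sim$truth$rbp_sites$motif_name, kind = "rbp",
          planted_proximal = FALSE),
    cbind(sim$truth$mirna_sites[, c("transcript_id", "start", "end")],
          name = paste(sim$truth$mirna_sites$family_id,
                       sim$truth$mirna_sites$seed_type, sep = "|"),
          kind = "mirna",
          planted_proximal = sim$truth$mirna_sites$planted_proximal))
  write_tsv_table(truth, paths["truth"])
  paths
}
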