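# End-to-end pipeline: motif gating -> localization -> co-localization ->
# decay/conservation groups -> structure rescue -> seed hybridization,
# driven by a single configuration with every analysis constant exposed.

#' Default pipeline configuration
#'
#' Every constant of the analysis surfaces here: the +/-10 nt conservation
#' window, the 50 nt proximity window, permutation count, FDR threshold,
#' the 5 nt pair-window flanks and 1 nt mask flank, the -1 kcal/mol open
#' rule, the top-25% expression quantile, the 0.6 precision / 10 hit gate,
#' the 200/10/3 shuffled-motif counts, and the 2/0/-1 alignment scoring.
#'
#' @param seed Master seed.
#' @param ... Overrides of any default entry.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    conservation_window = 10L,
    proximity_nt = 50L,
    n_perm = 10000L,
    fdr = 0.05,
    pair_flank = 5L,
    mask_flank = 1L,
    open_energy = -1,
    expression_quantile = 0.25,
    gate_precision = 0.6,
    gate_min_hits = 10L,
    shuffle_n_raw = 200L,
    shuffle_max_keep = 10L,
    shuffle_min_keep = 3L,
    hyb_match = 2, hyb_mismatch = 0, hyb_gap = -1,
    engine = "fallback",
    rescue_n_background = 10L,
    rescue_max_pairs = 400L,
    pvalue_add_one = FALSE,
    stages = c("gate", "localize", "colocalize", "decay", "rescue",
               "hybridize")
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0L) {
    stop("unknown pipeline config key(s): ", paste(bad, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys override [pipeline_config()] defaults.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Scan UTR sequences for all seed-family site motifs
#'
#' Scans both site types (7mer-m8 and 7mer-1A) of every family across the
#' reference sequences and returns one combined site table, annotated with
#' `family_id`, `seed_type` and the site `pattern` — the format the
#' co-localization and decay stages expect.
#'
#' @param ref_seqs Named character vector of reference UTR sequences.
#' @param families A [build_seed_families()] table.
#' @return Site-call data.frame with `family_id`, `seed_type`, `pattern`.
#' @export
scan_family_sites <- function(ref_seqs, families) {
  out <- list()
  for (i in seq_len(nrow(families))) {
    for (st in c("m8", "1a")) {
      pat <- if (st == "m8") families$m8_pattern[i] else
        families$a1_pattern[i]
      m <- parse_motif_consensus(pat, families$family_id[i],
                                 if (st == "m8") "mirna_m8" else "mirna_1a")
      s <- scan_utr_sites(ref_seqs, m)
      if (nrow(s) > 0L) {
        s$family_id <- families$family_id[i]
        s$seed_type <- st
        s$pattern <- pat
        out[[length(out) + 1L]] <- s
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(transcript_id = character(0),
                      motif_name = character(0), start = integer(0),
                      end = integer(0), family_id = character(0),
                      seed_type = character(0), pattern = character(0))
  }
  rownames(res) <- NULL
  res
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order on a loaded or simulated dataset, writes
#' one report TSV per stage into `out_dir`, and returns a run manifest
#' (config snapshot, input checksums, stage timings, output paths, seeds).
#'
#' @param data A `sim_dataset` or the list returned by [load_dataset()].
#' @param out_dir Output directory for stage reports.
#' @param config A [pipeline_config()].
#' @return List of class `run_manifest` (also contains a `results` list
#'   with the in-memory stage outputs).
#' @export
run_pipeline <- function(data, out_dir, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), outputs = character(0),
                   timings = numeric(0), seeds = list(seed = config$seed))
  results <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    manifest$timings[name] <<- proc.time()[["elapsed"]] - t0
    val
  }
  emit <- function(name, df) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    write_tsv_table(df, path)
    manifest$outputs <<- c(manifest$outputs, path)
    path
  }
  ref_seqs <- utr_ref_seqs(data$utrs)
  utr_lengths <- nchar(ref_seqs)
  rbp_motif <- if (!is.null(data$rbp_motif)) data$rbp_motif else
    data$motifs[[1]]
  families <- data$families
  stages <- config$stages

  rbp_sites <- scan_utr_sites(ref_seqs, rbp_motif)
  mirna_sites <- scan_family_sites(ref_seqs, families)

  controls <- NULL
  if (any(c("gate", "decay", "hybridize") %in% stages)) {
    controls <- generate_control_motifs(
      rbp_motif, ref_seqs, n_raw = config$shuffle_n_raw,
      max_keep = config$shuffle_max_keep,
      min_keep = config$shuffle_min_keep, seed = config$seed + 11L)
  }

  if ("gate" %in% stages) {
    results$gate <- t_stage("gate", {
      sites_bls <- bls_annotate_sites(rbp_sites, data$utrs, rbp_motif,
                                      data$tree,
                                      config$conservation_window)
      shuf_bls <- lapply(controls$motifs, function(m) {
        s <- scan_utr_sites(ref_seqs, m)
        bls_annotate_sites(s, data$utrs, m, data$tree,
                           config$conservation_window)$bls
      })
      curve <- precision_curve(sites_bls$bls, shuf_bls)
      list(sites = sites_bls, curve = curve,
           passes = gate_rbp_motif(curve, config$gate_precision,
                                   config$gate_min_hits))
    })
    emit("gate_precision_curve", results$gate$curve)
    rbp_sites <- results$gate$sites  # keep the BLS annotation downstream
  }

  if ("localize" %in% stages) {
    results$localize <- t_stage("localize", {
      profs <- lapply(UTR_LENGTH_CLASSES, function(cl) {
        tryCatch(decile_site_fractions(rbp_sites, utr_lengths, cl),
                 error = function(e) NULL)
      })
      names(profs) <- UTR_LENGTH_CLASSES
      profs[!vapply(profs, is.null, logical(1))]
    })
    emit("localization_profiles",
         do.call(rbind, results$localize))
  }

  if ("colocalize" %in% stages) {
    results$colocalize <- t_stage("colocalize", {
      it <- colocalization_test(rbp_sites, mirna_sites, utr_lengths,
                                n_perm = config$n_perm,
                                seed = config$seed + 23L,
                                add_one = config$pvalue_add_one)
      list(table = it,
           interacting = call_interacting_mirnas(it, config$fdr),
           enrichment = window_enrichment_matrix(it))
    })
    emit("interaction_table", as.data.frame(results$colocalize$table))
    emit("window_enrichment",
         data.frame(family_id = rownames(results$colocalize$enrichment),
                    results$colocalize$enrichment, check.names = FALSE))
  }

  interacting <- if (!is.null(results$colocalize)) {
    results$colocalize$interacting
  } else {
    character(0)
  }
  expressed <- filter_expressed_mirnas(data$expression,
                                       config$expression_quantile)

  if ("decay" %in% stages) {
    results$decay <- t_stage("decay", {
      assign <- classify_transcripts_by_pairing(
        rbp_sites, mirna_sites, interacting, expressed,
        names(data$utrs), config$proximity_nt)
      hl <- data$halflife
      vals <- stats::setNames(hl[[2]], hl[[1]])[assign$transcript_id]
      cmp <- compare_group_values(split(vals, assign$group))
      cons <- if ("bls" %in% names(rbp_sites)) {
        site_conservation_by_group(rbp_sites, mirna_sites, interacting,
                                   expressed, config$proximity_nt)
      }
      list(assignments = assign, comparison = cmp, conservation = cons)
    })
    emit("decay_groups", results$decay$assignments)
    emit("decay_comparison", results$decay$comparison$summary)
    emit("decay_tests", results$decay$comparison$tests)
  }

  if ("rescue" %in% stages) {
    results$rescue <- t_stage("rescue", {
      prox <- colocalization_pairs(rbp_sites, mirna_sites,
                                   max_gap = config$proximity_nt + 1L)
      prox <- prox[prox$gap <= config$proximity_nt, , drop = FALSE]
      rescue_pair_analysis(prox, rbp_sites, mirna_sites, ref_seqs,
                           interacting, config)
    })
    emit("rescue_histogram", results$rescue$histogram)
  }

  if ("hybridize" %in% stages) {
    results$hybridize <- t_stage("hybridize", {
      if (length(interacting) == 0L ||
          length(interacting) == nrow(families)) {
        NULL
      } else {
        score_groups(families, rbp_motif, interacting,
                     control_motifs = controls$motifs)
      }
    })
    if (!is.null(results$hybridize)) {
      emit("hybridization_scores", results$hybridize$scores)
    }
  }

  manifest$checksums <- tryCatch(
    tools::md5sum(manifest$outputs), error = function(e) NULL)
  manifest$results <- results
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

# Rescue-stage work: build pair windows for interacting and non-interacting
# proximal pairs, compute rescue counts and the shuffle background.
rescue_pair_analysis <- function(prox, rbp_sites, mirna_sites, ref_seqs,
                                 interacting, config) {
  if (nrow(prox) == 0L) {
    return(list(real = numeric(0), histogram = data.frame(),
                p_int_vs_non = NA_real_, p_real_vs_background = NA_real_))
  }
  # pair windows; skip pairs whose mask would cover the miRNA site
  build_windows <- function(sub) {
    out <- list()
    for (i in seq_len(nrow(sub))) {
      # locate the rbp site row feeding this pair: nearest on transcript
      tx <- sub$transcript_id[i]
      mir <- mirna_sites[sub$mirna_idx[i], ]
      r <- rbp_sites[rbp_sites$transcript_id == tx, , drop = FALSE]
      gw <- gap_window_vec(r$start, r$end, mir$start, mir$end)
      r <- r[which.min(gw$gap), ]
      w <- tryCatch(extract_pair_window(ref_seqs[[tx]], r, mir,
                                        config$pair_flank),
                    error = function(e) NULL)
      if (is.null(w)) next
      # overlapping sites are unsupported by the mask rule
      if (max(0L, w$rbp[1] - config$mask_flank) <
          w$mirna[2] &&
          w$mirna[1] < min(nchar(w$seq), w$rbp[2] + config$mask_flank)) next
      out[[length(out) + 1L]] <- w
    }
    out
  }
  cap <- config$rescue_max_pairs
  int_pairs <- prox[prox$family_id %in% interacting, , drop = FALSE]
  non_pairs <- prox[!(prox$family_id %in% interacting), , drop = FALSE]
  if (nrow(int_pairs) > cap) int_pairs <- int_pairs[seq_len(cap), ]
  if (nrow(non_pairs) > cap) non_pairs <- non_pairs[seq_len(cap), ]
  w_int <- build_windows(int_pairs)
  w_non <- build_windows(non_pairs)
  c_int <- rescue_counts_for_pairs(w_int, config$engine,
                                   config$open_energy,
                                   mask_flank = config$mask_flank)
  c_non <- rescue_counts_for_pairs(w_non, config$engine,
                                   config$open_energy,
                                   mask_flank = config$mask_flank)
  bg <- NULL
  p_bg <- NA_real_
  if (length(w_int) > 0L) {
    bg <- rescue_background(w_int, n = config$rescue_n_background,
                            engine = config$engine,
                            open_energy = config$open_energy,
                            mask_flank = config$mask_flank,
                            seed = config$seed + 31L)
    p_bg <- compare_rescue_distributions(
      attr(bg, "real"), as.vector(attr(bg, "background")))$p_greater
  }
  p_int <- if (length(c_int) > 0L && length(c_non) > 0L) {
    compare_rescue_distributions(c_int, c_non)$p_greater
  } else NA_real_
  hist_df <- if (!is.null(bg)) bg else {
    bins <- sort(unique(c(c_int, c_non)))
    data.frame(bin = bins,
               real_count = vapply(bins, function(b)
                 sum(c_int == b), numeric(1)),
               bg_mean = NA_real_, bg_sd = NA_real_)
  }
  list(real = c_int, nonint = c_non, histogram = hist_df,
       p_int_vs_non = p_int, p_real_vs_background = p_bg)
}
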