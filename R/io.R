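# Standard-format I/O and the AlignedUTR container.
#
# All site coordinates in this package are 0-based, half-open intervals on
# the reference UTR sequence, 5'->3' sense; strand resolution is assumed to
# have happened at annotation time.

#' Construct an aligned 3'UTR
#'
#' A reference 3'UTR with per-species gapped alignment rows.  Ungapping the
#' reference row must reproduce the reference sequence; all rows must have
#' equal length; reference UTRs shorter than 10 nt are rejected (the standard
#' minimum-length filter for 3'UTR annotations).
#'
#' @param transcript_id Transcript identifier.
#' @param ref_species Name of the reference species (must be a row name).
#' @param rows Named character vector of gapped aligned rows (gap = `-`),
#'   RNA alphabet plus `N`.
#' @return An object of class `aligned_utr` with fields `transcript_id`,
#'   `ref_species`, `ref_seq`, `rows`, `ref_to_column` (integer vector:
#'   1-based alignment column of each 0-based reference position).
#' @export
aligned_utr <- function(transcript_id, ref_species, rows) {
  stopifnot(is.character(rows), !is.null(names(rows)),
            ref_species %in% names(rows))
  rows <- toupper(chartr("T", "U", rows))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("aligned rows of transcript ", transcript_id,
         " have unequal lengths")
  }
  ref_row <- rows[[ref_species]]
  ref_seq <- gsub("-", "", ref_row, fixed = TRUE)
  if (nchar(ref_seq) < 10L) {
    stop("reference UTR of ", transcript_id, " shorter than 10 nt")
  }
  ref_chars <- strsplit(ref_row, "")[[1]]
  structure(list(
    transcript_id = transcript_id,
    ref_species = ref_species,
    ref_seq = ref_seq,
    rows = rows,
    ref_to_column = which(ref_chars != "-")
  ), class = "aligned_utr")
}

#' @export
print.aligned_utr <- function(x, ...) {
  cat(sprintf("<aligned_utr> %s: %d nt reference (%s), %d species\n",
              x$transcript_id, nchar(x$ref_seq), x$ref_species,
              length(x$rows)))
  invisible(x)
}

# Reference coordinate (0-based) anchored at an alignment column: the number
# of reference bases strictly before the column.  For a non-gap reference
# column this is the reference index of that column.
column_to_ref_pos <- function(autr, column) {
  ref_chars <- strsplit(autr$rows[[autr$ref_species]], "")[[1]]
  cumsum(ref_chars != "-")[column] - as.integer(ref_chars[column] != "-")
}

#' Write aligned UTRs to a MAF file
#'
#' Minimal MAF (multiple alignment format) writer: one `a` block per UTR,
#' `s` lines named `species.transcript_id`, reference row first.
#'
#' @param utrs List of `aligned_utr`.
#' @param path Output file.
#' @export
write_maf <- function(utrs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=none", con)
  for (u in utrs) {
    writeLines("", con)
    writeLines("a score=0.0", con)
    ord <- c(u$ref_species, setdiff(names(u$rows), u$ref_species))
    for (sp in ord) {
      row <- u$rows[[sp]]
      ung <- gsub("-", "", row, fixed = TRUE)
      writeLines(sprintf("s %s.%s 0 %d + %d %s", sp, u$transcript_id,
                         nchar(ung), nchar(ung), row), con)
    }
  }
  invisible(path)
}

#' Read aligned UTRs from a MAF file
#'
#' Parses `s` lines grouped into `a` blocks; the first `s` line of each block
#' is taken as the reference row.  Sequence names must be
#' `species.transcript_id`.
#'
#' @param path MAF file.
#' @param min_length Reference UTRs shorter than this are dropped (with a
#'   message reporting the count).
#' @return Named list of `aligned_utr` keyed by transcript id.
#' @export
read_maf <- function(path, min_length = 10L) {
  lines <- readLines(path)
  utrs <- list()
  block <- character(0)
  dropped <- 0L
  flush_block <- function(block) {
    if (length(block) == 0L) return(NULL)
    parts <- strsplit(trimws(block), "[ \t]+")
    rows <- character(0)
    tx <- NULL
    for (i in seq_along(parts)) {
      p <- parts[[i]]
      if (length(p) != 7L) {
        stop("malformed MAF s-line in ", path, ": '", block[i], "'")
      }
      src <- strsplit(p[2], ".", fixed = TRUE)[[1]]
      if (length(src) < 2L) {
        stop("MAF sequence name must be species.transcript: ", p[2])
      }
      sp <- src[1]
      tx <- paste(src[-1], collapse = ".")
      rows[sp] <- p[7]
    }
    if (length(unique(nchar(rows))) != 1L) {
      stop("MAF block for ", tx, " in ", path, " has rows of unequal length")
    }
    list(tx = tx, ref = names(rows)[1], rows = rows)
  }
  out <- list()
  for (ln in c(lines, "a")) {
    if (grepl("^a( |$)", ln)) {
      b <- flush_block(block)
      if (!is.null(b)) out[[length(out) + 1L]] <- b
      block <- character(0)
    } else if (grepl("^s ", ln)) {
      block <- c(block, ln)
    }
  }
  for (b in out) {
    ref_len <- nchar(gsub("-", "", b$rows[[b$ref]], fixed = TRUE))
    if (ref_len < min_length) {
      dropped <- dropped + 1L
      next
    }
    utrs[[b$tx]] <- aligned_utr(b$tx, b$ref, b$rows)
  }
  if (dropped > 0L) {
    message("read_maf: dropped ", dropped, " UTR(s) shorter than ",
            min_length, " nt")
  }
  utrs
}

#' Write site calls as BED6
#'
#' `chrom` is the transcript id, `name` the motif or family id and the score
#' column carries `round(BLS * 1000)` when a `bls` column is present
#' (0 otherwise).
#'
#' @param sites Site-call data.frame.
#' @param path Output file.
#' @export
write_sites_bed <- function(sites, path) {
  score <- if ("bls" %in% names(sites) && nrow(sites) > 0) {
    ifelse(is.na(sites$bls), 0L, as.integer(round(sites$bls * 1000)))
  } else {
    rep(0L, nrow(sites))
  }
  df <- data.frame(sites$transcript_id, sites$start, sites$end,
                   sites$motif_name, score, rep("+", nrow(sites)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file of sites or regions
#'
#' @param path BED file (no header, >= 3 columns).
#' @param bls_from_score If TRUE, recover a `bls` column as score / 1000.
#' @return data.frame with `transcript_id`, `start`, `end` and, when present,
#'   `motif_name`, `score`/`bls`.
#' @export
read_bed <- function(path, bls_from_score = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file ", path, " has fewer than 3 columns")
  out <- data.frame(transcript_id = as.character(df[[1]]),
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$start < 0 | out$end <= out$start)) {
    stop("BED file ", path, " contains invalid intervals")
  }
  if (ncol(df) >= 4L) out$motif_name <- as.character(df[[4]])
  if (ncol(df) >= 5L) {
    out$score <- as.numeric(df[[5]])
    if (bls_from_score) out$bls <- out$score / 1000
  }
  out
}

#' Read a two-column motif definition file
#'
#' Whitespace-separated `name pattern` lines; `#` comments allowed.
#'
#' @param path Motif file.
#' @param kind Motif kind passed to [parse_motif_consensus()].
#' @return Named list of `motif_consensus`.
#' @export
read_motif_table <- function(path, kind = "rbp") {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    p <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(p) != 2L) {
      stop("malformed motif line ", i, " in ", path, ": '", lines[i], "'")
    }
    out[[p[1]]] <- parse_motif_consensus(p[2], p[1], kind)
  }
  out
}

#' Read a simple headered TSV table
#'
#' @param path TSV with a one-line header.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a TSV table with header
#' @param df data.frame.
#' @param path Output file.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a full analysis dataset
#'
#' Reads and cross-references the inputs of a genome-scale run: phylogeny
#' (newick with branch lengths), aligned UTRs (MAF), RBP motifs, mature
#' miRNAs (TSV: `family_id`, `mature_seq`), and optional half-life /
#' decay-rate, miRNA read-count and binding-region tables.
#'
#' @param tree_path Newick file.
#' @param maf_path MAF file of aligned 3'UTRs.
#' @param motif_path Two-column RBP motif definitions.
#' @param mirna_path TSV of mature miRNAs.
#' @param halflife_path,expression_path,regions_path Optional TSV/BED paths.
#' @param orientation Seed-site orientation, see [derive_seed_site_motifs()].
#' @return List with `tree` (ape `phylo`), `utrs`, `motifs`, `families`,
#'   `halflife`, `expression`, `regions`.
#' @export
load_dataset <- function(tree_path, maf_path, motif_path, mirna_path,
                         halflife_path = NULL, expression_path = NULL,
                         regions_path = NULL,
                         orientation = "reverse_complement") {
  tree <- ape::read.tree(tree_path)
  if (is.null(tree)) stop("could not parse newick tree from ", tree_path)
  utrs <- read_maf(maf_path)
  motifs <- read_motif_table(motif_path, "rbp")
  mirnas <- read_tsv_table(mirna_path)
  families <- build_seed_families(mirnas, orientation)
  sp_utr <- unique(unlist(lapply(utrs, function(u) names(u$rows))))
  missing_sp <- setdiff(sp_utr, tree$tip.label)
  if (length(missing_sp) > 0L) {
    stop("species in alignments absent from tree: ",
         paste(missing_sp, collapse = ", "))
  }
  halflife <- if (!is.null(halflife_path)) read_tsv_table(halflife_path)
  expression <- if (!is.null(expression_path)) read_tsv_table(expression_path)
  if (!is.null(expression) &&
      any(expression[[2]] < 0)) {
    stop("negative read counts in ", expression_path)
  }
  regions <- if (!is.null(regions_path)) read_bed(regions_path)
  list(tree = tree, utrs = utrs, motifs = motifs, families = families,
       halflife = halflife, expression = expression, regions = regions)
}

#' Reference sequences of a UTR collection
#' @param utrs List of `aligned_utr`.
#' @return Named character vector of reference sequences.
#' @export
utr_ref_seqs <- function(utrs) {
  vapply(utrs, function(u) u$ref_seq, character(1))
}
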