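# RNA secondary-structure folding engines and the dinucleotide-preserving
# shuffle used as the folding background model.
#
# Folding is a pluggable boundary: "vienna" shells out to RNAfold for true
# thermodynamic MFE structures, "fallback" is a maximum-base-pairing
# (Nussinov) engine with minimum hairpin loop 3 and G-U wobble, assigning a
# pseudo-energy of -1 per pair.  Structures with energy above the open
# threshold (-1 kcal/mol) are treated as totally open.

RNA_PAIRS <- matrix(FALSE, 5, 5,
                    dimnames = list(c("A", "C", "G", "U", "N"),
                                    c("A", "C", "G", "U", "N")))
RNA_PAIRS["A", "U"] <- RNA_PAIRS["U", "A"] <- TRUE
RNA_PAIRS["G", "C"] <- RNA_PAIRS["C", "G"] <- TRUE
RNA_PAIRS["G", "U"] <- RNA_PAIRS["U", "G"] <- TRUE

#' Fold an RNA sequence
#'
#' Computes a secondary structure with the selected engine.  `N` positions
#' are never paired.  If the reported energy is above `open_energy`
#' (default -1 kcal/mol) the structure is replaced by the all-unpaired
#' structure ("totally open").
#'
#' @param seq RNA sequence over `A,C,G,U,N`.
#' @param engine `"fallback"` (maximum pairing, always available) or
#'   `"vienna"` (requires the RNAfold executable on the PATH).
#' @param open_energy Open-structure energy threshold in kcal/mol.
#' @param min_loop Minimum hairpin loop size for the fallback engine.
#' @return Object of class `fold_result`: `structure` (dot-bracket),
#'   `energy`, `paired` (logical per position), `open` (flag).
#' @export
fold <- function(seq, engine = c("fallback", "vienna"), open_energy = -1,
                 min_loop = 3L) {
  engine <- match.arg(engine)
  seq <- chartr("Tt", "Uu", toupper(seq))
  if (!nzchar(seq)) stop("empty sequence")
  res <- switch(engine,
                fallback = fold_nussinov(seq, min_loop),
                vienna = fold_vienna(seq))
  # "totally open" rule: thermodynamic energies use the strict threshold
  # (energy larger than -1 kcal/mol); the fallback's integer pseudo-energy
  # of -1 per pair uses >=, so single-pair structures count as open
  is_open <- if (engine == "fallback") res$energy >= open_energy
             else res$energy > open_energy
  if (is_open) {
    res$structure <- strrep(".", nchar(seq))
    res$paired <- rep(FALSE, nchar(seq))
    res$open <- TRUE
  } else {
    res$open <- FALSE
  }
  res$seq <- seq
  res$engine <- engine
  class(res) <- "fold_result"
  res
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$seq, "\n", x$structure,
      sprintf(" (%.2f%s)\n", x$energy,
              if (x$engine == "fallback") " pseudo" else " kcal/mol"),
      sep = "")
  invisible(x)
}

#' Test for the RNAfold executable
#' @return TRUE when RNAfold can be invoked.
#' @export
has_rnafold <- function() {
  nzchar(Sys.which("RNAfold"))
}

fold_vienna <- function(seq) {
  if (!has_rnafold()) {
    stop("RNAfold executable not found; use engine = 'fallback'")
  }
  out <- system2("RNAfold", args = c("--noPS"), input = seq, stdout = TRUE)
  if (length(out) < 2L) stop("unexpected RNAfold output")
  line <- out[2]
  struct <- sub(" .*$", "", line)
  energy <- as.numeric(gsub("[()\\s]", "",
                            regmatches(line,
                                       regexpr("\\(\\s*-?[0-9.]+\\s*\\)$",
                                               line))))
  if (nchar(struct) != nchar(seq) || is.na(energy)) {
    stop("could not parse RNAfold output: ", line)
  }
  paired <- strsplit(struct, "")[[1]] %in% c("(", ")")
  list(structure = struct, energy = energy, paired = paired)
}

# Maximum base-pairing (Nussinov) engine, compiled.  dp[i,j] = maximum
# number of pairs in subsequence i..j; pairing k with j requires
# j - k > min_loop.
fold_nussinov <- function(seq, min_loop = 3L) {
  res <- .nussinov_fold(gsub("[^ACGU]", "N", seq), min_loop)
  list(structure = res$structure,
       energy = -1.0 * res$n_pairs,
       paired = res$paired)
}

# Pure-R reference implementation of the same recursion (kept for
# cross-checking the compiled engine on small inputs).
fold_nussinov_r <- function(seq, min_loop = 3L) {
  b <- strsplit(seq, "")[[1]]
  b[!(b %in% c("A", "C", "G", "U"))] <- "N"
  n <- length(b)
  pairable <- RNA_PAIRS[b, b, drop = FALSE]
  dp <- matrix(0L, n, n)
  if (n > min_loop + 1L) {
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- dp[i, j - 1L]
        ks <- i:(j - min_loop - 1L)
        ks <- ks[pairable[ks, j]]
        if (length(ks) > 0L) {
          left <- ifelse(ks > i, dp[cbind(pmax(i, 1L), pmax(ks - 1L, 1L))], 0L)
          left[ks == i] <- 0L
          inner <- dp[cbind(pmin(ks + 1L, n), j - 1L)]
          inner[ks + 1L > j - 1L] <- 0L
          cand <- left + inner + 1L
          best <- max(best, cand)
        }
        dp[i, j] <- best
      }
    }
  }
  # traceback
  paired_with <- integer(n)
  stack <- list(c(1L, n))
  while (length(stack) > 0L) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j || j - i <= min_loop) next
    if (dp[i, j] == dp[i, j - 1L]) {
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
      next
    }
    for (k in i:(j - min_loop - 1L)) {
      if (!pairable[k, j]) next
      left <- if (k > i) dp[i, k - 1L] else 0L
      inner <- if (k + 1L <= j - 1L) dp[k + 1L, j - 1L] else 0L
      if (left + inner + 1L == dp[i, j]) {
        paired_with[k] <- j
        paired_with[j] <- k
        if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
        if (k + 1L <= j - 1L) stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
        break
      }
    }
  }
  struct <- rep(".", n)
  struct[paired_with > seq_len(n)] <- "("
  struct[paired_with > 0L & paired_with < seq_len(n)] <- ")"
  npairs <- sum(paired_with > 0L) / 2
  list(structure = paste(struct, collapse = ""),
       energy = -1.0 * npairs,
       paired = paired_with > 0L)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson Eulerian-path shuffle: the output is a uniform-ish
#' random sequence with exactly the same mono- and di-nucleotide counts as
#' the input; the first and last nucleotides are preserved.
#'
#' @param seq Sequence of length at least 3.
#' @param seed Optional integer seed for reproducibility.
#' @return Shuffled sequence (character scalar).
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  b <- strsplit(toupper(chartr("t", "u", seq)), "")[[1]]
  n <- length(b)
  if (n < 3L) stop("sequence must be at least 3 nt")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  verts <- unique(b)
  if (length(verts) == 1L) return(paste(b, collapse = ""))
  from <- b[-n]
  to <- b[-1L]
  terminal <- b[n]
  edges <- split(to, factor(from, levels = verts))
  # Altschul-Erickson: pick, for every non-terminal vertex that has edges, a
  # random "last" out-edge such that following last edges from any vertex
  # reaches the terminal vertex; then randomly order the remaining edges.
  non_term <- setdiff(names(Filter(length, edges)), terminal)
  repeat {
    last_edge <- vapply(non_term, function(v) sample(edges[[v]], 1L),
                        character(1))
    ok <- all(vapply(non_term, function(v) {
      seen <- character(0)
      cur <- v
      while (!(cur %in% seen)) {
        if (cur == terminal || !(cur %in% non_term)) return(TRUE)
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      FALSE
    }, logical(1)))
    if (ok) break
  }
  shuffled_edges <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (is.null(e) || length(e) == 0L) return(character(0))
    if (v %in% non_term) {
      # remove one instance of the chosen last edge, shuffle, append it
      i <- match(last_edge[[v]], e)
      rest <- e[-i]
      c(if (length(rest) > 1L) sample(rest) else rest, last_edge[[v]])
    } else {
      if (length(e) > 1L) sample(e) else e
    }
  })
  names(shuffled_edges) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- b[1]
  cur <- b[1]
  for (i in 2:n) {
    e <- shuffled_edges[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- e
    cur <- e
  }
  paste(out, collapse = "")
}
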