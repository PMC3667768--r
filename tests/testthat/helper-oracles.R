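# Independent oracles and small fixture builders used across the suite.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

# Brute-force motif scan: check every window against the expanded
# degenerate alphabet (subject N matches nothing).
brute_scan <- function(seq, pattern) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  k <- length(p)
  starts <- integer(0)
  if (length(s) >= k) {
    for (i in 0:(length(s) - k)) {
      win <- s[(i + 1):(i + k)]
      if (all(vapply(seq_len(k), function(j)
        win[j] %in% IUPAC_SETS[[p[j]]], logical(1)))) {
        starts <- c(starts, i)
      }
    }
  }
  starts
}

# Brute-force branch length score: an edge belongs to the minimal spanning
# subtree iff the tips below it contain some but not all of the species set.
tips_below_edge <- function(tree, edge_row) {
  child <- tree$edge[edge_row, 2]
  n_tip <- length(tree$tip.label)
  if (child <= n_tip) return(tree$tip.label[child])
  below <- child
  repeat {
    kids <- tree$edge[tree$edge[, 1] %in% below, 2]
    new <- setdiff(kids, below)
    if (length(new) == 0L) break
    below <- c(below, new)
  }
  tree$tip.label[below[below <= n_tip]]
}

brute_bls <- function(tree, species_set) {
  if (length(species_set) < 2L) return(0)
  total <- sum(tree$edge.length)
  len <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tb <- tips_below_edge(tree, e)
    n_in <- length(intersect(tb, species_set))
    if (n_in > 0L && n_in < length(species_set)) {
      len <- len + tree$edge.length[e]
    }
  }
  len / total
}

# Independent maximum-pairing oracle: top-down recursion on the leftmost
# position (pair it with some k, or leave it unpaired), memoized on (i, j).
# The recurrence direction differs from the package engine's iterative
# span/right-end DP, so the two implementations are independent checks of
# the same quantity.
brute_max_pairs <- function(seq, min_loop = 3L) {
  b <- strsplit(gsub("[^ACGU]", "N", seq), "")[[1]]
  n <- length(b)
  if (n < min_loop + 2L) return(0L)
  can <- function(x, y) {
    paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(0L)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- rec(i + 1L, j)
    for (k in seq.int(i + min_loop + 1L,
                      length.out = max(0L, j - i - min_loop))) {
      if (can(b[i], b[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, n)
}

# Fully exhaustive structure enumeration (every legal structure visited),
# feasible only for very short sequences; used to spot-check the memoized
# oracle itself.
enumerate_max_pairs <- function(seq, min_loop = 3L) {
  b <- strsplit(gsub("[^ACGU]", "N", seq), "")[[1]]
  can <- function(x, y) {
    paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  rec <- function(i, j) {
    if (i >= j) return(0L)
    best <- rec(i + 1L, j)
    for (k in seq.int(i + min_loop + 1L, length.out =
                        max(0L, j - i - min_loop))) {
      if (can(b[i], b[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  if (length(b) < min_loop + 2L) return(0L)
  rec(1L, length(b))
}

# Exhaustive local-alignment maximum for the hybridization score: recursion
# over all alignment extensions from every start pair.
brute_local_align <- function(seed, motif_pattern, match = 2, mismatch = 0,
                              gap = -1) {
  s <- strsplit(toupper(seed), "")[[1]]
  m <- strsplit(toupper(motif_pattern), "")[[1]]
  pairs_ok <- function(a, letter) {
    exp <- IUPAC_SETS[[letter]]
    any(paste0(a, exp) %in% c("AU", "UA", "GC", "CG", "GU", "UG"))
  }
  memo <- new.env(parent = emptyenv())
  ext <- function(i, j) {
    # best score of an alignment starting at (i, j), allowed to stop
    # anywhere (suffix recursion; the package DP works on prefixes)
    if (i > length(s) || j > length(m)) return(0)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    sub <- if (pairs_ok(s[i], m[j])) match else mismatch
    best <- max(0,
                sub + ext(i + 1, j + 1),
                gap + ext(i + 1, j),
                gap + ext(i, j + 1))
    memo[[key]] <- best
    best
  }
  best <- 0
  for (i in seq_along(s)) {
    for (j in seq_along(m)) {
      best <- max(best, ext(i, j))
    }
  }
  best
}

# All distinct permutations of a label vector within strata (for exact
# permutation p-values on tiny co-localization instances).
all_strata_perms <- function(labels, strata) {
  perms_of <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms_of(v[-i])) {
        out[[length(out) + 1L]] <- c(v[i], rest)
      }
    }
    out
  }
  idx_by_stratum <- split(seq_along(labels), strata)
  per_stratum <- lapply(idx_by_stratum, function(idx)
    perms_of(labels[idx]))
  grids <- expand.grid(lapply(per_stratum, seq_along))
  lapply(seq_len(nrow(grids)), function(g) {
    lab <- labels
    for (s in seq_along(idx_by_stratum)) {
      lab[idx_by_stratum[[s]]] <- per_stratum[[s]][[grids[g, s]]]
    }
    lab
  })
}

# Fixed 4-leaf tree used in several conservation tests.
tree4 <- function() {
  ape::read.tree(text = "((Ref:1,S1:1):1,(S2:1,S3:1):1);")
}

# A small aligned-UTR block with a reference hit and a shifted hit in one
# other species (gapless rows unless specified).
make_block <- function(rows, ref = "Ref", tx = "tx1") {
  aligned_utr(tx, ref, rows)
}

random_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

dinuc_counts <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  if (length(b) < 2) return(table(character(0)))
  table(paste0(b[-length(b)], b[-1]))
}
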