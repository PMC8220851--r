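# Independent brute-force machinery: window matching re-implemented from
# the allowed-residue sets directly, and full-screen assignment by
# exhaustive enumeration over all 6-tuples of occurrences. Used as the
# oracle against which the package's scanner and DFS assembler are
# checked; shares no code path with them.

oracle_match <- function(window, matrix, allow_r6 = FALSE) {
  ch <- strsplit(window, "")[[1]]
  if (length(ch) != matrix$length) stop("window length mismatch")
  if (!allow_r6 && matrix$motif_index == 2L && ch[6] == "R") return(FALSE)
  for (p in seq_along(ch)) {
    if (!(ch[p] %in% matrix$positions[[p]])) return(FALSE)
  }
  TRUE
}

oracle_occurrences <- function(sequence, matrix, allow_r6 = FALSE) {
  n <- nchar(sequence)
  L <- matrix$length
  if (n < L) return(integer(0))
  starts <- integer(0)
  for (i in seq_len(n - L + 1L)) {
    if (oracle_match(substring(sequence, i, i + L - 1L), matrix, allow_r6)) {
      starts <- c(starts, i)
    }
  }
  starts
}

# Merged narrow/extended occurrence table for one motif, with extension cost.
oracle_motif_occ <- function(sequence, mset, k) {
  L <- mset$narrow[[k]]$length
  ns <- oracle_occurrences(sequence, mset$narrow[[k]])
  es <- setdiff(oracle_occurrences(sequence, mset$extended[[k]]), ns)
  starts <- sort(c(ns, es))
  data.frame(start = starts, end = starts + L - 1L,
             cost = as.integer(starts %in% es))
}

# Exhaustive screen: enumerate every 6-tuple of occurrences, keep the
# feasible ones, pick min (extended count, start tuple).
oracle_screen <- function(sequence, mset = alph_matrix_set(),
                          constraints = distance_constraints(),
                          budget = 2L) {
  sequence <- toupper(sequence)
  occ <- lapply(1:6, function(k) oracle_motif_occ(sequence, mset, k))
  if (any(vapply(occ, nrow, integer(1)) == 0L)) return(NULL)
  grid <- expand.grid(lapply(occ, function(t) seq_len(nrow(t))))
  bounds <- constraints$bounds
  best <- NULL
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    st <- vapply(1:6, function(k) occ[[k]]$start[idx[k]], integer(1))
    en <- vapply(1:6, function(k) occ[[k]]$end[idx[k]], integer(1))
    ext <- sum(vapply(1:6, function(k) occ[[k]]$cost[idx[k]], integer(1)))
    if (ext > budget) next
    ok <- TRUE
    for (k in 1:5) {
      if (st[k + 1] <= en[k]) { ok <- FALSE; break }
      b <- bounds[[paste0(k, "_", k + 1)]]
      if (!is.null(b)) {
        d <- if (constraints$convention == "gap") st[k + 1] - en[k] - 1L
             else st[k + 1] - st[k]
        if (d < b[1] || d > b[2]) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    cand <- list(ext = ext, starts = st)
    if (is.null(best) || oracle_key_lt(cand, best)) best <- cand
  }
  best
}

oracle_key_lt <- function(a, b) {
  if (a$ext != b$ext) return(a$ext < b$ext)
  cmp <- a$starts - b$starts
  nz <- which(cmp != 0)
  length(nz) > 0 && cmp[nz[1]] < 0
}

random_aa_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# The worked six-motif fixture: all-narrow motifs with gaps 29/26/60/40/19
# between them, 10 leading and 20 trailing alanines.
fixture_alph <- function() {
  paste0(strrep("A", 10), "GDVHG", strrep("A", 29), "GDLVGKG",
         strrep("A", 26), "GNHE", strrep("A", 60), "HGG",
         strrep("A", 40), "VIFGH", strrep("A", 19), "LDTG", strrep("A", 20))
}

# Compact generator settings used where short planted proteins are needed.
compact_spec <- function(n_positive, n_decoy_per_class = 0L, seed = 1L, ...) {
  synthetic_spec(
    n_positive = n_positive, n_decoy_per_class = n_decoy_per_class,
    d45 = data.frame(value = 20:40, prob = rep(1 / 21, 21)),
    n_term_meanlog = log(15), n_term_sdlog = 0.4,
    c_term_meanlog = log(10), c_term_sdlog = 0.4,
    seed = seed, ...
  )
}
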