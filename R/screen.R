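# Assembly of per-motif occurrences into complete ALPH calls.
#
# The search is a depth-first walk over occurrences in motif order with
# pruning on ordering, non-overlap, the three distance bounds and the
# extended-motif budget. Motifs are short and the constrained spacings
# tight, so the feasible space is tiny for real proteins; the walk is
# exact (it enumerates every feasible assignment) and the best assignment
# is chosen by (fewest extended motifs, then leftmost start tuple).

.normalise_sequence <- function(sequence) {
  gsub("[[:space:]]+", "", toupper(sequence))
}

# Bounds lookup for the adjacent pair (i, i+1); NULL when unconstrained.
.pair_bound <- function(constraints, i, j) {
  constraints$bounds[[paste0(i, "_", j)]]
}

# Exact DFS over one occurrence table per motif slot.
# occ: list of data.frames (start, end, ext_cost, ...), one per slot in order.
# pair_info: list per gap between consecutive slots with fields lo, hi (or NULL).
# Returns indices of the chosen occurrence per slot, or NULL.
.assign_motifs <- function(occ, pair_info, budget) {
  n_slots <- length(occ)
  if (any(vapply(occ, nrow, integer(1)) == 0L)) return(NULL)
  best <- NULL
  best_key <- NULL

  key_better <- function(ext, starts) {
    if (is.null(best_key)) return(TRUE)
    if (ext != best_key$ext) return(ext < best_key$ext)
    cmp <- starts - best_key$starts
    nz <- which(cmp != 0L)
    length(nz) > 0L && cmp[nz[1]] < 0L
  }

  sel <- integer(n_slots)
  recurse <- function(slot, prev_end, prev_start, ext) {
    if (slot > n_slots) {
      starts <- vapply(seq_len(n_slots), function(s) occ[[s]]$start[sel[s]], integer(1))
      if (key_better(ext, starts)) {
        best <<- sel
        best_key <<- list(ext = ext, starts = starts)
      }
      return(invisible(NULL))
    }
    tab <- occ[[slot]]
    info <- if (slot > 1L) pair_info[[slot - 1L]] else NULL
    for (i in seq_len(nrow(tab))) {
      s <- tab$start[i]
      if (slot > 1L) {
        if (s <= prev_end) next             # ordering + non-overlap
        if (!is.null(info)) {
          d <- if (info$convention == "gap") s - prev_end - 1L else s - prev_start
          if (d < info$lo) next
          if (d > info$hi) break             # starts ascend; overshoot is final
        }
      }
      e2 <- ext + tab$ext_cost[i]
      if (e2 > budget) next
      sel[slot] <<- i
      recurse(slot + 1L, tab$end[i], s, e2)
    }
    invisible(NULL)
  }
  recurse(1L, -1L, -1L, 0L)
  if (is.null(best)) NULL else best
}

.empty_call <- function() NULL

.make_call <- function(protein_id, occ, idx, motif_ids, constraints) {
  hits <- do.call(rbind, lapply(seq_along(idx), function(s) {
    row <- occ[[s]][idx[s], c("start", "end", "matched", "flavour", "ext_cost")]
    row$motif_index <- motif_ids[s]
    row
  }))
  hits <- hits[, c("motif_index", "start", "end", "matched", "flavour", "ext_cost")]
  rownames(hits) <- NULL
  dist <- rep(NA_integer_, 5L)
  names(dist) <- c("d12", "d23", "d34", "d45", "d56")
  for (s in seq_len(length(idx) - 1L)) {
    i <- motif_ids[s]; j <- motif_ids[s + 1L]
    if (j == i + 1L) {
      dist[paste0("d", i, j)] <- .pair_distance(hits$start[s], hits$end[s],
                                                hits$start[s + 1L],
                                                constraints$convention)
    }
  }
  structure(
    list(protein_id = protein_id, hits = hits, distances = dist,
         extended_count = sum(hits$ext_cost),
         convention = constraints$convention),
    class = "alph_call"
  )
}

#' @export
print.alph_call <- function(x, ...) {
  cat(sprintf("<alph_call> %s: extended_count=%d (%s convention)\n",
              x$protein_id, x$extended_count, x$convention))
  print(x$hits[, c("motif_index", "start", "end", "matched", "flavour")])
  d <- x$distances[!is.na(x$distances)]
  cat("distances:", paste(names(x$distances), x$distances, sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}

.outcome <- function(protein_id, status, call = NULL, missing_motif = NA_integer_,
                     truncated_terminal = NA_character_, notes = character(0)) {
  structure(
    list(protein_id = protein_id, status = status, call = call,
         missing_motif = missing_motif, truncated_terminal = truncated_terminal,
         notes = notes),
    class = "screen_outcome"
  )
}

#' @export
print.screen_outcome <- function(x, ...) {
  cat(sprintf("<screen_outcome> %s: %s", x$protein_id, x$status))
  if (!is.na(x$missing_motif)) cat(sprintf(" (motif %d missing", x$missing_motif),
                                   if (!is.na(x$truncated_terminal))
                                     sprintf("; candidate %s-terminal truncation", x$truncated_terminal),
                                   ")", sep = "")
  cat("\n")
  if (!is.null(x$call)) print(x$call)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

# Occurrence tables for a set of motif slots, shared by screen and audit.
.occurrence_tables <- function(sequence, mset, motif_ids, allow_r6 = FALSE) {
  seq_int <- .encode_seq(sequence)
  lapply(motif_ids, function(k)
    .motif_occurrences(seq_int, sequence, mset, k, allow_r6))
}

.pair_infos <- function(motif_ids, constraints) {
  lapply(seq_len(length(motif_ids) - 1L), function(s) {
    i <- motif_ids[s]; j <- motif_ids[s + 1L]
    b <- if (j == i + 1L) .pair_bound(constraints, i, j) else NULL
    if (is.null(b)) NULL
    else list(lo = b[1], hi = b[2], convention = constraints$convention)
  })
}

#' Screen one protein for the six ALPH motifs
#'
#' Scans the sequence with the narrow matrices, falls back on the extended
#' matrices, and searches for an ordered, non-overlapping assignment of
#' one occurrence per motif that satisfies the three inter-motif distance
#' bounds with at most `extended_budget` motifs matched only by the
#' extended matrix. Among valid assignments the one with the fewest
#' extended motifs is chosen; ties are broken by the leftmost (smallest)
#' start-position tuple. A protein with a valid assignment is an ALPH
#' call; otherwise the outcome is negative (the audit modes
#' [missing_motif_scan()] are separate).
#'
#' @param protein_id Identifier carried into the outcome.
#' @param sequence Amino-acid string; uppercased, whitespace stripped.
#' @param matrices An `alph_matrix_set` (default: built-ins).
#' @param constraints A `distance_constraints` object.
#' @param extended_budget Maximum number of extended-matrix motifs per
#'   call (default 2).
#' @param multi_domain If `TRUE`, after a positive call the remainder of
#'   the sequence downstream of motif 6 is rescanned and any additional
#'   candidate ALPH domain is reported in `notes` (the call itself is
#'   unchanged; one call per protein).
#' @param allow_r6 See [matches_at()].
#' @return A `screen_outcome` with `status` `"alph"` (and a `call`) or
#'   `"negative"`.
#' @export
screen_protein <- function(protein_id, sequence,
                           matrices = alph_matrix_set(),
                           constraints = distance_constraints(),
                           extended_budget = 2L,
                           multi_domain = FALSE,
                           allow_r6 = FALSE) {
  sequence <- .normalise_sequence(sequence)
  if (!nzchar(sequence)) stop("empty sequence for protein ", protein_id)
  occ <- .occurrence_tables(sequence, matrices, 1:6, allow_r6)
  idx <- .assign_motifs(occ, .pair_infos(1:6, constraints), extended_budget)
  if (is.null(idx)) return(.outcome(protein_id, "negative"))
  call <- .make_call(protein_id, occ, idx, 1:6, constraints)
  notes <- character(0)
  if (multi_domain) {
    tail_from <- call$hits$end[6] + 1L
    if (tail_from <= nchar(sequence)) {
      rest <- substring(sequence, tail_from)
      occ2 <- .occurrence_tables(rest, matrices, 1:6, allow_r6)
      idx2 <- .assign_motifs(occ2, .pair_infos(1:6, constraints), extended_budget)
      if (!is.null(idx2)) {
        s2 <- occ2[[1]]$start[idx2[1]] + tail_from - 1L
        notes <- sprintf("additional candidate ALPH domain starting at %d", s2)
      }
    }
  }
  .outcome(protein_id, "alph", call = call, notes = notes)
}

#' One-motif-missing audit scan
#'
#' Asks whether a protein that fails the full six-motif screen would pass
#' if one given motif were waived: the remaining five motifs must admit an
#' ordered, non-overlapping assignment with every distance bound not
#' involving the waived motif satisfied. Such proteins are candidates for
#' matrix auditing and -- when the waived motif is terminal (motif 1 or 6)
#' -- for truncated ALPHs arising from annotation or sequencing artefacts.
#' A protein that already passes the full screen returns `"negative"` for
#' this scan.
#'
#' @inheritParams screen_protein
#' @param missing Motif index 1..6 to waive.
#' @return A `screen_outcome`: `status` `"missing_one"` with
#'   `missing_motif` set (and `truncated_terminal` `"N"`/`"C"` when the
#'   waived motif is 1/6), else `"negative"`.
#' @export
missing_motif_scan <- function(protein_id, sequence,
                               matrices = alph_matrix_set(),
                               constraints = distance_constraints(),
                               missing,
                               extended_budget = 2L,
                               allow_r6 = FALSE) {
  missing <- as.integer(missing)
  if (length(missing) != 1L || is.na(missing) || missing < 1L || missing > 6L) {
    stop("missing motif index must be a single integer in 1..6")
  }
  sequence <- .normalise_sequence(sequence)
  if (!nzchar(sequence)) stop("empty sequence for protein ", protein_id)
  full <- screen_protein(protein_id, sequence, matrices, constraints,
                         extended_budget, allow_r6 = allow_r6)
  if (full$status == "alph") {
    return(.outcome(protein_id, "negative",
                    notes = "full six-motif screen already positive"))
  }
  keep <- setdiff(1:6, missing)
  occ <- .occurrence_tables(sequence, matrices, keep, allow_r6)
  idx <- .assign_motifs(occ, .pair_infos(keep, constraints), extended_budget)
  if (is.null(idx)) return(.outcome(protein_id, "negative"))
  term <- if (missing == 1L) "N" else if (missing == 6L) "C" else NA_character_
  .outcome(protein_id, "missing_one", missing_motif = missing,
           truncated_terminal = term)
}

#' Screen a whole proteome
#'
#' Runs [screen_protein()] over every record of a proteome, preserving
#' input order, and tallies a run summary.
#'
#' @param proteome Path to a FASTA file (optionally gzipped) or a proteome
#'   data frame from [read_proteome()].
#' @inheritParams screen_protein
#' @return A list of class `proteome_screen` with elements `outcomes`
#'   (list of `screen_outcome`, input order) and `summary` (records
#'   scanned, ALPH calls, fraction of motifs and fraction of calls using
#'   the extended flavour).
#' @export
screen_proteome <- function(proteome,
                            matrices = alph_matrix_set(),
                            constraints = distance_constraints(),
                            extended_budget = 2L,
                            multi_domain = FALSE,
                            allow_r6 = FALSE) {
  if (is.character(proteome)) proteome <- read_proteome(proteome)
  outcomes <- vector("list", nrow(proteome))
  for (i in seq_len(nrow(proteome))) {
    outcomes[[i]] <- screen_protein(proteome$record_id[i], proteome$sequence[i],
                                    matrices, constraints, extended_budget,
                                    multi_domain, allow_r6)
  }
  calls <- Filter(Negate(is.null), lapply(outcomes, `[[`, "call"))
  n_alph <- length(calls)
  ext_motifs <- sum(vapply(calls, `[[`, numeric(1), "extended_count"))
  summary <- list(
    n_records = nrow(proteome),
    n_alph = n_alph,
    n_extended_motifs = ext_motifs,
    frac_motifs_extended = if (n_alph) ext_motifs / (6 * n_alph) else NA_real_,
    frac_calls_extended = if (n_alph)
      mean(vapply(calls, `[[`, numeric(1), "extended_count") > 0) else NA_real_
  )
  structure(list(outcomes = outcomes, summary = summary),
            class = "proteome_screen")
}

#' @export
print.proteome_screen <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<proteome_screen> %d records, %d ALPH call(s)\n",
              s$n_records, s$n_alph))
  if (s$n_alph > 0) {
    cat(sprintf("  extended-flavour usage: %.2f%% of motifs, %.2f%% of calls\n",
                100 * s$frac_motifs_extended, 100 * s$frac_calls_extended))
  }
  invisible(x)
}

#' Tabulate screen outcomes
#'
#' Flattens a list of `screen_outcome` objects (or a `proteome_screen`)
#' into one row per protein, with per-motif 1-based inclusive start
#' positions, matched strings and flavours, the five inter-motif
#' distances, and the extended-motif count. Stable column order; suitable
#' for TSV export via [write_table_tsv()].
#'
#' @param outcomes A `proteome_screen` or list of `screen_outcome`.
#' @return A data frame, one row per outcome, input order.
#' @export
outcomes_table <- function(outcomes) {
  if (inherits(outcomes, "proteome_screen")) outcomes <- outcomes$outcomes
  if (inherits(outcomes, "screen_outcome")) outcomes <- list(outcomes)
  cols <- c("protein_id", "status", "missing_motif", "truncated_terminal",
            as.vector(t(outer(paste0("m", 1:6),
                              c("_start", "_match", "_flavour"), paste0))),
            paste0("d", c(12, 23, 34, 45, 56)), "extended_count", "notes")
  if (!length(outcomes)) {
    empty <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                           stringsAsFactors = FALSE)
    return(empty)
  }
  rows <- lapply(outcomes, function(o) {
    row <- stats::setNames(as.list(rep(NA, length(cols))), cols)
    row$protein_id <- o$protein_id
    row$status <- o$status
    row$missing_motif <- o$missing_motif
    row$truncated_terminal <- o$truncated_terminal
    row$notes <- if (length(o$notes)) paste(o$notes, collapse = "; ") else ""
    if (!is.null(o$call)) {
      h <- o$call$hits
      for (k in 1:6) {
        row[[paste0("m", k, "_start")]] <- h$start[h$motif_index == k]
        row[[paste0("m", k, "_match")]] <- h$matched[h$motif_index == k]
        row[[paste0("m", k, "_flavour")]] <- h$flavour[h$motif_index == k]
      }
      d <- o$call$distances
      for (nm in names(d)) row[[sub("^d", "d", nm)]] <- d[[nm]]
      row$extended_count <- o$call$extended_count
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
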