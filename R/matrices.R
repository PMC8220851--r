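# Built-in position-specific allowed-residue sets for the six ALPH motifs.
# Motifs 1-4 are the PPP-family signature motifs (GDxHG, GDxxDKG-type,
# GNHE-type, HGG); motifs 5 and 6 are ALPH-specific C-terminal motifs.
# The "narrow" sets drive the initial screen; the "extended" sets relax
# selected positions and admit the unknown-residue code X.
.narrow_sets <- list(
  c("G", "D", "VILT", "HQ", "G"),
  c("G", "DN", "LMIFVT", "EIVTLAC", "NSATFGVQIDHM", "KQN", "GASHT"),
  c("G", "N", "HNWQ", "ED"),
  c("H", "AG", "G"),
  c("VIT", "IVYFLAMT", "FY", "G", "H"),
  c("LVIMT", "DE", "STG", "GASRN")
)

.extended_sets <- list(
  c("GX", "DX", "VILTX", "HQX", "GX"),
  c("GX", "DNX", "TIFLYVMX", "ETIALCVMX", "EQTIASDFGHCVNMX", "KQNX", "GASHTX"),
  c("GX", "NX", "HNWQX", "EDX"),
  c("HX", "AGLVX", "GX"),
  c("AVILCMTX", "IVYFLAMTX", "FYX", "GX", "HX"),
  c("LVIMTX", "DEX", "LATGSVX", "LMGRASNEX")
)

#' Built-in motif lengths
#'
#' Lengths (in residues) of the six ALPH motifs, in motif order.
#' @return Integer vector of length 6: `c(5, 7, 4, 3, 5, 4)`.
#' @export
motif_lengths <- function() c(5L, 7L, 4L, 3L, 5L, 4L)

.set_to_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Construct a single motif matrix
#'
#' A motif matrix models one of the six ALPH motifs as an ordered list of
#' allowed-residue sets: a window of sequence matches the motif if and only
#' if every residue is a member of the corresponding set. There is no
#' scoring; membership is all-or-nothing.
#'
#' @param motif_index Integer 1..6.
#' @param positions Character vector, one string of allowed one-letter
#'   residue codes per motif position (e.g. `c("G","D","VILT","HQ","G")`).
#'   `X` as a member means the unknown-residue code is tolerated at that
#'   position (extended matrices only, by convention).
#' @param flavour One of `"narrow"`, `"extended"`, `"custom"`.
#' @return An object of class `motif_matrix` with fields `motif_index`,
#'   `flavour`, `positions` (list of character vectors), `length`, and a
#'   precomputed A-Z membership table used by the scanner.
#' @export
motif_matrix <- function(motif_index, positions, flavour = c("narrow", "extended", "custom")) {
  flavour <- match.arg(flavour)
  motif_index <- as.integer(motif_index)
  stopifnot(length(motif_index) == 1L, motif_index >= 1L, motif_index <= 6L)
  pos_sets <- lapply(positions, function(s) sort(unique(toupper(.set_to_chars(s)))))
  bad <- !vapply(pos_sets, function(p) all(p %in% LETTERS), logical(1))
  if (any(bad)) {
    stop("motif ", motif_index, ": allowed sets must contain one-letter amino-acid codes only (position ",
         paste(which(bad), collapse = ","), ")")
  }
  memb <- matrix(FALSE, nrow = length(pos_sets), ncol = 26L,
                 dimnames = list(NULL, LETTERS))
  for (i in seq_along(pos_sets)) memb[i, pos_sets[[i]]] <- TRUE
  structure(
    list(motif_index = motif_index, flavour = flavour,
         positions = pos_sets, length = length(pos_sets), memb = memb),
    class = "motif_matrix"
  )
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("<motif_matrix> motif %d, %s flavour, length %d\n",
              x$motif_index, x$flavour, x$length))
  for (i in seq_len(x$length)) {
    cat(sprintf("  pos %d: [%s]\n", i, paste(x$positions[[i]], collapse = "")))
  }
  invisible(x)
}

#' Built-in ALPH motif matrices
#'
#' Returns the six built-in motif matrices of one flavour. The narrow
#' matrices are strict; every narrow set is a subset of the corresponding
#' extended set, and the extended sets additionally admit the
#' unknown-residue code `X` at every position. In no built-in flavour is
#' `R` allowed at position 6 of motif 2: that arginine is the hallmark of
#' the related ApaH/RLPH/PPP enzymes and its exclusion is what separates
#' ALPHs from them.
#'
#' @param flavour `"narrow"` or `"extended"`.
#' @return A list of six `motif_matrix` objects, in motif order.
#' @export
alph_matrices <- function(flavour = c("narrow", "extended")) {
  flavour <- match.arg(flavour)
  sets <- if (flavour == "narrow") .narrow_sets else .extended_sets
  lapply(seq_along(sets), function(k) motif_matrix(k, sets[[k]], flavour))
}

#' Paired narrow/extended matrix set for screening
#'
#' The screening algorithm uses the narrow matrices for its primary pass
#' and falls back on the extended matrices for at most `extended_budget`
#' motifs per protein. This helper bundles the two flavours (or a custom
#' pair) into the structure the screener consumes.
#'
#' @param narrow,extended Lists of six `motif_matrix` objects. Defaults to
#'   the built-ins. Supplying the same list twice disables the
#'   narrow/extended distinction (every hit is primary).
#' @return An object of class `alph_matrix_set`.
#' @export
alph_matrix_set <- function(narrow = alph_matrices("narrow"),
                            extended = alph_matrices("extended")) {
  for (ms in list(narrow, extended)) {
    stopifnot(length(ms) == 6L)
    lens <- vapply(ms, function(m) m$length, integer(1))
    if (!identical(lens, motif_lengths())) {
      stop("matrix set must contain six motifs of lengths ",
           paste(motif_lengths(), collapse = ","))
    }
  }
  structure(list(narrow = narrow, extended = extended), class = "alph_matrix_set")
}

#' Inter-motif distance constraints
#'
#' Three of the five inter-motif spacings are conserved enough to be used
#' as screening restrictions: motif 1 to 2 (14-150 residues), motif 2 to 3
#' (25-80) and motif 5 to 6 (17-40). Spacings 3-4 and 4-5 are
#' unconstrained. Distances are measured either as the gap (residues
#' strictly between the last residue of the upstream motif and the first
#' residue of the downstream motif; the default) or start-to-start;
#' which convention the original screen used is not documented, so both
#' are available.
#'
#' @param convention `"gap"` (default) or `"start_to_start"`.
#' @param bounds Named list of two-element numeric vectors keyed
#'   `"1_2"`, `"2_3"`, `"5_6"`. Override to recalibrate.
#' @return An object of class `distance_constraints`.
#' @export
distance_constraints <- function(convention = c("gap", "start_to_start"),
                                 bounds = list(`1_2` = c(14, 150),
                                               `2_3` = c(25, 80),
                                               `5_6` = c(17, 40))) {
  convention <- match.arg(convention)
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2L || b[1] > b[2]) stop("invalid bound for pair ", nm)
  }
  structure(list(convention = convention, bounds = bounds),
            class = "distance_constraints")
}

# Distance between two motif placements under the active convention.
# Coordinates are 1-based with inclusive ends.
.pair_distance <- function(start_i, end_i, start_j, convention) {
  if (convention == "gap") start_j - end_i - 1L else start_j - start_i
}

#' Test a sequence window against a motif matrix
#'
#' Pure set-membership: the window matches if every residue belongs to the
#' allowed set at its position. Residues outside the allowed set --
#' including non-standard codes such as `B`, `Z`, `U`, `O`, `*` and gap
#' characters -- simply fail to match (no error). The unknown-residue code
#' `X` matches only where `X` is itself a member of the set, i.e. in the
#' extended matrices. Independently of the matrix supplied, `R` at
#' position 6 of motif 2 is rejected: this guards the ALPH/ApaH boundary
#' and cannot be lifted by a custom matrix unless `allow_r6 = TRUE` is
#' passed explicitly.
#'
#' @param window Character scalar, uppercase, exactly `matrix$length` long.
#' @param matrix A `motif_matrix`.
#' @param allow_r6 Set `TRUE` to disable the motif-2 position-6 arginine
#'   exclusion (expert use only).
#' @return `TRUE` or `FALSE`.
#' @export
matches_at <- function(window, matrix, allow_r6 = FALSE) {
  stopifnot(inherits(matrix, "motif_matrix"))
  if (nchar(window) != matrix$length) {
    stop("window length ", nchar(window), " does not equal matrix length ",
         matrix$length)
  }
  chars <- .set_to_chars(window)
  idx <- match(chars, LETTERS)
  if (anyNA(idx)) return(FALSE)
  if (!allow_r6 && matrix$motif_index == 2L && chars[6] == "R") return(FALSE)
  all(matrix$memb[cbind(seq_len(matrix$length), idx)])
}

# Vectorised occurrence scan used by find_occurrences() and the screener.
# seq_int: sequence residues encoded as positions in LETTERS (NA = non-letter).
# Returns 1-based start positions of matching windows, ascending.
.scan_starts <- function(seq_int, matrix, allow_r6 = FALSE) {
  n <- length(seq_int)
  L <- matrix$length
  if (n < L) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  memb <- matrix$memb
  for (p in seq_len(L)) {
    v <- memb[p, ][seq_int[p:(p + n - L)]]
    v[is.na(v)] <- FALSE
    ok <- ok & v
  }
  starts <- which(ok)
  if (!allow_r6 && matrix$motif_index == 2L && length(starts)) {
    r <- match("R", LETTERS)
    starts <- starts[seq_int[starts + 5L] != r | is.na(seq_int[starts + 5L])]
    starts <- starts[!is.na(starts)]
  }
  starts
}

.encode_seq <- function(sequence) match(.set_to_chars(toupper(sequence)), LETTERS)

#' Find all occurrences of a motif in a sequence
#'
#' Exhaustively scans every window of the sequence against one motif
#' matrix. Coordinates are 1-based with inclusive ends.
#'
#' @param sequence Amino-acid string (uppercased on entry).
#' @param matrix A `motif_matrix`.
#' @param allow_r6 See [matches_at()].
#' @return A data frame with columns `motif_index`, `start`, `end`,
#'   `matched`, `flavour`, sorted by `start`; zero rows when the sequence
#'   is shorter than the motif.
#' @export
find_occurrences <- function(sequence, matrix, allow_r6 = FALSE) {
  sequence <- toupper(sequence)
  starts <- .scan_starts(.encode_seq(sequence), matrix, allow_r6)
  if (!length(starts)) {
    return(data.frame(motif_index = integer(0), start = integer(0),
                      end = integer(0), matched = character(0),
                      flavour = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    motif_index = rep(matrix$motif_index, length(starts)),
    start = starts,
    end = starts + matrix$length - 1L,
    matched = substring(sequence, starts, starts + matrix$length - 1L),
    flavour = rep(matrix$flavour, length(starts)),
    stringsAsFactors = FALSE
  )
}

# Merged narrow/extended occurrences for one motif: a start matching the
# narrow matrix is labelled with the narrow flavour at extension cost 0; a
# start matching only the extended matrix carries cost 1.
.motif_occurrences <- function(seq_int, sequence, mset, k, allow_r6 = FALSE) {
  nmat <- mset$narrow[[k]]
  emat <- mset$extended[[k]]
  ns <- .scan_starts(seq_int, nmat, allow_r6)
  es <- .scan_starts(seq_int, emat, allow_r6)
  eo <- setdiff(es, ns)
  starts <- c(ns, eo)
  if (!length(starts)) {
    return(data.frame(start = integer(0), end = integer(0),
                      matched = character(0), flavour = character(0),
                      ext_cost = integer(0), stringsAsFactors = FALSE))
  }
  cost <- c(rep(0L, length(ns)), rep(1L, length(eo)))
  flav <- c(rep(nmat$flavour, length(ns)), rep(emat$flavour, length(eo)))
  o <- order(starts)
  data.frame(
    start = starts[o], end = starts[o] + nmat$length - 1L,
    matched = substring(sequence, starts[o], starts[o] + nmat$length - 1L),
    flavour = flav[o], ext_cost = cost[o],
    stringsAsFactors = FALSE
  )
}
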