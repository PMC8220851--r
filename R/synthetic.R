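# Labelled synthetic proteomes for end-to-end testing. Positives are
# assembled from motif residues sampled out of the matrices themselves,
# joined by background spacers at spacings drawn from the conserved
# distance distributions; decoys violate exactly one property each.
# Background stretches are rejection-sampled so that they contain no
# occurrence of any motif under the extended matrices: labels are clean
# by construction, not by luck.

.aa20 <- .set_to_chars("ACDEFGHIKLMNPQRSTVWY")

# Categorical distance sampler spec: data.frame(value, prob).
.dist_table <- function(values, probs) {
  stopifnot(length(values) == length(probs), abs(sum(probs) - 1) < 1e-9)
  data.frame(value = as.integer(values), prob = probs)
}

# Spread `mass` uniformly over the integers in `range` minus `excl`.
.spread <- function(range, excl, mass) {
  v <- setdiff(seq(range[1], range[2]), excl)
  .dist_table(c(excl, v), c(attr(excl, "probs"), rep(mass / length(v), length(v))))
}

.default_d12 <- function() {
  core <- c(29L, 28L, 30L)
  attr(core, "probs") <- c(0.72, 0.1085, 0.1085)
  .spread(c(14, 150), core, 0.063)
}
.default_d23 <- function() {
  # 83% exactly 26; 98% within 25-33; remainder anywhere legal
  inner <- setdiff(25:33, 26L)
  core <- c(26L, inner)
  attr(core, "probs") <- c(0.83, rep(0.15 / length(inner), length(inner)))
  .spread(c(25, 80), core, 0.02)
}
.default_d34 <- function() {
  core <- 55:64
  attr(core, "probs") <- rep(0.94 / 10, 10)
  .spread(c(35, 95), core, 0.06)
}
.default_d45 <- function() {
  v <- 20:120
  .dist_table(v, rep(1 / length(v), length(v)))
}
.default_d56 <- function() {
  core <- 19L
  attr(core, "probs") <- 0.925
  .spread(c(17, 40), core, 0.075)
}

#' Specification for a synthetic ALPH proteome
#'
#' Bundles the generative parameters: the number of planted ALPHs and of
#' decoys per class, the inter-motif distance distributions (defaults
#' reflect the conserved spacings of real ALPHs: distance 1-2
#' concentrated on 28-30 with mode 29, 2-3 on 26, 3-4 on 55-64, 4-5
#' broad, 5-6 on 19), terminal-extension length distributions (lognormal
#' with medians 87 and 26 residues for N- and C-terminus), the fraction
#' of positives carrying one extended-flavour motif (default 0.113, i.e.
#' 1.9% of motifs; never two per protein), and the fraction of positive
#' organisms with multiple isoforms (default 0.25, of which 81% have
#' exactly two).
#'
#' Decoy classes: `ppp_like_R6` (arginine at motif-2 position 6, the
#' PPP/ApaH hallmark), `distance_violation` (one conserved spacing pushed
#' outside its bound), `one_missing` (one motif replaced by background),
#' `terminal_truncation` (sequence cut through motif 1 or 6),
#' `random_background` (no motifs at all).
#'
#' @param n_positive Number of planted ALPH proteins.
#' @param n_decoy_per_class Decoys per class (same count for each of the
#'   five classes).
#' @param d12,d23,d34,d45,d56 Distance distributions as
#'   `data.frame(value, prob)`; positives must draw constrained distances
#'   within the screening bounds.
#' @param n_term_meanlog,n_term_sdlog,c_term_meanlog,c_term_sdlog
#'   Lognormal parameters for terminal-extension lengths.
#' @param extended_rate Probability a positive carries exactly one
#'   extended-only motif.
#' @param multi_isoform_rate Fraction of positive organisms with >1
#'   isoform.
#' @param seed Integer seed; all randomness in [generate_synthetic_proteome()]
#'   flows from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_positive = 100L,
                           n_decoy_per_class = 25L,
                           d12 = .default_d12(),
                           d23 = .default_d23(),
                           d34 = .default_d34(),
                           d45 = .default_d45(),
                           d56 = .default_d56(),
                           n_term_meanlog = log(87),
                           n_term_sdlog = 0.6,
                           c_term_meanlog = log(26),
                           c_term_sdlog = 0.7,
                           extended_rate = 0.113,
                           multi_isoform_rate = 0.25,
                           seed = 1L) {
  spec <- list(n_positive = as.integer(n_positive),
               n_decoy_per_class = as.integer(n_decoy_per_class),
               d12 = d12, d23 = d23, d34 = d34, d45 = d45, d56 = d56,
               n_term_meanlog = n_term_meanlog, n_term_sdlog = n_term_sdlog,
               c_term_meanlog = c_term_meanlog, c_term_sdlog = c_term_sdlog,
               extended_rate = extended_rate,
               multi_isoform_rate = multi_isoform_rate,
               seed = as.integer(seed))
  bounds <- distance_constraints()$bounds
  pair_key <- c(d12 = "1_2", d23 = "2_3", d56 = "5_6")
  for (nm in c("d12", "d23", "d56")) {
    b <- bounds[[pair_key[[nm]]]]
    v <- spec[[nm]]$value[spec[[nm]]$prob > 0]
    if (any(v < b[1] | v > b[2])) {
      stop("synthetic spec: ", nm, " support must lie within the screening bound [",
           b[1], ",", b[2], "]")
    }
  }
  structure(spec, class = "synthetic_spec")
}

.sample_dist <- function(tab, n = 1L) {
  tab$value[sample.int(nrow(tab), n, replace = TRUE, prob = tab$prob)]
}

.sample_lnorm_len <- function(n, meanlog, sdlog, min = 0L, max = 1500L) {
  v <- round(stats::rlnorm(n, meanlog, sdlog))
  as.integer(pmin(pmax(v, min), max))
}

# Background of length n containing no extended-matrix occurrence of any
# motif (narrow occurrences are a fortiori excluded by the superset
# property). Resampled wholesale until clean.
.clean_background <- function(n, mset, max_tries = 200L) {
  if (n <= 0L) return("")
  for (t in seq_len(max_tries)) {
    s <- paste(sample(.aa20, n, replace = TRUE), collapse = "")
    seq_int <- .encode_seq(s)
    hit <- FALSE
    for (k in 1:6) {
      if (length(.scan_starts(seq_int, mset$extended[[k]], allow_r6 = TRUE))) {
        hit <- TRUE
        break
      }
    }
    if (!hit) return(s)
  }
  stop("failed to draw a motif-free background of length ", n)
}

# One motif instance: residues sampled from the narrow sets, or (for an
# extended-only motif) narrow residues with one position flipped to a
# residue allowed only in the extended set. Motif-2 position 6 never
# receives R (no built-in set contains it; asserted defensively).
.sample_motif <- function(mset, k, extended_only = FALSE) {
  nmat <- mset$narrow[[k]]
  emat <- mset$extended[[k]]
  res <- vapply(nmat$positions, function(s) sample(s, 1L)[[1]], character(1))
  if (extended_only) {
    extra <- lapply(seq_len(emat$length), function(p)
      setdiff(emat$positions[[p]], nmat$positions[[p]]))
    ok <- which(vapply(extra, length, integer(1)) > 0L)
    p <- if (length(ok) == 1L) ok else sample(ok, 1L)
    res[p] <- sample(extra[[p]], 1L)[[1]]
  }
  if (k == 2L && res[6] == "R") stop("internal: R sampled at motif-2 position 6")
  paste(res, collapse = "")
}

# Assemble a positive protein. Returns sequence plus planted coordinates.
.build_positive <- function(spec, mset) {
  ext_motif <- if (stats::runif(1) < spec$extended_rate) sample.int(6L, 1L) else 0L
  motifs <- vapply(1:6, function(k)
    .sample_motif(mset, k, extended_only = (k == ext_motif)), character(1))
  gaps <- c(.sample_dist(spec$d12), .sample_dist(spec$d23),
            .sample_dist(spec$d34), .sample_dist(spec$d45),
            .sample_dist(spec$d56))
  # terminal-length distributions describe the *annotated* N-/C-termini;
  # the catalytic domain claims 6 residues upstream of motif 1 and 8
  # downstream of motif 6, so the planted spacers are longer by that much
  n_term <- .sample_lnorm_len(1L, spec$n_term_meanlog, spec$n_term_sdlog)
  c_term <- .sample_lnorm_len(1L, spec$c_term_meanlog, spec$c_term_sdlog)
  n_spacer <- n_term + 6L
  c_spacer <- c_term + 8L
  lens <- motif_lengths()
  starts <- integer(6)
  pos <- n_spacer
  parts <- .clean_background(n_spacer, mset)
  for (k in 1:6) {
    starts[k] <- pos + 1L
    parts <- c(parts, motifs[k])
    pos <- pos + lens[k]
    if (k < 6L) {
      parts <- c(parts, .clean_background(gaps[k], mset))
      pos <- pos + gaps[k]
    }
  }
  parts <- c(parts, .clean_background(c_spacer, mset))
  list(sequence = paste(parts, collapse = ""),
       starts = starts, ends = starts + lens - 1L,
       motifs = motifs, gaps = gaps,
       flavours = ifelse(1:6 == ext_motif, "extended", "narrow"),
       extended_motif = ext_motif,
       n_term = n_term, c_term = c_term)
}

#' Replace one planted motif with motif-free background
#'
#' Perturbs a planted positive so the chosen motif is absent: its span is
#' replaced by background residues drawn until no occurrence of that
#' motif (in any flavour) remains anywhere in the protein. Used to build
#' `one_missing` decoys and to exercise the one-motif-missing audit scan.
#'
#' @param sequence The positive protein sequence.
#' @param starts,ends 1-based inclusive spans of the six planted motifs.
#' @param motif_index Motif 1..6 to delete.
#' @param matrices An `alph_matrix_set`.
#' @param max_tries Resampling bound before giving up (an ambiguous
#'   fixture is never emitted).
#' @return The perturbed sequence.
#' @export
perturb_to_missing <- function(sequence, starts, ends, motif_index,
                               matrices = alph_matrix_set(),
                               max_tries = 100L) {
  k <- as.integer(motif_index)
  stopifnot(k >= 1L, k <= 6L)
  L <- ends[k] - starts[k] + 1L
  for (t in seq_len(max_tries)) {
    repl <- paste(sample(.aa20, L, replace = TRUE), collapse = "")
    cand <- paste0(substring(sequence, 1L, starts[k] - 1L), repl,
                   substring(sequence, ends[k] + 1L))
    # re-check every window overlapping the replaced span (windows fully
    # outside it are untouched by construction)
    lo <- max(1L, starts[k] - L + 1L)
    hi <- min(nchar(cand), ends[k] + L - 1L)
    region_int <- .encode_seq(substring(cand, lo, hi))
    if (!length(.scan_starts(region_int, matrices$extended[[k]], allow_r6 = TRUE)) &&
        !length(.scan_starts(region_int, matrices$narrow[[k]], allow_r6 = TRUE))) {
      return(cand)
    }
  }
  stop("failed to erase motif ", k, " cleanly after ", max_tries, " tries")
}

.decoy_classes <- c("ppp_like_R6", "distance_violation", "one_missing",
                    "terminal_truncation", "random_background")

# Build one decoy of the given class from positive-style material and
# verify it is class-respecting (negative under the full screen).
.build_decoy <- function(class, spec, mset, constraints, max_tries = 50L) {
  bounds <- constraints$bounds
  for (t in seq_len(max_tries)) {
    detail <- NA_character_
    if (class == "random_background") {
      tot <- sum(.sample_lnorm_len(1L, spec$n_term_meanlog, spec$n_term_sdlog),
                 motif_lengths(),
                 .sample_dist(spec$d12), .sample_dist(spec$d23),
                 .sample_dist(spec$d34), .sample_dist(spec$d45),
                 .sample_dist(spec$d56),
                 .sample_lnorm_len(1L, spec$c_term_meanlog, spec$c_term_sdlog))
      seqn <- .clean_background(tot, mset)
    } else if (class == "ppp_like_R6") {
      p <- .build_positive(spec, mset)
      m2 <- .set_to_chars(p$motifs[2])
      m2[6] <- "R"
      seqn <- paste0(substring(p$sequence, 1L, p$starts[2] - 1L),
                     paste(m2, collapse = ""),
                     substring(p$sequence, p$ends[2] + 1L))
    } else if (class == "distance_violation") {
      pair <- sample(c("1_2", "2_3", "5_6"), 1L)
      b <- bounds[[pair]]
      side <- sample(c("low", "high"), 1L)
      bad <- if (side == "low") {
        if (b[1] <= 0L) b[2] + sample(5:60, 1L) else sample(0:(b[1] - 1L), 1L)
      } else b[2] + sample(5:60, 1L)
      sp <- spec
      slot <- paste0("d", gsub("_", "", pair))
      sp[[slot]] <- .dist_table(bad, 1)
      # bypass the legality check: build directly
      p <- .build_positive(sp, mset)
      seqn <- p$sequence
      detail <- paste0(slot, "=", bad)
    } else if (class == "one_missing") {
      k <- sample.int(6L, 1L)
      p <- .build_positive(spec, mset)
      seqn <- perturb_to_missing(p$sequence, p$starts, p$ends, k, mset)
      detail <- as.character(k)
    } else if (class == "terminal_truncation") {
      side <- sample(c("N", "C"), 1L)
      p <- .build_positive(spec, mset)
      seqn <- if (side == "N") {
        # start inside motif 1: its tail alone must not rescue the motif
        substring(p$sequence, p$starts[1] + 2L)
      } else {
        substring(p$sequence, 1L, p$ends[6] - 2L)
      }
      detail <- side
    }
    out <- screen_protein("decoy_check", seqn, mset, constraints)
    if (out$status == "negative") {
      return(list(sequence = seqn, detail = detail))
    }
  }
  stop("failed to build a class-respecting '", class, "' decoy")
}

#' Generate a labelled synthetic proteome
#'
#' Builds `n_positive` planted ALPH proteins plus `n_decoy_per_class`
#' decoys of each class, per the generative parameters of the spec (see
#' [synthetic_spec()]). Positives are grouped into synthetic organisms to
#' carry the multi-isoform structure; decoys get one organism each.
#' Identical seeds give byte-identical output.
#'
#' @param spec A `synthetic_spec`.
#' @param fasta Optional path: write the proteome FASTA here.
#' @param truth Optional path: write the truth table TSV here.
#' @return A list with `proteome` (data frame: `record_id`, `description`,
#'   `organism_name`, `taxon_id`, `sequence`) and `truth` (one row per
#'   record: `record_id`, `organism`, `label`, `detail`, planted motif
#'   spans `m1_start..m6_end`, `flavours`, gap distances, terminal
#'   lengths).
#' @export
generate_synthetic_proteome <- function(spec, fasta = NULL, truth = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  mset <- alph_matrix_set()
  constraints <- distance_constraints()

  # organism assignment for positives: 25% of organisms multi-isoform,
  # of those 81% two, 15% three, 4% four
  sizes <- integer(0)
  remaining <- spec$n_positive
  while (remaining > 0L) {
    k <- if (stats::runif(1) < spec$multi_isoform_rate) {
      sample(c(2L, 3L, 4L), 1L, prob = c(0.81, 0.15, 0.04))
    } else 1L
    k <- min(k, remaining)
    sizes <- c(sizes, k)
    remaining <- remaining - k
  }

  recs <- list()
  truths <- list()
  idx <- 0L
  org_i <- 0L
  na6 <- function(x = NA_integer_) rep(x, 6L)
  add_rec <- function(id, org, seqn, label, detail, p = NULL) {
    idx <<- idx + 1L
    recs[[idx]] <<- data.frame(
      record_id = id, description = paste0("synthetic ", label),
      organism_name = org, taxon_id = NA_integer_, sequence = seqn,
      stringsAsFactors = FALSE
    )
    tr <- data.frame(record_id = id, organism = org, label = label,
                     detail = detail, stringsAsFactors = FALSE)
    st <- if (is.null(p)) na6() else p$starts
    en <- if (is.null(p)) na6() else p$ends
    fl <- if (is.null(p)) rep(NA_character_, 6L) else p$flavours
    for (k in 1:6) {
      tr[[paste0("m", k, "_start")]] <- st[k]
      tr[[paste0("m", k, "_end")]] <- en[k]
      tr[[paste0("m", k, "_flavour")]] <- fl[k]
    }
    gaps <- if (is.null(p)) rep(NA_integer_, 5L) else p$gaps
    for (i in 1:5) tr[[paste0("d", c(12, 23, 34, 45, 56)[i])]] <- gaps[i]
    tr$n_term <- if (is.null(p)) NA_integer_ else p$n_term
    tr$c_term <- if (is.null(p)) NA_integer_ else p$c_term
    truths[[idx]] <<- tr
  }

  pos_i <- 0L
  for (sz in sizes) {
    org_i <- org_i + 1L
    org <- sprintf("SynOrg%04d", org_i)
    for (j in seq_len(sz)) {
      pos_i <- pos_i + 1L
      # resample until the planted assignment is the one the screen makes
      # (a junction window can occasionally offer an equally valid,
      # more leftmost placement; such sequences are rejected so the truth
      # table is canonical)
      for (t in 1:50) {
        p <- .build_positive(spec, mset)
        chk <- screen_protein("check", p$sequence, mset, constraints)
        if (chk$status == "alph" && identical(chk$call$hits$start, p$starts) &&
            identical(chk$call$hits$flavour, p$flavours)) break
        if (t == 50L) stop("failed to build a canonical positive")
      }
      add_rec(sprintf("ALPH%05d", pos_i), org, p$sequence, "alph", NA_character_, p)
    }
  }

  for (cls in .decoy_classes) {
    for (j in seq_len(spec$n_decoy_per_class)) {
      org_i <- org_i + 1L
      d <- .build_decoy(cls, spec, mset, constraints)
      add_rec(sprintf("DECOY_%s_%04d", toupper(substr(cls, 1, 4)), j),
              sprintf("SynOrg%04d", org_i), d$sequence, cls, d$detail)
    }
  }

  proteome <- do.call(rbind, recs)
  rownames(proteome) <- NULL
  class(proteome) <- c("proteome", "data.frame")
  truth_df <- do.call(rbind, truths)
  rownames(truth_df) <- NULL
  if (!is.null(fasta)) {
    write_fasta(data.frame(record_id = proteome$record_id,
                           description = proteome$description,
                           sequence = proteome$sequence,
                           stringsAsFactors = FALSE), fasta)
  }
  if (!is.null(truth)) write_table_tsv(truth_df, truth)
  list(proteome = proteome, truth = truth_df)
}
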