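# Corpus-level characterisation of a set of ALPH annotations: domain-size
# medians and IQRs, inter-motif distance distributions with
# fraction-in-range statistics, isoform counts per organism, and
# extended-flavour usage.

.frac_in <- function(x, lo, hi = lo) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  mean(x >= lo & x <= hi)
}

.med_iqr <- function(x) {
  x <- x[!is.na(x)]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

.summarise_block <- function(ann) {
  dist_hist <- lapply(paste0("d", c(12, 23, 34, 45, 56)), function(nm) {
    table(ann[[nm]], dnn = NULL)
  })
  names(dist_hist) <- paste0("d", c(12, 23, 34, 45, 56))
  list(
    n_alph = nrow(ann),
    n_term = .med_iqr(ann$n_term_len),
    cat_domain = .med_iqr(ann$cat_domain_len),
    c_term = .med_iqr(ann$c_term_len),
    dist_hist = dist_hist,
    frac_d12_29 = .frac_in(ann$d12, 29),
    frac_d12_28_30 = .frac_in(ann$d12, 28, 30),
    frac_d23_26 = .frac_in(ann$d23, 26),
    frac_d23_25_33 = .frac_in(ann$d23, 25, 33),
    frac_d34_55_64 = .frac_in(ann$d34, 55, 64),
    frac_d56_19 = .frac_in(ann$d56, 19),
    frac_motifs_extended = sum(ann$extended_count) / (6 * nrow(ann)),
    frac_proteins_extended = mean(ann$extended_count > 0)
  )
}

#' Summarise an annotated ALPH corpus
#'
#' Computes the corpus-level characterisation from an annotation table:
#' per phylogenetic group (when a group map is supplied) and overall,
#' the number of organisms screened and with at least one ALPH, the
#' ALPH-isoform count histogram, medians and IQRs of the N-terminal,
#' catalytic-domain and C-terminal lengths, the inter-motif distance
#' histograms with the conserved-range fractions (share of proteins with
#' 28-30 / exactly 29 residues between motifs 1 and 2, exactly 26 and
#' 25-33 between 2 and 3, 55-64 between 3 and 4, exactly 19 between 5 and
#' 6), and extended-flavour usage. Medians are the standard order
#' statistic (mean of the central pair for even n).
#'
#' @param annotations Annotation data frame from [annotate_screen()],
#'   optionally with an `organism` column.
#' @param group_map Optional data frame with columns `organism` and
#'   `group` mapping each organism to a phylogenetic group; organisms
#'   absent from the map are tallied under `"unassigned"` with a warning.
#' @param organisms Optional character vector of all organisms screened
#'   (including ALPH-negative ones); defaults to the organisms present in
#'   `annotations`.
#' @return A list of class `corpus_summary` with elements `overall`,
#'   `by_group` (when grouped), `isoforms` and `convention` metadata.
#' @export
summarise_corpus <- function(annotations, group_map = NULL, organisms = NULL) {
  stopifnot(nrow(annotations) >= 1L)
  ann <- as.data.frame(annotations)
  overall <- .summarise_block(ann)

  iso <- NULL
  if (!is.null(ann$organism)) {
    if (is.null(organisms)) organisms <- unique(ann$organism)
    counts <- table(factor(ann$organism, levels = organisms))
    iso <- isoform_histogram(counts)
  }

  by_group <- NULL
  if (!is.null(group_map) && !is.null(ann$organism)) {
    gm <- stats::setNames(group_map$group, group_map$organism)
    grp <- gm[ann$organism]
    if (anyNA(grp)) {
      warning(sum(is.na(grp)), " annotation row(s) reference organisms ",
              "absent from the group map; counted as 'unassigned'")
      grp[is.na(grp)] <- "unassigned"
    }
    by_group <- lapply(split(ann, grp), .summarise_block)
  }

  structure(
    list(overall = overall, by_group = by_group, isoforms = iso,
         n_organisms = if (!is.null(organisms)) length(organisms) else NA_integer_,
         n_organisms_with_alph = if (!is.null(iso)) iso$n_positive else NA_integer_),
    class = "corpus_summary"
  )
}

#' @export
print.corpus_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf("<corpus_summary> %d ALPH protein(s)\n", o$n_alph))
  if (!is.na(x$n_organisms)) {
    cat(sprintf("  organisms: %d screened, %d with >=1 ALPH\n",
                x$n_organisms, x$n_organisms_with_alph))
  }
  cat(sprintf("  N-terminus median %.0f (IQR %.0f-%.0f); catalytic domain median %.0f; C-terminus median %.0f (IQR %.0f-%.0f)\n",
              o$n_term["median"], o$n_term["q1"], o$n_term["q3"],
              o$cat_domain["median"],
              o$c_term["median"], o$c_term["q1"], o$c_term["q3"]))
  cat(sprintf("  d12 in 28-30: %.1f%% (exactly 29: %.1f%%); d23 = 26: %.1f%%; d56 = 19: %.1f%%\n",
              100 * o$frac_d12_28_30, 100 * o$frac_d12_29,
              100 * o$frac_d23_26, 100 * o$frac_d56_19))
  cat(sprintf("  extended flavour: %.2f%% of motifs, %.2f%% of proteins\n",
              100 * o$frac_motifs_extended, 100 * o$frac_proteins_extended))
  invisible(x)
}

#' Isoform-count histogram
#'
#' Distribution of ALPH counts per organism, together with the number of
#' ALPH-positive organisms and the fraction of those carrying more than
#' one isoform.
#'
#' @param counts Named integer vector or table: ALPH count per organism
#'   (zero-count organisms allowed).
#' @return A list with `histogram` (table of count values), `n_positive`
#'   and `multi_fraction`.
#' @export
isoform_histogram <- function(counts) {
  counts <- as.integer(counts)
  pos <- counts[counts > 0L]
  list(
    histogram = table(counts, dnn = NULL),
    n_positive = length(pos),
    multi_fraction = if (length(pos)) mean(pos > 1L) else NA_real_
  )
}

#' Residue count matrix for one motif
#'
#' Tallies, across the matched motif strings of a set of calls, how often
#' each residue occurs at each motif position — the count-matrix input of
#' standard sequence-logo tools. Every column (position) sums to the
#' number of calls counted.
#'
#' @param outcomes A `proteome_screen`, list of `screen_outcome`, or list
#'   of `alph_call`.
#' @param motif_index Motif 1..6.
#' @param flavour Optional filter: count only hits of this flavour.
#' @return Integer matrix, rows = residues (A-Z subset observed, always
#'   including the 20 standard amino acids), columns = motif positions.
#' @export
motif_count_matrix <- function(outcomes, motif_index, flavour = NULL) {
  motif_index <- as.integer(motif_index)
  if (length(motif_index) != 1L || is.na(motif_index) ||
      motif_index < 1L || motif_index > 6L) {
    stop("motif_index must be a single integer in 1..6")
  }
  if (inherits(outcomes, "proteome_screen")) outcomes <- outcomes$outcomes
  calls <- lapply(outcomes, function(o) {
    if (inherits(o, "alph_call")) o else o$call
  })
  calls <- Filter(Negate(is.null), calls)
  if (!length(calls)) stop("no calls to count")
  rows <- lapply(calls, function(cl) {
    h <- cl$hits[cl$hits$motif_index == motif_index, ]
    if (!is.null(flavour) && h$flavour != flavour) return(NULL)
    h$matched
  })
  strings <- unlist(Filter(Negate(is.null), rows))
  if (!length(strings)) stop("no motif-", motif_index, " hits after filtering")
  L <- motif_lengths()[motif_index]
  aa <- sort(unique(c(.set_to_chars("ACDEFGHIKLMNPQRSTVWY"),
                      unlist(strsplit(strings, "")))))
  mat <- matrix(0L, nrow = length(aa), ncol = L,
                dimnames = list(aa, as.character(seq_len(L))))
  for (s in strings) {
    ch <- .set_to_chars(s)
    for (p in seq_len(L)) mat[ch[p], p] <- mat[ch[p], p] + 1L
  }
  mat
}

#' Write a motif count matrix as TSV
#'
#' One row per motif position (column `position`), one column per residue;
#' directly consumable by count-matrix logo tools.
#'
#' @param mat Matrix from [motif_count_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(mat, path) {
  df <- cbind(data.frame(position = as.integer(colnames(mat))),
              as.data.frame(t(mat)))
  write_table_tsv(df, path)
}
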