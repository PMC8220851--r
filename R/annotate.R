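# Domain architecture derived from an ALPH call: the catalytic domain runs
# from 6 residues upstream of motif 1 to 8 residues downstream of motif 6
# (clipped at the sequence ends); whatever flanks it is the N- and
# C-terminal extension.

#' Annotate the domain architecture of an ALPH call
#'
#' @param call An `alph_call` from [screen_protein()].
#' @param protein_length Length of the protein in residues.
#' @return An `alph_annotation`: a one-row data frame with `protein_id`,
#'   `protein_length`, `n_term_len`, `cat_domain_start`, `cat_domain_end`
#'   (1-based inclusive), `cat_domain_len`, `c_term_len`, the five
#'   inter-motif distances and `extended_count`. The three segment lengths
#'   always sum to `protein_length`.
#' @export
annotate_call <- function(call, protein_length) {
  stopifnot(inherits(call, "alph_call"))
  protein_length <- as.integer(protein_length)
  h <- call$hits
  s1 <- h$start[h$motif_index == 1L]
  e6 <- h$end[h$motif_index == 6L]
  if (e6 > protein_length) stop("protein_length shorter than the motif-6 end")
  cat_start <- max(1L, s1 - 6L)
  cat_end <- min(protein_length, e6 + 8L)
  out <- data.frame(
    protein_id = call$protein_id,
    protein_length = protein_length,
    n_term_len = cat_start - 1L,
    cat_domain_start = cat_start,
    cat_domain_end = cat_end,
    cat_domain_len = cat_end - cat_start + 1L,
    c_term_len = protein_length - cat_end,
    stringsAsFactors = FALSE
  )
  for (nm in names(call$distances)) out[[nm]] <- call$distances[[nm]]
  out$extended_count <- call$extended_count
  class(out) <- c("alph_annotation", "data.frame")
  out
}

#' Annotate every ALPH call in a proteome screen
#'
#' @param screen A `proteome_screen` from [screen_proteome()].
#' @param proteome The proteome data frame the screen was run on (used for
#'   protein lengths).
#' @return A data frame with one row per ALPH call (input order); zero
#'   rows when the screen found none.
#' @export
annotate_screen <- function(screen, proteome) {
  stopifnot(inherits(screen, "proteome_screen"))
  len <- stats::setNames(nchar(proteome$sequence), proteome$record_id)
  rows <- lapply(screen$outcomes, function(o) {
    if (is.null(o$call)) return(NULL)
    annotate_call(o$call, len[[o$protein_id]])
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    empty <- data.frame(
      protein_id = character(0), protein_length = integer(0),
      n_term_len = integer(0), cat_domain_start = integer(0),
      cat_domain_end = integer(0), cat_domain_len = integer(0),
      c_term_len = integer(0), d12 = integer(0), d23 = integer(0),
      d34 = integer(0), d45 = integer(0), d56 = integer(0),
      extended_count = integer(0), stringsAsFactors = FALSE
    )
    return(empty)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract the catalytic-domain subsequence
#'
#' Returns the catalytic-domain span (6 residues upstream of motif 1 to 8
#' downstream of motif 6, clipped to the sequence) as a string, for
#' downstream alignment or tree building.
#'
#' @param call An `alph_call`.
#' @param sequence The protein sequence the call was made on.
#' @return Character scalar: the catalytic-domain subsequence.
#' @export
extract_catalytic_domain <- function(call, sequence) {
  sequence <- .normalise_sequence(sequence)
  ann <- annotate_call(call, nchar(sequence))
  substring(sequence, ann$cat_domain_start, ann$cat_domain_end)
}

#' Write catalytic domains of a screen to a multi-FASTA file
#'
#' @param screen A `proteome_screen`.
#' @param proteome The proteome data frame the screen was run on.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_catalytic_domains <- function(screen, proteome, path) {
  seqs <- stats::setNames(proteome$sequence, proteome$record_id)
  doms <- character(0)
  for (o in screen$outcomes) {
    if (is.null(o$call)) next
    doms[[o$protein_id]] <- extract_catalytic_domain(o$call, seqs[[o$protein_id]])
  }
  write_fasta(data.frame(record_id = names(doms),
                         sequence = unname(doms),
                         stringsAsFactors = FALSE), path)
}
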