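# FASTA ingestion (UniProt / TriTrypDB / bare header dialects) and stable
# TSV output. Parsing of the FASTA container is delegated to Biostrings;
# the header-field extraction is ours.

# UniProt reference-proteome headers look like
#   >sp|P0XXXX|NAME_ORG Description OS=Organism name OX=12345 GN=...
# TriTrypDB headers are ">Tb927.4.4330 | product | ..." or plain
# whitespace-delimited; bare headers are just an identifier.
.parse_header <- function(header) {
  first <- sub("[[:space:]].*$", "", header)
  desc <- sub("^[^[:space:]]+[[:space:]]*", "", header)
  acc <- first
  if (grepl("^[A-Za-z0-9]{2,3}\\|[^|]+\\|", first)) {
    acc <- strsplit(first, "|", fixed = TRUE)[[1]][2]
  }
  os <- if (grepl("OS=", header)) {
    sub("[[:space:]]+(OX|GN|PE|SV)=.*$", "",
        sub("^.*OS=", "", header))
  } else NA_character_
  ox <- if (grepl("OX=[0-9]+", header)) {
    as.integer(sub("^.*OX=([0-9]+).*$", "\\1", header))
  } else NA_integer_
  list(record_id = acc, description = desc, organism_name = os, taxon_id = ox)
}

#' Read a proteome FASTA file
#'
#' Reads amino-acid FASTA (gzip transparently supported) and extracts the
#' identifier fields of the common header dialects: UniProt
#' (`db|ACCESSION|NAME ... OS=... OX=...`) yields the accession, organism
#' name and taxon id; TriTrypDB and bare headers yield the first
#' whitespace-delimited token. Sequences are uppercased. Duplicate record
#' ids are disambiguated with `__dupN` suffixes and a warning; records
#' with empty sequences are a hard error.
#'
#' @param path FASTA file path (optionally `.gz`).
#' @return A data frame of class `proteome` with columns `record_id`,
#'   `description`, `organism_name`, `taxon_id`, `sequence`, in file
#'   order.
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  headers <- names(aa)
  if (any(!nzchar(seqs))) {
    bad <- which(!nzchar(seqs))[1]
    stop("record ", bad, " ('", headers[bad], "') has an empty sequence")
  }
  parsed <- lapply(headers, .parse_header)
  ids <- vapply(parsed, `[[`, character(1), "record_id")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning("duplicate record id(s) disambiguated with __dupN suffixes: ",
            paste(utils::head(dup, 5), collapse = ", "))
    ids <- stats::ave(ids, ids, FUN = function(v) {
      if (length(v) == 1L) v else c(v[1], paste0(v[-1], "__dup", seq_len(length(v) - 1L)))
    })
  }
  out <- data.frame(
    record_id = ids,
    description = vapply(parsed, `[[`, character(1), "description"),
    organism_name = vapply(parsed, `[[`, character(1), "organism_name"),
    taxon_id = vapply(parsed, `[[`, integer(1), "taxon_id"),
    sequence = unname(seqs),
    stringsAsFactors = FALSE
  )
  class(out) <- c("proteome", "data.frame")
  out
}

#' Write sequences to a FASTA file
#'
#' @param records Data frame with columns `record_id` and `sequence`
#'   (optionally `description`, appended to the header after a space).
#' @param path Output path (`.gz` for gzip).
#' @param width Line width for wrapping (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 80L) {
  headers <- records$record_id
  if (!is.null(records$description)) {
    has_desc <- nzchar(records$description) & !is.na(records$description)
    headers[has_desc] <- paste(headers[has_desc], records$description[has_desc])
  }
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- headers
  compress <- grepl("\\.gz$", path)
  Biostrings::writeXStringSet(aa, path, width = width, compress = compress)
  invisible(path)
}

#' Write a data frame as a deterministic TSV file
#'
#' Plain tab-separated output with a header line, no quoting and no row
#' names; byte-stable for identical input.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     eol = "\n")
  invisible(path)
}

#' Read a TSV file written by [write_table_tsv()]
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
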