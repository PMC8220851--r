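# Plain-text matrix configuration.
#
# Grammar (one line per motif position; '#' starts a comment; blank lines
# ignored):
#
#   motif<k> <flavour> <position> <residues>
#
# e.g.   motif1 narrow 3 VILT
#        motif2 extended 6 KQNX
#
# <flavour> is "narrow", "extended" or "custom"; <residues> is a string of
# one-letter codes ('x' and 'X' both denote the unknown-residue code).
# Every motif must be fully specified at the built-in lengths (5,7,4,3,5,4).

#' Write motif matrices to a configuration file
#'
#' Serialises a list of six `motif_matrix` objects (or an
#' `alph_matrix_set`) in the plain-text format read by
#' [read_matrix_config()]. Round-trips losslessly.
#'
#' @param matrices A list of six `motif_matrix` objects or an
#'   `alph_matrix_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_config <- function(matrices, path) {
  lines <- c("# alphscreen motif matrix configuration",
             "# motif<k> <flavour> <position> <residues>")
  emit <- function(ms) {
    for (m in ms) {
      for (i in seq_len(m$length)) {
        lines <<- c(lines, sprintf("motif%d %s %d %s", m$motif_index,
                                   m$flavour, i,
                                   paste(m$positions[[i]], collapse = "")))
      }
    }
  }
  if (inherits(matrices, "alph_matrix_set")) {
    emit(matrices$narrow)
    emit(matrices$extended)
  } else {
    emit(matrices)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read motif matrices from a configuration file
#'
#' Parses the plain-text matrix configuration format (see
#' [write_matrix_config()] for the grammar). The configuration must define
#' all six motifs at the built-in lengths; a wrong motif count or a wrong
#' length is a configuration error naming the offending motif. When `path`
#' is `NULL` the built-in narrow/extended set is returned unchanged, so
#' callers can treat "no config" uniformly.
#'
#' If the file defines two flavours they become the primary ("narrow"
#' slot) and relaxed ("extended" slot) matrices of the returned set; a
#' single-flavour file is used for both slots, which disables the
#' extended-budget mechanism (every hit is primary).
#'
#' @param path Configuration file path, or `NULL` for the built-ins.
#' @return An `alph_matrix_set`.
#' @export
read_matrix_config <- function(path = NULL) {
  if (is.null(path)) return(alph_matrix_set())
  raw <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", raw)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  if (!length(raw)) stop("matrix configuration is empty: ", path)
  parts <- strsplit(raw, "[[:space:]]+")
  bad <- which(vapply(parts, length, integer(1)) != 4L)
  if (length(bad)) {
    stop("matrix configuration line ", bad[1],
         " does not have 4 fields (motif<k> flavour position residues)")
  }
  df <- data.frame(
    motif = vapply(parts, `[`, character(1), 1L),
    flavour = vapply(parts, `[`, character(1), 2L),
    position = as.integer(vapply(parts, `[`, character(1), 3L)),
    residues = toupper(vapply(parts, `[`, character(1), 4L)),
    stringsAsFactors = FALSE
  )
  k <- as.integer(sub("^motif", "", df$motif))
  if (anyNA(k) || any(k < 1L | k > 6L)) {
    stop("matrix configuration: motif labels must be motif1..motif6")
  }
  df$k <- k
  lens <- motif_lengths()

  build_flavour <- function(sub) {
    got <- sort(unique(sub$k))
    if (!identical(got, 1:6)) {
      stop("matrix configuration must define six motifs; flavour '",
           sub$flavour[1], "' defines motif(s) ", paste(got, collapse = ","))
    }
    lapply(1:6, function(kk) {
      rows <- sub[sub$k == kk, ]
      if (anyDuplicated(rows$position)) {
        stop("matrix configuration: duplicate position for motif ", kk)
      }
      if (!identical(sort(rows$position), seq_len(lens[kk]))) {
        stop("matrix configuration: motif ", kk, " must have positions 1..",
             lens[kk])
      }
      rows <- rows[order(rows$position), ]
      flav <- if (rows$flavour[1] %in% c("narrow", "extended")) rows$flavour[1] else "custom"
      motif_matrix(kk, rows$residues, flav)
    })
  }

  flavs <- unique(df$flavour)
  if (!all(flavs %in% c("narrow", "extended", "custom"))) {
    stop("matrix configuration: unknown flavour '",
         setdiff(flavs, c("narrow", "extended", "custom"))[1], "'")
  }
  if (length(flavs) == 1L) {
    ms <- build_flavour(df)
    alph_matrix_set(narrow = ms, extended = ms)
  } else if (length(flavs) == 2L && all(c("narrow", "extended") %in% flavs)) {
    alph_matrix_set(
      narrow = build_flavour(df[df$flavour == "narrow", ]),
      extended = build_flavour(df[df$flavour == "extended", ])
    )
  } else {
    stop("matrix configuration must define one flavour or the narrow/extended pair")
  }
}
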