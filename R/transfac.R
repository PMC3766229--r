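#' Read a TRANSFAC flat-file motif library
#'
#' Parses the TRANSFAC matrix flat-file dialect: records delimited by `//`,
#' `AC` (accession) and `ID` lines, an optional `BF` (binding factor) line,
#' a `P0` header over `A C G T`, and numbered matrix rows whose values may
#' be integer counts or reals. Each matrix is normalised per column into a
#' [pssm()]; stored values are taken as-is (no extra smoothing), so a file
#' written by [write_motif_library()] round-trips exactly. A missing
#' terminating `//` on the final record is tolerated with a warning.
#'
#' @param path File path.
#' @param pseudocount Per-base smoothing applied when normalising matrix
#'   rows (default 0, i.e. plain normalisation).
#' @return A `motif_library`: tibble with columns `accession`, `id`, `tf`
#'   and a `pssm` list-column.
#' @export
read_transfac <- function(path, pseudocount = 0) {
  lines <- readLines(path)
  recs <- list()
  cur <- NULL
  flush_record <- function(cur) {
    if (is.null(cur) || (is.null(cur$rows) && is.null(cur$ac) && is.null(cur$id))) {
      return(NULL)
    }
    if (is.null(cur$rows) || !length(cur$rows)) {
      abort(sprintf("TRANSFAC record `%s` has no matrix rows.",
                    cur$ac %||% cur$id %||% "?"))
    }
    counts <- do.call(rbind, cur$rows)
    ac <- cur$ac %||% cur$id %||% sprintf("M%04d", length(recs) + 1L)
    id <- cur$id %||% ac
    tf <- cur$bf %||% cur$id %||% ac
    mot <- pssm_from_counts(t(counts), pseudocount = pseudocount, name = id)
    tibble(accession = ac, id = id, tf = tf, pssm = list(mot))
  }
  open_rec <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || grepl("^XX", ln)) next
    if (grepl("^//", ln)) {
      recs <- c(recs, list(flush_record(cur)))
      cur <- NULL; open_rec <- FALSE
      next
    }
    open_rec <- TRUE
    if (is.null(cur)) cur <- list(rows = list())
    tag <- substr(ln, 1, 2)
    rest <- trimws(substr(ln, 3, nchar(ln)))
    if (tag == "AC") {
      cur$ac <- rest
    } else if (tag == "ID") {
      cur$id <- rest
    } else if (tag == "BF") {
      # keep the factor name only (strip trailing species annotation)
      cur$bf <- if (is.null(cur$bf)) sub(";.*$", "", rest) else cur$bf
    } else if (tag == "P0" || tag == "PO") {
      hdr <- strsplit(rest, "\\s+")[[1]]
      if (!identical(toupper(hdr[1:4]), DNA_BASES)) {
        abort(sprintf("Line %d: P0 header must list columns A C G T.", i))
      }
    } else if (grepl("^[0-9]+\\s", ln)) {
      fields <- strsplit(ln, "\\s+")[[1]][-1]
      vals <- suppressWarnings(as.numeric(fields))
      vals <- vals[!is.na(vals)]  # drop trailing consensus letter if present
      if (length(vals) != 4L) {
        abort(sprintf("Record `%s`, line %d: matrix row has %d numeric fields, expected 4.",
                      cur$ac %||% cur$id %||% "?", i, length(vals)))
      }
      cur$rows <- c(cur$rows, list(vals))
    }
    # other tags (NA, DE, CC, ...) are ignored
  }
  if (open_rec) {
    warn("TRANSFAC file does not end with `//`; final record accepted anyway.")
    recs <- c(recs, list(flush_record(cur)))
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  out <- if (length(recs)) bind_rows(recs) else {
    tibble(accession = character(), id = character(), tf = character(),
           pssm = list())
  }
  if (anyDuplicated(out$id)) abort("Duplicate motif identifiers in library.")
  class(out) <- c("motif_library", class(out))
  out
}

#' Write motifs to a TRANSFAC flat file
#'
#' Serialises PSSMs (or a `motif_library`) in the TRANSFAC matrix dialect:
#' `AC`/`ID`/`BF` lines, a `P0` header, one numbered row per column and a
#' `//` terminator. Source counts are written when the motif carries them
#' and was built without smoothing; otherwise the frequency matrix itself is
#' written (as reals), so reading the file back reproduces the frequencies
#' exactly.
#'
#' @param motifs A list of [pssm()] objects, a single `pssm`, or a
#'   `motif_library`.
#' @param path Output file path.
#' @param names Optional character vector of record identifiers (defaults
#'   to the motif names).
#' @param tf Optional character vector of binding-factor names for `BF`
#'   lines.
#' @return `path`, invisibly.
#' @export
write_motif_library <- function(motifs, path, names = NULL, tf = NULL) {
  if (inherits(motifs, "pssm")) motifs <- list(motifs)
  if (is.data.frame(motifs) && "pssm" %in% base::names(motifs)) {
    if (is.null(names)) names <- motifs$id
    if (is.null(tf) && "tf" %in% base::names(motifs)) tf <- motifs$tf
    motifs <- motifs$pssm
  }
  if (!length(motifs)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (is.null(names)) names <- vapply(motifs, function(m) m$name, character(1))
  if (anyDuplicated(names)) abort("Duplicate motif names in library.")
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(motifs)) {
    m <- motifs[[k]]
    mat <- if (!is.null(m$counts) && (is.na(m$pseudocount) || m$pseudocount == 0)) {
      m$counts
    } else {
      m$frequencies
    }
    writeLines(c(sprintf("AC  M%04d", k), "XX",
                 sprintf("ID  %s", names[[k]]), "XX"), con)
    if (!is.null(tf) && !is.na(tf[[k]])) {
      writeLines(c(sprintf("BF  %s", tf[[k]]), "XX"), con)
    }
    writeLines(sprintf("P0      %s", paste(DNA_BASES, collapse = "  ")), con)
    for (j in seq_len(ncol(mat))) {
      writeLines(sprintf("%02d      %s", j,
                         paste(sprintf("%.15g", mat[, j]), collapse = "  ")), con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}
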