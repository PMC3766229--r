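#' Import motifs from a MEME minimal-format file
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix:` headers,
#' taking the width from `w=` and the significance from the `E=` token.
#' Each matrix row must contain exactly 4 numbers summing to ~1; violations
#' raise an error naming the offending line. Imported motifs carry
#' `finder = "imported"` and their genuine E-value, so the printed E-value
#' filter of [filter_cascade()] applies to them.
#'
#' @param path File path.
#' @return A `ucr_motif_set` (empty for an empty file).
#' @export
import_meme_motifs <- function(path) {
  lines <- readLines(path)
  motifs <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[[i]])
    if (grepl("^MOTIF\\b", ln)) {
      name <- strsplit(ln, "\\s+")[[1]][2]
      if (is.na(name)) name <- sprintf("motif_%d", length(motifs) + 1L)
      # find the letter-probability header
      j <- i + 1L
      while (j <= length(lines) && !grepl("^letter-probability matrix:", trimws(lines[[j]]))) {
        if (grepl("^MOTIF\\b", trimws(lines[[j]]))) {
          abort(sprintf("Line %d: MOTIF `%s` has no letter-probability matrix.", i, name))
        }
        j <- j + 1L
      }
      if (j > length(lines)) {
        abort(sprintf("Line %d: MOTIF `%s` has no letter-probability matrix.", i, name))
      }
      hdr <- trimws(lines[[j]])
      get_tok <- function(key) {
        m <- regmatches(hdr, regexpr(paste0("\\b", key, "\\s*=?\\s*[0-9.eE+-]+"), hdr))
        if (!length(m)) return(NA_real_)
        as.numeric(sub(paste0("^", key, "\\s*=?\\s*"), "", m))
      }
      w <- get_tok("w")
      nsites <- get_tok("nsites")
      evalue <- get_tok("E")
      rows <- list()
      k <- j + 1L
      while (k <= length(lines)) {
        rl <- trimws(lines[[k]])
        if (rl == "" || grepl("^(MOTIF|URL)\\b", rl)) break
        vals <- suppressWarnings(as.numeric(strsplit(rl, "\\s+")[[1]]))
        if (length(vals) != 4L || anyNA(vals)) {
          abort(sprintf("Line %d: matrix row must contain exactly 4 numbers.", k))
        }
        if (abs(sum(vals) - 1) > 0.02) {
          abort(sprintf("Line %d: matrix row sums to %.4f, expected ~1.", k, sum(vals)))
        }
        rows <- c(rows, list(vals))
        k <- k + 1L
        if (is.finite(w) && length(rows) == w) break
      }
      if (is.finite(w) && length(rows) != w) {
        abort(sprintf("MOTIF `%s`: expected %d matrix rows, found %d.",
                      name, w, length(rows)))
      }
      if (!length(rows)) abort(sprintf("MOTIF `%s`: empty matrix.", name))
      freq <- t(do.call(rbind, rows))
      freq <- sweep(freq, 2, colSums(freq), "/")
      pm <- pssm(freq, name = name)
      motifs <- c(motifs, list(ucr_motif(pm, evalue = evalue, finder = "imported")))
      i <- k
    } else {
      i <- i + 1L
    }
  }
  motif_set(motifs)
}

#' Write motifs to a MEME minimal-format file
#'
#' @param motifs A `ucr_motif_set`, list of `ucr_motif`, or list of
#'   [pssm()] objects.
#' @param path Output file path.
#' @param background Background base frequencies to record (default
#'   uniform).
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(motifs, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, background), collapse = " "),
               ""), con)
  for (m in motifs) {
    if (inherits(m, "pssm")) m <- ucr_motif(m)
    f <- m$pssm$frequencies
    ns <- max(nrow(m$sites), 1L)
    ev <- if (is.finite(m$evalue)) sprintf(" E= %g", m$evalue) else ""
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d%s",
                       ncol(f), ns, ev), con)
    for (j in seq_len(ncol(f))) {
      writeLines(paste(sprintf("%.6f", f[, j]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
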