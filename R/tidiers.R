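#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PSSM into a long tibble
#'
#' @param x A [pssm()].
#' @param ... Unused.
#' @return Tibble with `position` (1-based column), `base`, `frequency`,
#'   `information_bits` (per column).
#' @export
tidy.pssm <- function(x, ...) {
  ic <- information_content(x)$per_column
  w <- pssm_width(x)
  tibble(
    position = rep(seq_len(w), each = 4),
    base = rep(DNA_BASES, w),
    frequency = as.numeric(x$frequencies),
    information_bits = rep(ic, each = 4)
  )
}

#' One-row summary of a PSSM
#'
#' @param x A [pssm()].
#' @param ... Unused.
#' @return Tibble with `name`, `width`, `consensus`, `total_bits`,
#'   `bits_per_column`.
#' @export
glance.pssm <- function(x, ...) {
  ic <- information_content(x)
  tibble(name = x$name, width = pssm_width(x), consensus = pssm_consensus(x),
         total_bits = ic$total, bits_per_column = ic$total / pssm_width(x))
}

#' Tidy a motif set into one row per motif
#'
#' @param x A `ucr_motif_set`.
#' @param ... Unused.
#' @return Tibble with `motif`, `width`, `consensus`, `n_sites`,
#'   `map_score`, `evalue`, `evalue_proxy`, `finder`.
#' @export
tidy.ucr_motif_set <- function(x, ...) {
  bind_rows(map(seq_along(x), function(k) {
    m <- x[[k]]
    tibble(motif = m$name, width = m$width,
           consensus = pssm_consensus(m$pssm), n_sites = nrow(m$sites),
           map_score = m$map_score, evalue = m$evalue,
           evalue_proxy = m$evalue_proxy, finder = m$finder)
  }))
}

#' Tidy a regulatory network into its edge list
#'
#' @param x A `regulatory_network`.
#' @param ... Unused.
#' @return Edge tibble joined with gene categories and motif TF
#'   annotations.
#' @export
tidy.regulatory_network <- function(x, ...) {
  x$edges |>
    left_join(x$genes, by = "gene_id") |>
    left_join(x$motifs, by = "motif")
}

#' One-row summary of a regulatory network
#'
#' @param x A `regulatory_network`.
#' @param ... Unused.
#' @return Tibble with node/edge counts and the number of motifs shared
#'   between the CP and muscle categories.
#' @export
glance.regulatory_network <- function(x, ...) {
  tibble(
    n_motifs = nrow(x$motifs), n_genes = nrow(x$genes),
    n_edges = nrow(x$edges),
    n_shared_cp_muscle = length(shared_motifs(x))
  )
}
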