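#' Summarise differential-expression spot tables
#'
#' Per comparison: the number of significant spots, their percentage of
#' the array (1 decimal), and the number and percentage (2 decimals) of
#' spots mapping to annotated genes (gene-set members, `gene_id` not
#' `NA`). Across comparisons: unique significant genes per comparison,
#' their union, and up/down counts.
#'
#' @param spots Tibble with columns `spot_id`, `gene_id` (`NA` for
#'   non-gene-set spots), `comparison`, `direction` (`"up"`/`"down"`),
#'   `significant` (logical).
#' @param array_size Number of spots on the array.
#' @return List with `per_comparison` (tibble) and `overall` (one-row
#'   tibble with `union_genes`, `up_genes`, `down_genes`).
#' @export
deg_summary <- function(spots, array_size) {
  needed <- c("spot_id", "gene_id", "comparison", "direction", "significant")
  if (!all(needed %in% names(spots))) {
    abort(sprintf("Spot table needs columns: %s.", paste(needed, collapse = ", ")))
  }
  if (!nrow(spots)) abort("Empty spot table.")
  if (!all(spots$direction %in% c("up", "down"))) {
    abort("Spot direction must be 'up' or 'down'.")
  }
  dup <- spots |> group_by(.data$comparison, .data$spot_id) |>
    summarise(n = dplyr::n(), .groups = "drop") |> filter(.data$n > 1)
  if (nrow(dup)) abort("Spot ids must be unique within a comparison.")
  sig <- filter(spots, .data$significant)
  per <- sig |>
    group_by(comparison = .data$comparison) |>
    summarise(
      n_spots = dplyr::n(),
      pct_of_array = round(100 * dplyr::n() / array_size, 1),
      n_gene_set = sum(!is.na(.data$gene_id)),
      pct_gene_set = round(100 * sum(!is.na(.data$gene_id)) / dplyr::n(), 2),
      unique_genes = dplyr::n_distinct(.data$gene_id[!is.na(.data$gene_id)]),
      .groups = "drop"
    )
  gene_rows <- filter(sig, !is.na(.data$gene_id))
  union_genes <- dplyr::n_distinct(gene_rows$gene_id)
  dir_of <- gene_rows |> distinct(.data$gene_id, .data$direction)
  overall <- tibble(
    union_genes = union_genes,
    up_genes = dplyr::n_distinct(dir_of$gene_id[dir_of$direction == "up"]),
    down_genes = dplyr::n_distinct(dir_of$gene_id[dir_of$direction == "down"])
  )
  list(per_comparison = per, overall = overall)
}

#' Cross-platform direction concordance
#'
#' Percentage of comparisons in which the two platforms agree on the
#' direction of change. The percentage is truncated (not rounded) to one
#' decimal, so 58 agreements out of 72 reports as 80.5.
#'
#' @param table Tibble with columns `gene_id`, `comparison`,
#'   `direction_platform1`, `direction_platform2` (values `"up"`,
#'   `"down"` or `"unchanged"`).
#' @return List with `percent_agreement` and `verdicts` (the input with an
#'   `agree` column).
#' @export
concordance <- function(table) {
  needed <- c("gene_id", "comparison", "direction_platform1",
              "direction_platform2")
  if (!all(needed %in% names(table))) {
    abort(sprintf("Concordance table needs columns: %s.",
                  paste(needed, collapse = ", ")))
  }
  if (!nrow(table)) abort("Empty concordance table.")
  ok <- c("up", "down", "unchanged")
  if (!all(table$direction_platform1 %in% ok) ||
      !all(table$direction_platform2 %in% ok)) {
    abort("Directions must be 'up', 'down' or 'unchanged'.")
  }
  verdicts <- mutate(as_tibble(table),
                     agree = .data$direction_platform1 == .data$direction_platform2)
  pct <- floor(1000 * sum(verdicts$agree) / nrow(verdicts)) / 10
  list(percent_agreement = pct, verdicts = verdicts)
}

#' PCR amplification efficiency from a standard-curve slope
#'
#' `E = 10^(-1 / slope)`; a perfect doubling corresponds to a slope of
#' about -3.32 and `E = 2`.
#'
#' @param slope Slope of the Ct vs log-dilution standard curve (negative).
#' @return Efficiency `E`.
#' @export
pcr_efficiency <- function(slope) {
  if (any(!is.finite(slope)) || any(slope >= 0)) {
    abort("Standard-curve slope must be negative (non-physical otherwise).")
  }
  10^(-1 / slope)
}

# average and monoisotopic residue masses (Da); mass of free water added once
RESIDUE_MASS_AVG <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
RESIDUE_MASS_MONO <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841
)
WATER_AVG <- 18.01524
WATER_MONO <- 18.010565

# 0-based offsets of possibly-overlapping literal substring occurrences
substring_offsets <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

#' Cuticular-protein style sequence features
#'
#' Per-residue composition (percent, 1 decimal), molecular mass (sum of
#' residue masses plus one water), 0-based offsets of the glycine-rich
#' `GGYGG` and `GGY` amino-acid motifs (overlaps allowed; `Y` is
#' tyrosine), and a below-30-kDa flag. When a signal-peptide span is
#' supplied as metadata, the same features are recomputed for the mature
#' protein (the sequence after the span).
#'
#' @param sequence Amino-acid sequence (20-letter alphabet).
#' @param id Sequence identifier.
#' @param signal_peptide Optional length of the N-terminal signal peptide
#'   (input metadata, not predicted), in residues.
#' @param monoisotopic Use monoisotopic instead of average masses?
#' @return List with `id`, `length`, `composition` (named percents),
#'   `glycine_pct`, `mass_da`, `mass_kda`, `below_30kda`, `ggygg_offsets`,
#'   `ggy_offsets`, `has_signal_peptide` and, when a span is given,
#'   `mature` (the same features for the mature form).
#' @export
protein_features <- function(sequence, id = "protein", signal_peptide = NULL,
                             monoisotopic = FALSE) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) abort("Empty protein sequence.")
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  masses <- if (monoisotopic) RESIDUE_MASS_MONO else RESIDUE_MASS_AVG
  water <- if (monoisotopic) WATER_MONO else WATER_AVG
  bad <- setdiff(unique(aa), names(masses))
  if (length(bad)) {
    abort(sprintf("Non-amino-acid character(s): %s.", paste(bad, collapse = ", ")))
  }
  comp_counts <- table(factor(aa, levels = names(masses)))
  composition <- round(100 * as.numeric(comp_counts) / length(aa), 1)
  names(composition) <- names(masses)
  mass <- sum(masses[aa]) + water
  out <- list(
    id = id, length = length(aa), composition = composition,
    glycine_pct = composition[["G"]],
    mass_da = mass, mass_kda = mass / 1000, below_30kda = mass < 30000,
    ggygg_offsets = substring_offsets(sequence, "GGYGG"),
    ggy_offsets = substring_offsets(sequence, "GGY"),
    has_signal_peptide = !is.null(signal_peptide)
  )
  if (!is.null(signal_peptide)) {
    if (signal_peptide < 1 || signal_peptide >= length(aa)) {
      abort("Signal-peptide span must be shorter than the sequence.")
    }
    out$mature <- protein_features(substring(sequence, signal_peptide + 1),
                                   id = paste0(id, "_mature"),
                                   monoisotopic = monoisotopic)
  }
  out
}
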