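#' Sanger-validated mutations from a sunflower EMS TILLING screen
#'
#' The 16 substitutions validated by Sanger sequencing in the
#' 2048-individual sunflower screen this package models, with their
#' positions in the TILLING fragment, confidence scores, zygosity,
#' amino-acid changes and the severity class reported by the original
#' analysis. Bundled as a worked example for the spectrum and severity
#' classifiers.
#'
#' @return Data frame with columns `gene`, `dna_change`, `position`, `ref`,
#'   `alt`, `f_score`, `zygosity`, `category`, `aa_ref`, `aa_position`,
#'   `aa_alt`, `severity_reported`.
#' @examples
#' vm <- validated_mutations()
#' spectrum_summary(vm)
#' @export
validated_mutations <- function() {
  path <- system.file("extdata", "sunflower_validated_mutations.tsv",
                      package = "tillcall", mustWork = TRUE)
  read.delim(path, colClasses = c(
    gene = "character", dna_change = "character", position = "integer",
    ref = "character", alt = "character", f_score = "numeric",
    zygosity = "character", category = "character", aa_ref = "character",
    aa_position = "integer", aa_alt = "character",
    severity_reported = "character"))
}

#' Per-fragment mutation summary of the sunflower screen
#'
#' Medium- and high-confidence candidate counts (1123 in total) for the 23
#' tilled fragments of the 21 screened sunflower genes, broken down by EMS
#' canonicity and effect class, together with tilled sequence lengths.
#' Bundled as the worked example for [length_correlation()] and
#' [poisson_expected()].
#'
#' @return Data frame with one row per fragment; see the TSV header for the
#'   columns.
#' @examples
#' fs <- fragment_summary()
#' length_correlation(fs$tilled_length, fs$total)
#' @export
fragment_summary <- function() {
  path <- system.file("extdata", "sunflower_fragment_summary.tsv",
                      package = "tillcall", mustWork = TRUE)
  read.delim(path, check.names = TRUE)
}
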