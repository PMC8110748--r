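SUBSTITUTION_CLASS_MAP <- c(
  GA = "GC>AT", CT = "GC>AT",
  AG = "AT>GC", TC = "AT>GC",
  GT = "GC>TA", CA = "GC>TA",
  GC = "GC>CG", CG = "GC>CG",
  AT = "AT>TA", TA = "AT>TA",
  AC = "AT>CG", TG = "AT>CG"
)

#' Strand-collapsed substitution class
#'
#' Maps a base substitution to one of the six strand-collapsed classes used
#' to summarise a mutation spectrum: `GC>AT`, `AT>GC`, `GC>TA`, `GC>CG`,
#' `AT>TA`, `AT>CG`. A change and its complement map to the same class
#' (`C>T` and `G>A` are both `GC>AT`, the canonical EMS alkylation product).
#'
#' @param ref,alt Reference and alternate bases (vectors of single
#'   characters in ACGT, `ref != alt`).
#' @return Character vector of classes.
#' @export
substitution_class <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!all(ref %in% c("A", "C", "G", "T")) ||
      !all(alt %in% c("A", "C", "G", "T")))
    stop("ref and alt must be single bases in ACGT")
  if (any(ref == alt)) stop("ref and alt must differ")
  unname(SUBSTITUTION_CLASS_MAP[paste0(ref, alt)])
}

#' Is a substitution the canonical EMS change?
#'
#' EMS alkylates guanine, so induced mutations are overwhelmingly (>90% in
#' most TILLING populations) G:C to A:T transitions. A much lower canonical
#' fraction among candidate calls is a red flag for noise or genetic
#' contamination.
#'
#' @inheritParams substitution_class
#' @return Logical vector.
#' @export
is_canonical_ems <- function(ref, alt) {
  substitution_class(ref, alt) == "GC>AT"
}

#' BLOSUM62 substitution matrix
#'
#' The 20x20 amino-acid substitution score table (plus stop) used for
#' missense severity classification, taken from Biostrings.
#'
#' @return Integer matrix with residue one-letter row/column names.
#' @export
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62
    }
    cache
  }
})

#' Predict the protein-level effect of a substitution
#'
#' Locates a 1-based amplicon position within the gene model of a
#' [target_reference()] and classifies the substitution:
#' \itemize{
#'   \item intronic within 2 nt of an exon boundary (the canonical GT/AG
#'     dinucleotides): `splice`;
#'   \item deeper intron: `intron`;
#'   \item exonic but outside the CDS (or outside the gene span entirely):
#'     `utr`;
#'   \item in the CDS: the affected codon is rebuilt in transcript
#'     orientation (reverse-complemented for `-` strand genes), translated
#'     with the standard genetic code, and classified `silent`, `missense`
#'     or `truncation` (premature stop). Amino-acid positions count the
#'     start codon as 1.
#' }
#' Loss of the stop codon is reported as `missense` with a warning, since
#' the screen's reporting categories do not include stop-loss.
#'
#' @param reference A [target_reference()].
#' @param position 1-based position on the amplicon.
#' @param ref_base Expected reference base (guards misaligned pileups).
#' @param alt_base Alternate base.
#' @return An object of class `effect`: list with `category` and, for coding
#'   categories, `aa_ref`, `aa_position`, `aa_alt`, `codon_ref`,
#'   `codon_alt`, `aa_change`.
#' @export
predict_effect <- function(reference, position, ref_base, alt_base) {
  stopifnot(inherits(reference, "target_reference"))
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  if (position < 1L || position > nchar(reference$sequence))
    stop("position ", position, " outside amplicon ", reference$target_id)
  actual <- substring(reference$sequence, position, position)
  if (actual != ref_base)
    stop("reference mismatch at ", reference$target_id, ":", position,
         " (expected ", ref_base, ", reference has ", actual, ")")
  if (ref_base == alt_base) stop("ref and alt must differ")

  eff <- function(category, aa_ref = NA, aa_pos = NA, aa_alt = NA,
                  codon_ref = NA, codon_alt = NA) {
    aa_change <- if (!is.na(aa_ref)) paste0(aa_ref, aa_pos, aa_alt) else NA_character_
    structure(list(category = category, aa_ref = aa_ref,
                   aa_position = aa_pos, aa_alt = aa_alt,
                   codon_ref = codon_ref, codon_alt = codon_alt,
                   aa_change = aa_change),
              class = "effect")
  }

  ex <- reference$exons
  tp <- transcript_position(reference, position)
  if (is.na(tp)) {
    # not exonic: flank (utr) or intron/splice
    if (position < ex[1L, 1L] || position > ex[nrow(ex), 2L])
      return(eff("utr"))
    prev_end <- max(ex[ex[, 2L] < position, 2L])
    next_start <- min(ex[ex[, 1L] > position, 1L])
    if (position - prev_end <= 2L || next_start - position <= 2L)
      return(eff("splice"))
    return(eff("intron"))
  }
  if (tp < reference$cds_start || tp > reference$cds_end)
    return(eff("utr"))

  tx <- reference$transcript
  cpos <- tp - reference$cds_start + 1L
  codon_idx <- (cpos - 1L) %/% 3L + 1L
  within <- (cpos - 1L) %% 3L + 1L
  codon_from <- reference$cds_start + (codon_idx - 1L) * 3L
  codon_ref <- substring(tx, codon_from, codon_from + 2L)
  alt_tx <- if (reference$strand == "+") alt_base else complement_base(alt_base)
  codon_alt <- codon_ref
  substr(codon_alt, within, within) <- alt_tx
  gc <- Biostrings::GENETIC_CODE
  aa_ref <- unname(gc[codon_ref]); aa_alt <- unname(gc[codon_alt])
  category <- if (aa_ref == aa_alt) "silent"
    else if (aa_alt == "*") "truncation"
    else "missense"
  if (aa_ref == "*" && aa_alt != "*") {
    warning("stop-loss at ", reference$target_id, ":", position,
            " reported as missense")
    category <- "missense"
  }
  if (category == "missense" && codon_idx == 1L && aa_ref == "M")
    warning("start-loss at ", reference$target_id, ":", position,
            " reported as missense")
  eff(category, aa_ref, codon_idx, aa_alt, codon_ref, codon_alt)
}

#' @export
print.effect <- function(x, ...) {
  if (is.na(x$aa_change)) cat("effect:", x$category, "\n")
  else cat(sprintf("effect: %s %s (%s -> %s)\n", x$category, x$aa_change,
                   x$codon_ref, x$codon_alt))
  invisible(x)
}

severity_one <- function(category, aa_ref, aa_alt, matrix) {
  switch(category,
    truncation = , splice = "PSM",
    silent = , intron = , utr = NA_character_,
    missense = {
      if (is.na(aa_ref) || is.na(aa_alt) ||
          !aa_ref %in% rownames(matrix) || !aa_alt %in% colnames(matrix))
        stop("unknown residue in missense change: ", aa_ref, " -> ", aa_alt)
      if (matrix[aa_ref, aa_alt] >= 0) "NSM" else "PSM"
    },
    stop("unknown effect category: ", category)
  )
}

#' Missense severity class (PSM / NSM)
#'
#' Severity classification used to triage candidates for validation:
#' truncations and splice-site changes are always possible severe mutations
#' (`PSM`); silent, intronic and UTR changes get `NA`; a missense change is
#' not severe (`NSM`) when the BLOSUM62 score of the substitution is >= 0
#' (conservative replacement) and `PSM` otherwise.
#'
#' @param effect An `effect` object from [predict_effect()], or a data frame
#'   with columns `category` (or `effect`), `aa_ref`, `aa_alt`.
#' @param matrix Substitution score matrix; defaults to [blosum62()].
#' @return Character vector of `"PSM"`, `"NSM"` or `NA`.
#' @export
severity <- function(effect, matrix = blosum62()) {
  if (inherits(effect, "effect"))
    return(severity_one(effect$category, effect$aa_ref, effect$aa_alt, matrix))
  df <- as.data.frame(effect)
  cat_col <- if ("category" %in% names(df)) "category" else "effect"
  vapply(seq_len(nrow(df)), function(i)
    severity_one(df[[cat_col]][i], df$aa_ref[i], df$aa_alt[i], matrix),
    NA_character_)
}

#' Annotate candidate mutations with effect and severity
#'
#' Runs [predict_effect()] and [severity()] over a candidate table and adds
#' the columns `effect`, `aa_change`, `severity`, `canonical` and
#' `substitution` (strand-collapsed class).
#'
#' @param candidates Candidate data frame (needs `target_id`, `position`,
#'   `ref`, `alt`).
#' @param references Named list of [target_reference()] objects.
#' @return The candidate data frame with annotation columns filled in.
#' @export
annotate_candidates <- function(candidates, references) {
  n <- nrow(candidates)
  candidates$effect <- rep(NA_character_, n)
  candidates$aa_change <- rep(NA_character_, n)
  candidates$severity <- rep(NA_character_, n)
  if (n == 0L) {
    candidates$canonical <- logical(0)
    candidates$substitution <- character(0)
    return(candidates)
  }
  aa_ref <- aa_alt <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ref <- references[[candidates$target_id[i]]]
    if (is.null(ref)) stop("no reference for target ", candidates$target_id[i])
    e <- predict_effect(ref, candidates$position[i],
                        candidates$ref[i], candidates$alt[i])
    candidates$effect[i] <- e$category
    candidates$aa_change[i] <- e$aa_change
    aa_ref[i] <- e$aa_ref; aa_alt[i] <- e$aa_alt
  }
  candidates$severity <- severity(
    data.frame(category = candidates$effect, aa_ref = aa_ref,
               aa_alt = aa_alt))
  candidates$substitution <- substitution_class(candidates$ref, candidates$alt)
  candidates$canonical <- candidates$substitution == "GC>AT"
  candidates
}
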