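#' Amplicon reference with gene model
#'
#' A `target_reference` couples an amplicon sequence (always stored in the
#' forward orientation in which reads were piled up) with the gene model
#' needed for effect prediction: exon intervals on the amplicon, the coding
#' region, and the strand of the gene relative to the amplicon.
#'
#' `cds_start`/`cds_end` are 1-based positions in *transcript* space, i.e.
#' along the spliced exon sequence read 5' to 3' of the mRNA (for a `-`
#' strand gene the transcript is the reverse complement of the concatenated
#' exons taken in reverse order). The CDS includes the stop codon and its
#' spliced length must be divisible by 3.
#'
#' @param target_id Amplicon/gene name.
#' @param sequence Amplicon DNA string (ACGT only; uppercased).
#' @param exons Two-column matrix or data frame of 1-based inclusive
#'   `start`,`end` exon intervals on the amplicon, non-overlapping.
#' @param cds_start,cds_end 1-based CDS bounds in transcript space.
#' @param strand `"+"` or `"-"`: orientation of the gene on the amplicon.
#' @return An object of class `target_reference`.
#' @export
target_reference <- function(target_id, sequence, exons, cds_start, cds_end,
                             strand = "+") {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("reference ", target_id, " contains non-ACGT characters")
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L) stop("exons must have two columns (start, end)")
  colnames(exons) <- c("start", "end")
  storage.mode(exons) <- "integer"
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] < exons[, 1L]))
    stop("exon end before start in ", target_id)
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L]))
    stop("overlapping exons in ", target_id)
  if (exons[1L, 1L] < 1L || exons[nrow(exons), 2L] > nchar(sequence))
    stop("exons outside amplicon in ", target_id)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  lex <- sum(exons[, 2L] - exons[, 1L] + 1L)
  if (cds_start < 1L || cds_end > lex || cds_end < cds_start)
    stop("CDS bounds outside exon space in ", target_id)
  if ((cds_end - cds_start + 1L) %% 3L != 0L)
    stop("spliced CDS length of ", target_id, " is not divisible by 3")
  obj <- structure(
    list(target_id = target_id, sequence = sequence, exons = exons,
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
         strand = strand),
    class = "target_reference"
  )
  obj$transcript <- spliced_transcript(obj)
  obj
}

#' @export
print.target_reference <- function(x, ...) {
  cat(sprintf(
    "target_reference %s: %d bp amplicon, %d exon(s), CDS %d-%d (transcript), strand %s\n",
    x$target_id, nchar(x$sequence), nrow(x$exons), x$cds_start, x$cds_end,
    x$strand))
  invisible(x)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, "", USE.NAMES = FALSE)
}

complement_base <- function(b) chartr("ACGT", "TGCA", b)

# spliced exon sequence in mRNA orientation
spliced_transcript <- function(ref) {
  parts <- substring(ref$sequence, ref$exons[, 1L], ref$exons[, 2L])
  fwd <- paste(parts, collapse = "")
  if (ref$strand == "+") fwd else revcomp(fwd)
}

# 1-based transcript position of an amplicon position, or NA if intronic /
# outside the exons
transcript_position <- function(ref, position) {
  ex <- ref$exons
  w <- which(position >= ex[, 1L] & position <= ex[, 2L])
  if (length(w) != 1L) return(NA_integer_)
  before <- if (w > 1L) sum(ex[seq_len(w - 1L), 2L] - ex[seq_len(w - 1L), 1L] + 1L) else 0L
  es <- before + (position - ex[w, 1L] + 1L)
  lex <- sum(ex[, 2L] - ex[, 1L] + 1L)
  if (ref$strand == "+") as.integer(es) else as.integer(lex - es + 1L)
}

# amplicon intervals covered by the CDS (for GFF3 export)
cds_amplicon_ranges <- function(ref) {
  ex <- ref$exons
  lex <- sum(ex[, 2L] - ex[, 1L] + 1L)
  # CDS bounds in forward exon space
  if (ref$strand == "+") {
    lo <- ref$cds_start; hi <- ref$cds_end
  } else {
    lo <- lex - ref$cds_end + 1L; hi <- lex - ref$cds_start + 1L
  }
  out <- NULL
  off <- 0L
  for (i in seq_len(nrow(ex))) {
    w <- ex[i, 2L] - ex[i, 1L] + 1L
    a <- max(lo, off + 1L); b <- min(hi, off + w)
    if (a <= b)
      out <- rbind(out, c(start = ex[i, 1L] + (a - off - 1L),
                          end = ex[i, 1L] + (b - off - 1L)))
    off <- off + w
  }
  out
}
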