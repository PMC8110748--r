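#' Read / write amplicon reference FASTA
#'
#' Thin wrappers around Biostrings that enforce the constraints this pipeline
#' needs from a reference: unique record names, non-empty file, and (on read)
#' strictly ACGT sequences, uppercased.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  # keep only the first whitespace-delimited token of each header
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    stop("duplicate FASTA ids: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad))
    stop("non-ACGT characters in reference record(s): ",
         paste(nm[bad], collapse = ", "))
  names(seqs) <- nm
  seqs
}

#' @rdname read_fasta
#' @param sequences Named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)), all(nzchar(names(sequences))))
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read gene models (GFF3 subset) into target references
#'
#' Reads `exon` and `CDS` features from a GFF3 file whose `seqid`s are the
#' amplicon ids of `references`, and assembles one [target_reference()] per
#' amplicon. CDS intervals are converted from amplicon coordinates to
#' transcript space; a spliced CDS length not divisible by 3 is an error
#' naming the offending target.
#'
#' @param path GFF3 file.
#' @param references Named character vector from [read_fasta()].
#' @return Named list of `target_reference` objects.
#' @export
read_gene_models <- function(path, references) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type)
  )
  df <- df[df$type %in% c("exon", "CDS"), ]
  ids <- unique(df$seqid)
  missing <- setdiff(ids, names(references))
  if (length(missing))
    stop("gene model seqid(s) not found in references: ",
         paste(missing, collapse = ", "))
  out <- lapply(ids, function(id) {
    d <- df[df$seqid == id, ]
    ex <- d[d$type == "exon", c("start", "end")]
    cds <- d[d$type == "CDS", c("start", "end")]
    if (nrow(ex) == 0L) stop("no exon features for ", id)
    if (nrow(cds) == 0L) stop("no CDS features for ", id)
    strand <- unique(d$strand)
    if (length(strand) != 1L || !strand %in% c("+", "-"))
      stop("inconsistent or missing strand for ", id)
    ex <- ex[order(ex$start), , drop = FALSE]
    cds <- cds[order(cds$start), , drop = FALSE]
    # CDS bounds -> forward exon space, then transcript space
    tmp <- target_reference(id, references[[id]], ex, 1L, 3L, strand = "+")
    es_lo <- transcript_position(tmp, min(cds$start))
    es_hi <- transcript_position(tmp, max(cds$end))
    if (is.na(es_lo) || is.na(es_hi))
      stop("CDS of ", id, " not contained in exons")
    lex <- sum(ex$end - ex$start + 1L)
    if (strand == "+") {
      cs <- es_lo; ce <- es_hi
    } else {
      cs <- lex - es_hi + 1L; ce <- lex - es_lo + 1L
    }
    cds_len <- sum(cds$end - cds$start + 1L)
    if (cds_len %% 3L != 0L)
      stop("CDS length of ", id, " is not divisible by 3")
    target_reference(id, references[[id]], ex, cs, ce, strand = strand)
  })
  names(out) <- ids
  out
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gene_models()]: emits one `gene` line plus `exon` and
#' `CDS` features per target, in amplicon coordinates.
#'
#' @param models Named list of [target_reference()] objects.
#' @param path Output file.
#' @export
write_gene_models <- function(models, path) {
  lines <- "##gff-version 3"
  for (ref in models) {
    id <- ref$target_id
    gene_range <- range(ref$exons)
    lines <- c(lines, paste(id, "tillcall", "gene", gene_range[1L],
                            gene_range[2L], ".", ref$strand, ".",
                            sprintf("ID=%s.g", id), sep = "\t"))
    for (i in seq_len(nrow(ref$exons)))
      lines <- c(lines, paste(id, "tillcall", "exon", ref$exons[i, 1L],
                              ref$exons[i, 2L], ".", ref$strand, ".",
                              sprintf("ID=%s.e%d;Parent=%s.g", id, i, id),
                              sep = "\t"))
    cr <- cds_amplicon_ranges(ref)
    for (i in seq_len(nrow(cr)))
      lines <- c(lines, paste(id, "tillcall", "CDS", cr[i, 1L], cr[i, 2L],
                              ".", ref$strand, ".",
                              sprintf("ID=%s.c%d;Parent=%s.g", id, i, id),
                              sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

PILEUP_COLUMNS <- c("pool_id", "target_id", "position", "ref",
                    "A", "C", "G", "T", "depth")

validate_pileup <- function(tab, references = NULL, where = "pileup") {
  if (!identical(names(tab), PILEUP_COLUMNS))
    stop(where, " must have columns ", paste(PILEUP_COLUMNS, collapse = ", "))
  bad <- which(tab$depth != tab$A + tab$C + tab$G + tab$T)
  if (length(bad))
    stop(where, ": depth != A+C+G+T at line(s) ",
         paste(utils::head(bad, 5L) + 1L, collapse = ", "),
         " (1 header line counted)")
  if (!all(tab$ref %in% c("A", "C", "G", "T")))
    stop(where, ": ref base must be one of A, C, G, T")
  if (!is.null(references)) {
    ids <- unique(tab$target_id)
    missing <- setdiff(ids, names(references))
    if (length(missing))
      stop(where, ": target id(s) not in references: ",
           paste(missing, collapse = ", "))
    for (id in ids) {
      sub <- tab[tab$target_id == id, ]
      len <- nchar(references[[id]])
      if (any(sub$position < 1L | sub$position > len))
        stop(where, ": position outside reference ", id)
      refbase <- substring(references[[id]], sub$position, sub$position)
      if (any(refbase != sub$ref))
        stop(where, ": ref base mismatch with reference ", id)
    }
  }
  invisible(tab)
}

#' Read / write a parsed pileup table
#'
#' The parsed pileup is this package's per-pool, per-position base-count
#' dialect: a TSV with columns `pool_id target_id position ref A C G T depth`
#' (positions 1-based on the amplicon). `depth` must equal the sum of the
#' four base counts; inconsistent records are rejected with their line
#' number. Writer and reader are exact inverses on valid data.
#'
#' @param path TSV file.
#' @param references Optional named sequences; if given, positions and ref
#'   bases are validated against them.
#' @return Data frame with the columns above.
#' @export
read_parsed_pileup <- function(path, references = NULL) {
  tab <- read.delim(path, colClasses = c(
    pool_id = "character", target_id = "character", position = "integer",
    ref = "character", A = "integer", C = "integer", G = "integer",
    T = "integer", depth = "integer"))
  validate_pileup(tab, references, where = path)
}

#' @rdname read_parsed_pileup
#' @param pileup Data frame as returned by [read_parsed_pileup()] or
#'   [generate_pileup()].
#' @export
write_parsed_pileup <- function(pileup, path) {
  validate_pileup(pileup)
  write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# tally the base symbols of one samtools-mpileup read-base string
# (strand-collapsed); returns c(A=, C=, G=, T=)
tally_mpileup_bases <- function(bases, ref) {
  s <- bases
  s <- gsub("\\^.", "", s)      # read-start marker + mapping quality char
  s <- gsub("\\$", "", s)       # read-end marker
  # indels: "+<n><seq>" / "-<n><seq>" refer to the *next* position; skip
  repeat {
    m <- regexpr("[+-][0-9]+", s)
    if (m == -1L) break
    n <- as.integer(substr(s, m + 1L, m + attr(m, "match.length") - 1L))
    s <- paste0(substr(s, 1L, m - 1L),
                substring(s, m + attr(m, "match.length") + n))
  }
  ch <- toupper(strsplit(s, "", fixed = TRUE)[[1L]])
  ch[ch %in% c(".", ",")] <- ref
  known <- c("A", "C", "G", "T", "*", "N", ">", "<")
  if (!all(ch %in% known))
    stop("malformed mpileup read-base string: ", bases)
  counts <- c(A = sum(ch == "A"), C = sum(ch == "C"),
              G = sum(ch == "G"), T = sum(ch == "T"))
  counts  # '*' deletions and reference skips are dropped, reducing depth
}

#' Read samtools mpileup text for one pool
#'
#' Parses standard single-sample `samtools mpileup` text (columns: target,
#' position, ref base, depth, read bases, qualities) into the parsed-pileup
#' table. Match/mismatch symbols (`.`/`,` and `ACGTacgt`) are tallied
#' strand-collapsed; read start/end marks and indel fields are skipped; `*`
#' deletion placeholders are dropped with the depth reduced accordingly, so
#' `depth` in the output is the sum of the four base counts.
#'
#' @param path mpileup text file.
#' @param references Named sequences (used to validate positions/ref bases).
#' @param pool_id Pool id to stamp on the records.
#' @return Parsed pileup data frame.
#' @export
read_samtools_mpileup <- function(path, references, pool_id) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty mpileup file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 5L))
    stop("malformed mpileup line ", which(nf < 5L)[1L], " in ", path)
  tgt <- vapply(fields, `[`, "", 1L)
  pos <- as.integer(vapply(fields, `[`, "", 2L))
  ref <- toupper(vapply(fields, `[`, "", 3L))
  bases <- vapply(fields, `[`, "", 5L)
  counts <- t(mapply(tally_mpileup_bases, bases, ref))
  tab <- data.frame(
    pool_id = pool_id, target_id = tgt, position = pos, ref = ref,
    A = as.integer(counts[, "A"]), C = as.integer(counts[, "C"]),
    G = as.integer(counts[, "G"]), T = as.integer(counts[, "T"]))
  tab$depth <- tab$A + tab$C + tab$G + tab$T
  validate_pileup(tab, references, where = path)
}

#' Write candidate mutations as TSV or VCF
#'
#' @param candidates Candidate table from [call_mutations()] (possibly after
#'   [annotate_candidates()]).
#' @param path Output file.
#' @param format `"tsv"` (default) or `"vcf"` (VCF 4.2 against the amplicon
#'   as contig, with INFO keys `FT` (confidence score), `IND` (decoded
#'   0-based individual), `ZYG`, `EFF`, `SEV`).
#' @param references Optional named sequences used to emit `##contig` header
#'   lines with lengths.
#' @export
write_candidates <- function(candidates, path, format = c("tsv", "vcf"),
                             references = NULL) {
  format <- match.arg(format)
  cols <- c("target_id", "position", "ref", "alt", "set", "individual",
            "zygosity", "f_score", "confidence_class", "effect", "aa_change",
            "severity", "canonical")
  for (col in setdiff(cols, names(candidates))) candidates[[col]] <- NA
  if (format == "tsv") {
    write.table(candidates[, cols], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    return(invisible(path))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=tillcall",
    '##INFO=<ID=FT,Number=1,Type=Float,Description="log10 posterior odds of the mutation configuration vs no mutation">',
    '##INFO=<ID=IND,Number=1,Type=Integer,Description="Decoded carrier individual (0-based)">',
    '##INFO=<ID=ZYG,Number=1,Type=String,Description="Zygosity of the carrier (het/hom)">',
    '##INFO=<ID=EFF,Number=1,Type=String,Description="Predicted effect category">',
    '##INFO=<ID=SEV,Number=1,Type=String,Description="Missense severity class (PSM/NSM/NA)">')
  if (!is.null(references))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(references), nchar(references)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  if (nrow(candidates) > 0L) {
    info <- sprintf("FT=%.3f;IND=%d;ZYG=%s;EFF=%s;SEV=%s",
                    candidates$f_score, candidates$individual,
                    candidates$zygosity,
                    ifelse(is.na(candidates$effect), ".", candidates$effect),
                    ifelse(is.na(candidates$severity), ".", candidates$severity))
    rows <- paste(candidates$target_id, candidates$position, ".",
                  candidates$ref, candidates$alt, ".", "PASS", info,
                  sep = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a candidate TSV written by [write_candidates()]
#' @param path TSV file.
#' @return Candidate data frame.
#' @export
read_candidates <- function(path) {
  read.delim(path, colClasses = c(
    target_id = "character", position = "integer", ref = "character",
    alt = "character", set = "integer", individual = "integer",
    zygosity = "character", f_score = "numeric",
    confidence_class = "character", effect = "character",
    aa_change = "character", severity = "character", canonical = "logical"))
}
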