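SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

#' Simulation configuration
#'
#' Study conditions for the synthetic EMS screen. The defaults reproduce the
#' screen this package models: 2048 M2 individuals pooled 64-plex in a
#' tridimensional scheme, about 0.55 induced mutations per individual over
#' the tilled space, >90% canonical G:C>A:T changes, 1/3 homozygous
#' carriers, mean pool coverage around 12,000x with strong negative-binomial
#' fluctuation, and a per-base sequencing error of 0.1%.
#'
#' @param seed RNG seed (one global seed for the whole simulation).
#' @param n_individuals,pool_size Population and pooling design.
#' @param lambda Expected induced mutations per individual over the tilled
#'   space (default 0.548 = 1123/2048).
#' @param canonical_bias Marginal fraction of induced mutations that are
#'   canonical G:C>A:T transitions (default 0.9).
#' @param p_hom Probability a mutant individual is homozygous (default 1/3,
#'   M2 segregation of an M1 heterozygote).
#' @param depth_mean,depth_dispersion Negative-binomial per-pool-position
#'   coverage (mean 12000, size 5: sd about 5400, spanning the large
#'   pool-to-pool fluctuation seen in real amplicon screens).
#' @param base_error Total per-base sequencing error rate (default 0.001);
#'   each specific alternate base receives `base_error / 3` of it.
#' @param n_contaminants Number of genetically contaminated individuals
#'   (outcrossed / seed-stock) carrying extra natural polymorphisms.
#' @param contaminant_extra_range Range (inclusive) of extra variant counts
#'   per contaminant, drawn uniformly; default 5..10.
#' @param dropout_prob Probability that a pool x position cell falls into a
#'   low-coverage trough (its depth is multiplied by `dropout_factor`),
#'   mimicking primer-shadow coverage declines; default 0.
#' @param dropout_factor Depth multiplier inside a trough (default 0.02).
#' @param share_positions Allow two individuals to mutate the same position
#'   (default `FALSE`; see the methods vignette).
#' @param n_targets,target_cds_codons,target_exons,intron_length,utr_length,flank_length,rev_strand_prob
#'   Reference-generation parameters passed to [generate_references()].
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_individuals = 2048L,
                              pool_size = 64L,
                              lambda = 1123 / 2048,
                              canonical_bias = 0.9,
                              p_hom = 1 / 3,
                              depth_mean = 12000,
                              depth_dispersion = 5,
                              base_error = 0.001,
                              n_contaminants = 0L,
                              contaminant_extra_range = c(5L, 10L),
                              dropout_prob = 0,
                              dropout_factor = 0.02,
                              share_positions = FALSE,
                              n_targets = 6L,
                              target_cds_codons = c(60L, 140L),
                              target_exons = c(1L, 3L),
                              intron_length = c(60L, 160L),
                              utr_length = c(30L, 80L),
                              flank_length = c(15L, 40L),
                              rev_strand_prob = 0.3) {
  stopifnot(lambda >= 0, canonical_bias >= 0, canonical_bias <= 1,
            p_hom >= 0, p_hom <= 1, depth_mean > 0, depth_dispersion > 0,
            base_error >= 0, base_error < 1,
            dropout_prob >= 0, dropout_prob <= 1,
            length(contaminant_extra_range) == 2L,
            contaminant_extra_range[1L] <= contaminant_extra_range[2L])
  structure(as.list(environment()), class = "simulation_config")
}

#' Generate random amplicon references with valid gene models
#'
#' Builds random target genes the way the effect predictor expects them: an
#' ATG start codon, a run of sense codons, an in-frame stop, UTR flanks,
#' introns starting GT and ending AG, plus short primer flanks outside the
#' gene. A fraction of genes is placed on the reverse strand of the
#' amplicon to exercise strand handling.
#'
#' @param n_targets Number of amplicons.
#' @param cds_codons_range Range of internal codon counts.
#' @param exons_range Range of exon counts.
#' @param intron_length_range,utr_length_range,flank_length_range Length
#'   ranges (bp).
#' @param rev_strand_prob Probability of a reverse-strand gene.
#' @param prefix Target id prefix.
#' @param seed Optional RNG seed.
#' @return Named list of [target_reference()] objects.
#' @export
generate_references <- function(n_targets = 6L,
                                cds_codons_range = c(60L, 140L),
                                exons_range = c(1L, 3L),
                                intron_length_range = c(60L, 160L),
                                utr_length_range = c(30L, 80L),
                                flank_length_range = c(15L, 40L),
                                rev_strand_prob = 0.3,
                                prefix = "amp",
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rint <- function(range) sample(range[1L]:range[2L], 1L)
  rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  out <- list()
  for (i in seq_len(n_targets)) {
    ncod <- rint(cds_codons_range)
    cds <- paste0("ATG", paste(sample(SENSE_CODONS, ncod, TRUE),
                               collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    utr5 <- rdna(rint(utr_length_range))
    utr3 <- rdna(rint(utr_length_range))
    mrna <- paste0(utr5, cds, utr3)
    cds_start <- nchar(utr5) + 1L
    cds_end <- nchar(utr5) + nchar(cds)
    n_exons <- rint(exons_range)
    # intron insertion points strictly inside the transcript
    cuts <- sort(sample(2:(nchar(mrna) - 1L), n_exons - 1L))
    starts <- c(1L, cuts); ends <- c(cuts - 1L, nchar(mrna))
    gene <- ""
    exons <- matrix(0L, n_exons, 2L,
                    dimnames = list(NULL, c("start", "end")))
    for (k in seq_len(n_exons)) {
      exons[k, 1L] <- nchar(gene) + 1L
      gene <- paste0(gene, substring(mrna, starts[k], ends[k]))
      exons[k, 2L] <- nchar(gene)
      if (k < n_exons)
        gene <- paste0(gene, "GT", rdna(rint(intron_length_range) - 4L), "AG")
    }
    strand <- if (runif(1L) < rev_strand_prob) "-" else "+"
    if (strand == "-") {
      gene <- revcomp(gene)
      L <- nchar(gene)
      exons <- cbind(start = L - exons[, 2L] + 1L,
                     end = L - exons[, 1L] + 1L)
      exons <- exons[order(exons[, 1L]), , drop = FALSE]
    }
    lflank <- rdna(rint(flank_length_range))
    rflank <- rdna(rint(flank_length_range))
    amplicon <- paste0(lflank, gene, rflank)
    exons <- exons + nchar(lflank)
    id <- sprintf("%s%02d", prefix, i)
    out[[id]] <- target_reference(id, amplicon, exons, cds_start, cds_end,
                                  strand = strand)
  }
  out
}

draw_alt <- function(ref, canonical) {
  if (canonical) return(chartr("GC", "AT", ref))
  pool <- setdiff(c("A", "C", "G", "T"), ref)
  if (ref %in% c("G", "C"))
    pool <- setdiff(pool, chartr("GC", "AT", ref))
  sample(pool, 1L)
}

#' Generate the mutated population (truth table)
#'
#' Per individual the induced mutation count is Poisson(`lambda`); a
#' mutation is canonical (uniform over G/C sites, G>A or C>T) with
#' probability `canonical_bias` and otherwise a uniform non-canonical
#' change at a uniform site, so the marginal canonical fraction equals
#' `canonical_bias`. Carriers are homozygous with probability `p_hom`.
#' Contaminant individuals additionally receive extra variants that ignore
#' the canonical bias (uniform site, uniform alternate base) and are
#' heterozygous, emulating natural polymorphisms acquired by outcrossing.
#'
#' @param config [simulation_config()].
#' @param references Named list of [target_reference()] objects.
#' @return Data frame (truth table) with columns `individual`, `target_id`,
#'   `position`, `ref`, `alt`, `zygosity`, `is_contaminant_variant`, plus
#'   attribute `contaminants` (the contaminated individual ids).
#' @export
generate_population <- function(config, references) {
  stopifnot(inherits(config, "simulation_config"))
  sites <- do.call(rbind, lapply(references, function(r) data.frame(
    target_id = r$target_id,
    position = seq_len(nchar(r$sequence)),
    ref = strsplit(r$sequence, "")[[1L]])))
  rownames(sites) <- NULL
  n <- config$n_individuals
  counts <- rpois(n, config$lambda)
  contaminants <- sort(sample(n, config$n_contaminants)) - 1L
  extra <- if (config$n_contaminants > 0)
    sample(config$contaminant_extra_range[1L]:config$contaminant_extra_range[2L],
           config$n_contaminants, TRUE) else integer(0)
  ind <- c(rep(0:(n - 1L), counts), rep(contaminants, extra))
  is_extra <- c(rep(FALSE, sum(counts)), rep(TRUE, sum(extra)))
  m <- length(ind)
  if (m == 0L)
    return(structure(data.frame(
      individual = integer(0), target_id = character(0),
      position = integer(0), ref = character(0), alt = character(0),
      zygosity = character(0), is_contaminant_variant = logical(0)),
      contaminants = contaminants))
  canonical <- !is_extra & runif(m) < config$canonical_bias
  gc_sites <- which(sites$ref %in% c("G", "C"))
  pick <- integer(m)
  if (config$share_positions) {
    pick[canonical] <- sample(gc_sites, sum(canonical), TRUE)
    pick[!canonical] <- sample(nrow(sites), sum(!canonical), TRUE)
  } else {
    if (m > nrow(sites) || sum(canonical) > length(gc_sites))
      stop("not enough sites to place ", m,
           " unique variants; enlarge the references or set share_positions")
    pick[canonical] <- sample(gc_sites, sum(canonical))
    pick[!canonical] <- sample(setdiff(seq_len(nrow(sites)),
                                       pick[canonical]), sum(!canonical))
  }
  ref <- sites$ref[pick]
  alt <- character(m)
  for (k in seq_len(m))
    alt[k] <- if (is_extra[k]) sample(setdiff(c("A", "C", "G", "T"), ref[k]), 1L)
              else draw_alt(ref[k], canonical[k])
  zyg <- ifelse(is_extra, "het",
                ifelse(runif(m) < config$p_hom, "hom", "het"))
  truth <- data.frame(
    individual = ind, target_id = sites$target_id[pick],
    position = sites$position[pick], ref = ref, alt = alt,
    zygosity = zyg, is_contaminant_variant = is_extra)
  truth <- truth[order(truth$target_id, truth$position, truth$individual), ]
  rownames(truth) <- NULL
  structure(truth, contaminants = contaminants)
}

#' Generate a pooled pileup from a truth table
#'
#' The generative mirror of the caller's binomial error model. For every
#' pool x position, depth is negative binomial; the specific alternate base
#' of a variant carried by the pool is drawn as
#' `Binomial(depth, e + f * (1 - e))` with `f` summed over the pool's
#' carriers (`1/(2 * pool_size)` per heterozygote, `1/pool_size` per
#' homozygote); every other alternate base draws error reads at `e / 3`
#' each; the reference base takes the remaining depth, so the depth
#' identity holds exactly.
#'
#' @param truth Truth table from [generate_population()].
#' @param scheme [build_scheme()] result.
#' @param config [simulation_config()].
#' @param references Named list of [target_reference()] objects.
#' @return Parsed pileup data frame.
#' @export
generate_pileup <- function(truth, scheme, config, references) {
  pools <- pool_ids(scheme)
  P <- length(pools)
  e <- config$base_error
  bases <- c("A", "C", "G", "T")
  res <- vector("list", length(references))
  for (t in seq_along(references)) {
    r <- references[[t]]
    L <- nchar(r$sequence)
    refb <- strsplit(r$sequence, "")[[1L]]
    D <- matrix(rnbinom(P * L, mu = config$depth_mean,
                        size = config$depth_dispersion), P, L)
    if (config$dropout_prob > 0) {
      drop <- matrix(runif(P * L) < config$dropout_prob, P, L)
      D[drop] <- as.integer(round(D[drop] * config$dropout_factor))
    }
    # per-cell success probability per alternate base: start at e/3
    cnt <- list()
    for (b in bases) {
      M <- matrix(rbinom(P * L, D, e / 3), P, L)
      M[matrix(refb == b, P, L, byrow = TRUE)] <- 0L
      cnt[[b]] <- M
    }
    tv <- truth[truth$target_id == r$target_id, , drop = FALSE]
    if (nrow(tv) > 0L) {
      fz <- ifelse(tv$zygosity == "hom", 1 / scheme$pool_size,
                   1 / (2 * scheme$pool_size))
      carrier <- pools_of(scheme, tv$individual)
      if (is.null(dim(carrier))) carrier <- matrix(carrier, 1L)
      # accumulate carrier fractions per (pool, position, alt)
      fmap <- new.env(parent = emptyenv())
      for (k in seq_len(nrow(tv))) {
        for (pid in carrier[k, ]) {
          key <- paste(pid, tv$position[k], tv$alt[k])
          fmap[[key]] <- (if (is.null(fmap[[key]])) 0 else fmap[[key]]) + fz[k]
        }
      }
      for (key in ls(fmap)) {
        parts <- strsplit(key, " ", fixed = TRUE)[[1L]]
        i <- match(parts[1L], pools); j <- as.integer(parts[2L])
        b <- parts[3L]; fsum <- fmap[[key]]
        cnt[[b]][i, j] <- rbinom(1L, D[i, j], e + fsum * (1 - e))
      }
    }
    refcnt <- D - cnt$A - cnt$C - cnt$G - cnt$T
    short <- which(refcnt < 0L)
    for (s in short) {
      # pathological cell (tiny depth, many error draws): resample jointly
      i <- (s - 1L) %% P + 1L; j <- (s - 1L) %/% P + 1L
      pr <- rep(e / 3, 4L); names(pr) <- bases
      pr[refb[j]] <- 0
      pr <- c(pr, ref = 1 - sum(pr))
      draw <- rmultinom(1L, D[i, j], pr)[, 1L]
      for (b in bases) cnt[[b]][i, j] <- draw[[b]]
      refcnt[i, j] <- draw[["ref"]]
    }
    refmat <- matrix(refb, P, L, byrow = TRUE)
    tab <- data.frame(
      pool_id = rep(pools, L), target_id = r$target_id,
      position = rep(seq_len(L), each = P), ref = as.vector(refmat),
      A = as.vector(cnt$A), C = as.vector(cnt$C), G = as.vector(cnt$G),
      T = as.vector(cnt$T), depth = 0L)
    # the reference base's own column carries the reference count, so the
    # depth identity depth = A+C+G+T holds by construction
    ridx <- match(tab$ref, bases)
    m4 <- as.matrix(tab[, bases])
    m4[cbind(seq_len(nrow(tab)), ridx)] <- as.vector(refcnt)
    tab[, bases] <- m4
    tab$depth <- as.integer(rowSums(m4))
    res[[t]] <- tab
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  validate_pileup(out)
}

#' Run a complete synthetic screen
#'
#' Seeds the RNG once and chains [build_scheme()],
#' [generate_references()], [generate_population()] and
#' [generate_pileup()].
#'
#' @param config [simulation_config()].
#' @return List with `config`, `scheme`, `references`, `truth`, `pileup`.
#' @export
simulate_screen <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  scheme <- build_scheme(config$n_individuals, config$pool_size)
  references <- generate_references(
    n_targets = config$n_targets,
    cds_codons_range = config$target_cds_codons,
    exons_range = config$target_exons,
    intron_length_range = config$intron_length,
    utr_length_range = config$utr_length,
    flank_length_range = config$flank_length,
    rev_strand_prob = config$rev_strand_prob)
  truth <- generate_population(config, references)
  pileup <- generate_pileup(truth, scheme, config, references)
  list(config = config, scheme = scheme, references = references,
       truth = truth, pileup = pileup)
}
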