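#' Caller configuration
#'
#' Parameters of the Bayesian pooled mutation caller.
#'
#' @param mutation_prior Prior probability `mu` of an induced mutation per
#'   base per individual (default `1e-5`, of the order of one mutation per
#'   ~100 kb expected from a standard EMS dose).
#' @param canonical_weight Fraction of `mu` assigned to the canonical
#'   G:C>A:T change when the reference base is G or C (default 0.9,
#'   mirroring the expected EMS spectrum); the remainder is split evenly
#'   over the other alternate bases, and at A/T sites `mu` is split evenly
#'   over all three.
#' @param error_floor Minimum per-change sequencing error rate `e_min`
#'   (default 0.001; short-read platforms do not do better than ~0.1%).
#' @param zygosity_prior_hom Prior probability that a mutant individual is
#'   homozygous (default 1/3, the M2 segregation expectation for an M1
#'   heterozygote).
#' @param confidence_bounds Two increasing F-score bounds `c(low, high)`
#'   separating the `low` (< first), `medium` (between, inclusive) and
#'   `high` (> second) confidence classes; defaults `c(2, 7.69)`.
#' @param validated_bound F score above which, in the screen this package
#'   models, no Sanger false positives were observed (19.1); used by
#'   [validation_curve()] as the default top bin edge.
#' @param min_depth Minimum pool depth for a pool to contribute to noise
#'   estimation and for a carrier pool not to be flagged (default 100).
#' @param het_fraction,hom_fraction Expected allele fraction contributed to
#'   a pool by one heterozygous / homozygous carrier. Default `NULL` derives
#'   them from the pooling scheme as `1/(2 * pool_size)` and `1/pool_size`.
#' @return Object of class `caller_config`.
#' @export
caller_config <- function(mutation_prior = 1e-5,
                          canonical_weight = 0.9,
                          error_floor = 0.001,
                          zygosity_prior_hom = 1 / 3,
                          confidence_bounds = c(low = 2, high = 7.69),
                          validated_bound = 19.1,
                          min_depth = 100,
                          het_fraction = NULL,
                          hom_fraction = NULL) {
  stopifnot(mutation_prior > 0, mutation_prior < 1,
            canonical_weight > 0, canonical_weight < 1,
            error_floor > 0, error_floor < 1,
            zygosity_prior_hom > 0, zygosity_prior_hom < 1,
            length(confidence_bounds) == 2L,
            confidence_bounds[1L] < confidence_bounds[2L],
            confidence_bounds[2L] < validated_bound,
            min_depth >= 0)
  structure(
    list(mutation_prior = mutation_prior,
         canonical_weight = canonical_weight,
         error_floor = error_floor,
         zygosity_prior_hom = zygosity_prior_hom,
         confidence_bounds = unname(confidence_bounds),
         validated_bound = validated_bound,
         min_depth = min_depth,
         het_fraction = het_fraction,
         hom_fraction = hom_fraction),
    class = "caller_config")
}

carrier_fractions <- function(config, scheme) {
  f_het <- config$het_fraction %||% (1 / (2 * scheme$pool_size))
  f_hom <- config$hom_fraction %||% (1 / scheme$pool_size)
  if (!(config$error_floor < f_het && f_het < f_hom && f_hom < 1))
    stop("need error_floor < het_fraction < hom_fraction < 1; got ",
         config$error_floor, ", ", f_het, ", ", f_hom)
  c(het = f_het, hom = f_hom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Confidence class of an F score
#'
#' `low` below the first bound, `high` strictly above the second, `medium`
#' between them (inclusive on both sides).
#'
#' @param f Numeric F scores.
#' @param bounds Two increasing bounds, default `c(2, 7.69)`.
#' @return Character vector `"low"` / `"medium"` / `"high"`.
#' @export
confidence_class <- function(f, bounds = c(2, 7.69)) {
  ifelse(f < bounds[1L], "low", ifelse(f > bounds[2L], "high", "medium"))
}

# internal matrix layout of one target's pileup: list of P x L matrices
# (depth + one per base), position and ref vectors, pool ids as rownames
pileup_matrices <- function(pileup, target, pools) {
  pu <- pileup[pileup$target_id == target, ]
  positions <- sort(unique(pu$position))
  i <- match(pu$pool_id, pools)
  if (anyNA(i))
    stop("pileup contains pool ids not in the scheme: ",
         paste(unique(pu$pool_id[is.na(i)]), collapse = ", "))
  j <- match(pu$position, positions)
  mk <- function(col) {
    m <- matrix(0, length(pools), length(positions),
                dimnames = list(pools, positions))
    m[cbind(i, j)] <- pu[[col]]
    m
  }
  refbase <- character(length(positions))
  refbase[j] <- pu$ref
  list(depth = mk("depth"), A = mk("A"), C = mk("C"), G = mk("G"),
       T = mk("T"), positions = positions, ref = refbase)
}

#' Estimate the per-position noise model
#'
#' Sequence variation is visible at essentially every position of a deep
#' pooled amplicon pileup; most of it is sequencing error. For each
#' (target, position, alternate base) the error rate is estimated as the
#' mean alternate-allele frequency across pools after excluding, per set,
#' the 3 highest-frequency pools — a true single-carrier mutation occupies
#' exactly 3 pools of one set, so the trimming prevents a real mutation from
#' inflating its own noise estimate. Estimates are floored at
#' `config$error_floor`. Pools below `config$min_depth` are ignored;
#' positions with fewer than 6 usable pools are marked unscorable.
#'
#' @param pileup Parsed pileup data frame.
#' @param scheme [build_scheme()] result.
#' @param config [caller_config()].
#' @return Object of class `noise_model`: per target a list with `positions`
#'   (1-based), `ref`, `e` (positions x ACGT matrix, `NA` at the reference
#'   base) and `scorable` (logical).
#' @export
estimate_noise <- function(pileup, scheme, config = caller_config()) {
  validate_pileup(pileup)
  pools <- pool_ids(scheme)
  set_of_pool <- parse_pool_id(pools)$set
  out <- lapply(unique(pileup$target_id), function(tg) {
    mats <- pileup_matrices(pileup, tg, pools)
    D <- mats$depth
    usable <- D >= config$min_depth & D > 0
    n_usable <- colSums(usable)
    L <- length(mats$positions)
    e <- matrix(NA_real_, L, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
    for (b in c("A", "C", "G", "T")) {
      freq <- mats[[b]] / D
      freq[!usable] <- NA
      sums <- numeric(L); ns <- numeric(L)
      for (st in unique(set_of_pool)) {
        fs <- freq[set_of_pool == st, , drop = FALSE]
        trimmed <- apply(fs, 2L, function(v) {
          v <- v[!is.na(v)]
          if (length(v) <= 3L) return(c(0, 0))
          v <- sort(v, decreasing = TRUE)[-(1:3)]
          c(sum(v), length(v))
        })
        sums <- sums + trimmed[1L, ]
        ns <- ns + trimmed[2L, ]
      }
      e[, b] <- ifelse(ns > 0, pmax(config$error_floor, sums / ns), NA)
    }
    e[cbind(seq_len(L), match(mats$ref, c("A", "C", "G", "T")))] <- NA
    list(positions = mats$positions, ref = mats$ref, e = e,
         scorable = n_usable >= 6L & apply(!is.na(e), 1L, any))
  })
  names(out) <- unique(pileup$target_id)
  structure(out, class = "noise_model")
}

#' Log-likelihood of one mutation configuration
#'
#' Under the binomial sequencing-error model the alternate-base count of
#' pool `j` is `Binomial(d_j, p_j)` with `p_j = e + f * (1 - e)` for the
#' three pools carrying the mutant individual and `p_j = e` otherwise
#' (error and true allele both contribute, which keeps `p` a proper
#' probability at any `e`). The null (no-mutation) configuration is the
#' special case `carrier_pools = NULL` (or `f = 0`).
#'
#' @param alt_counts,depths Integer vectors over pools.
#' @param carrier_pools Indices (into the vectors) of the carrier pools, or
#'   `NULL` for the null configuration.
#' @param e Per-change error rate.
#' @param f Carrier allele fraction (`het` or `hom` fraction).
#' @return Scalar log-likelihood (natural log).
#' @export
config_log_likelihood <- function(alt_counts, depths, carrier_pools = NULL,
                                  e, f = 0) {
  if (any(alt_counts > depths))
    stop("alternate count exceeds depth")
  p <- rep(e, length(depths))
  if (!is.null(carrier_pools) && length(carrier_pools))
    p[carrier_pools] <- e + f * (1 - e)
  sum(dbinom(alt_counts, depths, p, log = TRUE))
}

# Core scoring engine for one target/set/alt over all positions at once.
# Returns NULL or a data.frame of per-position best configurations.
# Arguments: Cb/D = P x L count & depth matrices for this set's pools,
# e = per-position error vector, mu_change = per-position prior mass vector,
# usable = positions to score (logical).
score_engine <- function(Cb, D, e, mu_change, usable, M3, f, p_hom, config) {
  L <- ncol(D)
  if (nrow(M3) * max(mu_change) >= 1)
    stop("configuration priors sum to >= 1; lower mutation_prior")
  keep <- usable & !is.na(e)
  if (!any(keep)) return(NULL)
  idx <- which(keep)
  Cb <- Cb[, idx, drop = FALSE]; D <- D[, idx, drop = FALSE]
  ev <- e[idx]; mu <- mu_change[idx]
  P <- nrow(D)
  E <- matrix(ev, P, length(idx), byrow = TRUE)
  A <- dbinom(Cb, D, E, log = TRUE)
  Bhet <- dbinom(Cb, D, E + f["het"] * (1 - E), log = TRUE)
  Bhom <- dbinom(Cb, D, E + f["hom"] * (1 - E), log = TRUE)
  Dhet <- M3 %*% (Bhet - A)          # n_ind x L' log-likelihood gains
  Dhom <- M3 %*% (Bhom - A)
  n_ind <- nrow(M3)
  lp_het <- log(mu * (1 - p_hom))
  lp_hom <- log(mu * p_hom)
  lp0 <- log(1 - n_ind * mu)
  ih <- max.col(t(Dhet), ties.method = "first")
  io <- max.col(t(Dhom), ties.method = "first")
  vh <- Dhet[cbind(ih, seq_along(idx))]
  vo <- Dhom[cbind(io, seq_along(idx))]
  F_het <- (vh + lp_het - lp0) / log(10)
  F_hom <- (vo + lp_hom - lp0) / log(10)
  het_wins <- F_het >= F_hom        # ties: het before hom
  data.frame(
    col = idx,
    ind_in_set = ifelse(het_wins, ih, io) - 1L,
    zygosity = ifelse(het_wins, "het", "hom"),
    f_score = pmax(F_het, F_hom)
  )
}

#' Call mutations from a pooled pileup
#'
#' Scores every covered position of every target for every alternate base.
#' Per set, the configuration space at a position comprises the null
#' configuration plus one configuration per (individual, zygosity) — at most
#' one mutation per individual per position. Priors are
#' `pi(individual, zyg) = mu_change * P(zyg | mutant)` with `mu_change`
#' splitting the per-base mutation prior according to EMS canonicity (see
#' [caller_config()]), and `pi(null) = 1 - sum(priors)`. The F score of the
#' best non-null configuration is its log10 posterior odds against the null;
#' positions whose best F falls below the low confidence bound return no
#' candidate. Ties between configurations break to the lower individual id,
#' het before hom, so calls are deterministic.
#'
#' @param pileup Parsed pileup data frame covering the references.
#' @param scheme [build_scheme()] result.
#' @param references Named list of [target_reference()] (effect annotation
#'   and ref-base validation), or a named character vector of sequences for
#'   calling without annotation.
#' @param config [caller_config()].
#' @param noise Optional precomputed [estimate_noise()] result.
#' @param annotate Add effect/severity columns (default `TRUE` when
#'   `references` are `target_reference` objects).
#' @return Data frame of candidate mutations sorted by decreasing
#'   `f_score`, with columns `target_id`, `position`, `ref`, `alt`, `set`,
#'   `individual`, `zygosity`, `f_score`, `confidence_class`, `low_depth`
#'   and (if annotated) `effect`, `aa_change`, `severity`, `substitution`,
#'   `canonical`.
#' @export
call_mutations <- function(pileup, scheme, references,
                           config = caller_config(), noise = NULL,
                           annotate = NULL) {
  is_refobj <- is.list(references) &&
    all(vapply(references, inherits, TRUE, "target_reference"))
  seqs <- if (is_refobj)
    vapply(references, `[[`, "", "sequence") else references
  if (is.null(annotate)) annotate <- is_refobj
  validate_pileup(pileup, seqs)
  if (is.null(noise)) noise <- estimate_noise(pileup, scheme, config)
  f <- carrier_fractions(config, scheme)
  pools <- pool_ids(scheme)
  set_of_pool <- parse_pool_id(pools)$set
  cube <- scheme$cube_side^3
  bases <- c("A", "C", "G", "T")
  res <- list()
  for (tg in unique(pileup$target_id)) {
    mats <- pileup_matrices(pileup, tg, pools)
    nm <- noise[[tg]]
    if (is.null(nm)) stop("no noise model for target ", tg)
    stopifnot(identical(nm$positions, mats$positions))
    canonical_alt <- chartr("GC", "AT", mats$ref)  # G>A, C>T partner
    for (st in 0:(scheme$n_sets - 1L)) {
      rows <- set_of_pool == st
      M3 <- set_membership(scheme, st)
      D <- mats$depth[rows, , drop = FALSE]
      for (b in bases) {
        is_gc <- mats$ref %in% c("G", "C")
        mu_change <- ifelse(is_gc,
          ifelse(canonical_alt == b,
                 config$mutation_prior * config$canonical_weight,
                 config$mutation_prior * (1 - config$canonical_weight) / 2),
          config$mutation_prior / 3)
        hits <- score_engine(
          mats[[b]][rows, , drop = FALSE], D, nm$e[, b], mu_change,
          nm$scorable & mats$ref != b, M3, f,
          config$zygosity_prior_hom, config)
        if (is.null(hits)) next
        hits <- hits[hits$f_score >= config$confidence_bounds[1L], ,
                     drop = FALSE]
        if (nrow(hits) == 0L) next
        ind <- as.integer(st * cube + hits$ind_in_set)
        carrier <- pools_of(scheme, ind)
        if (is.null(dim(carrier))) carrier <- matrix(carrier, 1L)
        low_depth <- vapply(seq_len(nrow(hits)), function(k) {
          any(mats$depth[carrier[k, ], hits$col[k]] < config$min_depth)
        }, TRUE)
        res[[length(res) + 1L]] <- data.frame(
          target_id = tg, position = mats$positions[hits$col],
          ref = mats$ref[hits$col], alt = b, set = st, individual = ind,
          zygosity = hits$zygosity, f_score = hits$f_score,
          confidence_class = confidence_class(hits$f_score,
                                              config$confidence_bounds),
          low_depth = low_depth)
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else data.frame(
    target_id = character(0), position = integer(0), ref = character(0),
    alt = character(0), set = integer(0), individual = integer(0),
    zygosity = character(0), f_score = numeric(0),
    confidence_class = character(0), low_depth = logical(0))
  out <- out[order(-out$f_score, out$target_id, out$position, out$alt), ]
  rownames(out) <- NULL
  if (annotate && is_refobj) out <- annotate_candidates(out, references)
  out
}

#' Score a single position
#'
#' Runs the caller's configuration enumeration on one (target, position)
#' slice of a pileup. With `return_posterior = TRUE` the full normalized
#' posterior over all configurations (null plus every individual x zygosity,
#' for each alternate base) is returned, which is what exhaustive
#' enumeration oracles compare against.
#'
#' @param pileup Parsed pileup rows for one target and position (additional
#'   rows are filtered out using `target` / `position`).
#' @param scheme,config,noise As in [call_mutations()]; `noise` may be
#'   omitted, in which case it is estimated from the slice itself.
#' @param target,position Which slice to score (defaults: the unique
#'   target/position present).
#' @param return_posterior Return the posterior table instead of the best
#'   candidate.
#' @return One-row candidate data frame, `NULL` if the best F score falls
#'   below the low confidence bound, or (with `return_posterior`) a data
#'   frame of configurations with a `posterior` column summing to 1 per
#'   alternate base.
#' @export
score_position <- function(pileup, scheme, noise = NULL,
                           config = caller_config(), target = NULL,
                           position = NULL, return_posterior = FALSE) {
  if (is.null(target)) target <- unique(pileup$target_id)
  if (is.null(position)) position <- unique(pileup$position)
  stopifnot(length(target) == 1L, length(position) == 1L)
  slice <- pileup[pileup$target_id == target & pileup$position == position, ]
  if (is.null(noise)) noise <- estimate_noise(slice, scheme, config)
  if (!return_posterior) {
    out <- call_mutations(slice, scheme, references = NULL,
                          config = config, noise = noise, annotate = FALSE)
    return(if (nrow(out)) out[1L, ] else NULL)
  }
  # exhaustive posterior table
  f <- carrier_fractions(config, scheme)
  pools <- pool_ids(scheme)
  mats <- pileup_matrices(slice, target, pools)
  nm <- noise[[target]]
  col <- match(position, nm$positions)
  if (is.na(col) || !nm$scorable[col]) return(NULL)
  ref <- mats$ref[match(position, mats$positions)]
  canonical_alt <- chartr("GC", "AT", ref)
  cube <- scheme$cube_side^3
  out <- list()
  for (b in setdiff(c("A", "C", "G", "T"), ref)) {
    e <- nm$e[col, b]
    if (is.na(e)) next
    mu_change <- if (ref %in% c("G", "C")) {
      if (canonical_alt == b) config$mutation_prior * config$canonical_weight
      else config$mutation_prior * (1 - config$canonical_weight) / 2
    } else config$mutation_prior / 3
    m <- mats[[b]][, match(position, mats$positions)]
    d <- mats$depth[, match(position, mats$positions)]
    for (st in 0:(scheme$n_sets - 1L)) {
      in_set <- parse_pool_id(pools)$set == st
      ms <- m[in_set]; ds <- d[in_set]
      lp <- numeric(0); labs <- list()
      ll0 <- config_log_likelihood(ms, ds, NULL, e)
      lp <- c(lp, log(1 - cube * mu_change) + ll0)
      labs[[1L]] <- data.frame(individual = NA_integer_,
                               zygosity = "null")
      for (i in 0:(cube - 1L)) {
        carriers <- match(pools_of(scheme, st * cube + i),
                          pools[in_set])
        for (z in c("het", "hom")) {
          pz <- if (z == "hom") config$zygosity_prior_hom
                else 1 - config$zygosity_prior_hom
          ll <- config_log_likelihood(ms, ds, carriers, e, f[[z]])
          lp <- c(lp, log(mu_change * pz) + ll)
          labs[[length(labs) + 1L]] <- data.frame(
            individual = st * cube + i, zygosity = z)
        }
      }
      post <- exp(lp - max(lp)); post <- post / sum(post)
      tab <- do.call(rbind, labs)
      tab$alt <- b; tab$set <- st
      tab$log_posterior_weight <- lp
      tab$posterior <- post
      out[[length(out) + 1L]] <- tab
    }
  }
  do.call(rbind, out)
}
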