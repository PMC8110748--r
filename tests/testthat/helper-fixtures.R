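# Shared fixtures: a hand-built two-exon gene (codon walk worked out by
# hand), tiny pooling schemes, pileup builders, and a brute-force posterior
# oracle independent of the package's vectorised scoring path.

# Amplicon layout (45 bp, + strand):
#   1-5    TTGAC        left primer flank
#   6-17   CCAATATGTATG exon 1  (5'UTR CCAAT + ATG TAT G...)
#   18-27  GTAAAAAAAG   intron  (GT ... AG)
#   28-40  ATGCATAAGGTTA exon 2 (...AT GCA TAA + 3'UTR GGTTA)
#   41-45  ACGTC        right primer flank
# Transcript: CCAAT ATG TAT GAT GCA TAA GGTTA; CDS transcript 6..20,
# protein M Y D A *. Codon 2 (TAT, Tyr) sits at amplicon 14-16; codon 3
# (GAT, Asp) spans the splice junction (amplicon 17, 28, 29).
two_exon_reference <- function(strand = "+") {
  seq_fwd <- "TTGACCCAATATGTATGGTAAAAAAAGATGCATAAGGTTAACGTC"
  if (strand == "+") {
    target_reference("toy", seq_fwd,
                     rbind(c(6L, 17L), c(28L, 40L)), 6L, 20L, "+")
  } else {
    L <- nchar(seq_fwd)
    seq_rev <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq_fwd)))
    ex <- rbind(c(L - 40L + 1L, L - 28L + 1L), c(L - 17L + 1L, L - 6L + 1L))
    target_reference("toy", seq_rev, ex, 6L, 20L, "-")
  }
}

# pileup with constant depth and given alt counts for one target/position
# over the pools of a scheme; counts: named list alt base -> vector over
# pools (default 0)
flat_pileup <- function(scheme, target = "t1", position = 1L, ref = "G",
                        depth = 10000L, alt_counts = list()) {
  pools <- pool_ids(scheme)
  n <- length(pools)
  depth <- rep(as.integer(depth), length.out = n)
  cnt <- list(A = integer(n), C = integer(n), G = integer(n), T = integer(n))
  for (b in names(alt_counts))
    cnt[[b]] <- as.integer(rep(alt_counts[[b]], length.out = n))
  cnt[[ref]] <- depth - Reduce(`+`, cnt[setdiff(names(cnt), ref)])
  stopifnot(all(cnt[[ref]] >= 0))
  data.frame(pool_id = pools, target_id = target,
             position = as.integer(position), ref = ref,
             A = cnt$A, C = cnt$C, G = cnt$G, T = cnt$T, depth = depth)
}

# Brute-force posterior over {null} + {(individual, zygosity)} for one set
# and one alternate base, using explicit per-pool binomial pmf products.
oracle_posterior <- function(scheme, set, alt_counts, depths, e, f_het,
                             f_hom, mu_change, p_hom) {
  pools <- pool_ids(scheme)
  in_set <- grepl(paste0("^set", set, "_"), pools)
  ms <- alt_counts[in_set]; ds <- depths[in_set]
  set_pools <- pools[in_set]
  cube <- scheme$cube_side^3
  lik0 <- prod(dbinom(ms, ds, e))
  rows <- data.frame(individual = NA_integer_, zygosity = "null",
                     weight = (1 - cube * mu_change) * lik0)
  for (i in 0:(cube - 1L)) {
    carriers <- pools_of(scheme, set * cube + i)
    cidx <- match(carriers, set_pools)
    for (z in c("het", "hom")) {
      f <- if (z == "het") f_het else f_hom
      pz <- if (z == "het") 1 - p_hom else p_hom
      lik <- 1
      for (j in seq_along(ms)) {
        p <- if (j %in% cidx) e + f * (1 - e) else e
        lik <- lik * dbinom(ms[j], ds[j], p)
      }
      rows <- rbind(rows, data.frame(individual = set * cube + i,
                                     zygosity = z,
                                     weight = mu_change * pz * lik))
    }
  }
  rows$posterior <- rows$weight / sum(rows$weight)
  rows
}
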