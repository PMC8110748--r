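test_that("generated references carry valid translatable gene models", {
  refs <- generate_references(n_targets = 5, seed = 91,
                              rev_strand_prob = 0.5)
  for (r in refs) {
    cds <- substr(r$transcript, r$cds_start, r$cds_end)
    expect_identical(nchar(cds) %% 3L, 0L)
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    aa <- unname(Biostrings::GENETIC_CODE[codons])
    expect_identical(aa[1], "M")
    expect_identical(aa[length(aa)], "*")
    expect_false("*" %in% aa[-length(aa)])   # no internal stops
    # introns between consecutive exons start GT and end AG (gene strand)
    if (nrow(r$exons) > 1) {
      for (k in seq_len(nrow(r$exons) - 1)) {
        intron <- substr(r$sequence, r$exons[k, 2] + 1,
                         r$exons[k + 1, 1] - 1)
        if (r$strand == "-")
          intron <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(intron)))
        expect_identical(substr(intron, 1, 2), "GT")
        expect_identical(substr(intron, nchar(intron) - 1, nchar(intron)),
                         "AG")
      }
    }
  }
  # determinism under a fixed seed
  again <- generate_references(n_targets = 5, seed = 91,
                               rev_strand_prob = 0.5)
  expect_identical(refs, again)
})

test_that("population mutation load is Poisson with the configured spectrum", {
  cfg <- simulation_config(seed = 5, n_individuals = 2048, lambda = 0.548,
                           canonical_bias = 0.9, n_targets = 6)
  set.seed(cfg$seed)
  refs <- generate_references(n_targets = cfg$n_targets)
  truth <- generate_population(cfg, refs)
  per_ind <- tabulate(truth$individual + 1L, nbins = cfg$n_individuals)
  # mean within 3 standard errors of lambda
  se <- sqrt(cfg$lambda / cfg$n_individuals)
  expect_lt(abs(mean(per_ind) - cfg$lambda), 3 * se)
  # canonical fraction within a 99.7% binomial CI of the bias
  canon <- is_canonical_ems(truth$ref, truth$alt)
  ci <- 3 * sqrt(0.9 * 0.1 / nrow(truth))
  expect_lt(abs(mean(canon) - 0.9), ci)
  # zygosity split ~ 1/3 hom
  expect_lt(abs(mean(truth$zygosity == "hom") - 1 / 3),
            3 * sqrt(2 / 9 / nrow(truth)))
  # lambda = 0 -> empty truth table
  cfg0 <- simulation_config(seed = 5, n_individuals = 64, pool_size = 16,
                            lambda = 0)
  expect_identical(nrow(generate_population(cfg0, refs)), 0L)
})

test_that("contaminants receive extra heterozygous variants in range", {
  cfg <- simulation_config(seed = 9, n_individuals = 512,
                           pool_size = 64, lambda = 0.5,
                           n_contaminants = 10, n_targets = 6)
  set.seed(cfg$seed)
  refs <- generate_references(n_targets = cfg$n_targets)
  truth <- generate_population(cfg, refs)
  contam <- attr(truth, "contaminants")
  expect_length(contam, 10L)
  extras <- table(truth$individual[truth$is_contaminant_variant])
  expect_identical(sort(as.integer(names(extras))), as.integer(contam))
  expect_true(all(extras >= 5 & extras <= 10))
  expect_true(all(truth$zygosity[truth$is_contaminant_variant] == "het"))
})

test_that("carrier pools and only carrier pools show elevated alt fractions", {
  sch <- build_scheme(64, 16)
  refs <- generate_references(n_targets = 1, seed = 3,
                              cds_codons_range = c(40, 40),
                              exons_range = c(1, 1))
  r <- refs[[1]]
  pos <- 60L
  ref_base <- substr(r$sequence, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  mk_truth <- function(zyg) data.frame(
    individual = 21L, target_id = r$target_id, position = pos,
    ref = ref_base, alt = alt, zygosity = zyg,
    is_contaminant_variant = FALSE)
  cfg <- simulation_config(seed = 3, n_individuals = 64, pool_size = 16,
                           depth_mean = 20000, depth_dispersion = 50)
  set.seed(101)
  pu_het <- generate_pileup(mk_truth("het"), sch, cfg, refs)
  set.seed(101)
  pu_hom <- generate_pileup(mk_truth("hom"), sch, cfg, refs)
  carrier <- pools_of(sch, 21L)
  for (pu in list(pu_het, pu_hom)) {
    slice <- pu[pu$position == pos, ]
    freq <- slice[[alt]] / slice$depth
    names(freq) <- slice$pool_id
    expect_true(min(freq[carrier]) > max(freq[setdiff(names(freq), carrier)]))
  }
  # homozygous carriers contribute about twice the het allele fraction
  fr <- function(pu) {
    slice <- pu[pu$position == pos, ]
    mean(slice[[alt]][slice$pool_id %in% carrier] /
           slice$depth[slice$pool_id %in% carrier])
  }
  e <- cfg$base_error
  ratio <- (fr(pu_hom) - e) / (fr(pu_het) - e)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.6)
  # no variants and no error -> pure reference table
  cfg0 <- simulation_config(seed = 3, n_individuals = 64, pool_size = 16,
                            base_error = 0)
  pu0 <- generate_pileup(mk_truth("het")[0, ], sch, cfg0, refs)
  m <- as.matrix(pu0[, c("A", "C", "G", "T")])
  expect_true(all(m[cbind(seq_len(nrow(pu0)),
                          match(pu0$ref, c("A", "C", "G", "T")))] ==
                    pu0$depth))
})

test_that("the caller closes the loop on a small simulated screen", {
  cfg <- simulation_config(seed = 21, n_individuals = 64, pool_size = 16,
                           lambda = 0.4, n_targets = 2,
                           depth_mean = 9000, n_contaminants = 0)
  sim <- simulate_screen(cfg)
  calls <- suppressWarnings(
    call_mutations(sim$pileup, sim$scheme, sim$references))
  key <- function(d) paste(d$target_id, d$position, d$alt, d$individual)
  recalled <- key(sim$truth) %in% key(calls)
  expect_gte(mean(recalled), 0.9)
  hit <- merge(sim$truth, calls,
               by.x = c("target_id", "position", "alt", "individual"),
               by.y = c("target_id", "position", "alt", "individual"))
  expect_gte(mean(hit$zygosity.x == hit$zygosity.y), 0.9)
})
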