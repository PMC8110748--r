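sch24 <- build_scheme(512, 64)   # one set, 24 pools
sch6 <- build_scheme(8, 4)       # 2-cube: 8 individuals, 6 pools

test_that("noise is the set-trimmed mean of alt frequencies, floored", {
  cfg <- caller_config()
  # all pools clean -> floor
  pu <- flat_pileup(sch24, ref = "G", depth = 10000)
  nm <- estimate_noise(pu, sch24, cfg)
  expect_equal(unname(nm$t1$e[1, c("A", "C", "T")]), rep(0.001, 3))
  expect_true(is.na(nm$t1$e[1, "G"]))
  # constant frequency 0.004: trimming three pools changes nothing
  pu <- flat_pileup(sch24, ref = "G", depth = 10000,
                    alt_counts = list(A = rep(40L, 24)))
  nm <- estimate_noise(pu, sch24, cfg)
  expect_equal(unname(nm$t1$e[1, "A"]), 0.004)
  # 21 pools at 0.002 + 3 pools at 0.02: the three outliers (a putative
  # carrier triple) are excluded
  pu <- flat_pileup(sch24, ref = "G", depth = 10000,
                    alt_counts = list(A = c(rep(20L, 21), rep(200L, 3))))
  nm <- estimate_noise(pu, sch24, cfg)
  expect_equal(unname(nm$t1$e[1, "A"]), 0.002)
  # fewer than 6 usable pools -> unscorable
  pu <- flat_pileup(sch24, ref = "G", depth = c(rep(10L, 20), rep(5000L, 4)))
  nm <- estimate_noise(pu, sch24, cfg)
  expect_false(nm$t1$scorable[1])
})

test_that("configuration log-likelihood equals the longhand binomial product", {
  ms <- c(3L, 0L, 5L, 1L, 4L, 0L)
  ds <- c(900L, 850L, 1000L, 950L, 870L, 990L)
  e <- 0.002; f <- 0.25
  carriers <- c(1L, 3L, 5L)
  longhand <- 0
  for (j in 1:6) {
    p <- if (j %in% carriers) e + f * (1 - e) else e
    longhand <- longhand + log(choose(ds[j], ms[j]) * p^ms[j] *
                                 (1 - p)^(ds[j] - ms[j]))
  }
  expect_equal(config_log_likelihood(ms, ds, carriers, e, f), longhand,
               tolerance = 1e-12)
  # f = 0 degenerates the carrier configuration to the null
  expect_equal(config_log_likelihood(ms, ds, carriers, e, 0),
               config_log_likelihood(ms, ds, NULL, e))
  expect_error(config_log_likelihood(c(10L), c(5L), NULL, e), "depth")
})

test_that("carrier likelihood advantage grows with the alt count while m/d < f", {
  ds <- rep(2000L, 6)
  e <- 0.001; f <- 1 / 8
  carriers <- c(1L, 3L, 5L)
  rel <- vapply(c(5L, 50L, 150L, 240L), function(m) {
    ms <- integer(6); ms[carriers] <- m
    config_log_likelihood(ms, ds, carriers, e, f) -
      config_log_likelihood(ms, ds, NULL, e)
  }, 0)
  expect_true(all(diff(rel) > 0))
})

test_that("posterior over configurations matches exhaustive enumeration to 1e-9", {
  cfg <- caller_config()
  f <- c(het = 1 / 8, hom = 1 / 4)
  # planted het carrier: individual 5 of the 2-cube
  carrier <- pools_of(sch6, 5L)
  alt <- setNames(rep(8L, 6), pool_ids(sch6))
  alt[carrier] <- 600L
  pu <- flat_pileup(sch6, ref = "G", position = 7L, depth = 5000,
                    alt_counts = list(A = unname(alt)))
  post <- score_position(pu, sch6, config = cfg, return_posterior = TRUE)
  pa <- post[post$alt == "A", ]
  expect_equal(sum(pa$posterior), 1, tolerance = 1e-9)
  nm <- estimate_noise(pu, sch6, cfg)
  oracle <- oracle_posterior(sch6, 0L, alt,
                             setNames(rep(5000L, 6), pool_ids(sch6)),
                             e = nm$t1$e[1, "A"], f_het = f["het"],
                             f_hom = f["hom"],
                             mu_change = cfg$mutation_prior * cfg$canonical_weight,
                             p_hom = cfg$zygosity_prior_hom)
  ord <- order(pa$individual, pa$zygosity, na.last = FALSE)
  oord <- order(oracle$individual, oracle$zygosity, na.last = FALSE)
  expect_equal(pa$posterior[ord], oracle$posterior[oord], tolerance = 1e-9)
  # and the argmax configuration decodes the planted carrier
  best <- score_position(pu, sch6, config = cfg)
  expect_identical(best$individual, 5L)
  expect_identical(best$alt, "A")
})

test_that("null data yields no candidate; strong het signal decodes its carrier", {
  cfg <- caller_config()
  pu <- flat_pileup(sch24, ref = "C", depth = 10000)
  expect_identical(nrow(call_mutations(pu, sch24, references = NULL,
                                       config = cfg)), 0L)
  # het carrier at 64-plex: f = 1/128, expected alt ~ 0.0088 * 10000
  carrier <- pools_of(sch24, 300L)
  alt <- setNames(rep(10L, 24), pool_ids(sch24))
  alt[carrier] <- 88L
  pu <- flat_pileup(sch24, ref = "C", depth = 10000,
                    alt_counts = list(T = unname(alt)))
  best <- score_position(pu, sch24, config = cfg)
  expect_identical(best$individual, 300L)
  expect_identical(best$zygosity, "het")
  expect_gt(best$f_score, 7.69)
  # only 2 of the 3 carrier pools elevated -> weaker call
  alt2 <- alt; alt2[carrier[3L]] <- 10L
  pu2 <- flat_pileup(sch24, ref = "C", depth = 10000,
                     alt_counts = list(T = unname(alt2)))
  best2 <- score_position(pu2, sch24, config = cfg)
  if (!is.null(best2)) expect_lt(best2$f_score, best$f_score)
})

test_that("F grows with carrier alt counts and survives pool relabeling", {
  cfg <- caller_config()
  carrier <- pools_of(sch6, 2L)
  fs <- vapply(c(200L, 300L, 400L, 480L), function(m) {
    alt <- setNames(rep(4L, 6), pool_ids(sch6))
    alt[carrier] <- m
    pu <- flat_pileup(sch6, ref = "G", depth = 4000,
                      alt_counts = list(T = unname(alt)))
    score_position(pu, sch6, config = cfg)$f_score
  }, 0)
  expect_true(all(diff(fs) > 0))
  # shuffling pileup row order never changes the result
  alt <- setNames(rep(4L, 6), pool_ids(sch6))
  alt[carrier] <- 240L
  pu <- flat_pileup(sch6, ref = "G", depth = 4000,
                    alt_counts = list(T = unname(alt)))
  set.seed(7)
  pu_shuffled <- pu[sample(nrow(pu)), ]
  expect_equal(score_position(pu_shuffled, sch6, config = cfg),
               score_position(pu, sch6, config = cfg))
})

test_that("confidence classes split at the screen's bounds", {
  expect_identical(confidence_class(c(1.9, 2, 5, 7.69, 7.7, 146)),
                   c("low", "medium", "medium", "medium", "high", "high"))
})
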