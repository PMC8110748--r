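#' Expected Poisson mutation-count histogram
#'
#' Induced mutations are rare, so the number carried by one individual over
#' the tilled space is well modelled as Poisson with rate
#' `lambda = M / N`. Returns the expected number of individuals carrying
#' exactly `k` mutations for `k = 0..k_max`, with the tail mass beyond
#' `k_max` folded into the last bin so the expectation sums to `N`.
#'
#' @param N Number of individuals.
#' @param M Total number of mutations.
#' @param k_max Largest count bin (default 10).
#' @return Named numeric vector over `k = 0..k_max`.
#' @examples
#' round(poisson_expected(2048, 1123)[["1"]])  # 649 expected singletons
#' @export
poisson_expected <- function(N, M, k_max = 10L) {
  stopifnot(N > 0, M >= 0, k_max >= 1)
  lambda <- M / N
  k <- 0:k_max
  exp_k <- N * dpois(k, lambda)
  exp_k[k_max + 1L] <- N * (1 - ppois(k_max - 1L, lambda))
  setNames(exp_k, k)
}

# chi-square GOF with tail bins pooled (from the right) so that every
# pooled bin has expected count >= min_expected; df = bins - 1 - n_estimated
pooled_chisq <- function(observed, expected, min_expected = 5,
                         n_estimated = 1L) {
  stopifnot(length(observed) == length(expected))
  # pool from the right until the tail bin reaches min_expected
  obs <- observed; exp_ <- expected
  while (length(exp_) > 1L && exp_[length(exp_)] < min_expected) {
    n <- length(exp_)
    exp_[n - 1L] <- exp_[n - 1L] + exp_[n]
    obs[n - 1L] <- obs[n - 1L] + obs[n]
    exp_ <- exp_[-n]; obs <- obs[-n]
  }
  stat <- sum((obs - exp_)^2 / exp_)
  df <- length(exp_) - 1L - n_estimated
  p <- if (df >= 1L) pchisq(stat, df, lower.tail = FALSE) else NA_real_
  list(statistic = stat, df = df, p_value = p,
       observed = obs, expected = exp_)
}

#' Poisson mutation-load test and contamination flagging
#'
#' Compares the observed per-individual mutation-count histogram with the
#' Poisson expectation at `lambda = M / N`. Genetic contaminants (outcrossed
#' or seed-stock-heterogeneous individuals) carry natural polymorphisms on
#' top of induced mutations and show up as an excess of multi-mutation
#' individuals; noise instead distributes across individuals. A chi-square
#' goodness-of-fit test is run with tail bins pooled so every expected cell
#' is at least 5 (one degree of freedom spent on estimating `lambda`), and
#' individuals with more than `load_threshold` mutations are flagged.
#'
#' @param candidates Candidate data frame with an `individual` column (or a
#'   bare integer vector of carrier ids, one entry per mutation).
#' @param scheme [build_scheme()] result (supplies `N`); alternatively a
#'   single integer `N`.
#' @param load_threshold Flag individuals with load strictly above this
#'   (default 3).
#' @return Object of class `poisson_diagnostics`: a list with
#'   `n_individuals`, `total_mutations`, `lambda`, `observed_counts`,
#'   `expected_counts`, `chi_square`, `df`, `p_value`, `singleton_deficit`
#'   (expected minus observed individuals with exactly one mutation) and
#'   `flagged_individuals`.
#' @export
mutation_load_test <- function(candidates, scheme, load_threshold = 3L) {
  ids <- if (is.data.frame(candidates)) candidates$individual else candidates
  N <- if (inherits(scheme, "pooling_scheme")) scheme$n_individuals
       else as.integer(scheme)
  stopifnot(N > 0, all(is.na(ids) | (ids >= 0 & ids < N)))
  ids <- ids[!is.na(ids)]
  M <- length(ids)
  per_ind <- tabulate(ids + 1L, nbins = N)
  k_max <- max(per_ind, 1L)
  observed <- setNames(tabulate(per_ind + 1L, nbins = k_max + 1L), 0:k_max)
  expected <- poisson_expected(N, M, k_max)
  gof <- pooled_chisq(observed, expected)
  flagged <- which(per_ind > load_threshold) - 1L
  structure(
    list(n_individuals = N, total_mutations = M, lambda = M / N,
         observed_counts = observed, expected_counts = expected,
         chi_square = gof$statistic, df = gof$df, p_value = gof$p_value,
         singleton_deficit = unname(expected["1"] - observed["1"]),
         load_threshold = load_threshold,
         flagged_individuals = flagged,
         flagged_load = per_ind[flagged + 1L]),
    class = "poisson_diagnostics")
}

#' @export
print.poisson_diagnostics <- function(x, ...) {
  cat(sprintf(
    "Poisson mutation-load diagnostics: N = %d, M = %d, lambda = %.3f\n",
    x$n_individuals, x$total_mutations, x$lambda))
  cat(sprintf("  chi-square = %.2f (df = %d), p = %.3g\n",
              x$chi_square, x$df, x$p_value))
  cat(sprintf("  singleton deficit (expected - observed) = %.1f\n",
              x$singleton_deficit))
  cat(sprintf("  %d individual(s) flagged with load > %d\n",
              length(x$flagged_individuals), x$load_threshold))
  invisible(x)
}

#' Substitution-spectrum summary
#'
#' Tallies candidates by strand-collapsed substitution class, reports the
#' canonical (G:C>A:T) fraction and the zygosity breakdown. Fractions are
#' kept raw; `percent` gives the integer-rounded presentation.
#'
#' @param candidates Data frame with `ref` and `alt` columns (and optionally
#'   `zygosity`).
#' @return Object of class `spectrum_summary`: list with `counts`,
#'   `fractions`, `percent` (per observed class), `canonical_fraction`,
#'   `n` and `zygosity`.
#' @export
spectrum_summary <- function(candidates) {
  stopifnot(is.data.frame(candidates))
  n <- nrow(candidates)
  if (n == 0L)
    return(structure(list(counts = integer(0), fractions = numeric(0),
                          percent = numeric(0), canonical_fraction = NaN,
                          n = 0L, zygosity = table(character(0))),
                     class = "spectrum_summary"))
  cls <- substitution_class(candidates$ref, candidates$alt)
  counts <- sort(table(cls), decreasing = TRUE)
  fractions <- as.numeric(counts) / n
  names(fractions) <- names(counts)
  zyg <- if ("zygosity" %in% names(candidates))
    table(candidates$zygosity) else table(character(0))
  structure(
    list(counts = counts, fractions = fractions,
         percent = round(100 * fractions),
         canonical_fraction = unname(sum(cls == "GC>AT") / n),
         n = n, zygosity = zyg),
    class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("Substitution spectrum over", x$n, "mutations:\n")
  for (nm in names(x$counts))
    cat(sprintf("  %s: %d (%d%%)\n", nm, x$counts[[nm]], x$percent[[nm]]))
  cat(sprintf("  canonical EMS fraction: %.3f\n", x$canonical_fraction))
  if (length(x$zygosity))
    cat("  zygosity:", paste(names(x$zygosity), as.integer(x$zygosity),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Validation outcomes per F-score bin
#'
#' Given candidates with truth labels (from simulation or Sanger-style
#' validation) tallies true and false calls per confidence bin. The default
#' bin edges are the low/high confidence bounds and the empirically
#' validated threshold above which no false positives were observed.
#'
#' @param f_scores Numeric F scores.
#' @param is_true Logical truth labels, same length.
#' @param bounds Increasing bin edges (default `c(2, 7.69, 19.1)`).
#' @return Data frame with one row per bin: `bin`, `n`, `n_true`,
#'   `n_false`, `true_fraction`.
#' @export
validation_curve <- function(f_scores, is_true, bounds = c(2, 7.69, 19.1)) {
  stopifnot(length(f_scores) == length(is_true),
            !is.unsorted(bounds, strictly = TRUE))
  edges <- c(-Inf, bounds, Inf)
  labels <- character(length(edges) - 1L)
  labels[1L] <- sprintf("F < %g", bounds[1L])
  labels[length(labels)] <- sprintf("F > %g", bounds[length(bounds)])
  if (length(bounds) > 1L)
    for (i in seq_len(length(bounds) - 1L))
      labels[i + 1L] <- sprintf("%g <= F <= %g", bounds[i], bounds[i + 1L])
  if (length(f_scores) == 0L)
    return(data.frame(bin = character(0), n = integer(0),
                      n_true = integer(0), n_false = integer(0),
                      true_fraction = numeric(0)))
  bin <- cut(f_scores, edges, labels = labels, right = TRUE)
  tab <- data.frame(
    bin = labels,
    n = as.integer(table(bin)[labels]),
    n_true = as.integer(tapply(is_true, bin, sum, default = 0L)[labels]),
    row.names = NULL)
  tab$n_true[is.na(tab$n_true)] <- 0L
  tab$n_false <- tab$n - tab$n_true
  tab$true_fraction <- ifelse(tab$n > 0, tab$n_true / tab$n, NaN)
  tab
}

#' Correlation between tilled length and mutation count
#'
#' Longer tilled fragments accumulate proportionally more induced mutations;
#' a weak correlation indicates per-fragment artefacts. Standard Pearson
#' product-moment correlation with a two-sided t-test.
#'
#' @param lengths Tilled sequence lengths (bp) per fragment.
#' @param counts Mutation counts per fragment.
#' @return List with `r`, `p_value`, `n`.
#' @export
length_correlation <- function(lengths, counts) {
  stopifnot(length(lengths) == length(counts))
  if (length(lengths) < 3L)
    stop("need at least 3 fragments")
  if (stats::sd(lengths) == 0 || stats::sd(counts) == 0)
    stop("correlation undefined: zero variance in lengths or counts")
  ct <- cor.test(lengths, counts, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(lengths))
}

#' JSON diagnostics report
#'
#' Bundles [mutation_load_test()] and [spectrum_summary()] results into one
#' list and optionally writes it as JSON (the `diagnose` subcommand's
#' report).
#'
#' @param candidates Candidate data frame.
#' @param scheme [build_scheme()] result.
#' @param load_threshold Passed to [mutation_load_test()].
#' @param path Optional JSON output path.
#' @return The report list, invisibly if written.
#' @export
diagnostics_report <- function(candidates, scheme, load_threshold = 3L,
                               path = NULL) {
  load <- mutation_load_test(candidates, scheme, load_threshold)
  spec <- spectrum_summary(candidates)
  rep <- list(
    n_individuals = load$n_individuals,
    total_mutations = load$total_mutations,
    lambda = load$lambda,
    observed_counts = as.list(load$observed_counts),
    expected_counts = as.list(load$expected_counts),
    chi_square = load$chi_square, df = load$df, p_value = load$p_value,
    singleton_deficit = load$singleton_deficit,
    flagged_individuals = as.integer(load$flagged_individuals),
    spectrum_counts = as.list(spec$counts),
    spectrum_fractions = as.list(spec$fractions),
    canonical_fraction = spec$canonical_fraction,
    zygosity = as.list(spec$zygosity))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
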