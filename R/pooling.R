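#' Construct a tridimensional pooling scheme
#'
#' Arranges `n_individuals` into sets of `s^3` individuals (where
#' `s = sqrt(pool_size)` is the cube side) and assigns each individual of a
#' set to one row, one column and one dimension pool of an `s x s x s` cube.
#' Every pool then contains exactly `s^2` individuals, every individual sits
#' in exactly three pools, and within a set the intersection of one row, one
#' column and one dimension pool is a single individual, which is what makes
#' single-carrier deconvolution possible. A screen of 2048 individuals pooled
#' 64-plex yields 4 sets of 512 and 96 pools in total.
#'
#' The cube is filled row-major and deterministically: individual `k` of a set
#' maps to `row = k %/% s^2`, `column = (k %/% s) %% s`,
#' `dimension = k %% s`. Real populations with a different bench layout can be
#' ingested through a scheme file instead ([read_scheme()]).
#'
#' @param n_individuals Total number of individuals. Must be an exact
#'   multiple of `pool_size^(3/2)` (the cube volume).
#' @param pool_size Individuals per pool; must be a perfect square.
#' @return An object of class `pooling_scheme`: a list with elements
#'   `n_individuals`, `cube_side`, `pool_size`, `n_sets` and `assignment`
#'   (a data frame with columns `individual`, `set`, `row`, `column`,
#'   `dimension`, all 0-based).
#' @examples
#' sch <- build_scheme(512, 64)
#' length(pool_ids(sch))   # 24 pools: 8 rows + 8 columns + 8 dimensions
#' pools_of(sch, 0)
#' @export
build_scheme <- function(n_individuals, pool_size) {
  if (length(pool_size) != 1L || pool_size < 4 || pool_size != round(pool_size))
    stop("pool_size must be a single integer >= 4, got ", pool_size)
  s <- as.integer(round(sqrt(pool_size)))
  if (s * s != pool_size)
    stop("pool_size must be a perfect square, got ", pool_size)
  cube <- s * s * s
  if (length(n_individuals) != 1L || n_individuals < cube ||
      n_individuals != round(n_individuals) || n_individuals %% cube != 0)
    stop("n_individuals must be a positive multiple of pool_size^(3/2) = ",
         cube, ", got ", n_individuals)
  n_individuals <- as.integer(n_individuals)
  n_sets <- n_individuals %/% cube
  ind <- 0:(n_individuals - 1L)
  k <- ind %% cube
  assignment <- data.frame(
    individual = ind,
    set = ind %/% cube,
    row = k %/% (s * s),
    column = (k %/% s) %% s,
    dimension = k %% s
  )
  structure(
    list(n_individuals = n_individuals, cube_side = s,
         pool_size = as.integer(pool_size), n_sets = n_sets,
         assignment = assignment),
    class = "pooling_scheme"
  )
}

#' @export
print.pooling_scheme <- function(x, ...) {
  cat(sprintf(
    "Tridimensional pooling scheme: %d individuals, %d set(s) of %d,\n  cube side %d, %d pools of %d individuals (3 pools per individual)\n",
    x$n_individuals, x$n_sets, x$cube_side^3, x$cube_side,
    3L * x$cube_side * x$n_sets, x$pool_size))
  invisible(x)
}

pool_id <- function(set, axis, index) sprintf("set%d_%s%d", set, axis, index)

parse_pool_id <- function(id) {
  m <- regmatches(id, regexec("^set([0-9]+)_([RCD])([0-9]+)$", id))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed pool id: ", paste(id[bad], collapse = ", "))
  data.frame(
    set = as.integer(vapply(m, `[`, "", 2L)),
    axis = vapply(m, `[`, "", 3L),
    index = as.integer(vapply(m, `[`, "", 4L))
  )
}

#' All pool identifiers of a scheme
#'
#' Pool ids are strings `"set{t}_{axis}{i}"` with axis `R` (row), `C`
#' (column) or `D` (dimension), e.g. `"set0_R3"`. They are stable across
#' runs and human-readable in output files.
#'
#' @param scheme A [build_scheme()] result.
#' @return Character vector of `3 * cube_side * n_sets` pool ids, grouped by
#'   set and axis.
#' @export
pool_ids <- function(scheme) {
  stopifnot(inherits(scheme, "pooling_scheme"))
  s <- scheme$cube_side
  unlist(lapply(0:(scheme$n_sets - 1L), function(t)
    c(pool_id(t, "R", 0:(s - 1L)),
      pool_id(t, "C", 0:(s - 1L)),
      pool_id(t, "D", 0:(s - 1L)))))
}

#' Pools containing an individual
#'
#' @param scheme A [build_scheme()] result.
#' @param individual 0-based individual id (scalar or vector).
#' @return For a scalar id, a named character vector of the three pool ids
#'   (`row`, `column`, `dimension`); for a vector, a 3-column character
#'   matrix with one row per individual.
#' @export
pools_of <- function(scheme, individual) {
  stopifnot(inherits(scheme, "pooling_scheme"))
  if (any(individual < 0 | individual >= scheme$n_individuals |
          individual != round(individual)))
    stop("individual id out of range [0, ", scheme$n_individuals - 1L, "]")
  a <- scheme$assignment[individual + 1L, ]
  out <- cbind(row = pool_id(a$set, "R", a$row),
               column = pool_id(a$set, "C", a$column),
               dimension = pool_id(a$set, "D", a$dimension))
  if (length(individual) == 1L) out[1L, ] else out
}

#' Deconvolve a pool triple to its unique individual
#'
#' Inverse of [pools_of()]: given one row, one column and one dimension pool
#' of the same set, returns the single individual at their intersection.
#'
#' @param scheme A [build_scheme()] result.
#' @param row,column,dimension Pool ids (one per axis, same set).
#' @return 0-based individual id.
#' @export
individual_of <- function(scheme, row, column, dimension) {
  stopifnot(inherits(scheme, "pooling_scheme"))
  p <- parse_pool_id(c(row, column, dimension))
  if (length(unique(p$set)) != 1L)
    stop("pools belong to different sets: ", paste(c(row, column, dimension), collapse = ", "))
  if (!identical(p$axis, c("R", "C", "D")))
    stop("expected one pool per axis in order row, column, dimension; got axes ",
         paste(p$axis, collapse = ", "))
  if (p$set[1L] >= scheme$n_sets || any(p$index >= scheme$cube_side))
    stop("pool index out of range for this scheme")
  s <- scheme$cube_side
  p$set[1L] * s * s * s + p$index[1L] * s * s + p$index[2L] * s + p$index[3L]
}

#' Write / read a pooling scheme file
#'
#' Plain TSV with header `individual set row column dimension` and 0-based
#' indices; writing then reading is byte-identical. This is also the format
#' for ingesting an externally designed pooling layout.
#'
#' @param scheme A [build_scheme()] result.
#' @param path File path.
#' @return `write_scheme()` returns `path` invisibly; `read_scheme()`
#'   returns a `pooling_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "pooling_scheme"))
  write.table(scheme$assignment, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  tab <- read.delim(path, colClasses = "integer")
  expected <- c("individual", "set", "row", "column", "dimension")
  if (!identical(names(tab), expected))
    stop("scheme file must have columns ", paste(expected, collapse = ", "))
  n <- nrow(tab)
  if (n == 0L) stop("empty scheme file: ", path)
  s <- max(tab$row, tab$column, tab$dimension) + 1L
  sch <- build_scheme(n, s * s)
  tab <- tab[order(tab$individual), ]
  rownames(tab) <- NULL
  # accept any bijection consistent with the invariants, not just the
  # row-major default
  key <- with(tab, paste(set, row, column, dimension))
  if (anyDuplicated(key) || any(tab$individual != 0:(n - 1L)))
    stop("scheme file is not a bijection between individuals and cube cells")
  sch$assignment <- tab
  sch
}

# n_ind x n_pools 0/1 membership matrix for one set, columns in the order of
# the set's pool ids (R0..R{s-1}, C0.., D0..); used by the caller's
# vectorised likelihood updates.
set_membership <- function(scheme, set) {
  s <- scheme$cube_side
  a <- scheme$assignment[scheme$assignment$set == set, ]
  a <- a[order(a$individual), ]
  n <- nrow(a)
  M <- matrix(0, n, 3L * s)
  M[cbind(seq_len(n), a$row + 1L)] <- 1
  M[cbind(seq_len(n), s + a$column + 1L)] <- 1
  M[cbind(seq_len(n), 2L * s + a$dimension + 1L)] <- 1
  rownames(M) <- a$individual
  colnames(M) <- c(pool_id(set, "R", 0:(s - 1L)),
                   pool_id(set, "C", 0:(s - 1L)),
                   pool_id(set, "D", 0:(s - 1L)))
  M
}
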