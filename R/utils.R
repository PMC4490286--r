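#' @keywords internal
"_PACKAGE"

# Validation helpers ---------------------------------------------------------

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_in <- function(x, field, lo, hi, lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a finite numeric scalar")
  lo_ok <- if (lo_open) x > lo else x >= lo
  hi_ok <- if (hi_open) x < hi else x <= hi
  if (!lo_ok || !hi_ok)
    stop_field(field, sprintf("must lie in %s%g, %g%s",
                              if (lo_open) "(" else "[", lo, hi,
                              if (hi_open) ")" else "]"))
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop_field(field, sprintf("must be an integer >= %d", min))
  as.integer(x)
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fan a master seed out to reproducible child seeds
#'
#' All stochastic stages take an explicit seed; a single master seed is
#' expanded into per-stage child seeds so that stages are individually
#' reproducible and mutually independent.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
fan_seeds <- function(master, n) {
  master <- check_count(master, "master", min = 0L)
  n <- check_count(n, "n")
  with_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

# Column-wise Pearson correlation between two matrices (na-free inputs)
colcor <- function(A, B) stats::cor(A, B)

# Standardize columns to zero mean / unit sd (sd 0 -> zero column)
zstd_cols <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
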