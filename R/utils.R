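# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

.assertNonneg <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0) {
    stop(sprintf("'%s' must be a single nonnegative number", name),
         call. = FALSE)
  }
  as.numeric(x)
}

.assertRange <- function(x, name) {
  if (length(x) != 2L || !is.numeric(x) || any(is.na(x)) || x[1] > x[2]) {
    stop(sprintf("'%s' must be a numeric interval c(lo, hi)", name),
         call. = FALSE)
  }
  as.numeric(x)
}

# Largest-remainder apportionment of `r` blocks over category counts.
.apportion <- function(r, counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("no genes to apportion blocks over")
  if (r < length(counts)) {
    stop("planted rank smaller than the number of gene categories")
  }
  quota <- r * counts / sum(counts)
  base <- floor(quota)
  base[base < 1] <- 1
  while (sum(base) > r) {
    i <- which.max(base - quota)
    base[i] <- base[i] - 1L
  }
  rem <- quota - base
  while (sum(base) < r) {
    i <- which.max(rem)
    base[i] <- base[i] + 1L
    rem[i] <- -Inf
  }
  stats::setNames(as.integer(base), names(base))
}

.msg <- function(...) message("[MetageneNMF] ", sprintf(...))

# sample() without the scalar-x surprise: always samples from the vector x
.resample <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}
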