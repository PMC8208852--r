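#' @importFrom rlang %||% abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join row_number n
#' @importFrom purrr map map_dbl map_int map_lgl map_chr map2
#' @importFrom stats setNames runif
NULL

# The 26 neighbourhood offsets (Moore neighbourhood) as a 26 x 3 integer matrix.
nb26 <- function() {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  storage.mode(g) <- "integer"
  dimnames(g) <- NULL
  g
}

# Linear index from 1-based (i, j, k) coordinates given a dim vector.
lin_index <- function(coords, shape) {
  coords <- matrix(as.integer(coords), ncol = 3)
  coords[, 1L] + (coords[, 2L] - 1L) * shape[1L] +
    (coords[, 3L] - 1L) * shape[1L] * shape[2L]
}

# Squared Euclidean distance between two coordinate vectors.
sqdist <- function(a, b) sum((a - b)^2)

# Pairwise Euclidean distances between rows of two coordinate matrices,
# optionally anisotropic (per-axis spacing).
cross_dist <- function(a, b, spacing = c(1, 1, 1)) {
  a <- sweep(matrix(a, ncol = 3), 2L, spacing, `*`)
  b <- sweep(matrix(b, ncol = 3), 2L, spacing, `*`)
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) abort("cannot normalize a zero-length vector")
  v / n
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    abort(sprintf("`%s` must be a single non-negative integer", name))
}
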