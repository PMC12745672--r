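# geometry + seed helpers. Domain is the unit torus [0,1) x [0,1).

#' Wrap coordinates onto the unit torus
#' @param x numeric vector.
#' @return values reduced modulo 1 into [0, 1).
#' @export
wrap01 <- function(x) x - floor(x)

#' Toroidal distance between points on the unit square
#'
#' @param x1,y1,x2,y2 coordinates (recycled).
#' @return Euclidean distance with periodic boundaries; maximum possible
#'   value is `sqrt(0.5)`.
#' @export
torus_dist <- function(x1, y1, x2, y2) {
  dx <- abs(x1 - x2); dx <- pmin(dx, 1 - dx)
  dy <- abs(y1 - y2); dy <- pmin(dy, 1 - dy)
  sqrt(dx^2 + dy^2)
}

#' All pairwise toroidal distances
#' @param x,y coordinate vectors of equal length n.
#' @return n x n symmetric matrix of toroidal distances.
#' @export
torus_dist_matrix <- function(x, y) {
  n <- length(x)
  dx <- abs(outer(x, x, "-")); dx <- pmin(dx, 1 - dx)
  dy <- abs(outer(y, y, "-")); dy <- pmin(dy, 1 - dy)
  matrix(sqrt(dx^2 + dy^2), n, n)
}

#' Expand a master seed into a stream of sub-seeds
#'
#' Counter-based: sub-seed k is a deterministic function of (master, k), so
#' replicate r always receives the same seed regardless of how many other
#' replicates are drawn. Values stay below 2^31.
#'
#' @param master integer master seed.
#' @param n number of sub-seeds.
#' @param offset skip this many counters first (for batched estimation).
#' @return integer vector of length `n`.
#' @export
expand_seeds <- function(master, n, offset = 0L) {
  stopifnot(n >= 0)
  if (n == 0) return(integer(0))
  k <- (offset + seq_len(n)) * 1.0
  # splitmix-style integer hash done in double precision (exact below 2^53)
  h <- (master %% 2147483647) * 2654435.0 + k * 40503.0 + k * k * 97.0
  as.integer(h %% 2147483629) + 1L
}

# grid cell index (row-major over a G x G grid), 1-based
grid_cell <- function(x, y, G) {
  cx <- pmin(floor(x * G), G - 1)
  cy <- pmin(floor(y * G), G - 1)
  as.integer(cy * G + cx + 1)
}
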