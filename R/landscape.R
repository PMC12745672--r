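# Landscapes: spatial intensity of resource-particle production on the unit
# torus, in three flavours used throughout:
#   homogeneous   - every resource type produced uniformly everywhere
#   heterogeneous - circular habitat patches differing in WHICH types they
#                   produce, over a weak uniform background (habitable
#                   everywhere, i.e. a continuous landscape)
#   patchy        - discrete habitat patches producing ALL types; the matrix
#                   between patches is unhabitable (zero production)

#' Construct a landscape
#'
#' @param kind one of `"homogeneous"`, `"heterogeneous"`, `"patchy"`.
#' @param n_types number of resource types.
#' @param total_rate total production rate over the whole domain per unit
#'   time, summed over types. Kept comparable across kinds so scenarios
#'   support similar consumer abundances.
#' @param n_patches number of circular patches (ignored for homogeneous).
#' @param patch_radius patch radius; patches must fit in the unit square.
#' @param background fraction of `total_rate` produced uniformly everywhere
#'   in the heterogeneous landscape (keeps it habitable between patches).
#' @param seed integer; patch centres and per-patch type weights are drawn
#'   deterministically from it.
#' @return an object of class `landscape` with fields `kind`, `n_types`,
#'   `base_rates` (uniform per-type rates) and `patches` (data frame of
#'   centres/radii plus a `weights` matrix of per-type rates per patch).
#' @export
make_landscape <- function(kind = c("homogeneous", "heterogeneous", "patchy"),
                           n_types = 4L, total_rate = 300,
                           n_patches = 9L, patch_radius = 0.11,
                           background = 0.05, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_types >= 1, total_rate > 0)
  ls <- list(kind = kind, n_types = as.integer(n_types),
             total_rate = total_rate,
             base_rates = numeric(n_types),
             patches = NULL, weights = NULL, seed = as.integer(seed))
  if (kind == "homogeneous") {
    ls$base_rates <- rep(total_rate / n_types, n_types)
  } else {
    stopifnot(n_patches >= 1)
    if (2 * patch_radius >= 1)
      stop("patches of radius ", patch_radius, " do not fit the unit domain")
    old <- .Random.seed_guard(seed)
    on.exit(old(), add = TRUE)
    # jittered grid of centres: regular enough to tile the domain, irregular
    # enough not to align with the space-use grid
    g <- ceiling(sqrt(n_patches))
    cx <- (rep(seq_len(g), length.out = n_patches) - 0.5) / g
    cy <- (rep(seq_len(g), each = g)[seq_len(n_patches)] - 0.5) / g
    jit <- 0.25 / g
    cx <- wrap01(cx + runif(n_patches, -jit, jit))
    cy <- wrap01(cy + runif(n_patches, -jit, jit))
    ls$patches <- data.frame(cx = cx, cy = cy, radius = patch_radius)
    if (kind == "patchy") {
      # every patch produces every type in equal amounts; no background
      w <- matrix(total_rate / (n_patches * n_types), n_patches, n_types)
    } else {
      # each patch concentrates on 2 of the n_types; background keeps all
      # of the domain habitable
      bg <- background * total_rate
      ls$base_rates <- rep(bg / n_types, n_types)
      w <- matrix(0, n_patches, n_types)
      per_patch <- (total_rate - bg) / n_patches
      for (p in seq_len(n_patches)) {
        pick <- sample.int(n_types, 2L)
        w[p, pick] <- per_patch / 2
      }
    }
    ls$weights <- w
  }
  class(ls) <- "landscape"
  ls
}

# deterministic local RNG scope: returns a restore function
.Random.seed_guard <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  }
}

#' Production intensity at given locations
#'
#' @param landscape a [make_landscape()] object.
#' @param x,y coordinates.
#' @param rtype resource type index.
#' @return intensity (rate per unit area per unit time), vectorised over
#'   `x`/`y`.
#' @export
production_intensity <- function(landscape, x, y, rtype) {
  stopifnot(inherits(landscape, "landscape"),
            rtype >= 1, rtype <= landscape$n_types)
  out <- rep(landscape$base_rates[rtype], length(x))
  p <- landscape$patches
  if (!is.null(p)) {
    for (i in seq_len(nrow(p))) {
      inside <- torus_dist(x, y, p$cx[i], p$cy[i]) < p$radius[i]
      # per-patch rate is total over the patch; convert to per-area
      out[inside] <- out[inside] +
        landscape$weights[i, rtype] / (pi * p$radius[i]^2)
    }
  }
  out
}

# component table handed to the C++ engine: one Poisson stream per
# (uniform background type) and per (patch, type) with positive weight.
# columns: type, rate, cx, cy, radius, uniform
landscape_components <- function(landscape) {
  rows <- list()
  for (ty in seq_len(landscape$n_types)) {
    if (landscape$base_rates[ty] > 0)
      rows[[length(rows) + 1L]] <-
        c(ty, landscape$base_rates[ty], 0, 0, 0, 1)
  }
  p <- landscape$patches
  if (!is.null(p)) {
    for (i in seq_len(nrow(p))) for (ty in seq_len(landscape$n_types)) {
      w <- landscape$weights[i, ty]
      if (w > 0)
        rows[[length(rows) + 1L]] <-
          c(ty, w, p$cx[i], p$cy[i], p$radius[i], 0)
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- c("type", "rate", "cx", "cy", "radius", "uniform")
  m
}

#' Sample the resource-production point process directly
#'
#' Draws the space-time stream of resource particles a landscape would
#' produce over a time horizon, independently of any consumers. Counts in
#' any region and window are Poisson with mean intensity x area x time.
#'
#' @param landscape a [make_landscape()] object.
#' @param horizon duration (> 0).
#' @param seed integer seed.
#' @return data frame with columns `id`, `rtype`, `x`, `y`, `created_at`,
#'   `consumed_by`, `consumed_at` (the latter two `NA`), ordered by time.
#' @export
sample_resource_events <- function(landscape, horizon, seed = 1L) {
  stopifnot(horizon > 0)
  comps <- landscape_components(landscape)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  out <- list()
  for (k in seq_len(nrow(comps))) {
    n <- rpois(1, comps[k, "rate"] * horizon)
    if (n == 0) next
    if (comps[k, "uniform"] > 0.5) {
      x <- runif(n); y <- runif(n)
    } else {
      r <- comps[k, "radius"] * sqrt(runif(n))
      th <- 2 * pi * runif(n)
      x <- wrap01(comps[k, "cx"] + r * cos(th))
      y <- wrap01(comps[k, "cy"] + r * sin(th))
    }
    out[[length(out) + 1L]] <- data.frame(
      rtype = as.integer(comps[k, "type"]), x = x, y = y,
      created_at = runif(n, 0, horizon))
  }
  if (length(out) == 0) {
    return(data.frame(id = integer(0), rtype = integer(0), x = numeric(0),
                      y = numeric(0), created_at = numeric(0),
                      consumed_by = integer(0), consumed_at = numeric(0)))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$created_at), , drop = FALSE]
  df <- data.frame(id = seq_len(nrow(df)), df,
                   consumed_by = NA_integer_, consumed_at = NA_real_)
  rownames(df) <- NULL
  df
}

#' Default consumer niche matrix
#'
#' Eight consumer species over four resource types, each species using two
#' adjacent types on a ring and each ring position duplicated, so species
#' pairs of all three overlap classes (none / partial / complete) exist.
#'
#' @param n_species,n_types dimensions; `n_species` rows cycle over
#'   consecutive type pairs.
#' @return binary matrix (species x types) with at least one usable type per
#'   species.
#' @export
default_niche <- function(n_species = 8L, n_types = 4L) {
  u <- matrix(0L, n_species, n_types)
  for (s in seq_len(n_species)) {
    a <- (s - 1L) %% n_types + 1L
    b <- s %% n_types + 1L
    u[s, c(a, b)] <- 1L
  }
  rownames(u) <- paste0("sp", seq_len(n_species))
  colnames(u) <- paste0("rt", seq_len(n_types))
  u
}

#' Niche-overlap class of a species pair
#'
#' @param sp_i,sp_j species indices or row names.
#' @param niche binary usage matrix (species x resource types).
#' @return `"none"` (disjoint usable types), `"complete"` (identical rows) or
#'   `"partial"`.
#' @export
niche_overlap_class <- function(sp_i, sp_j, niche) {
  for (s in list(sp_i, sp_j)) {
    ok <- if (is.character(s)) s %in% rownames(niche)
          else s >= 1 && s <= nrow(niche)
    if (!ok) stop("unknown species: ", s)
  }
  a <- niche[sp_i, ] > 0
  b <- niche[sp_j, ] > 0
  if (!any(a & b)) "none"
  else if (all(a == b)) "complete"
  else "partial"
}
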