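# Demographic rate model for the agent-based engine. All rates are per
# individual per unit time unless noted; lengths are in domain units (the
# domain is the unit torus).

#' Construct the demographic rate model
#'
#' Consumers move by wrapped-Gaussian steps, die at a base rate, consume
#' in-range usable resource particles at a contact rate, and each
#' consumption triggers a birth with a fixed probability (offspring placed
#' by the same Gaussian kernel). Parasites live on consumer hosts, raise
#' host mortality by `delta`, and transmit to in-range susceptible hosts of
#' species in their host range; a transmission creates a new parasite
#' individual in the recipient host.
#'
#' @param niche binary consumer usage matrix (species x resource types),
#'   see [default_niche()].
#' @param dispersal `"short"`, `"long"` or `"mixed"` (first half of the
#'   species short, second half long).
#' @param sigma_short,sigma_long Gaussian step scales for the two regimes.
#' @param m movement rate; `d` base death rate; `r_c` consumption radius;
#'   `b` per-consumption birth probability. Scalars are recycled over
#'   species; vectors allow per-species values.
#' @param contact consumption contact rate per (consumer, in-range usable
#'   particle) pair. Large by default, so encounters are usually realised.
#' @param tau_R mean resource-particle lifetime if unconsumed (expiry keeps
#'   resources limiting).
#' @param parasites logical; include the host-parasite layer?
#' @param n_parasite_species number of parasite species.
#' @param host_range binary matrix (parasite species x consumer species); by
#'   default each parasite species uses a sliding window of `host_breadth`
#'   host species, offset so that neighbouring parasite species partially
#'   share hosts.
#' @param host_breadth host species per parasite species for the default
#'   sliding-window host ranges.
#' @param par_d parasite death rate; `beta` transmission rate per in-range
#'   susceptible host; `r_t` transmission radius; `delta` host-mortality
#'   increment while infected.
#' @return object of class `rate_model`.
#' @export
default_rates <- function(niche = default_niche(),
                          dispersal = c("short", "long", "mixed"),
                          sigma_short = 0.03, sigma_long = 0.3,
                          m = 1, d = 0.5, r_c = 0.035, b = 0.5,
                          contact = 50, tau_R = 1,
                          parasites = FALSE, n_parasite_species = 4L,
                          host_range = NULL, host_breadth = 3L,
                          par_d = 0.3, beta = 1, r_t = 0.1, delta = 0.25) {
  dispersal <- match.arg(dispersal)
  S <- nrow(niche)
  stopifnot(all(rowSums(niche) >= 1))
  sigma <- switch(dispersal,
    short = rep(sigma_short, S),
    long  = rep(sigma_long, S),
    mixed = c(rep(sigma_short, ceiling(S / 2)),
              rep(sigma_long, floor(S / 2))))
  rm_ <- list(
    usage = matrix(as.integer(niche), nrow(niche), ncol(niche)),
    niche = niche,
    dispersal = dispersal,
    m = rep_len(m, S), sigma = sigma, d = rep_len(d, S),
    r_c = rep_len(r_c, S), b = rep_len(b, S),
    contact = contact, tau_R = tau_R,
    parasites = parasites)
  if (parasites) {
    Sp <- as.integer(n_parasite_species)
    if (is.null(host_range)) {
      host_range <- matrix(0L, Sp, S)
      width <- min(S, max(1L, as.integer(host_breadth)))
      for (p in seq_len(Sp)) {
        start <- ((p - 1L) * S) %/% Sp
        host_range[p, (start + seq_len(width) - 1L) %% S + 1L] <- 1L
      }
    }
    stopifnot(ncol(host_range) == S, all(rowSums(host_range) >= 1))
    rm_$host_range <- host_range
    rm_$par_d <- rep_len(par_d, Sp)
    rm_$par_beta <- rep_len(beta, Sp)
    rm_$par_rt <- rep_len(r_t, Sp)
    rm_$par_delta <- rep_len(delta, Sp)
  } else {
    rm_$host_range <- matrix(0L, 0, S)
    rm_$par_d <- numeric(0); rm_$par_beta <- numeric(0)
    rm_$par_rt <- numeric(0); rm_$par_delta <- numeric(0)
  }
  stopifnot(all(rm_$m >= 0), all(rm_$d >= 0), all(rm_$b >= 0 & rm_$b <= 1),
            contact >= 0, tau_R > 0, all(rm_$par_delta > 0))
  class(rm_) <- "rate_model"
  rm_
}

#' Bundle a landscape and a rate model into a simulation configuration
#' @param landscape a [make_landscape()] object.
#' @param rates a [default_rates()] object.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(landscape, rates) {
  stopifnot(inherits(landscape, "landscape"), inherits(rates, "rate_model"))
  structure(list(landscape = landscape, rates = rates,
                 comps = landscape_components(landscape)),
            class = "sim_config")
}
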