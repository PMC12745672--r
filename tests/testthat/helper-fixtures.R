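# shared builders for small deterministic test systems

# snapshot with the given consumer positions (one species by default),
# no resource particles
toy_snapshot <- function(x, y, species = 1L, guild = 0L,
                         host_id = NA_integer_, time = 0) {
  n <- length(x)
  ind <- data.frame(id = seq_len(n), species = rep_len(species, n),
                    guild = rep_len(guild, n), x = x, y = y,
                    host_id = rep_len(host_id, n), born_at = time)
  snapshot(time, ind,
           data.frame(pid = integer(0), prtype = integer(0),
                      px = numeric(0), py = numeric(0),
                      pcreated = numeric(0)),
           next_id = n + 1L, next_pid = 1L)
}

# landscape with (numerically) no production, for configs where only
# individual-level events should happen
dead_landscape <- function() {
  make_landscape("homogeneous", n_types = 2L, total_rate = 1e-9)
}

# niche for tiny systems: two species sharing type 1, species 3 disjoint
tiny_niche <- function() {
  u <- matrix(c(1L, 0L,
                1L, 0L,
                0L, 1L), 3, 2, byrow = TRUE)
  rownames(u) <- paste0("sp", 1:3)
  colnames(u) <- paste0("rt", 1:2)
  u
}

# rate model where nothing happens unless switched on
inert_rates <- function(niche = tiny_niche(), ...) {
  args <- list(niche = niche, dispersal = "short", m = 0, d = 0,
               r_c = 0, b = 0, contact = 0, tau_R = 1)
  over <- list(...)
  args[names(over)] <- over
  do.call(default_rates, args)
}
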