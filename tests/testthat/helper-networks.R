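# Fixture builders shared by the test files.  Everything is generated
# in code; no stored fixtures.

# A hand-built two-source, one-receptor network with controlled
# characterisation.  `x_cost` = 0 silences the logistics term so cost
# index values can be computed by hand.
tiny_network <- function(bounds = constraint_bounds(),
                         params = objective_params(quantum = 1000),
                         x_cost = 0) {
  src <- data.frame(
    id = c("A", "B"), kind = c("sludge", "industrial"),
    volume_l_per_day = c(2000, 1000),
    cod_mg_l = c(20000, 500000),
    cn_ratio = c(18, 60),
    alk_mg_l = c(4000, 300),
    tox_mg_l = c(1.0, 0.01),
    x_cost_per_km = x_cost,
    stringsAsFactors = FALSE)
  rec <- data.frame(id = "R1", max_volume_l_per_day = 2500,
                    cod_mg_l = 19000, cn_ratio = 19, alk_mg_l = 3000,
                    tox_mg_l = 1.5, stringsAsFactors = FALSE)
  dist <- matrix(c(10, 20), 2, 1, dimnames = list(src$id, rec$id))
  case_network(src, rec, dist, bounds = bounds, params = params)
}

# Wide-open operating bounds: every volume-respecting allocation is
# feasible, which isolates solver mechanics from the chemistry corridor.
permissive_bounds <- function()
  constraint_bounds(cn_min = 1e-6, cn_max = 1e9, alk_min = 1e-9,
                    alk_max = 1e9, tox_max = 1e9)

# Small synthetic instance with few volume options (large quantum).
small_instance <- function(seed, receptors = 1) {
  q <- if (receptors == 1) 20000 else 30000
  generate_network(synth_spec(2, 1, receptors, seed = seed),
                   params = objective_params(quantum = q))
}

# Deterministic scan for tiny instances whose exhaustive optimum is
# positive (instances where only the empty allocation is feasible would
# make solver-vs-oracle comparisons vacuous).  The screen uses only the
# oracle, never the solvers.
oracle_instances <- function(n_single = 10, n_double = 10, cap = 1e4) {
  out <- list()
  scan <- function(n, receptors) {
    found <- list(); s <- 0
    while (length(found) < n && s < 10000) {
      s <- s + 1
      net <- small_instance(s, receptors = receptors)
      o <- brute_force_oracle(net, cap = cap)
      if (o$feasible && o$best_b > 0)
        found[[length(found) + 1]] <- list(net = net, oracle = o$best_b)
    }
    found
  }
  c(scan(n_single, 1), scan(n_double, 2))
}

# A structurally valid random allocation: each source ships one random
# volume option to one random receptor (row sums trivially within V_w).
random_allocation <- function(net) {
  a <- allocation(net)
  for (w in seq_len(nrow(net$sources))) {
    opts <- volume_options(net$sources$volume_l_per_day[w],
                           net$params$quantum)
    r <- sample.int(ncol(a), 1)
    a[w, r] <- sample(opts, 1)
  }
  a
}

# Fast solver settings for unit-level checks.
fast_config <- function(algorithm, seed = 1, repetitions = 2, ...)
  solver_config(algorithm, population = 40, iterations = 80,
                repetitions = repetitions, seed = seed, ...)
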