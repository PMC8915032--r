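# Shared solver plumbing -----------------------------------------------

# Wrap a batch of option-index matrices into fitness values and keep the
# running best.  idxmat entries are 1-based indices into each edge's
# option set (option 1 is always volume 0).
solver_state <- function(net, cfg, mixing = "external_only") {
  ed <- edge_data(net)
  list(net = net, cfg = cfg, ed = ed, mixing = mixing)
}

evaluate_population <- function(st, idxmat, vol = NULL) {
  if (is.null(vol)) vol <- decode_volumes(idxmat, st$ed)
  res <- batch_evaluate(vol, st$ed, st$net, st$mixing)
  res$fitness <- fitness_from_batch(res, st$cfg$penalty,
                                    st$cfg$penalty_lambda)
  # constraint-dominance score for solver-internal comparisons: any
  # feasible solution outranks any infeasible one, infeasible solutions
  # are ranked by (negated) violation magnitude.  Reported fitness is
  # untouched.
  res$sel <- res$fitness - res$violation * !res$feasible
  res
}

# Track the best feasible solution ever seen (first-encountered wins at
# equal fitness).
update_best <- function(best, idxmat, res) {
  cand <- which(res$feasible)
  if (length(cand) == 0) return(best)
  i <- cand[which.max(res$b_abs[cand])]
  if (is.null(best) || res$b_abs[i] > best$b_abs)
    best <- list(idx = idxmat[i, ], b_abs = res$b_abs[i])
  best
}

finish_run <- function(st, best, trace, seed, tau_range = NULL) {
  net <- st$net
  trace <- as.data.frame(trace)
  names(trace) <- c("iteration", "best_b", "mean_b")
  feasible_found <- !is.null(best)
  if (feasible_found) {
    a <- allocation(net, 0)
    a[] <- decode_volumes(matrix(best$idx, nrow = 1), st$ed)
    best_b <- best$b_abs
  } else {
    a <- NULL
    best_b <- NA_real_
  }
  structure(list(best_allocation = a, best_b = best_b,
                 iteration_trace = trace,
                 seed = seed, feasible_found = feasible_found,
                 algorithm = st$cfg$algorithm,
                 tau_range = tau_range),
            class = "ancd_run")
}

random_population <- function(st, n) {
  idx <- matrix(0L, n, st$ed$E)
  for (e in seq_len(st$ed$E))
    idx[, e] <- sample.int(st$ed$n_opts[e], n, replace = TRUE)
  idx
}

trace_row <- function(iter, best, res)
  c(iter, if (is.null(best)) NA_real_ else best$b_abs,
    mean(res$fitness))

# Ant colony optimisation ----------------------------------------------

#' Solve an allocation problem with a max-min ant colony system
#'
#' Each ant constructs an allocation edge by edge, choosing one discrete
#' volume option per generator-receptor edge with probability
#' proportional to `tau^alpha * eta^beta`, where `tau` is the edge
#' option's pheromone trail and `eta` its heuristic information (the
#' option's marginal contribution to the cost index, floored at a small
#' epsilon so the zero option stays selectable). Construction is
#' capacity-aware, in the usual knapsack-ACO fashion: at each edge only
#' the options that keep the receptor's remaining intake capacity and
#' the generator's remaining volume non-negative are admissible (the
#' zero option always is), so constructed solutions always satisfy the
#' volume constraints and the death penalty acts on the blend-chemistry
#' constraints. After each iteration the trails persist by the factor
#' `rho` and the iteration-best feasible ant deposits pheromone on its
#' chosen options; trails are clamped to `[tau_min, tau_max]` in the
#' max-min fashion to avoid stagnation.
#'
#' @param net An `ancd_network`.
#' @param cfg A [solver_config()] with `algorithm = "aco"`.
#' @param mixing Blend mixing mode, see [blend_profile()].
#' @return An object of class `ancd_run`: the best-ever feasible
#'   allocation, its index, the per-iteration trace, the seed and a
#'   `feasible_found` flag.
#' @export
aco_solve <- function(net, cfg = solver_config("aco"),
                      mixing = "external_only") {
  stopifnot(cfg$algorithm == "aco")
  set.seed(cfg$seed)
  st <- solver_state(net, cfg, mixing)
  ed <- st$ed
  # heuristic information: the option's marginal cost-index term, with
  # an epsilon floor.  The zero option gets the edge's median nonzero
  # eta so that excluding a generator stays a competitive, learnable
  # choice at beta = 2 (a vanishing eta would make exclusion
  # unreachable for any realistic pheromone ratio).
  eps <- 1e-6
  eta <- lapply(seq_len(ed$E), function(e) {
    h <- pmax(ed$options[[ed$w_of[e]]] * ed$cfac[e], 0) + eps
    h[1] <- stats::median(h[-1])
    h
  })
  tau <- lapply(seq_len(ed$E), function(e)
    rep(cfg$aco_tau_max, length(eta[[e]])))
  best <- NULL
  trace <- matrix(NA_real_, cfg$iterations, 3)
  tau_lo <- Inf; tau_hi <- -Inf
  n <- cfg$population
  single <- net$params$single_receptor
  for (iter in seq_len(cfg$iterations)) {
    idx <- matrix(1L, n, ed$E)
    vol <- matrix(0, n, ed$E)
    used_r <- matrix(0, n, ed$R)
    used_w <- matrix(0, n, ed$W)
    for (e in seq_len(ed$E)) {
      w <- ed$w_of[e]; r <- ed$r_of[e]
      opts <- ed$options[[w]]
      p <- tau[[e]]^cfg$aco_alpha * eta[[e]]^cfg$aco_beta
      allow <- pmin(ed$cap[r] - used_r[, r], ed$vmax[w] - used_w[, w])
      if (single) allow[used_w[, w] > 0] <- 0
      k <- findInterval(allow * (1 + 1e-12) + 1e-9, opts)
      for (kk in unique(k)) {
        i <- which(k == kk)
        idx[i, e] <- if (kk == 1L) 1L else
          sample.int(kk, length(i), replace = TRUE, prob = p[seq_len(kk)])
      }
      v <- opts[idx[, e]]
      vol[, e] <- v
      used_r[, r] <- used_r[, r] + v
      used_w[, w] <- used_w[, w] + v
    }
    res <- evaluate_population(st, idx, vol = vol)
    best <- update_best(best, idx, res)
    # evaporation, iteration-best deposit, max-min clamp.  The
    # iteration-best feasible ant deposits; while no ant is feasible,
    # the least-violating ant deposits instead so the trails learn the
    # blend-chemistry constraints.
    feas <- which(res$feasible)
    if (length(feas) > 0) {
      ib <- feas[which.max(res$fitness[feas])]
      amount <- if (!is.null(best) && best$b_abs > 0)
        min(1, res$fitness[ib] / best$b_abs) else 1
    } else {
      ib <- which.max(res$sel)
      amount <- 0.5
    }
    dep <- list(idx = idx[ib, ], amount = amount)
    for (e in seq_len(ed$E)) {
      tau[[e]] <- tau[[e]] * cfg$aco_rho
      if (!is.null(dep))
        tau[[e]][dep$idx[e]] <- tau[[e]][dep$idx[e]] + dep$amount
      tau[[e]] <- pmin(cfg$aco_tau_max, pmax(cfg$aco_tau_min, tau[[e]]))
    }
    tau_lo <- min(tau_lo, min(unlist(tau)))
    tau_hi <- max(tau_hi, max(unlist(tau)))
    trace[iter, ] <- trace_row(iter, best, res)
  }
  finish_run(st, best, trace, cfg$seed, tau_range = c(tau_lo, tau_hi))
}

# Genetic algorithm -----------------------------------------------------

#' Solve an allocation problem with a genetic algorithm
#'
#' Chromosomes are integer vectors of option indices, one gene per
#' generator-receptor edge. Parents are chosen by tournament (size 2)
#' or rank selection; the configured crossover fraction of the non-elite
#' offspring is produced by uniform crossover; every non-elite gene
#' mutates with a per-gene probability (default 1/E) by resampling a
#' random option; the elite fraction is copied unchanged to the next
#' generation. Selection compares individuals by constraint dominance:
#' feasible individuals rank by penalised fitness, infeasible ones below
#' them by violation magnitude, which steers the population into the
#' feasible region before optimising within it.
#'
#' @inheritParams aco_solve
#' @param cfg A [solver_config()] with `algorithm = "ga"`.
#' @return An `ancd_run`.
#' @export
ga_solve <- function(net, cfg = solver_config("ga"),
                     mixing = "external_only") {
  stopifnot(cfg$algorithm == "ga")
  set.seed(cfg$seed)
  st <- solver_state(net, cfg, mixing)
  ed <- st$ed
  n <- cfg$population
  E <- ed$E
  mut_rate <- if (is.null(cfg$ga_mutation_rate)) 1 / E else
    cfg$ga_mutation_rate
  n_elite <- min(n, round(cfg$ga_elite_fraction * n))
  pop <- random_population(st, n)
  best <- NULL
  trace <- matrix(NA_real_, cfg$iterations, 3)
  for (iter in seq_len(cfg$iterations)) {
    res <- evaluate_population(st, pop)
    best <- update_best(best, pop, res)
    trace[iter, ] <- trace_row(iter, best, res)
    if (iter == cfg$iterations) break
    fit <- res$sel
    ord <- order(fit, decreasing = TRUE)
    select <- if (cfg$ga_selection == "tournament") {
      function(k) {
        i <- sample.int(n, k, replace = TRUE)
        j <- sample.int(n, k, replace = TRUE)
        ifelse(fit[i] >= fit[j], i, j)
      }
    } else {  # rank: probability proportional to n - rank + 1
      rank_w <- numeric(n); rank_w[ord] <- n:1
      function(k) sample.int(n, k, replace = TRUE, prob = rank_w)
    }
    n_child <- n - n_elite
    n_cross <- round(cfg$ga_crossover_fraction * n_child)
    child <- matrix(0L, n_child, E)
    if (n_cross > 0) {
      p1 <- pop[select(n_cross), , drop = FALSE]
      p2 <- pop[select(n_cross), , drop = FALSE]
      mask <- matrix(stats::runif(n_cross * E) < 0.5, n_cross, E)
      child[seq_len(n_cross), ] <- ifelse(mask, p1, p2)
    }
    if (n_child > n_cross)
      child[(n_cross + 1):n_child, ] <-
        pop[select(n_child - n_cross), , drop = FALSE]
    mmask <- matrix(stats::runif(n_child * E) < mut_rate, n_child, E)
    if (any(mmask)) {
      ne <- ed$n_opts[rep(seq_len(E), each = n_child)[as.vector(mmask)]]
      child[mmask] <- 1L + floor(stats::runif(sum(mmask)) * ne)
    }
    pop <- rbind(pop[ord[seq_len(n_elite)], , drop = FALSE], child)
  }
  finish_run(st, best, trace, cfg$seed)
}

# Particle swarm optimisation -------------------------------------------

#' Solve an allocation problem with particle swarm optimisation
#'
#' Particles move in the continuous unit cube, one coordinate per edge;
#' a position is decoded to the nearest discrete volume option for
#' evaluation. Velocities follow the standard update
#' `v <- w*v + c_cog*r1*(pbest - x) + c_soc*r2*(gbest - x)` with the
#' inertia weight interpolated linearly across iterations and velocities
#' clamped to a fraction of the unit range; positions are clamped to
#' `[0, 1]`. Personal and global bests are compared by constraint
#' dominance (feasible by fitness, infeasible below them by violation),
#' so the swarm is first attracted into the feasible region.
#'
#' @inheritParams aco_solve
#' @param cfg A [solver_config()] with `algorithm = "pso"`.
#' @return An `ancd_run`.
#' @export
pso_solve <- function(net, cfg = solver_config("pso"),
                      mixing = "external_only") {
  stopifnot(cfg$algorithm == "pso")
  set.seed(cfg$seed)
  st <- solver_state(net, cfg, mixing)
  ed <- st$ed
  n <- cfg$population; E <- ed$E
  clamp <- cfg$pso_velocity_clamp
  x <- matrix(stats::runif(n * E), n, E)
  v <- matrix(stats::runif(n * E, -clamp, clamp), n, E)
  to_idx <- function(x)
    matrix(1L + as.integer(round(x * rep(ed$n_opts - 1L, each = nrow(x)))),
           nrow(x), E)
  pbest_x <- x
  res <- evaluate_population(st, to_idx(x))
  pbest_f <- res$sel
  best <- update_best(NULL, to_idx(x), res)
  g <- which.max(pbest_f)
  gbest_x <- x[g, ]
  gbest_f <- pbest_f[g]
  trace <- matrix(NA_real_, cfg$iterations, 3)
  trace[1, ] <- trace_row(1, best, res)
  for (iter in seq_len(cfg$iterations)[-1]) {
    wgt <- cfg$pso_inertia[1] +
      (cfg$pso_inertia[2] - cfg$pso_inertia[1]) *
        (iter - 1) / max(1, cfg$iterations - 1)
    r1 <- matrix(stats::runif(n * E), n, E)
    r2 <- matrix(stats::runif(n * E), n, E)
    v <- wgt * v + cfg$pso_cognitive * r1 * (pbest_x - x) +
      cfg$pso_social * r2 * (sweep(-x, 2, gbest_x, "+"))
    v <- pmin(pmax(v, -clamp), clamp)
    x <- pmin(pmax(x + v, 0), 1)
    idx <- to_idx(x)
    res <- evaluate_population(st, idx)
    best <- update_best(best, idx, res)
    better <- res$sel > pbest_f
    pbest_f[better] <- res$sel[better]
    pbest_x[better, ] <- x[better, ]
    g <- which.max(pbest_f)
    if (pbest_f[g] > gbest_f) {
      gbest_f <- pbest_f[g]
      gbest_x <- pbest_x[g, ]
    }
    trace[iter, ] <- trace_row(iter, best, res)
  }
  finish_run(st, best, trace, cfg$seed)
}

# Campaign ---------------------------------------------------------------

#' Run a best-of-N solver campaign
#'
#' Runs the configured number of independent repetitions (each with a
#' derived seed, `seed + repetition - 1`) and selects the feasible run
#' with the highest absolute cost index as the campaign best.
#'
#' @inheritParams aco_solve
#' @param cfg A [solver_config()]; its `algorithm` field picks the
#'   solver.
#' @return An object of class `ancd_campaign` with elements `runs`
#'   (list of `ancd_run`), `best` (the winning run, or `NULL` when no
#'   repetition found a feasible solution), `mean_best_b`, `feasible`,
#'   `algorithm` and `config`.
#' @export
#' @examples
#' net <- besos_network()
#' cfg <- solver_config("ga", population = 30, iterations = 50,
#'                      repetitions = 2, seed = 1)
#' cam <- run_campaign(net, cfg)
#' cam$best$best_b
run_campaign <- function(net, cfg = solver_config(),
                         mixing = "external_only") {
  solver <- switch(cfg$algorithm, aco = aco_solve, ga = ga_solve,
                   pso = pso_solve)
  runs <- vector("list", cfg$repetitions)
  for (rep in seq_len(cfg$repetitions)) {
    rep_cfg <- cfg
    rep_cfg$seed <- cfg$seed + rep - 1L
    runs[[rep]] <- solver(net, rep_cfg, mixing = mixing)
  }
  feas <- vapply(runs, function(r) r$feasible_found, logical(1))
  best <- NULL
  if (any(feas)) {
    bb <- vapply(runs, function(r)
      if (r$feasible_found) r$best_b else -Inf, numeric(1))
    best <- runs[[which.max(bb)]]
  }
  structure(list(runs = runs, best = best,
                 mean_best_b = mean(vapply(runs, function(r) r$best_b,
                                           numeric(1)), na.rm = TRUE),
                 feasible = any(feas), algorithm = cfg$algorithm,
                 config = cfg, mixing = mixing),
            class = "ancd_campaign")
}

#' Solve a co-digestion network
#'
#' Main entry point: runs a best-of-N campaign of the chosen stochastic
#' solver on a network and returns a classed result with `print`,
#' `summary`, `plot` and `coef` methods.
#'
#' @param net An `ancd_network`.
#' @param algorithm `"aco"`, `"ga"` or `"pso"`.
#' @param ... Further arguments to [solver_config()].
#' @param config A full [solver_config()]; overrides `algorithm`/`...`.
#' @param mixing Blend mixing mode, see [blend_profile()].
#' @return An `ancd_campaign`.
#' @export
ancd_solve <- function(net, algorithm = c("aco", "ga", "pso"), ...,
                       config = NULL, mixing = "external_only") {
  if (is.null(config))
    config <- solver_config(match.arg(algorithm), ...)
  run_campaign(net, config, mixing = mixing)
}

# Exhaustive oracle ------------------------------------------------------

#' Exhaustive search oracle for small instances
#'
#' Enumerates every combination of per-edge volume options, filters by
#' [check_feasibility()] and returns the feasible maximiser of the
#' absolute cost index (ties broken by the lexicographically smallest
#' option-index vector). Intended as an independent reference for
#' testing the stochastic solvers on small networks; refuses instances
#' whose combination count exceeds `cap`.
#'
#' @param net An `ancd_network`.
#' @param cap Maximum number of combinations to enumerate.
#' @param mixing Blend mixing mode.
#' @return A list with `best_allocation` (an `ancd_allocation`, or
#'   `NULL`), `best_b`, `best_idx`, `feasible` and `n_combinations`.
#' @export
brute_force_oracle <- function(net, cap = 1e6, mixing = "external_only") {
  ed <- edge_data(net)
  n_opts <- ed$n_opts
  total <- prod(n_opts)
  if (total > cap)
    stop("brute_force_oracle: ", format(total, big.mark = ","),
         " combinations exceed the cap of ", format(cap, big.mark = ","),
         call. = FALSE)
  # lexicographic enumeration: first edge varies slowest
  grid <- as.matrix(rev(expand.grid(rev(lapply(n_opts, seq_len)))))
  dimnames(grid) <- NULL
  storage.mode(grid) <- "integer"
  best_idx <- NULL; best_b <- -Inf
  chunk <- 65536L
  for (start in seq(1L, nrow(grid), by = chunk)) {
    rows <- start:min(nrow(grid), start + chunk - 1L)
    vol <- decode_volumes(grid[rows, , drop = FALSE], ed)
    res <- batch_evaluate(vol, ed, net, mixing)
    cand <- which(res$feasible & res$b_abs > best_b)
    if (length(cand) > 0) {
      i <- cand[which.max(res$b_abs[cand])]
      best_b <- res$b_abs[i]
      best_idx <- grid[rows[i], ]
    }
  }
  if (is.null(best_idx))
    return(list(best_allocation = NULL, best_b = NA_real_,
                best_idx = NULL, feasible = FALSE,
                n_combinations = total))
  a <- allocation(net, 0)
  a[] <- decode_volumes(matrix(best_idx, nrow = 1), ed)
  list(best_allocation = a, best_b = best_b, best_idx = best_idx,
       feasible = TRUE, n_combinations = total)
}
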