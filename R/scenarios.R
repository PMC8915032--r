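#' Define a scenario transformation
#'
#' A scenario is a reproducible transformation of a case network used to
#' stress the solvers: scaling every COD concentration, scaling or
#' square-rooting the distance matrix, scaling every generator volume
#' (which recomputes the volume option sets), or resampling the C/N
#' ratio of selected generators within a target range.
#'
#' @param id Scenario label.
#' @param cod_multiplier Multiplies every generator COD. Default 1.
#' @param distance_mode `"identity"`, `"linear"` (multiply by
#'   `distance_factor`) or `"sqrt"` (replace each distance in km by its
#'   square root).
#' @param distance_factor Factor for `distance_mode = "linear"`.
#' @param volume_multiplier Multiplies every generator daily volume.
#' @param cn_override `NULL`, or a list with `sources` (character vector
#'   of generator ids), `range` (`c(lo, hi)`) and `seed`: the matching
#'   generators' C/N ratios are resampled uniformly in `[lo, hi]`.
#'
#' @return An object of class `ancd_scenario`.
#' @export
scenario_spec <- function(id, cod_multiplier = 1,
                          distance_mode = c("identity", "linear", "sqrt"),
                          distance_factor = 1, volume_multiplier = 1,
                          cn_override = NULL) {
  distance_mode <- match.arg(distance_mode)
  if (!(cod_multiplier > 0) || !(volume_multiplier > 0) ||
      !(distance_factor > 0))
    stop("scenario_spec: multipliers must be > 0", call. = FALSE)
  if (!is.null(cn_override)) {
    if (!is.list(cn_override) ||
        !all(c("sources", "range", "seed") %in% names(cn_override)))
      stop("scenario_spec: cn_override needs 'sources', 'range', 'seed'",
           call. = FALSE)
    if (length(cn_override$range) != 2 ||
        cn_override$range[1] <= 0 ||
        cn_override$range[1] > cn_override$range[2])
      stop("scenario_spec: cn_override range must be 0 < lo <= hi",
           call. = FALSE)
  }
  structure(list(id = id, cod_multiplier = cod_multiplier,
                 distance_mode = distance_mode,
                 distance_factor = distance_factor,
                 volume_multiplier = volume_multiplier,
                 cn_override = cn_override),
            class = "ancd_scenario")
}

#' Apply a scenario transformation to a network
#'
#' Returns a new, revalidated network; the input network is never
#' modified. Volume scaling recomputes every generator's volume option
#' set implicitly (options are derived from the stored volumes).
#'
#' @param net An `ancd_network`.
#' @param spec An [scenario_spec()].
#' @return A transformed `ancd_network`.
#' @export
#' @examples
#' net <- besos_network()
#' s1 <- apply_scenario(net, scenario_spec("S1", cod_multiplier = 10))
#' s1$sources$cod_mg_l[1]  # 199000
apply_scenario <- function(net, spec) {
  stopifnot(inherits(net, "ancd_network"), inherits(spec, "ancd_scenario"))
  src <- net$sources
  dist <- net$distances
  src$cod_mg_l <- src$cod_mg_l * spec$cod_multiplier
  src$volume_l_per_day <- src$volume_l_per_day * spec$volume_multiplier
  dist <- switch(spec$distance_mode,
                 identity = dist,
                 linear = dist * spec$distance_factor,
                 sqrt = sqrt(dist))
  if (!is.null(spec$cn_override)) {
    ov <- spec$cn_override
    i <- match(ov$sources, src$id)
    if (anyNA(i))
      stop("apply_scenario: unknown source id(s) in cn_override: ",
           paste(ov$sources[is.na(i)], collapse = ", "), call. = FALSE)
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(ov$seed)
    src$cn_ratio[i] <- stats::runif(length(i), ov$range[1], ov$range[2])
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  case_network(src, net$receptors, dist, bounds = net$bounds,
               params = net$params)
}

#' The bundled study scenarios
#'
#' The five stress scenarios applied to the baseline case network:
#' tenfold COD, tenfold distances, square-rooted distances, threefold
#' volumes, and resampling the sludge generators' (W1-W12) C/N ratio
#' uniformly in the 50-60 range.
#'
#' @param cn_seed Seed for the C/N resampling scenario.
#' @param include_baseline Prepend an identity scenario labelled
#'   `"baseline"`.
#' @return A named list of [scenario_spec()] objects.
#' @export
standard_scenarios <- function(cn_seed = 42, include_baseline = TRUE) {
  sc <- list(
    S1 = scenario_spec("S1", cod_multiplier = 10),
    S2a = scenario_spec("S2a", distance_mode = "linear",
                        distance_factor = 10),
    S2b = scenario_spec("S2b", distance_mode = "sqrt"),
    S3 = scenario_spec("S3", volume_multiplier = 3),
    S4 = scenario_spec("S4", cn_override = list(
      sources = paste0("W", 1:12), range = c(50, 60), seed = cn_seed)))
  if (include_baseline)
    sc <- c(list(baseline = scenario_spec("baseline")), sc)
  sc
}

#' Read scenario specifications from a config file
#'
#' Scenario config files are plain structured text in DCF form: one
#' block of `key: value` lines per scenario, blocks separated by blank
#' lines. Recognised keys are `id`, `cod_multiplier`, `distance_mode`,
#' `distance_factor`, `volume_multiplier`, `cn_sources` (comma
#' separated), `cn_lo`, `cn_hi`, `cn_seed`.
#'
#' @param path Config file path.
#' @return A named list of [scenario_spec()] objects.
#' @export
read_scenario_config <- function(path) {
  blocks <- read.dcf(path)
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    g <- function(key, default) {
      v <- if (key %in% colnames(blocks)) blocks[i, key] else NA
      if (is.na(v)) default else v
    }
    num <- function(key, default) as.numeric(g(key, default))
    cn <- NULL
    if (!is.na(g("cn_sources", NA)))
      cn <- list(sources = trimws(strsplit(g("cn_sources", ""), ",")[[1]]),
                 range = c(num("cn_lo", 50), num("cn_hi", 60)),
                 seed = as.integer(num("cn_seed", 1)))
    sp <- scenario_spec(g("id", paste0("scenario", i)),
                        cod_multiplier = num("cod_multiplier", 1),
                        distance_mode = g("distance_mode", "identity"),
                        distance_factor = num("distance_factor", 1),
                        volume_multiplier = num("volume_multiplier", 1),
                        cn_override = cn)
    out[[sp$id]] <- sp
  }
  out
}

#' Benchmark solvers across scenarios
#'
#' For every (scenario, algorithm) pair: applies the scenario, runs a
#' best-of-N campaign, evaluates the winning allocation and emits one
#' metric row (best index B, biogas, average organic load, average C/N,
#' average alkalinity, feasibility, elapsed seconds). Campaigns that
#' never find a feasible solution emit a row with `feasible = FALSE` and
#' `NA` metrics.
#'
#' @param net The baseline `ancd_network`.
#' @param scenarios List of [scenario_spec()] objects.
#' @param algorithms Character vector among `"aco"`, `"ga"`, `"pso"`.
#' @param cfg A [solver_config()]; its `algorithm` field is overridden
#'   per row.
#' @param mixing Blend mixing mode.
#' @return A data frame, one row per (scenario, algorithm) attempted,
#'   with the winning allocations attached as the `"allocations"`
#'   attribute.
#' @export
run_benchmark <- function(net, scenarios, algorithms = c("aco", "ga", "pso"),
                          cfg = solver_config(), mixing = "external_only") {
  rows <- list(); allocs <- list()
  for (sc in scenarios) {
    snet <- apply_scenario(net, sc)
    for (alg in algorithms) {
      acfg <- cfg; acfg$algorithm <- alg
      t0 <- proc.time()[["elapsed"]]
      cam <- run_campaign(snet, acfg, mixing = mixing)
      elapsed <- proc.time()[["elapsed"]] - t0
      if (cam$feasible) {
        ev <- evaluate_allocation(cam$best$best_allocation, snet,
                                  mixing = mixing)
        row <- data.frame(scenario = sc$id, algorithm = alg,
                          best_b = ev$b_abs,
                          biogas_nm3_per_day = ev$biogas_total,
                          organic_load_avg = mean(ev$organic_load),
                          avg_cn = ev$avg_cn, avg_alk = ev$avg_alk,
                          feasible = TRUE, elapsed = elapsed,
                          stringsAsFactors = FALSE)
        allocs[[paste(sc$id, alg, sep = ".")]] <- cam$best$best_allocation
      } else {
        row <- data.frame(scenario = sc$id, algorithm = alg,
                          best_b = NA_real_,
                          biogas_nm3_per_day = NA_real_,
                          organic_load_avg = NA_real_,
                          avg_cn = NA_real_, avg_alk = NA_real_,
                          feasible = FALSE, elapsed = elapsed,
                          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(scenario = character(), algorithm = character(),
               best_b = numeric(), biogas_nm3_per_day = numeric(),
               organic_load_avg = numeric(), avg_cn = numeric(),
               avg_alk = numeric(), feasible = logical(),
               elapsed = numeric(), stringsAsFactors = FALSE)
  attr(out, "allocations") <- allocs
  out
}

#' Per-receptor blending profile
#'
#' The composition of each receptor's intake: for every receptor, the
#' contributing generators with shipped volume and fraction of the
#' receptor's external intake (fractions sum to 1 for receptors with
#' nonzero intake).
#'
#' @param a An `ancd_allocation`.
#' @param net An `ancd_network`.
#' @param drop_zero Drop zero-volume rows (default `TRUE`).
#' @return A data frame with columns `receptor`, `source`, `volume`,
#'   `fraction`.
#' @export
blending_profile_report <- function(a, net, drop_zero = TRUE) {
  validate_allocation(a, net)
  rows <- list()
  for (r in seq_len(ncol(a))) {
    tot <- sum(a[, r])
    keep <- if (drop_zero) which(a[, r] > 0) else seq_len(nrow(a))
    if (length(keep) == 0) next
    rows[[r]] <- data.frame(
      receptor = net$receptors$id[r],
      source = net$sources$id[keep],
      volume = a[keep, r],
      fraction = if (tot > 0) a[keep, r] / tot else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(receptor = character(), source = character(),
                      volume = numeric(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Truck logistics schedule for an allocation
#'
#' Converts an allocation into a cyclic trucking plan: over one
#' hydraulic-retention-time cycle, each active generator-receptor edge
#' accumulates `volume * density * hrt` kg of substrate, moved in
#' `ceiling(mass / truck capacity)` full truck loads. Zero-volume edges
#' are pruned.
#'
#' @param a An `ancd_allocation`.
#' @param net An `ancd_network`.
#' @param truck_capacity_t Truck capacity in metric tonnes. Default 20.
#' @param density_kg_l Substrate density, kg/L. Default 1.
#' @param hrt_days Cycle length = hydraulic retention time, days.
#'   Default 20.
#' @return A data frame (class `ancd_schedule`) with one row per active
#'   edge: `source`, `receptor`, `volume_l_per_day`, `cycle_mass_kg`,
#'   `loads_per_cycle`, `cycle_days`; the attribute
#'   `feasible_within_hrt` flags whether the cycle fits the retention
#'   time.
#' @export
#' @examples
#' net <- besos_network()
#' a <- allocation(net); a["W1", "R1"] <- 2000
#' logistics_schedule(a, net)  # 40,000 kg per cycle -> 2 loads
logistics_schedule <- function(a, net, truck_capacity_t = 20,
                               density_kg_l = 1, hrt_days = 20) {
  stopifnot(truck_capacity_t > 0, density_kg_l > 0, hrt_days > 0)
  validate_allocation(a, net)
  act <- which(a > 0, arr.ind = TRUE)
  mass <- a[act] * density_kg_l * hrt_days
  out <- data.frame(
    source = rownames(a)[act[, 1]],
    receptor = colnames(a)[act[, 2]],
    volume_l_per_day = a[act],
    cycle_mass_kg = mass,
    loads_per_cycle = ceiling(mass / (truck_capacity_t * 1000)),
    cycle_days = rep(hrt_days, length(mass)),
    stringsAsFactors = FALSE)
  out <- out[order(out$receptor, out$source), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "feasible_within_hrt") <- all(out$cycle_days <= hrt_days)
  class(out) <- c("ancd_schedule", "data.frame")
  out
}

#' Hyper-parameter trimming sweep
#'
#' Reproduces the trimming procedure used to tune the solvers: for each
#' value of each swept parameter (all other settings fixed at `cfg`),
#' one full campaign is run and its best index recorded; the best value
#' per parameter is marked.
#'
#' @param net An `ancd_network`.
#' @param algorithm Solver to sweep.
#' @param grid Named list mapping [solver_config()] field names to value
#'   vectors, e.g. `list(ga_crossover_fraction = c(0.2, 0.5, 0.8))`.
#' @param cfg Base [solver_config()].
#' @param mixing Blend mixing mode.
#' @return A data frame with columns `parameter`, `value`, `best_b`,
#'   `feasible`, `elapsed`, `is_best` (best within its parameter).
#' @export
parameter_sweep <- function(net, algorithm, grid, cfg = solver_config(),
                            mixing = "external_only") {
  bad <- setdiff(names(grid), names(cfg))
  if (length(bad) > 0)
    stop("parameter_sweep: unknown solver_config parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  rows <- list()
  for (par in names(grid)) {
    for (val in grid[[par]]) {
      pcfg <- cfg
      pcfg$algorithm <- algorithm
      pcfg[[par]] <- val
      t0 <- proc.time()[["elapsed"]]
      cam <- run_campaign(net, pcfg, mixing = mixing)
      elapsed <- proc.time()[["elapsed"]] - t0
      rows[[length(rows) + 1]] <- data.frame(
        parameter = par, value = val,
        best_b = if (cam$feasible) cam$best$best_b else NA_real_,
        feasible = cam$feasible, elapsed = elapsed,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$is_best <- FALSE
  for (par in unique(out$parameter)) {
    i <- which(out$parameter == par)
    bb <- out$best_b[i]
    if (any(!is.na(bb)))
      out$is_best[i[which.max(ifelse(is.na(bb), -Inf, bb))]] <- TRUE
  }
  rownames(out) <- NULL
  out
}
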