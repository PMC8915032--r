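#' Feasibility bounds for a digester feed blend
#'
#' Operating ranges that every receptor's accepted blend must satisfy:
#' the COD/TN ratio window that avoids acidification and ammonia
#' inhibition, the alkalinity window that keeps the digester buffered,
#' and a lead-concentration ceiling as the toxicity proxy.
#'
#' @param cn_min,cn_max COD/TN ratio window (dimensionless). Defaults 20-60.
#' @param alk_min,alk_max Alkalinity window, mg CaCO3/L. Defaults 2500-6000.
#' @param tox_max Maximum blend lead concentration, mg Pb/L. Default 2.1.
#'
#' @return An object of class `ancd_bounds`.
#' @export
#' @examples
#' constraint_bounds()
constraint_bounds <- function(cn_min = 20, cn_max = 60,
                              alk_min = 2500, alk_max = 6000,
                              tox_max = 2.1) {
  stopifnot(is.numeric(cn_min), is.numeric(cn_max),
            is.numeric(alk_min), is.numeric(alk_max), is.numeric(tox_max))
  if (!(cn_min < cn_max))
    stop("constraint_bounds: cn_min must be < cn_max", call. = FALSE)
  if (!(alk_min < alk_max))
    stop("constraint_bounds: alk_min must be < alk_max", call. = FALSE)
  if (!(tox_max > 0))
    stop("constraint_bounds: tox_max must be > 0", call. = FALSE)
  structure(list(cn_min = cn_min, cn_max = cn_max,
                 alk_min = alk_min, alk_max = alk_max,
                 tox_max = tox_max),
            class = "ancd_bounds")
}

#' Objective-function and discretisation parameters
#'
#' Parameters of the normalised quality-plus-logistics cost index and of
#' the volume discretisation. The index sums, over every selected
#' generator-receptor edge, the normalised shipped volume times the
#' toxicity coefficient times a combination of the quality term
#' (sum of the three dimensionless quality coefficients, weighted by
#' `rho_q`) and the logistics term (`X_w * d_wr * I_w`, weighted by
#' `rho_x`).
#'
#' @param rho_q Weight of the quality term, in (0, 1]. Default 0.5.
#' @param rho_x Weight of the logistics term, in (0, 1]. Default 0.5.
#' @param K Sign convention, +1 or -1. Maximising solvers use +1;
#'   the comparison metric is the absolute value either way.
#' @param quality_weight_mode `"exponent"` raises the coefficient sum to
#'   the power `rho_q` (default); `"multiplier"` multiplies it by `rho_q`.
#' @param logistics_mode `"penalty"` (default) subtracts the
#'   max-normalised logistics term from the quality term and clamps at
#'   zero, so long hauls are penalised; `"literal"` adds the raw
#'   logistics term to the quality term.
#' @param quantum Volume quantum q in L/day; selectable volumes are
#'   multiples of q (plus the exact daily volume). Default 1000.
#' @param biogas_yield Biogas conversion factor, m3 biogas per kg COD.
#'   Default 0.268.
#' @param coefficient_mode `"fallback"` (default) uses the built-in
#'   dimensionless coefficient forms (see [quality_coefficients()]);
#'   `"figure2"` requires `figure2` to carry transcribed equations.
#' @param figure2 Optional named list of four functions
#'   (`f1`, `f2`, `f3`, `t`), each taking `(source, bounds)` and returning
#'   a numeric vector, used when `coefficient_mode = "figure2"`.
#' @param cod_ref Reference COD (mg/L) normalising the biogas-potential
#'   coefficient; `NULL` (default) uses the maximum COD in the network.
#' @param cn_shoulder,alk_shoulder Width of the linear shoulders of the
#'   trapezoidal C/N and alkalinity coefficients; `NULL` (default) uses
#'   half the plateau width.
#' @param single_receptor If `TRUE`, each generator may ship to at most
#'   one receptor; the default `FALSE` allows splitting a generator's
#'   volume across receptors.
#'
#' @return An object of class `ancd_params`.
#' @export
objective_params <- function(rho_q = 0.5, rho_x = 0.5, K = 1,
                             quality_weight_mode = c("exponent", "multiplier"),
                             logistics_mode = c("penalty", "literal"),
                             quantum = 1000, biogas_yield = 0.268,
                             coefficient_mode = c("fallback", "figure2"),
                             figure2 = NULL, cod_ref = NULL,
                             cn_shoulder = NULL, alk_shoulder = NULL,
                             single_receptor = FALSE) {
  quality_weight_mode <- match.arg(quality_weight_mode)
  logistics_mode <- match.arg(logistics_mode)
  coefficient_mode <- match.arg(coefficient_mode)
  if (!(rho_q > 0 && rho_q <= 1))
    stop("objective_params: rho_q must be in (0, 1]", call. = FALSE)
  if (!(rho_x > 0 && rho_x <= 1))
    stop("objective_params: rho_x must be in (0, 1]", call. = FALSE)
  if (!K %in% c(-1, 1))
    stop("objective_params: K must be -1 or +1", call. = FALSE)
  if (!(quantum > 0))
    stop("objective_params: quantum must be > 0", call. = FALSE)
  if (!(biogas_yield > 0))
    stop("objective_params: biogas_yield must be > 0", call. = FALSE)
  structure(list(rho_q = rho_q, rho_x = rho_x, K = K,
                 quality_weight_mode = quality_weight_mode,
                 logistics_mode = logistics_mode,
                 quantum = quantum, biogas_yield = biogas_yield,
                 coefficient_mode = coefficient_mode, figure2 = figure2,
                 cod_ref = cod_ref, cn_shoulder = cn_shoulder,
                 alk_shoulder = alk_shoulder,
                 single_receptor = isTRUE(single_receptor)),
            class = "ancd_params")
}

#' Solver configuration
#'
#' Hyper-parameters shared by the three stochastic solvers, with the
#' campaign defaults used in the case study: population 100, 500
#' iterations, best of 10 repetitions. Algorithm-specific parameters
#' follow the trimmed values: ACO alpha = 1, beta = 2, pheromone
#' persistence rho = 0.98; GA crossover fraction 0.8, elite fraction
#' 0.05; PSO cognitive attraction 0.8, social attraction 1.25.
#'
#' @param algorithm One of `"aco"`, `"ga"`, `"pso"`.
#' @param population Individuals (ants / chromosomes / particles) per
#'   iteration.
#' @param iterations Iterations (generations) per repetition.
#' @param repetitions Independent repetitions per campaign; the best
#'   feasible run is reported.
#' @param seed Integer seed; repetition r uses `seed + r - 1`.
#' @param penalty Constraint handling: `"death"` (infeasible fitness 0,
#'   default) or `"linear"` (fitness reduced by `penalty_lambda` times
#'   the summed normalised violation magnitudes, clamped at 0).
#' @param penalty_lambda Linear-penalty weight. Default 1.
#' @param aco_alpha,aco_beta Pheromone / heuristic importance exponents.
#' @param aco_rho Pheromone persistence per iteration, in (0, 1).
#' @param aco_tau_min,aco_tau_max Max-min pheromone clamp bounds.
#' @param ga_crossover_fraction Fraction of non-elite offspring produced
#'   by uniform crossover.
#' @param ga_elite_fraction Fraction of the population copied unchanged.
#' @param ga_mutation_rate Per-gene mutation probability; `NULL`
#'   (default) uses 1/E with E the number of edges.
#' @param ga_selection `"tournament"` (size 2, default) or `"rank"`.
#' @param pso_cognitive,pso_social Attraction factors.
#' @param pso_inertia Length-2 vector, inertia weight interpolated
#'   linearly from the first to the second value across iterations.
#' @param pso_velocity_clamp Velocity clamp as a fraction of the unit
#'   position range.
#'
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(algorithm = c("aco", "ga", "pso"),
                          population = 100, iterations = 500,
                          repetitions = 10, seed = 1,
                          penalty = c("death", "linear"), penalty_lambda = 1,
                          aco_alpha = 1, aco_beta = 2, aco_rho = 0.98,
                          aco_tau_min = 0.001, aco_tau_max = 1,
                          ga_crossover_fraction = 0.8,
                          ga_elite_fraction = 0.05,
                          ga_mutation_rate = NULL,
                          ga_selection = c("tournament", "rank"),
                          pso_cognitive = 0.8, pso_social = 1.25,
                          pso_inertia = c(0.9, 0.4),
                          pso_velocity_clamp = 0.2) {
  algorithm <- match.arg(algorithm)
  penalty <- match.arg(penalty)
  ga_selection <- match.arg(ga_selection)
  if (population < 1 || iterations < 1 || repetitions < 1)
    stop("solver_config: population, iterations and repetitions must be >= 1",
         call. = FALSE)
  if (!(aco_rho > 0 && aco_rho < 1))
    stop("solver_config: aco_rho must be in (0, 1)", call. = FALSE)
  frac_ok <- function(x) x >= 0 && x <= 1
  if (!frac_ok(ga_crossover_fraction) || !frac_ok(ga_elite_fraction))
    stop("solver_config: GA fractions must be in [0, 1]", call. = FALSE)
  if (!is.null(ga_mutation_rate) && !frac_ok(ga_mutation_rate))
    stop("solver_config: ga_mutation_rate must be in [0, 1]", call. = FALSE)
  if (!(aco_tau_min > 0 && aco_tau_min <= aco_tau_max))
    stop("solver_config: need 0 < aco_tau_min <= aco_tau_max", call. = FALSE)
  if (length(pso_inertia) != 2)
    stop("solver_config: pso_inertia must be a length-2 schedule",
         call. = FALSE)
  structure(list(algorithm = algorithm,
                 population = as.integer(population),
                 iterations = as.integer(iterations),
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed),
                 penalty = penalty, penalty_lambda = penalty_lambda,
                 aco_alpha = aco_alpha, aco_beta = aco_beta,
                 aco_rho = aco_rho,
                 aco_tau_min = aco_tau_min, aco_tau_max = aco_tau_max,
                 ga_crossover_fraction = ga_crossover_fraction,
                 ga_elite_fraction = ga_elite_fraction,
                 ga_mutation_rate = ga_mutation_rate,
                 ga_selection = ga_selection,
                 pso_cognitive = pso_cognitive, pso_social = pso_social,
                 pso_inertia = pso_inertia,
                 pso_velocity_clamp = pso_velocity_clamp),
            class = "solver_config")
}
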