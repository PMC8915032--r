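#' Default characterisation envelopes for synthetic networks
#'
#' Marginal ranges mirroring the bundled case-study dataset: sewage
#' sludge with moderate COD and low C/N, industrial substrates with very
#' high COD and C/N spanning three orders of magnitude (drawn
#' log-uniformly), low industrial alkalinity, and road distances of
#' 5-67 km.
#'
#' @return A nested list of `c(lo, hi)` envelopes.
#' @export
synth_ranges <- function() {
  list(
    sludge = list(cod = c(16900, 23400), cn = c(14, 21),
                  alk = c(1800, 10100), tox = c(0.01, 2.30),
                  volume = c(4400, 47000)),
    industrial = list(cod = c(155900, 667400), cn = c(32, 33000),
                      alk = c(20, 660), tox = c(0.01, 2.30),
                      volume = c(9000, 9000)),
    distance = c(5, 67),
    receptor = list(cod = c(16900, 23400), cn = c(14, 21),
                    alk = c(1800, 10100), tox = c(0.01, 2.30)),
    capacity_ratio = c(1, 4))
}

#' Synthetic network specification
#'
#' @param n_sludge,n_industrial,n_receptors Counts of sludge generators,
#'   industrial generators and receptor plants.
#' @param seed Integer seed; generation is fully reproducible.
#' @param ranges Envelope list as returned by [synth_ranges()].
#' @return An object of class `ancd_synth_spec`.
#' @export
synth_spec <- function(n_sludge, n_industrial, n_receptors, seed = 1,
                       ranges = synth_ranges()) {
  if (n_sludge < 0 || n_industrial < 0 || n_receptors < 1)
    stop("synth_spec: counts must be >= 0 (receptors >= 1)", call. = FALSE)
  if (n_sludge + n_industrial < 1)
    stop("synth_spec: need at least one generator", call. = FALSE)
  ok <- function(r) length(r) == 2 && r[1] <= r[2]
  for (k in c("sludge", "industrial", "receptor"))
    for (f in names(ranges[[k]]))
      if (!ok(ranges[[k]][[f]]))
        stop("synth_spec: impossible envelope ", k, "$", f, call. = FALSE)
  if (!ok(ranges$distance) || !ok(ranges$capacity_ratio))
    stop("synth_spec: impossible distance/capacity envelope", call. = FALSE)
  structure(list(n_sludge = as.integer(n_sludge),
                 n_industrial = as.integer(n_industrial),
                 n_receptors = as.integer(n_receptors),
                 seed = as.integer(seed), ranges = ranges),
            class = "ancd_synth_spec")
}

#' Generate a synthetic case network
#'
#' Draws a reproducible random network within the envelope ranges:
#' uniform draws for sludge characterisation, log-uniform draws for
#' industrial COD and C/N (whose empirical ranges span orders of
#' magnitude), uniform distances, and receptor capacities drawn so the
#' instance is non-trivially constrained (total generator volume between
#' 1x and 4x total receptor capacity, split randomly across receptors).
#' The result passes the full [case_network()] validation.
#'
#' @param spec An [synth_spec()].
#' @param bounds An [constraint_bounds()].
#' @param params An [objective_params()].
#' @return An `ancd_network`.
#' @export
#' @examples
#' net <- generate_network(synth_spec(3, 2, 2, seed = 1))
#' nrow(net$sources)
generate_network <- function(spec, bounds = constraint_bounds(),
                             params = objective_params()) {
  stopifnot(inherits(spec, "ancd_synth_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(spec$seed)
  rg <- spec$ranges
  u <- function(n, r) stats::runif(n, r[1], r[2])
  lu <- function(n, r) exp(stats::runif(n, log(r[1]), log(r[2])))
  ns <- spec$n_sludge; ni <- spec$n_industrial; nr <- spec$n_receptors
  src <- data.frame(
    id = c(if (ns > 0) paste0("W", seq_len(ns)),
           if (ni > 0) paste0("C", seq_len(ni))),
    kind = c(rep("sludge", ns), rep("industrial", ni)),
    volume_l_per_day = c(u(ns, rg$sludge$volume),
                         u(ni, rg$industrial$volume)),
    cod_mg_l = c(u(ns, rg$sludge$cod), lu(ni, rg$industrial$cod)),
    cn_ratio = c(u(ns, rg$sludge$cn), lu(ni, rg$industrial$cn)),
    alk_mg_l = c(u(ns, rg$sludge$alk), u(ni, rg$industrial$alk)),
    tox_mg_l = c(u(ns, rg$sludge$tox), u(ni, rg$industrial$tox)),
    stringsAsFactors = FALSE)
  total_vol <- sum(src$volume_l_per_day)
  ratio <- u(1, rg$capacity_ratio)  # total volume / total capacity
  share <- u(nr, c(0.5, 1)); share <- share / sum(share)
  rec <- data.frame(
    id = paste0("R", seq_len(nr)),
    max_volume_l_per_day = total_vol / ratio * share,
    cod_mg_l = u(nr, rg$receptor$cod),
    cn_ratio = u(nr, rg$receptor$cn),
    alk_mg_l = u(nr, rg$receptor$alk),
    tox_mg_l = u(nr, rg$receptor$tox),
    stringsAsFactors = FALSE)
  dist <- matrix(u((ns + ni) * nr, rg$distance), ns + ni, nr,
                 dimnames = list(src$id, rec$id))
  case_network(src, rec, dist, bounds = bounds, params = params)
}
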