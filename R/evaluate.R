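#' Mass-balance profile of a receptor's blend
#'
#' Volume-weighted mass balance of the substrates routed to one
#' receptor. COD mass is `sum(v * cod) * 1e-6` kg/day; total nitrogen is
#' derived per source as `cod / cn_ratio` before mixing, so the blend
#' C/N ratio is the ratio of total COD mass to total TN mass (never an
#' average of ratios); alkalinity and toxicity are volume-weighted mean
#' concentrations. With `mixing = "with_base"` the receptor's own sludge
#' stream (at `base_feed_l_per_day` with its own characterisation) is
#' included in the blend.
#'
#' @param a An `ancd_allocation`.
#' @param receptor Receptor id (character) or index.
#' @param net An `ancd_network`.
#' @param mixing `"external_only"` (default) or `"with_base"`.
#'
#' @return An object of class `ancd_blend`: a list with
#'   `receptor_id`, `total_volume` (L/day), `cod_conc` (mg/L),
#'   `cod_mass` (kg/day), `tn_mass` (kg/day), `cn_ratio`, `alkalinity`
#'   (mg CaCO3/L), `toxicity` (mg Pb/L) and `defined` (FALSE when the
#'   blend volume is zero, in which case concentrations are `NA`).
#' @export
blend_profile <- function(a, receptor, net,
                          mixing = c("external_only", "with_base")) {
  mixing <- match.arg(mixing)
  stopifnot(inherits(net, "ancd_network"))
  if (is.character(receptor)) {
    r <- match(receptor, net$receptors$id)
    if (is.na(r)) stop("blend_profile: unknown receptor '", receptor, "'",
                       call. = FALSE)
  } else r <- as.integer(receptor)
  src <- net$sources
  v <- a[, r]
  vol <- sum(v)
  cod_mass <- sum(v * src$cod_mg_l) * 1e-6
  tn_mass <- sum(v * src$cod_mg_l / src$cn_ratio) * 1e-6
  alk_v <- sum(v * src$alk_mg_l)
  tox_v <- sum(v * src$tox_mg_l)
  if (mixing == "with_base") {
    rec <- net$receptors[r, ]
    if (is.na(rec$base_feed_l_per_day))
      stop("blend_profile: mixing = 'with_base' requires ",
           "base_feed_l_per_day on receptor '", rec$id, "'", call. = FALSE)
    b <- rec$base_feed_l_per_day
    vol <- vol + b
    cod_mass <- cod_mass + b * rec$cod_mg_l * 1e-6
    tn_mass <- tn_mass + b * rec$cod_mg_l / rec$cn_ratio * 1e-6
    alk_v <- alk_v + b * rec$alk_mg_l
    tox_v <- tox_v + b * rec$tox_mg_l
  }
  defined <- vol > 0
  structure(list(
    receptor_id = net$receptors$id[r],
    total_volume = vol,
    cod_conc = if (defined) cod_mass * 1e6 / vol else NA_real_,
    cod_mass = cod_mass,
    tn_mass = tn_mass,
    cn_ratio = if (defined && tn_mass > 0) cod_mass / tn_mass else NA_real_,
    alkalinity = if (defined) alk_v / vol else NA_real_,
    toxicity = if (defined) tox_v / vol else NA_real_,
    defined = defined), class = "ancd_blend")
}

# Per-edge precomputation shared by cost_index, feasibility and the
# solvers.  Edges are ordered as as.vector(allocation): receptor-major,
# edge e = (r - 1) * W + w.
edge_data <- function(net) {
  src <- net$sources; rec <- net$receptors
  W <- nrow(src); R <- nrow(rec); E <- W * R
  p <- net$params
  w_of <- rep(seq_len(W), times = R)
  r_of <- rep(seq_len(R), each = W)
  qc <- quality_coefficients(src, net$bounds, p)
  fsum <- qc$f1 + qc$f2 + qc$f3
  quality <- if (p$quality_weight_mode == "exponent") fsum^p$rho_q
             else p$rho_q * fsum
  lraw <- src$x_cost_per_km[w_of] * as.vector(net$distances) *
    src$social_impact[w_of]
  if (p$logistics_mode == "penalty") {
    lnorm <- if (max(lraw) > 0) lraw / max(lraw) else lraw
    combine <- pmax(0, quality[w_of] - p$rho_x * lnorm)
  } else {
    combine <- quality[w_of] + p$rho_x * lraw
  }
  cfac <- qc$t[w_of] * combine / src$volume_l_per_day[w_of]
  options <- lapply(src$volume_l_per_day, volume_options,
                    quantum = p$quantum)
  IR <- matrix(0, E, R); IR[cbind(seq_len(E), r_of)] <- 1
  IW <- matrix(0, E, W); IW[cbind(seq_len(E), w_of)] <- 1
  codm <- src$cod_mg_l[w_of] * 1e-6
  tnm <- src$cod_mg_l[w_of] / src$cn_ratio[w_of] * 1e-6
  list(W = W, R = R, E = E, w_of = w_of, r_of = r_of, qc = qc,
       cfac = cfac, options = options,
       n_opts = vapply(options, length, integer(1))[w_of],
       IR = IR, IW = IW,
       M = unname(cbind(IR, IR * codm, IR * tnm, IR * src$alk_mg_l[w_of],
                        IR * src$tox_mg_l[w_of], IW, cfac)),
       cap = rec$max_volume_l_per_day,
       vmax = src$volume_l_per_day)
}

# Base-stream constant offsets per receptor (zero for external_only).
base_offsets <- function(net, mixing) {
  rec <- net$receptors; R <- nrow(rec)
  z <- list(vol = numeric(R), codm = numeric(R), tnm = numeric(R),
            alkv = numeric(R), toxv = numeric(R))
  if (mixing == "external_only") return(z)
  if (anyNA(rec$base_feed_l_per_day))
    stop("mixing = 'with_base' requires base_feed_l_per_day on every ",
         "receptor", call. = FALSE)
  b <- rec$base_feed_l_per_day
  list(vol = b, codm = b * rec$cod_mg_l * 1e-6,
       tnm = b * rec$cod_mg_l / rec$cn_ratio * 1e-6,
       alkv = b * rec$alk_mg_l, toxv = b * rec$tox_mg_l)
}

# Batch evaluation of n candidate volume matrices (n x E), returning
# the signed/absolute index, feasibility and summed normalised
# violation magnitudes.  This is the solvers' hot path: one matrix
# product gives every per-receptor and per-source aggregate, and the
# rest is recycled-vector arithmetic (no sweep/ifelse, which dominate
# at small population sizes).
batch_evaluate <- function(vol, ed, net, mixing = "external_only") {
  n <- nrow(vol); R <- ed$R; W <- ed$W
  X <- vol %*% ed$M
  cols <- function(k) X[, (k - 1L) * R + seq_len(R), drop = FALSE]
  extvol <- cols(1L)
  codm <- cols(2L); tnm <- cols(3L); alkv <- cols(4L); toxv <- cols(5L)
  srcv <- X[, 5L * R + seq_len(W), drop = FALSE]
  bsum <- X[, 5L * R + W + 1L]
  totvol <- extvol
  if (mixing != "external_only") {
    off <- base_offsets(net, mixing)
    addc <- function(m, c) m + rep(c, each = n)
    totvol <- addc(extvol, off$vol)
    codm <- addc(codm, off$codm); tnm <- addc(tnm, off$tnm)
    alkv <- addc(alkv, off$alkv); toxv <- addc(toxv, off$toxv)
  }
  b <- net$bounds
  tol <- 1e-9
  active <- totvol > 0
  cn <- codm / tnm        # NaN only where the blend is empty
  alk <- alkv / totvol
  tox <- toxv / totvol
  capv <- rep(ed$cap, each = n)
  vmaxv <- rep(ed$vmax, each = n)
  cap_exc <- pmax(extvol - capv, 0)
  src_exc <- pmax(srcv - vmaxv, 0)
  relexc <- function(x, lo, hi) {  # summed relative violation, 0 inside
    out <- pmax(x - hi, 0) / hi
    if (lo > 0) out <- out + pmax(lo - x, 0) / lo
    out[!active] <- 0
    .rowSums(out, n, R)
  }
  viol <- .rowSums(cap_exc / rep(ed$cap, each = n), n, R) +
    .rowSums(src_exc / vmaxv, n, W) +
    relexc(cn, b$cn_min, b$cn_max) +
    relexc(alk, b$alk_min, b$alk_max) +
    relexc(tox, 0, b$tox_max)
  bad <- (extvol > capv * (1 + tol)) |
    (active & (cn < b$cn_min * (1 - tol) | cn > b$cn_max * (1 + tol) |
               alk < b$alk_min * (1 - tol) | alk > b$alk_max * (1 + tol) |
               tox > b$tox_max * (1 + tol)))
  feas <- .rowSums(bad, n, R) == 0 &
    .rowSums(srcv > vmaxv * (1 + tol), n, W) == 0
  if (net$params$single_receptor) {
    nz <- (vol > 0) %*% ed$IW
    feas <- feas & .rowSums(nz > 1, n, W) == 0
    viol <- viol + .rowSums(pmax(nz - 1, 0), n, W)
  }
  b_signed <- net$params$K * bsum
  list(b_signed = b_signed, b_abs = abs(b_signed), feasible = feas,
       violation = viol,
       extvol = extvol, cn = cn, alk = alk, tox = tox, codm = codm,
       totvol = totvol)
}

decode_volumes <- function(idxmat, ed) {
  n <- nrow(idxmat)
  vol <- matrix(0, n, ed$E)
  for (e in seq_len(ed$E))
    vol[, e] <- ed$options[[ed$w_of[e]]][idxmat[, e]]
  vol
}

#' Cost index of an allocation
#'
#' Evaluates the normalised quality-plus-logistics index: per selected
#' edge, the shipped volume normalised by the generator's daily volume,
#' times the toxicity coefficient, times the combined quality/logistics
#' term (see [objective_params()] for the combination modes). The signed
#' index carries the solver sign convention `K`; algorithms are compared
#' on its absolute value.
#'
#' @param a An `ancd_allocation`.
#' @param net An `ancd_network`.
#'
#' @return A list with `b_signed` and `b_abs`.
#' @export
cost_index <- function(a, net) {
  ed <- edge_data(net)
  bs <- net$params$K * sum(as.vector(a) * ed$cfac)
  list(b_signed = bs, b_abs = abs(bs))
}

#' Check feasibility of an allocation
#'
#' Verifies, for every receptor with nonzero intake, that the external
#' intake does not exceed the acceptable volume and that the blend's
#' C/N ratio, alkalinity and toxicity lie within the operating bounds
#' (inclusive); and, for every generator, that the total shipped volume
#' does not exceed its daily production.
#'
#' @inheritParams blend_profile
#' @return A list with `feasible` (logical) and `violations`, a data
#'   frame with columns `constraint`, `where`, `observed`, `bound`
#'   (zero rows when feasible).
#' @export
check_feasibility <- function(a, net,
                              mixing = c("external_only", "with_base")) {
  mixing <- match.arg(mixing)
  stopifnot(inherits(net, "ancd_network"))
  b <- net$bounds
  viol <- list()
  add <- function(constraint, where, observed, bound)
    viol[[length(viol) + 1]] <<- data.frame(
      constraint = constraint, where = where, observed = observed,
      bound = bound, stringsAsFactors = FALSE)
  tol <- 1e-9
  for (r in seq_len(nrow(net$receptors))) {
    rid <- net$receptors$id[r]
    extvol <- sum(a[, r])
    cap <- net$receptors$max_volume_l_per_day[r]
    if (extvol > cap * (1 + tol))
      add("volume_max", rid, extvol, cap)
    bl <- blend_profile(a, r, net, mixing = mixing)
    if (!bl$defined) next
    if (bl$cn_ratio < b$cn_min * (1 - tol))
      add("cn_min", rid, bl$cn_ratio, b$cn_min)
    if (bl$cn_ratio > b$cn_max * (1 + tol))
      add("cn_max", rid, bl$cn_ratio, b$cn_max)
    if (bl$alkalinity < b$alk_min * (1 - tol))
      add("alk_min", rid, bl$alkalinity, b$alk_min)
    if (bl$alkalinity > b$alk_max * (1 + tol))
      add("alk_max", rid, bl$alkalinity, b$alk_max)
    if (bl$toxicity > b$tox_max * (1 + tol))
      add("tox_max", rid, bl$toxicity, b$tox_max)
  }
  for (w in seq_len(nrow(net$sources))) {
    shipped <- sum(a[w, ])
    vmax <- net$sources$volume_l_per_day[w]
    if (shipped > vmax * (1 + tol))
      add("source_volume", net$sources$id[w], shipped, vmax)
    if (net$params$single_receptor && sum(a[w, ] > 0) > 1)
      add("single_receptor", net$sources$id[w], sum(a[w, ] > 0), 1)
  }
  violations <- if (length(viol) > 0) do.call(rbind, viol) else
    data.frame(constraint = character(), where = character(),
               observed = numeric(), bound = numeric(),
               stringsAsFactors = FALSE)
  list(feasible = nrow(violations) == 0, violations = violations)
}

#' Biogas production estimate
#'
#' Converts the COD mass carried by one or more blends into an expected
#' daily biogas volume, at the default conversion factor of 0.268 m3 of
#' biogas per kg of COD.
#'
#' @param blends An `ancd_blend` or a list of them.
#' @param yield Conversion factor, m3 biogas / kg COD.
#' @return Estimated biogas production, Nm3/day.
#' @export
#' @examples
#' net <- besos_network()
#' a <- allocation(net)
#' a["C1", "R1"] <- 9000
#' biogas_estimate(blend_profile(a, "R1", net))  # ~1609.8
biogas_estimate <- function(blends, yield = 0.268) {
  if (!(yield > 0))
    stop("biogas_estimate: yield must be > 0", call. = FALSE)
  if (inherits(blends, "ancd_blend")) blends <- list(blends)
  sum(vapply(blends, function(b) b$cod_mass, numeric(1))) * yield
}

# Digester working volume (m3): the recorded value, or the approximation
# HRT 20 days x (acceptable external volume + base feed), L -> m3.
digester_volumes <- function(net, hrt_days = 20) {
  rec <- net$receptors
  v <- rec$digester_m3
  base <- ifelse(is.na(rec$base_feed_l_per_day), 0,
                 rec$base_feed_l_per_day)
  approx <- hrt_days * (rec$max_volume_l_per_day + base) / 1000
  derived <- is.na(v)
  v[derived] <- approx[derived]
  attr(v, "derived") <- derived
  v
}

#' Evaluate an allocation
#'
#' Full evaluation of one allocation: cost index, feasibility with the
#' list of violations, per-receptor blend profiles, total biogas
#' estimate, per-receptor organic loading rate (kg COD per m3 of
#' digester and day; the digester volume is the recorded value or an
#' HRT-based approximation) and volume-weighted average C/N and
#' alkalinity across the receptors with intake.
#'
#' @inheritParams blend_profile
#' @return An object of class `ancd_eval`.
#' @export
evaluate_allocation <- function(a, net,
                                mixing = c("external_only", "with_base")) {
  mixing <- match.arg(mixing)
  validate_allocation(a, net)
  ci <- cost_index(a, net)
  fz <- check_feasibility(a, net, mixing = mixing)
  R <- nrow(net$receptors)
  blends <- lapply(seq_len(R), function(r)
    blend_profile(a, r, net, mixing = mixing))
  names(blends) <- net$receptors$id
  dvol <- digester_volumes(net)
  cod_mass <- vapply(blends, function(b) b$cod_mass, numeric(1))
  organic_load <- cod_mass / dvol
  vols <- vapply(blends, function(b) b$total_volume, numeric(1))
  wmean <- function(x) {
    keep <- vols > 0 & !is.na(x)
    if (!any(keep)) return(NA_real_)
    sum(x[keep] * vols[keep]) / sum(vols[keep])
  }
  structure(list(
    b_signed = ci$b_signed, b_abs = ci$b_abs,
    feasible = fz$feasible, violations = fz$violations,
    blends = blends,
    biogas_total = biogas_estimate(blends, net$params$biogas_yield),
    organic_load = organic_load,
    digester_volume_derived = attr(dvol, "derived"),
    avg_cn = wmean(vapply(blends, function(b) b$cn_ratio, numeric(1))),
    avg_alk = wmean(vapply(blends, function(b) b$alkalinity, numeric(1))),
    mixing = mixing), class = "ancd_eval")
}

#' Performance summary of an evaluation
#'
#' Flattens an evaluation into the standard benchmark metric row: best
#' index B, total biogas production, per-receptor and average organic
#' load, and volume-weighted average C/N ratio and alkalinity.
#'
#' @param ev An `ancd_eval`.
#' @param net The `ancd_network` it was evaluated on.
#' @return A one-row data frame.
#' @export
performance_summary <- function(ev, net) {
  stopifnot(inherits(ev, "ancd_eval"))
  out <- data.frame(best_b = ev$b_abs,
                    biogas_nm3_per_day = ev$biogas_total,
                    organic_load_avg = mean(ev$organic_load),
                    avg_cn = ev$avg_cn, avg_alk = ev$avg_alk,
                    feasible = ev$feasible)
  for (r in seq_along(ev$organic_load))
    out[[paste0("organic_load_", net$receptors$id[r])]] <-
      ev$organic_load[r]
  out
}

#' Penalised fitness of an allocation
#'
#' The solvers' evaluation contract: a feasible allocation scores its
#' absolute cost index; an infeasible one scores 0 under the death
#' penalty (default), or `max(0, b_abs - lambda * V)` under the linear
#' penalty, where `V` sums the normalised violation magnitudes.
#'
#' @inheritParams blend_profile
#' @param penalty `"death"` or `"linear"`.
#' @param lambda Linear-penalty weight.
#' @return A single non-negative number.
#' @export
fitness <- function(a, net, penalty = c("death", "linear"), lambda = 1,
                    mixing = "external_only") {
  penalty <- match.arg(penalty)
  ed <- edge_data(net)
  res <- batch_evaluate(matrix(as.vector(a), nrow = 1), ed, net, mixing)
  fitness_from_batch(res, penalty, lambda)[1]
}

fitness_from_batch <- function(res, penalty, lambda) {
  if (penalty == "death") {
    res$b_abs * res$feasible
  } else {
    out <- pmax(res$b_abs - lambda * res$violation, 0)
    out[res$feasible] <- res$b_abs[res$feasible]
    out
  }
}
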