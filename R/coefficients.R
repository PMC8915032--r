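#' Dimensionless substrate quality coefficients
#'
#' Computes, per generator, the four dimensionless coefficients entering
#' the cost index: `f1` (biogas potential, from COD), `f2` (COD/TN
#' ratio), `f3` (alkalinity) and `t` (toxicity). The shipped default
#' (`coefficient_mode = "fallback"`) uses:
#'
#' * `f1 = cod / cod_ref`, with `cod_ref` the maximum COD in the network
#'   unless overridden, so the richest substrate scores 1;
#' * `f2`: trapezoidal membership of the C/N ratio on the operating
#'   window — 1 on the plateau `[cn_min, cn_max]`, falling linearly to 0
#'   over shoulders of configurable width (default half the plateau);
#' * `f3`: the same trapezoidal form for alkalinity on
#'   `[alk_min, alk_max]`;
#' * `t = max(0, 1 - toxicity / tox_max)`, so a substrate at or above
#'   the lead ceiling contributes nothing.
#'
#' `coefficient_mode = "figure2"` instead applies user-supplied
#' equation functions carried in `params$figure2` (a named list of
#' `f1`, `f2`, `f3`, `t`, each `function(source, bounds)`); it errors if
#' they have not been configured.
#'
#' @param source One-row data frame (or the full sources table) of
#'   generators, as in an `ancd_network`.
#' @param bounds An [constraint_bounds()] object.
#' @param params An [objective_params()] object.
#' @param cod_ref Reference COD overriding `params$cod_ref`.
#'
#' @return A data frame with columns `f1`, `f2`, `f3`, `t`, one row per
#'   source row.
#' @export
#' @examples
#' net <- besos_network()
#' quality_coefficients(net$sources, net$bounds, net$params)
quality_coefficients <- function(source, bounds = constraint_bounds(),
                                 params = objective_params(),
                                 cod_ref = NULL) {
  stopifnot(inherits(bounds, "ancd_bounds"), inherits(params, "ancd_params"))
  source <- as.data.frame(source)
  if (params$coefficient_mode == "figure2") {
    fns <- params$figure2
    if (!is.list(fns) || !all(c("f1", "f2", "f3", "t") %in% names(fns)))
      stop("quality_coefficients: coefficient_mode = 'figure2' requires ",
           "transcribed equations in params$figure2 (named list of ",
           "functions f1, f2, f3, t)", call. = FALSE)
    return(data.frame(f1 = fns$f1(source, bounds),
                      f2 = fns$f2(source, bounds),
                      f3 = fns$f3(source, bounds),
                      t  = fns$t(source, bounds)))
  }
  ref <- cod_ref
  if (is.null(ref)) ref <- params$cod_ref
  if (is.null(ref)) ref <- max(source$cod_mg_l)
  cn_sh <- params$cn_shoulder
  if (is.null(cn_sh)) cn_sh <- (bounds$cn_max - bounds$cn_min) / 2
  alk_sh <- params$alk_shoulder
  if (is.null(alk_sh)) alk_sh <- (bounds$alk_max - bounds$alk_min) / 2
  data.frame(
    f1 = source$cod_mg_l / ref,
    f2 = trapezoid_membership(source$cn_ratio, bounds$cn_min, bounds$cn_max,
                              cn_sh),
    f3 = trapezoid_membership(source$alk_mg_l, bounds$alk_min,
                              bounds$alk_max, alk_sh),
    t = pmax(0, 1 - source$tox_mg_l / bounds$tox_max))
}

# 1 on [lo, hi], linear shoulders of width `shoulder` on either side,
# 0 beyond.
trapezoid_membership <- function(x, lo, hi, shoulder) {
  below <- pmax(0, pmin(1, (x - (lo - shoulder)) / shoulder))
  above <- pmax(0, pmin(1, ((hi + shoulder) - x) / shoulder))
  pmin(below, above)
}
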