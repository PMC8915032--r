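#' @export
print.ancd_network <- function(x, ...) {
  cat("Anaerobic co-digestion network\n")
  cat(sprintf("  %d generators (%d sludge, %d industrial), %d receptors, %d edges\n",
              nrow(x$sources), sum(x$sources$kind == "sludge"),
              sum(x$sources$kind == "industrial"), nrow(x$receptors),
              nrow(x$sources) * nrow(x$receptors)))
  cat(sprintf("  total generator volume %s L/day, total acceptance capacity %s L/day\n",
              format(sum(x$sources$volume_l_per_day), big.mark = ","),
              format(sum(x$receptors$max_volume_l_per_day),
                     big.mark = ",")))
  cat(sprintf("  blend bounds: C/N [%g, %g], alkalinity [%g, %g] mg/L, toxicity <= %g mg Pb/L\n",
              x$bounds$cn_min, x$bounds$cn_max, x$bounds$alk_min,
              x$bounds$alk_max, x$bounds$tox_max))
  invisible(x)
}

#' @export
print.ancd_run <- function(x, ...) {
  cat(sprintf("<%s run> seed %d: ", toupper(x$algorithm), x$seed))
  if (x$feasible_found)
    cat(sprintf("best |B| = %.6g (feasible)\n", x$best_b))
  else cat("no feasible solution found\n")
  invisible(x)
}

#' @export
print.ancd_campaign <- function(x, ...) {
  cat(sprintf("%s campaign: %d repetition(s) of %d x %d\n",
              toupper(x$algorithm), x$config$repetitions,
              x$config$population, x$config$iterations))
  if (x$feasible)
    cat(sprintf("  best |B| = %.6g (mean over repetitions %.6g)\n",
                x$best$best_b, x$mean_best_b))
  else cat("  no repetition found a feasible solution\n")
  invisible(x)
}

#' @export
summary.ancd_campaign <- function(object, net = NULL, ...) {
  bb <- vapply(object$runs, function(r) r$best_b, numeric(1))
  cat(sprintf("%s campaign over %d repetitions\n",
              toupper(object$algorithm), object$config$repetitions))
  cat(sprintf("  best_b per repetition: %s\n",
              paste(signif(bb, 5), collapse = " ")))
  if (object$feasible && !is.null(net)) {
    ev <- evaluate_allocation(object$best$best_allocation, net,
                              mixing = object$mixing)
    print(performance_summary(ev, net))
  }
  invisible(object)
}

#' Extract the winning allocation of a campaign
#'
#' @param object An `ancd_campaign`.
#' @param ... Unused.
#' @return The best feasible `ancd_allocation`, or `NULL` when the
#'   campaign found none.
#' @export
coef.ancd_campaign <- function(object, ...) {
  if (!object$feasible) return(NULL)
  object$best$best_allocation
}

#' Plot the convergence traces of a campaign
#'
#' Draws the best-so-far absolute cost index against iteration for every
#' repetition.
#'
#' @param x An `ancd_campaign`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ancd_campaign <- function(x, ...) {
  tr <- lapply(x$runs, function(r) r$iteration_trace$best_b)
  m <- do.call(cbind, tr)
  graphics::matplot(m, type = "l", lty = 1,
                    xlab = "iteration", ylab = "best |B| so far",
                    main = sprintf("%s campaign convergence",
                                   toupper(x$algorithm)), ...)
  invisible(x)
}

#' @export
print.ancd_blend <- function(x, ...) {
  cat(sprintf("Blend at %s: %s L/day", x$receptor_id,
              format(x$total_volume, big.mark = ",")))
  if (x$defined)
    cat(sprintf(" | COD %.0f mg/L (%.1f kg/d), C/N %.1f, alk %.0f mg/L, tox %.3g mg Pb/L\n",
                x$cod_conc, x$cod_mass, x$cn_ratio, x$alkalinity,
                x$toxicity))
  else cat(" (empty; concentrations undefined)\n")
  invisible(x)
}

#' @export
print.ancd_eval <- function(x, ...) {
  cat(sprintf("Allocation evaluation: |B| = %.6g, %s\n", x$b_abs,
              if (x$feasible) "feasible" else
                sprintf("INFEASIBLE (%d violation(s))",
                        nrow(x$violations))))
  cat(sprintf("  biogas %.1f Nm3/day, avg C/N %.1f, avg alkalinity %.0f mg/L\n",
              x$biogas_total, x$avg_cn, x$avg_alk))
  invisible(x)
}

#' Export an evaluation as structured text
#'
#' Writes the full evaluation (index, feasibility, violations, blends,
#' biogas, organic loads, averages) as JSON.
#'
#' @param ev An `ancd_eval`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(ev, path) {
  stopifnot(inherits(ev, "ancd_eval"))
  out <- ev
  out$blends <- lapply(ev$blends, function(b) unclass(b))
  class(out) <- NULL
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  invisible(path)
}
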