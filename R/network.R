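#' Assemble a co-digestion case network
#'
#' Builds the complete bipartite network of W waste generators and R
#' receptor plants: every generator carries a road distance to every
#' receptor, so the network has `W * R` edges, each with its own
#' discrete set of shippable volumes.
#'
#' @param sources Data frame of waste generators, one row each, with
#'   columns `id`, `kind` (`"sludge"` or `"industrial"`),
#'   `volume_l_per_day`, `cod_mg_l`, `cn_ratio`, `alk_mg_l`, `tox_mg_l`
#'   and optionally `x_cost_per_km` (transport cost rate, default 1) and
#'   `social_impact` (integer 1-3, default 1).
#' @param receptors Data frame of receptor plants with columns `id`,
#'   `max_volume_l_per_day` (acceptable external intake) and own-sludge
#'   characterisation `cod_mg_l`, `cn_ratio`, `alk_mg_l`, `tox_mg_l`,
#'   plus optional `base_feed_l_per_day` and `digester_m3`.
#' @param distances Numeric W x R matrix of road distances in km;
#'   rows ordered and named as `sources$id`, columns as `receptors$id`.
#' @param bounds An [constraint_bounds()] object.
#' @param params An [objective_params()] object.
#'
#' @return An object of class `ancd_network` with elements `sources`,
#'   `receptors`, `distances`, `bounds`, `params`.
#' @export
case_network <- function(sources, receptors, distances,
                         bounds = constraint_bounds(),
                         params = objective_params()) {
  stopifnot(inherits(bounds, "ancd_bounds"), inherits(params, "ancd_params"))
  sources <- validate_sources(sources)
  receptors <- validate_receptors(receptors)
  distances <- as.matrix(distances)
  storage.mode(distances) <- "double"
  if (nrow(distances) != nrow(sources) || ncol(distances) != nrow(receptors))
    stop("case_network: distance matrix must be ", nrow(sources), " x ",
         nrow(receptors), call. = FALSE)
  if (is.null(rownames(distances))) rownames(distances) <- sources$id
  if (is.null(colnames(distances))) colnames(distances) <- receptors$id
  if (!identical(rownames(distances), sources$id) ||
      !identical(colnames(distances), receptors$id))
    stop("case_network: distance matrix dimnames must match source and ",
         "receptor ids", call. = FALSE)
  bad <- which(!is.finite(distances) | distances <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("case_network: missing or non-positive distance for source '",
         sources$id[bad[1, 1]], "', receptor '", receptors$id[bad[1, 2]],
         "'", call. = FALSE)
  structure(list(sources = sources, receptors = receptors,
                 distances = distances, bounds = bounds, params = params),
            class = "ancd_network")
}

validate_sources <- function(sources) {
  sources <- as.data.frame(sources, stringsAsFactors = FALSE)
  required <- c("id", "kind", "volume_l_per_day", "cod_mg_l", "cn_ratio",
                "alk_mg_l", "tox_mg_l")
  miss <- setdiff(required, names(sources))
  if (length(miss) > 0)
    stop("sources: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(sources$x_cost_per_km)) sources$x_cost_per_km <- 1
  if (is.null(sources$social_impact)) sources$social_impact <- 1L
  sources$id <- as.character(sources$id)
  if (anyDuplicated(sources$id))
    stop("sources: duplicate id '",
         sources$id[duplicated(sources$id)][1], "'", call. = FALSE)
  num_cols <- c("volume_l_per_day", "cod_mg_l", "cn_ratio", "alk_mg_l",
                "tox_mg_l", "x_cost_per_km", "social_impact")
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(sources[[cn]]))
    bad <- which(is.na(v))
    if (length(bad) > 0)
      stop("sources: non-numeric value in column '", cn, "', row ", bad[1],
           " (id '", sources$id[bad[1]], "')", call. = FALSE)
    sources[[cn]] <- v
  }
  check_pos <- function(cn) {
    bad <- which(sources[[cn]] <= 0)
    if (length(bad) > 0)
      stop("sources: column '", cn, "' must be > 0; violated in row ",
           bad[1], " (id '", sources$id[bad[1]], "', value ",
           sources[[cn]][bad[1]], ")", call. = FALSE)
  }
  check_pos("volume_l_per_day"); check_pos("cod_mg_l"); check_pos("cn_ratio")
  if (any(sources$alk_mg_l < 0) || any(sources$tox_mg_l < 0))
    stop("sources: alkalinity and toxicity must be >= 0", call. = FALSE)
  if (!all(sources$kind %in% c("sludge", "industrial")))
    stop("sources: kind must be 'sludge' or 'industrial'", call. = FALSE)
  if (!all(sources$social_impact %in% 1:3))
    stop("sources: social_impact must be 1, 2 or 3", call. = FALSE)
  rownames(sources) <- NULL
  sources
}

validate_receptors <- function(receptors) {
  receptors <- as.data.frame(receptors, stringsAsFactors = FALSE)
  required <- c("id", "max_volume_l_per_day", "cod_mg_l", "cn_ratio",
                "alk_mg_l", "tox_mg_l")
  miss <- setdiff(required, names(receptors))
  if (length(miss) > 0)
    stop("receptors: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(receptors$base_feed_l_per_day))
    receptors$base_feed_l_per_day <- NA_real_
  if (is.null(receptors$digester_m3)) receptors$digester_m3 <- NA_real_
  receptors$id <- as.character(receptors$id)
  if (anyDuplicated(receptors$id))
    stop("receptors: duplicate id '",
         receptors$id[duplicated(receptors$id)][1], "'", call. = FALSE)
  num_cols <- setdiff(names(receptors), "id")
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(receptors[[cn]]))
    bad <- which(is.na(v) & !is.na(receptors[[cn]]))
    if (length(bad) > 0)
      stop("receptors: non-numeric value in column '", cn, "', row ",
           bad[1], call. = FALSE)
    receptors[[cn]] <- v
  }
  if (any(receptors$max_volume_l_per_day <= 0))
    stop("receptors: max_volume_l_per_day must be > 0", call. = FALSE)
  for (cn in c("base_feed_l_per_day", "digester_m3")) {
    v <- receptors[[cn]]
    if (any(!is.na(v) & v <= 0))
      stop("receptors: column '", cn, "', when present, must be > 0",
           call. = FALSE)
  }
  rownames(receptors) <- NULL
  receptors
}

#' Load a case network from delimited text files
#'
#' Reads the generator table (with `dist_<receptor-id>_km` distance
#' columns) and the receptor table, validates every invariant and
#' returns the assembled network. Row order is preserved. Missing
#' optional columns (`x_cost_per_km`, `social_impact`,
#' `base_feed_l_per_day`, `digester_m3`) are filled with defaults.
#'
#' @param sources_path Path to the generator CSV (or a data frame).
#' @param receptors_path Path to the receptor CSV (or a data frame).
#' @inheritParams case_network
#'
#' @return An `ancd_network`.
#' @export
#' @examples
#' net <- besos_network()
#' nrow(net$sources)   # 19 generators
#' net$receptors$max_volume_l_per_day
load_case_network <- function(sources_path, receptors_path,
                              bounds = constraint_bounds(),
                              params = objective_params()) {
  read_tbl <- function(x) {
    if (is.data.frame(x)) return(x)
    if (!file.exists(x))
      stop("load_case_network: file not found: ", x, call. = FALSE)
    utils::read.csv(x, stringsAsFactors = FALSE, check.names = FALSE)
  }
  src <- read_tbl(sources_path)
  rec <- read_tbl(receptors_path)
  rec_ids <- as.character(rec$id)
  dist_cols <- paste0("dist_", rec_ids, "_km")
  miss <- setdiff(dist_cols, names(src))
  if (length(miss) > 0)
    stop("load_case_network: generator table lacks distance column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  distances <- as.matrix(src[, dist_cols, drop = FALSE])
  storage.mode(distances) <- "double"
  rownames(distances) <- as.character(src$id)
  colnames(distances) <- rec_ids
  src <- src[, setdiff(names(src), dist_cols), drop = FALSE]
  case_network(src, rec, distances, bounds = bounds, params = params)
}

#' The bundled Besos-basin case network
#'
#' The characterised case study shipped with the package: 12 wastewater
#' treatment plants producing undigested sewage sludge (W1-W12), 7
#' industrial substrate generators (C1-C7) and 3 receptor plants with
#' spare digestion capacity (R1-R3), with road distances for all 57
#' generator-receptor pairs.
#'
#' @inheritParams case_network
#' @return An `ancd_network` with 19 sources and 3 receptors.
#' @export
besos_network <- function(bounds = constraint_bounds(),
                          params = objective_params()) {
  load_case_network(
    system.file("extdata", "besos_generators.csv", package = "ancdnet",
                mustWork = TRUE),
    system.file("extdata", "besos_receptors.csv", package = "ancdnet",
                mustWork = TRUE),
    bounds = bounds, params = params)
}

#' Discrete volume options for a generator
#'
#' The selectable daily volumes for one generator: multiples of the
#' quantum `0, q, 2q, ..., floor(V/q) * q`, with the exact daily volume
#' `V` appended as a final partial quantum when `V` is not a multiple of
#' `q`, so full utilisation is always representable.
#'
#' @param volume Generator daily volume V, L/day (or a `SubstrateSource`
#'   row; the `volume_l_per_day` field is used).
#' @param quantum Volume quantum q, L/day.
#'
#' @return Strictly increasing numeric vector starting at 0 and ending
#'   at `volume`.
#' @export
#' @examples
#' volume_options(4400, 1000)  # 0 1000 2000 3000 4000 4400
volume_options <- function(volume, quantum = 1000) {
  if (is.data.frame(volume) || is.list(volume))
    volume <- volume$volume_l_per_day
  if (!(quantum > 0))
    stop("volume_options: quantum must be > 0", call. = FALSE)
  if (!(volume > 0))
    stop("volume_options: volume must be > 0", call. = FALSE)
  lw <- floor(volume / quantum)
  opts <- seq(0, lw) * quantum
  if (opts[length(opts)] < volume) opts <- c(opts, volume)
  opts
}

#' Create an allocation
#'
#' An allocation is the decision variable of the blending problem: the
#' volume (L/day) shipped from each generator to each receptor, stored
#' as a W x R matrix with source ids as row names and receptor ids as
#' column names. Every entry must be one of the generator's discrete
#' volume options and each generator's row total must not exceed its
#' daily volume.
#'
#' @param net An `ancd_network`.
#' @param volumes Either a scalar (recycled; default 0) or a W x R
#'   matrix of volumes.
#'
#' @return An object of class `ancd_allocation` (a named matrix).
#' @export
allocation <- function(net, volumes = 0) {
  stopifnot(inherits(net, "ancd_network"))
  W <- nrow(net$sources); R <- nrow(net$receptors)
  m <- matrix(volumes, nrow = W, ncol = R,
              dimnames = list(net$sources$id, net$receptors$id))
  a <- structure(m, class = c("ancd_allocation", "matrix"))
  validate_allocation(a, net)
  a
}

#' Validate an allocation against a network
#'
#' Checks structural validity: matching dimensions and ids, non-negative
#' entries, membership of each entry in the generator's volume option
#' set, and per-generator conservation (row totals not exceeding the
#' daily volume).
#'
#' @param a An `ancd_allocation` (or plain matrix with dimnames).
#' @param net An `ancd_network`.
#' @return `a`, invisibly, if valid; otherwise an error.
#' @export
validate_allocation <- function(a, net) {
  stopifnot(inherits(net, "ancd_network"))
  W <- nrow(net$sources); R <- nrow(net$receptors)
  if (!is.matrix(a) || nrow(a) != W || ncol(a) != R)
    stop("allocation must be a ", W, " x ", R, " matrix", call. = FALSE)
  if (!identical(rownames(a), net$sources$id) ||
      !identical(colnames(a), net$receptors$id))
    stop("allocation dimnames must match the network's source and ",
         "receptor ids", call. = FALSE)
  if (any(a < 0))
    stop("allocation entries must be >= 0", call. = FALSE)
  tol <- 1e-9
  for (w in seq_len(W)) {
    opts <- volume_options(net$sources$volume_l_per_day[w],
                           net$params$quantum)
    for (r in seq_len(R)) {
      v <- a[w, r]
      if (min(abs(opts - v)) > tol * max(1, v))
        stop("allocation entry (", net$sources$id[w], ", ",
             net$receptors$id[r], ") = ", v,
             " is not a member of the generator's volume option set",
             call. = FALSE)
    }
    if (sum(a[w, ]) > net$sources$volume_l_per_day[w] * (1 + tol))
      stop("allocation ships more than generator '", net$sources$id[w],
           "' produces (", sum(a[w, ]), " > ",
           net$sources$volume_l_per_day[w], " L/day)", call. = FALSE)
  }
  if (net$params$single_receptor && any(rowSums(a > 0) > 1))
    stop("allocation splits a generator across receptors but the network ",
         "is configured for single-receptor assignment", call. = FALSE)
  invisible(a)
}

#' Write / read an allocation as structured text
#'
#' Serialises an allocation as a JSON array of
#' `{source, receptor, volume}` records (all entries, including zeros)
#' at full numeric precision; reading back reproduces the allocation
#' exactly. Writing validates the allocation against the network first
#' and refuses invalid allocations.
#'
#' @param a An `ancd_allocation`.
#' @param path Output (input) file path.
#' @param net The `ancd_network` the allocation belongs to.
#'
#' @return `write_allocation` returns `path` invisibly;
#'   `read_allocation` returns an `ancd_allocation`.
#' @export
write_allocation <- function(a, path, net) {
  validate_allocation(a, net)
  rec <- data.frame(source = rep(rownames(a), times = ncol(a)),
                    receptor = rep(colnames(a), each = nrow(a)),
                    volume = as.vector(a), stringsAsFactors = FALSE)
  jsonlite::write_json(rec, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_allocation
#' @export
read_allocation <- function(path, net) {
  stopifnot(inherits(net, "ancd_network"))
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown_s <- setdiff(rec$source, net$sources$id)
  unknown_r <- setdiff(rec$receptor, net$receptors$id)
  if (length(unknown_s) > 0 || length(unknown_r) > 0)
    stop("read_allocation: unknown id(s): ",
         paste(c(unknown_s, unknown_r), collapse = ", "), call. = FALSE)
  a <- allocation(net, 0)
  a[cbind(match(rec$source, net$sources$id),
          match(rec$receptor, net$receptors$id))] <- rec$volume
  validate_allocation(a, net)
  a
}

#' Write a case network back to delimited text
#'
#' Writes the generator table (with `dist_<id>_km` columns) and the
#' receptor table as CSV at full double precision, so that
#' [load_case_network()] round-trips losslessly. Used to materialise
#' scenario-transformed and synthetic datasets.
#'
#' @param net An `ancd_network`.
#' @param sources_path,receptors_path Output file paths.
#' @return Invisibly, `c(sources_path, receptors_path)`.
#' @export
write_case_network <- function(net, sources_path, receptors_path) {
  stopifnot(inherits(net, "ancd_network"))
  fmt <- function(df) {
    for (cn in names(df))
      if (is.numeric(df[[cn]])) {
        x <- trimws(formatC(df[[cn]], digits = 17, format = "g"))
        x[is.na(df[[cn]])] <- NA
        df[[cn]] <- x
      }
    df
  }
  src <- net$sources
  for (r in seq_len(ncol(net$distances)))
    src[[paste0("dist_", colnames(net$distances)[r], "_km")]] <-
      net$distances[, r]
  utils::write.csv(fmt(src), sources_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(net$receptors), receptors_path, row.names = FALSE,
                   quote = FALSE)
  invisible(c(sources_path, receptors_path))
}
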