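#' Read a binding-network configuration from YAML
#'
#' The configuration lists `species` (each with `name` and `conc_uM`),
#' `reactions` (each with `a`, `b`, `complex`, `Kd_uM` and optional `kf`)
#' and optionally a model `variant` label.
#'
#' @param path YAML file path.
#' @return a [reaction_network()]; the `variant` label, if present, is
#'   attached as an attribute.
#' @export
read_network_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$species)) stop("configuration lacks 'species'",
                                 call. = FALSE)
  species <- dplyr::bind_rows(lapply(cfg$species, tibble::as_tibble))
  reactions <- if (!is.null(cfg$reactions)) {
    dplyr::bind_rows(lapply(cfg$reactions, tibble::as_tibble))
  } else NULL
  net <- reaction_network(species, reactions)
  attr(net, "variant") <- cfg$variant
  net
}

#' Write a steady-state report as TSV
#'
#' @param steady_state named concentration vector from
#'   [solve_steady_state()].
#' @param path output TSV path (columns `species`, `concentration_uM`).
#' @return invisibly, the path.
#' @export
write_steady_state_tsv <- function(steady_state, path) {
  utils::write.table(
    data.frame(species = names(steady_state),
               concentration_uM = as.numeric(steady_state)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rate dataset from TSV
#'
#' Expects columns `condition`, `atp_uM`, `activity_nmol_min_mg` (or
#' `activity`).
#'
#' @param path TSV path.
#' @return tibble with `condition`, `atp_uM`, `activity`.
#' @export
read_rate_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if ("activity_nmol_min_mg" %in% names(df) && !"activity" %in% names(df)) {
    df$activity <- df$activity_nmol_min_mg
  }
  stopifnot(all(c("condition", "atp_uM", "activity") %in% names(df)))
  tibble::as_tibble(df[c("condition", "atp_uM", "activity")])
}

#' Write a rate dataset as TSV
#'
#' @param data tibble with `condition`, `atp_uM`, `activity`.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_rate_tsv <- function(data, path) {
  out <- data.frame(condition = data$condition, atp_uM = data$atp_uM,
                    activity_nmol_min_mg = data$activity)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a fit result to JSON
#'
#' Stores parameters, bounds, seed and residual so a fit can be reproduced
#' and its residual re-evaluated.
#'
#' @param fit a `rim_fit` from [fit_model_params()].
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "rim_fit"))
  jsonlite::write_json(
    list(variant = fit$variant, params = fit$params,
         residual = fit$residual, seed = fit$seed, bounds = fit$bounds),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
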