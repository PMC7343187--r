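#' Composite multi-state Michaelis-Menten rate
#'
#' The observed ATPase specific activity of a mixture of RimK activation
#' states is additive over states: `rate(S) = sum_s w_s kcat_s S / (Km_s + S)`
#' where `w_s` is the steady-state weight of state `s` (concentration, or
#' fraction of total enzyme when the kcat values are specific activities).
#' As `S -> Inf` the rate tends to `sum_s w_s kcat_s`.
#'
#' @param states a `kinetic_state_set` (see [state_weights()]) or any data
#'   frame with columns `kcat`, `Km`, `weight`.
#' @param substrate_conc ATP concentration(s) in uM; must be non-negative.
#' @return numeric vector of rates, one per substrate concentration.
#' @export
composite_rate <- function(states, substrate_conc) {
  stopifnot(all(c("kcat", "Km", "weight") %in% names(states)))
  if (any(substrate_conc < 0)) {
    stop("substrate concentration must be non-negative", call. = FALSE)
  }
  if (any(states$kcat < 0) || any(states$Km <= 0) || any(states$weight < 0)) {
    stop("invalid kinetic state set: kcat >= 0, Km > 0, weight >= 0",
         call. = FALSE)
  }
  vapply(substrate_conc,
         function(S) sum(states$weight * states$kcat * S / (states$Km + S)),
         numeric(1))
}

#' Construct a rate dataset
#'
#' @param condition condition label (which ligands are present).
#' @param atp_uM substrate concentrations in uM; strictly positive, distinct.
#' @param activity specific activities in nmol ATP/min/mg; non-negative.
#' @return a tibble of class `rate_dataset`.
#' @export
rate_dataset <- function(condition, atp_uM, activity) {
  stopifnot(length(atp_uM) == length(activity))
  if (any(atp_uM <= 0)) stop("substrate concentrations must be > 0",
                             call. = FALSE)
  if (anyDuplicated(atp_uM)) stop("substrate concentrations must be distinct",
                                  call. = FALSE)
  if (any(activity < 0)) stop("activities must be >= 0", call. = FALSE)
  out <- tibble::tibble(condition = condition, atp_uM = atp_uM,
                        activity = activity)
  class(out) <- c("rate_dataset", class(out))
  out
}

#' Single-curve Michaelis-Menten fit
#'
#' Nonlinear least-squares estimate of `(Vmax, Km)` from a rate dataset,
#' via the self-starting Michaelis-Menten model with a Levenberg-Marquardt
#' fallback. On noiseless model-generated data the generating parameters are
#' recovered to numerical precision.
#'
#' @param data a [rate_dataset()] or data frame with `atp_uM`, `activity`.
#' @return named numeric `c(Vmax = , Km = )` with attribute `rss`.
#' @export
michaelis_menten_fit <- function(data) {
  stopifnot(all(c("atp_uM", "activity") %in% names(data)))
  s <- data$atp_uM
  v <- data$activity
  if (length(unique(s)) < 3) {
    stop("need >= 3 distinct substrate concentrations", call. = FALSE)
  }
  if (all(v == 0)) {
    warning("all activities are zero; Vmax = 0, Km undetermined")
    return(structure(c(Vmax = 0, Km = NA_real_), rss = 0))
  }
  df <- data.frame(S = s, v = v)
  fit <- tryCatch(
    stats::nls(v ~ stats::SSmicmen(S, Vm, K), data = df),
    error = function(e) {
      minpack.lm::nlsLM(v ~ Vm * S / (K + S), data = df,
                        start = list(Vm = max(v) * 1.2, K = stats::median(s)),
                        lower = c(0, 1e-9))
    })
  cf <- stats::coef(fit)
  structure(c(Vmax = unname(cf[1]), Km = unname(cf[2])),
            rss = sum(stats::resid(fit)^2))
}

# Default condition registry for the multi-condition ATPase experiment:
# RimA and cdG titrations around their Kds plus the canonical four
# combinations, all at 1 uM RimK.
#' Default condition registry for RimK ATPase experiments
#'
#' Each condition maps to the total concentrations (uM) of the elementary
#' species present. The set includes the canonical combinations (basal,
#' +RimA, +cdG 25 uM, +both) and RimA/cdG titration points so that the
#' binding constants are identifiable from rate data alone.
#'
#' @return named list of named concentration vectors.
#' @export
default_conditions <- function() {
  list(
    basal        = c(RimK = 1, RimA = 0,   cdG = 0),
    rimA_0.1     = c(RimK = 1, RimA = 0.1, cdG = 0),
    rimA_0.3     = c(RimK = 1, RimA = 0.3, cdG = 0),
    rimA_1       = c(RimK = 1, RimA = 1,   cdG = 0),
    rimA_3       = c(RimK = 1, RimA = 3,   cdG = 0),
    cdG_0.3      = c(RimK = 1, RimA = 0,   cdG = 0.3),
    cdG_1        = c(RimK = 1, RimA = 0,   cdG = 1),
    cdG_3        = c(RimK = 1, RimA = 0,   cdG = 3),
    cdG_25       = c(RimK = 1, RimA = 0,   cdG = 25),
    rimA1_cdG25  = c(RimK = 1, RimA = 1,   cdG = 25)
  )
}

# Reaction Kd vector for a variant, mirroring make_model's construction
# order (thermodynamic closure included), without re-validating the network.
.reaction_kds <- function(variant, kd, alpha = 1) {
  base <- c(kd[["Kd_rimk_rima"]], kd[["Kd_rimk_cdg"]])
  switch(variant,
         two_state = base,
         four_state = c(base, kd[["Kd_rimk_cdg"]] * alpha,
                        kd[["Kd_rimk_rima"]] * alpha),
         rimb_extended = c(base, kd[["Kd_rimk_cdg"]] * alpha,
                           kd[["Kd_rimk_rima"]] * alpha,
                           kd[["Kd_rimk_rimb"]]),
         trigger = c(base, kd[["Kd_rimk_cdg"]] * alpha,
                     kd[["Kd_rimk_rima"]] * alpha,
                     kd[["Kd_rima_cdg"]]))
}

# Pooled design information used by the fitting objective: for given Kd
# overrides, the per-condition normalized state occupancies (which depend
# only on the Kds), then for given Km the kcat vector enters linearly.
# Operates on a pre-built template model for speed: only Kds and total
# concentrations change between objective evaluations.
.fit_design <- function(template, kd_par, conditions, data) {
  net <- template$network
  net$reactions$Kd_uM <- .reaction_kds(template$variant, as.list(kd_par),
                                       template$params$alpha)
  occ <- lapply(conditions, function(cond) {
    idx <- match(names(cond), net$species$name)
    net$species$conc_uM[idx] <- unname(cond)
    ss <- .equilibrium_speciation(net)
    w <- vapply(template$states$species, function(sp) sum(ss[sp]), numeric(1))
    total <- sum(moiety_totals(net)["RimK"])
    if (total > 0) w / total else w * 0
  })
  do.call(rbind, occ[data$condition])  # n_obs x n_states
}

# kcat by linear least squares given occupancy/Km design; states never
# populated under the conditions give aliased (NA) coefficients -> 0
.profiled_kcat <- function(X, y, kcat_bounds) {
  kcat <- stats::lm.fit(X, y)$coefficients
  kcat[is.na(kcat)] <- 0
  pmin(pmax(kcat, kcat_bounds[1]), kcat_bounds[2])
}

.kd_names_for <- function(variant) {
  switch(variant,
         two_state = c("Kd_rimk_cdg", "Kd_rimk_rima"),
         four_state = c("Kd_rimk_cdg", "Kd_rimk_rima"),
         rimb_extended = c("Kd_rimk_cdg", "Kd_rimk_rima", "Kd_rimk_rimb"),
         trigger = c("Kd_rimk_cdg", "Kd_rimk_rima", "Kd_rima_cdg"))
}

#' Global fit of a RimK kinetic model to pooled rate data
#'
#' Fits the free binding constants and the per-state Michaelis-Menten
#' parameters of a model variant to rate datasets from several conditions
#' jointly, by minimising the pooled squared residual. The search is a seeded
#' differential-evolution stage over `log10(Kd)` and `log10(Km)` (the kcat
#' vector is profiled out by linear least squares at each point, since state
#' occupancies depend only on the Kds), followed by an `L-BFGS-B` polish.
#' Results are deterministic given `seed`.
#'
#' @param variant model variant label (see [make_model()]).
#' @param data a tibble with columns `condition`, `atp_uM`, `activity`
#'   (e.g. stacked [rate_dataset()] rows, or [gen_rate_data()] output).
#' @param conditions named list mapping condition labels to total
#'   concentration vectors; defaults to [default_conditions()].
#' @param bounds list with elements `Kd`, `Km`, `kcat`, each `c(lower,
#'   upper)`; defaults `Kd [1e-3, 1e3]` uM, `Km [1, 1e5]` uM,
#'   `kcat [0, 1e5]`.
#' @param seed integer seed for the stochastic search.
#' @param control list: `pop_size`, `generations` for the evolution stage.
#' @return an object of class `rim_fit`: list with `variant`, `params`
#'   (named list: Kds, per-state `kcat` and `Km`), `residual` (pooled SSR),
#'   `seed`, `bounds`, and the `data`/`conditions` used.
#' @export
fit_model_params <- function(variant, data, conditions = default_conditions(),
                             bounds = NULL, seed = 1, control = list()) {
  stopifnot(all(c("condition", "atp_uM", "activity") %in% names(data)))
  missing_cond <- setdiff(unique(data$condition), names(conditions))
  if (length(missing_cond) > 0) {
    stop("conditions without registry entries: ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  bounds <- utils::modifyList(
    list(Kd = c(1e-3, 1e3), Km = c(1, 1e5), kcat = c(0, 1e5)), bounds %||% list())
  if (any(vapply(bounds, function(b) b[2] <= b[1], logical(1)))) {
    stop("bounds exclude any feasible point", call. = FALSE)
  }
  kd_names <- .kd_names_for(variant)
  template <- make_model(variant)
  n_states <- nrow(template$states)
  ctl <- utils::modifyList(list(pop_size = 36, generations = 100), control)

  S <- data$atp_uM
  y <- data$activity
  conds_used <- conditions[unique(data$condition)]

  # theta = c(log10 Kds, log10 Km per state); kcat profiled by least squares
  obj <- function(theta) {
    kd <- stats::setNames(10^theta[seq_along(kd_names)], kd_names)
    km <- 10^theta[-seq_along(kd_names)]
    W <- tryCatch(.fit_design(template, kd, conds_used, data),
                  error = function(e) NULL)
    if (is.null(W)) return(1e12)
    X <- W * outer(S, km, function(s, k) s / (k + s))
    kcat <- .profiled_kcat(X, y, bounds$kcat)
    sum((y - drop(X %*% kcat))^2)
  }

  lower <- c(rep(log10(bounds$Kd[1]), length(kd_names)),
             rep(log10(bounds$Km[1]), n_states))
  upper <- c(rep(log10(bounds$Kd[2]), length(kd_names)),
             rep(log10(bounds$Km[2]), n_states))

  res <- withr::with_seed(seed, {
    global <- .de_optimize(obj, lower, upper, pop_size = ctl$pop_size,
                           generations = ctl$generations)
    polish <- stats::optim(global$par, obj, method = "L-BFGS-B",
                           lower = lower, upper = upper,
                           control = list(maxit = 200))
    if (polish$value <= global$value) polish else global
  })

  theta <- res$par
  kd <- stats::setNames(10^theta[seq_along(kd_names)], kd_names)
  km <- 10^theta[-seq_along(kd_names)]
  W <- .fit_design(template, kd, conds_used, data)
  X <- W * outer(S, km, function(s, k) s / (k + s))
  kcat <- .profiled_kcat(X, y, bounds$kcat)
  state_labels <- template$states$state

  structure(list(
    variant = variant,
    params = c(as.list(kd),
               list(kcat = stats::setNames(kcat, state_labels),
                    Km = stats::setNames(km, state_labels))),
    residual = sum((y - drop(X %*% kcat))^2),
    n_params = length(kd_names) + 2 * n_states,
    seed = seed, bounds = bounds,
    data = tibble::as_tibble(data[c("condition", "atp_uM", "activity")]),
    conditions = conds_used
  ), class = "rim_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rim_fit <- function(x, ...) {
  cat("<rim_fit> variant:", x$variant, " pooled SSR:",
      format(x$residual, digits = 6), "\n")
  kds <- x$params[setdiff(names(x$params), c("kcat", "Km"))]
  cat("  Kds (uM):", paste(names(kds), format(unlist(kds), digits = 4),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Compare two model fits on identical data
#'
#' Orders two fits of (possibly different) model variants to the same pooled
#' datasets by residual sum of squares. No significance statement is made:
#' only residuals and parameter counts are reported.
#'
#' @param fit_a,fit_b objects from [fit_model_params()].
#' @return list with a `models` tibble (variant, n_params, residual, ordered
#'   best first) and `delta_residual` (`fit_a - fit_b`).
#' @export
compare_models <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "rim_fit"), inherits(fit_b, "rim_fit"))
  if (!isTRUE(all.equal(fit_a$data, fit_b$data))) {
    stop("fits were not computed on identical datasets", call. = FALSE)
  }
  tab <- tibble::tibble(
    variant = c(fit_a$variant, fit_b$variant),
    n_params = c(fit_a$n_params, fit_b$n_params),
    residual = c(fit_a$residual, fit_b$residual)
  )
  list(models = tab[order(tab$residual), ],
       delta_residual = fit_a$residual - fit_b$residual)
}
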