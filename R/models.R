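#' Kinetic model variants of RimK activation
#'
#' Builds the binding network and the activity-state roster for one of the
#' RimK ATPase model variants:
#'
#' * `two_state`: RimK has a basal and a single shared active conformation,
#'   reached by binding either cyclic-di-GMP (cdG) or RimA. Two activity
#'   states, one free Kd per activating ligand.
#' * `four_state`: apo RimK, RimK·RimA, RimK·cdG and RimK·cdG·RimA each have
#'   their own turnover. The binding square is closed, so one of the four Kds
#'   is derived from the thermodynamic cycle constraint (imposed at
#'   construction, not merely checked): `Kd(RimA|apo) * Kd(cdG|RimK·RimA) =
#'   Kd(cdG|apo) * Kd(RimA|RimK·cdG)`.
#' * `rimb_extended`: the four-state square plus a RimK·RimB complex formed
#'   from apo RimK, providing a further level of ATPase activation.
#' * `trigger`: the four-state square plus cdG binding to RimA (default Kd
#'   5 uM). The catalytic switch of RimA is RimB-dependent (no attenuation of
#'   RimA stimulation is seen without the protease), so the RimA·cdG complex
#'   is included only when total RimB > 0; with `RimB = 0` the trigger model
#'   reduces exactly to the four-state model.
#'   Under the default `arrangement = "sequester"` the RimA·cdG
#'   complex is catalytically engaged in cdG degradation and does not hold
#'   RimK, so rising cdG titrates RimA away from RimK; `"competent"` instead
#'   lets RimA·cdG bind RimK like free RimA (consistent Kds derived from the
#'   cycle).
#'
#' Default parameters: Kd(RimK·cdG) = 1 uM, Kd(RimK·RimA) = 0.2 uM,
#' Kd(RimA·cdG) = 5 uM (trigger), Kd(RimK·RimB) = 1 uM, binding cooperativity
#' `alpha` = 1 (the cdG Kd on RimK·RimA relative to apo). Initial
#' concentrations default to 1 uM for RimK, RimA, RimB and cdG, the standard
#' modelling condition; ligands absent from a variant are set to 0.
#'
#' @param variant one of `"two_state"`, `"four_state"`, `"rimb_extended"`,
#'   `"trigger"`.
#' @param overrides named list of parameter or concentration overrides.
#'   Parameters: `Kd_rimk_cdg`, `Kd_rimk_rima`, `Kd_rimk_rimb`
#'   (rimb_extended), `Kd_rima_cdg` (trigger), `alpha`, and per-state `kcat_*`
#'   / `Km_*` (see the returned state table for labels). Concentrations:
#'   `RimK`, `RimA`, `RimB`, `cdG` (uM). Overriding a parameter absent from
#'   the variant is a configuration error.
#' @param arrangement trigger-variant topology switch, see above.
#' @return an object of class `rim_model`: list with `variant`, `network`
#'   (a [reaction_network()] that passes [check_thermodynamic_consistency()]),
#'   `states` (tibble: `state`, `species` list column, `kcat`, `Km`) and
#'   `params` (named list of the resolved parameters).
#' @examples
#' m <- make_model("four_state", overrides = list(cdG = 25))
#' state_weights(m)
#' @export
make_model <- function(variant = c("two_state", "four_state",
                                   "rimb_extended", "trigger"),
                       overrides = list(),
                       arrangement = c("sequester", "competent")) {
  variant <- match.arg(variant)
  arrangement <- match.arg(arrangement)

  defaults <- list(
    Kd_rimk_cdg = 1, Kd_rimk_rima = 0.2, alpha = 1,
    RimK = 1, RimA = 1, cdG = 1,
    kcat_apo = 20, Km_apo = 500,
    kcat_rima = 60, Km_rima = 500,
    kcat_cdg = 60, Km_cdg = 500,
    kcat_rima_cdg = 100, Km_rima_cdg = 500
  )
  if (variant == "two_state") {
    defaults <- c(defaults[c("Kd_rimk_cdg", "Kd_rimk_rima",
                             "RimK", "RimA", "cdG",
                             "kcat_apo", "Km_apo")],
                  list(kcat_active = 100, Km_active = 500))
  }
  if (variant == "rimb_extended") {
    defaults <- c(defaults, list(Kd_rimk_rimb = 1, RimB = 1,
                                 kcat_rimb = 150, Km_rimb = 500))
  }
  if (variant == "trigger") {
    defaults <- c(defaults, list(Kd_rima_cdg = 5, RimB = 1))
  }

  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("parameter(s) not present in variant '", variant, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  p <- utils::modifyList(defaults, overrides)

  conc <- c(RimK = p$RimK, RimA = p$RimA, cdG = p$cdG)
  if (!is.null(p$RimB)) conc <- c(conc, RimB = p$RimB)

  rx <- function(a, b, complex, Kd) {
    tibble::tibble(a = a, b = b, complex = complex, Kd_uM = Kd, kf = 1e9)
  }
  base_square <- dplyr::bind_rows(
    rx("RimK", "RimA", "RimK.RimA", p$Kd_rimk_rima),
    rx("RimK", "cdG", "RimK.cdG", p$Kd_rimk_cdg),
    rx("RimK.RimA", "cdG", "RimK.cdG.RimA", p$Kd_rimk_cdg * p$alpha),
    # derived by cycle closure, not a free parameter
    rx("RimK.cdG", "RimA", "RimK.cdG.RimA", p$Kd_rimk_rima * p$alpha)
  )

  if (variant == "two_state") {
    reactions <- base_square[1:2, ]
    complexes <- c("RimK.RimA", "RimK.cdG")
    states <- tibble::tibble(
      state = c("basal", "active"),
      species = list("RimK", c("RimK.RimA", "RimK.cdG")),
      kcat = c(p$kcat_apo, p$kcat_active),
      Km = c(p$Km_apo, p$Km_active)
    )
  } else {
    reactions <- base_square
    complexes <- c("RimK.RimA", "RimK.cdG", "RimK.cdG.RimA")
    states <- tibble::tibble(
      state = c("apo", "rima", "cdg", "rima_cdg"),
      species = list("RimK", "RimK.RimA", "RimK.cdG", "RimK.cdG.RimA"),
      kcat = c(p$kcat_apo, p$kcat_rima, p$kcat_cdg, p$kcat_rima_cdg),
      Km = c(p$Km_apo, p$Km_rima, p$Km_cdg, p$Km_rima_cdg)
    )
  }
  if (variant == "rimb_extended") {
    reactions <- dplyr::bind_rows(
      reactions, rx("RimK", "RimB", "RimK.RimB", p$Kd_rimk_rimb))
    complexes <- c(complexes, "RimK.RimB")
    states <- dplyr::bind_rows(states, tibble::tibble(
      state = "rimb", species = list("RimK.RimB"),
      kcat = p$kcat_rimb, Km = p$Km_rimb))
  }
  if (variant == "trigger" && p$RimB > 0) {
    # The catalytic (cdG-degrading, RimK-inhibitory) switch of RimA is only
    # observed when the protease is present, so the RimA.cdG complex is part
    # of the network only when RimB > 0; with RimB absent the trigger model
    # reduces exactly to the four-state model.
    reactions <- dplyr::bind_rows(
      reactions, rx("RimA", "cdG", "RimA.cdG", p$Kd_rima_cdg))
    complexes <- c(complexes, "RimA.cdG")
    if (arrangement == "competent") {
      # RimA.cdG binds RimK with the RimA affinity; the closing Kd for cdG
      # binding to RimA within RimK.RimA.cdG is derived by the cycle.
      reactions <- dplyr::bind_rows(
        reactions,
        rx("RimK", "RimA.cdG", "RimK.RimA.cdG", p$Kd_rimk_rima),
        rx("RimK.RimA", "cdG", "RimK.RimA.cdG", p$Kd_rima_cdg)
      )
      complexes <- c(complexes, "RimK.RimA.cdG")
      states <- dplyr::bind_rows(states, tibble::tibble(
        state = "rima_cdga", species = list("RimK.RimA.cdG"),
        kcat = p$kcat_rima, Km = p$Km_rima))
    }
  }

  species <- tibble::tibble(
    name = c(names(conc), complexes),
    conc_uM = c(unname(conc), rep(0, length(complexes)))
  )
  network <- reaction_network(species, reactions)
  consistency <- check_thermodynamic_consistency(network)
  stopifnot(isTRUE(attr(consistency, "consistent")))

  structure(list(variant = variant, arrangement = arrangement,
                 network = network, states = states, params = p),
            class = "rim_model")
}

#' @export
print.rim_model <- function(x, ...) {
  cat("<rim_model> variant:", x$variant, "-", nrow(x$states),
      "activity states\n")
  print(x$network)
  invisible(x)
}

#' Steady-state weights of the RimK activity states
#'
#' Solves the model network to steady state under a given condition (total
#' concentrations of the elementary species, uM) and returns the activity
#' states with their weights: the summed steady-state concentration (uM) of
#' the RimK species mapped to each state, or fractions of total RimK when
#' `normalize = TRUE`.
#'
#' @param model a [make_model()] object.
#' @param condition named numeric vector of total concentrations (uM) to
#'   override the model defaults, e.g. `c(cdG = 25, RimA = 0)`.
#' @param normalize return weights as fractions of total RimK.
#' @param method steady-state route passed to [solve_steady_state()].
#' @return a `kinetic_state_set`: tibble with `state`, `kcat`, `Km`, `weight`.
#' @export
state_weights <- function(model, condition = NULL, normalize = FALSE,
                          method = c("equilibrium", "ode")) {
  stopifnot(inherits(model, "rim_model"))
  method <- match.arg(method)
  net <- model$network
  if (!is.null(condition)) {
    unknown <- setdiff(names(condition), net$moieties)
    if (length(unknown) > 0) {
      stop("condition names not elementary species of the model: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    idx <- match(names(condition), net$species$name)
    net$species$conc_uM[idx] <- unname(condition)
  }
  ss <- solve_steady_state(net, method = method)
  w <- vapply(model$states$species, function(sp) sum(ss[sp]), numeric(1))
  if (normalize) {
    total <- sum(moiety_totals(net)["RimK"])
    w <- if (total > 0) w / total else w * 0
  }
  out <- tibble::tibble(state = model$states$state,
                        kcat = model$states$kcat,
                        Km = model$states$Km,
                        weight = w)
  class(out) <- c("kinetic_state_set", class(out))
  out
}
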