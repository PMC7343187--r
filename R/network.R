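#' Protein-ligand binding reaction networks
#'
#' A reaction network is the substrate of the mass-action kinetic models of
#' RimK regulation: a set of named species with total/initial concentrations
#' (in micromolar) and a set of reversible bimolecular binding reactions
#' `A + B <-> AB`, each parameterised by an equilibrium dissociation constant
#' `Kd` (uM) and a diffusion-limited forward rate constant `kf`
#' (M^-1 s^-1, default 1e9). The reverse rate `kr = kf * Kd` is always
#' derived, never stored independently, so the equilibrium point of the ODE
#' system is fixed by the Kd values alone.
#'
#' Elementary species (those never produced as a reaction complex) define the
#' conserved moieties of the network; every complex must be reachable by
#' composing elementary species through the listed reactions.
#'
#' @param species a data frame with columns `name` and `conc_uM`, or a named
#'   numeric vector of total/initial concentrations in uM.
#' @param reactions a data frame with columns `a`, `b`, `complex`, `Kd_uM`
#'   and optionally `kf` (M^-1 s^-1, default 1e9). May have zero rows.
#' @return an object of class `reaction_network`: a list with elements
#'   `species` (tibble), `reactions` (tibble), `moieties` (character vector of
#'   elementary species) and `composition` (species x moiety integer matrix).
#' @examples
#' net <- reaction_network(
#'   c(R = 2.5, L = 25, RL = 0),
#'   data.frame(a = "R", b = "L", complex = "RL", Kd_uM = 1)
#' )
#' solve_steady_state(net)
#' @export
reaction_network <- function(species, reactions = NULL) {
  if (is.numeric(species) && !is.null(names(species))) {
    species <- tibble::tibble(name = names(species), conc_uM = unname(species))
  }
  species <- tibble::as_tibble(species)
  stopifnot(all(c("name", "conc_uM") %in% names(species)))
  if (anyDuplicated(species$name)) {
    stop("species names must be unique within a network", call. = FALSE)
  }
  if (any(species$conc_uM < 0) || anyNA(species$conc_uM)) {
    stop("species concentrations must be non-negative", call. = FALSE)
  }
  if (is.null(reactions)) {
    reactions <- tibble::tibble(a = character(), b = character(),
                                complex = character(), Kd_uM = numeric(),
                                kf = numeric())
  }
  reactions <- tibble::as_tibble(reactions)
  if (nrow(reactions) > 0) {
    stopifnot(all(c("a", "b", "complex", "Kd_uM") %in% names(reactions)))
    if (!"kf" %in% names(reactions)) reactions$kf <- 1e9
    reactions$kf[is.na(reactions$kf)] <- 1e9
    if (any(reactions$Kd_uM <= 0)) stop("Kd must be > 0", call. = FALSE)
    if (any(reactions$kf <= 0)) stop("kf must be > 0", call. = FALSE)
    referenced <- unique(c(reactions$a, reactions$b, reactions$complex))
    unknown <- setdiff(referenced, species$name)
    if (length(unknown) > 0) {
      stop("reaction references unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  } else if (!"kf" %in% names(reactions)) {
    reactions$kf <- numeric()
  }

  comp <- .composition_matrix(species$name, reactions)
  net <- structure(
    list(species = species, reactions = reactions,
         moieties = colnames(comp), composition = comp),
    class = "reaction_network"
  )
  net
}

# Resolve every species into counts of elementary moieties. A complex formed
# by several routes must resolve identically on each route (structural check,
# independent of Kd consistency).
.composition_matrix <- function(names, reactions) {
  elementary <- setdiff(names, reactions$complex)
  if (length(elementary) == 0 && length(names) > 0) {
    stop("network has no elementary species: every species is a complex",
         call. = FALSE)
  }
  comp <- matrix(0L, nrow = length(names), ncol = length(elementary),
                 dimnames = list(names, elementary))
  known <- names %in% elementary
  names(known) <- names
  for (m in elementary) comp[m, m] <- 1L
  progress <- TRUE
  while (progress && !all(known)) {
    progress <- FALSE
    for (j in seq_len(nrow(reactions))) {
      a <- reactions$a[j]; b <- reactions$b[j]; ab <- reactions$complex[j]
      if (known[a] && known[b]) {
        candidate <- comp[a, ] + comp[b, ]
        if (!known[ab]) {
          comp[ab, ] <- candidate
          known[ab] <- TRUE
          progress <- TRUE
        } else if (!identical(unname(comp[ab, ]), unname(candidate))) {
          stop("complex '", ab, "' has inconsistent composition across routes",
               call. = FALSE)
        }
      }
    }
  }
  if (!all(known)) {
    stop("complex(es) not reachable from free species: ",
         paste(names[!known], collapse = ", "), call. = FALSE)
  }
  comp
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", nrow(x$species), " species, ",
      nrow(x$reactions), " binding reactions, moieties: ",
      paste(x$moieties, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Internal unit convention: concentrations in uM throughout; kf is declared in
# M^-1 s^-1 and converted to uM^-1 s^-1 (1e9 M^-1 s^-1 -> 1e3 uM^-1 s^-1)
# so that kr = kf_uM * Kd_uM is in s^-1.
.rate_constants <- function(network) {
  kf_uM <- network$reactions$kf * 1e-6
  list(kf = kf_uM, kr = kf_uM * network$reactions$Kd_uM)
}

#' Mass-action ODE right-hand side for a binding network
#'
#' Translates the binding reactions into ordinary differential equations under
#' mass action kinetics: each reaction `A + B <-> AB` contributes
#' `-kf [A][B] + kr [AB]` to A and B and the opposite to AB. The returned
#' function has the `deSolve` signature `function(t, y, parms)`.
#'
#' Conservation of each moiety total holds by construction: the net
#' stoichiometry of every reaction is exactly zero in moiety counts (see
#' [moiety_balance()], which verifies this symbolically).
#'
#' @param network a [reaction_network()].
#' @return a derivative function `function(t, y, parms)` returning
#'   `list(dy)`, with `y` named by species.
#' @export
build_odes <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  k <- .rate_constants(network)
  ia <- match(network$reactions$a, network$species$name)
  ib <- match(network$reactions$b, network$species$name)
  ic <- match(network$reactions$complex, network$species$name)
  n <- nrow(network$species)
  nm <- network$species$name
  function(t, y, parms = NULL) {
    r <- k$kf * y[ia] * y[ib] - k$kr * y[ic]
    dy <- numeric(n)
    for (j in seq_along(r)) {
      dy[ia[j]] <- dy[ia[j]] - r[j]
      dy[ib[j]] <- dy[ib[j]] - r[j]
      dy[ic[j]] <- dy[ic[j]] + r[j]
    }
    names(dy) <- nm
    list(dy)
  }
}

#' Symbolic moiety balance of every reaction
#'
#' For each reaction, the net production of each conserved moiety
#' (`composition(complex) - composition(a) - composition(b)`). All entries are
#' identically zero for any structurally valid network, which makes the
#' conservation of moiety totals under the ODE flow an exact (symbolic)
#' property rather than a numerical one.
#'
#' @param network a [reaction_network()].
#' @return an integer matrix, reactions x moieties.
#' @export
moiety_balance <- function(network) {
  comp <- network$composition
  out <- matrix(0L, nrow(network$reactions), ncol(comp),
                dimnames = list(network$reactions$complex, colnames(comp)))
  for (j in seq_len(nrow(network$reactions))) {
    out[j, ] <- comp[network$reactions$complex[j], ] -
      comp[network$reactions$a[j], ] - comp[network$reactions$b[j], ]
  }
  out
}

#' Total concentration of each conserved moiety
#'
#' @param network a [reaction_network()].
#' @param conc optional named concentration vector (uM); defaults to the
#'   network's initial concentrations.
#' @return named numeric vector of moiety totals in uM.
#' @export
moiety_totals <- function(network, conc = NULL) {
  if (is.null(conc)) {
    conc <- stats::setNames(network$species$conc_uM, network$species$name)
  }
  drop(t(network$composition) %*% conc[rownames(network$composition)])
}

#' Thermodynamic cycle consistency of a binding network
#'
#' Detailed balance requires that for every closed binding cycle the product
#' of Kd values is route-independent (the Wegscheider condition). Cycles are
#' the null space of the reaction stoichiometry matrix; for each independent
#' cycle the signed product of Kd values is evaluated and compared with 1.
#'
#' @param network a [reaction_network()].
#' @param rtol relative tolerance on the cycle Kd product (default 1e-9).
#' @return a tibble with one row per independent cycle: `cycle`, `reactions`
#'   (signed reaction indices, list column), `kd_ratio` (product normalised to
#'   be >= 1) and `pass`. The attribute `consistent` is `TRUE` when all cycles
#'   pass (and trivially for acyclic networks).
#' @export
check_thermodynamic_consistency <- function(network, rtol = 1e-9) {
  stopifnot(inherits(network, "reaction_network"))
  empty <- tibble::tibble(cycle = integer(), reactions = list(),
                          kd_ratio = numeric(), pass = logical())
  nr <- nrow(network$reactions)
  if (nr == 0) return(structure(empty, consistent = TRUE))
  # stoichiometry matrix: species x reactions
  S <- matrix(0, nrow(network$species), nr)
  for (j in seq_len(nr)) {
    ia <- match(network$reactions$a[j], network$species$name)
    ib <- match(network$reactions$b[j], network$species$name)
    ic <- match(network$reactions$complex[j], network$species$name)
    S[ia, j] <- S[ia, j] - 1
    S[ib, j] <- S[ib, j] - 1
    S[ic, j] <- S[ic, j] + 1
  }
  N <- pracma::nullspace(S)
  if (is.null(N) || length(N) == 0) return(structure(empty, consistent = TRUE))
  N <- as.matrix(N)
  rows <- lapply(seq_len(ncol(N)), function(i) {
    v <- N[, i]
    v <- v / min(abs(v[abs(v) > 1e-8]))   # binding cycles have +/-1 entries
    v <- round(v, 6)
    logratio <- sum(v * log(network$reactions$Kd_uM))
    ratio <- exp(abs(logratio))
    tibble::tibble(
      cycle = i,
      reactions = list(stats::setNames(v[v != 0], which(v != 0))),
      kd_ratio = ratio,
      pass = abs(ratio - 1) <= rtol
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, consistent = all(out$pass))
}

#' Steady-state concentrations of a binding network
#'
#' The reference route (`method = "ode"`) integrates the mass-action ODEs with
#' a high-accuracy explicit solver (`deSolve` ode45, rtol 1e-8 / atol 1e-10),
#' extending the horizon tenfold until the infinity norm of the derivative
#' falls below `atol`, then polishes the endpoint with damped Newton steps on
#' the derivative (minimum-norm, so conservation is preserved). The
#' `"equilibrium"` route solves the equivalent equilibrium-speciation problem
#' directly: Newton iteration on the log free concentrations of the conserved
#' moieties, with complex concentrations given by products of Kds. For a
#' detailed-balanced binding-only network both routes agree; the algebraic
#' route is orders of magnitude faster and is used inside model fitting.
#'
#' @param network a [reaction_network()].
#' @param rtol,atol integrator tolerances; `atol` also serves as the
#'   steady-state criterion on the derivative infinity norm.
#' @param max_time maximum integration horizon in seconds (default 1e6).
#' @param method `"ode"` (integrate to steady state) or `"equilibrium"`
#'   (algebraic speciation solve).
#' @return named numeric vector of steady-state concentrations (uM) with
#'   attribute `residual` (infinity norm of the derivative at the solution).
#' @export
solve_steady_state <- function(network, rtol = 1e-8, atol = 1e-10,
                               max_time = 1e6,
                               method = c("ode", "equilibrium")) {
  stopifnot(inherits(network, "reaction_network"))
  method <- match.arg(method)
  y0 <- stats::setNames(network$species$conc_uM, network$species$name)
  if (method == "equilibrium") {
    y <- .equilibrium_speciation(network)
    rhs <- build_odes(network)
    res <- max(abs(rhs(0, y)[[1]]))
    return(structure(y, residual = res))
  }
  rhs <- build_odes(network)
  y <- y0
  comp <- network$composition
  totals0 <- moiety_totals(network)
  resid <- function(v) max(abs(rhs(0, v)[[1]]))
  horizon <- 1e-4
  repeat {
    if (resid(y) < atol) break
    # explicit integration tracks the relaxation; the Newton polish removes
    # the integrator's noise floor once the trajectory is near equilibrium
    sol <- suppressWarnings(
      deSolve::ode(y = y, times = c(0, horizon), func = rhs, parms = NULL,
                   method = "ode45", rtol = rtol, atol = atol,
                   maxsteps = 50000))
    cand <- sol[nrow(sol), -1]
    if (!anyNA(cand)) y <- cand
    y <- .newton_polish(rhs, y, atol, comp, totals0)
    if (resid(y) < atol) break
    if (horizon > max_time) {
      worst <- names(y)[which.max(abs(rhs(0, y)[[1]]))]
      stop("steady state not reached within ", max_time,
           " s; worst species: ", worst, call. = FALSE)
    }
    horizon <- horizon * 10
  }
  y[y < 0 & y > -1e-12] <- 0
  structure(y, residual = resid(y))
}

# Gauss-Newton refinement of an ODE steady state. The mass-action root set
# is a manifold (any point satisfying detailed balance), so the derivative
# equations are augmented with the moiety conservation equations to pin the
# root belonging to the initial totals.
.newton_polish <- function(rhs, y, atol, comp, totals, max_iter = 10) {
  f <- function(v) {
    v <- stats::setNames(v, names(y))
    c(rhs(0, v)[[1]], drop(t(comp) %*% v[rownames(comp)]) - totals)
  }
  n_ode <- length(y)
  for (i in seq_len(max_iter)) {
    fv <- f(y)
    if (max(abs(fv[seq_len(n_ode)])) < atol / 10 &&
        max(abs(fv[-seq_len(n_ode)])) < 1e-12) break
    J <- pracma::jacobian(f, unname(y))
    step <- tryCatch(qr.solve(J, fv), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    cand <- y - step
    if (any(cand < -1e-9) || max(abs(f(cand))) >= max(abs(fv))) break
    y <- stats::setNames(cand, names(y))
  }
  y
}

# Equilibrium speciation: [complex] = beta * prod_m x_m^nu, with beta the
# product of 1/Kd along any formation route (route-independent under detailed
# balance). Newton in u = log x on the moiety conservation equations.
.equilibrium_speciation <- function(network, tol = 1e-12, max_iter = 200) {
  sp <- network$species$name
  comp <- network$composition
  log_beta <- stats::setNames(rep(NA_real_, length(sp)), sp)
  log_beta[network$moieties] <- 0
  repeat {
    progress <- FALSE
    for (j in seq_len(nrow(network$reactions))) {
      a <- network$reactions$a[j]; b <- network$reactions$b[j]
      ab <- network$reactions$complex[j]
      if (!is.na(log_beta[a]) && !is.na(log_beta[b]) && is.na(log_beta[ab])) {
        log_beta[ab] <- log_beta[a] + log_beta[b] -
          log(network$reactions$Kd_uM[j])
        progress <- TRUE
      }
    }
    if (!progress) break
  }
  totals <- moiety_totals(network)
  active <- totals > 0
  y <- stats::setNames(numeric(length(sp)), sp)
  if (!any(active)) return(y)
  # species containing an absent moiety stay at zero
  viable <- rowSums(comp[, !active, drop = FALSE]) == 0
  m_idx <- which(active)
  u <- log(totals[m_idx])
  compA <- comp[viable, m_idx, drop = FALSE]
  lbA <- log_beta[viable]
  for (iter in seq_len(max_iter)) {
    conc <- exp(lbA + drop(compA %*% u))
    tot_m <- drop(t(compA) %*% conc)
    fval <- log(tot_m) - log(totals[m_idx])
    if (max(abs(fval)) < tol) break
    J <- t(compA) %*% (conc * compA) / tot_m
    step <- tryCatch(solve(J, fval), error = function(e) fval)
    step <- pmax(pmin(step, 5), -5)  # damping in log space
    u <- u - step
  }
  y[viable] <- exp(lbA + drop(compA %*% u))
  y
}

#' Exact fraction of receptor bound at binary binding equilibrium
#'
#' Solves the quadratic equilibrium for `R + L <-> RL` exactly (no
#' excess-ligand approximation): with totals `R_t`, `L_t` and dissociation
#' constant `Kd`, the complex concentration is the smaller root of
#' `x^2 - (R_t + L_t + Kd) x + R_t L_t = 0`. At the assay concentrations used
#' for RimK and cyclic-di-GMP (2.5 uM receptor, 25 uM ligand, Kd 1 uM) the
#' bound fraction is 0.9576, i.e. ~96% of RimK is cdG-bound.
#'
#' @param total_receptor,total_ligand totals in uM (vectorised).
#' @param Kd dissociation constant in uM; must be > 0.
#' @return fraction of total receptor in the complex, in `[0, 1]`.
#' @examples
#' pairwise_bound_fraction(2.5, 25, 1)  # 0.9576...
#' @export
pairwise_bound_fraction <- function(total_receptor, total_ligand, Kd) {
  if (any(Kd <= 0)) stop("Kd must be > 0", call. = FALSE)
  if (any(total_receptor < 0) || any(total_ligand < 0)) {
    stop("totals must be non-negative", call. = FALSE)
  }
  b <- total_receptor + total_ligand + Kd
  rl <- (b - sqrt(b^2 - 4 * total_receptor * total_ligand)) / 2
  ifelse(total_receptor > 0, rl / total_receptor, 0)
}
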