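## Mass-action ODE semantics: rate laws, the differential system, stiff
## numerical integration via deSolve, and the dynamic side of emulation
## checking (derivative identities, paired trajectories, steady-state
## transfer).

#' Mass action of a reaction in a state
#'
#' Returns `v^rho`, the product of the reactant concentrations raised to
#' their multiplicities.  A species with reactant multiplicity zero
#' contributes a factor 1 even at concentration zero (the 0^0 = 1
#' convention), so the empty reactant complex has mass action 1 in every
#' state and boundary states are well defined.
#'
#' @param r a [reaction()].
#' @param v a named nonnegative state vector covering the reaction's
#'   reactant species.
#' @return a nonnegative number.
#' @examples
#' mass_action(reaction("2A + B", "C"), c(A = 2, B = 3))  # 2^2 * 3 = 12
#' @export
mass_action <- function(r, v) {
  stopifnot(inherits(r, "crn_reaction"))
  rho <- r$reactants
  if (length(rho) == 0L) return(1)
  missing <- setdiff(names(rho), names(v))
  if (length(missing))
    stop("state does not cover species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  vv <- v[names(rho)]
  if (any(vv < 0)) stop("negative concentration", call. = FALSE)
  prod(vv ^ as.numeric(rho))
}

## internal: mass-action vector [r]_v for all reactions, given the
## reactant matrix (species x reactions) and a state vector in species
## order.  Implemented by direct products over the nonzero multiplicities
## so that 0^0 never arises.
mass_action_vector <- function(rho, v) {
  nr <- ncol(rho)
  out <- numeric(nr)
  for (j in seq_len(nr)) {
    idx <- which(rho[, j] > 0L)
    out[j] <- if (length(idx)) prod(v[idx] ^ as.numeric(rho[idx, j])) else 1
  }
  out
}

#' Mass-action derivative field of a network
#'
#' Computes `F(v)(s) = sum_r phi(s, r) * [r]_v`: the instantaneous
#' stoichiometry matrix times the vector of reaction mass actions.
#'
#' @param net a [crn()].
#' @param v named nonnegative state vector on the network's species.
#' @return named numeric vector of concentration derivatives.
#' @export
derivatives <- function(net, v) {
  stopifnot(inherits(net, "crn"))
  sm <- stoich_matrices(net)
  vv <- as.numeric(v[net$species])
  if (any(is.na(vv)))
    stop("state does not cover all network species", call. = FALSE)
  if (any(vv < 0)) stop("negative concentration", call. = FALSE)
  drop(sm$instantaneous %*% mass_action_vector(sm$reactant, vv)) |>
    stats::setNames(net$species)
}

#' Simulate the mass-action kinetics of a network
#'
#' Integrates the mass-action ODE system from an initial state on a
#' uniform time grid with a stiff-capable solver (deSolve's `lsoda`).
#' Nonnegativity of the solution is checked after the fact (never enforced
#' by clipping): values below `-10 * atol` mark the trajectory as failed.
#'
#' @param net a [crn()].
#' @param v0 named nonnegative initial state; species missing from `v0`
#'   start at 0.
#' @param t_end end time (> 0).
#' @param grid number of output time points (including 0).
#' @param rtol,atol relative/absolute solver tolerances.
#' @param method deSolve integration method.
#' @return an object of class `crn_trajectory`: list with `times`, the
#'   `grid x |S|` concentration matrix `conc`, and `meta` (tolerances,
#'   success and nonnegativity flags).
#' @export
simulate_crn <- function(net, v0, t_end, grid = 201L, rtol = 1e-9,
                         atol = 1e-9, method = "lsoda") {
  stopifnot(inherits(net, "crn"), t_end > 0, grid >= 2L)
  y0 <- stats::setNames(numeric(n_species(net)), net$species)
  if (length(v0)) {
    unknown <- setdiff(names(v0), net$species)
    if (length(unknown))
      stop("initial state names not in network: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    y0[names(v0)] <- v0
  }
  if (any(y0 < 0)) stop("negative initial concentration", call. = FALSE)
  sm <- stoich_matrices(net)
  deriv <- function(t, y, parms) {
    list(drop(sm$instantaneous %*% mass_action_vector(sm$reactant, y)))
  }
  times <- seq(0, t_end, length.out = grid)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  if (nrow(sol) < length(times) || anyNA(sol))
    stop("ODE solver failed before t_end (istate = ",
         attr(sol, "istate")[1], ")", call. = FALSE)
  conc <- unclass(sol)[, net$species, drop = FALSE]
  nonneg_ok <- min(conc) >= -10 * atol
  if (!nonneg_ok)
    warning("trajectory dips below -10*atol; flagged as failed",
            call. = FALSE)
  structure(list(times = times, conc = conc,
                 meta = list(rtol = rtol, atol = atol, method = method,
                             success = nonneg_ok, min_conc = min(conc))),
            class = "crn_trajectory")
}

#' @export
print.crn_trajectory <- function(x, ...) {
  cat("Mass-action trajectory: ", ncol(x$conc), " species, ",
      length(x$times), " time points on [0, ",
      format(max(x$times)), "]\n", sep = "")
  cat("final state:\n")
  print(round(x$conc[nrow(x$conc), ], 6))
  invisible(x)
}

#' @export
plot.crn_trajectory <- function(x, species = colnames(x$conc), lty = 1,
                                col = NULL, ...) {
  conc <- x$conc[, species, drop = FALSE]
  if (is.null(col)) col <- seq_len(ncol(conc))
  graphics::matplot(x$times, conc, type = "l", lty = lty, col = col,
                    xlab = "time", ylab = "concentration", ...)
  graphics::legend("topright", legend = species, col = col, lty = lty,
                   bty = "n")
  invisible(x)
}

#' Write a trajectory as CSV
#'
#' Header `time,<species...>`, one row per grid point.
#'
#' @param traj a [simulate_crn()] result.
#' @param path output file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "crn_trajectory"))
  df <- data.frame(time = traj$times, traj$conc, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pull a target state back through a species map
#'
#' Initial conditions are *copied* through the map, never summed: the
#' pulled-back state assigns to each source species the concentration of
#' its image, `v(s) = v_hat(m_S(s))`.
#'
#' @param m_S named character species map (source -> target).
#' @param v_hat named state on the target species.
#' @return named state on the source species.
#' @export
pullback_state <- function(m_S, v_hat) {
  missing <- setdiff(unname(m_S), names(v_hat))
  if (length(missing))
    stop("target state does not cover species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  stats::setNames(as.numeric(v_hat[unname(m_S)]), names(m_S))
}

#' Derivative identity of an emulation
#'
#' For each supplied target state `v_hat` computes the residual
#' `max_s | F(v_hat o m)(s) - F_hat(v_hat)(m(s)) |` between the source
#' derivative field at the pulled-back state and the pulled-back target
#' derivative field.  For a reactant morphism that is also a
#' stoichiomorphism this residual is zero up to floating-point rounding at
#' every state.
#'
#' @param m a [crn_morphism()].
#' @param states a list of named target states (a single state may be
#'   passed directly).
#' @return the maximum residual over all states, with per-state residuals
#'   as the `"residuals"` attribute.
#' @export
check_emulation_derivative <- function(m, states) {
  stopifnot(inherits(m, "crn_morphism"))
  if (!is.list(states)) states <- list(states)
  res <- vapply(states, function(v_hat) {
    v <- pullback_state(m$species_map, v_hat)
    lhs <- derivatives(m$source, v)
    rhs <- derivatives(m$target, v_hat)[unname(m$species_map)]
    max(abs(lhs - rhs))
  }, numeric(1))
  structure(max(res), residuals = res)
}

#' Trajectory coincidence of an emulation
#'
#' Simulates the target from `v0_hat` and the source from the pulled-back
#' state on the same time grid, and measures the worst deviation
#' `max_{t, s} | f_s(t) - f_hat_{m(s)}(t) |` between each source species
#' and its image trajectory.  The static checks (reactant morphism,
#' homomorphism, stoichiomorphism) and the derivative residual over the
#' target grid states are bundled into the report; the verdict is true
#' when the reactant and stoichiomorphism conditions hold and the
#' deviation is below `tol` (a threshold that only absorbs solver error:
#' the emulation theorem predicts exact coincidence).
#'
#' @param m a [crn_morphism()].
#' @param v0_hat named initial state on the target species.
#' @param t_end,grid,rtol,atol simulation controls, see [simulate_crn()].
#' @param tol deviation threshold for the verdict.
#' @return an object of class `emulation_report`.
#' @export
check_emulation_trajectory <- function(m, v0_hat, t_end = 50, grid = 201L,
                                       rtol = 1e-9, atol = 1e-9,
                                       tol = 1e-6) {
  stopifnot(inherits(m, "crn_morphism"))
  static <- list(reactant = is_reactant_morphism(m),
                 homomorphism = is_homomorphism(m),
                 stoichiomorphism = is_stoichiomorphism(m))
  traj_t <- simulate_crn(m$target, v0_hat, t_end, grid, rtol, atol)
  v0 <- pullback_state(m$species_map, v0_hat)
  traj_s <- simulate_crn(m$source, v0, t_end, grid, rtol, atol)
  img <- unname(m$species_map)
  dev <- max(abs(traj_s$conc[, names(m$species_map), drop = FALSE] -
                 traj_t$conc[, img, drop = FALSE]))
  ## derivative residual sampled along the target trajectory (clamped to
  ## zero from below: solver output can undershoot 0 by ~atol)
  samp <- lapply(seq(1L, grid, length.out = min(grid, 20L)), function(i)
    pmax(traj_t$conc[round(i), ], 0))
  dres <- check_emulation_derivative(m, samp)
  verdict <- static$reactant$holds && static$stoichiomorphism$holds &&
    dev < tol
  structure(list(static = static, derivative_residual = as.numeric(dres),
                 trajectory_deviation = dev, tol = tol, verdict = verdict,
                 source_trajectory = traj_s, target_trajectory = traj_t,
                 morphism = m),
            class = "emulation_report")
}

#' @export
print.emulation_report <- function(x, ...) {
  cat("Emulation report\n")
  cat("  reactant morphism:   ", x$static$reactant$holds, "\n")
  cat("  homomorphism:        ", x$static$homomorphism$holds, "\n")
  cat("  stoichiomorphism:    ", x$static$stoichiomorphism$holds, "\n")
  cat("  derivative residual: ",
      format(x$derivative_residual, digits = 4), "\n")
  cat("  trajectory deviation:",
      format(x$trajectory_deviation, digits = 4), " (tol ",
      format(x$tol), ")\n", sep = "")
  cat("  verdict:             ", x$verdict, "\n")
  invisible(x)
}

#' @export
plot.emulation_report <- function(x, ...) {
  src <- x$source_trajectory; tgt <- x$target_trajectory
  graphics::matplot(tgt$times, tgt$conc, type = "l", lty = 1, lwd = 3,
                    col = grDevices::adjustcolor(
                      seq_len(ncol(tgt$conc)), alpha.f = 0.35),
                    xlab = "time", ylab = "concentration", ...)
  img <- match(unname(x$morphism$species_map), colnames(tgt$conc))
  graphics::matlines(src$times, src$conc, lty = 2, lwd = 1, col = img)
  invisible(x)
}

#' Steady-state transfer across an emulation
#'
#' An emulation preserves steady states from target to source: if
#' `F_hat(v_hat) = 0` then the pulled-back state `v_hat o m` is a steady
#' state of the source.  The target residual is verified as a
#' precondition; when the species map is a bijection the converse
#' direction (source steady state pushed forward) is checked as well.
#'
#' @param m a [crn_morphism()].
#' @param v_hat_ss a steady state of the target (max derivative below
#'   `10 * tol`).
#' @param tol residual threshold.
#' @return a `crn_check` whose `max_residual` is the source derivative
#'   residual at the pulled-back state.
#' @export
steady_state_transfer <- function(m, v_hat_ss, tol = 1e-9) {
  stopifnot(inherits(m, "crn_morphism"))
  res_t <- max(abs(derivatives(m$target, v_hat_ss)))
  if (res_t >= 10 * tol)
    stop("v_hat_ss is not a steady state of the target (residual ",
         format(res_t), ")", call. = FALSE)
  v <- pullback_state(m$species_map, v_hat_ss)
  dv <- derivatives(m$source, v)
  res_s <- max(abs(dv))
  bad <- which(abs(dv) > tol)
  wit <- data.frame(species = names(dv)[bad],
                    derivative = unname(dv[bad]),
                    stringsAsFactors = FALSE)
  holds <- res_s < tol
  if (holds && !anyDuplicated(unname(m$species_map)) &&
      setequal(unname(m$species_map), m$target$species)) {
    ## bijective on species: the converse direction also holds
    inv <- stats::setNames(names(m$species_map), unname(m$species_map))
    res_back <- max(abs(derivatives(m$target, v[inv[m$target$species]] |>
                                      stats::setNames(m$target$species))))
    holds <- holds && res_back < 10 * tol
  }
  structure(list(holds = holds, witnesses = wit, max_residual = res_s,
                 target_residual = res_t),
            class = "crn_check")
}
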