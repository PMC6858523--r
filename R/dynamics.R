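# Langevin molecular dynamics on any electronic surface, and gradient-based
# HOMO-LUMO gap optimisation.

#' Molecular-dynamics configuration
#'
#' @param timestep integration step (fs).
#' @param temperature target temperature (K); 0 disables the thermostat
#'   noise.
#' @param friction_time Langevin time constant (fs); the friction is its
#'   inverse, and `Inf` disables friction (NVE limit together with
#'   `temperature = 0`).
#' @param n_steps number of integration steps.
#' @param seed integer seed for the thermostat noise and initial velocities.
#' @param stride record every `stride`-th frame.
#' @param masses optional per-atom masses (amu); defaults to standard atomic
#'   masses.
#' @return an object of class `slite_mdconfig`.
#' @export
md_config <- function(timestep = 0.5, temperature = 300, friction_time = 100,
                      n_steps = 1000L, seed = 1L, stride = 1L,
                      masses = NULL) {
  if (timestep <= 0) stop("timestep must be > 0")
  if (temperature < 0) stop("temperature must be >= 0")
  if (friction_time <= 0) stop("friction_time must be > 0")
  structure(list(timestep = timestep, temperature = temperature,
                 friction_time = friction_time, n_steps = as.integer(n_steps),
                 seed = as.integer(seed), stride = as.integer(stride),
                 masses = masses),
            class = "slite_mdconfig")
}

#' Langevin molecular dynamics
#'
#' BAOAB-splitting Langevin integration driven by the surface's energy and
#' analytic forces (generator or trained model interchangeably). With
#' `temperature = 0` and `friction_time = Inf` the thermostat step becomes
#' the identity and the integrator reduces to velocity Verlet. Initial
#' velocities are Maxwell-Boltzmann at the target temperature with the
#' center-of-mass motion removed (at initialisation only).
#'
#' @param surface a `slite_surface` ([hueckel_surface()] or trained model).
#' @param mol starting [molecule()].
#' @param cfg an [md_config()].
#' @param velocities optional initial velocities (Angstrom/fs), overriding
#'   the Maxwell-Boltzmann draw.
#' @return an object of class `slite_trajectory`: recorded `positions` and
#'   `velocities` (lists of matrices) plus a per-frame tibble `frames` with
#'   step, time (fs), potential and kinetic energy (eV) and instantaneous
#'   temperature (K).
#' @export
langevin_md <- function(surface, mol, cfg, velocities = NULL) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(cfg$seed)
  n <- n_atoms(mol)
  mass <- cfg$masses
  if (is.null(mass)) mass <- element_mass(mol$atomic_numbers)
  dt <- cfg$timestep
  gamma <- 1 / cfg$friction_time
  kT <- KB_EV * cfg$temperature
  c1 <- exp(-gamma * dt)
  c2 <- sqrt(1 - c1^2)
  sig <- sqrt(kT / (mass * KE_UNIT))    # thermal velocity std, Angstrom/fs
  pos <- mol$positions
  if (is.null(velocities)) {
    v <- matrix(stats::rnorm(3 * n), n, 3) * sig
    if (cfg$temperature == 0) v[] <- 0
  } else {
    v <- velocities
  }
  # remove center-of-mass drift at initialisation only
  v <- sweep(v, 2, colSums(v * mass) / sum(mass))
  cur <- mol
  ef <- energy_forces(surface, cur)
  acc <- ef$F / mass * ACC_UNIT
  ke <- function(v) 0.5 * sum(mass * rowSums(v^2)) * KE_UNIT
  rec_pos <- list(); rec_vel <- list(); rows <- list()
  record <- function(step, epot, v) {
    k <- ke(v)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      step = step, time = step * dt, epot = epot, ekin = k,
      etot = epot + k, temperature = 2 * k / (3 * n * KB_EV))
    rec_pos[[length(rec_pos) + 1L]] <<- pos
    rec_vel[[length(rec_vel) + 1L]] <<- v
  }
  record(0L, ef$E, v)
  for (step in seq_len(cfg$n_steps)) {
    v <- v + 0.5 * dt * acc                    # B
    pos <- pos + 0.5 * dt * v                  # A
    if (cfg$temperature > 0 && is.finite(cfg$friction_time)) {
      v <- c1 * v + c2 * sig * matrix(stats::rnorm(3 * n), n, 3)  # O
    } else if (is.finite(cfg$friction_time) && gamma > 0) {
      v <- c1 * v
    }
    pos <- pos + 0.5 * dt * v                  # A
    cur$positions <- pos
    ef <- energy_forces(surface, cur)
    if (!all(is.finite(ef$F))) {
      stop("non-finite force encountered at MD step ", step)
    }
    acc <- ef$F / mass * ACC_UNIT
    v <- v + 0.5 * dt * acc                    # B
    if (step %% cfg$stride == 0L) record(step, ef$E, v)
  }
  structure(list(frames = do.call(rbind, rows), positions = rec_pos,
                 velocities = rec_vel, molecule = mol, cfg = cfg),
            class = "slite_trajectory")
}

#' @export
print.slite_trajectory <- function(x, ...) {
  fr <- x$frames
  cat("<slite_trajectory> ", nrow(fr), " frames over ",
      fr$time[nrow(fr)], " fs; mean T = ",
      sprintf("%.1f", mean(fr$temperature[-1])), " K\n", sep = "")
  invisible(x)
}

#' Per-frame trajectory summary
#' @param x a `slite_trajectory`.
#' @param ... unused.
#' @return tibble with step, time, energies and instantaneous temperature.
#' @method tidy slite_trajectory
#' @export
tidy.slite_trajectory <- function(x, ...) x$frames

# HOMO and LUMO gradients from one hs_gradients evaluation.
gap_state <- function(surface, mol, n_electrons) {
  hs <- hs_matrices(surface, mol)
  spec <- solve_orbitals(hs$H, hs$S, n_electrons)
  nocc <- sum(spec$occupation > 0)
  if (nocc < 1L || nocc >= length(spec$epsilon)) {
    stop("gap undefined: need at least one occupied and one virtual orbital")
  }
  gap <- spec$epsilon[nocc + 1L] - spec$epsilon[nocc]
  sep_h <- if (nocc > 1L) spec$epsilon[nocc] - spec$epsilon[nocc - 1L] else Inf
  sep_l <- if (nocc + 1L < length(spec$epsilon)) {
    spec$epsilon[nocc + 2L] - spec$epsilon[nocc + 1L]
  } else Inf
  if (min(sep_h, sep_l, gap) <= 1e-6) {
    stop("frontier orbitals are degenerate (separation <= 1e-6 eV); ",
         "gap gradient ill-defined")
  }
  gr <- hs_gradients(surface, mol)
  grad1 <- function(m) {
    cm <- spec$C[, m]
    out <- matrix(0, n_atoms(mol), 3)
    for (a in seq_len(n_atoms(mol))) {
      for (cc in 1:3) {
        out[a, cc] <- sum(cm * ((gr$dH[, , a, cc] -
                                   spec$epsilon[m] * gr$dS[, , a, cc]) %*% cm))
      }
    }
    out
  }
  list(gap = gap, grad = grad1(nocc + 1L) - grad1(nocc))
}

#' Gradient-based HOMO-LUMO gap optimisation
#'
#' Gradient ascent (`mode = "max"`) or descent (`mode = "min"`) on the gap
#' `eps_LUMO - eps_HOMO` using the surface's exact orbital-energy gradients.
#' A step is accepted only if the objective moves in the requested
#' direction; otherwise the step size is halved (backtracking), so the
#' accepted-gap trace is monotone. Stops when the accepted change falls
#' below `tol`, the step underflows, `max_iter` is reached, or a frontier
#' degeneracy is encountered (partial trace returned with status
#' `"degenerate"`).
#'
#' @param surface a `slite_surface`.
#' @param mol starting [molecule()].
#' @param n_electrons even electron count (defaults to the surface's own,
#'   when it carries one).
#' @param mode `"min"` or `"max"`.
#' @param step initial step size (Angstrom per unit gradient, eV/Angstrom).
#' @param max_iter maximum accepted iterations.
#' @param tol convergence threshold on the accepted gap change (eV).
#' @return an object of class `slite_gapopt`: final `molecule`, numeric
#'   `trace` of accepted gaps (starting gap first), `status` and `mode`.
#' @export
optimize_gap <- function(surface, mol, n_electrons = NULL,
                         mode = c("max", "min"), step = 0.01,
                         max_iter = 50L, tol = 1e-4) {
  mode <- match.arg(mode)
  if (is.null(n_electrons)) n_electrons <- surface$n_electrons
  if (is.null(n_electrons)) stop("n_electrons required for this surface")
  sgn <- if (mode == "max") 1 else -1
  st <- tryCatch(gap_state(surface, mol, n_electrons),
                 error = function(e) e)
  if (inherits(st, "error")) stop(st)
  trace <- st$gap
  status <- "max_iter"
  cur <- mol
  for (it in seq_len(max_iter)) {
    moved <- FALSE
    while (step > 1e-8) {
      cand <- cur
      cand$positions <- cur$positions + sgn * step * st$grad
      stc <- tryCatch(gap_state(surface, cand, n_electrons),
                      error = function(e) e)
      if (inherits(stc, "error")) {
        status <- "degenerate"
        break
      }
      if (sgn * (stc$gap - st$gap) > 0) {
        delta <- abs(stc$gap - st$gap)
        cur <- cand; st <- stc
        trace <- c(trace, st$gap)
        moved <- TRUE
        if (delta < tol) status <- "converged"
        break
      }
      step <- step / 2
    }
    if (status %in% c("degenerate", "converged")) break
    if (!moved) { status <- "step_underflow"; break }
  }
  structure(list(molecule = cur, trace = trace, status = status, mode = mode,
                 step = step),
            class = "slite_gapopt")
}

#' @export
print.slite_gapopt <- function(x, ...) {
  cat("<slite_gapopt> mode=", x$mode, ": gap ",
      sprintf("%.4f", x$trace[1]), " -> ",
      sprintf("%.4f", x$trace[length(x$trace)]), " eV in ",
      length(x$trace) - 1L, " accepted steps (", x$status, ")\n", sep = "")
  invisible(x)
}
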