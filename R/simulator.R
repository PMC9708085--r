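#' Simulator configuration
#'
#' Parameters of the stochastic division model: for each simulation a
#' volume ratio rho is drawn uniformly in `rho_range`, the mother's voxels
#' are assigned to the two daughters with probability rho / (1 - rho), and
#' the interface area is minimized by Metropolis Monte Carlo. One cycle is
#' N single-voxel flip proposals (N = mother voxel count); beta is adapted
#' after each cycle so that about `target_acceptance` of the proposals that
#' would increase interface area are accepted.
#'
#' @param rho_range interval for the drawn volume ratio (smaller daughter /
#'   mother), within (0, 0.5].
#' @param n_cycles number of Monte Carlo cycles per simulation.
#' @param target_acceptance setpoint for the acceptance rate of
#'   area-increasing flips.
#' @param n_simulations default number of independent runs per mother cell.
#' @param kappa gain of the multiplicative beta controller.
#' @param beta_bounds clamp for beta.
#' @param volume_tether strength of the volume-ratio tether in units of the
#'   median voxel-face area: the energy is the interface area plus
#'   `volume_tether * a_med * |n_A - rho N|`. Single-voxel flips do not
#'   conserve volume, and on desk-scale masks the minority daughter would
#'   otherwise vanish by curvature flow before the interface settles; the
#'   tether keeps the achieved ratio near the drawn one while area remains
#'   the only term shaping the interface. Set 0 for the untethered model.
#' @param cooling_cycles length of the cooling tail appended after the
#'   setpoint phase, during which the acceptance target decays to ~2% of
#'   `target_acceptance` so the run settles into a single local area
#'   minimum; acceptance statistics are reported for the setpoint phase
#'   only.
#' @param anneal_cycles number of zero-temperature (greedy descent) cycles
#'   appended after the cooling tail, removing residual interface
#'   roughness so each run lands in its nearest local area minimum.
#' @param cleanup keep only the largest 6-connected component per daughter
#'   at the end of a run, reassigning stray voxels to the other daughter.
#' @return an object of class `simulator_config`.
#' @export
simulator_config <- function(rho_range = c(0.2, 0.5), n_cycles = 500,
                             target_acceptance = 0.05, n_simulations = 1000,
                             kappa = 0.5, beta_bounds = c(1e-4, 1e4),
                             volume_tether = 1, cooling_cycles = 100,
                             anneal_cycles = 25, cleanup = TRUE) {
  if (rho_range[1] <= 0 || rho_range[2] > 0.5 ||
      rho_range[1] > rho_range[2])
    stop("rho_range must satisfy 0 < rho_min <= rho_max <= 0.5")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  structure(list(rho_range = rho_range, n_cycles = as.integer(n_cycles),
                 target_acceptance = target_acceptance,
                 n_simulations = as.integer(n_simulations), kappa = kappa,
                 beta_bounds = beta_bounds,
                 volume_tether = volume_tether,
                 cooling_cycles = as.integer(cooling_cycles),
                 anneal_cycles = as.integer(anneal_cycles),
                 cleanup = cleanup),
            class = "simulator_config")
}

as_partition_labels <- function(mask) {
  if (is.logical(mask)) return(mask)
  unclass(mask) != 0
}

partition_voxel_dims <- function(mask, voxel_dims) {
  if (!is.null(voxel_dims)) return(as.numeric(voxel_dims))
  vd <- attr(mask, "voxel_dims")
  if (is.null(vd)) c(1, 1, 1) else vd
}

#' Binary partition of a mother cell
#'
#' Wraps an integer array with values 0 (outside the mother), 1 (daughter
#' A) and 2 (daughter B), plus the voxel calibration.
#'
#' @param labels integer 3D array in {0, 1, 2}.
#' @param voxel_dims voxel edge lengths (micrometres).
#' @return an object of class `division_partition`.
#' @export
division_partition <- function(labels, voxel_dims = c(1, 1, 1)) {
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:2)) stop("labels must be 0, 1 or 2")
  structure(list(labels = labels, voxel_dims = as.numeric(voxel_dims)),
            class = "division_partition")
}

#' @export
print.division_partition <- function(x, ...) {
  n <- tabulate(x$labels[x$labels > 0], 2L)
  cat(sprintf("division_partition: |A| = %d, |B| = %d, area = %.3f um^2\n",
              n[1], n[2], interface_area(x)))
  invisible(x)
}

#' Random initial partition at a volume ratio
#'
#' Assigns each mother voxel independently to daughter A with probability
#' rho and to B otherwise.
#'
#' @param mask logical 3D mother mask (or a binary `label_image`).
#' @param rho target volume ratio, in (0, 1).
#' @param voxel_dims voxel calibration; taken from `mask` when present.
#' @return a [division_partition()].
#' @export
initialize_partition <- function(mask, rho, voxel_dims = NULL) {
  if (!is.finite(rho) || rho <= 0 || rho >= 1)
    stop("rho must lie strictly between 0 and 1")
  vd <- partition_voxel_dims(mask, voxel_dims)
  fg <- as_partition_labels(mask)
  lab <- array(0L, dim(fg))
  n <- sum(fg)
  lab[fg] <- ifelse(stats::runif(n) < rho, 1L, 2L)
  division_partition(lab, vd)
}

#' Interface area between the two daughters
#'
#' Sum of the physical areas of the voxel faces shared by differently
#' labelled mother voxels (6-connectivity; a face normal to axis k has area
#' equal to the product of the other two voxel edge lengths).
#'
#' @param partition a [division_partition()].
#' @return area in square micrometres.
#' @export
interface_area <- function(partition) {
  cpp_interface_area(as.integer(partition$labels),
                     dim(partition$labels), partition$voxel_dims)
}

#' One Metropolis cycle
#'
#' Performs N single-voxel flip proposals (N = mother voxel count) at fixed
#' beta: proposals decreasing the interface area are always accepted,
#' others with probability exp(-beta * deltaA).
#'
#' @param partition a [division_partition()].
#' @param beta inverse-temperature parameter (>= 0).
#' @return list with the updated `partition`, `area`, and the counts
#'   `proposed_up` / `accepted_up` of area-increasing proposals.
#' @export
metropolis_cycle <- function(partition, beta) {
  if (beta < 0) stop("beta must be >= 0")
  res <- cpp_metropolis(as.integer(partition$labels), dim(partition$labels),
                        partition$voxel_dims, 1L, beta, 0, 0, beta, beta,
                        FALSE, 0, 0, 0L)
  list(partition = division_partition(
         array(res$labels, dim(partition$labels)), partition$voxel_dims),
       area = res$area,
       proposed_up = res$prop_up[1], accepted_up = res$acc_up[1])
}

#' Adapt beta toward the target acceptance rate
#'
#' Multiplicative controller `beta' = beta * (1 + kappa * (observed -
#' target))`, clamped to `bounds`. Raising beta lowers the acceptance of
#' area-increasing flips, so the control moves the observed rate toward the
#' target.
#'
#' @param beta current beta.
#' @param observed observed acceptance fraction of area-increasing flips.
#' @param target setpoint (default 0.05).
#' @param kappa controller gain.
#' @param bounds clamp interval for beta.
#' @return updated beta.
#' @export
adapt_beta <- function(beta, observed, target = 0.05, kappa = 0.5,
                       bounds = c(1e-4, 1e4)) {
  if (observed < 0 || observed > 1)
    stop("observed acceptance must be in [0, 1]")
  min(max(beta * (1 + kappa * (observed - target)), bounds[1]), bounds[2])
}

# beta such that a flip costing one median voxel-face area is accepted with
# probability 1/2.
default_beta0 <- function(voxel_dims) {
  areas <- c(voxel_dims[2] * voxel_dims[3], voxel_dims[1] * voxel_dims[3],
             voxel_dims[1] * voxel_dims[2])
  log(2) / stats::median(areas)
}

#' Simulate one stochastic division
#'
#' Draws a volume ratio, initializes a Bernoulli partition and runs the
#' adaptive Metropolis minimization of interface area. No volume penalty is
#' applied, so the achieved ratio may drift from the drawn one. By default
#' the final partition is cleaned by keeping the largest 6-connected
#' component per daughter and reassigning stray voxels.
#'
#' @param mask logical 3D mother mask (must be 6-connected).
#' @param config a [simulator_config()].
#' @param seed RNG seed for this run (recorded in the result).
#' @param voxel_dims voxel calibration; taken from `mask` when present.
#' @return a `simulation_result`: list with `partition`, `interface_area`,
#'   `distance_to_center`, `volume_ratio` (achieved), `rho_drawn`,
#'   `beta_traj`, `acc_frac`, `prop_up`, `acc_up`, `area_traj`, `cleaned`,
#'   `seed`, `cycles`.
#' @export
simulate_division <- function(mask, config = simulator_config(),
                              seed = NULL, voxel_dims = NULL) {
  vd <- partition_voxel_dims(mask, voxel_dims)
  fg <- as_partition_labels(mask)
  if (!any(fg)) stop("input error: empty mask")
  comp <- array(cpp_label_components(as.integer(fg), dim(fg)), dim(fg))
  if (max(comp) != 1L) stop("input error: mask must be 6-connected")
  if (!is.null(seed)) set.seed(seed)
  rho <- stats::runif(1, config$rho_range[1], config$rho_range[2])
  init <- initialize_partition(fg, rho, vd)
  a_med <- stats::median(c(vd[2] * vd[3], vd[1] * vd[3], vd[1] * vd[2]))
  w <- config$volume_tether * a_med
  res <- cpp_metropolis(as.integer(init$labels), dim(fg), vd,
                        config$n_cycles, default_beta0(vd),
                        config$target_acceptance, config$kappa,
                        config$beta_bounds[1], config$beta_bounds[2], TRUE,
                        rho * sum(fg), w, config$cooling_cycles)
  lab <- array(res$labels, dim(fg))
  if (config$anneal_cycles > 0L) {
    # tethered greedy descent: removes most thermal roughness while the
    # volume tether keeps the run in the family the adaptive phase selected
    # (untethered descent would slide oblique cuts toward the nearest
    # corner, since their area decreases monotonically with volume)
    ann <- cpp_metropolis(as.integer(lab), dim(fg), vd,
                          config$anneal_cycles, config$beta_bounds[2],
                          config$target_acceptance, 0,
                          config$beta_bounds[2], config$beta_bounds[2],
                          FALSE, rho * sum(fg), w, 0L)
    lab <- array(ann$labels, dim(fg))
  }
  cleaned <- FALSE
  if (config$cleanup) {
    out <- cleanup_partition(lab)
    cleaned <- out$changed
    lab <- out$labels
  }
  part <- division_partition(lab, vd)
  ctr <- cell_center(fg, voxel_dims = vd)
  degenerate <- length(unique(lab[lab > 0L])) < 2L
  structure(list(
    partition = part,
    interface_area = interface_area(part),
    distance_to_center = if (degenerate) NA_real_
                         else distance_to_center(part, ctr),
    volume_ratio = if (degenerate) 0 else volume_ratio(part),
    degenerate = degenerate,
    rho_drawn = rho,
    beta_traj = res$beta_traj, acc_frac = res$acc_frac,
    prop_up = res$prop_up, acc_up = res$acc_up,
    area_traj = res$area_traj,
    cleaned = cleaned, seed = seed, cycles = config$n_cycles),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(paste0("simulation_result: area %.3f um^2, distance %.3f um,",
                     " ratio %.3f (rho drawn %.3f)\n"),
              x$interface_area, x$distance_to_center, x$volume_ratio,
              x$rho_drawn))
  invisible(x)
}

# Keep the largest 6-connected component per daughter label; voxels in the
# discarded fragments are reassigned to the other daughter.
cleanup_partition <- function(lab) {
  changed <- FALSE
  for (value in 1:2) {
    m <- lab == value
    if (!any(m)) next
    comp <- array(cpp_label_components(as.integer(m), dim(lab)), dim(lab))
    ids <- comp[m]
    if (length(unique(ids)) > 1L) {
      keep <- as.integer(names(which.max(table(ids))))
      lab[m & comp != keep] <- 3L - value
      changed <- TRUE
    }
  }
  list(labels = lab, changed = changed)
}

#' Minimum distance from the cell center to the interface
#'
#' Distance from a reference point (typically the mother cell center) to
#' the nearest interface voxel-face center.
#'
#' @param partition a [division_partition()].
#' @param center physical point (micrometres), e.g. from [cell_center()].
#' @return distance in micrometres.
#' @export
distance_to_center <- function(partition, center) {
  img <- label_image(partition$labels, partition$voxel_dims)
  faces <- interface_faces(img, 1L, 2L)
  if (nrow(faces$centers) == 0L)
    stop("degenerate division: partition has no interface")
  d2 <- rowSums(sweep(faces$centers, 2L, center)^2)
  sqrt(min(d2))
}

#' Achieved volume ratio of a partition
#'
#' Ratio of the smaller daughter's voxel count to the mother's (the voxel
#' volume cancels), in (0, 0.5].
#'
#' @param partition a [division_partition()].
#' @return numeric ratio.
#' @export
volume_ratio <- function(partition) {
  n <- tabulate(partition$labels[partition$labels > 0L], 2L)
  if (any(n == 0L)) stop("degenerate division: one daughter is empty")
  min(n) / sum(n)
}
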