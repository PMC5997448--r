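#' Potential energy of a tube mesh
#'
#' Evaluates \eqn{U = U_L + U_{ES} + U_{EV} + U_B}: total weighted edge
#' length of the lateral cells (by default each interior edge is counted
#' through both incident cells; see the \code{edge_count} field of
#' \code{\link{model_params}}; cap faces carry no edge energy), areal
#' elasticity
#' \eqn{\kappa_S \sum_\alpha (S_\alpha - S_o)^2} over the lateral cells,
#' volumetric elasticity \eqn{\kappa_V (V - V_o)^2} of the enclosed tube,
#' and the end-ring restriction
#' \eqn{\kappa_B \sum_j [(r_j - r_{ring})^2 - R^2]^2} with the ring centre
#' taken as the instantaneous ring centroid.
#'
#' @param mesh a \code{tube_mesh}.
#' @param params a \code{\link{model_params}}.
#' @param special optional per-cell list of special edges (2-column vertex
#'   pair matrices) carrying weight \code{w_special}.
#' @param w_special weight of the special edges (default 1 = no anisotropy).
#' @return A list with components \code{U_L}, \code{U_ES}, \code{U_EV},
#'   \code{U_B} and their sum \code{U}.
#' @export
potential_energy <- function(mesh, params = model_params(), special = NULL,
                             w_special = 1) {
  topo <- mesh_topology(mesh, special, w_special, params$edge_count)
  cpp_energy(mesh$vertices, topo$fptr, topo$fvert, topo$nlat, topo$e1,
             topo$e2, topo$emult, topo$topv, topo$botv, unclass(params))
}

#' Forces on the mesh vertices
#'
#' The analytic negative gradient of \code{\link{potential_energy}} with
#' respect to every vertex coordinate. The z components on end-ring
#' vertices are always zeroed (the rings stay in their initial planes); with
#' \code{fix_end_rotation} their x and y components are zeroed as well.
#'
#' @inheritParams potential_energy
#' @param fix_end_rotation freeze the end rings completely.
#' @return An n x 3 matrix of force vectors.
#' @export
vertex_forces <- function(mesh, params = model_params(), special = NULL,
                          w_special = 1, fix_end_rotation = FALSE) {
  topo <- mesh_topology(mesh, special, w_special, params$edge_count)
  cpp_forces(mesh$vertices, topo$fptr, topo$fvert, topo$nlat, topo$e1,
             topo$e2, topo$emult, topo$topv, topo$botv, unclass(params),
             fix_end_rotation)
}

#' One classical Runge-Kutta step of the overdamped dynamics
#'
#' Advances all free vertex coordinates by one step of size \code{params$h}
#' under \eqn{dr_i/dt = -\nabla_i U}; constrained coordinates (end-ring z,
#' plus x/y when \code{fix_end_rotation}) are untouched.
#'
#' @inheritParams vertex_forces
#' @return The mesh after one step.
#' @export
step_rk4 <- function(mesh, params = model_params(), special = NULL,
                     w_special = 1, fix_end_rotation = FALSE) {
  topo <- mesh_topology(mesh, special, w_special, params$edge_count)
  res <- cpp_run(mesh$vertices, topo$fptr, topo$fvert, topo$nlat, topo$e1,
                 topo$e2, topo$emult, topo$topv, topo$botv, unclass(params),
                 params$h, 1L, 0L, 1L, params$delta, FALSE,
                 rep(FALSE, length(topo$e1)), rep(TRUE, length(topo$e1)),
                 1.5 * params$delta, fix_end_rotation)
  if (res$status == 2L)
    stop("non-finite coordinates after RK4 step")
  mesh$vertices <- res$V
  dimnames(mesh$vertices) <- list(NULL, c("x", "y", "z"))
  mesh
}

#' Run the overdamped vertex dynamics
#'
#' Integrates the equation of motion with fixed-step RK4, scanning after
#' every step for interior edges shorter than \code{params$delta}. When
#' reconnection is enabled, sub-threshold edges are processed in ascending
#' length order by the T1 neighbor-exchange of \code{\link{reconnect_edge}};
#' a swap that would leave a face with fewer than 3 sides, or that touches
#' an end ring, is skipped and logged. States and the energy breakdown are
#' recorded every \code{save_every} time units (and at t = 0).
#'
#' @param mesh starting \code{tube_mesh}.
#' @param params a \code{\link{model_params}}.
#' @param t_end duration (truncated to a whole number of steps).
#' @param reconnect enable T1 reconnection (default TRUE).
#' @param fix_end_rotation freeze end-ring x/y (stopped-rotation control).
#' @param save_every recording interval in time units.
#' @param chirality optional anisotropy: a list with \code{polarity}
#'   (n_cells x 3), \code{special} (per-cell special-edge list) and
#'   \code{w_special}; special edges destroyed by a reconnection are
#'   re-selected for the affected cells.
#' @param verbose print progress every 1000 steps.
#' @return A \code{trajectory}: saved \code{times}, \code{states} (list of
#'   vertex matrices), \code{energy} matrix (columns U_L, U_ES, U_EV, U_B,
#'   U), per-save topology ids, the topology versions, the reconnection
#'   \code{events} data frame, the final \code{mesh}, and the inputs.
#' @export
run_dynamics <- function(mesh, params = model_params(), t_end = 80,
                         reconnect = TRUE, fix_end_rotation = FALSE,
                         save_every = 0.5, chirality = NULL,
                         verbose = FALSE) {
  if (t_end <= 0) stop("'t_end' must be positive")
  h <- params$h
  nsteps <- floor(t_end / h + 1e-9)
  save_steps <- max(1L, as.integer(round(save_every / h)))

  special <- chirality$special
  w_special <- if (is.null(chirality)) 1 else chirality$w_special

  U0 <- potential_energy(mesh, params, special, w_special)
  times <- 0
  states <- list(mesh$vertices)
  energy <- matrix(unlist(U0), 1, 5,
                   dimnames = list(NULL, c("U_L", "U_ES", "U_EV", "U_B", "U")))
  topologies <- list(list(faces = mesh$faces, cap_top = mesh$cap_top,
                          cap_bottom = mesh$cap_bottom))
  topo_id <- 1L
  events <- list()
  # Reconnection fires when an edge *becomes* shorter than delta (a
  # downward crossing), with hysteresis: an edge that starts below delta,
  # was just created by a T1, or whose swap was refused stays disarmed
  # until it has grown past 1.5 * delta.
  unarmed <- character(0)
  step0 <- 0L
  first_chunk <- TRUE

  while (step0 < nsteps) {
    topo <- mesh_topology(mesh, special, w_special, params$edge_count)
    ekey <- paste(topo$edges[, 1], topo$edges[, 2])
    armed <- !(ekey %in% unarmed)
    if (first_chunk) {
      len <- sqrt(rowSums((mesh$vertices[topo$edges[, 1], , drop = FALSE] -
                             mesh$vertices[topo$edges[, 2], , drop = FALSE])^2))
      armed <- armed & len >= params$delta
      first_chunk <- FALSE
    }
    res <- cpp_run(mesh$vertices, topo$fptr, topo$fvert, topo$nlat, topo$e1,
                   topo$e2, topo$emult, topo$topv, topo$botv,
                   unclass(params), h, nsteps - step0, step0, save_steps,
                   params$delta, reconnect, topo$reco_ok, armed,
                   1.5 * params$delta, fix_end_rotation)
    unarmed <- ekey[!res$armed]
    mesh$vertices <- res$V
    dimnames(mesh$vertices) <- list(NULL, c("x", "y", "z"))
    step0 <- step0 + res$steps_done
    ns <- length(res$save_steps)
    if (ns > 0) {
      times <- c(times, res$save_steps * h)
      energy <- rbind(energy, res$save_U)
      st <- res$states
      for (k in seq_len(ns)) states <- c(states, list(t(st[, , k])))
      topo_id <- c(topo_id, rep.int(length(topologies), ns))
      if (verbose && step0 %% 1000L == 0L)
        message(sprintf("  step %d / %d (t = %.2f), U = %.6g",
                        step0, nsteps, step0 * h, energy[nrow(energy), 5]))
    }
    if (res$status == 2L) {
      dump <- tempfile("chiratube_state_", fileext = ".json")
      save_state_json(mesh, dump, params = params)
      stop("non-finite coordinates at step ", step0,
           "; diagnostic state dumped to ", dump)
    }
    if (res$status == 1L) {
      e <- topo$edges[res$short_edge, ]
      sw <- try(reconnect_edge(mesh, e[1], e[2], delta = params$delta,
                               min_area = 0.05 * params$S_o),
                silent = TRUE)
      unarmed <- c(unarmed, paste(e[1], e[2]))
      if (inherits(sw, "try-error") || is.null(sw$mesh)) {
        events[[length(events) + 1L]] <- data.frame(
          t = step0 * h, step = step0, v1 = e[1], v2 = e[2],
          length_before = res$short_length,
          faces_lost_1 = NA_integer_, faces_lost_2 = NA_integer_,
          faces_gained_1 = NA_integer_, faces_gained_2 = NA_integer_,
          skipped = TRUE)
      } else {
        mesh <- sw$mesh
        topologies <- c(topologies, list(list(faces = mesh$faces,
                                              cap_top = mesh$cap_top,
                                              cap_bottom = mesh$cap_bottom)))
        events[[length(events) + 1L]] <- data.frame(
          t = step0 * h, step = step0, v1 = e[1], v2 = e[2],
          length_before = res$short_length,
          faces_lost_1 = sw$faces_lost[1], faces_lost_2 = sw$faces_lost[2],
          faces_gained_1 = sw$faces_gained[1],
          faces_gained_2 = sw$faces_gained[2],
          skipped = FALSE)
        if (!is.null(special)) {
          affected <- c(sw$faces_lost, sw$faces_gained)
          for (f in affected) {
            sp <- special[[f]]
            if (is.null(sp) || nrow(sp) == 0) next
            still <- edges_in_loop(sp, mesh$faces[[f]])
            if (!all(still)) {
              # a reconnection destroyed a special edge: drop it (the
              # cell's anisotropy fades as junctions remodel); optionally
              # re-select from the current geometry
              special[[f]] <- if (isTRUE(chirality$reselect))
                select_special_edges(mesh, f, chirality$polarity[f, ])
              else sp[still, , drop = FALSE]
            }
          }
        }
      }
    }
  }

  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(t = numeric(0), step = integer(0), v1 = integer(0),
               v2 = integer(0), length_before = numeric(0),
               faces_lost_1 = integer(0), faces_lost_2 = integer(0),
               faces_gained_1 = integer(0), faces_gained_2 = integer(0),
               skipped = logical(0))

  structure(list(times = times, states = states, energy = energy,
                 topo_id = topo_id, topologies = topologies, events = ev,
                 mesh = mesh, special = special, params = params,
                 options = list(t_end = t_end, reconnect = reconnect,
                                fix_end_rotation = fix_end_rotation,
                                save_every = save_every)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  nev <- sum(!x$events$skipped)
  cat(sprintf("Vertex-dynamics trajectory: t = 0 .. %.4g (%d saved states)\n",
              max(x$times), length(x$times)))
  cat(sprintf("  U: %.6g -> %.6g; %d reconnection event(s)%s\n",
              x$energy[1, "U"], x$energy[nrow(x$energy), "U"], nev,
              if (any(x$events$skipped))
                sprintf(" (+%d skipped)", sum(x$events$skipped)) else ""))
  invisible(x)
}

# are the rows of edge-matrix 'sp' edges of loop?
edges_in_loop <- function(sp, loop) {
  nx <- c(loop[-1], loop[1])
  lk <- paste(pmin(loop, nx), pmax(loop, nx))
  paste(pmin(sp[, 1], sp[, 2]), pmax(sp[, 1], sp[, 2])) %in% lk
}

# mesh (with given topology version) at saved state k of a trajectory
mesh_at <- function(traj, k) {
  topo <- traj$topologies[[traj$topo_id[k]]]
  structure(list(vertices = traj$states[[k]], faces = topo$faces,
                 cap_top = topo$cap_top, cap_bottom = topo$cap_bottom,
                 geometry = traj$mesh$geometry),
            class = "tube_mesh")
}
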