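#' Model parameters for the tube vertex dynamics
#'
#' Bundles every constant of the potential energy
#' \eqn{U = U_L + U_{ES} + U_{EV} + U_B} together with the solver step and
#' the reconnection threshold. Defaults are the standard parameter set used
#' for the full-size (452-cell) tube; lengths are in units of the relaxed
#' cell size \eqn{R_o = S_o^{1/2}} and time in units of \eqn{1/(\eta R_o)},
#' so the drag coefficient never appears explicitly.
#'
#' @param sigma_L edge energy density (default 2.2).
#' @param kappa_S areal elastic density of the cell polygons (default 10.0).
#' @param kappa_V volumetric elastic density of the enclosed tube (0.2).
#' @param kappa_B elastic constant of the end-ring restriction (1.0).
#' @param S_o relaxed polygon area (1 after rescaling).
#' @param V_o relaxed tube volume (566.64 for the full-size tube).
#' @param R_top,R_bottom radii of the top and bottom end rings (2.5).
#' @param h Runge-Kutta step size (0.005).
#' @param delta critical edge length triggering vertex reconnection (0.3).
#' @param w_special edge-weight multiplier applied to the two strongly
#'   contracting ("special") edges of each cell during chirality induction
#'   (default 3.5; all other edges have weight 1).
#' @param fix_ring_z hold the z coordinate of end-ring vertices at its
#'   initial value (TRUE, default), so the end rings stay in their planes;
#'   with FALSE the rings are restricted to spheres about their
#'   instantaneous centroids only.
#' @param edge_count counting convention of the edge energy:
#'   \code{"per_cell"} (default) sums each cell's own edge energies, so an
#'   interior edge is counted through both incident cells (the literal
#'   reading of the per-cell edge sum); \code{"per_edge"} gives every
#'   physical cell-cell boundary the energy density once, with weight
#'   \code{w_special} if either incident cell declares it special. See the
#'   methods vignette for the consequences of each convention.
#'
#' @return An object of class \code{model_params} (a validated list).
#' @examples
#' p <- model_params()
#' p$sigma_L
#' @export
model_params <- function(sigma_L = 2.2, kappa_S = 10.0, kappa_V = 0.2,
                         kappa_B = 1.0, S_o = 1.0, V_o = 566.64,
                         R_top = 2.5, R_bottom = 2.5, h = 0.005,
                         delta = 0.3, w_special = 3.5,
                         edge_count = c("per_cell", "per_edge"),
                         fix_ring_z = TRUE) {
  edge_count <- match.arg(edge_count)
  p <- list(sigma_L = sigma_L, kappa_S = kappa_S, kappa_V = kappa_V,
            kappa_B = kappa_B, S_o = S_o, V_o = V_o, R_top = R_top,
            R_bottom = R_bottom, h = h, delta = delta,
            w_special = w_special, edge_count = edge_count,
            fix_ring_z = isTRUE(fix_ring_z))
  validate_model_params(p)
  class(p) <- "model_params"
  p
}

validate_model_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("sigma_L", "kappa_S", "kappa_V", "kappa_B")) {
    if (!num1(p[[nm]]) || p[[nm]] < 0)
      stop(sprintf("'%s' must be a single non-negative number", nm))
  }
  for (nm in c("S_o", "V_o", "R_top", "R_bottom", "h", "delta")) {
    if (!num1(p[[nm]]) || p[[nm]] <= 0)
      stop(sprintf("'%s' must be a single positive number", nm))
  }
  if (!num1(p$w_special) || p$w_special < 1)
    stop("'w_special' must be a single number >= 1")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Vertex-model parameters\n")
  cat(sprintf("  sigma_L = %g, kappa_S = %g, kappa_V = %g, kappa_B = %g\n",
              x$sigma_L, x$kappa_S, x$kappa_V, x$kappa_B))
  cat(sprintf("  S_o = %g, V_o = %g, R_top = %g, R_bottom = %g\n",
              x$S_o, x$V_o, x$R_top, x$R_bottom))
  cat(sprintf("  h = %g, delta = %g, w_special = %g\n",
              x$h, x$delta, x$w_special))
  invisible(x)
}

#' Chirality-induction protocols
#'
#' The induction protocol fixes the polarity deflection angle, the special
#' edge weight and the duration of the induction run. Two presets are
#' provided: \code{"wildtype"} (+30 degrees, weight 3.5, run to t = 5)
#' yields leftward-tilted cells; \code{"inverted"} (-35 degrees, weight
#' 3.5, run to t = 10) yields the enantiomorphic, rightward-tilted tube.
#'
#' @param name preset name, \code{"wildtype"} or \code{"inverted"}, or
#'   \code{NULL} to build a custom protocol from the remaining arguments.
#' @param deflection_deg polarity deflection angle from the tube (AP) axis,
#'   degrees; positive tilts leftward (toward decreasing azimuth on the
#'   unrolled plane).
#' @param w_special weight multiplier for the two special edges.
#' @param t_induction duration of the induction run.
#'
#' @return A \code{chirality_protocol} list.
#' @examples
#' chirality_protocol("inverted")
#' @export
chirality_protocol <- function(name = NULL, deflection_deg = 30,
                               w_special = 3.5, t_induction = 5.0) {
  if (!is.null(name)) {
    name <- match.arg(name, c("wildtype", "inverted"))
    if (name == "wildtype") {
      deflection_deg <- 30; w_special <- 3.5; t_induction <- 5.0
    } else {
      deflection_deg <- -35; w_special <- 3.5; t_induction <- 10.0
    }
  }
  if (abs(deflection_deg) >= 90)
    stop("'deflection_deg' must satisfy |deflection_deg| < 90")
  if (t_induction <= 0) stop("'t_induction' must be positive")
  if (w_special < 1) stop("'w_special' must be >= 1")
  structure(list(deflection_deg = deflection_deg, w_special = w_special,
                 t_induction = t_induction),
            class = "chirality_protocol")
}

#' Tube geometry of the standard full-size model
#'
#' @return A list with the rectangle dimensions used for the tessellation,
#'   the disc diameter of the packing, the number of cells, and the nominal
#'   tube diameter used for end-ring radii and cylinder projection.
#' @export
default_geometry <- function() {
  list(n_cells = 452L, rect_width = 15.75, rect_height = 28.7,
       disc_diameter = 0.82, tube_diameter = 5.0)
}

#' Load a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys fall back to the standard
#' defaults (\code{\link{model_params}}, \code{\link{default_geometry}},
#' wild-type protocol). The configuration has four blocks:
#' \code{geometry}, \code{params}, \code{protocol} (either a preset name or
#' explicit fields) and \code{options} (\code{t_end}, \code{reconnect},
#' \code{fix_end_rotation}, \code{save_every}, \code{seed}).
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A validated \code{run_config} list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml, .yml or .json, got .", ext)
  if (is.null(raw)) raw <- list()
  build_run_config(raw)
}

build_run_config <- function(raw) {
  known_blocks <- c("geometry", "params", "protocol", "options", "preset")
  bad <- setdiff(names(raw), known_blocks)
  if (length(bad))
    stop("unknown config block(s): ", paste(bad, collapse = ", "))

  take <- function(block, defaults, validate_extra = NULL) {
    blk <- raw[[block]]
    if (is.null(blk)) blk <- list()
    bad <- setdiff(names(blk), names(defaults))
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s': %s (valid: %s)", block,
                   paste(bad, collapse = ", "),
                   paste(names(defaults), collapse = ", ")))
    utils::modifyList(defaults, blk)
  }

  geometry <- take("geometry", default_geometry())
  pdef <- unclass(model_params())
  params <- do.call(model_params, take("params", pdef))

  prot_raw <- raw$protocol
  protocol <- if (is.character(prot_raw) && length(prot_raw) == 1L) {
    chirality_protocol(prot_raw)
  } else {
    pd <- list(deflection_deg = 30, w_special = 3.5, t_induction = 5.0)
    if (!is.null(prot_raw)) {
      bad <- setdiff(names(prot_raw), names(pd))
      if (length(bad))
        stop("unknown key(s) in 'protocol': ", paste(bad, collapse = ", "))
      pd <- utils::modifyList(pd, prot_raw)
    }
    do.call(chirality_protocol, c(list(name = NULL), pd))
  }

  odef <- list(t_end = 80, reconnect = TRUE, fix_end_rotation = FALSE,
               save_every = 0.5, seed = 1L)
  options <- take("options", odef)
  if (options$t_end <= 0) stop("'t_end' must be positive")
  if (options$save_every <= 0) stop("'save_every' must be positive")

  preset <- raw$preset
  if (!is.null(preset)) {
    cfgp <- preset_config(preset)
    protocol <- cfgp$protocol
    options$reconnect <- cfgp$options$reconnect
    options$fix_end_rotation <- cfgp$options$fix_end_rotation
  }

  structure(list(geometry = geometry, params = params, protocol = protocol,
                 options = options),
            class = "run_config")
}

#' Experiment presets
#'
#' Four presets reproduce the published simulation variants:
#' \describe{
#'   \item{wildtype}{+30 degree induction to t = 5, relaxation with
#'     reconnections enabled.}
#'   \item{inverted}{-35 degree induction to t = 10 (enantiomorphic tube).}
#'   \item{no_reconnect}{wild-type protocol but vertex reconnection
#'     disabled during relaxation.}
#'   \item{fixed_ends}{wild-type protocol with the x/y coordinates of the
#'     end-ring vertices frozen during relaxation (stopped-rotation
#'     control).}
#' }
#'
#' @param preset preset name (dashes and underscores both accepted).
#' @return A list with \code{protocol} and \code{options} entries.
#' @export
preset_config <- function(preset) {
  preset <- gsub("-", "_", preset)
  preset <- match.arg(preset,
                      c("wildtype", "inverted", "no_reconnect", "fixed_ends"))
  protocol <- chirality_protocol(
    if (preset == "inverted") "inverted" else "wildtype")
  list(preset = preset,
       protocol = protocol,
       options = list(reconnect = preset != "no_reconnect",
                      fix_end_rotation = preset == "fixed_ends"))
}
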