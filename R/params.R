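#' Model parameters for the topological swarm
#'
#' Bundles the constants of the pairwise interaction force, the force
#' weights, the displacement gain, and the run-control settings. The
#' defaults are the reference simulation values used throughout:
#' agents repel below the expected distance `d_e` and attract above it, with
#' attraction saturating at `k3` beyond the threshold `(d_e + d_h)/2`.
#'
#' @param d_l Lower bound of the repulsive range. Repulsion acts only at
#'   pairwise distances in `(d_l, d_e)`. Same length units as coordinates.
#' @param d_e Expected (equilibrium) distance at which the pair force
#'   vanishes.
#' @param d_h Upper bound entering the attractive sine branch; together with
#'   `d_e` it sets the sine period and the saturation threshold
#'   `(d_e + d_h)/2`.
#' @param k1 Repulsion coefficient (> 0).
#' @param k2 Coefficient of the sine attraction branch (> 0).
#' @param k3 Saturated attraction magnitude (> 0). Values different from
#'   `k2` make the force discontinuous at the saturation threshold and
#'   trigger a warning.
#' @param a Weight of attraction in the resultant force (> 0).
#' @param b Weight of repulsion in the resultant force (> 0).
#' @param c Proportionality between resultant force and per-step
#'   displacement (> 0).
#' @param dims Spatial dimensionality, 2 or 3.
#' @param t_max Maximum number of simulation steps.
#' @param stability_tol Relative tolerance for stationarity: the run is
#'   stationary once the largest per-step change of any pairwise distance
#'   stays below `stability_tol * d_e`.
#' @param stability_window Number of consecutive quiet steps required before
#'   the configuration is declared stationary.
#'
#' @return An object of class `swarm_params` (a validated named list).
#' @examples
#' p <- swarm_params()
#' p$d_e
#' @export
swarm_params <- function(d_l = 0, d_e = 5.2, d_h = 12,
                         k1 = 1, k2 = 0.3, k3 = 0.3,
                         a = 0.08, b = 0.2, c = 1,
                         dims = 3, t_max = 20000,
                         stability_tol = 1e-6, stability_window = 50) {
  num <- c(d_l = d_l, d_e = d_e, d_h = d_h, k1 = k1, k2 = k2, k3 = k3,
           a = a, b = b, c = c, stability_tol = stability_tol)
  if (!all(is.finite(num))) stop("all parameters must be finite", call. = FALSE)
  if (!(d_l >= 0 && d_l < d_e && d_e < d_h)) {
    stop("require 0 <= d_l < d_e < d_h", call. = FALSE)
  }
  if (!all(c(k1, k2, k3, a, b, c) > 0)) {
    stop("k1, k2, k3, a, b, c must all be positive", call. = FALSE)
  }
  if (!dims %in% c(2, 3)) stop("dims must be 2 or 3", call. = FALSE)
  t_max <- check_count(t_max, "t_max")
  stability_window <- check_count(stability_window, "stability_window")
  if (stability_tol <= 0) stop("stability_tol must be positive", call. = FALSE)
  if (k3 != k2) {
    warning("k3 != k2: the pair force is discontinuous at the saturation ",
            "threshold (d_e + d_h)/2", call. = FALSE)
  }
  structure(
    list(d_l = d_l, d_e = d_e, d_h = d_h, k1 = k1, k2 = k2, k3 = k3,
         a = a, b = b, c = c, dims = as.integer(dims), t_max = t_max,
         stability_tol = stability_tol, stability_window = stability_window),
    class = "swarm_params"
  )
}

#' @export
print.swarm_params <- function(x, ...) {
  cat("<swarm_params>\n")
  cat(sprintf("  force:  d_l=%g d_e=%g d_h=%g  k1=%g k2=%g k3=%g\n",
              x$d_l, x$d_e, x$d_h, x$k1, x$k2, x$k3))
  cat(sprintf("  update: a=%g b=%g c=%g  dims=%d\n", x$a, x$b, x$c, x$dims))
  cat(sprintf("  run:    t_max=%d stability_tol=%g stability_window=%d\n",
              x$t_max, x$stability_tol, x$stability_window))
  invisible(x)
}

# saturation threshold of the attractive branch
saturation_threshold <- function(params) (params$d_e + params$d_h) / 2
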