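## Parallel-bias well-tempered metadynamics.
##
## One 1-D bias V_k(s_k) per collective variable; the combined potential is
## the softmin  V_PB = -kBT log( (1/n) sum_k exp(-V_k/kBT) ), gauged so that
## V_PB = 0 when all per-CV biases are zero.  Hills are deposited with the
## well-tempered height damping exp(-V_k/((gamma-1) kBT)) times the
## conditional-probability weight exp(-V_k/kBT)/sum_j exp(-V_j/kBT); with a
## single CV the scheme reduces exactly to standard well-tempered
## metadynamics.

#' Collective-variable specification
#'
#' @param kind `"radius_of_gyration"`, `"inter_bead_distance"` or
#'   `"segment_com_distance"`.
#' @param sel_a 0-based bead selection (whole chain for Rg if missing; first
#'   bead / first segment otherwise).
#' @param sel_b Second bead / segment (distance kinds).
#' @param grid_min,grid_max,grid_spacing Bias grid, CV units (nm).
#' @param width Gaussian hill width, CV units (nm).
#' @return List of class `"afmi_cv"`.
#' @export
cv_spec <- function(kind = c("radius_of_gyration", "inter_bead_distance",
                             "segment_com_distance"),
                    sel_a, sel_b = integer(), grid_min = 0, grid_max = 10,
                    grid_spacing = 0.01, width = 0.1) {
  kind <- match.arg(kind)
  stopifnot(width > 0, grid_max > grid_min, grid_spacing > 0)
  code <- match(kind, c("radius_of_gyration", "inter_bead_distance",
                        "segment_com_distance")) - 1L
  structure(list(kind = code, kind_name = kind,
                 sel_a = as.integer(sel_a), sel_b = as.integer(sel_b),
                 grid_min = grid_min, grid_max = grid_max,
                 grid_spacing = grid_spacing, width = width),
            class = "afmi_cv")
}

#' Bias state for parallel-bias metadynamics
#'
#' @param cvs List of [cv_spec()] objects.
#' @param height Nominal hill height, kJ/mol.
#' @param bias_factor Well-tempering factor gamma (> 1; `Inf` disables
#'   tempering).
#' @param pace Steps between depositions (bookkeeping only at this level).
#' @return List of class `"afmi_bias"` with zeroed per-CV value/derivative
#'   grids and an empty hill log.
#' @export
bias_state <- function(cvs, height = 0.5, bias_factor = 10, pace = 500) {
  stopifnot(bias_factor > 1)
  grids <- lapply(cvs, function(cv) {
    ng <- floor((cv$grid_max - cv$grid_min) / cv$grid_spacing + 0.5) + 1
    list(s = cv$grid_min + (seq_len(ng) - 1) * cv$grid_spacing,
         V = numeric(ng), dV = numeric(ng))
  })
  structure(list(cvs = cvs, grids = grids, height = height,
                 bias_factor = bias_factor, pace = pace,
                 hills = data.frame()), class = "afmi_bias")
}

bias_interp <- function(grid, s) {
  ng <- length(grid$s)
  sc <- min(max(s, grid$s[1]), grid$s[ng])
  u <- (sc - grid$s[1]) / (grid$s[2] - grid$s[1])
  i0 <- min(floor(u), ng - 2)
  w <- u - i0
  list(V = (1 - w) * grid$V[i0 + 1] + w * grid$V[i0 + 2],
       dV = (1 - w) * grid$dV[i0 + 1] + w * grid$dV[i0 + 2])
}

#' Combined parallel-bias potential and CV forces
#'
#' @param cv_values Numeric vector, one current value per CV.
#' @param bias An `afmi_bias`.
#' @param temperature Kelvin.
#' @return List with `V_PB` (kJ/mol), `dV_ds` (derivative of the combined
#'   bias with respect to each CV), and the per-CV `V_k`.
#' @export
evaluate_bias <- function(cv_values, bias, temperature) {
  n <- length(bias$cvs)
  stopifnot(length(cv_values) == n)
  kt <- kBT(temperature)
  vk <- dvk <- numeric(n)
  for (k in seq_len(n)) {
    bi <- bias_interp(bias$grids[[k]], cv_values[k])
    vk[k] <- bi$V; dvk[k] <- bi$dV
  }
  ex <- exp(-vk / kt)
  vpb <- -kt * log(sum(ex) / n)
  pk <- ex / sum(ex)
  list(V_PB = vpb, dV_ds = pk * dvk, V_k = vk)
}

#' Deposit one parallel-bias hill
#'
#' @param bias An `afmi_bias`.
#' @param cv_values Current CV values.
#' @param temperature Kelvin.
#' @param step Step label recorded in the hill log.
#' @return Updated `afmi_bias`.
#' @export
deposit_hill <- function(bias, cv_values, temperature, step = NA) {
  n <- length(bias$cvs)
  kt <- kBT(temperature)
  vk <- vapply(seq_len(n), function(k)
    bias_interp(bias$grids[[k]], cv_values[k])$V, numeric(1))
  ex <- exp(-vk / kt)
  pk <- ex / sum(ex)
  damp <- if (is.finite(bias$bias_factor))
    exp(-vk / ((bias$bias_factor - 1) * kt)) else rep(1, n)
  h <- bias$height * damp * pk
  for (k in seq_len(n)) {
    g <- bias$grids[[k]]
    z <- (g$s - cv_values[k]) / bias$cvs[[k]]$width
    e <- h[k] * exp(-0.5 * z^2)
    g$V <- g$V + e
    g$dV <- g$dV - z / bias$cvs[[k]]$width * e
    bias$grids[[k]] <- g
  }
  bias$hills <- rbind(bias$hills,
                      data.frame(step = step, t(cv_values), t(h)))
  bias
}

#' Final per-frame bias over a trajectory
#'
#' Evaluates the end-of-run combined bias at every frame's CV values --
#' either from the final grids of an `afmi_bias` or from a hill log (direct
#' Gaussian summation).
#'
#' @param cv_series Matrix (frames x n_cvs) of CV values.
#' @param bias An `afmi_bias`, or `NULL` to use `hills`.
#' @param hills Hill log matrix with columns (step, replica, s_1..s_n,
#'   h_1..h_n) as returned by [run_replicas()]; requires `cvs` and
#'   `temperature`.
#' @param cvs List of [cv_spec()] (hill-log route).
#' @param temperature Kelvin.
#' @return Numeric vector of per-frame combined bias values V_PB, kJ/mol.
#' @export
recompute_final_bias <- function(cv_series, bias = NULL, hills = NULL,
                                 cvs = NULL, temperature = 298) {
  cv_series <- as.matrix(cv_series)
  kt <- kBT(temperature)
  if (!is.null(bias)) {
    return(apply(cv_series, 1, function(s)
      evaluate_bias(s, bias, temperature)$V_PB))
  }
  if (is.null(hills)) stop("missing hill history")
  n <- length(cvs)
  if (nrow(hills) == 0) return(rep(0, nrow(cv_series)))
  out <- numeric(nrow(cv_series))
  centers <- hills[, 2 + seq_len(n), drop = FALSE]
  heights <- hills[, 2 + n + seq_len(n), drop = FALSE]
  for (f in seq_len(nrow(cv_series))) {
    vk <- vapply(seq_len(n), function(k) {
      z <- (cv_series[f, k] - centers[, k]) / cvs[[k]]$width
      sum(heights[, k] * exp(-0.5 * z^2))
    }, numeric(1))
    out[f] <- -kt * log(sum(exp(-vk / kt)) / n)
  }
  out
}

#' Compute CV values on an ensemble or coordinate matrix
#'
#' @param coords N x 3 matrix (nm).
#' @param cv A [cv_spec()].
#' @return CV value (nm).
#' @export
cv_value <- function(coords, cv) {
  kind <- cv$kind
  if (kind == 0) {
    sel <- if (length(cv$sel_a)) cv$sel_a + 1 else seq_len(nrow(coords))
    x <- coords[sel, , drop = FALSE]
    cm <- colMeans(x)
    sqrt(mean(rowSums(sweep(x, 2, cm)^2)))
  } else if (kind == 1) {
    sqrt(sum((coords[cv$sel_a[1] + 1, ] - coords[cv$sel_b[1] + 1, ])^2))
  } else {
    ca <- colMeans(coords[cv$sel_a + 1, , drop = FALSE])
    cb <- colMeans(coords[cv$sel_b + 1, , drop = FALSE])
    sqrt(sum((ca - cb)^2))
  }
}

#' Default CV set for a chain
#'
#' Radius of gyration plus end-to-end distance, with grids sized from the
#' chain length (contour length upper bound) and hill widths of 10% of an
#' extended-coil scale.
#'
#' @param n Number of beads.
#' @param bond Bond length, nm.
#' @return List of two [cv_spec()] objects.
#' @export
default_cvs <- function(n, bond = 0.38) {
  lmax <- bond * (n - 1)
  rg0 <- bond * sqrt(n / 6)
  list(
    cv_spec("radius_of_gyration", sel_a = 0:(n - 1), grid_min = 0,
            grid_max = lmax, grid_spacing = lmax / 800, width = 0.1 * rg0),
    cv_spec("inter_bead_distance", sel_a = 0L, sel_b = n - 1L, grid_min = 0,
            grid_max = 1.2 * lmax, grid_spacing = 1.2 * lmax / 800,
            width = 0.25 * rg0))
}
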