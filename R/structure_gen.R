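#' Refractive-index model for a nacre-like stack
#'
#' Bundles the (purely real, lossless) refractive indices of the two
#' alternating media of a nacreous layer together with the semi-infinite
#' ambient and substrate media.  The defaults describe Ammolite: aragonite
#' platelets with an effective isotropic index of 1.63 and air-filled
#' interlamellar gaps.  Aragonite is in fact birefringent (principal indices
#' 1.530 / 1.681 / 1.686); the single effective value 1.63 is the standard
#' choice for nacre interference models and is used throughout.
#'
#' @param n1 Refractive index of the aragonite platelets.
#' @param n2 Refractive index of the interlamellar medium: 1.00 for the air
#'   nanogaps of Ammolite, 1.43 for the organic sheets of abalone.
#' @param n_ambient Index of the semi-infinite medium above the stack
#'   (default air).
#' @param n_substrate Index of the semi-infinite medium below the stack
#'   (default bulk aragonite, i.e. the shell the nacre sits on).
#' @return An object of class `refractive_model`.
#' @examples
#' refractive_model()                 # Ammolite: air gaps
#' refractive_model(n2 = 1.43)       # abalone: organic sheets
#' @export
refractive_model <- function(n1 = 1.63, n2 = 1.00, n_ambient = 1.00,
                             n_substrate = n1) {
  for (nm in c("n1", "n2", "n_ambient", "n_substrate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1)
      stop(sprintf("'%s' must be a single finite number >= 1", nm))
  }
  structure(list(n1 = n1, n2 = n2, n_ambient = n_ambient,
                 n_substrate = n_substrate),
            class = "refractive_model")
}

#' @export
print.refractive_model <- function(x, ...) {
  cat(sprintf(
    "refractive_model: n1 = %.3f (plate), n2 = %.3f (gap), ambient %.3f, substrate %.3f\n",
    x$n1, x$n2, x$n_ambient, x$n_substrate))
  invisible(x)
}

#' Stochastic recipe for a nacre-like layer stack
#'
#' A `stack_spec` describes how to draw a finite stack of alternating
#' aragonite plates and interlamellar gaps: mean plate thickness `d1_mean`
#' with standard deviation `d1_sd`, gap thickness `d2_mean` with `d2_sd`,
#' and the number of plate/gap periods.  Thicknesses are drawn from
#' truncated Gaussians (plates floored at 1 nm, gaps at 0.5 nm) so that no
#' non-physical layer can be generated; at the standard deviations observed
#' in real nacres the truncation perturbs the moments negligibly.
#'
#' The depth profile of the lamination period can be `"constant"`
#' (Ammolite-like, homogeneous over tens of micrometres), a linear drift of
#' the mean plate thickness with depth (abalone / Madagascar-like), or a
#' custom per-period sequence of mean plate thicknesses.
#'
#' The default of 300 periods corresponds to roughly 50 micrometres of
#' stack at a lamination period of ~164 nm, the thickness of homogeneous
#' periodicity associated with brilliant color.
#'
#' @param d1_mean,d1_sd Mean and SD of the plate thickness, nm.
#' @param d2_mean,d2_sd Mean and SD of the interlamellar gap, nm.
#' @param n_periods Number of plate/gap periods (>= 1).
#' @param profile `"constant"`, `"linear_drift"` or `"custom"`.
#' @param drift_rate Drift of the mean plate thickness, nm per period
#'   (used when `profile = "linear_drift"`).
#' @param d1_profile Numeric vector of per-period mean plate thicknesses
#'   (used when `profile = "custom"`; length must equal `n_periods`).
#' @param refr A [refractive_model()].
#' @param seed Integer seed; the same spec always generates the same stack.
#' @return An object of class `stack_spec`.
#' @examples
#' green_ammolite <- stack_spec(d1_mean = 160, d1_sd = 8, d2_mean = 4,
#'                              d2_sd = 2, n_periods = 300, seed = 1)
#' @export
stack_spec <- function(d1_mean, d1_sd = 0, d2_mean = 4, d2_sd = 0,
                       n_periods = 300, profile = c("constant",
                                                    "linear_drift",
                                                    "custom"),
                       drift_rate = 0, d1_profile = NULL,
                       refr = refractive_model(), seed = 1L) {
  profile <- match.arg(profile)
  if (!is.numeric(d1_mean) || d1_mean <= 0) stop("'d1_mean' must be > 0")
  if (!is.numeric(d2_mean) || d2_mean < 0) stop("'d2_mean' must be >= 0")
  if (d1_sd < 0 || d2_sd < 0) stop("standard deviations must be >= 0")
  if (n_periods < 1) stop("'n_periods' must be >= 1")
  if (!inherits(refr, "refractive_model")) stop("'refr' must be a refractive_model")
  if (profile == "custom") {
    if (is.null(d1_profile) || length(d1_profile) != n_periods ||
        any(d1_profile <= 0))
      stop("'d1_profile' must give a positive mean for each period")
  }
  structure(list(d1_mean = d1_mean, d1_sd = d1_sd,
                 d2_mean = d2_mean, d2_sd = d2_sd,
                 n_periods = as.integer(n_periods), profile = profile,
                 drift_rate = drift_rate, d1_profile = d1_profile,
                 refr = refr, seed = as.integer(seed)),
            class = "stack_spec")
}

#' @export
print.stack_spec <- function(x, ...) {
  cat(sprintf("stack_spec: %d periods, d1 = %g +/- %g nm, d2 = %g +/- %g nm\n",
              x$n_periods, x$d1_mean, x$d1_sd, x$d2_mean, x$d2_sd))
  cat(sprintf("  profile: %s%s, n1 = %g, n2 = %g, seed = %d\n", x$profile,
              if (x$profile == "linear_drift")
                sprintf(" (%+g nm/period)", x$drift_rate) else "",
              x$refr$n1, x$refr$n2, x$seed))
  invisible(x)
}

#' Explicit planar layer stack
#'
#' The object the optical solver consumes: an ordered sequence of
#' (refractive index, thickness) layers between a semi-infinite ambient
#' above and substrate below.  Zero-thickness layers are dropped at
#' construction, so a spec with `d2_mean = 0` and no gap spread collapses
#' cleanly to plates only.
#'
#' @param index Numeric vector of layer refractive indices (top to bottom).
#' @param thickness Numeric vector of layer thicknesses, nm.
#' @param n_ambient,n_substrate Semi-infinite bounding media.
#' @return An object of class `layer_stack`.
#' @export
layer_stack <- function(index, thickness, n_ambient = 1.00,
                        n_substrate = 1.63) {
  if (length(index) != length(thickness))
    stop("'index' and 'thickness' must have equal length")
  if (any(!is.finite(index)) || any(index < 1))
    stop("layer indices must be finite and >= 1")
  if (any(!is.finite(thickness)) || any(thickness < 0))
    stop("layer thicknesses must be finite and >= 0")
  keep <- thickness > 0
  structure(list(index = as.numeric(index[keep]),
                 thickness = as.numeric(thickness[keep]),
                 n_ambient = n_ambient, n_substrate = n_substrate),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("layer_stack: %d layers, total thickness %.1f nm (%.2f um)\n",
              length(x$index), sum(x$thickness), sum(x$thickness) / 1e3))
  cat(sprintf("  ambient n = %g | ... | substrate n = %g\n",
              x$n_ambient, x$n_substrate))
  invisible(x)
}

#' Total thickness of a stack
#' @param stack A [layer_stack()].
#' @return Total thickness in nm.
#' @export
total_thickness <- function(stack) sum(stack$thickness)

# Evaluate code with a private RNG stream; the caller's RNG state is
# untouched.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Truncated-Gaussian draw: redraw below-floor values.  When sd = 0 the
# means are returned exactly (no truncation applied), so deterministic
# specs stay bit-exact.
rnorm_truncated <- function(mean, sd, floor) {
  if (all(sd == 0)) return(mean)
  x <- stats::rnorm(length(mean), mean, sd)
  bad <- which(x < floor)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < floor]
  }
  x
}

# Per-period mean plate thicknesses implied by the depth profile.
period_means <- function(spec) {
  switch(spec$profile,
         constant     = rep(spec$d1_mean, spec$n_periods),
         linear_drift = spec$d1_mean +
           spec$drift_rate * (seq_len(spec$n_periods) - 1),
         custom       = spec$d1_profile)
}

#' Sample a layer stack from a stochastic spec
#'
#' Draws `n_periods` plate/gap pairs.  Plate thicknesses come from a
#' truncated Gaussian around the (possibly depth-dependent) mean plate
#' thickness; gap widths from a truncated Gaussian around `d2_mean`.
#' Plates and gaps are drawn independently.  With all SDs zero the stack is
#' exactly periodic (or exactly follows the drift/custom profile).  The
#' draw is governed entirely by `spec$seed`: the same spec yields the
#' identical stack, and the caller's RNG state is left untouched.
#'
#' @param spec A [stack_spec()].
#' @return A [layer_stack()] alternating plate, gap, plate, gap, ...
#' @examples
#' st <- sample_stack(stack_spec(d1_mean = 160, d2_mean = 4, n_periods = 3))
#' st$thickness   # 160 4 160 4 160 4
#' @export
sample_stack <- function(spec) {
  if (!inherits(spec, "stack_spec")) stop("'spec' must be a stack_spec")
  n <- spec$n_periods
  mu1 <- period_means(spec)
  d1 <- d2 <- NULL
  with_local_seed(spec$seed, {
    d1 <- rnorm_truncated(mu1, rep(spec$d1_sd, n), floor = 1)
    d2 <- rnorm_truncated(rep(spec$d2_mean, n), rep(spec$d2_sd, n),
                          floor = 0.5)
  })
  idx <- rep(c(spec$refr$n1, spec$refr$n2), n)
  thk <- as.vector(rbind(d1, d2))
  layer_stack(idx, thk, n_ambient = spec$refr$n_ambient,
              n_substrate = spec$refr$n_substrate)
}

#' Depth profile of the lamination period
#'
#' Reduces a plate/gap stack to one lamination period d = d1 + d2 per
#' plate/gap pair, against cumulative depth (measured at the start of each
#' period, top surface = 0).  This is the quantity profiled through real
#' nacres to assess periodicity homogeneity: Ammolite-grade material keeps
#' d constant over ~50 um while duller nacres drift.
#'
#' @param stack A [layer_stack()] built from complete plate/gap pairs.
#' @return A data frame with columns `depth_nm` and `period_nm`.
#' @export
depth_profile <- function(stack) {
  if (!inherits(stack, "layer_stack")) stop("'stack' must be a layer_stack")
  nl <- length(stack$thickness)
  if (nl %% 2L != 0L)
    stop("stack has an odd number of layers: incomplete plate/gap period")
  thk <- stack$thickness
  period <- thk[seq(1, nl, by = 2)] + thk[seq(2, nl, by = 2)]
  depth <- c(0, cumsum(period))[seq_along(period)]
  data.frame(depth_nm = depth, period_nm = period)
}
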