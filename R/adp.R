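#' ADP secretion with a finite-memory release kernel
#'
#' Newly bound platelets secrete ADP over roughly 1-5 s.  The volumetric
#' source is the convolution of the newly-bound-platelet rate with a
#' normalised bell-shaped release-rate kernel centred at 3 s, truncated to a
#' finite window and evaluated by trapezoid quadrature over a ring buffer of
#' rate snapshots sampled every `dtau` seconds.
#'
#' @name adp_release
NULL

#' ADP release-rate kernel
#'
#' A Gaussian bell curve centred at 3 s,
#' `R(tau) = exp(-(tau - 3)^2) / Z`, normalised so that the release-rate
#' density integrates to exactly 1 over `tau >= 0`:
#' `Z = (sqrt(pi)/2) * (1 + erf(3))`.  `Z` differs from the plain Gaussian
#' mass `sqrt(pi)` only by the `tau < 0` tail (about 1.1e-5), so
#' `R(3) = 0.564196`, within 1e-5 of `1/sqrt(pi)`.
#'
#' @param tau time since binding (s)
#' @return release-rate density (1/s)
#' @export
release_kernel_R <- function(tau) {
  Z <- sqrt(pi) / 2 * (1 + (2 * stats::pnorm(3 * sqrt(2)) - 1))
  exp(-(tau - 3)^2) / Z
}

#' Rate of newly bound platelets
#'
#' Finite-difference estimate `P_max * (thetaB_now - thetaB_prev) / (t_now -
#' t_prev)`; may be negative if platelets unbind (clipped later inside the
#' release quadrature).
#'
#' @param theta_B_now,theta_B_prev per-cell bound fractions
#' @param t_now,t_prev times (s), `t_now > t_prev`
#' @param P_max packing density (platelets/um^3)
#' @return per-cell rate (platelets/um^3/s)
#' @export
newly_bound_rate <- function(theta_B_now, theta_B_prev, t_now, t_prev, P_max) {
  if (t_now <= t_prev) stop("newly_bound_rate: non-increasing time")
  P_max * (theta_B_now - theta_B_prev) / (t_now - t_prev)
}

#' Create a release-history ring buffer
#'
#' Stores `floor(tau_f / dtau) + 1` per-cell snapshots of the
#' newly-bound-platelet rate, sampled every `dtau`, covering the window
#' `[t - tau_f, t]`.  Missing history before start-up counts as zero.
#'
#' @param mesh a `clot_mesh`
#' @param dtau sampling interval (s; config key `sigma_dt`)
#' @param tau_f window length (s; config key `sigma_Tf`, default 6)
#' @return class `clot_release_history`
#' @export
new_release_history <- function(mesh, dtau, tau_f = 6) {
  stopifnot(dtau > 0, tau_f > 0)
  n <- floor(tau_f / dtau) + 1L
  list(dtau = dtau, tau_f = tau_f, n = n,
       snapshots = array(0, dim = c(mesh$nx, mesh$ny, n)),
       ## snapshots[ , , k] holds B(t - (k-1)*dtau): index 1 is the newest
       t_last = 0)
}

#' Push a snapshot onto the release history
#'
#' @param history a `clot_release_history`
#' @param B per-cell newly-bound rate at the current sample time
#' @param t_now current time (s); must advance by `dtau` per push (within
#'   rounding)
#' @return updated history
#' @export
push_release_history <- function(history, B, t_now) {
  if (history$t_last > 0 &&
      abs((t_now - history$t_last) - history$dtau) > 1e-9 * max(1, history$dtau))
    stop("release history sampled at interval ", format(t_now - history$t_last),
         " != dtau = ", format(history$dtau),
         "; sigma_dt must be commensurate with the snapshot cadence")
  history$snapshots <- array(c(B, history$snapshots[, , seq_len(history$n - 1L)]),
                             dim = dim(history$snapshots))
  history$t_last <- t_now
  history
}

#' ADP release source by trapezoid quadrature over the history window
#'
#' `sigma(t_n) = sum_k (A_hat * dtau / 2) * [R(t_n - tau_k) B(tau_k) +
#' R(t_n - tau_{k+1}) B(tau_{k+1})]` over the stored window, with negative
#' stored rates clipped to zero (unbinding does not un-release ADP) and the
#' per-platelet amount `A_hat` (mol/platelet) converted to nM/s.
#'
#' @param history a `clot_release_history` whose newest snapshot is at `t_now`
#' @param A_hat total ADP released per activated platelet (mol/platelet)
#' @return list with `sigma` (per-cell source, nM/s) and `clipped` (TRUE if
#'   any negative rate was clipped)
#' @export
sigma_release <- function(history, A_hat) {
  n <- history$n
  taus <- (seq_len(n) - 1) * history$dtau      # age of each snapshot
  w <- release_kernel_R(taus)
  w[c(1, n)] <- w[c(1, n)] / 2                 # trapezoid end weights
  w <- w * history$dtau * A_hat * MOL_UM3_TO_NM
  B <- history$snapshots
  clipped <- any(B < 0)
  if (clipped) B[B < 0] <- 0
  dims <- dim(B)
  sig <- matrix(matrix(B, dims[1] * dims[2], dims[3]) %*% w, dims[1], dims[2])
  list(sigma = sig, clipped = clipped)
}

#' Advance the ADP field by one step
#'
#' One unhindered transport step (the ADP equation carries no packing
#' hindrance) plus explicit addition of the release source.  ADP is not part
#' of the fractional-step reaction system because its source is only updated
#' at the (coarser) history cadence.
#'
#' @param adp `nx x ny` ADP concentration (nM)
#' @param flux face-flux list
#' @param sigma per-cell release source (nM/s)
#' @param D_ADP diffusivity (um^2/s)
#' @param dt time step (s)
#' @param mesh a `clot_mesh`
#' @param bc per-patch boundary spec
#' @param cache transport cache
#' @return list as [advance_transport()], with the source included
#' @export
advance_adp <- function(adp, flux, sigma, D_ADP, dt, mesh, bc, cache = NULL) {
  r <- advance_transport(adp, flux, D_ADP, dt, mesh, bc, cache = cache,
                         cfl = "silent")
  r$values <- r$values + sigma * dt
  r
}
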