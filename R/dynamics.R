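# Coupled node dynamics on a connectome: stochastic FitzHugh-Nagumo
# relaxation oscillators, Wilson-Cowan excitatory/inhibitory mass pairs and
# the Mimura-Murray reaction-diffusion system on the graph Laplacian, with
# spike detection, coactivation and Kuramoto-synchrony summaries.

#' Network coupling matrix of a connectome
#'
#' The transposed weighted adjacency matrix (entry `[i, j]` is the weight of
#' the connection j -> i, i.e. presynaptic drive onto i), optionally
#' normalized so coupled input is a weighted mean rather than an unbounded
#' sum.
#'
#' @param c a connectome.
#' @param normalize `"instrength"` (each row divided by its sum; default),
#'   `"spectral"` (divided by the spectral radius) or `"none"`.
#' @return n x n numeric matrix.
#' @export
coupling_matrix <- function(c, normalize = c("instrength", "spectral", "none")) {
  normalize <- match.arg(normalize)
  D <- t(adjacency_matrix(c, weighted = TRUE))
  switch(normalize,
    instrength = {
      rs <- rowSums(D)
      rs[rs == 0] <- 1
      D / rs
    },
    spectral = {
      lam <- max(Mod(eigen(D, only.values = TRUE)$values))
      if (lam > 0) D / lam else D
    },
    none = D)
}

new_sim_result <- function(time, act, states, model, params, regions) {
  structure(list(time = time, act = act, states = states, model = model,
                 params = params, regions = regions),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %s: %d steps x %d regions\n",
              x$model, length(x$time), ncol(x$act)))
  invisible(x)
}

divergence_guard <- function(x, step, guard = 1e6) {
  if (any(!is.finite(x)) || any(abs(x) > guard))
    stop(sprintf("trajectory diverged at step %d (overflow guard %g)", step, guard))
}

#' FitzHugh-Nagumo simulation parameters
#'
#' Defaults follow the connectome-scale parameterization used throughout
#' this package: `alpha = 0`, `beta = -0.064`, `gamma = 1`, `phi = 1`
#' (scaling of the logistic coupling function), `epsilon = 2` (scaling of
#' the recovery equation), `k = 1` (global coupling), `sigma = 0.25`
#' (Gaussian noise scale), `tau_x = tau_y = 1`, 500 steps of 1 ms, and
#' initial states drawn uniformly from \[-2, 2\].
#'
#' The recovery equation couples to the membrane potential through
#' `recovery_x_sign`. The default `+1` gives the classic negative feedback
#' loop (x excites y, y inhibits x) under which the node is a relaxation
#' oscillator; `-1` flips the sign, which makes each node bistable (two
#' stable rest states) rather than oscillatory.
#'
#' @param alpha,beta,gamma,phi,epsilon,k,sigma,tau_x,tau_y model constants.
#' @param recovery_x_sign sign of the membrane-potential term in the
#'   recovery equation (+1 oscillatory, -1 bistable).
#' @param x0_range,y0_range initial-condition intervals.
#' @param dt recorded time step (ms).
#' @param steps number of recorded steps.
#' @param euler_substeps internal Euler-Maruyama substeps per recorded step
#'   (the cubic nonlinearity is unstable under a full 1 ms Euler step).
#' @param normalize coupling normalization, see [coupling_matrix()].
#' @param seed RNG seed for noise and initial conditions.
#' @return an `fhn_params` list.
#' @export
fhn_params <- function(alpha = 0, beta = -0.064, gamma = 1, phi = 1,
                       epsilon = 2, k = 1, sigma = 0.25,
                       tau_x = 1, tau_y = 1, recovery_x_sign = 1,
                       x0_range = c(-2, 2), y0_range = c(-2, 2),
                       dt = 1, steps = 500L, euler_substeps = 50L,
                       normalize = "instrength", seed = 1L) {
  stopifnot(tau_x > 0, tau_y > 0, dt > 0, steps >= 1, euler_substeps >= 1)
  structure(as.list(environment()), class = "fhn_params")
}

#' Simulate coupled FitzHugh-Nagumo neurons on a connectome
#'
#' One FHN unit per region, coupled through the transposed weighted
#' adjacency matrix `D` and the logistic function `f(x) = 1/(1+exp(-x))`:
#' `tau_x dx/dt = gamma x - x^3/3 - y + k D (phi f(x)) + sigma nu_x`,
#' `tau_y dy/dt = epsilon (beta y + s x + alpha) + sigma nu_y`,
#' with `s = recovery_x_sign`, integrated with the Euler-Maruyama scheme
#' (noise scaled by `sqrt(dt)`).
#'
#' @param c a connectome.
#' @param p an [fhn_params()].
#' @return a `sim_result`; `act` holds the membrane potentials x.
#' @export
simulate_fhn <- function(c, p = fhn_params()) {
  n <- n_regions(c)
  if (!n) stop("empty connectome")
  D <- coupling_matrix(c, p$normalize)
  with_seed(p$seed, {
    x <- runif(n, p$x0_range[1], p$x0_range[2])
    y <- runif(n, p$y0_range[1], p$y0_range[2])
    X <- matrix(NA_real_, p$steps + 1L, n)
    Y <- matrix(NA_real_, p$steps + 1L, n)
    X[1, ] <- x; Y[1, ] <- y
    h <- p$dt / p$euler_substeps
    sq <- sqrt(h)
    for (s in seq_len(p$steps)) {
      for (sub in seq_len(p$euler_substeps)) {
        fx <- 1 / (1 + exp(-x))
        dx <- (p$gamma * x - x^3 / 3 - y + p$k * drop(D %*% (p$phi * fx))) / p$tau_x
        dy <- (p$epsilon * (p$beta * y + p$recovery_x_sign * x + p$alpha)) / p$tau_y
        nx <- if (p$sigma > 0) rnorm(n) else 0
        ny <- if (p$sigma > 0) rnorm(n) else 0
        x <- x + h * dx + p$sigma * sq * nx / p$tau_x
        y <- y + h * dy + p$sigma * sq * ny / p$tau_y
      }
      divergence_guard(x, s)
      X[s + 1L, ] <- x; Y[s + 1L, ] <- y
    }
    colnames(X) <- colnames(Y) <- region_abbrev(c)
    new_sim_result(seq(0, by = p$dt, length.out = p$steps + 1L), X,
                   list(x = X, y = Y), "fhn", p, region_abbrev(c))
  })
}

#' Threshold spike detection on regional traces
#'
#' A region is "spiking" at a sample when its activity exceeds its own
#' temporal mean by `z` standard deviations:
#' `C_i(t) = 1  iff  x_i(t) > mean_t(x_i) + z sd_t(x_i)`.
#'
#' @param r a `sim_result` (or a time x regions matrix).
#' @param z threshold multiplier (default 1).
#' @return binary matrix of the trajectory's shape; zero-variance traces
#'   yield all-zero rows and are flagged in attribute `flat_regions`.
#' @export
detect_spikes <- function(r, z = 1) {
  act <- if (inherits(r, "sim_result")) r$act else as.matrix(r)
  mu <- colMeans(act)
  sdv <- apply(act, 2, sd)
  flat <- sdv == 0
  thr <- mu + z * sdv
  raster <- sweep(act, 2, thr, ">") + 0
  raster[, flat] <- 0
  attr(raster, "flat_regions") <- colnames(act)[flat]
  raster
}

#' Coactivation matrix of a spike raster
#'
#' Relative mode normalizes joint activity by the union of active samples,
#' `Co_ij = sum_t c_i(t) c_j(t) / sum_t max(c_i(t), c_j(t))`, so two regions
#' with identical nonempty spike trains score 1 regardless of their firing
#' density; per-time mode divides the joint count by the number of samples.
#'
#' @param raster binary time x regions matrix (see [detect_spikes()]).
#' @param mode `"relative"` (default) or `"per_time"`.
#' @return symmetric matrix; in relative mode the diagonal is 1 for active
#'   regions and pairs with no activity at all score 0 (flagged via
#'   attribute `inactive_regions`).
#' @export
coactivation <- function(raster, mode = c("relative", "per_time")) {
  mode <- match.arg(mode)
  raster <- as.matrix(raster)
  if (!all(raster %in% c(0, 1))) stop("raster must be binary")
  joint <- crossprod(raster)
  s <- diag(joint)
  if (mode == "per_time") {
    out <- joint / nrow(raster)
  } else {
    un <- outer(s, s, "+") - joint
    out <- ifelse(un > 0, joint / un, 0)
    diag(out) <- ifelse(s > 0, 1, 0)
  }
  attr(out, "inactive_regions") <- colnames(raster)[s == 0]
  out
}

#' Wilson-Cowan simulation parameters
#'
#' Per-region excitatory (x) / inhibitory (y) population pair with logistic
#' activation `F(z) = 1/(1+exp(-z))`. The default coupling strengths
#' (`w_xx = 16, w_yx = 12, w_xy = 15, w_yy = 3`) with negative external
#' drives place an isolated pair in an oscillatory regime.
#'
#' @param w_xx,w_yx,w_xy,w_yy population coupling strengths.
#' @param I_ext_x,I_ext_y external drives.
#' @param tau_x,tau_y time constants.
#' @param k_net global gain of the network coupling added to the excitatory
#'   input.
#' @param x0_range,y0_range initial-condition intervals.
#' @param dt,steps integration grid.
#' @param normalize coupling normalization, see [coupling_matrix()].
#' @param seed RNG seed.
#' @return a `wc_params` list.
#' @export
wc_params <- function(w_xx = 16, w_yx = 12, w_xy = 15, w_yy = 3,
                      I_ext_x = -3.7, I_ext_y = -9,
                      tau_x = 1, tau_y = 1, k_net = 1,
                      x0_range = c(0.1, 0.4), y0_range = c(0.1, 0.4),
                      dt = 0.05, steps = 2000L, normalize = "instrength",
                      seed = 1L) {
  stopifnot(tau_x > 0, tau_y > 0, dt > 0, steps >= 1)
  structure(as.list(environment()), class = "wc_params")
}

#' Simulate Wilson-Cowan population pairs on a connectome
#'
#' `dx/dt = (-x + F(w_xx x - w_yx y + I_ext_x + k_net (D x)_i)) / tau_x`,
#' `dy/dt = (-y + F(w_xy x - w_yy y + I_ext_y)) / tau_y`,
#' with the network term entering the excitatory population's input through
#' the row-normalized transposed weight matrix `D` (same convention as
#' [simulate_fhn()], so the three node models are comparable).
#'
#' @param c a connectome.
#' @param p a [wc_params()].
#' @return a `sim_result`; `act` holds the excitatory rates x.
#' @export
simulate_wilson_cowan <- function(c, p = wc_params()) {
  n <- n_regions(c)
  if (!n) stop("empty connectome")
  D <- coupling_matrix(c, p$normalize)
  Fz <- function(z) 1 / (1 + exp(-z))
  with_seed(p$seed, {
    x <- runif(n, p$x0_range[1], p$x0_range[2])
    y <- runif(n, p$y0_range[1], p$y0_range[2])
    X <- matrix(NA_real_, p$steps + 1L, n)
    Y <- matrix(NA_real_, p$steps + 1L, n)
    X[1, ] <- x; Y[1, ] <- y
    for (s in seq_len(p$steps)) {
      zx <- p$w_xx * x - p$w_yx * y + p$I_ext_x + p$k_net * drop(D %*% x)
      zy <- p$w_xy * x - p$w_yy * y + p$I_ext_y
      x <- x + p$dt * (-x + Fz(zx)) / p$tau_x
      y <- y + p$dt * (-y + Fz(zy)) / p$tau_y
      divergence_guard(x, s)
      X[s + 1L, ] <- x; Y[s + 1L, ] <- y
    }
    colnames(X) <- colnames(Y) <- region_abbrev(c)
    new_sim_result(seq(0, by = p$dt, length.out = p$steps + 1L), X,
                   list(x = X, y = Y), "wilson_cowan", p, region_abbrev(c))
  })
}

#' Mimura-Murray simulation parameters
#'
#' Activator-inhibitor kinetics
#' `f(P,Q) = ((a + bP - P^2)/c - Q) P` and `g(P,Q) = (P - (1 + dQ)) Q` with
#' defaults `a = 13, b = 16, c = 9, d = 0.4`, diffusing on the graph
#' Laplacian with coefficients `D_P = 0.1`, `D_Q = 0.01`. Initial states are
#' uniform (`P = 6`, `Q = 12`), perturbed at the stimulus region.
#'
#' @param a,b,cc,d local kinetic constants (`cc` is the parameter usually
#'   written c).
#' @param D_P,D_Q diffusion coefficients of the two species.
#' @param P0,Q0 ranges (min, max) of the uniform initial conditions.
#' @param solver `"dopri45"` (adaptive Dormand-Prince via deSolve, default)
#'   or `"euler"`.
#' @param rtol,atol relative/absolute error tolerances of the adaptive
#'   solver.
#' @param dt recorded time step.
#' @param steps number of recorded steps.
#' @param euler_substeps internal Euler substeps per recorded step.
#' @param stimulus_region abbreviation of the stimulated region (or `NULL`).
#' @param stimulus_mode `"initial"` (multiplicative perturbation of the
#'   region's initial P) or `"drive"` (sustained additive input).
#' @param stimulus_strength relative perturbation (default 0.1 = +10%) or
#'   drive amplitude.
#' @param seed RNG seed (only used when the initial ranges are non-degenerate).
#' @return an `mm_params` list.
#' @export
mm_params <- function(a = 13, b = 16, cc = 9, d = 0.4,
                      D_P = 0.1, D_Q = 0.01,
                      P0 = c(6, 6), Q0 = c(12, 12),
                      solver = c("dopri45", "euler"), rtol = 1e-8, atol = 1e-8,
                      dt = 1, steps = 1000L, euler_substeps = 100L,
                      stimulus_region = NULL,
                      stimulus_mode = c("initial", "drive"),
                      stimulus_strength = 0.1, seed = 1L) {
  solver <- match.arg(solver)
  stimulus_mode <- match.arg(stimulus_mode)
  stopifnot(cc != 0, steps >= 1, dt > 0)
  structure(as.list(environment()), class = "mm_params")
}

mm_laplacian <- function(c) {
  W <- adjacency_matrix(c, weighted = TRUE)
  Ws <- (W + t(W)) / 2
  rs <- rowSums(Ws)
  rs[rs == 0] <- 1
  Wn <- Ws / rs
  list(Wn = Wn, deg = rowSums(Wn))
}

#' Simulate the Mimura-Murray reaction-diffusion system on a connectome
#'
#' Each region carries an activator-inhibitor pair (P, Q) evolving under the
#' local kinetics of [mm_params()] plus network diffusion
#' `D_P L[P]`, `D_Q L[Q]`, where `L[u]_i = sum_j What_ij (u_j - u_i)` and
#' `What` is the symmetrized, in-strength-normalized weight matrix. The
#' uniform equilibrium of the local kinetics is an exact steady state of the
#' full network system (the Laplacian of a constant field vanishes).
#'
#' @param c a connectome.
#' @param p an [mm_params()].
#' @return a `sim_result`; `act` holds the activator P.
#' @export
simulate_mimura_murray <- function(c, p = mm_params()) {
  n <- n_regions(c)
  if (!n) stop("empty connectome")
  lap <- mm_laplacian(c)
  Wn <- lap$Wn; dg <- lap$deg
  ab <- region_abbrev(c)
  stim <- NULL
  if (!is.null(p$stimulus_region)) {
    stim <- match(p$stimulus_region, ab)
    if (is.na(stim)) stop("stimulus region not in connectome: ", p$stimulus_region)
  }
  kin <- function(P, Q) {
    drive <- numeric(n)
    if (!is.null(stim) && p$stimulus_mode == "drive")
      drive[stim] <- p$stimulus_strength
    dP <- ((p$a + p$b * P - P^2) / p$cc - Q) * P +
      p$D_P * (drop(Wn %*% P) - dg * P) + drive
    dQ <- (P - (1 + p$d * Q)) * Q + p$D_Q * (drop(Wn %*% Q) - dg * Q)
    list(dP = dP, dQ = dQ)
  }
  with_seed(p$seed, {
    P <- runif(n, p$P0[1], p$P0[2])
    Q <- runif(n, p$Q0[1], p$Q0[2])
    if (!is.null(stim) && p$stimulus_mode == "initial")
      P[stim] <- P[stim] * (1 + p$stimulus_strength)
    times <- seq(0, by = p$dt, length.out = p$steps + 1L)
    if (p$solver == "dopri45") {
      rhs <- function(t, y, parms) {
        P <- y[seq_len(n)]; Q <- y[n + seq_len(n)]
        k <- kin(P, Q)
        list(c(k$dP, k$dQ))
      }
      sol <- deSolve::ode(y = c(P, Q), times = times, func = rhs, parms = NULL,
                          method = "ode45", rtol = p$rtol, atol = p$atol)
      Pm <- sol[, 1 + seq_len(n), drop = FALSE]
      Qm <- sol[, 1 + n + seq_len(n), drop = FALSE]
    } else {
      Pm <- matrix(NA_real_, p$steps + 1L, n)
      Qm <- matrix(NA_real_, p$steps + 1L, n)
      Pm[1, ] <- P; Qm[1, ] <- Q
      h <- p$dt / p$euler_substeps
      for (s in seq_len(p$steps)) {
        for (sub in seq_len(p$euler_substeps)) {
          k <- kin(P, Q)
          P <- P + h * k$dP
          Q <- Q + h * k$dQ
        }
        divergence_guard(P, s)
        if (any(P < -1e-6) || any(Q < -1e-6))
          stop("negative population at step ", s,
               "; the kinetics assume P, Q >= 0 (reduce the step size)")
        Pm[s + 1L, ] <- P; Qm[s + 1L, ] <- Q
      }
    }
    colnames(Pm) <- colnames(Qm) <- ab
    new_sim_result(times, Pm, list(P = Pm, Q = Qm), "mimura_murray", p, ab)
  })
}

#' Homogeneous equilibrium of the Mimura-Murray kinetics
#'
#' The positive fixed point of the local kinetics, which is also a uniform
#' steady state of the network system.
#'
#' @param p an [mm_params()].
#' @return named vector `c(P = ..., Q = ...)`.
#' @export
mm_equilibrium <- function(p = mm_params()) {
  # P = 1 + dQ and Q = (a + bP - P^2)/c  =>  quadratic in P;
  # substitute Q = (P - 1)/d into (a + bP - P^2)/c - Q = 0:
  # d(a + bP - P^2) = c(P - 1)
  roots <- polyroot(c(p$d * p$a + p$cc, p$d * p$b - p$cc, -p$d))
  P <- Re(roots[abs(Im(roots)) < 1e-9 & Re(roots) > 1])
  P <- max(P)
  c(P = P, Q = (P - 1) / p$d)
}

analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Kuramoto order parameter of regional traces
#'
#' Instantaneous phases are extracted from the analytic signal (FFT-based
#' Hilbert transform) of each mean-subtracted trace;
#' `R(t) = |mean_j exp(i theta_j(t))|` measures phase synchrony: 1 = full
#' synchrony, about `1/sqrt(N)` for independent phases.
#'
#' @param r a `sim_result` or time x regions matrix.
#' @param subset region abbreviations to include (default: all).
#' @return list with `R` (time series in \[0, 1\]), `mean` (its time mean)
#'   and `dropped` (constant-trace regions excluded, with a warning).
#' @export
kuramoto_index <- function(r, subset = NULL) {
  act <- if (inherits(r, "sim_result")) r$act else as.matrix(r)
  if (!is.null(subset)) {
    miss <- setdiff(subset, colnames(act))
    if (length(miss)) stop("regions not in trajectory: ", paste(miss, collapse = ", "))
    act <- act[, subset, drop = FALSE]
  }
  sdv <- apply(act, 2, sd)
  dropped <- colnames(act)[sdv < 1e-12]
  if (length(dropped)) {
    warning("dropping constant traces: ", paste(dropped, collapse = ", "))
    act <- act[, sdv >= 1e-12, drop = FALSE]
  }
  if (ncol(act) < 2) stop("kuramoto_index needs at least 2 non-constant regions")
  theta <- apply(act, 2, function(x) Arg(analytic_signal(x - mean(x))))
  R <- Mod(rowMeans(exp(1i * theta)))
  list(R = R, mean = mean(R), dropped = dropped)
}

#' Scalar summary measures of a simulation
#'
#' Mean activation (over time and regions), mean coactivation (off-diagonal
#' mean of the relative coactivation matrix of the detected spike raster)
#' and mean Kuramoto order parameter.
#'
#' @param r a `sim_result`.
#' @param z spike-detection threshold multiplier.
#' @param subset optional region subset for the Kuramoto index.
#' @return list with `mean_activation`, `mean_coactivation`, `mean_kuramoto`
#'   (`NA` with fewer than 2 usable regions).
#' @export
summary_measures <- function(r, z = 1, subset = NULL) {
  stopifnot(inherits(r, "sim_result"))
  raster <- detect_spikes(r, z)
  co <- coactivation(raster)
  off <- co[upper.tri(co)]
  mk <- if (ncol(r$act) >= 2) {
    ki <- tryCatch(kuramoto_index(r, subset), error = function(e) NULL)
    if (is.null(ki)) NA_real_ else ki$mean
  } else NA_real_
  list(mean_activation = mean(r$act),
       mean_coactivation = if (length(off)) mean(off) else NA_real_,
       mean_kuramoto = mk)
}
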