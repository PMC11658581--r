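# Spiking population model: a population of leaky integrate-and-fire
# neurons per connectome region (80% excitatory by default), delta-current
# synapses with a fixed delay, Poisson external drive onto a stimulated
# region, and interspike-interval variability statistics.

#' LIF population simulation parameters
#'
#' Membrane equation `dV/dt = (I - V/R - (V - V_rest)/R_leak)/C` with
#' threshold/reset/refractory rules. The electrical constants are
#' configuration (defaults give a 10 ms effective membrane time constant and
#' a 2 ms refractory period). Synapses are delta increments of the
#' postsynaptic potential (`w_exc` / `w_inh`) delivered after `delay` ms.
#'
#' @param R membrane resistance.
#' @param C membrane capacitance.
#' @param V_rest,V_reset,V_thresh resting, reset and threshold potentials
#'   (mV); `V_reset < V_thresh`.
#' @param R_leak leak resistance toward `V_rest` (`Inf` disables the term).
#' @param refractory absolute refractory period (ms).
#' @param neurons_per_region LIF units per region.
#' @param exc_fraction fraction of excitatory neurons per region.
#' @param w_exc,w_inh synaptic increments (mV); `w_inh` should be negative.
#' @param delay synaptic delay (ms), `delay >= dt`.
#' @param p_connect_intra within-region connection probability.
#' @param p_connect_inter scale of the between-region connection
#'   probability; an edge of relative weight w yields pairwise probability
#'   `p_connect_inter * w / max(w)`.
#' @param stimulus_region abbreviation receiving Poisson drive (or `NULL`).
#' @param stimulus_rate Poisson rate (Hz) per stimulated excitatory neuron.
#' @param I_const constant input current to every neuron.
#' @param T simulation time (ms).
#' @param dt integration step (ms).
#' @param seed RNG seed.
#' @param max_neurons memory guard on the total neuron count.
#' @return a `lif_params` list.
#' @export
lif_params <- function(R = 20, C = 1, V_rest = 0, V_reset = 0, V_thresh = 15,
                       R_leak = 20, refractory = 2,
                       neurons_per_region = 500L, exc_fraction = 0.8,
                       w_exc = 1.5, w_inh = -6, delay = 1,
                       p_connect_intra = 0.05, p_connect_inter = 0.02,
                       stimulus_region = NULL, stimulus_rate = 10000,
                       I_const = 0, T = 300, dt = 0.1, seed = 1L,
                       max_neurons = 200000L) {
  stopifnot(V_reset < V_thresh, exc_fraction >= 0, exc_fraction <= 1,
            delay >= dt, dt > 0, T > 0)
  structure(as.list(environment()), class = "lif_params")
}

#' Build a LIF population network from a connectome
#'
#' Each region receives `neurons_per_region` neurons, the first
#' `exc_fraction` of them excitatory. Within a region every ordered neuron
#' pair is connected with probability `p_connect_intra`; between regions,
#' excitatory neurons of the source region project to neurons of the target
#' region with probability proportional to the connectome edge weight.
#' Inhibitory neurons project only locally.
#'
#' @param c a connectome.
#' @param p a [lif_params()].
#' @return a `lif_network`: sparse synaptic weight matrix `W`
#'   (`W[pre, post]`), neuron-to-region index, excitatory flags.
#' @export
build_population_network <- function(c, p = lif_params()) {
  n_reg <- n_regions(c)
  if (!n_reg) stop("empty connectome")
  npr <- p$neurons_per_region
  N <- n_reg * npr
  if (N > p$max_neurons)
    stop(sprintf("%d neurons exceed the max_neurons guard (%d)", N, p$max_neurons))
  region <- rep(seq_len(n_reg), each = npr)
  n_exc <- round(p$exc_fraction * npr)
  is_exc <- rep(c(rep(TRUE, n_exc), rep(FALSE, npr - n_exc)), n_reg)
  with_seed(p$seed, {
    pre <- integer(0); post <- integer(0)
    # intra-region connectivity (excitatory and inhibitory)
    if (p$p_connect_intra > 0) {
      for (r in seq_len(n_reg)) {
        ids <- (r - 1L) * npr + seq_len(npr)
        pick <- which(matrix(runif(npr * npr) < p$p_connect_intra, npr, npr) &
                        !diag(TRUE, npr), arr.ind = TRUE)
        pre <- c(pre, ids[pick[, 1]]); post <- c(post, ids[pick[, 2]])
      }
    }
    # inter-region projections: excitatory only, probability ~ edge weight
    if (nrow(c$edges) && p$p_connect_inter > 0) {
      ab <- region_abbrev(c)
      wmax <- max(c$edges$weight)
      for (e in seq_len(nrow(c$edges))) {
        r1 <- match(c$edges$from[e], ab); r2 <- match(c$edges$to[e], ab)
        pe <- p$p_connect_inter * c$edges$weight[e] / wmax
        if (pe <= 0) next
        src <- (r1 - 1L) * npr + seq_len(n_exc)
        tgt <- (r2 - 1L) * npr + seq_len(npr)
        pick <- which(matrix(runif(n_exc * npr) < pe, n_exc, npr), arr.ind = TRUE)
        pre <- c(pre, src[pick[, 1]]); post <- c(post, tgt[pick[, 2]])
      }
    }
    w <- ifelse(is_exc[pre], p$w_exc, p$w_inh)
    W <- Matrix::sparseMatrix(i = pre, j = post, x = w, dims = c(N, N))
    structure(list(W = W, region = region, is_exc = is_exc,
                   regions = region_abbrev(c), n_neurons = N,
                   neurons_per_region = npr, params = p),
              class = "lif_network")
  })
}

#' @export
print.lif_network <- function(x, ...) {
  cat(sprintf("<lif_network> %d neurons (%d regions x %d), %d synapses\n",
              x$n_neurons, length(x$regions), x$neurons_per_region,
              Matrix::nnzero(x$W)))
  invisible(x)
}

#' Simulate a LIF population network
#'
#' Forward-Euler integration of the membrane equation with threshold, reset
#' and absolute refractoriness; spikes deliver their synaptic increment
#' after the configured delay; the stimulated region's excitatory neurons
#' receive Poisson drive at `stimulus_rate`.
#'
#' @param network a [build_population_network()] result.
#' @param p a [lif_params()] (defaults to the network's).
#' @return a `spike_trains` object: vectors `neuron` and `time` (ms) of all
#'   spikes, the neuron-to-region map and the simulation horizon.
#' @export
simulate_lif <- function(network, p = network$params) {
  N <- network$n_neurons
  Wt <- Matrix::t(network$W)   # Wt[post, pre] for fast delivery
  steps <- ceiling(p$T / p$dt)
  delay_steps <- max(1L, round(p$delay / p$dt))
  leak1 <- 1 / p$R
  leak2 <- if (is.finite(p$R_leak)) 1 / p$R_leak else 0
  stim_ids <- integer(0)
  if (!is.null(p$stimulus_region)) {
    r <- match(p$stimulus_region, network$regions)
    if (is.na(r)) stop("stimulus region not in network: ", p$stimulus_region)
    npr <- network$neurons_per_region
    n_exc <- sum(network$is_exc[(r - 1L) * npr + seq_len(npr)])
    stim_ids <- (r - 1L) * npr + seq_len(n_exc)
  }
  p_event <- p$stimulus_rate * p$dt / 1000
  with_seed(p$seed, {
    V <- rep(p$V_rest, N)
    refr <- integer(N)
    buffer <- vector("list", delay_steps)
    spk_neuron <- vector("list", steps)
    for (s in seq_len(steps)) {
      slot <- ((s - 1L) %% delay_steps) + 1L
      arriving <- buffer[[slot]]
      buffer[slot] <- list(NULL)
      active <- refr == 0L
      if (!is.null(arriving)) V[active] <- V[active] + arriving[active]
      if (length(stim_ids)) {
        k <- rpois(length(stim_ids), p_event)
        ok <- active[stim_ids]
        V[stim_ids[ok]] <- V[stim_ids[ok]] + k[ok] * p$w_exc
      }
      dV <- (p$I_const - V * leak1 - (V - p$V_rest) * leak2) / p$C
      V[active] <- V[active] + p$dt * dV[active]
      refr[!active] <- refr[!active] - 1L
      fire <- which(V >= p$V_thresh & active)
      if (length(fire)) {
        spk_neuron[[s]] <- fire
        V[fire] <- p$V_reset
        refr[fire] <- as.integer(round(p$refractory / p$dt))
        deliver <- drop(as.matrix(Wt %*%
          Matrix::sparseVector(rep(1, length(fire)), fire, N)))
        tgt <- ((s - 1L + delay_steps) %% delay_steps) + 1L
        buffer[[tgt]] <- if (is.null(buffer[[tgt]])) deliver
                         else buffer[[tgt]] + deliver
      }
    }
    neuron <- unlist(spk_neuron)
    time <- rep(seq_len(steps) * p$dt,
                vapply(spk_neuron, length, integer(1)))
    structure(list(neuron = if (is.null(neuron)) integer(0) else neuron,
                   time = time, region = network$region,
                   region_names = network$regions, T = p$T,
                   n_neurons = N, params = p),
              class = "spike_trains")
  })
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf("<spike_trains> %d spikes from %d of %d neurons over %g ms\n",
              length(x$time), length(unique(x$neuron)), x$n_neurons, x$T))
  invisible(x)
}

#' Interspike-interval statistics per region
#'
#' For every neuron with at least `min_spikes` spikes, the coefficient of
#' variation of its interspike intervals `CV = sd(ISI)/mean(ISI)`; the
#' region-level `CE_isi` is the mean CV over qualifying neurons. Perfectly
#' periodic trains give 0; Poisson trains approach 1.
#'
#' @param s a `spike_trains` object.
#' @param min_spikes minimum spikes for a neuron to qualify (default 3,
#'   i.e. at least two intervals).
#' @return data.frame with one row per region: `region`, `n_neurons_spiking`,
#'   `n_qualifying`, `mean_isi`, `ce_isi` (`NA` when no neuron qualifies).
#' @export
isi_stats <- function(s, min_spikes = 3L) {
  stopifnot(inherits(s, "spike_trains"))
  n_reg <- length(s$region_names)
  ord <- order(s$neuron, s$time)
  neuron <- s$neuron[ord]; time <- s$time[ord]
  per_neuron <- split(time, neuron)
  nid <- as.integer(names(per_neuron))
  cv <- vapply(per_neuron, function(tt) {
    if (length(tt) < min_spikes) return(NA_real_)
    isi <- diff(tt)
    sd(isi) / mean(isi)
  }, numeric(1))
  mean_isi <- vapply(per_neuron, function(tt) {
    if (length(tt) < 2L) return(NA_real_)
    mean(diff(tt))
  }, numeric(1))
  reg_of <- s$region[nid]
  out <- do.call(rbind, lapply(seq_len(n_reg), function(r) {
    sel <- reg_of == r
    qual <- sel & !is.na(cv)
    data.frame(region = s$region_names[r],
               n_neurons_spiking = sum(sel),
               n_qualifying = sum(qual),
               mean_isi = if (any(qual)) mean(mean_isi[qual]) else NA_real_,
               ce_isi = if (any(qual)) mean(cv[qual]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
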