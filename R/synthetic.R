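# Synthetic bilateral connectomes with controllable reciprocity, hemispheric
# mirroring, cross-hemisphere density and hub structure. The defaults emulate
# the scale of a whole-brain rat tract-tracing collation (540 regions, 13183
# directed links) so every downstream stage can be exercised without the
# non-public source data.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Configuration for the synthetic connectome generator
#'
#' @param n_regions even number of regions (two bilateral halves).
#' @param n_links number of directed edges to place.
#' @param reciprocity_target fraction of edges whose reverse edge exists.
#' @param weight_category_probs probabilities of light / moderate / strong.
#' @param observation_dist probabilities of 1, 2, and 3-or-more observations;
#'   the 3+ class gets a geometric tail.
#' @param mirror_prob probability that an intra-hemispheric edge is mirrored
#'   in the opposite hemisphere.
#' @param cross_hemi_frac fraction of edges crossing the hemispheres.
#' @param hub_exponent skew of the endpoint-sampling propensities
#'   (0 = uniform; larger values concentrate edges on low-index hub regions).
#' @param coord_box list with `x`, `y`, `z` ranges (mm) for random region
#'   coordinates; the `x` range is the right hemisphere, mirrored to the left.
#' @param seed RNG seed; the same seed yields a byte-identical connectome.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_regions = 540L, n_links = 13183L,
                             reciprocity_target = 0.45,
                             weight_category_probs = c(0.5, 0.3, 0.2),
                             observation_dist = c(0.6, 0.25, 0.15),
                             mirror_prob = 0.7, cross_hemi_frac = 0.1,
                             hub_exponent = 0.8,
                             coord_box = list(x = c(0.5, 7), y = c(-13, 6), z = c(0, 10)),
                             seed = 1L) {
  if (n_regions %% 2L != 0L) stop("n_regions must be even (bilateral halves)")
  if (n_links > n_regions * (n_regions - 1L))
    stop("n_links exceeds the number of possible directed edges")
  fr <- c(reciprocity_target, mirror_prob, cross_hemi_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (abs(sum(weight_category_probs) - 1) > 1e-8)
    stop("weight_category_probs must sum to 1")
  if (reciprocity_target == 1 && n_links %% 2L != 0L)
    stop("reciprocity_target = 1 requires an even n_links")
  structure(list(n_regions = as.integer(n_regions), n_links = as.integer(n_links),
                 reciprocity_target = reciprocity_target,
                 weight_category_probs = weight_category_probs,
                 observation_dist = observation_dist,
                 mirror_prob = mirror_prob, cross_hemi_frac = cross_hemi_frac,
                 hub_exponent = hub_exponent, coord_box = coord_box,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Read / write a generator configuration as YAML
#'
#' @param path YAML file.
#' @return [read_generator_config()] returns a [generator_config()];
#'   `write_generator_config` returns `path` invisibly.
#' @export
read_generator_config <- function(path) {
  do.call(generator_config, yaml::read_yaml(path))
}

#' @rdname read_generator_config
#' @param cfg a [generator_config()].
#' @export
write_generator_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "generator_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

sample_observations <- function(n, dist) {
  cls <- sample.int(3L, n, replace = TRUE, prob = dist)
  obs <- cls
  tail3 <- cls == 3L
  if (any(tail3)) obs[tail3] <- 3L + rgeom(sum(tail3), 0.5)
  as.integer(obs)
}

#' Generate a synthetic bilateral connectome
#'
#' Edges are placed in units: an intra-hemispheric unit samples endpoints in
#' one hemisphere from hub-skewed propensities and is mirrored to the other
#' hemisphere with probability `mirror_prob`; cross-hemisphere units join the
#' two halves. Reciprocal pairs are inserted until the reciprocity target is
#' met, then one-way edges (whose reverse is absent) fill the remaining
#' budget, so exactly `n_links` edges are produced and the realized
#' reciprocity differs from the target by at most a few edges.
#'
#' @param cfg a [generator_config()].
#' @return a connectome with `n_links` edges; `meta` records the config.
#' @export
generate_connectome <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    nh <- cfg$n_regions %/% 2L
    ab_r <- sprintf("R%03d_R", seq_len(nh))
    ab_l <- sprintf("R%03d_L", seq_len(nh))
    abbrev <- c(ab_r, ab_l)   # indices 1..nh right, nh+1..2nh left
    n <- cfg$n_regions
    prop <- seq_len(nh)^(-cfg$hub_exponent)
    prop <- prop / sum(prop)

    A <- matrix(FALSE, n, n)
    m_target <- cfg$n_links
    recip_target <- round(cfg$reciprocity_target * m_target)
    total <- 0L
    recip <- 0L
    from <- integer(m_target); to <- integer(m_target)

    add_edge <- function(u, v) {
      total <<- total + 1L
      A[u, v] <<- TRUE
      from[total] <<- u; to[total] <<- v
    }

    # sample endpoints of one unit; returns matrix of (u, v) rows to insert
    draw_unit <- function(reciprocal, room) {
      for (trial in seq_len(10000L)) {
        cross <- runif(1) < cfg$cross_hemi_frac
        if (cross) {
          u <- sample.int(nh, 1L, prob = prop)
          v <- sample.int(nh, 1L, prob = prop) + nh
          if (runif(1) < 0.5) { tmp <- u; u <- v; v <- tmp }
          mirror <- FALSE
        } else {
          u <- sample.int(nh, 1L, prob = prop)
          v <- sample.int(nh, 1L, prob = prop)
          if (u == v) next
          mirror <- runif(1) < cfg$mirror_prob
          if (!mirror && runif(1) < 0.5) { u <- u + nh; v <- v + nh }
        }
        per <- (1L + reciprocal) * (1L + mirror)
        if (per > room) next
        ends <- rbind(c(u, v))
        if (reciprocal) ends <- rbind(ends, c(v, u))
        if (!cross && mirror) {
          mir <- function(i) ifelse(i > nh, i - nh, i + nh)
          ends <- rbind(ends, cbind(mir(ends[, 1]), mir(ends[, 2])))
        }
        # one-way units must not create accidental reciprocal pairs
        occupied <- any(A[ends]) ||
          (!reciprocal && any(A[ends[, c(2, 1), drop = FALSE]]))
        if (!occupied) return(ends)
      }
      stop("could not place edge; graph too dense for the configuration")
    }

    while (total < m_target) {
      room <- m_target - total
      reciprocal <- (recip + 1L < recip_target) && room >= 2L
      ends <- draw_unit(reciprocal, room)
      for (r in seq_len(nrow(ends))) add_edge(ends[r, 1], ends[r, 2])
      if (reciprocal) recip <- recip + nrow(ends)
    }

    m <- total
    wc <- sample(WEIGHT_CATEGORIES, m, replace = TRUE,
                 prob = cfg$weight_category_probs)
    obs <- sample_observations(m, cfg$observation_dist)
    # mirrored copies follow their base edge, so mirror-symmetric runs carry
    # identical attributes on both hemispheres
    mir_from <- ifelse(from > nh, from - nh, from + nh)
    mir_to <- ifelse(to > nh, to - nh, to + nh)
    key <- paste(from, to); mkey <- paste(mir_from, mir_to)
    twin <- match(mkey, key)
    fix <- which(!is.na(twin) & twin < seq_along(twin))
    if (length(fix)) { wc[fix] <- wc[twin[fix]]; obs[fix] <- obs[twin[fix]] }

    xr <- runif(nh, cfg$coord_box$x[1], cfg$coord_box$x[2])
    yr <- runif(nh, cfg$coord_box$y[1], cfg$coord_box$y[2])
    zr <- runif(nh, cfg$coord_box$z[1], cfg$coord_box$z[2])
    regions <- data.frame(abbrev = abbrev,
                          name = abbrev,
                          hemisphere = c(rep("right", nh), rep("left", nh)),
                          x = c(xr, -xr), y = c(yr, yr), z = c(zr, zr),
                          functional_group = "none",
                          stringsAsFactors = FALSE)
    edges <- data.frame(from = abbrev[from], to = abbrev[to],
                        weight_category = wc, weight = map_weight(wc),
                        observations = obs, stringsAsFactors = FALSE)
    connectome(regions, edges,
               meta = list(name = "synthetic", generator = unclass(cfg)))
  })
}

#' Assign motor / learning functional groups to connectome regions
#'
#' Regions listed in both groups are rejected. Regions that are also part of
#' a lesion set are removed from their functional group (a lesioned region
#' cannot serve as a functional readout) and recorded in the returned
#' connectome's `meta$group_overlap_removed`.
#'
#' @param c a connectome.
#' @param motor,learning character vectors of region abbreviations.
#' @param lesioned optional character vector (or [lesion_model()]) of
#'   lesioned regions excluded from the groups.
#' @return the connectome with `functional_group` set; unknown abbreviations
#'   are recorded in `meta$unknown_group_abbrevs` with a warning.
#' @export
assign_groups <- function(c, motor = character(), learning = character(),
                          lesioned = NULL) {
  if (inherits(lesioned, "lesion_model")) lesioned <- lesioned$regions
  both <- intersect(motor, learning)
  if (length(both))
    stop("regions in both motor and learning lists: ",
         paste(both, collapse = ", "))
  unknown <- setdiff(c(motor, learning), c$regions$abbrev)
  if (length(unknown)) {
    warning("group abbreviations not in connectome: ",
            paste(unknown, collapse = ", "))
    c$meta$unknown_group_abbrevs <- unknown
  }
  removed <- intersect(c(motor, learning), lesioned)
  if (length(removed)) c$meta$group_overlap_removed <- removed
  motor <- setdiff(setdiff(motor, lesioned), unknown)
  learning <- setdiff(setdiff(learning, lesioned), unknown)
  c$regions$functional_group <- "none"
  c$regions$functional_group[c$regions$abbrev %in% motor] <- "motor"
  c$regions$functional_group[c$regions$abbrev %in% learning] <- "learning"
  c
}

#' Sample a random lesion set from one hemisphere
#'
#' Fixture generator mirroring experimental stroke-lesion lists: a uniform
#' sample without replacement of regions from the chosen hemisphere.
#'
#' @param c a connectome.
#' @param size number of regions to lesion.
#' @param hemisphere `"right"`, `"left"`, `"midline"` or `"any"`.
#' @param seed RNG seed.
#' @param name lesion-model name.
#' @return a [lesion_model()].
#' @export
sample_lesion_set <- function(c, size, hemisphere = "right", seed = NULL,
                              name = "synthetic_lesion") {
  pool <- if (hemisphere == "any") c$regions$abbrev
          else c$regions$abbrev[c$regions$hemisphere == hemisphere]
  if (size > length(pool))
    stop(sprintf("lesion size %d exceeds the %d regions in hemisphere '%s'",
                 size, length(pool), hemisphere))
  with_seed(seed, lesion_model(name, sample(pool, size)))
}
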