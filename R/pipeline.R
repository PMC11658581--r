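# End-to-end orchestration: generate or load a connectome, apply lesion
# models, compute differential reports, ranks, MCRD and pair tables, run
# dynamics, and write a machine-readable report bundle with a manifest.

stage_seed <- function(global_seed, stage) {
  # stable per-stage seed below 2^31, derived from the stage name
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 7919 + h) %% 2147483647)
}

#' Pipeline configuration
#'
#' @param input a connectome, a [generator_config()], or a path readable by
#'   [load_connectome()].
#' @param lesions named list: each element a character vector of region
#'   abbreviations (or a [lesion_model()]).
#' @param motor,learning functional-group abbreviation lists.
#' @param outdir output directory for the report bundle (`NULL`: in-memory
#'   only).
#' @param seed global seed; per-stage seeds are derived from it.
#' @param sw_spec [ensemble_spec()] for small-worldness (or `NULL` to skip).
#' @param null_opts permutation-test options passed to
#'   [differential_report()] (or `NULL`).
#' @param mcrd list with `reli`, `muli`, `neti` filter settings.
#' @param dynamics `NULL`, or a list with `model`
#'   (`"mimura_murray"`, `"fhn"` or `"wilson_cowan"`), `params` (a matching
#'   params object or `NULL` for defaults), and optional `subset` of regions
#'   for the Kuramoto index.
#' @param run_fhn_coactivation compute an FHN coactivation matrix on the
#'   control connectome for the pair tables (slower).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, lesions, motor = character(),
                            learning = character(), outdir = NULL,
                            seed = 1L, sw_spec = ensemble_spec(size = 20L),
                            null_opts = NULL,
                            mcrd = list(reli = 2L, muli = 4L, neti = 0.2),
                            dynamics = NULL, run_fhn_coactivation = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

resolve_input <- function(input, seed) {
  if (inherits(input, "connectome")) input
  else if (inherits(input, "generator_config")) generate_connectome(input)
  else if (is.character(input) && length(input) == 1L) load_connectome(input)
  else stop("input must be a connectome, a generator_config or a file path")
}

#' Run the full lesion-connectomics pipeline
#'
#' For every lesion model: a [differential_report()], average local-parameter
#' ranks of the control and lesioned connectomes, the filtered MCRD table and
#' the ranked pair table; optional node dynamics on control and lesioned
#' connectomes with summary measures. When `cfg$outdir` is set, every table
#' is written as CSV, the report as JSON, and a manifest records file digests
#' and seeds.
#'
#' @param cfg a [pipeline_config()].
#' @return a report bundle (named list), invisibly when written to disk.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  control <- resolve_input(cfg$input, cfg$seed)
  control <- assign_groups(control, cfg$motor, cfg$learning)
  lesions <- lapply(names(cfg$lesions) %||% seq_along(cfg$lesions), function(nm) {
    l <- cfg$lesions[[nm]]
    if (inherits(l, "lesion_model")) l else lesion_model(as.character(nm), l)
  })
  names(lesions) <- vapply(lesions, function(l) l$name, character(1))

  ranks_control <- average_rank(local_parameters(
    control, seed = stage_seed(cfg$seed, "ranks_control")))

  coact <- NULL
  if (isTRUE(cfg$run_fhn_coactivation)) {
    fr <- simulate_fhn(control, fhn_params(seed = stage_seed(cfg$seed, "fhn")))
    coact <- coactivation(detect_spikes(fr))
  }

  per_lesion <- lapply(lesions, function(les) {
    lesioned <- apply_lesion(control, les)
    rep_ <- differential_report(control, les, sw_spec = cfg$sw_spec,
                                null_opts = cfg$null_opts)
    ranks_les <- average_rank(local_parameters(
      lesioned, seed = stage_seed(cfg$seed, paste0("ranks_", les$name))))
    mcrd_tab <- mcrd_filter(control, les, reli = cfg$mcrd$reli,
                            muli = cfg$mcrd$muli, neti = cfg$mcrd$neti,
                            ranks = ranks_control)
    pt <- if (length(les$regions))
      pair_rank_table(control, les, coactivation = coact) else NULL
    census <- if (any(control$regions$functional_group != "none"))
      connection_census(control, les) else NULL
    dyn <- NULL
    if (!is.null(cfg$dynamics)) {
      dseed <- stage_seed(cfg$seed, paste0("dyn_", les$name))
      simulate <- function(conn) {
        mdl <- cfg$dynamics$model %||% "mimura_murray"
        par0 <- cfg$dynamics$params
        r <- switch(mdl,
          mimura_murray = {
            pp <- par0 %||% mm_params()
            pp$seed <- dseed
            simulate_mimura_murray(conn, pp)
          },
          fhn = {
            pp <- par0 %||% fhn_params()
            pp$seed <- dseed
            simulate_fhn(conn, pp)
          },
          wilson_cowan = {
            pp <- par0 %||% wc_params()
            pp$seed <- dseed
            simulate_wilson_cowan(conn, pp)
          },
          stop("unknown dynamics model: ", mdl))
        subset <- intersect(cfg$dynamics$subset %||% character(),
                            region_abbrev(conn))
        summary_measures(r, subset = if (length(subset) >= 2) subset else NULL)
      }
      dyn <- list(control = simulate(control), lesioned = simulate(lesioned))
    }
    list(report = rep_, ranks_lesioned = ranks_les, mcrd = mcrd_tab,
         pair_table = pt, census = census, dynamics = dyn)
  })

  bundle <- list(control = control, ranks_control = ranks_control,
                 lesions = per_lesion, seed = cfg$seed)
  if (is.null(cfg$outdir)) return(bundle)

  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(obj, name) {
    f <- file.path(cfg$outdir, name)
    write.csv(obj, f, row.names = FALSE)
    files <<- c(files, f)
  }
  wr(data.frame(region = names(ranks_control), avg_rank = ranks_control),
     "ranks_control.csv")
  report_json <- list(seed = cfg$seed, lesions = list())
  for (nm in names(per_lesion)) {
    pl <- per_lesion[[nm]]
    wr(as.data.frame(pl$report), sprintf("report_%s.csv", nm))
    wr(pl$mcrd, sprintf("mcrd_%s.csv", nm))
    if (!is.null(pl$pair_table))
      wr(as.data.frame(pl$pair_table), sprintf("pairs_%s.csv", nm))
    wr(data.frame(region = names(pl$ranks_lesioned),
                  avg_rank = pl$ranks_lesioned),
       sprintf("ranks_%s.csv", nm))
    report_json$lesions[[nm]] <- c(
      unclass(pl$report)[!vapply(unclass(pl$report), is.null, logical(1))],
      list(dynamics = pl$dynamics))
  }
  jf <- file.path(cfg$outdir, "report.json")
  jsonlite::write_json(report_json, jf, auto_unbox = TRUE, digits = NA,
                       na = "null")
  files <- c(files, jf)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write.csv(manifest, file.path(cfg$outdir, "manifest.csv"), row.names = FALSE)
  invisible(bundle)
}
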