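# Differential connectomics: lesion application, control-vs-lesioned
# accounting, functional-group connection loss and the reliability /
# multi-lesion / network-importance (RELi / MULi / NETi) record filter behind
# multidimensional circular relationship diagrams (MCRD).

#' Define a lesion model
#'
#' A lesion model is a named set of region abbreviations to delete from a
#' connectome, e.g. the damaged regions mapped for one experimental stroke
#' model.
#'
#' @param name model name (e.g. `"dMCAO"`).
#' @param regions character vector of region abbreviations.
#' @return a `lesion_model` object.
#' @export
lesion_model <- function(name, regions) {
  structure(list(name = name, regions = unique(as.character(regions))),
            class = "lesion_model")
}

#' @export
print.lesion_model <- function(x, ...) {
  cat(sprintf("<lesion_model> %s: %d regions\n", x$name, length(x$regions)))
  invisible(x)
}

resolve_lesion <- function(c, lesion) {
  if (inherits(lesion, "lesion_model")) lesion <- lesion$regions
  lesion <- unique(as.character(lesion))
  unknown <- setdiff(lesion, c$regions$abbrev)
  if (length(unknown))
    stop("lesion regions not in connectome: ", paste(unknown, collapse = ", "))
  lesion
}

#' Apply a lesion to a connectome
#'
#' The lesioned connectome is the control connectome minus the lesioned
#' regions and every edge touching them.
#'
#' @param c control connectome.
#' @param lesion a [lesion_model()] or character vector of abbreviations.
#' @return the lesioned connectome.
#' @export
apply_lesion <- function(c, lesion) {
  les <- resolve_lesion(c, lesion)
  out <- subnetwork(c, setdiff(c$regions$abbrev, les))
  out$meta$lesion <- les
  out
}

pct_change <- function(before, after, sign = c("reduction", "increase")) {
  sign <- match.arg(sign)
  if (is.na(before) || is.na(after)) return(NA_real_)
  if (before == 0) return(if (after == 0) 0 else NA_real_)
  if (sign == "reduction") 100 * (before - after) / before
  else 100 * (after - before) / before
}

#' Differential report of global network structure after a lesion
#'
#' Computes the paired control / lesioned global metrics and their relative
#' changes: region, link and reciprocal-edge counts, percentage reduction in
#' reciprocal edges and clustering coefficient, percentage increase in
#' small-worldness and average path length. Optional permutation tests give a
#' null-model p-value per metric.
#'
#' @param control control connectome.
#' @param lesion a [lesion_model()] or character vector.
#' @param sw_spec [ensemble_spec()] for the small-worldness null ensemble, or
#'   `NULL` to skip small-worldness.
#' @param null_opts `NULL`, or a list with `spec` ([ensemble_spec()]),
#'   `n_perm`, `metrics` (registry names) and `null_mode` for
#'   [permutation_test()].
#' @return a `differential_report` list; metrics undefined on a degenerate
#'   lesioned graph are reported as `NA`, not as errors.
#' @export
differential_report <- function(control, lesion,
                                sw_spec = ensemble_spec(size = 20L),
                                null_opts = NULL) {
  les <- resolve_lesion(control, lesion)
  lesioned <- apply_lesion(control, les)
  rec_c <- reciprocity_stats(control); rec_l <- reciprocity_stats(lesioned)
  apl_c <- avg_path_length(control); apl_l <- avg_path_length(lesioned)
  cc_c <- avg_clustering(control); cc_l <- avg_clustering(lesioned)
  sw_c <- sw_l <- NA_real_
  if (!is.null(sw_spec) && n_edges(control) > 1 && n_edges(lesioned) > 1) {
    sw_c <- small_worldness(control, build_ensemble(control, sw_spec))$value
    spec_l <- sw_spec; spec_l$seed <- sw_spec$seed + 1L
    sw_l <- small_worldness(lesioned, build_ensemble(lesioned, spec_l))$value
  }
  pvals <- NULL
  if (!is.null(null_opts)) {
    metrics <- null_opts$metrics %||% c("reciprocal_edges", "transitivity",
                                        "avg_clustering", "avg_path_length")
    pvals <- vapply(metrics, function(mname) {
      permutation_test(mname, control, lesioned,
                       spec = null_opts$spec %||% ensemble_spec(),
                       n_perm = null_opts$n_perm %||% 199L,
                       null_mode = null_opts$null_mode %||% "lesion")$p_value
    }, numeric(1))
  }
  structure(list(
    lesion_name = if (inherits(lesion, "lesion_model")) lesion$name else "lesion",
    n_lesioned = length(les),
    n_regions_control = n_regions(control),
    n_regions_lesioned = n_regions(lesioned),
    n_links_control = n_edges(control),
    n_links_lesioned = n_edges(lesioned),
    reciprocal_edges_control = rec_c$count,
    reciprocal_edges_lesioned = rec_l$count,
    pct_reduction_reciprocal = pct_change(rec_c$count, rec_l$count, "reduction"),
    small_worldness_control = sw_c,
    small_worldness_lesioned = sw_l,
    pct_increase_small_world = pct_change(sw_c, sw_l, "increase"),
    cluster_coeff_control = cc_c,
    cluster_coeff_lesioned = cc_l,
    pct_reduction_cluster_coeff = pct_change(cc_c, cc_l, "reduction"),
    path_length_control = apl_c$value,
    path_length_lesioned = apl_l$value,
    pct_increase_path_length = pct_change(apl_c$value, apl_l$value, "increase"),
    p_values = pvals), class = "differential_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.differential_report <- function(x, ...) {
  cat(sprintf("<differential_report> %s (%d lesioned regions)\n",
              x$lesion_name, x$n_lesioned))
  cat(sprintf("  regions   %d -> %d\n", x$n_regions_control, x$n_regions_lesioned))
  cat(sprintf("  links     %d -> %d\n", x$n_links_control, x$n_links_lesioned))
  cat(sprintf("  reciprocal edges %d -> %d (%.2f%% reduction)\n",
              x$reciprocal_edges_control, x$reciprocal_edges_lesioned,
              x$pct_reduction_reciprocal))
  if (!is.na(x$pct_increase_small_world))
    cat(sprintf("  small-worldness %.3f -> %.3f (%+.2f%%)\n",
                x$small_worldness_control, x$small_worldness_lesioned,
                x$pct_increase_small_world))
  cat(sprintf("  clustering %.4f -> %.4f (%.2f%% reduction)\n",
              x$cluster_coeff_control, x$cluster_coeff_lesioned,
              x$pct_reduction_cluster_coeff))
  cat(sprintf("  path length %.3f -> %.3f (%+.2f%%)\n",
              x$path_length_control, x$path_length_lesioned,
              x$pct_increase_path_length))
  invisible(x)
}

#' @export
as.data.frame.differential_report <- function(x, ...) {
  flds <- x[!vapply(x, is.null, logical(1))]
  flds$p_values <- NULL
  as.data.frame(flds, stringsAsFactors = FALSE)
}

reciprocal_partner_count <- function(c, region, partners) {
  # partners connected to `region` in both directions
  key <- paste(c$edges$from, c$edges$to, sep = "\r")
  sum(vapply(partners, function(p)
    paste(region, p, sep = "\r") %in% key && paste(p, region, sep = "\r") %in% key,
    logical(1)))
}

#' Relative connection loss of functional regions after a lesion
#'
#' For each region of a functional group (motor or learning), counts its
#' connections in the control connectome, how many touch lesioned regions,
#' and the relative loss in percent; reciprocal connections (partner linked in
#' both directions) are accounted separately.
#'
#' @param control connectome with `functional_group` assigned
#'   (see [assign_groups()]).
#' @param lesion a [lesion_model()] or character vector.
#' @param group `"motor"` or `"learning"`.
#' @return data.frame, one row per group region, with attribute
#'   `group_mean_pct_loss`.
#' @export
functional_loss <- function(control, lesion, group = c("motor", "learning")) {
  group <- match.arg(group)
  les <- resolve_lesion(control, lesion)
  members <- setdiff(control$regions$abbrev[
    control$regions$functional_group == group], les)
  if (!length(members)) stop("no (non-lesioned) regions in group '", group, "'")
  ed <- control$edges
  rows <- lapply(members, function(r) {
    touch <- ed$from == r | ed$to == r
    partners <- unique(c(ed$to[ed$from == r], ed$from[ed$to == r]))
    lost <- touch & (ed$from %in% les | ed$to %in% les)
    rp_all <- reciprocal_partner_count(control, r, partners)
    rp_lost <- reciprocal_partner_count(control, r, intersect(partners, les))
    data.frame(region = r,
               n_connections = sum(touch),
               n_lost = sum(lost),
               pct_loss = if (sum(touch)) 100 * sum(lost) / sum(touch) else 0,
               n_reciprocal = rp_all,
               n_reciprocal_lost = rp_lost,
               pct_reciprocal_loss = if (rp_all) 100 * rp_lost / rp_all else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "group_mean_pct_loss") <- mean(out$pct_loss)
  attr(out, "group_mean_pct_reciprocal_loss") <- mean(out$pct_reciprocal_loss)
  out
}

#' Census of connections between lesioned and functional regions
#'
#' Counts the edges (either direction) between the lesion set and each
#' functional group, their percentages of the joint total, and a per-region
#' breakdown of connections with lesioned regions.
#'
#' @param c connectome with functional groups assigned.
#' @param lesion a [lesion_model()] or character vector.
#' @return list with `counts` (named), `percentages` (named; 0 with
#'   `defined = FALSE` flag when no link exists) and `per_region` data.frame.
#' @export
connection_census <- function(c, lesion) {
  les <- resolve_lesion(c, lesion)
  ed <- c$edges
  grp <- setNames(c$regions$functional_group, c$regions$abbrev)
  touches <- function(members)
    sum((ed$from %in% les & ed$to %in% members) |
        (ed$to %in% les & ed$from %in% members))
  motor <- setdiff(names(grp)[grp == "motor"], les)
  learning <- setdiff(names(grp)[grp == "learning"], les)
  counts <- c(motor = touches(motor), learning = touches(learning))
  tot <- sum(counts)
  pct <- if (tot) 100 * counts / tot else c(motor = 0, learning = 0)
  per_region <- do.call(rbind, lapply(c(motor, learning), function(r) {
    n <- sum((ed$from == r & ed$to %in% les) | (ed$to == r & ed$from %in% les))
    data.frame(region = r, group = unname(grp[r]), n_lesion_connections = n,
               stringsAsFactors = FALSE)
  }))
  list(counts = counts, percentages = pct, defined = tot > 0,
       per_region = per_region)
}

#' RELi / MULi / NETi filter for MCRD records
#'
#' Builds one record per (lesioned region, non-lesioned partner) pair with a
#' direct connection, then applies the triple filter: `reli` — minimum
#' tract-tracing observation count of the connection (reliability); `muli` —
#' minimum number of distinct lesioned regions the partner touches
#' (multi-lesion effect); `neti` — the partner's average local-parameter rank
#' must fall within the best `neti` quantile of all supplied ranks (low rank
#' = high network importance; boundary ties are kept).
#'
#' @param c control connectome.
#' @param lesion a [lesion_model()] or character vector.
#' @param reli minimum observations (default 2).
#' @param muli minimum partner lesion-degree (default 4).
#' @param neti kept importance quantile in (0, 1\] (default 0.2, the top 20%).
#' @param ranks named numeric vector of average ranks on the control
#'   connectome (see [average_rank()]).
#' @return data.frame of MCRD records, sorted by lesioned region then
#'   partner rank, with columns `lesioned_region`, `partner_region`,
#'   `direction` (afferent / efferent / reciprocal, relative to the lesioned
#'   region), `weight_category`, `observations`, `partner_avg_rank`,
#'   `partner_lesion_degree`.
#' @export
mcrd_filter <- function(c, lesion, reli = 2L, muli = 4L, neti = 0.2,
                        ranks) {
  if (!(neti > 0 && neti <= 1)) stop("neti must lie in (0, 1]")
  les <- resolve_lesion(c, lesion)
  ed <- c$edges
  # direct edges between a lesioned region and a non-lesioned partner
  eff <- ed[ed$from %in% les & !(ed$to %in% les), , drop = FALSE]     # lesioned -> partner
  aff <- ed[ed$to %in% les & !(ed$from %in% les), , drop = FALSE]     # partner -> lesioned
  pair <- rbind(
    data.frame(lesioned = eff$from, partner = eff$to,
               dir = rep("efferent", nrow(eff)),
               weight_category = eff$weight_category,
               observations = eff$observations, stringsAsFactors = FALSE),
    data.frame(lesioned = aff$to, partner = aff$from,
               dir = rep("afferent", nrow(aff)),
               weight_category = aff$weight_category,
               observations = aff$observations, stringsAsFactors = FALSE))
  if (!nrow(pair))
    return(data.frame(lesioned_region = character(), partner_region = character(),
                      direction = character(), weight_category = character(),
                      observations = integer(), partner_avg_rank = numeric(),
                      partner_lesion_degree = integer(), stringsAsFactors = FALSE))
  key <- paste(pair$lesioned, pair$partner, sep = "\r")
  ord_cat <- match(pair$weight_category, WEIGHT_CATEGORIES)
  rec <- do.call(rbind, lapply(split(seq_len(nrow(pair)), key), function(ii) {
    both <- length(unique(pair$dir[ii])) == 2L
    data.frame(lesioned_region = pair$lesioned[ii[1]],
               partner_region = pair$partner[ii[1]],
               direction = if (both) "reciprocal" else pair$dir[ii[1]],
               weight_category = WEIGHT_CATEGORIES[max(ord_cat[ii])],
               observations = max(pair$observations[ii]),
               stringsAsFactors = FALSE)
  }))
  lesion_degree <- tapply(rec$lesioned_region, rec$partner_region,
                          function(x) length(unique(x)))
  rec$partner_lesion_degree <- as.integer(lesion_degree[rec$partner_region])
  rec$partner_avg_rank <- unname(ranks[rec$partner_region])
  cutoff <- unname(quantile(ranks, neti, na.rm = TRUE, names = FALSE))
  keep <- rec$observations >= reli &
    rec$partner_lesion_degree >= muli &
    !is.na(rec$partner_avg_rank) & rec$partner_avg_rank <= cutoff
  out <- rec[keep, c("lesioned_region", "partner_region", "direction",
                     "weight_category", "observations", "partner_avg_rank",
                     "partner_lesion_degree")]
  out <- out[order(out$lesioned_region, out$partner_avg_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
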