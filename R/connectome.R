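#' @importFrom stats rbinom rnorm runif sd setNames quantile rgeom rpois rexp
#' @importFrom utils read.csv write.csv head
NULL

WEIGHT_CATEGORIES <- c("light", "moderate", "strong")

default_weight_mapping <- function() c(light = 1, moderate = 2, strong = 3)

#' Map an ordinal connection-weight category to a numeric weight
#'
#' Tract-tracing collations report connection strength on a semiquantitative
#' ordinal scale (light / moderate / strong). All network arithmetic in this
#' package uses a numeric weight obtained through a strictly increasing
#' mapping of that scale.
#'
#' @param category character vector of category labels.
#' @param mapping named numeric vector, strictly increasing over the ordinal
#'   scale. Default `c(light = 1, moderate = 2, strong = 3)`.
#' @return numeric vector of weights.
#' @export
map_weight <- function(category, mapping = default_weight_mapping()) {
  if (is.null(names(mapping)) || any(!nzchar(names(mapping))))
    stop("weight mapping must be a named numeric vector")
  if (any(diff(unname(mapping[WEIGHT_CATEGORIES[WEIGHT_CATEGORIES %in% names(mapping)]])) <= 0))
    stop("weight mapping must be strictly increasing over the ordinal scale")
  unknown <- setdiff(unique(category), names(mapping))
  if (length(unknown))
    stop("unknown weight category: ", paste(unknown, collapse = ", "))
  unname(mapping[category])
}

infer_hemisphere <- function(abbrev) {
  ifelse(grepl("_L$", abbrev), "left",
         ifelse(grepl("_R$", abbrev), "right", "midline"))
}

#' Construct a connectome object
#'
#' A connectome is a weighted directed graph over named bilateral brain
#' regions. Region identity is the abbreviation string; bilateral homologs
#' carry explicit `_L` / `_R` suffixes. Each edge records an ordinal weight
#' category, a numeric weight and the number of independent tract-tracing
#' observations supporting it.
#'
#' @param regions data.frame with at least a character column `abbrev`
#'   (unique). Optional columns: `name`, `hemisphere`
#'   (left/right/midline; inferred from the suffix when absent), `x`, `y`,
#'   `z` (stereotaxic mm), `functional_group` (motor/learning/none).
#' @param edges data.frame with character columns `from`, `to` and optional
#'   `weight_category`, `weight`, `observations`. Missing weights are filled
#'   through [map_weight()]; missing categories default to "light"
#'   when no weight is given, otherwise "moderate".
#' @param meta free-form list (name, provenance, generator seed, ...).
#' @param allow_self_loops keep self-loop edges instead of rejecting them.
#' @param weight_mapping ordinal-to-numeric mapping used to fill missing
#'   weights.
#' @return an object of class `connectome`.
#' @export
connectome <- function(regions, edges = NULL, meta = list(),
                       allow_self_loops = FALSE,
                       weight_mapping = default_weight_mapping()) {
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  if (!"abbrev" %in% names(regions)) stop("regions must have an 'abbrev' column")
  regions$abbrev <- as.character(regions$abbrev)
  dup <- regions$abbrev[duplicated(regions$abbrev)]
  if (length(dup))
    stop("duplicate region abbreviation: ", paste(unique(dup), collapse = ", "))
  if (!"name" %in% names(regions)) regions$name <- regions$abbrev
  if (!"hemisphere" %in% names(regions))
    regions$hemisphere <- infer_hemisphere(regions$abbrev)
  bad_h <- !regions$hemisphere %in% c("left", "right", "midline")
  if (any(bad_h)) stop("invalid hemisphere value for: ",
                       paste(regions$abbrev[bad_h], collapse = ", "))
  sfx <- infer_hemisphere(regions$abbrev)
  mism <- sfx != "midline" & sfx != regions$hemisphere
  if (any(mism))
    stop("hemisphere suffix inconsistent with hemisphere field for: ",
         paste(regions$abbrev[mism], collapse = ", "))
  for (cc in c("x", "y", "z")) if (!cc %in% names(regions)) regions[[cc]] <- NA_real_
  if (!"functional_group" %in% names(regions)) regions$functional_group <- "none"

  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        weight_category = character(), weight = numeric(),
                        observations = integer(), stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    if (!all(c("from", "to") %in% names(edges)))
      stop("edges must have 'from' and 'to' columns")
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    bad <- !(edges$from %in% regions$abbrev & edges$to %in% regions$abbrev)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("edge %d references unknown region: %s -> %s",
                   i, edges$from[i], edges$to[i]))
    }
    if (!allow_self_loops && any(edges$from == edges$to))
      stop("self-loop edges present; set allow_self_loops = TRUE to keep them")
    if (!"weight" %in% names(edges)) edges$weight <- NA_real_
    if (!"weight_category" %in% names(edges))
      edges$weight_category <- ifelse(is.na(edges$weight), "light", "moderate")
    miss_w <- is.na(edges$weight)
    if (any(miss_w))
      edges$weight[miss_w] <- map_weight(edges$weight_category[miss_w], weight_mapping)
    if (any(edges$weight <= 0)) stop("edge weights must be > 0")
    if (!"observations" %in% names(edges)) edges$observations <- 1L
    edges$observations <- as.integer(edges$observations)
    if (any(is.na(edges$observations)) || any(edges$observations < 1))
      stop("edge observations must be integers >= 1")
    key <- paste(edges$from, edges$to, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate edge: ", paste(head(key[duplicated(key)], 3), collapse = ", "))
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight_category = character(), weight = numeric(),
                        observations = integer(), stringsAsFactors = FALSE)
  }
  edges <- edges[, c("from", "to", "weight_category", "weight", "observations")]
  rownames(regions) <- NULL
  rownames(edges) <- NULL
  structure(list(regions = regions, edges = edges, meta = meta),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d regions, %d directed edges\n",
              nrow(x$regions), nrow(x$edges)))
  hem <- table(x$regions$hemisphere)
  cat("  hemispheres:", paste(sprintf("%s=%d", names(hem), hem), collapse = " "), "\n")
  if (!is.null(x$meta$name)) cat("  name:", x$meta$name, "\n")
  invisible(x)
}

#' Number of regions / edges of a connectome
#' @param c a connectome.
#' @return integer count.
#' @export
n_regions <- function(c) nrow(c$regions)

#' @rdname n_regions
#' @export
n_edges <- function(c) nrow(c$edges)

#' Region abbreviations of a connectome
#' @param c a connectome.
#' @return character vector in region order.
#' @export
region_abbrev <- function(c) c$regions$abbrev

#' Dense adjacency matrix of a connectome
#'
#' @param c a connectome.
#' @param weighted use numeric edge weights (`TRUE`) or the 0/1 pattern.
#' @return square matrix with region abbreviations as dimnames;
#'   `A[i, j]` is the weight of the edge i -> j (0 when absent).
#' @export
adjacency_matrix <- function(c, weighted = TRUE) {
  ab <- c$regions$abbrev
  n <- length(ab)
  A <- matrix(0, n, n, dimnames = list(ab, ab))
  if (nrow(c$edges)) {
    i <- match(c$edges$from, ab)
    j <- match(c$edges$to, ab)
    A[cbind(i, j)] <- if (weighted) c$edges$weight else 1
  }
  A
}

#' Convert a connectome to an igraph graph
#'
#' @param c a connectome.
#' @param weighted attach numeric weights as the `weight` edge attribute.
#' @return a directed `igraph` graph whose vertex names are the region
#'   abbreviations.
#' @export
as_igraph <- function(c, weighted = TRUE) {
  g <- igraph::graph_from_data_frame(
    c$edges[, c("from", "to"), drop = FALSE],
    directed = TRUE,
    vertices = data.frame(name = c$regions$abbrev, stringsAsFactors = FALSE))
  if (weighted && nrow(c$edges)) igraph::E(g)$weight <- c$edges$weight
  g
}

#' Induced subnetwork of a connectome
#'
#' Keeps the listed regions and every edge with both endpoints among them.
#' This is the primitive behind lesion application: the lesioned connectome
#' is the control connectome minus the lesioned areas.
#'
#' @param c a connectome.
#' @param keep character vector of region abbreviations to retain.
#' @return a connectome over `keep` (in the original region order).
#' @export
subnetwork <- function(c, keep) {
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, c$regions$abbrev)
  if (length(unknown))
    stop("unknown region(s) in keep: ", paste(unknown, collapse = ", "))
  regions <- c$regions[c$regions$abbrev %in% keep, , drop = FALSE]
  edges <- c$edges[c$edges$from %in% keep & c$edges$to %in% keep, , drop = FALSE]
  connectome(regions, edges, meta = c$meta, allow_self_loops = TRUE)
}

# ---- I/O -------------------------------------------------------------------

regions_sidecar_path <- function(path) {
  sub("(\\.[A-Za-z0-9]+)?$", ".regions.csv", path)
}

#' Read a connectome from disk
#'
#' Three interchange formats are supported. `edge_csv` is a fixed CSV dialect
#' (UTF-8, header `source,target,weight_category,weight,observations`) with an
#' optional `<stem>.regions.csv` sidecar carrying region metadata; without a
#' sidecar the region set is inferred from the edge list. `graphml` carries
#' node attributes `abbrev, hemisphere, group, x, y, z` and edge attributes
#' `weight, category, observations`. `json` mirrors the data model directly.
#'
#' @param path input file.
#' @param format one of `"edge_csv"`, `"graphml"`, `"json"`; guessed from the
#'   file extension when missing.
#' @return a validated connectome.
#' @export
load_connectome <- function(path, format = c("edge_csv", "graphml", "json")) {
  if (missing(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     graphml = "graphml", json = "json", "edge_csv")
  }
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    edge_csv = {
      ed <- read.csv(path, stringsAsFactors = FALSE)
      need <- c("source", "target")
      if (!all(need %in% names(ed)))
        stop("edge CSV must have 'source' and 'target' columns")
      names(ed)[match(c("source", "target"), names(ed))] <- c("from", "to")
      sidecar <- regions_sidecar_path(path)
      if (file.exists(sidecar)) {
        regions <- read.csv(sidecar, stringsAsFactors = FALSE)
      } else {
        regions <- data.frame(abbrev = unique(c(ed$from, ed$to)),
                              stringsAsFactors = FALSE)
      }
      connectome(regions, ed)
    },
    graphml = {
      g <- igraph::read_graph(path, format = "graphml")
      va <- igraph::vertex_attr(g)
      regions <- data.frame(abbrev = if (!is.null(va$abbrev)) va$abbrev else va$name,
                            stringsAsFactors = FALSE)
      if (!is.null(va$hemisphere)) regions$hemisphere <- va$hemisphere
      if (!is.null(va$group)) regions$functional_group <- va$group
      for (cc in c("x", "y", "z"))
        if (!is.null(va[[cc]])) regions[[cc]] <- as.numeric(va[[cc]])
      el <- igraph::as_edgelist(g, names = FALSE)
      ea <- igraph::edge_attr(g)
      edges <- data.frame(from = regions$abbrev[el[, 1]],
                          to = regions$abbrev[el[, 2]],
                          stringsAsFactors = FALSE)
      if (!is.null(ea$category)) edges$weight_category <- ea$category
      if (!is.null(ea$weight)) edges$weight <- as.numeric(ea$weight)
      if (!is.null(ea$observations)) edges$observations <- as.integer(ea$observations)
      connectome(regions, edges)
    },
    json = {
      doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
      meta <- if (!is.null(doc$meta)) as.list(doc$meta) else list()
      edges <- doc$edges
      if (is.null(edges) || (is.data.frame(edges) && !nrow(edges))) edges <- NULL
      connectome(doc$regions, edges, meta = meta)
    })
}

#' Write a connectome to disk
#'
#' Inverse of [load_connectome()]: a written file loads back to a
#' structurally identical connectome. Field order is deterministic.
#'
#' @param c a connectome.
#' @param path output file.
#' @param format see [load_connectome()].
#' @return `path`, invisibly.
#' @export
save_connectome <- function(c, path, format = c("edge_csv", "graphml", "json")) {
  if (missing(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     graphml = "graphml", json = "json", "edge_csv")
  }
  format <- match.arg(format)
  switch(format,
    edge_csv = {
      ed <- c$edges
      names(ed)[1:2] <- c("source", "target")
      write.csv(ed, path, row.names = FALSE)
      write.csv(c$regions, regions_sidecar_path(path), row.names = FALSE)
    },
    graphml = {
      g <- as_igraph(c)
      igraph::V(g)$abbrev <- c$regions$abbrev
      igraph::V(g)$hemisphere <- c$regions$hemisphere
      igraph::V(g)$group <- c$regions$functional_group
      igraph::V(g)$x <- ifelse(is.na(c$regions$x), 0, c$regions$x)
      igraph::V(g)$y <- ifelse(is.na(c$regions$y), 0, c$regions$y)
      igraph::V(g)$z <- ifelse(is.na(c$regions$z), 0, c$regions$z)
      if (nrow(c$edges)) {
        igraph::E(g)$category <- c$edges$weight_category
        igraph::E(g)$observations <- c$edges$observations
      }
      igraph::write_graph(g, path, format = "graphml")
    },
    json = {
      doc <- list(regions = c$regions, edges = c$edges, meta = c$meta)
      jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
    })
  invisible(path)
}
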