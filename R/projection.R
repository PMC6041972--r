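# Projection of component maps and their QTL onto a reference map through
# shared-marker piecewise (homothetic) rescaling.

# Maximum-cardinality strictly increasing subsequence of `y` (O(n^2) DP).
# Ties on length prefer the subsequence spanning the larger interval in
# both coordinate systems.
lis_indices <- function(x, y) {
  n <- length(y)
  if (n == 0) return(integer())
  len <- rep(1, n)
  span <- rep(0, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (y[j] < y[i] && x[j] < x[i]) {
        cand_len <- len[j] + 1
        cand_span <- span[j] + (y[i] - y[j]) + (x[i] - x[j])
        if (cand_len > len[i] ||
            (cand_len == len[i] && cand_span > span[i])) {
          len[i] <- cand_len
          span[i] <- cand_span
          prev[i] <- j
        }
      }
    }
  }
  best <- which(len == max(len))
  i <- best[which.max(span[best])]
  out <- integer()
  while (!is.na(i)) {
    out <- c(i, out)
    i <- prev[i]
  }
  out
}

#' Shared-marker anchors between a component map and the reference
#'
#' Finds the markers common to both maps on one chromosome and removes
#' inverted markers: the retained pairs are the maximum-cardinality subset
#' whose reference order matches component order (longest increasing
#' subsequence on reference position, ties broken toward the pairs spanning
#' the larger interval). The global ratio is the reference span over the
#' component span of the retained pairs and drives extrapolation beyond the
#' terminal anchors.
#'
#' @param component,reference [genetic_map()] objects.
#' @param chromosome chromosome label present in both maps.
#' @return an object of class `anchor_set`: list with `chromosome`, `pairs`
#'   (data.frame `marker`, `comp_pos`, `ref_pos`, ordered by component
#'   position, strictly increasing in both coordinates), `global_ratio`, and
#'   `status` (`"ok"` or `"no_anchors"` when fewer than 2 order-consistent
#'   shared markers exist).
#' @export
shared_markers <- function(component, reference, chromosome) {
  stopifnot(inherits(component, "genetic_map"),
            inherits(reference, "genetic_map"))
  chromosome <- as.character(chromosome)
  comp <- component[component$chromosome == chromosome, , drop = FALSE]
  ref <- reference[reference$chromosome == chromosome, , drop = FALSE]
  common <- intersect(comp$marker, ref$marker)
  pairs <- data.frame(
    marker = common,
    comp_pos = comp$position[match(common, comp$marker)],
    ref_pos = ref$position[match(common, ref$marker)],
    stringsAsFactors = FALSE
  )
  pairs <- pairs[order(pairs$comp_pos, pairs$ref_pos), , drop = FALSE]
  keep <- lis_indices(pairs$comp_pos, pairs$ref_pos)
  pairs <- pairs[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  status <- if (nrow(pairs) >= 2) "ok" else "no_anchors"
  gr <- if (status == "ok") {
    (max(pairs$ref_pos) - min(pairs$ref_pos)) /
      (max(pairs$comp_pos) - min(pairs$comp_pos))
  } else NA_real_
  structure(list(chromosome = chromosome, pairs = pairs,
                 global_ratio = gr, status = status),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("Anchor set on chromosome %s: %d shared marker(s), status %s",
              x$chromosome, nrow(x$pairs), x$status))
  if (x$status == "ok")
    cat(sprintf(", global ratio %.4f", x$global_ratio))
  cat("\n")
  invisible(x)
}

#' Project a component-map position onto the reference
#'
#' Inside the anchored region, positions are rescaled linearly within each
#' interval between consecutive shared markers (interval-specific ratio);
#' before the first or after the last anchor they are extrapolated from the
#' nearest terminal anchor with the chromosome-wide global ratio. The map is
#' monotone non-decreasing in the input position.
#'
#' @param pos numeric vector of component-map positions (cM).
#' @param anchors an [shared_markers()] anchor set with status `"ok"`.
#' @return projected reference positions (cM).
#' @export
project_position <- function(pos, anchors) {
  stopifnot(inherits(anchors, "anchor_set"))
  if (anchors$status != "ok")
    stop("cannot project on chromosome ", anchors$chromosome,
         ": fewer than 2 order-consistent shared markers")
  cp <- anchors$pairs$comp_pos
  rp <- anchors$pairs$ref_pos
  out <- stats::approx(cp, rp, xout = pos, rule = 1, ties = "ordered")$y
  g <- anchors$global_ratio
  lo <- !is.na(pos) & pos < cp[1]
  hi <- !is.na(pos) & pos > cp[length(cp)]
  out[lo] <- rp[1] + (pos[lo] - cp[1]) * g
  out[hi] <- rp[length(rp)] + (pos[hi] - cp[length(cp)]) * g
  out
}

#' Project QTL onto the reference map
#'
#' The position and each CI bound are projected independently through
#' [project_position()] (homothetic rescaling per anchor interval). Bounds
#' are re-ordered if a projection reverses them and clamped so the interval
#' brackets the projected position. A QTL any of whose projected coordinates
#' is negative is flagged `discarded_negative` and excluded from analysis;
#' QTL on chromosomes without a usable anchor set are flagged `no_anchors`.
#'
#' @param std data.frame of standardized QTL ([standardize_qtl()] output)
#'   from one study.
#' @param component the study's [genetic_map()].
#' @param reference the reference [genetic_map()].
#' @return the input with columns `ref_position`, `ref_ci_start`,
#'   `ref_ci_end`, `projection_status` (`projected`, `discarded_negative`,
#'   or `no_anchors`) added.
#' @export
project_qtl <- function(std, component, reference) {
  stopifnot(is.data.frame(std))
  out <- std
  out$ref_position <- NA_real_
  out$ref_ci_start <- NA_real_
  out$ref_ci_end <- NA_real_
  out$projection_status <- "no_anchors"
  for (chrom in unique(out$chromosome)) {
    idx <- which(out$chromosome == chrom)
    anchors <- shared_markers(component, reference, chrom)
    if (anchors$status != "ok") next
    p <- project_position(out$position_cM[idx], anchors)
    a <- project_position(out$ci95_start[idx], anchors)
    b <- project_position(out$ci95_end[idx], anchors)
    start <- pmin(a, b, p)
    end <- pmax(a, b, p)
    out$ref_position[idx] <- p
    out$ref_ci_start[idx] <- start
    out$ref_ci_end[idx] <- end
    out$projection_status[idx] <-
      ifelse(start < 0 | end < 0 | p < 0, "discarded_negative", "projected")
  }
  out
}

#' Build a consensus map by iterative projection
#'
#' Component maps are projected one at a time onto the growing consensus,
#' starting from the reference, in descending order of shared-marker count
#' with the reference (a similarity proxy; ties broken by map id). Markers
#' not already on the consensus are inserted at their projected positions;
#' existing marker positions are never moved, so the reference coordinates
#' are preserved. Markers projecting below zero are discarded and logged, as
#' are chromosomes with fewer than two usable anchors.
#'
#' @param reference the reference [genetic_map()].
#' @param components list of component [genetic_map()] objects.
#' @return list with `consensus` (a [genetic_map()]) and `log` (data.frame
#'   `map_id`, `chromosome`, `marker`, `event`).
#' @export
build_consensus <- function(reference, components = list()) {
  stopifnot(inherits(reference, "genetic_map"))
  if (inherits(components, "genetic_map")) components <- list(components)
  log <- data.frame(map_id = character(), chromosome = character(),
                    marker = character(), event = character(),
                    stringsAsFactors = FALSE)
  note <- function(map_id, chromosome, marker, event) {
    log[nrow(log) + 1L, ] <<- list(map_id, chromosome, marker, event)
  }
  n_shared <- vapply(components, function(m)
    length(intersect(m$marker, reference$marker)), integer(1))
  ids <- vapply(components, function(m) attr(m, "map_id"), character(1))
  consensus <- data.frame(marker = reference$marker,
                          chromosome = reference$chromosome,
                          position = reference$position,
                          stringsAsFactors = FALSE)
  for (i in order(-n_shared, ids)) {
    comp <- components[[i]]
    id <- ids[i]
    cons_map <- genetic_map(consensus, map_id = "consensus")
    projected_any <- FALSE
    for (chrom in unique(comp$chromosome)) {
      rows <- comp[comp$chromosome == chrom, , drop = FALSE]
      anchors <- shared_markers(comp, cons_map, chrom)
      if (anchors$status != "ok") {
        note(id, chrom, NA_character_, "no_anchors")
        next
      }
      projected_any <- TRUE
      new <- rows[!(rows$marker %in%
                      consensus$marker[consensus$chromosome == chrom]), ,
                  drop = FALSE]
      if (nrow(new) == 0) next
      pos <- project_position(new$position, anchors)
      neg <- pos < 0
      for (m in new$marker[neg]) note(id, chrom, m, "discarded_negative")
      if (any(!neg))
        consensus <- rbind(consensus,
                           data.frame(marker = new$marker[!neg],
                                      chromosome = chrom,
                                      position = pos[!neg],
                                      stringsAsFactors = FALSE))
    }
    if (!projected_any)
      warning("component map '", id,
              "' shares no chromosome with >= 2 anchors; skipped")
  }
  list(consensus = genetic_map(consensus, map_id = "consensus"),
       log = log)
}

#' Project a multi-study QTL set onto the reference map
#'
#' Convenience wrapper: matches each study's QTL (by `study_id`) to its
#' component map (by map id) and applies [project_qtl()].
#'
#' @param std data.frame of standardized QTL from all studies.
#' @param maps named list (or list with map ids) of component
#'   [genetic_map()] objects.
#' @param reference the reference [genetic_map()].
#' @return row-bound projected QTL (see [project_qtl()]).
#' @export
project_dataset <- function(std, maps, reference) {
  ids <- vapply(maps, function(m) attr(m, "map_id"), character(1))
  missing_maps <- setdiff(unique(std$study_id), ids)
  if (length(missing_maps))
    stop("no component map for study id(s): ",
         paste(missing_maps, collapse = ", "))
  pieces <- lapply(split(std, std$study_id), function(chunk) {
    project_qtl(chunk, maps[[match(chunk$study_id[1], ids)]], reference)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
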