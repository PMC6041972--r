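# Genome-coverage accounting: genetic coverage of QTL (overlap-merged) and
# meta-QTL (raw CI sums), percentages against the reference map length,
# coverage reduction, physical anchoring, and cross-tissue overlap regions.

#' Reference-map genetic length and genome physical length defaults
#'
#' Defaults used by [coverage_percent()] and [physical_coverage()]: the
#' genetic length of the 16,681-marker maize consensus reference map
#' (7980.637 cM) and the physical length of the maize B73 RefGen_v2 assembly
#' (2,066,432,718 bp).
#'
#' @name coverage-defaults
NULL

#' Total length of a set of intervals with overlaps merged
#'
#' Per-chromosome union length, summed over chromosomes. Always less than or
#' equal to the raw sum of widths, with equality iff the intervals are
#' pairwise disjoint within chromosomes.
#'
#' @param start,end interval bounds (cM), vectorized.
#' @param chromosome chromosome label per interval (a single label is
#'   recycled).
#' @return merged length in cM.
#' @export
merged_length <- function(start, end, chromosome = "1") {
  if (length(start) == 0) return(0)
  stopifnot(length(start) == length(end), all(end >= start))
  chromosome <- rep_len(as.character(chromosome), length(start))
  total <- 0
  for (g in split(seq_along(start), chromosome)) {
    o <- g[order(start[g])]
    s <- start[o]
    e <- end[o]
    cur_s <- s[1]
    cur_e <- e[1]
    for (i in seq_along(s)[-1]) {
      if (s[i] <= cur_e) {
        cur_e <- max(cur_e, e[i])
      } else {
        total <- total + (cur_e - cur_s)
        cur_s <- s[i]
        cur_e <- e[i]
      }
    }
    total <- total + (cur_e - cur_s)
  }
  total
}

#' Raw (un-merged) genetic coverage of meta-QTL
#'
#' Sum of the 95% CI widths without overlap correction, matching the
#' convention of published meta-QTL coverage totals. When the table carries
#' a `ci95_width` column (a printed width that may differ from end minus
#' start by source rounding) that column is summed; otherwise widths are
#' computed from the bounds.
#'
#' @param mqtls data.frame of meta-QTL of one tissue class.
#' @return coverage in cM.
#' @export
mqtl_coverage <- function(mqtls) {
  stopifnot(is.data.frame(mqtls))
  if (nrow(mqtls) == 0) return(0)
  if ("ci95_width" %in% names(mqtls)) return(sum(mqtls$ci95_width))
  sum(mqtls$ci95_end - mqtls$ci95_start)
}

#' Genetic coverage as a percentage of the reference map
#'
#' @param length_cM genetic coverage (cM).
#' @param map_length_cM reference map length (cM); see [coverage-defaults].
#' @return percent.
#' @export
coverage_percent <- function(length_cM, map_length_cM = 7980.637) {
  stopifnot(map_length_cM > 0)
  length_cM / map_length_cM * 100
}

#' QTL-to-meta-QTL coverage reduction
#'
#' @param qtl_cov overlap-merged QTL genetic coverage (cM), > 0.
#' @param mqtl_cov meta-QTL genetic coverage (cM).
#' @return percent reduction, `(qtl_cov - mqtl_cov) / qtl_cov * 100`.
#' @export
reduction_percent <- function(qtl_cov, mqtl_cov) {
  if (any(qtl_cov <= 0)) stop("qtl_cov must be > 0")
  (qtl_cov - mqtl_cov) / qtl_cov * 100
}

#' Per-tissue coverage report
#'
#' QTL coverage is overlap-merged per chromosome; meta-QTL coverage is the
#' raw CI sum (see [mqtl_coverage()]); percentages are computed against the
#' reference map length and the reduction via [reduction_percent()].
#'
#' @param projected data.frame of projected QTL (status `"projected"`) with
#'   `ref_ci_start`, `ref_ci_end`, `chromosome`, `tissue_class`.
#' @param mqtls data.frame of meta-QTL with `tissue_class` and CI columns.
#' @param map_length_cM reference map genetic length.
#' @return data.frame, one row per tissue class present in `mqtls`:
#'   `tissue_class`, `qtl_coverage_cM`, `qtl_pct`, `mqtl_coverage_cM`,
#'   `mqtl_pct`, `reduction_pct`.
#' @export
coverage_report <- function(projected, mqtls, map_length_cM = 7980.637) {
  use <- projected[projected$projection_status == "projected", , drop = FALSE]
  tissues <- sort(unique(mqtls$tissue_class))
  rows <- lapply(tissues, function(tt) {
    q <- use[use$tissue_class == tt, , drop = FALSE]
    m <- mqtls[mqtls$tissue_class == tt, , drop = FALSE]
    qcov <- merged_length(q$ref_ci_start, q$ref_ci_end, q$chromosome)
    mcov <- mqtl_coverage(m)
    data.frame(tissue_class = tt,
               qtl_coverage_cM = qcov,
               qtl_pct = coverage_percent(qcov, map_length_cM),
               mqtl_coverage_cM = mcov,
               mqtl_pct = coverage_percent(mcov, map_length_cM),
               reduction_pct = if (qcov > 0)
                 reduction_percent(qcov, mcov) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Physical interval of a meta-QTL from its flanking markers
#'
#' Looks up the base-pair positions of the CI flanking markers on the
#' reference map. When a flanking marker has no physical anchor, the search
#' walks outward along the reference marker order to the next anchored
#' marker. A side that exhausts the chromosome without finding an anchored
#' marker is returned as `NA` and flagged open.
#'
#' @param mqtl single-row data.frame (or list) with `chromosome`,
#'   `ci95_start`, `ci95_end`.
#' @param reference reference [genetic_map()].
#' @param anchors data.frame of physical anchors
#'   ([read_physical_anchors()] columns).
#' @return list with `start_bp`, `end_bp` (start <= end where both closed),
#'   `open_start`, `open_end`.
#' @export
anchor_physical <- function(mqtl, reference, anchors) {
  chrom <- as.character(mqtl$chromosome)
  ref <- reference[reference$chromosome == chrom, , drop = FALSE]
  anch <- anchors[anchors$chromosome == chrom, , drop = FALSE]
  bp_of <- function(marker) {
    hit <- match(marker, anch$marker)
    if (is.na(hit)) NA_real_ else anch$position_bp[hit]
  }
  # indices of reference markers at/outside each bound
  left_idx <- which(ref$position <= mqtl$ci95_start)
  right_idx <- which(ref$position >= mqtl$ci95_end)
  walk <- function(idx) {
    for (i in idx) {
      bp <- bp_of(ref$marker[i])
      if (!is.na(bp)) return(bp)
    }
    NA_real_
  }
  start_bp <- walk(rev(left_idx))   # nearest first, then outward toward 0
  end_bp <- walk(right_idx)         # nearest first, then outward to the end
  open_start <- is.na(start_bp)
  open_end <- is.na(end_bp)
  if (!open_start && !open_end && start_bp > end_bp) {
    tmp <- start_bp
    start_bp <- end_bp
    end_bp <- tmp
  }
  list(start_bp = start_bp, end_bp = end_bp,
       open_start = open_start, open_end = open_end)
}

#' Physical genome coverage of meta-QTL
#'
#' Sum of (end - start) over the physical intervals, as a percentage of the
#' genome length; no overlap merging (matching the published convention).
#' Open-ended intervals must be closed first with a chromosome-length table;
#' an `NA` bound raises an error naming the locus.
#'
#' @param start_bp,end_bp physical interval bounds in bp.
#' @param genome_bp genome physical length in bp; see [coverage-defaults].
#' @param ids optional locus ids used in error messages.
#' @return percent of the genome covered.
#' @export
physical_coverage <- function(start_bp, end_bp,
                              genome_bp = 2066432718, ids = NULL) {
  stopifnot(length(start_bp) == length(end_bp), genome_bp > 0)
  bad <- which(is.na(start_bp) | is.na(end_bp))
  if (length(bad)) {
    who <- if (!is.null(ids)) paste(ids[bad], collapse = ", ")
           else paste("row", paste(bad, collapse = ", "))
    stop("open-ended physical interval(s) for: ", who,
         "; supply chromosome lengths to close them")
  }
  sum(end_bp - start_bp) / genome_bp * 100
}

#' Cross-tissue meta-QTL overlap regions
#'
#' Per chromosome, connected components of the CI-overlap graph (closed
#' intervals) restricted to components whose members span at least two
#' distinct tissue classes. Input order and tissue labels do not affect the
#' result beyond region ordering.
#'
#' @param mqtls data.frame of meta-QTL across tissue classes sharing one
#'   coordinate system, with `mqtl_id`, `tissue_class`, `chromosome` and
#'   either genetic CI columns (`ci95_start`, `ci95_end`) or physical ones
#'   (`phys_start`, `phys_end`) according to `mode`.
#' @param mode `"genetic"` (default) or `"physical"`.
#' @return data.frame, one row per region: `chromosome`, `span_start`,
#'   `span_end`, `n_mqtl`, `members` (comma-separated ids), `tissue_classes`
#'   (comma-separated, sorted), `all_tissues` (flag: all three classes
#'   present).
#' @export
cross_tissue_overlaps <- function(mqtls, mode = c("genetic", "physical")) {
  mode <- match.arg(mode)
  if (mode == "genetic") {
    start <- mqtls$ci95_start
    end <- mqtls$ci95_end
  } else {
    start <- mqtls$phys_start
    end <- mqtls$phys_end
  }
  regions <- NULL
  for (chrom in unique(mqtls$chromosome)) {
    idx <- which(mqtls$chromosome == chrom)
    comp <- overlap_components(start[idx], end[idx])
    for (cc in split(idx, comp)) {
      classes <- sort(unique(mqtls$tissue_class[cc]))
      if (length(cc) < 2 || length(classes) < 2) next
      ord <- cc[order(start[cc])]
      regions <- rbind(regions, data.frame(
        chromosome = as.character(chrom),
        span_start = min(start[cc]),
        span_end = max(end[cc]),
        n_mqtl = length(cc),
        members = paste(mqtls$mqtl_id[ord], collapse = ","),
        tissue_classes = paste(classes, collapse = ","),
        all_tissues = length(classes) >= 3,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(regions))
    regions <- data.frame(chromosome = character(), span_start = numeric(),
                          span_end = numeric(), n_mqtl = integer(),
                          members = character(), tissue_classes = character(),
                          all_tissues = logical())
  ord <- order(suppressWarnings(as.numeric(regions$chromosome)),
               regions$chromosome, regions$span_start)
  regions <- regions[ord, , drop = FALSE]
  rownames(regions) <- NULL
  regions
}
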