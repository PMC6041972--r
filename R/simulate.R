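# Synthetic multi-study QTL datasets with known ground truth: a reference
# map, locally distorted component maps sharing a subset of its markers,
# planted true loci, and per-study QTL scattered around them with the
# dispersion implied by the k/(N*R2) confidence-interval formula.

#' Simulation configuration
#'
#' Bundles and validates everything the generator needs. All randomness in
#' the generator flows from `seed`; two runs with equal configs are
#' identical. Defaults emulate a literature meta-analysis: around ten
#' bi-parental studies of mixed population type (F2/F3/RIL/IRIL) and size
#' (100-472), component maps sharing most reference markers with mildly
#' distorted local distances, and per-QTL R-squared values spanning roughly
#' 0.5-47% (truncated Beta(1.2, 8)).
#'
#' @param seed integer master seed.
#' @param n_chromosomes,markers_per_chromosome,chromosome_length_cM reference
#'   map dimensions.
#' @param n_studies number of component studies.
#' @param population_types,population_sizes recycled across studies.
#' @param shared_marker_fraction probability a reference marker appears on a
#'   component map, in (0, 1].
#' @param distortion_sd standard deviation of the per-interval log scale
#'   factor (0 = undistorted).
#' @param planted_mqtl data.frame `chromosome`, `position`, `tissue_class`
#'   of the latent true loci; the default plants two per chromosome (at 30%
#'   and 70% of its length) cycling through the tissue classes.
#' @param qtl_per_mqtl_range integer range: how many studies re-detect each
#'   planted locus.
#' @param r2_shape,r2_bounds Beta shape parameters and truncation bounds of
#'   the per-QTL R-squared distribution.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 3,
                       markers_per_chromosome = 40,
                       chromosome_length_cM = 150,
                       n_studies = 10,
                       population_types = c("F2", "F3", "RIL", "IRIL"),
                       population_sizes = c(100, 150, 200, 250, 300, 472),
                       shared_marker_fraction = 0.7,
                       distortion_sd = 0.1,
                       planted_mqtl = NULL,
                       qtl_per_mqtl_range = c(4, 8),
                       r2_shape = c(1.2, 8),
                       r2_bounds = c(0.005, 0.47)) {
  stopifnot(n_chromosomes >= 1, markers_per_chromosome >= 1,
            chromosome_length_cM > 0, n_studies >= 1,
            shared_marker_fraction > 0, shared_marker_fraction <= 1,
            distortion_sd >= 0, length(qtl_per_mqtl_range) == 2,
            qtl_per_mqtl_range[1] >= 1,
            qtl_per_mqtl_range[2] >= qtl_per_mqtl_range[1],
            r2_bounds[1] > 0, r2_bounds[2] <= 1,
            r2_bounds[2] > r2_bounds[1])
  if (is.null(planted_mqtl)) {
    chroms <- as.character(seq_len(n_chromosomes))
    planted_mqtl <- data.frame(
      chromosome = rep(chroms, each = 2),
      position = rep(chromosome_length_cM * c(0.3, 0.7), n_chromosomes),
      tissue_class = rep_len(tissue_classes, 2 * n_chromosomes),
      stringsAsFactors = FALSE)
  }
  if (nrow(planted_mqtl)) {
    stopifnot(all(c("chromosome", "position", "tissue_class") %in%
                    names(planted_mqtl)),
              all(planted_mqtl$position >= 0),
              all(planted_mqtl$position <= chromosome_length_cM),
              all(planted_mqtl$tissue_class %in% tissue_classes))
    planted_mqtl$chromosome <- as.character(planted_mqtl$chromosome)
  }
  structure(list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    markers_per_chromosome = as.integer(markers_per_chromosome),
    chromosome_length_cM = chromosome_length_cM,
    n_studies = as.integer(n_studies),
    population_types = rep_len(population_types, n_studies),
    population_sizes = rep_len(population_sizes, n_studies),
    shared_marker_fraction = shared_marker_fraction,
    distortion_sd = distortion_sd,
    planted_mqtl = planted_mqtl,
    qtl_per_mqtl_range = as.integer(qtl_per_mqtl_range),
    r2_shape = r2_shape,
    r2_bounds = r2_bounds), class = "sim_config")
}

#' Simulate a reference genetic map
#'
#' Markers at sorted uniform positions on each chromosome (the first marker
#' is pinned to 0 so each chromosome has a zero origin). Deterministic under
#' the config seed.
#'
#' @param config a [sim_config()].
#' @return a [genetic_map()] with map id `"reference"`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rows <- lapply(seq_len(config$n_chromosomes), function(ci) {
    m <- config$markers_per_chromosome
    pos <- sort(stats::runif(m, 0, config$chromosome_length_cM))
    pos[1] <- 0
    data.frame(marker = sprintf("c%d_m%03d", ci, seq_len(m)),
               chromosome = as.character(ci),
               position = pos, stringsAsFactors = FALSE)
  })
  genetic_map(do.call(rbind, rows), map_id = "reference")
}

# draw one truncated-Beta r2
draw_r2 <- function(shape, bounds) {
  repeat {
    r2 <- stats::rbeta(1, shape[1], shape[2])
    if (r2 >= bounds[1] && r2 <= bounds[2]) return(r2)
  }
}

#' Simulate one component study
#'
#' The component map retains each reference marker with probability
#' `shared_marker_fraction` (a chromosome left with fewer than two markers
#' is resampled once, then an error is raised) and rescales each retained
#' inter-marker interval by exp(Normal(0, distortion_sd)); the first
#' retained marker keeps its reference position, so an undistorted fully
#' shared component reproduces the reference exactly. For each planted locus
#' assigned to the study, an R-squared is drawn from the truncated Beta, the
#' 95% CI width follows the k/(N*R2) formula for the study's population, the
#' per-QTL dispersion is width/3.92, and the reported position is drawn
#' normally around the true location expressed on the component scale.
#'
#' @param reference the reference [genetic_map()] (from
#'   [simulate_reference()]).
#' @param config a [sim_config()].
#' @param study_index integer in `1..n_studies`; determines the study's
#'   seed stream, population, and map id.
#' @param planted rows of `config$planted_mqtl` this study detects (default:
#'   all of them; duplicated rows yield independent QTL).
#' @return list with `map` (a [genetic_map()]), `qtl` (data.frame of
#'   QTL records in [read_qtl_table()] layout), and `truth` (data.frame
#'   `qtl_id`, `mqtl_index`, `true_position`, `r2`, `sd`).
#' @export
simulate_study <- function(reference, config, study_index,
                           planted = config$planted_mqtl) {
  stopifnot(inherits(config, "sim_config"),
            study_index >= 1, study_index <= config$n_studies)
  set.seed(config$seed + 7919L * as.integer(study_index))
  ptype <- config$population_types[study_index]
  psize <- config$population_sizes[study_index]
  map_id <- sprintf("study%02d", as.integer(study_index))

  comp_rows <- NULL
  ref_to_comp <- list()   # per-chromosome anchor pairs for truth mapping
  for (chrom in unique(reference$chromosome)) {
    ref <- reference[reference$chromosome == chrom, , drop = FALSE]
    keep <- stats::runif(nrow(ref)) <= config$shared_marker_fraction
    if (sum(keep) < 2)
      keep <- stats::runif(nrow(ref)) <= config$shared_marker_fraction
    if (sum(keep) < 2)
      stop("chromosome ", chrom, " of study ", study_index,
           " retained fewer than 2 markers after resampling; raise ",
           "shared_marker_fraction or markers_per_chromosome")
    kept <- ref[keep, , drop = FALSE]
    scale <- exp(stats::rnorm(nrow(kept) - 1, 0, config$distortion_sd))
    comp_pos <- kept$position[1] + c(0, cumsum(diff(kept$position) * scale))
    comp_rows <- rbind(comp_rows,
                       data.frame(marker = kept$marker, chromosome = chrom,
                                  position = comp_pos,
                                  stringsAsFactors = FALSE))
    ref_to_comp[[chrom]] <- structure(
      list(chromosome = chrom,
           pairs = data.frame(marker = kept$marker,
                              comp_pos = kept$position,  # source: reference
                              ref_pos = comp_pos,        # target: component
                              stringsAsFactors = FALSE),
           global_ratio = (max(comp_pos) - min(comp_pos)) /
             max(max(kept$position) - min(kept$position), .Machine$double.eps),
           status = "ok"),
      class = "anchor_set")
  }
  map <- genetic_map(comp_rows, map_id = map_id,
                     population_size = psize, population_type = ptype)

  empty_qtl <- data.frame(
    qtl_id = character(), study_id = character(), trait = character(),
    tissue_class = character(), trait_category = character(),
    chromosome = character(), position_cM = numeric(),
    ci_start_cM = numeric(), ci_end_cM = numeric(), lod = numeric(),
    lrs = numeric(), r2 = numeric(), population_size = numeric(),
    population_type = character(), stringsAsFactors = FALSE)
  truth <- data.frame(qtl_id = character(), mqtl_index = integer(),
                      true_position = numeric(), r2 = numeric(),
                      sd = numeric(), stringsAsFactors = FALSE)
  if (is.null(planted) || nrow(planted) == 0)
    return(list(map = map, qtl = empty_qtl, truth = truth))

  k <- unname(ci_k_constants[ptype])
  qtl <- empty_qtl
  for (j in seq_len(nrow(planted))) {
    chrom <- planted$chromosome[j]
    r2 <- draw_r2(config$r2_shape, config$r2_bounds)
    width <- k / (psize * r2)
    sd <- width / 3.92
    true_c <- project_position(planted$position[j], ref_to_comp[[chrom]])
    pos <- stats::rnorm(1, true_c, sd)
    qtl[nrow(qtl) + 1L, ] <- list(
      qtl_id = sprintf("%s_q%02d", map_id, j),
      study_id = map_id,
      trait = sprintf("SYN-%s", toupper(substr(planted$tissue_class[j], 1, 1))),
      tissue_class = planted$tissue_class[j],
      trait_category = "insect_resistance",
      chromosome = chrom,
      position_cM = pos,
      ci_start_cM = pos - width / 2,
      ci_end_cM = pos + width / 2,
      lod = -(psize / 2) * log10(1 - r2),
      lrs = NA_real_,
      r2 = r2,
      population_size = psize,
      population_type = ptype)
    truth[nrow(truth) + 1L, ] <- list(
      qtl_id = sprintf("%s_q%02d", map_id, j),
      mqtl_index = if (!is.null(planted$mqtl_index))
        planted$mqtl_index[j] else j,
      true_position = planted$position[j],
      r2 = r2, sd = sd)
  }
  list(map = map, qtl = qtl, truth = truth)
}

#' Simulate a full multi-study dataset
#'
#' Draws how many (and which) studies re-detect each planted locus from
#' `qtl_per_mqtl_range`, then simulates every study. The bundle is ready for
#' the full pipeline: [standardize_qtl()], [project_dataset()],
#' [meta_qtl()].
#'
#' @param config a [sim_config()].
#' @return list with `reference` ([genetic_map()]), `maps` (list of
#'   component maps), `qtl` (row-bound QTL records), `truth` (per-QTL
#'   generative parameters: planted locus index, true position, r2, sd),
#'   and `config`.
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 42))
#' nrow(sim$qtl)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  reference <- simulate_reference(config)
  planted <- config$planted_mqtl
  set.seed(config$seed + 1L)
  per_study <- rep(list(NULL), config$n_studies)
  if (!is.null(planted) && nrow(planted)) {
    planted$mqtl_index <- seq_len(nrow(planted))
    for (i in seq_len(nrow(planted))) {
      lo <- config$qtl_per_mqtl_range[1]
      hi <- config$qtl_per_mqtl_range[2]
      n_i <- if (hi > lo) sample(lo:hi, 1) else lo
      studies <- sample(config$n_studies, n_i,
                        replace = n_i > config$n_studies)
      for (s in studies)
        per_study[[s]] <- rbind(per_study[[s]], planted[i, , drop = FALSE])
    }
  }
  maps <- list()
  qtl <- NULL
  truth <- NULL
  for (s in seq_len(config$n_studies)) {
    res <- simulate_study(reference, config, s, planted = per_study[[s]])
    maps[[attr(res$map, "map_id")]] <- res$map
    qtl <- rbind(qtl, res$qtl)
    truth <- rbind(truth, res$truth)
  }
  rownames(qtl) <- NULL
  if (!is.null(truth)) rownames(truth) <- NULL
  list(reference = reference, maps = maps, qtl = qtl, truth = truth,
       config = config)
}

#' Write a simulated dataset as the package's TSV formats
#'
#' @param dataset a [simulate_dataset()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genetic_map(dataset$reference, file.path(dir, "reference_map.tsv"))
  for (m in dataset$maps)
    write_genetic_map(m, file.path(dir, paste0(attr(m, "map_id"),
                                               "_map.tsv")))
  write_qtl_table(dataset$qtl, file.path(dir, "qtl.tsv"))
  utils::write.table(dataset$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
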