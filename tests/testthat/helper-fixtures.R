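# Shared fixtures and independent oracles, built in code.

toy_map <- function(markers, positions, chromosome = "1", map_id = "toy",
                    ...) {
  genetic_map(data.frame(marker = markers, chromosome = chromosome,
                         position = positions, stringsAsFactors = FALSE),
              map_id = map_id, ...)
}

# A complete, valid QTL record; override fields as needed.
toy_qtl <- function(qtl_id = "q1", study_id = "s1", trait = "ECB-TL",
                    tissue_class = "stem",
                    trait_category = "insect_resistance",
                    chromosome = "1", position_cM = 50,
                    ci_start_cM = 40, ci_end_cM = 60, lod = NA_real_,
                    lrs = NA_real_, r2 = 0.1, population_size = 200,
                    population_type = "RIL") {
  data.frame(qtl_id = qtl_id, study_id = study_id, trait = trait,
             tissue_class = tissue_class, trait_category = trait_category,
             chromosome = chromosome, position_cM = position_cM,
             ci_start_cM = ci_start_cM, ci_end_cM = ci_end_cM, lod = lod,
             lrs = lrs, r2 = r2, population_size = population_size,
             population_type = population_type, stringsAsFactors = FALSE)
}

manual_anchor_set <- function(comp_pos, ref_pos, chromosome = "1") {
  structure(list(
    chromosome = chromosome,
    pairs = data.frame(marker = paste0("m", seq_along(comp_pos)),
                       comp_pos = comp_pos, ref_pos = ref_pos,
                       stringsAsFactors = FALSE),
    global_ratio = (max(ref_pos) - min(ref_pos)) /
      (max(comp_pos) - min(comp_pos)),
    status = "ok"), class = "anchor_set")
}

# Brute-force oracle for merged interval length: 0.01-cM grid rasterization.
grid_merged_length <- function(start, end, step = 0.01) {
  lo <- floor(min(start) / step)
  hi <- ceiling(max(end) / step)
  cells <- logical(hi - lo)
  for (i in seq_along(start)) {
    a <- floor(start[i] / step) - lo + 1L
    b <- ceiling(end[i] / step) - lo
    if (b >= a) cells[a:b] <- TRUE
  }
  sum(cells) * step
}

# Exhaustive-assignment oracle for the classification log-likelihood of a
# fixed-variance mixture: every labeling of n points into at most K groups,
# each group's mean set to its inverse-variance weighted mean and its weight
# to its proportion.
enum_best_classification_loglik <- function(x, s, K) {
  n <- length(x)
  w <- 1 / s^2
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    z <- grid[r, ]
    ll <- 0
    for (k in unique(z)) {
      idx <- z == k
      mu <- sum(w[idx] * x[idx]) / sum(w[idx])
      ll <- ll + sum(log(mean(idx)) + dnorm(x[idx], mu, s[idx], log = TRUE))
    }
    if (ll > best) best <- ll
  }
  best
}

# Classification log-likelihood of a fit's hardened partition under the same
# rule the enumeration oracle uses.
hardened_classification_loglik <- function(fit) {
  z <- max.col(fit$responsibilities, ties.method = "first")
  x <- fit$positions
  s <- fit$sds
  w <- 1 / s^2
  ll <- 0
  for (k in unique(z)) {
    idx <- z == k
    mu <- sum(w[idx] * x[idx]) / sum(w[idx])
    ll <- ll + sum(log(mean(idx)) + dnorm(x[idx], mu, s[idx], log = TRUE))
  }
  ll
}

# Configuration used for mixture parameter-recovery experiments: three loci
# planted on one chromosome with separation far exceeding five times the
# largest per-QTL dispersion the R2 bounds allow.
recovery_config <- function(seed) {
  sim_config(seed = seed,
             n_chromosomes = 1, markers_per_chromosome = 30,
             chromosome_length_cM = 200, n_studies = 10,
             population_types = c("RIL", "IRIL"),
             population_sizes = c(150, 200, 250, 300),
             shared_marker_fraction = 0.8, distortion_sd = 0.05,
             planted_mqtl = data.frame(chromosome = "1",
                                       position = c(40, 100, 160),
                                       tissue_class = "leaf"),
             qtl_per_mqtl_range = c(4, 8),
             r2_bounds = c(0.08, 0.4))
}

run_recovery <- function(seed, Kmax = 6) {
  sim <- simulate_dataset(recovery_config(seed))
  std <- standardize_qtl(sim$qtl)
  prj <- project_dataset(std, sim$maps, sim$reference)
  fit <- meta_qtl(prj, "leaf", reference = sim$reference, Kmax = Kmax,
                  seed = seed)
  list(sim = sim, projected = prj, fit = fit,
       chosen_K = nrow(fit$mqtl),
       means = sort(fit$mqtl$position))
}
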