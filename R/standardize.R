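# Standardization of heterogeneous reported QTL statistics to the uniform
# (LOD, R2, 95% CI) set the meta-analysis consumes.

#' Default population-type constants for the 95% CI approximation
#'
#' The empirical 95% confidence-interval width of a QTL is approximated as
#' k / (N * R2), with k = 530 for F2 and F3 populations and k = 163 for
#' recombinant (RIL) and intermated recombinant (IRIL) inbred lines.
#'
#' @export
ci_k_constants <- c(F2 = 530, F3 = 530, RIL = 163, IRIL = 163)

#' LOD score from a likelihood-ratio statistic
#'
#' LOD = LRS / 4.6 (4.6 = 2 * log(10)).
#'
#' @param lrs likelihood-ratio statistic, finite and >= 0. Vectorized.
#' @return LOD score(s).
#' @export
lod_from_lrs <- function(lrs) {
  lrs <- as.numeric(lrs)
  if (any(!is.na(lrs) & (!is.finite(lrs) | lrs < 0)))
    stop("lrs must be finite and >= 0")
  lrs / 4.6
}

#' Phenotypic variance explained from a LOD score
#'
#' R2 = 1 - 10^(-2 * LOD / N) for a population of size N.
#'
#' @param lod LOD score(s), >= 0.
#' @param n population size(s), >= 2.
#' @return fraction(s) of phenotypic variance explained, in `[0, 1)`.
#' @export
r2_from_lod <- function(lod, n) {
  lod <- as.numeric(lod)
  n <- as.numeric(n)
  if (any(!is.na(lod) & lod < 0)) stop("lod must be >= 0")
  if (any(!is.na(n) & n < 2)) stop("population size must be >= 2")
  1 - 10^(-2 * lod / n)
}

#' 95% confidence-interval width of a QTL
#'
#' Width (cM) = k / (N * R2), with k chosen by population type (see
#' [ci_k_constants]).
#'
#' @param n population size(s), > 0.
#' @param r2 fraction(s) of phenotypic variance explained, in (0, 1].
#' @param population_type character vector of population types; each must
#'   have an entry in `k`.
#' @param k named vector mapping population types to k constants.
#' @return CI width(s) in cM.
#' @export
ci95_width <- function(n, r2, population_type, k = ci_k_constants) {
  n <- as.numeric(n)
  r2 <- as.numeric(r2)
  if (any(!is.na(n) & n <= 0)) stop("population size must be > 0")
  if (any(!is.na(r2) & (r2 <= 0 | r2 > 1)))
    stop("r2 must lie in (0, 1]; a zero r2 gives an infinite interval")
  unknown <- setdiff(unique(population_type[!is.na(population_type)]),
                     names(k))
  if (length(unknown))
    stop("no k constant configured for population type(s): ",
         paste(unknown, collapse = ", "))
  unname(k[population_type]) / (n * r2)
}

#' Standardize QTL records
#'
#' Fills missing statistics in reporting-precedence order: a reported
#' R-squared is never touched; a missing LOD is derived from LRS via
#' [lod_from_lrs()]; a missing R-squared is then derived from LOD via
#' [r2_from_lod()]. The 95% CI width follows from [ci95_width()] and is
#' centered on the reported position, replacing the reported interval for
#' analysis (the reported bounds stay in `ci_start_cM`/`ci_end_cM` as
#' provenance).
#'
#' @param qtl data.frame of validated QTL records ([read_qtl_table()]
#'   columns).
#' @param k named vector of population-type CI constants.
#' @return the input with columns `lod` and `r2` filled, plus `ci95_width`,
#'   `ci95_start`, `ci95_end`, `k_constant`, `lod_source`
#'   (`reported`/`from_lrs`/`absent`) and `r2_source` (`reported`/`from_lod`).
#' @examples
#' q <- data.frame(qtl_id = "q1", study_id = "s", trait = "ECB-TL",
#'                 tissue_class = "stem", trait_category = "insect_resistance",
#'                 chromosome = "1", position_cM = 50, ci_start_cM = 40,
#'                 ci_end_cM = 60, lod = NA, lrs = 23, r2 = NA,
#'                 population_size = 171, population_type = "F3")
#' standardize_qtl(q)[, c("lod", "r2", "ci95_width")]
#' @export
standardize_qtl <- function(qtl, k = ci_k_constants) {
  stopifnot(is.data.frame(qtl))
  out <- qtl
  out$lod_source <- ifelse(!is.na(out$lod), "reported",
                           ifelse(!is.na(out$lrs), "from_lrs", "absent"))
  fill <- is.na(out$lod) & !is.na(out$lrs)
  out$lod[fill] <- lod_from_lrs(out$lrs[fill])
  out$r2_source <- ifelse(!is.na(out$r2), "reported", "from_lod")
  need_r2 <- is.na(out$r2)
  if (any(need_r2 & is.na(out$lod)))
    stop("cannot standardize record(s) ",
         paste(out$qtl_id[need_r2 & is.na(out$lod)], collapse = ", "),
         ": no r2 and no lod/lrs to derive it from")
  out$r2[need_r2] <- r2_from_lod(out$lod[need_r2],
                                 out$population_size[need_r2])
  if (any(out$r2 <= 0))
    stop("standardization produced a non-positive r2 for record(s) ",
         paste(out$qtl_id[out$r2 <= 0], collapse = ", "))
  out$k_constant <- unname(k[out$population_type])
  out$ci95_width <- ci95_width(out$population_size, out$r2,
                               out$population_type, k = k)
  out$ci95_start <- out$position_cM - out$ci95_width / 2
  out$ci95_end <- out$position_cM + out$ci95_width / 2
  out
}

# Connected components of the interval-overlap graph (closed intervals),
# returned as a component index per row.
overlap_components <- function(start, end) {
  n <- length(start)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      hit <- which(comp == 0L & start <= end[j] & end >= start[j])
      comp[hit] <- cur
      queue <- c(queue, hit)
    }
  }
  comp
}

#' De-duplicate overlapping QTL within a study
#'
#' Within each (study, trait, chromosome) group, QTL whose 95% CIs overlap
#' (closed intervals, connected components of the overlap graph) are reduced
#' to the single record with the highest R-squared, so the same underlying
#' locus is not over-represented in the meta-analysis. Ties on R-squared keep
#' the record with the narrower reported CI, then the lexicographically
#' smallest `qtl_id`, so output is deterministic. Idempotent.
#'
#' @param std data.frame of standardized QTL ([standardize_qtl()] output).
#' @param use_reported_ci test overlap on the reported CI instead of the
#'   standardized 95% CI.
#' @return the surviving records, unchanged.
#' @export
dedupe_overlapping <- function(std, use_reported_ci = FALSE) {
  stopifnot(is.data.frame(std))
  if (nrow(std) == 0) return(std)
  if (use_reported_ci) {
    start <- std$ci_start_cM
    end <- std$ci_end_cM
  } else {
    start <- std$ci95_start
    end <- std$ci95_end
  }
  key <- interaction(std$study_id, std$trait, std$chromosome, drop = TRUE)
  keep <- logical(nrow(std))
  for (g in split(seq_len(nrow(std)), key)) {
    comp <- overlap_components(start[g], end[g])
    for (cc in split(g, comp)) {
      reported_w <- std$ci_end_cM[cc] - std$ci_start_cM[cc]
      reported_w[is.na(reported_w)] <- Inf
      ord <- order(-std$r2[cc], reported_w, std$qtl_id[cc])
      keep[cc[ord[1]]] <- TRUE
    }
  }
  out <- std[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
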