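# Readers/writers for the native UTF-8 TSV formats and the genetic-map
# container shared by all pipeline stages.

#' Construct a genetic map
#'
#' A genetic map is an ordered set of marker loci with centiMorgan positions
#' on one or more chromosomes, plus the mapping-population metadata the
#' interval standardization needs (population size and type).
#'
#' @param markers data.frame with columns `marker`, `chromosome`, `position`
#'   (cM, finite, >= 0). Chromosome labels are kept as character strings.
#' @param map_id single string identifying the map (study or reference).
#' @param population_size integer population size N, or `NA` for a reference
#'   map assembled from many sources.
#' @param population_type one of `"F2"`, `"F3"`, `"RIL"`, `"IRIL"`,
#'   `"reference"`.
#' @param mapping_function free-text metadata (e.g. `"Haldane"`), not used in
#'   computation.
#'
#' @return An object of class `genetic_map`: the marker data.frame sorted by
#'   chromosome then position, with the metadata stored as attributes.
#' @examples
#' gm <- genetic_map(
#'   data.frame(marker = c("a", "b", "c"), chromosome = "1",
#'              position = c(0, 10, 20)),
#'   map_id = "toy")
#' map_length(gm)
#' @export
genetic_map <- function(markers, map_id,
                        population_size = NA_integer_,
                        population_type = "reference",
                        mapping_function = NA_character_) {
  stopifnot(is.data.frame(markers))
  need <- c("marker", "chromosome", "position")
  miss <- setdiff(need, names(markers))
  if (length(miss))
    stop("markers is missing column(s): ", paste(miss, collapse = ", "))
  markers <- data.frame(
    marker = as.character(markers$marker),
    chromosome = as.character(markers$chromosome),
    position = as.numeric(markers$position),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(markers$marker)))
    stop("marker names must be non-empty")
  if (any(!is.finite(markers$position)) || any(markers$position < 0))
    stop("marker positions must be finite and >= 0")
  dup <- duplicated(markers[c("chromosome", "marker")])
  if (any(dup))
    stop("duplicated marker name(s) within a chromosome: ",
         paste(unique(markers$marker[dup]), collapse = ", "))
  ord <- order(markers$chromosome, markers$position, markers$marker)
  markers <- markers[ord, , drop = FALSE]
  rownames(markers) <- NULL
  population_type <- match.arg(population_type,
                               c("reference", "F2", "F3", "RIL", "IRIL"))
  structure(markers,
            map_id = as.character(map_id)[1],
            population_size = as.integer(population_size)[1],
            population_type = population_type,
            mapping_function = mapping_function,
            class = c("genetic_map", "data.frame"))
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("Genetic map '%s': %d markers on %d chromosome(s), %.2f cM\n",
              attr(x, "map_id"), nrow(x),
              length(unique(x$chromosome)), map_length(x)))
  if (!is.na(attr(x, "population_size")))
    cat(sprintf("  population: %s, N = %d\n",
                attr(x, "population_type"), attr(x, "population_size")))
  invisible(x)
}

#' Total genetic length of a map
#'
#' Sum over chromosomes of the maximum marker position (0-based cM origin).
#'
#' @param map a [genetic_map()].
#' @return length in cM.
#' @export
map_length <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  sum(tapply(map$position, map$chromosome, max))
}

#' Read a genetic map from TSV
#'
#' Native format: UTF-8 tab-separated with a one-line header and columns
#' `map_id`, `chromosome`, `marker`, `position_cM` (a `position` column is
#' also accepted). Markers are sorted per chromosome, so row order in the
#' file is immaterial.
#'
#' @param path file path.
#' @param population_size,population_type,mapping_function metadata not
#'   carried by the map file itself; see [genetic_map()].
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path, population_size = NA_integer_,
                             population_type = "reference",
                             mapping_function = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  if (!"position_cM" %in% names(raw) && "position" %in% names(raw))
    names(raw)[names(raw) == "position"] <- "position_cM"
  need <- c("map_id", "chromosome", "marker", "position_cM")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("map file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  pos <- suppressWarnings(as.numeric(raw$position_cM))
  bad <- which(is.na(pos) | !nzchar(raw$marker))
  if (length(bad))
    stop("malformed map row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), " in ", path)
  ids <- unique(raw$map_id)
  if (length(ids) != 1)
    stop("map file must contain a single map_id, found: ",
         paste(ids, collapse = ", "))
  genetic_map(data.frame(marker = raw$marker, chromosome = raw$chromosome,
                         position = pos, stringsAsFactors = FALSE),
              map_id = ids,
              population_size = population_size,
              population_type = population_type,
              mapping_function = mapping_function)
}

#' Write a genetic map to TSV
#'
#' @param map a [genetic_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  out <- data.frame(map_id = attr(map, "map_id"),
                    chromosome = map$chromosome,
                    marker = map$marker,
                    position_cM = map$position)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

qtl_columns <- c("qtl_id", "study_id", "trait", "tissue_class",
                 "trait_category", "chromosome", "position_cM",
                 "ci_start_cM", "ci_end_cM", "lod", "lrs", "r2",
                 "population_size", "population_type")

tissue_classes <- c("leaf", "stem", "kernel")

#' Validate QTL records
#'
#' Validation is total: each row is either accepted or attached to a
#' diagnostic, and the two counts always sum to the rows examined. A row is
#' rejected when its confidence interval does not bracket the position, when
#' none of LOD/LRS/R-squared is present, when R-squared falls outside (0, 1],
#' or when the tissue class is unknown.
#'
#' @param qtl data.frame of QTL records (see [read_qtl_table()] for columns).
#' @param strict abort with an error on the first invalid row instead of
#'   excluding it.
#' @return the accepted rows, with a `rejected` attribute: a data.frame of
#'   row numbers and reasons (zero rows when everything passed).
#' @export
validate_qtl <- function(qtl, strict = FALSE) {
  stopifnot(is.data.frame(qtl))
  n <- nrow(qtl)
  reason <- character(n)
  has <- function(v) !is.na(v)
  pos <- qtl$position_cM
  cs <- qtl$ci_start_cM
  ce <- qtl$ci_end_cM
  bad_ci <- has(cs) & has(ce) & has(pos) & (cs > pos | pos > ce)
  reason[bad_ci] <- "ci_start <= position <= ci_end violated"
  no_stat <- !(has(qtl$lod) | has(qtl$lrs) | has(qtl$r2))
  reason[no_stat & reason == ""] <- "none of lod/lrs/r2 present"
  bad_r2 <- has(qtl$r2) & (qtl$r2 <= 0 | qtl$r2 > 1)
  reason[bad_r2 & reason == ""] <- "r2 outside (0, 1]"
  bad_tissue <- !(qtl$tissue_class %in% tissue_classes)
  reason[bad_tissue & reason == ""] <- "unknown tissue_class"
  bad_n <- has(qtl$population_size) & qtl$population_size <= 0
  reason[bad_n & reason == ""] <- "population_size must be positive"
  bad <- which(reason != "")
  if (length(bad) && strict)
    stop("invalid QTL record(s) at row(s) ",
         paste(bad, collapse = ", "), ": ", reason[bad[1]])
  ok <- qtl[setdiff(seq_len(n), bad), , drop = FALSE]
  rownames(ok) <- NULL
  attr(ok, "rejected") <- data.frame(row = bad,
                                     reason = reason[bad],
                                     stringsAsFactors = FALSE)
  ok
}

#' Read a QTL table from TSV
#'
#' Native format: tab-separated, one-line header, columns `qtl_id`,
#' `study_id`, `trait`, `tissue_class`, `trait_category`, `chromosome`,
#' `position_cM`, `ci_start_cM`, `ci_end_cM`, `lod`, `lrs`, `r2`,
#' `population_size`, `population_type`. Missing statistics are empty cells,
#' never 0. Rows failing validation are excluded and reported through the
#' `rejected` attribute (or abort under `strict = TRUE`).
#'
#' @param path file path.
#' @param strict see [validate_qtl()].
#' @return data.frame of accepted records with a `rejected` attribute.
#' @export
read_qtl_table <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  miss <- setdiff(qtl_columns, names(raw))
  if (length(miss))
    stop("QTL file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(raw) == 0) {
    warning("QTL file ", path, " contains no records")
    out <- raw
    attr(out, "rejected") <- data.frame(row = integer(), reason = character())
    return(out)
  }
  num <- function(v, rows) {
    v[!nzchar(v)] <- NA
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      stop("non-numeric value(s) at line(s) ",
           paste(bad + 1L, collapse = ", "), " in ", path)
    out
  }
  qtl <- data.frame(
    qtl_id = raw$qtl_id,
    study_id = raw$study_id,
    trait = raw$trait,
    tissue_class = raw$tissue_class,
    trait_category = raw$trait_category,
    chromosome = as.character(raw$chromosome),
    position_cM = num(raw$position_cM),
    ci_start_cM = num(raw$ci_start_cM),
    ci_end_cM = num(raw$ci_end_cM),
    lod = num(raw$lod),
    lrs = num(raw$lrs),
    r2 = num(raw$r2),
    population_size = num(raw$population_size),
    population_type = raw$population_type,
    stringsAsFactors = FALSE
  )
  validate_qtl(qtl, strict = strict)
}

#' Write a QTL table to TSV
#'
#' Inverse of [read_qtl_table()]; numeric columns are written at full
#' precision so a read/write round trip is the identity.
#'
#' @param qtl data.frame of QTL records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qtl_table <- function(qtl, path) {
  out <- qtl[, intersect(qtl_columns, names(qtl)), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a marker physical-anchor table
#'
#' Columns: `marker`, `chromosome`, `position_bp` (integer base pairs >= 0).
#'
#' @param path file path.
#' @return data.frame of anchors.
#' @export
read_physical_anchors <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  need <- c("marker", "chromosome", "position_bp")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("anchor file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  bp <- suppressWarnings(as.numeric(raw$position_bp))
  bad <- which(is.na(bp) | bp < 0)
  if (length(bad))
    stop("malformed anchor row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), " in ", path)
  data.frame(marker = raw$marker, chromosome = as.character(raw$chromosome),
             position_bp = bp, stringsAsFactors = FALSE)
}

# Round half away from zero, the convention used for all report-time
# rounding (R's round() rounds half to even). The epsilon keeps decimal
# halves that fall just under .5 in binary (e.g. 1.005) rounding up.
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

#' Write a meta-QTL report to TSV
#'
#' One row per meta-QTL with its chromosome, 95% CI bounds, position, CI
#' width (end minus start), flanking markers and, when available, the
#' physical interval. Positions are rounded half-up to 2 decimals at write
#' time only.
#'
#' @param mqtls data.frame of meta-QTL, e.g. the `mqtl` element of a
#'   [meta_qtl()] fit or rows of [ir_mqtl_catalog()]. Must be non-empty and
#'   contain `mqtl_id`, `chromosome`, `position`, `ci95_start`, `ci95_end`;
#'   flanking/physical columns are optional and written as `NA` when absent.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mqtl_report <- function(mqtls, path) {
  stopifnot(is.data.frame(mqtls))
  if (nrow(mqtls) == 0) stop("cannot write an empty meta-QTL report")
  need <- c("mqtl_id", "chromosome", "position", "ci95_start", "ci95_end")
  miss <- setdiff(need, names(mqtls))
  if (length(miss))
    stop("meta-QTL table is missing column(s): ", paste(miss, collapse = ", "))
  grab <- function(col) if (col %in% names(mqtls)) mqtls[[col]] else NA
  out <- data.frame(
    mqtl_id = mqtls$mqtl_id,
    chromosome = mqtls$chromosome,
    ci95_start = round_half_up(mqtls$ci95_start),
    position = round_half_up(mqtls$position),
    ci95_end = round_half_up(mqtls$ci95_end),
    ci_width = round_half_up(mqtls$ci95_end - mqtls$ci95_start),
    flank_left = grab("flank_left"),
    flank_right = grab("flank_right"),
    phys_start_bp = grab("phys_start_bp"),
    phys_end_bp = grab("phys_end_bp"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Bundled catalog of published maize insect-resistance meta-QTL
#'
#' A transcription of a published table of 86 tissue-specific maize
#' insect-resistance meta-QTL (24 leaf LIR, 42 stem SIR, 20 kernel KIR) on
#' the IBM2 2008 Neighbors reference map: per meta-QTL the chromosome, 95%
#' CI start/position/end (cM), the CI width as printed in the source, the
#' flanking markers, and the physical interval (Mbp, B73 RefGen_v2). One
#' physical interval (SIR28) is open-ended on the right; its end is `NA` and
#' `phys_open_end` is `TRUE`.
#'
#' The printed CI-width column is kept verbatim because the published
#' coverage totals are sums of that column; it occasionally differs from
#' `ci95_end - ci95_start` by rounding in the source.
#'
#' @return data.frame with columns `mqtl_id`, `tissue_class`, `chromosome`,
#'   `ci95_start`, `position`, `ci95_end`, `ci95_width`, `flank_left`,
#'   `flank_right`, `phys_start_mbp`, `phys_end_mbp`, `phys_open_end`.
#' @examples
#' cat3 <- ir_mqtl_catalog()
#' tapply(cat3$ci95_width, cat3$tissue_class, sum)
#' @export
ir_mqtl_catalog <- function() {
  path <- system.file("extdata", "maize_ir_mqtl.tsv", package = "qtlmeta",
                      mustWork = TRUE)
  raw <- utils::read.delim(path, colClasses = "character")
  num <- c("ci95_start", "position", "ci95_end", "ci95_width",
           "phys_start_mbp")
  for (col in num) raw[[col]] <- as.numeric(raw[[col]])
  open_end <- raw$phys_end_mbp == "END"
  raw$phys_end_mbp <- suppressWarnings(as.numeric(raw$phys_end_mbp))
  raw$phys_open_end <- open_end
  raw
}

#' Bundled per-tissue QTL genetic coverage (cM)
#'
#' The published overlap-merged genetic coverage of the projected QTL per
#' tissue class on the same reference map as [ir_mqtl_catalog()], used to
#' compute the coverage reduction achieved by the meta-analysis.
#'
#' @return data.frame with columns `tissue_class`, `qtl_coverage_cM`.
#' @export
ir_qtl_coverage <- function() {
  path <- system.file("extdata", "maize_ir_qtl_coverage.tsv",
                      package = "qtlmeta", mustWork = TRUE)
  out <- utils::read.delim(path, colClasses = "character")
  out$qtl_coverage_cM <- as.numeric(out$qtl_coverage_cM)
  out
}
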