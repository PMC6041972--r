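# The user-facing meta-QTL fit: per chromosome, fit mixtures for a range of
# K, select K by the five criteria, and declare consensus loci.

mqtl_prefixes <- c(leaf = "LIR", stem = "SIR", kernel = "KIR")

# Nearest reference markers at/outside a CI on one chromosome. Returns NA
# on a side with no marker at or beyond the bound.
flanking_markers <- function(reference, chromosome, ci_start, ci_end) {
  ref <- reference[reference$chromosome == as.character(chromosome), ,
                   drop = FALSE]
  left <- ref[ref$position <= ci_start, , drop = FALSE]
  right <- ref[ref$position >= ci_end, , drop = FALSE]
  c(left = if (nrow(left)) left$marker[which.max(left$position)]
           else NA_character_,
    right = if (nrow(right)) right$marker[which.min(right$position)]
            else NA_character_)
}

#' Declare meta-QTL from a mixture fit
#'
#' Each QTL is assigned to its argmax-responsibility component. Per
#' component, the meta-QTL position is the inverse-variance weighted mean of
#' member positions (weights 1/s_i^2), its standard deviation is
#' sqrt(1 / sum(1/s_i^2)), and the 95% CI is position +/- 1.96 sd. Members
#' carry their soft responsibility for the assigned component. Components
#' left empty by the hardening are dropped with a warning. Flanking markers
#' are the nearest reference markers at or outside each CI bound.
#'
#' @param fit a [fit_qtl_mixture()] object at the chosen K.
#' @param qtl_ids character vector of member QTL ids, parallel to the fit's
#'   observations.
#' @param tissue_class tissue label for the declared loci.
#' @param chromosome chromosome label.
#' @param reference optional reference [genetic_map()] for flanking markers.
#' @return list with `mqtl` (data.frame, one row per declared locus, ordered
#'   by position) and `members` (data.frame `mqtl_id`, `qtl_id`,
#'   `membership`).
#' @export
declare_mqtl <- function(fit, qtl_ids, tissue_class, chromosome,
                         reference = NULL) {
  stopifnot(inherits(fit, "qtl_mixture"))
  n <- length(fit$positions)
  stopifnot(length(qtl_ids) == n)
  z <- max.col(fit$responsibilities, ties.method = "first")
  live <- sort(unique(z))
  if (length(live) < fit$K)
    warning(sprintf("%d of %d components empty after hardening; dropped",
                    fit$K - length(live), fit$K))
  w <- 1 / fit$sds^2
  rows <- lapply(live, function(k) {
    idx <- which(z == k)
    pos <- sum(w[idx] * fit$positions[idx]) / sum(w[idx])
    sd <- sqrt(1 / sum(w[idx]))
    data.frame(tissue_class = tissue_class,
               chromosome = as.character(chromosome),
               position = pos,
               ci95_start = pos - 1.96 * sd,
               ci95_end = pos + 1.96 * sd,
               sd = sd,
               n_members = length(idx),
               stringsAsFactors = FALSE)
  })
  mq <- do.call(rbind, rows)
  ord <- order(mq$position)
  mq <- mq[ord, , drop = FALSE]
  comp_of_row <- live[ord]
  mq$mqtl_id <- sprintf("%s_chr%s_%d",
                        tissue_class, chromosome, seq_len(nrow(mq)))
  members <- do.call(rbind, lapply(seq_len(nrow(mq)), function(i) {
    k <- comp_of_row[i]
    idx <- which(z == k)
    data.frame(mqtl_id = mq$mqtl_id[i],
               qtl_id = qtl_ids[idx],
               membership = fit$responsibilities[idx, k],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(reference)) {
    fl <- t(vapply(seq_len(nrow(mq)), function(i)
      flanking_markers(reference, chromosome,
                       mq$ci95_start[i], mq$ci95_end[i]),
      character(2)))
    mq$flank_left <- fl[, "left"]
    mq$flank_right <- fl[, "right"]
  } else {
    mq$flank_left <- NA_character_
    mq$flank_right <- NA_character_
  }
  rownames(mq) <- NULL
  rownames(members) <- NULL
  list(mqtl = mq, members = members)
}

#' Meta-analysis of projected QTL for one tissue class
#'
#' The core fit of the package. Projected QTL of the requested tissue class
#' are grouped per chromosome; on each chromosome a fixed-variance Gaussian
#' mixture ([fit_qtl_mixture()]) is fitted for K = 1..Kmax (Kmax capped at
#' the chromosome's QTL count), the number of consensus loci is chosen by
#' five information criteria ([select_model()]), and meta-QTL are declared
#' ([declare_mqtl()]). Declared loci are renamed `<PREFIX><ordinal>`
#' (LIR/SIR/KIR for leaf/stem/kernel) in chromosome-then-position order.
#'
#' @param projected data.frame of projected QTL ([project_qtl()] output);
#'   rows with `projection_status != "projected"` or other tissue classes
#'   are ignored.
#' @param tissue_class one of `"leaf"`, `"stem"`, `"kernel"`.
#' @param reference optional reference [genetic_map()] for flanking markers.
#' @param Kmax largest component count tried per chromosome (default 10).
#' @param strategy model-selection rule, see [select_model()].
#' @param restarts,max_iter,tol EM controls, see [fit_qtl_mixture()].
#' @param seed integer seed; each (chromosome, K) fit derives its own
#'   sub-seed so results are reproducible and independent of chromosome
#'   order.
#' @return an object of class `meta_qtl`: list with `mqtl` (data.frame of
#'   declared loci), `members` (per-locus QTL memberships), `selection`
#'   (per-chromosome [select_model()] objects), `n_qtl` (QTL used),
#'   `tissue_class`, `call`. Methods: `print`, `summary`, `coef` (positions),
#'   `plot`, `as.data.frame`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(6, 20, 1.5), rnorm(6, 80, 1.5))
#' qtl <- data.frame(qtl_id = paste0("q", 1:12), tissue_class = "leaf",
#'                   chromosome = "1", ref_position = x,
#'                   ref_ci_start = x - 6, ref_ci_end = x + 6,
#'                   projection_status = "projected")
#' fit <- meta_qtl(qtl, "leaf", seed = 7)
#' coef(fit)
#' @export
meta_qtl <- function(projected, tissue_class, reference = NULL, Kmax = 10,
                     strategy = c("majority", "aicc_only", "consensus_min"),
                     restarts = 10, max_iter = 500, tol = 1e-8, seed = 1) {
  strategy <- match.arg(strategy)
  tissue_class <- match.arg(tissue_class, names(mqtl_prefixes))
  stopifnot(is.data.frame(projected))
  cl <- match.call()
  use <- projected[projected$tissue_class == tissue_class &
                     projected$projection_status == "projected", ,
                   drop = FALSE]
  chroms <- unique(use$chromosome)
  chroms <- chroms[order(suppressWarnings(as.numeric(chroms)), chroms)]
  selection <- list()
  mq_all <- NULL
  members_all <- NULL
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    rows <- use[use$chromosome == chrom, , drop = FALSE]
    x <- rows$ref_position
    s <- qtl_sd(rows$ref_ci_end - rows$ref_ci_start)
    kmax_c <- min(Kmax, length(x))
    fits <- lapply(seq_len(kmax_c), function(K)
      fit_qtl_mixture(x, s, K, restarts = restarts, max_iter = max_iter,
                      tol = tol, seed = seed + 1000L * ci + K))
    sel <- select_model(fits, n = length(x), strategy = strategy)
    selection[[chrom]] <- sel
    dec <- declare_mqtl(fits[[sel$chosen_K]], rows$qtl_id, tissue_class,
                        chrom, reference = reference)
    mq_all <- rbind(mq_all, dec$mqtl)
    members_all <- rbind(members_all, dec$members)
  }
  if (!is.null(mq_all)) {
    new_ids <- sprintf("%s%d", mqtl_prefixes[[tissue_class]],
                       seq_len(nrow(mq_all)))
    members_all$mqtl_id <- new_ids[match(members_all$mqtl_id,
                                         mq_all$mqtl_id)]
    mq_all$mqtl_id <- new_ids
    mq_all <- mq_all[, c("mqtl_id", "tissue_class", "chromosome",
                         "ci95_start", "position", "ci95_end", "sd",
                         "n_members", "flank_left", "flank_right")]
  } else {
    mq_all <- data.frame(mqtl_id = character(), tissue_class = character(),
                         chromosome = character(), ci95_start = numeric(),
                         position = numeric(), ci95_end = numeric(),
                         sd = numeric(), n_members = integer(),
                         flank_left = character(),
                         flank_right = character())
    members_all <- data.frame(mqtl_id = character(), qtl_id = character(),
                              membership = numeric())
  }
  structure(list(mqtl = mq_all, members = members_all,
                 selection = selection, n_qtl = nrow(use),
                 tissue_class = tissue_class, call = cl),
            class = "meta_qtl")
}

#' @export
print.meta_qtl <- function(x, ...) {
  cat(sprintf("Meta-QTL analysis (%s): %d QTL on %d chromosome(s) -> %d meta-QTL\n",
              x$tissue_class, x$n_qtl, length(x$selection), nrow(x$mqtl)))
  if (nrow(x$mqtl)) {
    show <- x$mqtl
    for (col in c("ci95_start", "position", "ci95_end", "sd"))
      show[[col]] <- round_half_up(show[[col]])
    print(show, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.meta_qtl <- function(object, ...) {
  cat(sprintf("Call: %s\n\n", deparse(object$call)))
  print(object)
  cat("\nModel selection per chromosome:\n")
  for (chrom in names(object$selection)) {
    sel <- object$selection[[chrom]]
    cat(sprintf("  chr %s: chosen K = %d (votes %s)\n", chrom, sel$chosen_K,
                paste(names(sel$votes), sel$votes, sep = "=",
                      collapse = " ")))
  }
  invisible(object)
}

#' @export
coef.meta_qtl <- function(object, ...) {
  stats::setNames(object$mqtl$position, object$mqtl$mqtl_id)
}

#' @export
as.data.frame.meta_qtl <- function(x, ...) x$mqtl

#' Plot declared meta-QTL along chromosomes
#'
#' One horizontal lane per chromosome; meta-QTL 95% CIs are drawn as thick
#' segments with their positions ticked.
#'
#' @param x a [meta_qtl()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.meta_qtl <- function(x, ...) {
  mq <- x$mqtl
  if (!nrow(mq)) {
    warning("no meta-QTL to plot")
    return(invisible(x))
  }
  chroms <- unique(mq$chromosome)
  lane <- match(mq$chromosome, chroms)
  graphics::plot(NA, xlim = c(0, max(mq$ci95_end) * 1.05),
                 ylim = c(length(chroms) + 0.5, 0.5),
                 xlab = "position (cM)", ylab = "chromosome", yaxt = "n",
                 main = sprintf("%s meta-QTL", x$tissue_class), ...)
  graphics::axis(2, at = seq_along(chroms), labels = chroms, las = 1)
  graphics::segments(mq$ci95_start, lane, mq$ci95_end, lane, lwd = 4,
                     col = grDevices::adjustcolor("firebrick", 0.6))
  graphics::points(mq$position, lane, pch = 3)
  graphics::text(mq$position, lane - 0.25, mq$mqtl_id, cex = 0.6)
  invisible(x)
}
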