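#' Profile parameters
#'
#' @param n_body_bins Number of equal-width bins each gene body is rescaled
#'   to (default 100).
#' @param flank_bp Flank width in bp taken on each side of the gene
#'   (default 1000).
#' @param flank_bins Number of bins each flank is divided into (default 50,
#'   i.e. 20-bp bins at the default flank width).
#' @param bin_size_genes Genes per bin in the ranked-bin comparison
#'   (default 690, giving 30 bins over a ~20,700-gene genome).
#' @return A list of class \code{ProfileParams}.
#' @export
profile_params <- function(n_body_bins = 100L, flank_bp = 1000L,
                           flank_bins = 50L, bin_size_genes = 690L) {
  stopifnot(n_body_bins >= 2, bin_size_genes >= 1, flank_bins >= 1)
  structure(list(n_body_bins = as.integer(n_body_bins),
                 flank_bp = as.integer(flank_bp),
                 flank_bins = as.integer(flank_bins),
                 bin_size_genes = as.integer(bin_size_genes)),
            class = "ProfileParams")
}

# Per-base score vector for an interval, bases inheriting their fragment's
# score; positions outside the chromosome yield NA.
.per_base_scores <- function(start, end, fs, fe, sc, clen) {
  pos <- seq.int(start, end - 1L)
  out <- rep(NA_real_, length(pos))
  inside <- pos >= 0L & pos < clen
  if (any(inside)) {
    j <- findInterval(pos[inside], fs)
    out[inside] <- sc[j]
  }
  out
}

# Mean of x over nb equal bins (length(x) need not divide nb evenly).
.bin_means <- function(x, nb) {
  idx <- pmin(floor((seq_along(x) - 1L) * nb / length(x)) + 1L, nb)
  as.numeric(tapply(x, factor(idx, levels = seq_len(nb)), mean, na.rm = TRUE))
}

#' Metagene profile of a track over gene bodies
#'
#' Each eligible gene body (length at least \code{n_body_bins} bp) is
#' rescaled to \code{n_body_bins} bins of per-base mean score; flanks of
#' \code{flank_bp} are binned at fixed bp resolution. Minus-strand genes
#' are reversed so the TSS is always on the left. The profile is the
#' unweighted mean across genes at each grid point. Bases a fragment track
#' covers inherit their fragment's score.
#'
#' @param track An \code{OccupancyTrack} (fragment table required).
#' @param genes Gene annotation table.
#' @param params A \code{ProfileParams}.
#' @return Object of class \code{metagene}: list with \code{position}
#'   (grid labels; negative = upstream flank, 0..1 = scaled body, >1 =
#'   downstream flank), \code{mean_score}, \code{n_genes},
#'   \code{n_skipped}.
#' @export
metagene <- function(track, genes, params = profile_params()) {
  fr <- track$fragments
  if (is.null(fr)) stop("track carries no fragment table")
  nb <- params$n_body_bins
  fb <- params$flank_bins
  frag_by_chrom <- split(seq_len(nrow(fr)), fr$chrom)
  eligible <- genes$end - genes$start >= nb
  if (!any(eligible)) stop("no genes long enough for body scaling")
  rows <- vector("list", sum(eligible))
  r <- 0L
  for (ch in unique(genes$chrom[eligible])) {
    idx <- frag_by_chrom[[ch]]
    if (is.null(idx)) stop("chromosome ", ch, " absent from track")
    fs <- fr$start[idx]; fe <- fr$end[idx]; sc <- track$score[idx]
    clen <- fe[length(fe)]
    for (g in which(eligible & genes$chrom == ch)) {
      gs <- genes$start[g]; ge <- genes$end[g]
      body <- .bin_means(.per_base_scores(gs, ge, fs, fe, sc, clen), nb)
      up <- .bin_means(.per_base_scores(gs - params$flank_bp, gs, fs, fe, sc, clen), fb)
      down <- .bin_means(.per_base_scores(ge, ge + params$flank_bp, fs, fe, sc, clen), fb)
      prof <- c(up, body, down)
      if (identical(genes$strand[g], "-")) prof <- rev(prof)
      r <- r + 1L
      rows[[r]] <- prof
    }
  }
  mat <- do.call(rbind, rows)
  position <- c(-rev(seq_len(fb)) / fb,                      # upstream flank
                (seq_len(nb) - 0.5) / nb,                    # scaled body
                1 + seq_len(fb) / fb)                        # downstream flank
  structure(list(position = position,
                 mean_score = colMeans(mat, na.rm = TRUE),
                 n_genes = nrow(mat),
                 n_skipped = sum(!eligible)),
            class = "metagene")
}

#' @export
print.metagene <- function(x, ...) {
  cat("Metagene profile over", x$n_genes, "genes (", x$n_skipped,
      "too short ), grid length", length(x$position), "\n")
  invisible(x)
}

#' Ranked-bin comparison of occupancy against expression
#'
#' Genes are ranked by occupancy (ascending, ties broken by gene id) and
#' grouped into consecutive bins of \code{bin_size_genes}; the mean
#' expression (e.g. TPM) of each bin is returned. A monotone trend of bin
#' means against bin rank indicates that the footprinting signal tracks
#' transcript abundance.
#'
#' @param gene_scores data.frame with \code{gene_id}, \code{occupancy}.
#' @param gene_expression data.frame with \code{gene_id} and an expression
#'   column (\code{tpm} or the second column).
#' @param params A \code{ProfileParams}.
#' @return data.frame with \code{bin}, \code{n_genes}, \code{occ_min},
#'   \code{occ_max}, \code{mean_expression}; attribute \code{n_joined}
#'   records the inner-join size.
#' @export
ranked_bin_comparison <- function(gene_scores, gene_expression,
                                  params = profile_params()) {
  expr_col <- if ("tpm" %in% names(gene_expression)) "tpm" else names(gene_expression)[2L]
  m <- merge(gene_scores[, c("gene_id", "occupancy")],
             gene_expression[, c("gene_id", expr_col)], by = "gene_id")
  if (nrow(m) == 0L) stop("no genes shared between score and expression tables")
  m <- m[order(m$occupancy, m$gene_id), ]
  bs <- params$bin_size_genes
  bin <- (seq_len(nrow(m)) - 1L) %/% bs + 1L
  out <- data.frame(
    bin = sort(unique(bin)),
    n_genes = as.integer(table(bin)),
    occ_min = as.numeric(tapply(m$occupancy, bin, min)),
    occ_max = as.numeric(tapply(m$occupancy, bin, max)),
    mean_expression = as.numeric(tapply(m[[expr_col]], bin, mean)))
  attr(out, "n_joined") <- nrow(m)
  out
}

#' Bootstrap parameters
#'
#' @param n_boot Number of bootstrap resamples (default 10000, min 1000).
#' @param ci_level Confidence level (default 0.95).
#' @param seed RNG seed.
#' @return A list of class \code{BootstrapParams}.
#' @export
bootstrap_params <- function(n_boot = 10000L, ci_level = 0.95, seed = 1L) {
  stopifnot(n_boot >= 1000, ci_level > 0, ci_level < 1)
  structure(list(n_boot = as.integer(n_boot), ci_level = ci_level,
                 seed = as.integer(seed)),
            class = "BootstrapParams")
}

#' Bootstrap confidence interval for a true-positive rate
#'
#' Given \code{n_positive} successes among \code{n_total} binary validation
#' outcomes (e.g. reporter assays scored positive/negative), resamples the
#' outcomes with replacement \code{n_boot} times and returns the percentile
#' confidence interval of the positive fraction. Resampling
#' \code{n_total} binary outcomes with replacement is a draw from
#' Binomial(\code{n_total}, \code{n_positive/n_total}), which is how the
#' resamples are generated.
#'
#' @param n_positive,n_total Counts of positive and total outcomes.
#' @param params A \code{BootstrapParams}.
#' @return Object of class \code{tpr_boot}: list with
#'   \code{point_estimate}, \code{ci_lower}, \code{ci_upper},
#'   \code{ci_level}, \code{n_boot}, \code{n_positive}, \code{n_total}.
#' @examples
#' bootstrap_tpr(8, 11, bootstrap_params(n_boot = 100000, seed = 1))
#' @export
bootstrap_tpr <- function(n_positive, n_total, params = bootstrap_params()) {
  stopifnot(n_total >= 1, n_positive >= 0, n_positive <= n_total)
  phat <- n_positive / n_total
  fracs <- with_seed(params$seed,
                     stats::rbinom(params$n_boot, n_total, phat) / n_total)
  a <- (1 - params$ci_level) / 2
  ci <- unname(stats::quantile(fracs, c(a, 1 - a)))
  structure(list(point_estimate = phat,
                 ci_lower = ci[1L], ci_upper = ci[2L],
                 ci_level = params$ci_level,
                 n_boot = params$n_boot,
                 n_positive = n_positive, n_total = n_total),
            class = "tpr_boot")
}

#' @export
print.tpr_boot <- function(x, ...) {
  cat(sprintf("True-positive rate %d/%d = %.1f%% (%.0f%% CI %.1f-%.1f%%, B = %d)\n",
              x$n_positive, x$n_total, 100 * x$point_estimate,
              100 * x$ci_level, 100 * x$ci_lower, 100 * x$ci_upper, x$n_boot))
  invisible(x)
}

#' Extrapolate a TPR interval to an expressed-gene count range
#'
#' Multiplies the CI bounds by the number of detected genes; with
#' \code{rounding = "nearest100"} the bounds are rounded to the nearest
#' hundred for headline-style reporting.
#'
#' @param tpr A \code{tpr_boot}.
#' @param n_detected Number of detected genes the rate applies to.
#' @param rounding \code{"nearest"} (default) or \code{"nearest100"}.
#' @return Integer vector \code{c(low, high)}.
#' @export
extrapolate_expressed <- function(tpr, n_detected,
                                  rounding = c("nearest", "nearest100")) {
  rounding <- match.arg(rounding)
  stopifnot(n_detected >= 0)
  lo <- tpr$ci_lower * n_detected
  hi <- tpr$ci_upper * n_detected
  if (rounding == "nearest100") {
    c(low = round(lo / 100) * 100, high = round(hi / 100) * 100)
  } else {
    c(low = round(lo), high = round(hi))
  }
}

#' Write a metagene profile as TSV
#' @param profile A \code{metagene}.
#' @param path Output path.
#' @export
write_metagene_tsv <- function(profile, path) {
  utils::write.table(
    data.frame(position = profile$position, mean_score = profile$mean_score,
               n_genes = profile$n_genes),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
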