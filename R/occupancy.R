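#' Normalization parameters
#'
#' @param pseudocount Pseudocount added to the library-scaled count
#'   fractions, expressed on the counts-per-million scale (default 0.5 CPM,
#'   i.e. 0.5e-6 on the fraction scale).
#' @param scaling \code{"library_size"} (total-count scaling, the default)
#'   or \code{"kde_mode"}, which additionally recenters the score
#'   distribution so its kernel-density mode sits at 0 — useful when most
#'   fragments are unbound.
#' @param chip_pseudocount Additive pseudocount for the ChIP-style
#'   comparison path ([chip_log2_ratio()]); the conventional value there
#'   is 8 raw counts.
#' @return A list of class \code{NormParams}.
#' @export
norm_params <- function(pseudocount = 0.5, scaling = c("library_size", "kde_mode"),
                        chip_pseudocount = 8) {
  stopifnot(pseudocount > 0)
  structure(list(pseudocount = pseudocount,
                 scaling = match.arg(scaling),
                 chip_pseudocount = chip_pseudocount),
            class = "NormParams")
}

#' Normalize fusion counts against the Dam-only control
#'
#' Converts a (polymerase::Dam fusion, free-Dam control) pair of
#' per-fragment counts into the log2 occupancy track: the per-fragment
#' polymerase footprinting signal. The free-Dam profile measures chromatin
#' accessibility, so the ratio cancels both sequencing depth and
#' accessibility:
#' \deqn{score_i = \log_2\frac{f_i/F + \psi'}{c_i/C + \psi'}}
#' with \eqn{F, C} the library totals and \eqn{\psi'} the scaled
#' pseudocount. With \code{scaling = "kde_mode"} a constant is subtracted so
#' the kernel-density mode of the scores is 0.
#'
#' @param fusion,control \code{FragmentCounts} for the fusion and Dam-only
#'   libraries (same fragment list).
#' @param params A \code{NormParams}. \code{params$pseudocount} is on the
#'   CPM scale; it is divided by 1e6 before being added to the count
#'   fractions.
#' @param fragments Optional fragment table stored with the track (needed
#'   for gene-level work and bedGraph output).
#' @return Object of class \code{OccupancyTrack}: list with \code{score}
#'   (numeric per fragment), \code{fragments}, \code{library_pair}.
#' @examples
#' fr <- data.frame(chrom = "c", start = c(0, 5, 10), end = c(5, 10, 15),
#'                  fragment_id = 1:3)
#' f <- structure(list(library_id = "f", counts = c(10L, 0L, 5L),
#'                     n_reads_in = 15L, n_reads_kept = 15L, n_anomalous = 0L),
#'                class = "FragmentCounts")
#' c0 <- structure(list(library_id = "c", counts = c(5L, 5L, 5L),
#'                      n_reads_in = 15L, n_reads_kept = 15L, n_anomalous = 0L),
#'                 class = "FragmentCounts")
#' tr <- normalize_counts(f, c0, norm_params(pseudocount = 1e6 / 15), fr)
#' round(tr$score, 3)  # log2(11/6), log2(1/6), 0
#' @export
normalize_counts <- function(fusion, control, params = norm_params(),
                             fragments = NULL) {
  if (length(fusion$counts) != length(control$counts)) {
    stop("fusion and control fragment lists differ in length (",
         length(fusion$counts), " vs ", length(control$counts), ")")
  }
  f_tot <- sum(fusion$counts)
  c_tot <- sum(control$counts)
  if (f_tot == 0 || c_tot == 0) stop("zero-total library: ",
                                     if (f_tot == 0) fusion$library_id else control$library_id)
  psi <- params$pseudocount / 1e6
  score <- log2((fusion$counts / f_tot + psi) / (control$counts / c_tot + psi))
  if (params$scaling == "kde_mode") {
    d <- stats::density(score)
    score <- score - d$x[which.max(d$y)]
  }
  structure(list(score = score,
                 fragments = fragments,
                 library_pair = c(fusion = fusion$library_id,
                                  control = control$library_id)),
            class = "OccupancyTrack")
}

#' @export
print.OccupancyTrack <- function(x, ...) {
  cat("OccupancyTrack ", x$library_pair[["fusion"]], "/",
      x$library_pair[["control"]], ": ", length(x$score),
      " fragments, score range [", round(min(x$score), 3), ", ",
      round(max(x$score), 3), "]\n", sep = "")
  invisible(x)
}

#' Pearson correlation between two tracks
#'
#' @param a,b \code{OccupancyTrack}s or numeric vectors of equal length
#'   (at least 3 values).
#' @return Pearson r, or \code{NA} with a warning when either input has
#'   zero variance.
#' @export
correlate_tracks <- function(a, b) {
  x <- if (inherits(a, "OccupancyTrack")) a$score else as.numeric(a)
  y <- if (inherits(b, "OccupancyTrack")) b$score else as.numeric(b)
  if (length(x) != length(y)) stop("tracks differ in length")
  if (length(x) < 3L) stop("need at least 3 fragments")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' ChIP-style log2 ratio of sample over input
#'
#' Emulates the conventional ChIP-seq display normalization: per-bin counts
#' are depth-scaled to a common reference depth, a fixed pseudocount (8 by
#' default) is added, and the log2 ratio to input is taken:
#' \deqn{\log_2\frac{s_i D + 8}{i_i D' + 8}}
#' where \eqn{D = R/\sum s} and \eqn{D' = R/\sum i} equalize both library
#' totals to the reference depth \eqn{R} before the pseudocount.
#'
#' Because the pseudocount is additive, scores are invariant to sequencing
#' depth only when \code{ref_depth} is held fixed across libraries; the
#' default uses the mean of the two observed totals.
#'
#' @param sample,input Numeric per-bin counts on the same binning.
#' @param params A \code{NormParams} (uses \code{chip_pseudocount}).
#' @param ref_depth Reference depth the two libraries are scaled to;
#'   default the mean of the two totals.
#' @return Numeric per-bin log2 ratios.
#' @export
chip_log2_ratio <- function(sample, input, params = norm_params(),
                            ref_depth = NULL) {
  if (length(sample) != length(input)) stop("sample and input binning differ")
  s_tot <- sum(sample); i_tot <- sum(input)
  if (s_tot == 0 || i_tot == 0) stop("zero-total library")
  if (is.null(ref_depth)) ref_depth <- mean(c(s_tot, i_tot))
  pc <- params$chip_pseudocount
  log2((sample * ref_depth / s_tot + pc) / (input * ref_depth / i_tot + pc))
}

#' Write an occupancy track as bedGraph
#'
#' @param track An \code{OccupancyTrack} whose \code{fragments} slot is set.
#' @param path Output path.
#' @param tsv If \code{TRUE}, write a TSV mirror with fragment_id and a
#'   header instead of bedGraph.
#' @export
write_track <- function(track, path, tsv = FALSE) {
  fr <- track$fragments
  if (is.null(fr)) stop("track carries no fragment table")
  if (tsv) {
    df <- cbind(fr[, c("chrom", "start", "end", "fragment_id")],
                score = track$score)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(fr$chrom, fr$start, fr$end, track$score)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a track TSV written by [write_track()]
#' @param path TSV path (with header).
#' @return An \code{OccupancyTrack}.
#' @export
read_track_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(list(score = df$score,
                 fragments = df[, c("chrom", "start", "end", "fragment_id")],
                 library_pair = c(fusion = NA, control = NA)),
            class = "OccupancyTrack")
}
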