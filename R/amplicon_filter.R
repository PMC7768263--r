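#' Read coordinate-level alignments from SAM/BAM
#'
#' Thin wrapper around [GenomicAlignments::readGAlignments()] returning the
#' plain data.frame of alignment records the filtering functions consume.
#' The aligned reference span (soft clips excluded) defines the read ends:
#' \code{ref_start} is 0-based inclusive, \code{ref_end} 0-based exclusive.
#'
#' @param path SAM or BAM file.
#' @return data.frame with columns \code{read_id}, \code{chrom},
#'   \code{ref_start}, \code{ref_end}, \code{mapq}, \code{secondary},
#'   \code{supplementary}.
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  ga <- as.data.frame(GenomicAlignments::readGAlignments(bam, param = param))
  data.frame(
    read_id = ga$qname,
    chrom = as.character(ga$seqnames),
    ref_start = ga$start - 1L,
    ref_end = ga$end,
    mapq = ifelse(is.na(ga$mapq), 0L, ga$mapq),
    secondary = bitwAnd(ga$flag, 256L) > 0L,
    supplementary = bitwAnd(ga$flag, 2048L) > 0L,
    stringsAsFactors = FALSE)
}

#' Amplicon filter parameters
#'
#' @param end_tolerance Maximum distance (bp) between a read end and the
#'   nearest GATC motif interval for the end to count as matched; the
#'   classical DamID rule is plus or minus 8 bp, inclusive.
#' @param min_mapq Minimum mapping quality.
#' @param keep_secondary Keep secondary/supplementary alignments.
#' @param read_extension Read extension in bp; fixed at 0 for amplicon data
#'   (an amplicon's genomic footprint is its aligned span).
#' @return A list of class \code{FilterParams}.
#' @export
filter_params <- function(end_tolerance = 8L, min_mapq = 10L,
                          keep_secondary = FALSE, read_extension = 0L) {
  stopifnot(end_tolerance >= 0, read_extension == 0)
  structure(list(end_tolerance = as.integer(end_tolerance),
                 min_mapq = as.integer(min_mapq),
                 keep_secondary = isTRUE(keep_secondary),
                 read_extension = 0L),
            class = "FilterParams")
}

# Distance from each point x to the nearest motif interval [m, m+4] on one
# chromosome: 0 inside the interval, boundary distance outside.
.motif_distance <- function(x, motifs) {
  if (!length(motifs)) return(rep(Inf, length(x)))
  i <- findInterval(x, motifs)                # last motif with start <= x
  d_prev <- ifelse(i >= 1L, x - (motifs[pmax(i, 1L)] + 4L), Inf)
  d_prev <- pmax(d_prev, 0)                   # inside interval -> 0
  d_next <- ifelse(i < length(motifs), motifs[pmin(i + 1L, length(motifs))] - x, Inf)
  d_next <- pmax(d_next, 0)
  pmin(d_prev, d_next)
}

# Start position of the motif nearest to each point (ties: left motif).
.nearest_motif <- function(x, motifs) {
  if (!length(motifs)) return(rep(NA_integer_, length(x)))
  i <- findInterval(x, motifs)
  d_prev <- ifelse(i >= 1L, pmax(x - (motifs[pmax(i, 1L)] + 4L), 0), Inf)
  d_next <- ifelse(i < length(motifs),
                   pmax(motifs[pmin(i + 1L, length(motifs))] - x, 0), Inf)
  ifelse(d_prev <= d_next, motifs[pmax(i, 1L)], motifs[pmin(i + 1L, length(motifs))])
}

#' Validate a read as a DamID amplicon
#'
#' A read is a genuine DamID amplicon when both aligned ends fall within
#' \code{end_tolerance} bp of a genomic GATC motif. Distance is measured to
#' the 4-bp motif interval \code{[m, m + 4)}: zero inside, boundary distance
#' outside.
#'
#' @param read One-row data.frame (or list) with \code{chrom},
#'   \code{ref_start}, \code{ref_end}.
#' @param index A \code{GATCIndex}.
#' @param params A \code{FilterParams}.
#' @return list(valid = logical, start_motif, end_motif) where the motifs
#'   are the 0-based start positions of the matched GATC sites (NA when not
#'   matched).
#' @export
validate_read <- function(read, index, params = filter_params()) {
  ch <- as.character(read$chrom)
  if (!ch %in% names(index$motif_starts)) {
    stop("read ", read$read_id %||% "<unnamed>",
         ": chromosome ", ch, " absent from GATC index")
  }
  m <- index$motif_starts[[ch]]
  d1 <- .motif_distance(read$ref_start, m)
  d2 <- .motif_distance(read$ref_end, m)
  ok <- d1 <= params$end_tolerance && d2 <= params$end_tolerance
  list(valid = ok,
       start_motif = if (ok) .nearest_motif(read$ref_start, m) else NA_integer_,
       end_motif = if (ok) .nearest_motif(read$ref_end, m) else NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter an alignment stream down to valid DamID amplicons
#'
#' Applies, in order: mapped check (rows are assumed mapped if no
#' \code{unmapped} column is present), secondary/supplementary drop, mapping
#' quality, then the dual-end GATC rule of [validate_read()]. The result is
#' independent of input order.
#'
#' @param reads data.frame of alignment records (see [read_alignments()]).
#' @param index A \code{GATCIndex}.
#' @param params A \code{FilterParams}.
#' @return list with \code{kept} (the retained rows) and \code{report}, a
#'   list carrying \code{n_reads_in}, \code{n_reads_kept} and the rejection
#'   tally \code{rejected} (unmapped, secondary, low_mapq, end_mismatch).
#' @export
filter_alignments <- function(reads, index, params = filter_params()) {
  n_in <- nrow(reads)
  unmapped <- if ("unmapped" %in% names(reads)) reads$unmapped else rep(FALSE, n_in)
  sec <- if (params$keep_secondary) rep(FALSE, n_in) else {
    s1 <- if ("secondary" %in% names(reads)) reads$secondary else FALSE
    s2 <- if ("supplementary" %in% names(reads)) reads$supplementary else FALSE
    (s1 | s2) & !unmapped
  }
  lowq <- !unmapped & !sec & reads$mapq < params$min_mapq
  candidate <- !unmapped & !sec & !lowq

  bad_chrom <- candidate & !(reads$chrom %in% names(index$motif_starts))
  if (any(bad_chrom)) {
    i <- which(bad_chrom)[1L]
    stop("read ", reads$read_id[i], ": chromosome ", reads$chrom[i],
         " absent from GATC index")
  }

  end_ok <- rep(FALSE, n_in)
  for (ch in unique(reads$chrom[candidate])) {
    sel <- candidate & reads$chrom == ch
    m <- index$motif_starts[[ch]]
    end_ok[sel] <- .motif_distance(reads$ref_start[sel], m) <= params$end_tolerance &
      .motif_distance(reads$ref_end[sel], m) <= params$end_tolerance
  }
  kept <- reads[candidate & end_ok, , drop = FALSE]
  report <- list(
    n_reads_in = n_in,
    n_reads_kept = nrow(kept),
    rejected = c(unmapped = sum(unmapped),
                 secondary = sum(sec),
                 low_mapq = sum(lowq),
                 end_mismatch = sum(candidate & !end_ok)))
  list(kept = kept, report = report)
}

#' Count amplicon coverage per GATC fragment
#'
#' A fragment is incremented when its entire interval lies within the read
#' span widened by the end tolerance, \code{[ref_start - delta,
#' ref_end + delta)}: a true amplicon is a union of consecutive complete
#' fragments and the margin absorbs end jitter. Reads covering zero
#' fragments under this rule are tallied as anomalous, never dropped
#' silently.
#'
#' @param kept data.frame of validated reads.
#' @param fragments Fragment table from [gatc_fragments()].
#' @param params A \code{FilterParams}.
#' @param library_id Label stored with the counts.
#' @param n_reads_in Optional total read count before filtering (for the
#'   record); defaults to \code{nrow(kept)}.
#' @return Object of class \code{FragmentCounts}: list with
#'   \code{library_id}, \code{counts} (integer vector aligned to
#'   \code{fragments} rows), \code{n_reads_in}, \code{n_reads_kept},
#'   \code{n_anomalous}.
#' @export
count_fragments <- function(kept, fragments, params = filter_params(),
                            library_id = "library", n_reads_in = nrow(kept)) {
  delta <- params$end_tolerance
  counts <- integer(nrow(fragments))
  anomalous <- 0L
  frag_chrom <- split(seq_len(nrow(fragments)), fragments$chrom)
  for (ch in unique(kept$chrom)) {
    idx <- frag_chrom[[ch]]
    if (is.null(idx)) stop("no fragments for chromosome ", ch)
    fs <- fragments$start[idx]
    fe <- fragments$end[idx]
    sel <- kept$chrom == ch
    lo_bound <- kept$ref_start[sel] - delta   # fragment start must be >= this
    hi_bound <- kept$ref_end[sel] + delta     # fragment end must be <= this
    # fragments sorted: first index with fs >= lo, last with fe <= hi
    first <- findInterval(lo_bound - 1L, fs) + 1L
    last <- findInterval(hi_bound, fe)
    valid <- first <= last
    anomalous <- anomalous + sum(!valid)
    if (any(valid)) {
      # difference-array accumulation of [first, last] interval increments
      f <- first[valid]; l <- last[valid]
      d_tab <- tabulate(f, nbins = length(idx))
      d_tab2 <- tabulate(l + 1L, nbins = length(idx) + 1L)
      inc <- cumsum(d_tab - d_tab2[seq_along(idx)])
      counts[idx] <- counts[idx] + inc
    }
  }
  structure(list(library_id = library_id,
                 counts = as.integer(counts),
                 n_reads_in = n_reads_in,
                 n_reads_kept = nrow(kept),
                 n_anomalous = anomalous),
            class = "FragmentCounts")
}

#' @export
print.FragmentCounts <- function(x, ...) {
  cat("FragmentCounts '", x$library_id, "': ", x$n_reads_kept, "/",
      x$n_reads_in, " reads kept over ", length(x$counts), " fragments (",
      x$n_anomalous, " anomalous)\n", sep = "")
  invisible(x)
}

#' Write fragment counts as TSV
#'
#' Columns: chrom, start, end, fragment_id, count.
#' @param counts A \code{FragmentCounts}.
#' @param fragments Matching fragment table.
#' @param path Output path.
#' @export
write_counts_tsv <- function(counts, fragments, path) {
  df <- cbind(fragments[, c("chrom", "start", "end", "fragment_id")],
              count = counts$counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
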