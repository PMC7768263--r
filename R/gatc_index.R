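#' Index GATC motifs in a genome
#'
#' Scans every chromosome of a genome for occurrences of the palindromic
#' 4-mer \code{GATC}, the Dam methyltransferase target and DpnI restriction
#' site. The resulting index is the coordinate backbone of DamID analysis:
#' restriction fragments ([gatc_fragments()]), amplicon end validation
#' ([filter_alignments()]) and occupancy tracks are all expressed on it.
#'
#' Matching is case-insensitive (soft-masked genomes keep their motifs) and
#' any window containing an ambiguity code such as \code{N} never matches.
#' All coordinates are 0-based: a motif at position \code{p} occupies the
#' half-open interval \code{[p, p + 4)}.
#'
#' @param genome A [Biostrings::DNAStringSet], a named character vector of
#'   sequences, or the path to a FASTA file.
#' @return An object of class \code{GATCIndex}: a list with
#'   \item{chrom_lengths}{named integer vector of chromosome lengths (bp)}
#'   \item{motif_starts}{named list of strictly increasing 0-based motif
#'     start positions per chromosome}
#' @examples
#' idx <- gatc_index(c(chrI = "AAGATCTTGATCAA"))
#' idx$motif_starts$chrI   # 2 8
#' @export
gatc_index <- function(genome) {
  seqs <- .as_dna(genome)
  if (length(seqs) == 0L) {
    return(.new_gatc_index(integer(0), list()))
  }
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  hits <- Biostrings::vmatchPattern("GATC", seqs, fixed = TRUE)
  starts <- lapply(Biostrings::startIndex(hits), function(s) {
    if (is.null(s)) integer(0) else as.integer(s) - 1L
  })
  names(starts) <- names(seqs)
  lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
  .new_gatc_index(lens, starts)
}

.new_gatc_index <- function(chrom_lengths, motif_starts) {
  structure(list(chrom_lengths = chrom_lengths, motif_starts = motif_starts),
            class = "GATCIndex")
}

# Coerce FASTA path / character vector / XStringSet to DNAStringSet,
# rejecting non-DNA characters with a format error.
.as_dna <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      is.null(names(genome))) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome)) {
    bad <- grepl("[^ACGTNacgtn]", genome)
    if (any(bad)) {
      stop("non-DNA characters in sequence(s): ",
           paste(utils::head(names(genome)[bad], 3), collapse = ", "))
    }
    return(Biostrings::DNAStringSet(genome))
  }
  stop("unsupported genome input of class ", paste(class(genome), collapse = "/"))
}

#' @export
print.GATCIndex <- function(x, ...) {
  st <- gatc_stats(x)
  cat("GATCIndex:", length(x$chrom_lengths), "chromosome(s),",
      format(sum(as.numeric(x$chrom_lengths)), big.mark = ",",
             scientific = FALSE), "bp,",
      format(st$n_motifs, big.mark = ","), "GATC motifs\n")
  if (!is.na(st$median_spacing)) {
    cat("  spacing: mean", round(st$mean_spacing, 1),
        "bp, median", st$median_spacing, "bp\n")
  }
  invisible(x)
}

#' Derive the GATC restriction-fragment partition
#'
#' Fragments tile each chromosome \code{[0, length)} without gaps or
#' overlaps; interior boundaries sit at motif start positions, so a
#' chromosome with \code{m} motifs yields \code{m + 1} fragments. The
#' fragment is the native resolution unit of the DamID signal.
#'
#' @param index A \code{GATCIndex}.
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open) and \code{fragment_id} (ordinal within chromosome,
#'   starting at 1).
#' @export
gatc_fragments <- function(index) {
  stopifnot(inherits(index, "GATCIndex"))
  out <- lapply(names(index$chrom_lengths), function(ch) {
    len <- index$chrom_lengths[[ch]]
    m <- index$motif_starts[[ch]]
    if (length(m) && any(m > len - 4L)) {
      stop("motif position beyond chromosome end on ", ch,
           " (position ", max(m), ", length ", len, ")")
    }
    bounds <- c(0L, m, len)
    data.frame(chrom = ch,
               start = bounds[-length(bounds)],
               end = bounds[-1L],
               fragment_id = seq_len(length(bounds) - 1L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Motif count and spacing statistics
#'
#' Spacing is the difference between consecutive motif start positions
#' within a chromosome, pooled genome-wide. With fewer than two motifs on
#' every chromosome the spacing summaries are undefined and reported as
#' \code{NA}.
#'
#' @param index A \code{GATCIndex}.
#' @return A list with \code{n_motifs}, \code{mean_spacing},
#'   \code{median_spacing}.
#' @export
gatc_stats <- function(index) {
  stopifnot(inherits(index, "GATCIndex"))
  spac <- unlist(lapply(index$motif_starts, function(m) {
    if (length(m) >= 2L) diff(m) else numeric(0)
  }), use.names = FALSE)
  list(n_motifs = sum(lengths(index$motif_starts)),
       mean_spacing = if (length(spac)) mean(spac) else NA_real_,
       median_spacing = if (length(spac)) stats::median(spac) else NA_real_)
}

#' Write GATC motifs or fragments as BED
#'
#' Motifs are written as BED4 (\code{chrom start start+4 GATC}); fragments
#' as BED4 with the fragment ordinal as name. Coordinates stay 0-based
#' half-open, as BED requires.
#'
#' @param index A \code{GATCIndex}.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_motif_bed <- function(index, path) {
  stopifnot(inherits(index, "GATCIndex"))
  rows <- lapply(names(index$motif_starts), function(ch) {
    m <- index$motif_starts[[ch]]
    if (!length(m)) return(NULL)
    data.frame(chrom = ch, start = m, end = m + 4L, name = "GATC")
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0), name = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motif_bed
#' @param fragments A fragment data.frame from [gatc_fragments()].
#' @export
write_fragment_bed <- function(fragments, path) {
  utils::write.table(fragments[, c("chrom", "start", "end", "fragment_id")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
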