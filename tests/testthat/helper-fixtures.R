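# Shared fixture builders for the suite. Everything is generated in code;
# no binary fixtures on disk.

# FragmentCounts from a bare count vector.
make_counts <- function(x, id = "lib") {
  structure(list(library_id = id, counts = as.integer(x),
                 n_reads_in = sum(x), n_reads_kept = sum(x),
                 n_anomalous = 0L),
            class = "FragmentCounts")
}

# OccupancyTrack from a score vector over an explicit fragment table.
make_track <- function(score, fragments) {
  structure(list(score = score, fragments = fragments,
                 library_pair = c(fusion = "f", control = "c")),
            class = "OccupancyTrack")
}

# Fragment table tiling one chromosome with given interior boundaries.
tile_fragments <- function(chrom, boundaries, length) {
  b <- c(0L, as.integer(boundaries), as.integer(length))
  data.frame(chrom = chrom, start = b[-length(b)], end = b[-1L],
             fragment_id = seq_len(length(b) - 1L),
             stringsAsFactors = FALSE)
}

# Independent naive per-position GATC scan (the test oracle for the
# production scanner).
naive_gatc_scan <- function(seq) {
  n <- nchar(seq)
  if (n < 4L) return(integer(0))
  s <- toupper(seq)
  win <- substring(s, 1:(n - 3L), 4:n)
  which(win == "GATC") - 1L
}

# Random DNA string.
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Reverse complement of a plain DNA string.
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Default-preset simulated study with its derived occupancy track, shared
# by the end-to-end checks (cached per session).
preset_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_rapid(sim_params())
      fp <- filter_params()
      ff <- filter_alignments(sim$fusion_reads, sim$index, fp)
      cf <- filter_alignments(sim$control_reads, sim$index, fp)
      fc <- count_fragments(ff$kept, sim$fragments, fp, "fusion")
      cc <- count_fragments(cf$kept, sim$fragments, fp, "control")
      tr <- normalize_counts(fc, cc, norm_params(), sim$fragments)
      occ <- gene_occupancy(tr, sim$genes)
      cache <<- list(sim = sim, track = tr, occ = occ)
    }
    cache
  }
})

# Reduced-scale simulated study shared by several tests (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- sim_params(chrom_length = 400000L, n_genes = 100L,
                      n_reads_fusion = 40000L, n_reads_control = 40000L,
                      seed = 7L)
      cache <<- simulate_rapid(p)
    }
    cache
  }
})
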