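#' Simulation parameters
#'
#' Defaults define the small study condition used throughout the test
#' suite: a 2 Mb single-chromosome genome, 500 non-overlapping genes of
#' which 30% are expressed with log-normal levels, expression-dependent
#' fragment methylation with saturating kinetics, log-normal accessibility
#' weights shared by the fusion and Dam-only libraries, and 200,000
#' amplicons per library with up to 8 bp of end jitter and 10% non-GATC
#' noise reads.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp (>= 1000).
#' @param gatc_enrichment Rate multiplier for extra planted GATC motifs on
#'   top of the ~1/256 background (0 = background only).
#' @param n_genes Number of genes to place.
#' @param expressed_fraction Fraction of genes given nonzero expression
#'   (the expressed count is exact by design, not Bernoulli).
#' @param expression_meanlog,expression_sdlog Log-normal parameters of the
#'   expression levels of expressed genes (arbitrary units; the
#'   methylation saturation scale is set by \code{kappa}).
#' @param kappa Methylation saturation slope: a fragment overlapping a gene
#'   expressed at level e is methylated with probability
#'   \code{1 - exp(-kappa * e)} — low expression is near-linear, high
#'   expression plateaus (full methylation cannot increase further).
#' @param baseline Baseline fusion weight for unmethylated fragments
#'   (background amplification).
#' @param accessibility_sigma Log-scale SD of per-fragment accessibility
#'   weights (chromatin accessibility seen identically by fusion and
#'   free-Dam libraries).
#' @param n_reads_fusion,n_reads_control Amplicons per library.
#' @param end_jitter_max Uniform end jitter half-width in bp (default 8).
#' @param noise_fraction Fraction of reads whose one end is displaced at
#'   least 9 bp from any motif (library noise the amplicon filter should
#'   reject).
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene length
#'   parameters (default: around 2 kb).
#' @param min_gap,max_gap Intergenic gap range (uniform) used when no
#'   explicit gaps are supplied.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A list of class \code{SimParams}.
#' @export
sim_params <- function(n_chroms = 1L, chrom_length = 2000000L,
                       gatc_enrichment = 0, n_genes = 500L,
                       expressed_fraction = 0.3,
                       expression_meanlog = 0.5, expression_sdlog = 1,
                       kappa = 1, baseline = 0.05,
                       accessibility_sigma = 0.3,
                       n_reads_fusion = 200000L, n_reads_control = 200000L,
                       end_jitter_max = 8L, noise_fraction = 0.1,
                       gene_length_meanlog = log(2000), gene_length_sdlog = 0.3,
                       min_gap = 500L, max_gap = 2000L, seed = 1L) {
  stopifnot(n_chroms >= 1, chrom_length >= 1000, n_genes >= 1,
            expressed_fraction > 0, expressed_fraction < 1,
            kappa > 0, accessibility_sigma >= 0,
            n_reads_fusion >= 1, n_reads_control >= 1,
            end_jitter_max >= 0, noise_fraction >= 0, noise_fraction < 1)
  structure(as.list(environment()), class = "SimParams")
}

#' Simulate a genome with GATC motifs
#'
#' Bases are i.i.d. uniform over ACGT (background GATC rate 1/256 per
#' position); \code{gatc_enrichment > 0} plants additional motifs at a
#' Poisson rate of \code{gatc_enrichment / 256} per bp. Deterministic under
#' the seed in \code{params}.
#'
#' @param params A \code{SimParams}.
#' @return list with \code{genome} (named character vector of sequences)
#'   and \code{planted} (list of 0-based planted motif positions per
#'   chromosome).
#' @export
simulate_genome <- function(params = sim_params()) {
  if (params$chrom_length < 1000) stop("chrom_length too short for genes")
  with_seed(params$seed, {
    genome <- character(params$n_chroms)
    planted <- vector("list", params$n_chroms)
    names(planted) <- paste0("chr", seq_len(params$n_chroms))
    for (i in seq_len(params$n_chroms)) {
      bases <- sample(c("A", "C", "G", "T"), params$chrom_length, replace = TRUE)
      n_plant <- stats::rpois(1, params$chrom_length * params$gatc_enrichment / 256)
      pos <- integer(0)
      if (n_plant > 0) {
        pos <- sort(unique(sample.int(params$chrom_length - 4L, n_plant))) - 1L
        # drop planted sites closer than 4 bp so writes never collide
        if (length(pos) > 1L) pos <- pos[c(TRUE, diff(pos) >= 4L)]
        for (p in pos) bases[(p + 1L):(p + 4L)] <- c("G", "A", "T", "C")
      }
      genome[i] <- paste(bases, collapse = "")
      planted[[i]] <- pos
    }
    names(genome) <- names(planted)
    list(genome = genome, planted = planted)
  })
}

#' Simulate a non-overlapping gene annotation with expression truth
#'
#' Genes are laid left to right with log-normal lengths and either random
#' uniform intergenic gaps or caller-supplied \code{gaps} (recycled), on
#' alternating random strands. Exactly
#' \code{round(expressed_fraction * n_genes)} genes receive a log-normal
#' expression level; the rest are silent (level 0).
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param params A \code{SimParams}.
#' @param gaps Optional integer vector of intergenic gaps in bp (recycled),
#'   e.g. to exercise the upstream-distance marker rule.
#' @return list with \code{genes} (annotation data.frame) and
#'   \code{expression} (data.frame gene_id, expression, expressed).
#' @export
simulate_annotation <- function(chrom_lengths, params = sim_params(),
                                gaps = NULL) {
  with_seed(params$seed + 1L, {
    n <- params$n_genes
    lens <- pmax(200L, round(stats::rlnorm(n, params$gene_length_meanlog,
                                           params$gene_length_sdlog)))
    gap_vec <- if (is.null(gaps)) {
      round(stats::runif(n, params$min_gap, params$max_gap))
    } else {
      rep_len(as.integer(gaps), n)
    }
    strands <- sample(c("+", "-"), n, replace = TRUE)
    chroms <- names(chrom_lengths)
    rows <- vector("list", n)
    ci <- 1L
    cursor <- 1000L
    for (g in seq_len(n)) {
      start <- cursor + gap_vec[g]
      end <- start + lens[g]
      while (end > chrom_lengths[[ci]] - 1000L) {
        ci <- ci + 1L
        if (ci > length(chroms)) {
          stop("cannot place ", n, " genes without overlap; reduce n_genes ",
               "or enlarge the genome")
        }
        cursor <- 1000L
        start <- cursor + gap_vec[g]
        end <- start + lens[g]
      }
      rows[[g]] <- data.frame(gene_id = sprintf("gene%04d", g),
                              chrom = chroms[ci], start = start, end = end,
                              strand = strands[g], stringsAsFactors = FALSE)
      cursor <- end
    }
    genes <- do.call(rbind, rows)
    n_expr <- round(params$expressed_fraction * n)
    expressed_idx <- sample.int(n, n_expr)
    expression <- numeric(n)
    expression[expressed_idx] <- stats::rlnorm(n_expr, params$expression_meanlog,
                                               params$expression_sdlog)
    list(genes = genes,
         expression = data.frame(gene_id = genes$gene_id,
                                 expression = expression,
                                 expressed = expression > 0,
                                 stringsAsFactors = FALSE))
  })
}

#' Ground-truth fragment weights for library simulation
#'
#' Computes, per GATC fragment: the maximum expression level of any
#' overlapping gene, the saturating methylation probability
#' \code{1 - exp(-kappa * e)}, and a log-normal accessibility weight shared
#' by fusion and control libraries (the free-Dam profile measures exactly
#' this accessibility).
#'
#' @param fragments Fragment table from [gatc_fragments()].
#' @param genes,expression Annotation and expression truth from
#'   [simulate_annotation()].
#' @param params A \code{SimParams}.
#' @return list of class \code{SimTruth}: \code{fragment_expression},
#'   \code{methylation_prob}, \code{accessibility}, plus the inputs'
#'   \code{expression} table.
#' @export
simulate_truth <- function(fragments, genes, expression, params = sim_params()) {
  frag_expr <- numeric(nrow(fragments))
  for (ch in unique(fragments$chrom)) {
    fsel <- which(fragments$chrom == ch)
    gsel <- which(genes$chrom == ch)
    if (!length(gsel)) next
    fs <- fragments$start[fsel]; fe <- fragments$end[fsel]
    for (g in gsel) {
      e <- expression$expression[g]
      if (e <= 0) next
      hit <- fsel[fe > genes$start[g] & fs < genes$end[g]]
      frag_expr[hit] <- pmax(frag_expr[hit], e)
    }
  }
  meth <- pmin(1 - exp(-params$kappa * frag_expr), 1 - 1e-12)
  acc <- with_seed(params$seed + 2L,
                   stats::rlnorm(nrow(fragments), 0, params$accessibility_sigma))
  structure(list(fragment_expression = frag_expr,
                 methylation_prob = meth,
                 accessibility = acc,
                 expression = expression),
            class = "SimTruth")
}

#' Simulate an aligned DamID amplicon library
#'
#' Amplicons are runs of 1-3 consecutive GATC fragments (geometric length
#' decay, mimicking size selection), sampled with probability proportional
#' to the fragment weight: \code{accessibility * (methylation + baseline)}
#' for the fusion role, \code{accessibility} alone for the Dam-only
#' control. Read ends sit at the bounding motifs, jittered uniformly in
#' \code{[-end_jitter_max, end_jitter_max]}; a \code{noise_fraction} of
#' reads has one end displaced at least 9 bp from any motif. Records are
#' emitted directly as coordinate-level alignments, so no aligner is
#' needed.
#'
#' @param index \code{GATCIndex} of the simulated genome.
#' @param fragments Fragment table.
#' @param truth A \code{SimTruth}.
#' @param params A \code{SimParams}.
#' @param role \code{"fusion"} or \code{"control"}.
#' @return data.frame of alignment records (\code{read_id}, \code{chrom},
#'   \code{ref_start}, \code{ref_end}, \code{mapq}, \code{secondary},
#'   \code{supplementary}, \code{noise}) where \code{noise} flags the
#'   planted non-amplicon reads.
#' @export
simulate_damid_library <- function(index, fragments, truth,
                                   params = sim_params(),
                                   role = c("fusion", "control")) {
  role <- match.arg(role)
  n_reads <- if (role == "fusion") params$n_reads_fusion else params$n_reads_control
  w <- if (role == "fusion") {
    truth$accessibility * (truth$methylation_prob + params$baseline)
  } else {
    truth$accessibility
  }
  # only fragments whose two bounds are genuine motifs can seed an amplicon
  interior <- rep(TRUE, nrow(fragments))
  for (ch in unique(fragments$chrom)) {
    sel <- which(fragments$chrom == ch)
    interior[sel[1L]] <- FALSE
    interior[sel[length(sel)]] <- FALSE
  }
  w <- w * interior
  if (sum(w) <= 0) stop("zero total fragment weight")
  seed_off <- if (role == "fusion") 3L else 4L
  with_seed(params$seed + seed_off, {
    start_frag <- sample.int(nrow(fragments), n_reads, replace = TRUE, prob = w)
    # run length 1-3 with geometric decay (p = 0.5, truncated)
    run <- sample(1:3, n_reads, replace = TRUE, prob = c(4, 2, 1) / 7)
    chrom <- fragments$chrom[start_frag]
    # clip runs at the last interior fragment of the chromosome
    chrom_last <- tapply(seq_len(nrow(fragments)), fragments$chrom,
                         function(i) max(i[interior[i]]))
    end_frag <- pmin(start_frag + run - 1L, as.integer(chrom_last[chrom]))
    rs <- fragments$start[start_frag]
    re <- fragments$end[end_frag] + 4L   # right motif interval end
    jmax <- params$end_jitter_max
    j1 <- sample.int(2L * jmax + 1L, n_reads, replace = TRUE) - jmax - 1L
    j2 <- sample.int(2L * jmax + 1L, n_reads, replace = TRUE) - jmax - 1L
    rs <- rs + j1
    re <- re + j2
    noise <- stats::runif(n_reads) < params$noise_fraction
    for (i in which(noise)) {
      m <- index$motif_starts[[chrom[i]]]
      clen <- index$chrom_lengths[[chrom[i]]]
      for (attempt in 1:50) {
        shift <- sample(c(-1, 1), 1) * sample(9:60, 1)
        cand <- re[i] + shift
        if (cand > rs[i] + 4 && cand <= clen && .motif_distance(cand, m) >= 9) {
          re[i] <- cand
          break
        }
      }
    }
    rs <- pmax(rs, 0L)
    re <- pmin(re, as.integer(index$chrom_lengths[chrom]))  # stay on reference
    re <- pmax(re, rs + 1L)   # jitter on a minimal fragment cannot invert a read
    data.frame(read_id = sprintf("%s_read%07d", role, seq_len(n_reads)),
               chrom = chrom,
               ref_start = as.integer(rs),
               ref_end = as.integer(re),
               mapq = 60L,
               secondary = FALSE,
               supplementary = FALSE,
               noise = noise,
               stringsAsFactors = FALSE)
  })
}

#' Complete small simulated study
#'
#' One call producing every fixture the pipeline consumes: genome, GATC
#' index and fragments, annotation with expression truth, fragment-level
#' truth, and fusion plus control alignment records.
#'
#' @param params A \code{SimParams}; [sim_params()] defaults are the small
#'   preset.
#' @return list with \code{params}, \code{genome}, \code{index},
#'   \code{fragments}, \code{genes}, \code{expression}, \code{truth},
#'   \code{fusion_reads}, \code{control_reads}.
#' @export
simulate_rapid <- function(params = sim_params()) {
  gen <- simulate_genome(params)
  index <- gatc_index(gen$genome)
  fragments <- gatc_fragments(index)
  ann <- simulate_annotation(index$chrom_lengths, params)
  truth <- simulate_truth(fragments, ann$genes, ann$expression, params)
  fusion <- simulate_damid_library(index, fragments, truth, params, "fusion")
  control <- simulate_damid_library(index, fragments, truth, params, "control")
  list(params = params, genome = gen$genome, index = index,
       fragments = fragments, genes = ann$genes,
       expression = ann$expression, truth = truth,
       fusion_reads = fusion, control_reads = control)
}

#' Write simulated alignment records as SAM
#'
#' Minimal single-end SAM with fully matched CIGARs, loadable by samtools
#' and [read_alignments()].
#'
#' @param reads Alignment record data.frame from
#'   [simulate_damid_library()].
#' @param chrom_lengths Named lengths for the header.
#' @param path Output path (.sam).
#' @export
write_sam <- function(reads, chrom_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (ch in names(chrom_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, chrom_lengths[[ch]]), con)
  }
  len <- reads$ref_end - reads$ref_start
  writeLines(sprintf("%s\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                     reads$read_id, reads$chrom, reads$ref_start + 1L,
                     reads$mapq, len), con)
  invisible(path)
}

#' Write a genome as FASTA
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              width = width)
  invisible(path)
}
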