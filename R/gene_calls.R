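#' Read gene annotations from BED or GFF
#'
#' Imports BED (0-based half-open, used as-is) or GFF/GTF (1-based closed,
#' converted) gene annotations into the plain table the calling functions
#' consume. For GFF, rows of type \code{gene} are used when present.
#'
#' @param path Annotation file (.bed, .gff, .gff3, .gtf).
#' @return data.frame with \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{strand}.
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if ("type" %in% names(df) && any(df$type == "gene")) df <- df[df$type == "gene", ]
  id <- if ("gene_id" %in% names(df)) df$gene_id
        else if ("ID" %in% names(df)) df$ID
        else if ("Name" %in% names(df)) df$Name
        else if ("name" %in% names(df)) df$name
        else paste0("gene", seq_len(nrow(df)))
  data.frame(gene_id = as.character(id),
             chrom = as.character(df$seqnames),
             start = df$start - 1L,   # GRanges is 1-based closed
             end = df$end,
             strand = as.character(df$strand),
             stringsAsFactors = FALSE)
}

#' Gene-call parameters
#'
#' @param alpha FDR threshold for calling a gene expressed (default 0.05).
#' @param n_permutations Number of genome-wide fragment-score permutations
#'   behind the null distribution (default 10000, minimum 100).
#' @param min_fragments_per_gene Genes overlapping fewer fragments than this
#'   are reported with NA p-values.
#' @param seed RNG seed making the permutation p-values reproducible.
#' @return A list of class \code{CallParams}.
#' @export
call_params <- function(alpha = 0.05, n_permutations = 10000L,
                        min_fragments_per_gene = 1L, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, n_permutations >= 100)
  structure(list(alpha = alpha,
                 n_permutations = as.integer(n_permutations),
                 min_fragments_per_gene = as.integer(min_fragments_per_gene),
                 seed = as.integer(seed)),
            class = "CallParams")
}

#' Per-gene occupancy from a fragment track
#'
#' The gene-level polymerase occupancy value is the overlap-length-weighted
#' mean of the scores of the fragments intersecting the gene body
#' (annotation start to end, introns included: the polymerase transits
#' introns, and DamID cannot resolve isoforms).
#'
#' @param track An \code{OccupancyTrack} with its fragment table.
#' @param genes Gene annotation data.frame (see [read_genes()]).
#' @return data.frame with \code{gene_id}, \code{occupancy},
#'   \code{n_fragments}.
#' @export
gene_occupancy <- function(track, genes) {
  fr <- track$fragments
  if (is.null(fr)) stop("track carries no fragment table")
  occ <- numeric(nrow(genes))
  nfr <- integer(nrow(genes))
  frag_by_chrom <- split(seq_len(nrow(fr)), fr$chrom)
  for (ch in unique(genes$chrom)) {
    idx <- frag_by_chrom[[ch]]
    if (is.null(idx)) stop("chromosome ", ch, " absent from track")
    fs <- fr$start[idx]; fe <- fr$end[idx]; sc <- track$score[idx]
    clen <- fe[length(fe)]
    gsel <- which(genes$chrom == ch)
    gs <- genes$start[gsel]; ge <- genes$end[gsel]
    bad <- gs < 0 | ge > clen | gs >= ge
    if (any(bad)) stop("gene outside chromosome bounds: ",
                       genes$gene_id[gsel[bad][1L]])
    # fragments tile, so the overlapping set is the contiguous run
    first <- findInterval(gs, fs)          # fragment containing gene start
    last <- findInterval(ge - 1L, fs)      # fragment containing last base
    for (k in seq_along(gsel)) {
      j <- first[k]:last[k]
      w <- pmin(ge[k], fe[j]) - pmax(gs[k], fs[j])
      occ[gsel[k]] <- sum(w * sc[j]) / sum(w)
      nfr[gsel[k]] <- length(j)
    }
  }
  data.frame(gene_id = genes$gene_id, occupancy = occ, n_fragments = nfr,
             stringsAsFactors = FALSE)
}

# Null distributions of mean fragment score for every stratum of gene
# fragment count: B permutations, each contributing its first-k mean for
# all k at once via cumulative sums.
.permutation_nulls <- function(scores, strata, B) {
  max_k <- max(strata)
  n <- length(scores)
  replace_draw <- max_k > n
  if (replace_draw) {
    warning("gene fragment count exceeds fragment total; sampling with replacement")
  }
  draws <- matrix(0, nrow = max_k, ncol = B)
  for (b in seq_len(B)) {
    draws[, b] <- sample(scores, max_k, replace = replace_draw)
  }
  cm <- apply(draws, 2L, cumsum) / seq_len(max_k)   # max_k x B matrix of means
  if (max_k == 1L) cm <- matrix(cm, nrow = 1L)
  lapply(stats::setNames(strata, strata), function(k) sort(cm[k, ]))
}

#' Call significantly footprinted genes
#'
#' Empirical permutation test: for a gene overlapping \code{k} fragments,
#' the null is the mean of \code{k} fragment scores drawn from a
#' genome-wide permutation of the track, with the null computed per
#' fragment-count stratum. P-values are plus-one corrected,
#' \eqn{p = (1 + \#\{null \ge obs\}) / (B + 1)}, and adjusted by
#' Benjamini-Hochberg across all tested genes. Deterministic for a fixed
#' seed.
#'
#' @param values Per-gene table from [gene_occupancy()].
#' @param track The \code{OccupancyTrack} the values came from.
#' @param params A \code{CallParams}.
#' @return data.frame of class \code{rapid_calls} with \code{gene_id},
#'   \code{occupancy}, \code{p_value}, \code{fdr}, \code{n_fragments};
#'   attribute \code{alpha} carries the calling threshold.
#' @export
call_expressed <- function(values, track, params = call_params()) {
  if (nrow(values) < 10L) stop("need at least 10 genes to calibrate an FDR")
  scores <- track$score
  B <- params$n_permutations
  testable <- values$n_fragments >= params$min_fragments_per_gene &
    values$n_fragments > 0L
  p <- rep(NA_real_, nrow(values))
  strata <- sort(unique(values$n_fragments[testable]))
  nulls <- with_seed(params$seed, .permutation_nulls(scores, strata, B))
  for (k in strata) {
    sel <- testable & values$n_fragments == k
    nk <- nulls[[as.character(k)]]
    # count of null >= obs via sorted lookup (exact under ties)
    n_ge <- B - findInterval(values$occupancy[sel], nk, left.open = TRUE)
    p[sel] <- (1 + n_ge) / (B + 1)
  }
  fdr <- rep(NA_real_, length(p))
  fdr[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  out <- data.frame(gene_id = values$gene_id,
                    occupancy = values$occupancy,
                    p_value = p, fdr = fdr,
                    n_fragments = values$n_fragments,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- params$alpha
  class(out) <- c("rapid_calls", "data.frame")
  out
}

# Evaluate code under a fixed seed, restoring the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(seed)
  code
}

#' @export
print.rapid_calls <- function(x, ...) {
  a <- attr(x, "alpha") %||% 0.05
  cat("Gene calls: ", nrow(x), " genes, ",
      sum(x$fdr < a, na.rm = TRUE), " with FDR < ", a, "\n", sep = "")
  NextMethod()
}

#' Significant gene set of one or more replicates
#'
#' \code{mode = "any"} returns genes significant (FDR below alpha) in at
#' least one replicate (the "detected" set); \code{mode = "all"} requires
#' every replicate (the "consistently detected" set). Replicates with
#' different gene universes are restricted to the common universe with a
#' warning.
#'
#' @param calls A \code{rapid_calls} or list of them (one per replicate).
#' @param mode \code{"any"} or \code{"all"}.
#' @param alpha FDR threshold (default 0.05).
#' @return Character vector of gene ids.
#' @export
detected_set <- function(calls, mode = c("any", "all"), alpha = 0.05) {
  mode <- match.arg(mode)
  if (inherits(calls, "data.frame")) calls <- list(calls)
  stopifnot(length(calls) >= 1L)
  universes <- lapply(calls, function(x) x$gene_id)
  common <- Reduce(intersect, universes)
  if (any(lengths(universes) != length(common))) {
    warning("replicate gene universes differ; restricted to ",
            length(common), " common genes")
  }
  sig <- lapply(calls, function(x) {
    x$gene_id[!is.na(x$fdr) & x$fdr < alpha & x$gene_id %in% common]
  })
  if (mode == "any") Reduce(union, sig) else Reduce(intersect, sig)
}

#' Partition tissue gene sets into unique and shared regions
#'
#' Given the consistently detected gene set of each tissue, computes the
#' tissue-unique sets (genes in exactly that tissue's set), the genes shared
#' by all tissues, and the full Venn region table.
#'
#' @param sets Named list (length >= 2) of character vectors of gene ids.
#' @return list with \code{unique} (named list), \code{shared_all},
#'   \code{regions}: data.frame of all 2^k - 1 membership patterns with
#'   exclusive region counts.
#' @export
tissue_partition <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  k <- length(sets)
  uniq <- lapply(seq_len(k), function(i) {
    setdiff(sets[[i]], Reduce(union, sets[-i]))
  })
  names(uniq) <- names(sets)
  shared_all <- Reduce(intersect, sets)
  univ <- Reduce(union, sets)
  member <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1L) member <- matrix(member, nrow = 1L)
  pat <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  names(pat) <- names(sets)
  counts <- apply(pat, 1L, function(row) {
    sum(apply(member, 1L, function(m) all(m == row)))
  })
  regions <- cbind(pat, count = counts)
  rownames(regions) <- NULL
  list(unique = uniq, shared_all = shared_all, regions = regions)
}

#' Refine tissue-unique genes into marker candidates
#'
#' A marker gene for a rare cell type should give no signal in whole-animal
#' samples and should not sit immediately downstream of another transcript
#' (a possible operon, where the promoter would not report the candidate's
#' own transcription). Candidates are therefore the target tissue's unique
#' genes minus (i) genes detected in any whole-animal replicate and (ii)
#' genes whose strand-aware upstream neighbor ends strictly less than
#' \code{upstream_gap} bp before their start (a neighbor exactly
#' \code{upstream_gap} bp away is retained).
#'
#' @param unique_set Character vector: the target tissue's unique genes.
#' @param whole_detected Character vector: genes detected in at least one
#'   whole-animal replicate (see [detected_set()] with \code{mode="any"}).
#' @param genes Full annotation table ([read_genes()]); used to locate
#'   upstream neighbors.
#' @param upstream_gap Exclusion distance in bp (default 200).
#' @param neighbor_strand \code{"same"} (default; operons run in one
#'   direction) or \code{"any"}.
#' @return Character vector of candidate gene ids.
#' @export
marker_candidates <- function(unique_set, whole_detected, genes,
                              upstream_gap = 200L,
                              neighbor_strand = c("same", "any")) {
  neighbor_strand <- match.arg(neighbor_strand)
  cand <- setdiff(unique_set, whole_detected)
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    g <- genes[genes$gene_id == cand[i], ]
    if (nrow(g) == 0L) { keep[i] <- FALSE; next }
    if (is.na(g$strand) || !g$strand %in% c("+", "-")) {
      warning("gene ", cand[i], " lacks strand; excluded")
      keep[i] <- FALSE
      next
    }
    nb <- genes[genes$chrom == g$chrom & genes$gene_id != g$gene_id, ]
    if (neighbor_strand == "same") nb <- nb[nb$strand == g$strand, ]
    # strand-aware gap to upstream neighbors only
    gap <- if (g$strand == "+") {
      g$start - nb$end[nb$end <= g$start]
    } else {
      nb$start[nb$start >= g$end] - g$end
    }
    keep[i] <- !any(gap < upstream_gap)
  }
  cand[keep]
}

#' Overlap of two gene sets
#'
#' @param a,b Character vectors of gene ids.
#' @return list with \code{count} and \code{fraction} (share of \code{a}
#'   covered; \code{NA} when \code{a} is empty).
#' @export
set_overlap <- function(a, b) {
  ov <- length(intersect(a, b))
  list(count = ov,
       fraction = if (length(unique(a)) == 0L) NA_real_ else ov / length(unique(a)))
}

#' Compare occupancy of a gene subset with its parent set
#'
#' Classical two-sample Student's t-test with pooled variance, reporting
#' the group means and SDs alongside the statistic — used to check that a
#' selected candidate subset is representative of the set it came from.
#'
#' @param subset_values,full_values Numeric occupancy vectors (>= 2 each).
#' @return list with \code{t}, \code{p_value}, \code{mean_subset},
#'   \code{sd_subset}, \code{mean_full}, \code{sd_full}, \code{df}.
#' @export
subset_similarity_test <- function(subset_values, full_values) {
  stopifnot(length(subset_values) >= 2L, length(full_values) >= 2L)
  if (stats::var(subset_values) == 0 && stats::var(full_values) == 0) {
    stop("zero pooled variance; t-test undefined")
  }
  tt <- stats::t.test(subset_values, full_values, var.equal = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_subset = mean(subset_values), sd_subset = stats::sd(subset_values),
       mean_full = mean(full_values), sd_full = stats::sd(full_values),
       df = unname(tt$parameter))
}

#' Write per-gene calls as TSV
#' @param calls A \code{rapid_calls}.
#' @param path Output path.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
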