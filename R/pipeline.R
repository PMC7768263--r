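#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent nested list) with a
#' \code{paths} block (genome FASTA, gene annotation, output directory), a
#' \code{libraries} list of \code{\{id, tissue, replicate, fusion,
#' control\}} alignment-file pairs, optional parameter blocks
#' (\code{filter}, \code{norm}, \code{call}, \code{profile}) overriding the
#' stage defaults, and a global \code{seed}. Defaults equal the standard
#' assay values where one exists: end tolerance 8 bp, read extension 0,
#' alpha 0.05, ChIP pseudocount 8, gene bin size 690.
#'
#' All validation problems are reported at once.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated config of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  errs <- character(0)
  if (is.null(config$paths$output_dir)) errs <- c(errs, "paths$output_dir missing")
  if (is.null(config$paths$genome)) {
    errs <- c(errs, "paths$genome missing")
  } else if (!file.exists(config$paths$genome)) {
    errs <- c(errs, paste0("paths$genome not found: ", config$paths$genome))
  }
  if (!is.null(config$paths$genes) && !file.exists(config$paths$genes)) {
    errs <- c(errs, paste0("paths$genes not found: ", config$paths$genes))
  }
  if (is.null(config$libraries) || !length(config$libraries)) {
    errs <- c(errs, "libraries missing or empty")
  } else {
    for (i in seq_along(config$libraries)) {
      lb <- config$libraries[[i]]
      for (fld in c("id", "fusion", "control")) {
        if (is.null(lb[[fld]])) {
          errs <- c(errs, sprintf("libraries[[%d]]$%s missing", i, fld))
        }
      }
      for (fld in c("fusion", "control")) {
        if (!is.null(lb[[fld]]) && !file.exists(lb[[fld]])) {
          errs <- c(errs, sprintf("libraries[[%d]]$%s not found: %s", i, fld, lb[[fld]]))
        }
      }
    }
  }
  al <- config$call$alpha
  if (!is.null(al) && (al <= 0 || al >= 1)) {
    errs <- c(errs, "call$alpha must lie in (0, 1)")
  }
  tol <- config$filter$end_tolerance
  if (!is.null(tol) && tol < 0) errs <- c(errs, "filter$end_tolerance must be >= 0")
  if (length(errs)) stop("invalid pipeline config:\n  - ",
                         paste(errs, collapse = "\n  - "))
  config$seed <- config$seed %||% 1L
  class(config) <- c("PipelineConfig", "list")
  config
}

# Stable stage seeds derived from the global seed, so adding a stage never
# shifts another stage's random stream.
.stage_seed <- function(seed, stage) {
  offsets <- c(index = 0L, filter = 101L, normalize = 211L, call = 307L,
               sets = 401L, profiles = 503L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full footprinting pipeline
#'
#' Executes index, filter, normalize, call, set-algebra and profile stages
#' in order, writing every artifact as a plain-text table under the
#' configured output directory, and returns (and writes) a manifest listing
#' each output with its MD5 checksum and the configuration hash. Rerunning
#' with an identical config and seed reproduces byte-identical outputs.
#'
#' @param config A \code{PipelineConfig}, YAML path or list (validated via
#'   [pipeline_config()]).
#' @return The manifest, invisibly a list with \code{config_hash},
#'   \code{stages}, \code{outputs}.
#' @export
run_rapid_pipeline <- function(config) {
  config <- pipeline_config(config)
  outdir <- config$paths$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(config), stages = character(0),
                   outputs = list())
  record <- function(stage, path) {
    manifest$stages <<- union(manifest$stages, stage)
    manifest$outputs[[basename(path)]] <<- list(
      path = path, stage = stage, md5 = unname(tools::md5sum(path)))
  }
  fail <- function(stage, e) {
    manifest$error <<- list(stage = stage, message = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }

  # --- index
  idx <- tryCatch({
    index <- gatc_index(config$paths$genome)
    fragments <- gatc_fragments(index)
    write_fragment_bed(fragments, file.path(outdir, "fragments.bed"))
    st <- gatc_stats(index)
    utils::write.table(data.frame(n_motifs = st$n_motifs,
                                  mean_spacing = st$mean_spacing,
                                  median_spacing = st$median_spacing),
                       file.path(outdir, "gatc_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(index = index, fragments = fragments)
  }, error = function(e) fail("index", e))
  record("index", file.path(outdir, "fragments.bed"))
  record("index", file.path(outdir, "gatc_stats.tsv"))

  fparams <- do.call(filter_params, config$filter %||% list())
  nparams <- do.call(norm_params, config$norm %||% list())
  cseed <- .stage_seed(config$seed, "call")
  cp_args <- config$call %||% list()
  cp_args$seed <- cp_args$seed %||% cseed
  cparams <- do.call(call_params, cp_args)
  pparams <- do.call(profile_params, config$profile %||% list())

  genes <- if (!is.null(config$paths$genes)) read_genes(config$paths$genes) else NULL

  calls_by_lib <- list()
  for (lb in config$libraries) {
    stage <- paste0("filter:", lb$id)
    res <- tryCatch({
      fus_reads <- read_alignments(lb$fusion)
      ctl_reads <- read_alignments(lb$control)
      fus_f <- filter_alignments(fus_reads, idx$index, fparams)
      ctl_f <- filter_alignments(ctl_reads, idx$index, fparams)
      fus_c <- count_fragments(fus_f$kept, idx$fragments, fparams,
                               library_id = paste0(lb$id, "_fusion"),
                               n_reads_in = fus_f$report$n_reads_in)
      ctl_c <- count_fragments(ctl_f$kept, idx$fragments, fparams,
                               library_id = paste0(lb$id, "_control"),
                               n_reads_in = ctl_f$report$n_reads_in)
      p1 <- file.path(outdir, paste0(lb$id, "_fusion_counts.tsv"))
      p2 <- file.path(outdir, paste0(lb$id, "_control_counts.tsv"))
      write_counts_tsv(fus_c, idx$fragments, p1)
      write_counts_tsv(ctl_c, idx$fragments, p2)
      list(fusion = fus_c, control = ctl_c, paths = c(p1, p2),
           reports = list(fusion = fus_f$report, control = ctl_f$report))
    }, error = function(e) fail(stage, e))
    for (p in res$paths) record(stage, p)

    stage <- paste0("normalize:", lb$id)
    track <- tryCatch({
      tr <- normalize_counts(res$fusion, res$control, nparams, idx$fragments)
      tp <- file.path(outdir, paste0(lb$id, "_track.bedgraph"))
      write_track(tr, tp)
      write_track(tr, file.path(outdir, paste0(lb$id, "_track.tsv")), tsv = TRUE)
      tr
    }, error = function(e) fail(stage, e))
    record(stage, file.path(outdir, paste0(lb$id, "_track.bedgraph")))
    record(stage, file.path(outdir, paste0(lb$id, "_track.tsv")))

    if (!is.null(genes)) {
      stage <- paste0("call:", lb$id)
      calls <- tryCatch({
        occ <- gene_occupancy(track, genes)
        cl <- call_expressed(occ, track, cparams)
        cpth <- file.path(outdir, paste0(lb$id, "_calls.tsv"))
        write_calls_tsv(cl, cpth)
        cl
      }, error = function(e) fail(stage, e))
      record(stage, file.path(outdir, paste0(lb$id, "_calls.tsv")))
      calls_by_lib[[lb$id]] <- calls
    }
  }

  # --- set algebra across tissues (when tissue labels and calls exist)
  tissues <- unique(vapply(config$libraries, function(lb) lb$tissue %||% lb$id,
                           character(1)))
  if (length(calls_by_lib) && length(tissues) >= 2L) {
    sets <- tryCatch({
      consistent <- lapply(tissues, function(tn) {
        ids <- vapply(config$libraries, function(lb) (lb$tissue %||% lb$id) == tn,
                      logical(1))
        detected_set(calls_by_lib[vapply(config$libraries[ids], `[[`, "", "id")],
                     mode = "all", alpha = cparams$alpha)
      })
      names(consistent) <- tissues
      part <- tissue_partition(consistent)
      for (tn in tissues) {
        writeLines(sort(part$unique[[tn]]),
                   file.path(outdir, paste0("unique_", tn, ".txt")))
      }
      utils::write.table(part$regions, file.path(outdir, "venn_regions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      part
    }, error = function(e) fail("sets", e))
    for (tn in tissues) record("sets", file.path(outdir, paste0("unique_", tn, ".txt")))
    record("sets", file.path(outdir, "venn_regions.tsv"))
  }

  # --- profiles (metagene of the first library's track)
  if (!is.null(genes) && length(config$libraries)) {
    lb1 <- config$libraries[[1L]]
    tr1 <- read_track_tsv(file.path(outdir, paste0(lb1$id, "_track.tsv")))
    prof <- tryCatch(metagene(tr1, genes, pparams),
                     error = function(e) fail("profiles", e))
    write_metagene_tsv(prof, file.path(outdir, "metagene.tsv"))
    record("profiles", file.path(outdir, "metagene.tsv"))
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Hash of a pipeline configuration
#'
#' MD5 of the deterministically serialized parameter content (paths block
#' excluded from hashing only for the output directory). Changes iff any
#' parameter changes.
#'
#' @param config A \code{PipelineConfig} or list.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$paths$output_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(cfg, file = tmp)
  unname(tools::md5sum(tmp))
}
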