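# End-to-end orchestration: scores -> p-values -> target matrix -> screen ->
# rank product -> q-values -> selection -> CRM calling, with a manifest that
# makes the run reproducible from one file.

#' Assemble a pipeline configuration
#'
#' Bundles the input paths and the per-stage parameter objects. All
#' randomness in the run derives from `seed` (it overrides the screen
#' config's seed so one number reproduces the whole experiment).
#'
#' @param annotation Path to the gene annotation TSV (or BED6).
#' @param peaks_dir Directory with one BED per TF.
#' @param foreground Path to a plain-text foreground gene list (one id per
#'   line).
#' @param out_dir Output directory.
#' @param evidence_dir Optional directory of evidence-track BEDs.
#' @param annotation_format `"tsv"` or `"bed"`.
#' @param decay A [decay_params()].
#' @param target_cutoff Empirical p-value cutoff for the target matrix
#'   (default 0.01).
#' @param screen A [screen_config()].
#' @param crm A [crm_params()].
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(annotation, peaks_dir, foreground, out_dir,
                            evidence_dir = NULL,
                            annotation_format = "tsv",
                            decay = decay_params(), target_cutoff = 0.01,
                            screen = screen_config(), crm = crm_params(),
                            seed = 1L) {
  stopifnot(inherits(decay, "decay_params"), inherits(screen, "screen_config"),
            inherits(crm, "crm_params"))
  if (!is_scalar_number(target_cutoff) || target_cutoff <= 0 ||
      target_cutoff > 1) {
    abort("target_cutoff must lie in (0, 1]")
  }
  screen$seed <- as.integer(seed)
  structure(list(annotation = annotation, peaks_dir = peaks_dir,
                 foreground = foreground, out_dir = out_dir,
                 evidence_dir = evidence_dir,
                 annotation_format = annotation_format,
                 decay = decay, target_cutoff = target_cutoff,
                 screen = screen, crm = crm, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `annotation`, `peaks_dir`, `foreground`,
#' `out_dir`, `evidence_dir`, `annotation_format`, `seed`, `target_cutoff`,
#' and blocks `decay` (`window_bp`, `alpha`, `beta`), `screen`
#' (`n_background_sets`, `background_set_size`, `n_replicates`, `q_cutoff`,
#' `n_permutations`, `seed`) and `crm` (the [crm_params()] fields). Missing
#' entries fall back to the package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!grepl("\\.ya?ml$", path)) {
    abort("config file must be YAML (.yaml/.yml)")
  }
  y <- yaml::read_yaml(path)
  cfg_call <- function(fun, block) do.call(fun, block %||% list())
  pipeline_config(
    annotation = y$annotation, peaks_dir = y$peaks_dir,
    foreground = y$foreground, out_dir = y$out_dir,
    evidence_dir = y$evidence_dir,
    annotation_format = y$annotation_format %||% "tsv",
    decay = cfg_call(decay_params, y$decay),
    target_cutoff = y$target_cutoff %||% 0.01,
    screen = cfg_call(screen_config, y$screen),
    crm = cfg_call(crm_params, y$crm),
    seed = y$seed %||% (y$screen$seed %||% 1L)
  )
}

#' Run the full pipeline
#'
#' Executes every stage in order and writes `scores.tsv`, `pvalues.tsv`,
#' `targets.tsv`, `ranking.tsv`, `crm.bed`, `crm.tsv` and `manifest.json`
#' under `config$out_dir`. Rerunning with the same configuration
#' byte-reproduces every output; the screen stage can equivalently be resumed
#' from a saved `targets.tsv` via [read_matrix_tsv()] +
#' [discover_regulators()]. Progress is reported to stderr; any stage error
#' aborts with the stage name.
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @param verbose Emit per-stage progress messages (default `TRUE`).
#' @return Invisibly, a list with the in-memory stage results
#'   (`annotation`, `foreground`, `scores`, `pvalues`, `targets`, `screen`,
#'   `top_regulators`, `crm`) and `paths` to the written files.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) inform(paste0("[crmscreen] ", ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    scores = file.path(config$out_dir, "scores.tsv"),
    pvalues = file.path(config$out_dir, "pvalues.tsv"),
    targets = file.path(config$out_dir, "targets.tsv"),
    ranking = file.path(config$out_dir, "ranking.tsv"),
    crm_bed = file.path(config$out_dir, "crm.bed"),
    crm_tsv = file.path(config$out_dir, "crm.tsv"),
    manifest = file.path(config$out_dir, "manifest.json")
  )

  say("reading inputs")
  ann <- stage("read_annotation",
               read_gene_annotation(config$annotation,
                                    config$annotation_format))
  peaks <- stage("read_peaks", read_peaks_dir(config$peaks_dir))
  fg <- stage("read_foreground", {
    x <- readr::read_lines(config$foreground, progress = FALSE)
    x[nzchar(x)]
  })
  evidence <- NULL
  if (!is.null(config$evidence_dir)) {
    evidence <- stage("read_evidence", read_peaks_dir(config$evidence_dir))
  }

  say("scoring regulatory potential (", length(unique(peaks$tf)), " TFs x ",
      nrow(ann), " genes)")
  scores <- stage("score_matrix", score_matrix(ann, peaks, config$decay))
  write_matrix_tsv(scores, paths$scores)

  say("computing empirical p-values")
  pvals <- stage("empirical_pvalues", empirical_pvalues(scores))
  write_matrix_tsv(pvals, paths$pvalues)

  say("building target matrix at cutoff ", config$target_cutoff)
  targets <- stage("build_target_matrix",
                   build_target_matrix(pvals, config$target_cutoff))
  write_matrix_tsv(targets, paths$targets)

  say("screening regulators (", config$screen$n_replicates, " replicates x ",
      config$screen$n_background_sets, " background sets, seed ",
      config$screen$seed, ")")
  screen_res <- stage("discover_regulators",
                      discover_regulators(targets, ann, fg, config$screen))
  write_ranking(screen_res, paths$ranking)
  top <- select_top_regulators(screen_res)
  say("selected ", length(top), " top regulator(s): ",
      paste(top, collapse = ", "))

  say("calling CRM near ", length(fg), " foreground gene(s)")
  crm <- stage("call_crm", {
    top_peaks <- peaks[peaks$tf %in% top, , drop = FALSE]
    call_crm(fg, ann, top_peaks, evidence = evidence, params = config$crm)
  })
  write_crm(crm, paths$crm_bed, paths$crm_tsv)
  say("called ", nrow(crm), " candidate CRM")

  write_manifest(config, paths)
  invisible(list(annotation = ann, foreground = fg, scores = scores,
                 pvalues = pvals, targets = targets, screen = screen_res,
                 top_regulators = top, crm = crm, paths = paths))
}

# Manifest: every parameter, the seed, and md5 checksums of inputs and
# outputs. Contains nothing run-dependent beyond these, so identical runs
# write identical manifests.
write_manifest <- function(config, paths) {
  input_files <- c(annotation = config$annotation,
                   foreground = config$foreground)
  peak_files <- list.files(config$peaks_dir, pattern = "\\.bed$",
                           full.names = TRUE)
  input_files <- c(input_files,
                   setNames(peak_files, paste0("peaks/", basename(peak_files))))
  if (!is.null(config$evidence_dir)) {
    ev_files <- list.files(config$evidence_dir, pattern = "\\.bed$",
                           full.names = TRUE)
    input_files <- c(input_files,
                     setNames(ev_files,
                              paste0("evidence/", basename(ev_files))))
  }
  out_files <- unlist(paths[names(paths) != "manifest"])
  manifest <- list(
    package = "crmscreen",
    version = as.character(utils::packageVersion("crmscreen")),
    config = list(
      annotation = config$annotation, peaks_dir = config$peaks_dir,
      foreground = config$foreground, out_dir = config$out_dir,
      evidence_dir = config$evidence_dir,
      annotation_format = config$annotation_format,
      decay = unclass(config$decay),
      target_cutoff = config$target_cutoff,
      screen = unclass(config$screen),
      crm = unclass(config$crm),
      seed = config$seed
    ),
    input_md5 = as.list(tools::md5sum(input_files)),
    output_md5 = as.list(setNames(unname(tools::md5sum(out_files)),
                                  basename(unname(out_files))))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(paths$manifest)
}

#' Rebuild a pipeline configuration from a run manifest
#'
#' The manifest written by [run_pipeline()] records every parameter and seed;
#' this reconstructs the `pipeline_config`, so the manifest alone is enough
#' to reproduce a run whose inputs are still in place.
#'
#' @param path Path to a `manifest.json`.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- m$config
  pipeline_config(
    annotation = cfg$annotation, peaks_dir = cfg$peaks_dir,
    foreground = cfg$foreground, out_dir = cfg$out_dir,
    evidence_dir = cfg$evidence_dir,
    annotation_format = cfg$annotation_format,
    decay = do.call(decay_params, as.list(cfg$decay)),
    target_cutoff = cfg$target_cutoff,
    screen = do.call(screen_config, as.list(cfg$screen)),
    crm = do.call(crm_params, as.list(cfg$crm)),
    seed = cfg$seed
  )
}
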