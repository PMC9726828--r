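# Synthetic annotation and per-TF peak sets with planted regulator
# enrichment, so every pipeline stage is testable without external data.

#' Simulation configuration
#'
#' Emulates the statistical structure the screen assumes: a single
#' chromosome, a gene universe with uniformly placed TSSs, per-TF genome-wide
#' background binding at a Poisson rate, and a configurable subset of
#' "planted" TFs that additionally bind near every foreground TSS. Defaults
#' describe the desk-scale study conditions: 200 genes and 20 TFs on a 10 Mb
#' chromosome, a 4-gene foreground, 300 expected background peaks per TF
#' (about one per 33 kb), 200 bp peaks, and planted peaks placed with
#' probability 1 within 1500 bp of each foreground TSS.
#'
#' @param n_genes Number of genes (default 200).
#' @param chrom_length_bp Chromosome length (default 1e7).
#' @param n_tfs Number of TFs, named `TF01..` (default 20).
#' @param planted_tfs Planted TFs, as names or integer indices (default none:
#'   a null dataset with exchangeable TFs).
#' @param n_foreground Foreground size (default 4, mirroring a small set of
#'   highly cell-type-specific genes).
#' @param background_peak_rate Expected background peaks per TF (default 300).
#' @param peak_width_bp Peak width (default 200).
#' @param planted_bind_prob Probability a planted TF places a peak near each
#'   foreground TSS (default 1).
#' @param planted_offset_max_bp Maximum |midpoint offset| of planted peaks
#'   from the foreground TSS (default 1500).
#' @param seed Master seed for the whole dataset.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200, chrom_length_bp = 1e7, n_tfs = 20,
                       planted_tfs = character(), n_foreground = 4,
                       background_peak_rate = 300, peak_width_bp = 200,
                       planted_bind_prob = 1.0, planted_offset_max_bp = 1500,
                       seed = 1L) {
  stopifnot(n_genes >= 1, chrom_length_bp > 0, n_tfs >= 1,
            n_foreground >= 0, n_foreground <= n_genes,
            background_peak_rate >= 0, peak_width_bp >= 1,
            planted_bind_prob >= 0, planted_bind_prob <= 1,
            planted_offset_max_bp >= 0,
            planted_offset_max_bp < chrom_length_bp)
  tf_names <- sprintf("TF%02d", seq_len(n_tfs))
  if (is.numeric(planted_tfs)) {
    stopifnot(all(planted_tfs >= 1), all(planted_tfs <= n_tfs))
    planted_tfs <- tf_names[planted_tfs]
  }
  unknown <- setdiff(planted_tfs, tf_names)
  if (length(unknown) > 0) {
    abort(paste0("unknown planted TF(s): ", paste(unknown, collapse = ", ")))
  }
  structure(list(
    n_genes = as.integer(n_genes),
    chrom_length_bp = as.integer(chrom_length_bp),
    n_tfs = as.integer(n_tfs),
    tf_names = tf_names,
    planted_tfs = planted_tfs,
    n_foreground = as.integer(n_foreground),
    background_peak_rate = background_peak_rate,
    peak_width_bp = as.integer(peak_width_bp),
    planted_bind_prob = planted_bind_prob,
    planted_offset_max_bp = as.integer(planted_offset_max_bp),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a gene annotation
#'
#' `n_genes` genes on one chromosome (`chr1`), TSSs sampled uniformly without
#' collision, random strands, ids `g001...`. The foreground is the first
#' `n_foreground` gene ids of a seeded shuffle and is attached as the
#' `foreground` attribute.
#'
#' @param config A [sim_config()].
#' @return Annotation tibble with a `foreground` attribute.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes > config$chrom_length_bp) {
    abort("n_genes exceeds the number of distinct TSS positions")
  }
  seeds <- derive_seeds(config$seed, 3L)
  width <- max(3L, nchar(as.character(config$n_genes)))
  ann <- withr::with_seed(seeds[1], {
    tibble(
      gene_id = sprintf(paste0("g%0", width, "d"), seq_len(config$n_genes)),
      chrom = "chr1",
      tss = sort(sample.int(config$chrom_length_bp, config$n_genes)) - 1L,
      strand = sample(c("+", "-"), config$n_genes, replace = TRUE)
    )
  })
  foreground <- withr::with_seed(seeds[2], {
    head(sample(ann$gene_id), config$n_foreground)
  })
  attr(ann, "foreground") <- foreground
  ann
}

#' Simulate per-TF binding regions
#'
#' Each TF receives `Poisson(background_peak_rate)` background peaks of width
#' `peak_width_bp`, midpoints uniform on the chromosome. Each planted TF
#' additionally places, with probability `planted_bind_prob` per foreground
#' gene, one peak whose midpoint offset from that TSS is uniform on
#' `[-planted_offset_max_bp, +planted_offset_max_bp]` (midpoints are clamped
#' away from the chromosome ends by half a peak width, which can only move
#' them closer to the TSS). Non-planted TFs receive no extra peaks, so an
#' empty `planted_tfs` gives a fully exchangeable null dataset.
#'
#' @param annotation Annotation from [simulate_annotation()].
#' @param foreground Foreground gene ids.
#' @param config A [sim_config()].
#' @return Tidy interval tibble with a `tf` column (one peak set per TF).
#' @export
simulate_peaks <- function(annotation, foreground, config) {
  stopifnot(inherits(config, "sim_config"))
  validate_annotation(annotation)
  missing_fg <- setdiff(foreground, annotation$gene_id)
  if (length(missing_fg) > 0) {
    abort(paste0("foreground gene(s) absent from annotation: ",
                 paste(missing_fg, collapse = ", ")))
  }
  L <- config$chrom_length_bp
  w <- config$peak_width_bp
  half <- w %/% 2L
  fg_tss <- annotation$tss[match(foreground, annotation$gene_id)]
  seeds <- derive_seeds(config$seed, 3L)
  peaks <- withr::with_seed(seeds[3], {
    purrr::map_dfr(config$tf_names, function(tf) {
      n_bg <- rpois(1, config$background_peak_rate)
      mid <- if (n_bg > 0) sample.int(L, n_bg, replace = TRUE) - 1L else integer()
      if (tf %in% config$planted_tfs && length(fg_tss) > 0) {
        bind <- runif(length(fg_tss)) <= config$planted_bind_prob
        off_max <- config$planted_offset_max_bp
        offs <- sample.int(2L * off_max + 1L, length(fg_tss),
                           replace = TRUE) - off_max - 1L
        mid <- c(mid, (fg_tss + offs)[bind])
      }
      mid <- pmin(pmax(mid, half), L - (w - half))
      if (length(mid) == 0) {
        return(tibble(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = numeric(),
                      strand = character(), tf = character()))
      }
      tibble(chrom = "chr1",
             start = as.integer(mid - half),
             end = as.integer(mid - half + w),
             name = paste0(tf, "_peak", seq_along(mid)),
             score = 0, strand = ".", tf = tf)
    })
  })
  validate_peaks(peaks)
  peaks
}

#' Simulate a complete dataset
#'
#' Bundles [simulate_annotation()] and [simulate_peaks()] with the planted
#' truth, ready for the pipeline or for [write_dataset()].
#'
#' @param config A [sim_config()].
#' @return A list with `annotation`, `foreground`, `peaks`, `planted_tfs`,
#'   and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  ann <- simulate_annotation(config)
  fg <- attr(ann, "foreground")
  peaks <- simulate_peaks(ann, fg, config)
  list(annotation = ann, foreground = fg, peaks = peaks,
       planted_tfs = config$planted_tfs, config = config)
}

#' Write a simulated dataset in the pipeline's file formats
#'
#' Emits `annotation.tsv`, `foreground.txt` (one gene id per line), one BED
#' per TF under `peaks/`, and `truth.tsv` listing the planted TFs.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "annotation.tsv"), open = "wb")
  readr::write_tsv(dataset$annotation, con, progress = FALSE)
  close(con)
  writeLines(dataset$foreground, file.path(dir, "foreground.txt"))
  tf_names <- dataset$config$tf_names %||% unique(dataset$peaks$tf)
  for (tf in tf_names) {
    write_intervals(dataset$peaks[dataset$peaks$tf == tf, , drop = FALSE],
                    file.path(dir, "peaks", paste0(tf, ".bed")))
  }
  con <- file(file.path(dir, "truth.tsv"), open = "wb")
  readr::write_tsv(tibble(planted_tf = dataset$planted_tfs), con,
                   progress = FALSE)
  close(con)
  invisible(dir)
}
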