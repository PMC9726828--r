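# Candidate cis-regulatory module (CRM) calling: clusters of top-regulator
# binding regions near foreground TSSs, with optional evidence-track filters.

#' CRM-calling parameters
#'
#' The caller scans a window around each foreground TSS ("within 2 kb" by
#' default, read as +/- 2000 bp: regulatory modules of this kind sit in
#' promoters and first introns, i.e. on both sides of the TSS), merges
#' binding regions by single linkage, and filters clusters by distinct-TF
#' membership, length, and evidence overlap. Length defaults bracket the
#' tens-to-hundreds-of-bp modules such screens report.
#'
#' @param tss_window_bp Half-width of the scanned TSS window (default 2000).
#' @param max_gap_bp Maximum gap joining two binding regions into one cluster
#'   (default 50; overlap counts as gap 0).
#' @param min_distinct_tfs Minimum distinct top regulators per cluster
#'   (default 2).
#' @param min_len_bp,max_len_bp Cluster length bounds after clipping to the
#'   window (defaults 50 and 400).
#' @param evidence_min_overlap_bp Minimum overlap (bp) required with each
#'   supplied evidence track (default 1; only applied when tracks are given).
#' @return An object of class `crm_params`.
#' @export
crm_params <- function(tss_window_bp = 2000, max_gap_bp = 50,
                       min_distinct_tfs = 2, min_len_bp = 50,
                       max_len_bp = 400, evidence_min_overlap_bp = 1) {
  stopifnot(tss_window_bp > 0, max_gap_bp >= 0, min_distinct_tfs >= 1,
            min_len_bp <= max_len_bp, min_len_bp >= 1,
            evidence_min_overlap_bp >= 1)
  structure(list(tss_window_bp = as.integer(tss_window_bp),
                 max_gap_bp = as.integer(max_gap_bp),
                 min_distinct_tfs = as.integer(min_distinct_tfs),
                 min_len_bp = as.integer(min_len_bp),
                 max_len_bp = as.integer(max_len_bp),
                 evidence_min_overlap_bp = as.integer(evidence_min_overlap_bp)),
            class = "crm_params")
}

#' Single-linkage merge of labelled intervals
#'
#' Two intervals join one cluster iff the gap between them is at most
#' `max_gap_bp` (overlapping or book-ended intervals have gap <= 0). The
#' merged interval spans the members' min start to max end and carries the
#' union of their labels.
#'
#' @param intervals Tibble with `start`, `end` (0-based half-open) and a
#'   `label` column, all on one chromosome.
#' @param max_gap_bp Maximum joining gap in bp.
#' @return Tibble with `start`, `end`, and a `labels` list-column of the
#'   distinct contributing labels (sorted), ordered by `start`.
#' @export
merge_clusters <- function(intervals, max_gap_bp) {
  intervals <- as_tibble(intervals)
  if (nrow(intervals) == 0) {
    return(tibble(start = integer(), end = integer(), labels = list()))
  }
  stopifnot(all(c("start", "end", "label") %in% names(intervals)))
  ir <- IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  red <- IRanges::reduce(ir, min.gapwidth = max_gap_bp + 1L,
                         with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  tibble(
    start = IRanges::start(red) - 1L,
    end = IRanges::end(red),
    labels = lapply(revmap, function(i) sort(unique(intervals$label[i])))
  ) %>% arrange(.data$start)
}

# Total overlap (bp) of one interval [a, b) with a set of intervals.
overlap_bp <- function(a, b, starts, ends) {
  if (length(starts) == 0) return(0L)
  # merge the track first so overlapping track intervals are not double-counted
  ir <- IRanges::reduce(IRanges::IRanges(starts + 1L, ends))
  sum(pmax(0L, pmin(IRanges::end(ir), b) - pmax(IRanges::start(ir) - 1L, a)))
}

#' Call candidate cis-regulatory modules near foreground genes
#'
#' For each foreground gene, all top-regulator binding regions intersecting
#' the TSS window are clipped to the window and merged by single linkage
#' ([merge_clusters()]). Clusters are kept when they contain at least
#' `min_distinct_tfs` distinct regulators, fall within the length bounds, and
#' (when evidence tracks are supplied) overlap every track by at least
#' `evidence_min_overlap_bp`. Candidates are named `<gene>_CRM<k>` with `k`
#' numbering the passing clusters per gene by start coordinate.
#'
#' @param foreground Foreground gene ids; each must exist in the annotation.
#' @param annotation Gene annotation tibble.
#' @param top_peaks Binding regions of the selected top regulators: tidy
#'   interval tibble with a `tf` column.
#' @param evidence Optional evidence tracks (open chromatin, conservation,
#'   ...) as a tidy interval tibble whose `tf` column names the track, or a
#'   named list of interval tibbles.
#' @param params A [crm_params()] object.
#' @return A `crm_calls` tibble: `chrom`, `start`, `end`, `name`, `gene_id`,
#'   `n_tfs`, `member_tfs` (comma-separated, sorted), plus one logical
#'   `evidence_<track>` column per supplied track; sorted by (gene, start).
#' @export
call_crm <- function(foreground, annotation, top_peaks, evidence = NULL,
                     params = crm_params()) {
  validate_annotation(annotation)
  missing_fg <- setdiff(foreground, annotation$gene_id)
  if (length(missing_fg) > 0) {
    abort(paste0("foreground gene(s) absent from annotation: ",
                 paste(missing_fg, collapse = ", ")))
  }
  top_peaks <- as_tibble(top_peaks)
  if (nrow(top_peaks) > 0) {
    validate_peaks(top_peaks)
    if (!"tf" %in% names(top_peaks)) abort("top_peaks must carry a 'tf' column")
  }
  evidence <- normalise_evidence(evidence)
  track_names <- names(evidence)

  fg_ann <- annotation[match(sort(foreground), annotation$gene_id), ,
                       drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(fg_ann))) {
    g <- fg_ann[i, ]
    win_lo <- max(0L, g$tss - params$tss_window_bp)
    win_hi <- g$tss + params$tss_window_bp
    sel <- top_peaks[top_peaks$chrom == g$chrom &
                       top_peaks$start < win_hi &
                       top_peaks$end > win_lo, , drop = FALSE]
    if (nrow(sel) == 0) next
    clipped <- tibble(start = pmax(sel$start, win_lo),
                      end = pmin(sel$end, win_hi),
                      label = sel$tf)
    clusters <- merge_clusters(clipped, params$max_gap_bp)
    if (nrow(clusters) == 0) next
    clusters$n_tfs <- lengths(clusters$labels)
    len <- clusters$end - clusters$start
    keep <- clusters$n_tfs >= params$min_distinct_tfs &
      len >= params$min_len_bp & len <= params$max_len_bp
    flags <- matrix(TRUE, nrow(clusters), length(track_names),
                    dimnames = list(NULL, track_names))
    for (tr in track_names) {
      ev <- evidence[[tr]]
      ev <- ev[ev$chrom == g$chrom, , drop = FALSE]
      flags[, tr] <- vapply(seq_len(nrow(clusters)), function(k) {
        overlap_bp(clusters$start[k], clusters$end[k], ev$start, ev$end) >=
          params$evidence_min_overlap_bp
      }, logical(1))
    }
    if (length(track_names) > 0) keep <- keep & apply(flags, 1, all)
    if (!any(keep)) next
    kept <- clusters[keep, , drop = FALSE]
    res <- tibble(
      chrom = g$chrom,
      start = as.integer(kept$start),
      end = as.integer(kept$end),
      name = paste0(g$gene_id, "_CRM", seq_len(nrow(kept))),
      gene_id = g$gene_id,
      n_tfs = as.integer(kept$n_tfs),
      member_tfs = vapply(kept$labels, paste, character(1), collapse = ",")
    )
    for (tr in track_names) {
      res[[paste0("evidence_", tr)]] <- flags[keep, tr]
    }
    out[[length(out) + 1]] <- res
  }
  res <- if (length(out) == 0) {
    empty <- tibble(chrom = character(), start = integer(), end = integer(),
                    name = character(), gene_id = character(),
                    n_tfs = integer(), member_tfs = character())
    for (tr in track_names) empty[[paste0("evidence_", tr)]] <- logical()
    empty
  } else {
    bind_rows(out)
  }
  structure(res, class = c("crm_calls", class(tibble())), crm_params = params)
}

normalise_evidence <- function(evidence) {
  if (is.null(evidence)) return(list())
  if (is.data.frame(evidence)) {
    if (!"tf" %in% names(evidence)) {
      abort("an evidence tibble must carry a 'tf' column naming the track")
    }
    evidence <- split(as_tibble(evidence), evidence$tf)
  }
  if (is.null(names(evidence)) || any(!nzchar(names(evidence)))) {
    abort("evidence tracks must be named")
  }
  lapply(evidence, function(e) {
    validate_peaks(e)
    as_tibble(e)
  })
}

#' Write called CRM as BED6 plus a TSV sidecar
#'
#' The BED file (name = candidate name, score = distinct-TF count) records
#' the calling parameters as `#` header lines; the sidecar lists member TFs
#' and evidence flags per candidate.
#'
#' @param x A `crm_calls` tibble from [call_crm()].
#' @param bed_path Output BED path.
#' @param tsv_path Output sidecar path (default: `bed_path` with `.tsv`).
#' @return `bed_path`, invisibly.
#' @export
write_crm <- function(x, bed_path, tsv_path = sub("\\.bed$", ".tsv", bed_path)) {
  params <- attr(x, "crm_params")
  hdr <- NULL
  if (!is.null(params)) {
    hdr <- paste0(names(unclass(params)), "=",
                  vapply(unclass(params), format, character(1)))
  }
  bed <- tibble(chrom = x$chrom, start = x$start, end = x$end,
                name = x$name, score = x$n_tfs,
                strand = rep(".", nrow(x)))
  write_intervals(bed, bed_path, header = hdr)
  con <- file(tsv_path, open = "wb")
  readr::write_tsv(as_tibble(as.data.frame(x)), con, progress = FALSE)
  close(con)
  invisible(bed_path)
}
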