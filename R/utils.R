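# Internal validators and seed plumbing shared across modules.

#' Validate a gene annotation table
#'
#' Checks the column contract (`gene_id`, `chrom`, `tss`, `strand`), uniqueness
#' of gene identifiers, and coordinate sanity. Called by every function that
#' consumes an annotation; exported so users can validate hand-built tables.
#'
#' @param annotation A data frame with columns `gene_id` (character, unique),
#'   `chrom` (character), `tss` (non-negative integer, 0-based), `strand`
#'   (`"+"` or `"-"`).
#' @return The annotation, invisibly, as a tibble.
#' @export
validate_annotation <- function(annotation) {
  annotation <- as_tibble(annotation)
  need <- c("gene_id", "chrom", "tss", "strand")
  missing <- setdiff(need, names(annotation))
  if (length(missing) > 0) {
    abort(paste0("annotation is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  dup <- annotation$gene_id[duplicated(annotation$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene_id in annotation: ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (anyNA(annotation$tss) || any(annotation$tss < 0)) {
    abort("annotation tss values must be non-negative and non-missing")
  }
  bad <- !annotation$strand %in% c("+", "-")
  if (any(bad)) {
    abort(paste0("annotation strand must be '+' or '-' (offending gene: ",
                 annotation$gene_id[which(bad)[1]], ")"))
  }
  invisible(annotation)
}

#' Validate a peak (interval) table
#'
#' @param peaks A data frame with at least `chrom`, `start`, `end`; intervals
#'   are 0-based half-open.
#' @return The peaks, invisibly, as a tibble.
#' @export
validate_peaks <- function(peaks) {
  peaks <- as_tibble(peaks)
  need <- c("chrom", "start", "end")
  missing <- setdiff(need, names(peaks))
  if (length(missing) > 0) {
    abort(paste0("peak table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(peaks) == 0) return(invisible(peaks))
  if (anyNA(peaks$start) || anyNA(peaks$end) || anyNA(peaks$chrom)) {
    abort("peak table contains missing chrom/start/end")
  }
  if (any(!nzchar(peaks$chrom))) abort("peak chrom names must be non-empty")
  bad <- which(peaks$start < 0 | peaks$start >= peaks$end)
  if (length(bad) > 0) {
    abort(paste0("invalid interval at row ", bad[1], ": start=",
                 peaks$start[bad[1]], " end=", peaks$end[bad[1]],
                 " (need 0 <= start < end)"))
  }
  invisible(peaks)
}

# Derive `n` independent sub-seeds from one master seed, without disturbing
# the caller's RNG state. Values stay below 2^31 - 1 (R integers).
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

# Midpoint of a 0-based half-open interval, floor convention.
interval_midpoint <- function(start, end) {
  (start + end) %/% 2L
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}
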