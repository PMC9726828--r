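# File I/O: gene annotation tables, BED interval files, and the shared
# matrix TSV format. All coordinates are 0-based half-open (BED convention)
# and are passed through unchanged.

#' Read a gene annotation
#'
#' Reads the gene universe used for all distance computations. Two dialects
#' are supported: a four-column TSV with header
#' `gene_id<TAB>chrom<TAB>tss<TAB>strand`, or BED6, in which case the TSS is
#' derived from the strand: `start` for `+` genes and `end - 1` for `-` genes
#' (the last covered base, 0-based).
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return A tibble with columns `gene_id`, `chrom`, `tss`, `strand`.
#'   Gene identifiers are guaranteed unique; duplicates are a hard error.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tchrom\ttss\tstrand", "g1\tchr1\t10000\t+"), tf)
#' read_gene_annotation(tf)
#' @export
read_gene_annotation <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  if (format == "tsv") {
    ann <- suppressWarnings(readr::read_tsv(
      path,
      col_types = readr::cols(
        gene_id = readr::col_character(),
        chrom = readr::col_character(),
        tss = readr::col_double(),
        strand = readr::col_character()
      ),
      progress = FALSE
    ))
    probs <- readr::problems(ann)
    if (nrow(probs) > 0) {
      # vroom reports the file line (header included)
      abort(paste0("malformed annotation row at line ", probs$row[1],
                   " of ", path))
    }
    missing <- setdiff(c("gene_id", "chrom", "tss", "strand"), names(ann))
    if (length(missing) > 0) {
      abort(paste0("annotation TSV header must name gene_id/chrom/tss/strand; ",
                   "missing: ", paste(missing, collapse = ", ")))
    }
    bad <- which(is.na(ann$tss) | is.na(ann$gene_id) | is.na(ann$strand))
    if (length(bad) > 0) {
      abort(paste0("malformed annotation row at line ", bad[1] + 1L,
                   " of ", path))
    }
    ann <- ann[, c("gene_id", "chrom", "tss", "strand")]
  } else {
    raw <- read_bed_raw(path, min_fields = 6L)
    bad <- which(!raw$X6 %in% c("+", "-"))
    if (length(bad) > 0) {
      abort(paste0("BED annotation needs strand '+' or '-' at line ",
                   raw$line[bad[1]], " of ", path))
    }
    ann <- tibble(
      gene_id = raw$X4,
      chrom = raw$X1,
      tss = ifelse(raw$X6 == "+", raw$X2, raw$X3 - 1),
      strand = raw$X6
    )
  }
  ann$tss <- as.integer(ann$tss)
  dup <- unique(ann$gene_id[duplicated(ann$gene_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate gene_id in ", path, ": ",
                 paste(dup, collapse = ", ")))
  }
  validate_annotation(ann)
  ann
}

# Shared raw BED reader: tab-separated, no header, "#" comments allowed.
# Returns the first fields as X1..Xk plus the originating line number, and
# hard-errors (with line number) on rows with too few fields or
# non-numeric / inverted coordinates.
read_bed_raw <- function(path, min_fields = 3L) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (length(keep) == 0) {
    out <- tibble(X1 = character(), X2 = numeric(), X3 = numeric(),
                  X4 = character(), X5 = numeric(), X6 = character(),
                  line = integer())
    return(out)
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_fields)) {
    i <- which(nf < min_fields)[1]
    abort(paste0("BED row with fewer than ", min_fields, " fields at line ",
                 keep[i], " of ", path))
  }
  pick <- function(j, default) {
    vapply(fields, function(f) if (length(f) >= j) f[j] else default,
           character(1))
  }
  start <- suppressWarnings(as.numeric(pick(2, NA_character_)))
  end <- suppressWarnings(as.numeric(pick(3, NA_character_)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(paste0("non-numeric BED coordinates at line ", keep[bad[1]],
                 " of ", path))
  }
  bad <- which(start < 0 | start >= end)
  if (length(bad) > 0) {
    abort(paste0("invalid BED interval (need 0 <= start < end) at line ",
                 keep[bad[1]], " of ", path, ": start=", start[bad[1]],
                 " end=", end[bad[1]]))
  }
  tibble(
    X1 = pick(1, NA_character_),
    X2 = start,
    X3 = end,
    X4 = pick(4, "."),
    X5 = suppressWarnings(as.numeric(pick(5, "0"))),
    X6 = pick(6, "."),
    line = keep
  )
}

#' Read one TF's binding regions (or an evidence track) from BED
#'
#' BED3 or wider; 0-based half-open coordinates are retained unchanged and
#' file order is preserved. An empty file yields an empty peak set, which is
#' legal (a TF with no binding regions).
#'
#' @param path Path to a BED file.
#' @param tf_name Label attached to every interval (the `tf` column). Defaults
#'   to the file name without its `.bed` extension.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `tf`.
#' @export
read_peaks <- function(path, tf_name = NULL) {
  tf_name <- tf_name %||% sub("\\.bed$", "", basename(path))
  raw <- read_bed_raw(path, min_fields = 3L)
  peaks <- tibble(
    chrom = raw$X1,
    start = as.integer(raw$X2),
    end = as.integer(raw$X3),
    name = raw$X4,
    score = ifelse(is.na(raw$X5), 0, raw$X5),
    strand = ifelse(raw$X6 %in% c("+", "-"), raw$X6, "."),
    tf = tf_name
  )
  validate_peaks(peaks)
  peaks
}

#' Read a directory of per-TF BED files
#'
#' Each `*.bed` file becomes one peak set labelled by its file name, bound
#' into a single tidy interval table.
#'
#' @param dir Directory containing one BED file per TF (or per evidence track).
#' @param pattern File-name regexp, default `"\\.bed$"`.
#' @return A tibble as from [read_peaks()], with one `tf` label per file.
#' @export
read_peaks_dir <- function(dir, pattern = "\\.bed$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0) abort(paste0("no BED files found under ", dir))
  purrr::map_dfr(files, read_peaks)
}

#' Write intervals as BED6
#'
#' Missing `name`/`score`/`strand` columns are filled with `"."`, `0`, `"."`.
#' Round-tripping through [read_peaks()] preserves chrom/start/end/name.
#'
#' @param intervals A data frame with at least `chrom`, `start`, `end`.
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed header lines to
#'   prepend (used to record caller parameters).
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path, header = NULL) {
  intervals <- as_tibble(intervals)
  if (nrow(intervals) > 0) validate_peaks(intervals)
  bed <- tibble(
    chrom = as.character(intervals$chrom %||% character()),
    start = as.integer(intervals$start),
    end = as.integer(intervals$end),
    name = if ("name" %in% names(intervals)) as.character(intervals$name) else rep(".", nrow(intervals)),
    score = if ("score" %in% names(intervals)) intervals$score else rep(0, nrow(intervals)),
    strand = if ("strand" %in% names(intervals)) as.character(intervals$strand) else rep(".", nrow(intervals))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0("# ", sub("^#\\s*", "", header)), con)
  }
  if (nrow(bed) > 0) {
    readr::write_tsv(bed, con, col_names = FALSE, progress = FALSE)
  }
  invisible(path)
}

#' Write a genes-by-TFs matrix as TSV
#'
#' One writer shared by score, p-value and target matrices: first column
#' `gene_id`, remaining columns named by TF. A target matrix's p-value cutoff
#' (its `cutoff` attribute) is recorded as a `# cutoff=<value>` comment line.
#'
#' @param x Wide tibble: `gene_id` plus one numeric column per TF.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  stopifnot(names(x)[1] == "gene_id")
  cutoff <- attr(x, "cutoff")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(cutoff)) {
    writeLines(paste0("# cutoff=", format(cutoff, digits = 15)), con)
  }
  readr::write_tsv(as_tibble(x), con, progress = FALSE)
  invisible(path)
}

#' Read a genes-by-TFs matrix TSV
#'
#' Counterpart of [write_matrix_tsv()]; a leading `# cutoff=` comment is
#' restored as the `cutoff` attribute.
#'
#' @param path Path to a matrix TSV.
#' @return Wide tibble `gene_id` + TF columns, with a `cutoff` attribute when
#'   the file carries one.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("matrix file not found: ", path))
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  cutoff <- NULL
  if (length(first) == 1 && grepl("^#\\s*cutoff=", first)) {
    cutoff <- as.numeric(sub("^#\\s*cutoff=", "", first))
  }
  x <- readr::read_tsv(
    path, comment = "#", progress = FALSE,
    col_types = readr::cols(gene_id = readr::col_character(),
                            .default = readr::col_double())
  )
  if (names(x)[1] != "gene_id") {
    abort(paste0("matrix TSV must have first column 'gene_id': ", path))
  }
  if (!is.null(cutoff)) attr(x, "cutoff") <- cutoff
  x
}
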