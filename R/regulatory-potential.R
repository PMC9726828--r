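# Distance-decayed regulatory potential, empirical p-values, and the binary
# TF-target matrix.

#' Decay-kernel parameters for regulatory potential
#'
#' A binding region at distance `d` bp from a TSS (peak midpoint to TSS)
#' contributes `exp(-(alpha + beta * d / window_bp))` to the gene's
#' regulatory potential for that TF; regions beyond `window_bp` contribute
#' nothing. The kernel decreases monotonically with distance: at the TSS a
#' region contributes `exp(-alpha)` (~0.607 at the default), at the window
#' edge `exp(-(alpha + beta))` (~0.011). Defaults follow the standard
#' published exponential regulatory-potential form.
#'
#' @param window_bp Maximum TSS distance considered, bp (default 100000).
#' @param alpha Decay offset (default 0.5).
#' @param beta Decay slope over the window (default 4).
#' @return An object of class `decay_params`.
#' @export
decay_params <- function(window_bp = 100000, alpha = 0.5, beta = 4.0) {
  if (!is_scalar_number(window_bp) || window_bp <= 0) {
    abort("window_bp must be a positive number")
  }
  if (!is_scalar_number(beta) || beta < 0) abort("beta must be >= 0")
  if (!is_scalar_number(alpha)) abort("alpha must be a number")
  structure(list(window_bp = window_bp, alpha = alpha, beta = beta),
            class = "decay_params")
}

# Kernel weights for absolute distances d (same chromosome assumed).
decay_weight <- function(d, params) {
  w <- exp(-(params$alpha + params$beta * d / params$window_bp))
  w[d > params$window_bp] <- 0
  w
}

#' Regulatory potential of one gene for one TF
#'
#' Sums the decay kernel over the TF's binding regions on the gene's
#' chromosome whose midpoints lie within `window_bp` of the TSS. Additive in
#' peaks; an empty peak set scores 0.
#'
#' @param gene A one-row annotation tibble (see [read_gene_annotation()]).
#' @param peaks Intervals for a single TF (tibble with `chrom`, `start`, `end`).
#' @param params A [decay_params()] object.
#' @return A single non-negative score.
#' @examples
#' gene <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 10000L, strand = "+")
#' pk <- tibble::tibble(chrom = "chr1", start = 9900L, end = 10100L)
#' regulatory_potential(gene, pk, decay_params())  # one midpoint at the TSS
#' @export
regulatory_potential <- function(gene, peaks, params = decay_params()) {
  stopifnot(nrow(gene) == 1)
  peaks <- as_tibble(peaks)
  if (nrow(peaks) == 0) return(0)
  validate_peaks(peaks)
  on_chrom <- peaks$chrom == gene$chrom
  if (!any(on_chrom)) return(0)
  d <- abs(interval_midpoint(peaks$start[on_chrom], peaks$end[on_chrom]) -
             gene$tss)
  sum(decay_weight(d, params))
}

#' Regulatory-potential score matrix (genes x TFs)
#'
#' Applies [regulatory_potential()] to every (gene, TF) pair. Genes with no
#' nearby binding regions keep all-zero rows: they shape the empirical null
#' used by [empirical_pvalues()]. A warning is raised for any TF whose peaks
#' share no chromosome name with the annotation (chromosome matching is
#' exact-string; no "chr" normalisation is attempted).
#'
#' @param annotation Gene annotation tibble.
#' @param peaks Tidy interval table with a `tf` column (as from
#'   [read_peaks_dir()]), or a list of per-TF peak tibbles.
#' @param params A [decay_params()] object.
#' @return A wide tibble: `gene_id` plus one non-negative numeric column per
#'   TF, in order of first appearance.
#' @export
score_matrix <- function(annotation, peaks, params = decay_params()) {
  validate_annotation(annotation)
  if (is.data.frame(peaks)) {
    if (!"tf" %in% names(peaks)) {
      abort("peaks must carry a 'tf' column (see read_peaks_dir())")
    }
  } else if (is.list(peaks)) {
    peaks <- bind_rows(peaks)
    if (!"tf" %in% names(peaks)) abort("each peak set must carry a 'tf' column")
  } else {
    abort("peaks must be a data frame or a list of data frames")
  }
  validate_peaks(peaks)
  tfs <- unique(peaks$tf)
  if (anyNA(tfs)) abort("peak 'tf' labels must be non-missing")
  out <- tibble(gene_id = annotation$gene_id)
  mids <- interval_midpoint(peaks$start, peaks$end)
  for (t in tfs) {
    sel <- peaks$tf == t
    if (sum(sel) > 0 &&
        !any(unique(peaks$chrom[sel]) %in% unique(annotation$chrom))) {
      warn(paste0("peak set '", t,
                  "' shares no chromosome names with the annotation; ",
                  "all its scores are 0"))
    }
    col <- numeric(nrow(annotation))
    for (ch in intersect(unique(peaks$chrom[sel]), unique(annotation$chrom))) {
      g <- which(annotation$chrom == ch)
      m <- mids[sel & peaks$chrom == ch]
      if (length(m) == 0) next
      d <- abs(outer(annotation$tss[g], m, "-"))
      col[g] <- col[g] + rowSums(decay_weight(d, params))
    }
    out[[t]] <- col
  }
  out
}

#' Empirical p-values of regulatory-potential scores
#'
#' Per TF column independently, a gene's p-value is the fraction of genes
#' (including itself) whose score is greater than or equal to its own:
#' `p = #\{score' >= score\} / N`. The strict maximum receives `1/N`, never 0;
#' tied scores share a p-value; a constant column is all 1.
#'
#' @param scores A score matrix from [score_matrix()].
#' @return Same shape and labels, values in `[1/N, 1]`.
#' @export
empirical_pvalues <- function(scores) {
  stopifnot(names(scores)[1] == "gene_id")
  n <- nrow(scores)
  if (n < 1) abort("empirical p-values need at least one gene")
  out <- scores
  for (j in seq_along(scores)[-1]) {
    v <- scores[[j]]
    # #{v' >= v_i} = N - (ascending min-rank of v_i) + 1, ties sharing
    out[[j]] <- (n - rank(v, ties.method = "min") + 1) / n
  }
  out
}

#' Threshold empirical p-values into a binary target matrix
#'
#' Entry is 1 iff the gene's empirical p-value for that TF is `<= cutoff`
#' (inclusive). The cutoff is recorded as the `cutoff` attribute and is
#' written out as a `# cutoff=` header by [write_matrix_tsv()].
#'
#' @param pvals A p-value matrix from [empirical_pvalues()].
#' @param cutoff P-value threshold in `(0, 1]` (default 0.01).
#' @return Wide tibble of 0/1 integers with a `cutoff` attribute.
#' @export
build_target_matrix <- function(pvals, cutoff = 0.01) {
  if (!is_scalar_number(cutoff) || cutoff <= 0 || cutoff > 1) {
    abort("cutoff must lie in (0, 1]")
  }
  stopifnot(names(pvals)[1] == "gene_id")
  out <- pvals
  for (j in seq_along(pvals)[-1]) {
    out[[j]] <- as.integer(pvals[[j]] <= cutoff)
  }
  attr(out, "cutoff") <- cutoff
  out
}
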