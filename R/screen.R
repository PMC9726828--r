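# Foreground-vs-background regulator screen: distance-difference scores over
# random background gene sets, replicated, aggregated by rank product with a
# permutation null and BH false-discovery-rate control.

#' Configuration of the regulator screen
#'
#' Defaults mirror the screening design the pipeline implements: 1000 random
#' background sets of 8 genes per replicate, 7 replicates to buffer sampling
#' bias, a q-value cutoff of 0.05 for selecting top regulators, and a
#' 10000-permutation Monte-Carlo null for rank-product significance.
#'
#' @param n_background_sets Background sets per replicate (default 1000).
#' @param background_set_size Genes per background set (default 8).
#' @param n_replicates Independent screen replicates (default 7).
#' @param q_cutoff FDR threshold for selection (default 0.05).
#' @param n_permutations Permutations for the rank-product null (default 10000).
#' @param seed Master seed; every random draw in the screen derives from it.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(n_background_sets = 1000, background_set_size = 8,
                          n_replicates = 7, q_cutoff = 0.05,
                          n_permutations = 10000, seed = 1L) {
  stopifnot(n_background_sets >= 1, background_set_size >= 1,
            n_replicates >= 1, q_cutoff > 0, q_cutoff <= 1,
            n_permutations >= 1)
  structure(list(
    n_background_sets = as.integer(n_background_sets),
    background_set_size = as.integer(background_set_size),
    n_replicates = as.integer(n_replicates),
    q_cutoff = q_cutoff,
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed)
  ), class = "screen_config")
}

#' Sample random background gene sets
#'
#' Draws `n_background_sets` sets of `background_set_size` distinct genes,
#' uniformly without replacement from the annotation's gene universe with the
#' foreground excluded. Fully reproducible from `replicate_seed`.
#'
#' @param annotation Gene annotation tibble (the sampling universe).
#' @param foreground Character vector of foreground gene ids (excluded).
#' @param config A [screen_config()].
#' @param replicate_seed Integer seed for this replicate's draws.
#' @return A list of character vectors of gene ids.
#' @export
sample_background_sets <- function(annotation, foreground, config,
                                   replicate_seed) {
  validate_annotation(annotation)
  universe <- setdiff(annotation$gene_id, foreground)
  k <- config$background_set_size
  if (length(universe) < k) {
    abort(paste0("insufficient genes for background sampling: need ", k,
                 ", have ", length(universe),
                 " after excluding the foreground"))
  }
  withr::with_seed(as.integer(replicate_seed), {
    purrr::map(seq_len(config$n_background_sets),
               function(i) sample(universe, k))
  })
}

# Exact integer-count core of the distance-difference contrast for binary
# target columns. s_f/s_b are per-TF foreground/background target counts.
# between = mean Hamming distance over all foreground x background pairs,
# within = mean Hamming distance over unordered foreground pairs; both are
# ratios of integer counts, so results are bitwise identical to explicit
# pair enumeration. The sign compares targeted fractions exactly via
# cross-multiplied integers; equal fractions give sign 0.
ddm_core <- function(s_f, n_f, s_b, n_b) {
  between <- (s_f * (n_b - s_b) + s_b * (n_f - s_f)) / (n_f * n_b)
  within <- (s_f * (n_f - s_f)) / (n_f * (n_f - 1) / 2)
  sgn <- sign(s_f * n_b - s_b * n_f)
  (between - within) * sgn
}

#' Distance-difference discrimination score of each TF
#'
#' For one foreground set and one background set, each TF's binary target
#' column is scored by how it separates the two sets: the mean Hamming
#' distance between foreground-background gene pairs minus the mean Hamming
#' distance among foreground pairs, signed by the direction of enrichment
#' (positive when the foreground is the more-targeted set; a TF whose
#' targeted fractions are equal in both sets scores exactly 0). A perfect
#' discriminator (all foreground targeted, no background targeted) scores 1.
#'
#' @param targets Binary target matrix from [build_target_matrix()].
#' @param foreground Character vector of foreground gene ids (length >= 2).
#' @param background Character vector of background gene ids.
#' @return A tibble with columns `tf` and `score`.
#' @export
ddm_score <- function(targets, foreground, background) {
  stopifnot(names(targets)[1] == "gene_id")
  if (length(foreground) < 2) abort("foreground must contain >= 2 genes")
  unknown <- setdiff(c(foreground, background), targets$gene_id)
  if (length(unknown) > 0) {
    abort(paste0("gene(s) absent from target matrix: ",
                 paste(unknown, collapse = ", ")))
  }
  m <- as.matrix(targets[, -1, drop = FALSE])
  if (!all(m %in% c(0, 1))) abort("target matrix values must be 0/1")
  rownames(m) <- targets$gene_id
  f <- m[foreground, , drop = FALSE]
  b <- m[background, , drop = FALSE]
  score <- ddm_core(colSums(f), nrow(f), colSums(b), nrow(b))
  tibble(tf = colnames(m), score = unname(score))
}

#' One replicate of the regulator screen
#'
#' Draws this replicate's background sets (seed derived deterministically from
#' `config$seed` and `replicate_index`), scores every TF by the mean
#' [ddm_score()] over the sets, and ranks TFs descending by score with
#' midranks for ties (rank 1 = most discriminative).
#'
#' @param targets Binary target matrix.
#' @param annotation Gene annotation (background sampling universe).
#' @param foreground Foreground gene ids.
#' @param config A [screen_config()].
#' @param replicate_index Which replicate (1-based).
#' @return A tibble with columns `tf`, `score`, `rank`.
#' @export
replicate_screen <- function(targets, annotation, foreground, config,
                             replicate_index) {
  stopifnot(replicate_index >= 1, replicate_index <= config$n_replicates)
  seeds <- derive_seeds(config$seed, config$n_replicates + 1L)
  sets <- sample_background_sets(annotation, foreground, config,
                                 seeds[replicate_index])
  m <- as.matrix(targets[, -1, drop = FALSE])
  rownames(m) <- targets$gene_id
  if (length(foreground) < 2) abort("foreground must contain >= 2 genes")
  if (!all(foreground %in% rownames(m))) {
    abort("foreground gene(s) absent from target matrix")
  }
  n_f <- length(foreground)
  s_f <- colSums(m[foreground, , drop = FALSE])
  per_set <- vapply(sets, function(g) {
    ddm_core(s_f, n_f, colSums(m[g, , drop = FALSE]), length(g))
  }, numeric(ncol(m)))
  score <- if (is.matrix(per_set)) rowMeans(per_set) else mean(per_set)
  tibble(tf = colnames(m), score = unname(score),
         rank = rank(-score, ties.method = "average"))
}

# Geometric mean of each row of a rank matrix (TFs x replicates). Shared by
# the observed statistic and the permutation null so that float results are
# comparable bitwise.
rp_geomean <- function(rank_matrix) {
  exp(rowMeans(log(rank_matrix)))
}

#' Rank product across replicates
#'
#' Geometric mean of each TF's per-replicate ranks:
#' `RP = (prod_r rank_r)^(1/R)`. Small values indicate consistent top ranking.
#'
#' @param ranks A tibble with a `tf` column and one numeric rank column per
#'   replicate (midranks allowed).
#' @return A tibble with columns `tf` and `rank_product`.
#' @export
rank_product <- function(ranks) {
  stopifnot("tf" %in% names(ranks))
  m <- as.matrix(ranks[, setdiff(names(ranks), "tf"), drop = FALSE])
  if (ncol(m) < 1) abort("ranks must contain at least one replicate column")
  if (anyNA(m)) {
    abort(paste0("missing rank for TF ",
                 ranks$tf[which(rowSums(is.na(m)) > 0)[1]]))
  }
  tibble(tf = ranks$tf, rank_product = rp_geomean(m))
}

#' Permutation p-values for rank products
#'
#' Monte-Carlo null: each permutation draws an independent uniform permutation
#' of ranks `1..n_tfs` for every replicate and computes every TF slot's rank
#' product; all `n_permutations * n_tfs` null values are pooled. The p-value
#' is `(1 + #\{null <= RP\}) / (1 + #null)` (add-one corrected, so p is never
#' 0 and the worst possible rank product gets p = 1 up to the correction).
#'
#' @param rank_products Numeric vector of observed rank products.
#' @param n_tfs Number of TFs ranked in each replicate.
#' @param n_replicates Number of replicates.
#' @param n_permutations Monte-Carlo permutations (default 10000).
#' @param seed Integer seed.
#' @return Numeric vector of p-values in (0, 1], aligned with
#'   `rank_products`.
#' @export
rank_product_pvalues <- function(rank_products, n_tfs, n_replicates,
                                 n_permutations = 10000, seed = 1L) {
  if (n_tfs < 2) abort("rank-product null needs n_tfs >= 2")
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  null_pool <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_permutations), function(p) {
      perm_ranks <- vapply(seq_len(n_replicates),
                           function(r) sample.int(n_tfs),
                           integer(n_tfs))
      rp_geomean(matrix(perm_ranks, nrow = n_tfs))
    }, numeric(n_tfs))
  })
  null_sorted <- sort(as.numeric(null_pool))
  cnt <- findInterval(rank_products, null_sorted)
  (1 + cnt) / (1 + length(null_sorted))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with enforced monotonicity, capped at 1
#' (delegates to [stats::p.adjust()] with `method = "BH"` after validating
#' the input).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values.
#' @export
fdr_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Run the full regulator screen
#'
#' Replicates the background-set screen `n_replicates` times, combines the
#' per-replicate TF ranks by rank product, attaches permutation p-values and
#' BH q-values, and flags TFs passing the q-value cutoff. The whole screen is
#' a pure function of its inputs and `config$seed`.
#'
#' @param targets Binary target matrix from [build_target_matrix()].
#' @param annotation Gene annotation tibble.
#' @param foreground Foreground gene ids (length >= 2).
#' @param config A [screen_config()].
#' @return An object of class `regulator_screen`; its `$ranking` tibble has
#'   one row per TF (ascending rank product, ties broken by name) with
#'   columns `tf`, `score_rep1..R`, `rank_rep1..R`, `rank_product`,
#'   `p_value`, `q_value`, `selected`. Use [tidy()], [glance()],
#'   [autoplot()], and [select_top_regulators()] on it.
#' @export
discover_regulators <- function(targets, annotation, foreground,
                                config = screen_config()) {
  validate_annotation(annotation)
  stopifnot(names(targets)[1] == "gene_id")
  missing_fg <- setdiff(foreground, annotation$gene_id)
  if (length(missing_fg) > 0) {
    abort(paste0("foreground gene(s) absent from annotation: ",
                 paste(missing_fg, collapse = ", ")))
  }
  R <- config$n_replicates
  reps <- purrr::map(seq_len(R), function(r) {
    replicate_screen(targets, annotation, foreground, config, r)
  })
  tf_names <- reps[[1]]$tf
  wide <- tibble(tf = tf_names)
  for (r in seq_len(R)) {
    wide[[paste0("score_rep", r)]] <- reps[[r]]$score
    wide[[paste0("rank_rep", r)]] <- reps[[r]]$rank
  }
  rp <- rank_product(wide[, c("tf", paste0("rank_rep", seq_len(R)))])
  seeds <- derive_seeds(config$seed, R + 1L)
  p <- rank_product_pvalues(rp$rank_product, n_tfs = length(tf_names),
                            n_replicates = R,
                            n_permutations = config$n_permutations,
                            seed = seeds[R + 1L])
  ranking <- wide %>%
    mutate(rank_product = rp$rank_product, p_value = p,
           q_value = fdr_adjust(p),
           selected = as.integer(.data$q_value <= config$q_cutoff)) %>%
    arrange(.data$rank_product, .data$tf)
  structure(list(ranking = ranking, config = config,
                 foreground = foreground, n_genes = nrow(targets),
                 target_cutoff = attr(targets, "cutoff")),
            class = "regulator_screen")
}

#' Select the top regulators
#'
#' TFs whose q-value passes the cutoff, ordered by ascending rank product
#' with ties broken alphabetically. An empty result is legal.
#'
#' @param ranking A `regulator_screen` object or its ranking tibble.
#' @param q_cutoff FDR threshold; defaults to the screen's configured cutoff
#'   (or 0.05 for a bare tibble).
#' @return Character vector of TF names.
#' @export
select_top_regulators <- function(ranking, q_cutoff = NULL) {
  if (inherits(ranking, "regulator_screen")) {
    q_cutoff <- q_cutoff %||% ranking$config$q_cutoff
    ranking <- ranking$ranking
  }
  q_cutoff <- q_cutoff %||% 0.05
  hit <- ranking[ranking$q_value <= q_cutoff, , drop = FALSE]
  hit <- hit[order(hit$rank_product, hit$tf), , drop = FALSE]
  hit$tf
}

#' Write a regulator ranking as TSV
#'
#' One row per TF in deterministic order (ascending rank product, then name);
#' columns `tf`, `score_rep1..R`, `rank_rep1..R`, `rank_product`, `p_value`,
#' `q_value`, `selected`.
#'
#' @param x A `regulator_screen` object or its ranking tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(x, path) {
  if (inherits(x, "regulator_screen")) x <- x$ranking
  con <- file(path, open = "wb")
  on.exit(close(con))
  readr::write_tsv(x, con, progress = FALSE)
  invisible(path)
}

#' Read a regulator ranking TSV
#'
#' @param path Path written by [write_ranking()].
#' @return The ranking tibble.
#' @export
read_ranking <- function(path) {
  readr::read_tsv(path, progress = FALSE,
                  col_types = readr::cols(tf = readr::col_character(),
                                          .default = readr::col_double()))
}
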