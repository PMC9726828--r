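# Independent oracles and tiny fixture builders used across test files.

# Brute-force distance-difference score: materialises every gene pair
# explicitly. Integer pair counts are accumulated and divided once, so the
# result is bitwise comparable with the package's closed form.
ddm_oracle <- function(targets, foreground, background) {
  m <- as.matrix(targets[, -1, drop = FALSE])
  rownames(m) <- targets$gene_id
  vapply(colnames(m), function(tf) {
    f <- m[foreground, tf]
    b <- m[background, tf]
    cnt_between <- 0
    for (x in f) for (y in b) cnt_between <- cnt_between + abs(x - y)
    between <- cnt_between / (length(f) * length(b))
    cnt_within <- 0
    for (i in seq_along(f)) {
      for (j in seq_along(f)) {
        if (j > i) cnt_within <- cnt_within + abs(f[i] - f[j])
      }
    }
    within <- cnt_within / (length(f) * (length(f) - 1) / 2)
    (between - within) * sign(mean(f) - mean(b))
  }, numeric(1))
}

# Random binary target matrix plus a foreground/background split, for the
# oracle-equivalence property.
random_ddm_case <- function(max_genes = 6, max_tfs = 4) {
  n_genes <- sample(4:max_genes, 1)
  n_tfs <- sample(1:max_tfs, 1)
  genes <- paste0("g", seq_len(n_genes))
  tm <- tibble::tibble(gene_id = genes)
  for (t in seq_len(n_tfs)) {
    tm[[paste0("TF", t)]] <- sample(0:1, n_genes, replace = TRUE)
  }
  n_f <- sample(2:(n_genes - 1), 1)
  fg <- sample(genes, n_f)
  n_b <- sample(1:(n_genes - n_f), 1)
  bg <- sample(setdiff(genes, fg), n_b)
  list(targets = tm, foreground = fg, background = bg)
}

# Exact distribution of a single slot's rank product when every replicate is
# an independent uniform permutation of 1..n_tfs: enumerate all rank tuples.
exact_rp_cdf <- function(n_tfs, n_replicates) {
  grids <- rep(list(seq_len(n_tfs)), n_replicates)
  tuples <- as.matrix(expand.grid(grids))
  rp <- exp(rowMeans(log(tuples)))
  function(x) mean(rp <= x + 1e-12)
}

# Minimal annotation fixture.
tiny_annotation <- function(n = 6, spacing = 10000L) {
  tibble::tibble(
    gene_id = paste0("g", seq_len(n)),
    chrom = "chr1",
    tss = spacing * seq_len(n),
    strand = rep(c("+", "-"), length.out = n)
  )
}

# A small planted dataset in the sparse-binding demonstration regime where
# the screen has power at 200 genes (see the methods vignette).
demo_dataset <- function(seed) {
  crmscreen::simulate_dataset(crmscreen::sim_config(
    planted_tfs = 1:3, background_peak_rate = 20,
    planted_offset_max_bp = 800, seed = seed
  ))
}

demo_screen_config <- function(seed) {
  crmscreen::screen_config(n_background_sets = 200, n_replicates = 7,
                           n_permutations = 2000, seed = seed)
}
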