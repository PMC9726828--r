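four_gene_targets <- function(col_a, col_b = NULL) {
  tm <- tibble::tibble(gene_id = paste0("g", seq_along(col_a)), A = col_a)
  if (!is.null(col_b)) tm$B <- col_b
  tm
}

test_that("background sampling is seeded, exclusive, and size-checked", {
  ann <- tiny_annotation(20)
  cfg <- screen_config(n_background_sets = 10, background_set_size = 5)
  s1 <- sample_background_sets(ann, c("g1", "g2"), cfg, replicate_seed = 99)
  s2 <- sample_background_sets(ann, c("g1", "g2"), cfg, replicate_seed = 99)
  expect_identical(s1, s2)
  expect_true(all(vapply(s1, function(s) length(intersect(s, c("g1", "g2"))),
                         integer(1)) == 0))
  expect_true(all(lengths(s1) == 5))
  expect_true(all(vapply(s1, anyDuplicated, integer(1)) == 0))

  # universe of exactly set_size genes: every set is the whole universe
  ann8 <- tiny_annotation(10)
  cfg8 <- screen_config(n_background_sets = 5, background_set_size = 8)
  s <- sample_background_sets(ann8, c("g1", "g2"), cfg8, replicate_seed = 1)
  expect_true(all(vapply(s, function(x) setequal(x, paste0("g", 3:10)),
                         logical(1))))

  expect_error(
    sample_background_sets(tiny_annotation(5), c("g1", "g2"),
                           screen_config(background_set_size = 8), 1),
    "insufficient"
  )
})

test_that("ddm_score matches hand-worked contrasts", {
  # perfect discriminator
  tm <- four_gene_targets(c(1L, 1L, 0L, 0L))
  expect_equal(ddm_score(tm, c("g1", "g2"), c("g3", "g4"))$score, 1)
  # constant column: no discrimination
  expect_equal(ddm_score(four_gene_targets(c(1L, 1L, 1L, 1L)),
                         c("g1", "g2"), c("g3", "g4"))$score, 0)
  # equal targeted fractions zero out via the sign factor
  expect_equal(ddm_score(four_gene_targets(c(1L, 0L, 1L, 0L)),
                         c("g1", "g2"), c("g3", "g4"))$score, 0)
  expect_error(ddm_score(tm, c("g1", "gX"), "g3"), "gX")
  expect_error(ddm_score(tm, "g1", c("g3", "g4")), ">= 2")
})

test_that("ddm_score equals the brute-force pair-enumeration oracle exactly", {
  withr::local_seed(101)
  for (i in 1:100) {
    case <- random_ddm_case()
    got <- ddm_score(case$targets, case$foreground, case$background)
    want <- ddm_oracle(case$targets, case$foreground, case$background)
    expect_identical(got$score, unname(want))
  }
})

test_that("swapping foreground and background negates the sign factor", {
  withr::local_seed(102)
  raw_contrast <- function(m, fg, bg) {
    # unsigned between-minus-within contrast, via explicit pair means
    vapply(colnames(m), function(tf) {
      f <- m[fg, tf]; b <- m[bg, tf]
      mean(abs(outer(f, b, "-"))) -
        mean(abs(outer(f, f, "-"))[upper.tri(diag(length(f)))])
    }, numeric(1))
  }
  for (i in 1:50) {
    case <- random_ddm_case(max_genes = 8)
    n <- min(length(case$foreground), length(case$background))
    if (n < 2) next
    fg <- case$foreground[seq_len(n)]
    bg <- case$background[seq_len(n)]
    m <- as.matrix(case$targets[, -1, drop = FALSE])
    rownames(m) <- case$targets$gene_id
    sgn <- sign(colMeans(m[fg, , drop = FALSE]) -
                  colMeans(m[bg, , drop = FALSE]))
    a <- ddm_score(case$targets, fg, bg)$score
    b <- ddm_score(case$targets, bg, fg)$score
    expect_equal(a, unname(raw_contrast(m, fg, bg) * sgn))
    expect_equal(b, unname(raw_contrast(m, bg, fg) * -sgn))
  }
})

test_that("replicate scores average background sets and use midranks", {
  ann <- tiny_annotation(12)
  tm <- tibble::tibble(gene_id = ann$gene_id,
                       A = c(1L, 1L, rep(0L, 10)),
                       B = c(1L, 0L, rep(0L, 10)))
  cfg <- screen_config(n_background_sets = 1, background_set_size = 4,
                       n_replicates = 2, seed = 5)
  rep1 <- replicate_screen(tm, ann, c("g1", "g2"), cfg, 1)
  seeds <- crmscreen:::derive_seeds(cfg$seed, cfg$n_replicates + 1L)
  set1 <- sample_background_sets(ann, c("g1", "g2"), cfg, seeds[1])[[1]]
  expect_equal(rep1$score,
               ddm_score(tm, c("g1", "g2"), set1)$score)

  # descending rank order, midranks for ties
  expect_equal(rank(-c(1.0, 0.2)), c(1, 2))
  tm_tie <- tibble::tibble(gene_id = ann$gene_id,
                           A = c(1L, 1L, rep(0L, 10)),
                           B = c(1L, 1L, rep(0L, 10)))
  rep_tie <- replicate_screen(tm_tie, ann, c("g1", "g2"), cfg, 1)
  expect_equal(rep_tie$rank, c(1.5, 1.5))
})

test_that("rank product is the geometric mean of replicate ranks", {
  rp <- rank_product(tibble::tibble(tf = c("A", "B"),
                                    r1 = c(1, 2), r2 = c(1, 8)))
  expect_equal(rp$rank_product, c(1, 4))
  rp3 <- rank_product(tibble::tibble(tf = "A", r1 = 1, r2 = 2, r3 = 3))
  expect_equal(rp3$rank_product, 6^(1 / 3), tolerance = 1e-12)
  expect_error(rank_product(tibble::tibble(tf = "A", r1 = NA_real_)),
               "missing rank")
})

test_that("rank-product p-values agree with exhaustive enumeration", {
  for (n_tfs in 2:3) {
    cdf <- exact_rp_cdf(n_tfs, n_replicates = 2)
    obs <- exp(rowMeans(log(cbind(seq_len(n_tfs), seq_len(n_tfs)))))
    p <- rank_product_pvalues(obs, n_tfs = n_tfs, n_replicates = 2,
                              n_permutations = 10000, seed = 42)
    for (k in seq_along(obs)) {
      exact <- cdf(obs[k])
      se <- sqrt(exact * (1 - exact) / 10000)
      expect_lt(abs(p[k] - exact), 3 * se + 1e-4)
    }
  }
})

test_that("the worst possible rank product gets p = 1 up to the correction", {
  n_tfs <- 5
  worst <- exp(mean(log(rep(n_tfs, 3))))
  p <- rank_product_pvalues(c(1e9, worst), n_tfs = n_tfs, n_replicates = 3,
                            n_permutations = 500, seed = 1)
  expect_equal(p[1], 1)             # nothing exceeds 1e9
  expect_gte(p[2], 1 - 1 / (500 * n_tfs))
})

test_that("p-values are reproducible and consistent across permutation counts", {
  obs <- c(1.2, 3.5, 8)
  p1 <- rank_product_pvalues(obs, 10, 4, n_permutations = 2000, seed = 7)
  p2 <- rank_product_pvalues(obs, 10, 4, n_permutations = 2000, seed = 7)
  expect_identical(p1, p2)
  p4 <- rank_product_pvalues(obs, 10, 4, n_permutations = 4000, seed = 7)
  se <- sqrt(p1 * (1 - p1) / 2000)
  expect_true(all(abs(p4 - p1) < 3 * se + 1e-3))
})

test_that("BH adjustment matches the hand-applied step-up formula", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04, 0.8)),
               c(0.04, 0.04, 0.16 / 3, 0.8), tolerance = 1e-12)
  expect_equal(fdr_adjust(rep(0.3, 4)), rep(0.3, 4))
  expect_equal(fdr_adjust(0.07), 0.07)
  expect_error(fdr_adjust(c(0.5, 0)), "0, 1")
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("top-regulator selection honours cutoff, order and name tie-break", {
  rk <- tibble::tibble(tf = c("Z", "A", "M"),
                       rank_product = c(1.2, 1.2, 3),
                       q_value = c(0.01, 0.01, 0.2))
  expect_equal(select_top_regulators(rk, 0.05), c("A", "Z"))
  expect_equal(select_top_regulators(rk, 0.001), character(0))
})

test_that("the full screen is a pure function of inputs and seed", {
  ds <- demo_dataset(seed = 31)
  tg <- build_target_matrix(
    empirical_pvalues(score_matrix(ds$annotation, ds$peaks)), 0.05)
  cfg <- screen_config(n_background_sets = 30, n_replicates = 3,
                       n_permutations = 300, seed = 17)
  s1 <- discover_regulators(tg, ds$annotation, ds$foreground, cfg)
  s2 <- discover_regulators(tg, ds$annotation, ds$foreground, cfg)
  expect_identical(s1$ranking, s2$ranking)
  # ranks within each replicate form a midrank assignment over the TF list
  n_tfs <- nrow(s1$ranking)
  for (r in 1:3) {
    expect_equal(sum(s1$ranking[[paste0("rank_rep", r)]]),
                 n_tfs * (n_tfs + 1) / 2)
  }
})
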