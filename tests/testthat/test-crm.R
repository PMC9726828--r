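trace_annotation <- tibble::tibble(gene_id = "geneA", chrom = "chr1",
                                   tss = 10000L, strand = "+")
trace_peaks <- tibble::tibble(
  chrom = "chr1",
  start = c(9900L, 9940L, 11500L),
  end = c(9950L, 9990L, 11550L),
  tf = c("TF1", "TF2", "TF3")
)

test_that("single-linkage merging joins intervals within the gap", {
  x <- tibble::tibble(start = c(9900L, 9940L), end = c(9950L, 9990L),
                      label = c("TF1", "TF2"))
  m <- merge_clusters(x, max_gap_bp = 50)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(9900L, 9990L))
  expect_equal(m$labels[[1]], c("TF1", "TF2"))

  # separated by exactly max_gap: one cluster; by max_gap + 1: two
  y <- tibble::tibble(start = c(100L, 200L), end = c(150L, 250L), label = "T")
  expect_equal(nrow(merge_clusters(y, max_gap_bp = 50)), 1)
  expect_equal(nrow(merge_clusters(y, max_gap_bp = 49)), 2)

  empty <- tibble::tibble(start = integer(), end = integer(),
                          label = character())
  expect_equal(nrow(merge_clusters(empty, 50)), 0)
})

test_that("the worked example yields exactly one two-TF CRM", {
  crm <- call_crm("geneA", trace_annotation, trace_peaks)
  expect_equal(nrow(crm), 1)
  expect_equal(crm$start, 9900L)
  expect_equal(crm$end, 9990L)
  expect_equal(crm$n_tfs, 2L)
  expect_equal(crm$member_tfs, "TF1,TF2")
  expect_equal(crm$name, "geneA_CRM1")
})

test_that("peaks outside the TSS window contribute nothing", {
  far <- tibble::tibble(chrom = "chr1", start = c(9900L, 20000L),
                        end = c(9990L, 20100L), tf = c("TF1", "TF2"))
  crm <- call_crm("geneA", trace_annotation, far)
  expect_equal(nrow(crm), 0)
})

test_that("evidence tracks act as mandatory overlap filters", {
  hit <- tibble::tibble(chrom = "chr1", start = 9890L, end = 9960L,
                        tf = "open_chromatin")
  miss <- tibble::tibble(chrom = "chr1", start = 11000L, end = 11100L,
                         tf = "open_chromatin")
  with_ev <- call_crm("geneA", trace_annotation, trace_peaks, evidence = hit)
  expect_equal(nrow(with_ev), 1)
  expect_true(with_ev$evidence_open_chromatin)
  expect_equal(nrow(call_crm("geneA", trace_annotation, trace_peaks,
                             evidence = miss)), 0)
  # a stricter overlap requirement can reject an otherwise-passing cluster
  small <- tibble::tibble(chrom = "chr1", start = 9900L, end = 9905L,
                          tf = "cons")
  expect_equal(nrow(call_crm("geneA", trace_annotation, trace_peaks,
                             evidence = small,
                             params = crm_params(evidence_min_overlap_bp = 10))),
               0)
})

test_that("unknown foreground genes are a hard error", {
  expect_error(call_crm("nope", trace_annotation, trace_peaks), "nope")
})

test_that("output is invariant to input interval and peak-set order", {
  withr::local_seed(21)
  ann <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                        tss = c(10000L, 50000L), strand = c("+", "-"))
  s <- sort(c(sample(8200:11800, 12), sample(48200:51800, 12)))
  pk <- tibble::tibble(chrom = "chr1", start = s, end = s + 120L,
                       tf = sample(paste0("TF", 1:3), 24, replace = TRUE))
  base <- call_crm(c("gA", "gB"), ann, pk)
  for (i in 1:5) {
    shuf <- pk[sample(nrow(pk)), ]
    expect_equal(call_crm(c("gB", "gA"), ann, shuf), base)
  }
  # every reported CRM's member TFs have a binding region inside the interval
  for (k in seq_len(nrow(base))) {
    tfs <- strsplit(base$member_tfs[k], ",")[[1]]
    for (tf in tfs) {
      hit <- pk$tf == tf & pk$start < base$end[k] & pk$end > base$start[k]
      expect_true(any(hit))
    }
  }
})

test_that("tightening parameters never grows clusters or adds CRM", {
  withr::local_seed(22)
  ann <- tibble::tibble(gene_id = "gA", chrom = "chr1", tss = 10000L,
                        strand = "+")
  for (i in 1:10) {
    s <- sample(8200:11600, 15)
    pk <- tibble::tibble(chrom = "chr1", start = s, end = s + 100L,
                         tf = sample(paste0("TF", 1:4), 15, replace = TRUE))
    wide <- call_crm("gA", ann, pk, params = crm_params(max_gap_bp = 100,
                                                        max_len_bp = 4000,
                                                        min_len_bp = 1))
    narrow <- call_crm("gA", ann, pk, params = crm_params(max_gap_bp = 20,
                                                          max_len_bp = 4000,
                                                          min_len_bp = 1))
    if (nrow(narrow) > 0) {
      expect_lte(max(narrow$end - narrow$start),
                 max(wide$end - wide$start))
    }
    loose <- call_crm("gA", ann, pk, params = crm_params(min_distinct_tfs = 2,
                                                         max_len_bp = 4000,
                                                         min_len_bp = 1))
    strict <- call_crm("gA", ann, pk, params = crm_params(min_distinct_tfs = 3,
                                                          max_len_bp = 4000,
                                                          min_len_bp = 1))
    expect_lte(nrow(strict), nrow(loose))
  }
})

test_that("clusters are clipped to the window before length filtering", {
  # one long peak crossing the window edge: clipped to the window boundary
  pk <- tibble::tibble(chrom = "chr1", start = c(7000L, 8010L),
                       end = c(8100L, 8200L), tf = c("TF1", "TF2"))
  crm <- call_crm("geneA", trace_annotation, pk,
                  params = crm_params(min_len_bp = 1))
  expect_equal(nrow(crm), 1)
  expect_equal(crm$start, 8000L)  # window lower edge at tss - 2000
  expect_equal(crm$end, 8200L)
})

test_that("CRM BED output round-trips and records parameters", {
  crm <- call_crm("geneA", trace_annotation, trace_peaks)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_crm(crm, bed)
  expect_true(any(grepl("tss_window_bp=2000", readLines(bed))))
  back <- read_peaks(bed, "crm")
  expect_equal(back$start, crm$start)
  expect_equal(back$end, crm$end)
  expect_equal(back$name, crm$name)
  sidecar <- readr::read_tsv(sub("\\.bed$", ".tsv", bed),
                             show_col_types = FALSE)
  expect_equal(sidecar$member_tfs, "TF1,TF2")
})
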