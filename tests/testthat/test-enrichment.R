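make_cm <- function(counts, wt, label = "lib") {
  dimnames(counts) <- list(position = seq_len(nrow(counts)),
                           mut = mutation_types())
  toy_count_matrix(counts, wt, label)
}

test_that("compute_probabilities is flat normalisation over non-WT cells", {
  wt <- c("M", "K", "L")
  f <- matrix(0L, 3, 21)
  f[2, 1] <- 7L
  p <- compute_probabilities(make_cm(f, wt))
  expect_equal(p$p[2, 1], 1.0)
  expect_equal(sum(p$p, na.rm = TRUE), 1.0)

  f2 <- matrix(0L, 3, 21)
  f2[2, 1] <- 30L; f2[3, 5] <- 10L
  p2 <- compute_probabilities(make_cm(f2, wt))
  expect_equal(unname(p2$p[2, 1]), 0.75)
  expect_equal(unname(p2$p[3, 5]), 0.25)

  # random matrix vs flat-sum oracle, cell by cell
  set.seed(3)
  f3 <- matrix(rpois(50 * 21, 4), 50, 21)
  wt3 <- sample(mutation_types()[1:20], 50, replace = TRUE)
  cm3 <- make_cm(f3, wt3)
  p3 <- compute_probabilities(cm3)
  wt_flag <- outer(wt3, mutation_types(), `==`)
  oracle <- f3 / sum(f3[!wt_flag])
  expect_equal(unname(p3$p[!wt_flag]), unname(oracle[!wt_flag]))
  expect_true(all(is.na(p3$p[wt_flag])))
  expect_equal(sum(p3$p, na.rm = TRUE), 1, tolerance = 1e-12)
  # p is 0 wherever f is 0 (non-WT cells)
  expect_true(all(p3$p[!wt_flag & f3 == 0] == 0))

  expect_error(compute_probabilities(make_cm(matrix(0L, 3, 21), wt)),
               "empty_library")
})

test_that("compute_enrichment reproduces a manual Eq-by-Eq computation", {
  wt <- c("M", "K", "L")
  wt_flag <- outer(wt, mutation_types(), `==`)

  # identical libraries, all counts > 15 -> all OK cells are exactly 0
  f <- matrix(20L, 3, 21)
  em0 <- compute_enrichment(make_cm(f, wt, "naive"), make_cm(f, wt, "r1"))
  expect_true(all(em0$E[em0$mask == "OK"] == 0))
  expect_true(all(em0$mask[wt_flag] == "WT_CELL"))

  # doubling one selected probability: a cell with p_sel exactly 2x p_naive
  fn <- matrix(0L, 3, 21); fs <- matrix(0L, 3, 21)
  fn[2, 1] <- 100L; fn[3, 2] <- 100L
  fs[2, 1] <- 200L; fs[3, 2] <- 100L
  # p_sel(2,1) = 2/3 vs p_naive 1/2 -> E = log2(4/3); use equal-total design
  fs2 <- matrix(0L, 3, 21)
  fs2[2, 1] <- 100L; fs2[3, 2] <- 50L; fs2[3, 3] <- 50L
  em1 <- compute_enrichment(make_cm(fn, wt, "naive"), make_cm(fs, wt, "r1"))
  expect_equal(unname(em1$E[2, 1]), log2((200 / 300) / (100 / 200)))

  # hand-built 3-position toy vs the manual Eq. 1-3 oracle
  # (column 8 = "I"; no collision with wt M/K/L at columns 11/9/10)
  fn2 <- matrix(0L, 3, 21)
  fn2[1, 3] <- 100L; fn2[2, 4] <- 50L; fn2[3, 5] <- 25L; fn2[2, 8] <- 10L
  fs3 <- matrix(0L, 3, 21)
  fs3[1, 3] <- 200L; fs3[2, 4] <- 25L; fs3[3, 5] <- 25L; fs3[2, 8] <- 40L
  em2 <- compute_enrichment(make_cm(fn2, wt, "naive"),
                            make_cm(fs3, wt, "r4"), min_count = 15)
  oracle <- oracle_enrichment(fn2, fs3, wt_flag, min_count = 15)
  ok <- em2$mask == "OK"
  expect_equal(unname(em2$E[ok]), unname(oracle[ok]), tolerance = 1e-12)
  # the 10-count cell is masked LOW_COUNT, not computed
  expect_equal(em2$mask[2, 8], "LOW_COUNT")
  expect_true(is.na(em2$E[2, 8]))
  # explicit values from the manual computation (totals 185 naive, 290 sel)
  expect_equal(unname(em2$E[1, 3]), log2((200 / 290) / (100 / 185)),
               tolerance = 1e-12)
  expect_equal(unname(em2$E[2, 4]), log2((25 / 290) / (50 / 185)),
               tolerance = 1e-12)
})

test_that("enrichment masks are exclusive and correct", {
  wt <- c("M", "K")
  fn <- matrix(0L, 2, 21); fs <- matrix(0L, 2, 21)
  fn[1, 2] <- 100L; fs[1, 2] <- 50L      # OK
  fn[2, 3] <- 100L; fs[2, 3] <- 0L       # NO_DATA
  fn[2, 4] <- 15L;  fs[2, 4] <- 99L      # LOW_COUNT (boundary: > 15 required)
  fn[2, 5] <- 16L;  fs[2, 5] <- 1L       # OK (16 > 15)
  em <- compute_enrichment(make_cm(fn, wt, "naive"), make_cm(fs, wt, "r1"))
  expect_equal(em$mask[1, 2], "OK")
  expect_equal(em$mask[2, 3], "NO_DATA")
  expect_equal(em$mask[2, 4], "LOW_COUNT")
  expect_equal(em$mask[2, 5], "OK")
  expect_true(is.na(em$E[2, 3]))
  expect_setequal(unique(as.vector(em$mask)),
                  c("OK", "NO_DATA", "LOW_COUNT", "WT_CELL"))
  # require_selected switch masks the selected side too
  em_rs <- compute_enrichment(make_cm(fn, wt, "naive"),
                              make_cm(fs, wt, "r1"), require_selected = TRUE)
  expect_equal(em_rs$mask[2, 5], "LOW_COUNT")

  # shape mismatch errors
  fn3 <- matrix(20L, 3, 21)
  expect_error(compute_enrichment(make_cm(fn3, c("M", "K", "L")),
                                  make_cm(fn, wt)), "shape")
})

test_that("scale invariance, antisymmetry and shared-denominator coupling", {
  set.seed(19)
  for (rep in 1:5) {
    wt <- sample(mutation_types()[1:20], 8, replace = TRUE)
    fn <- matrix(rpois(8 * 21, 40), 8, 21)
    fs <- matrix(rpois(8 * 21, 40), 8, 21)
    n <- make_cm(fn, wt, "naive"); s <- make_cm(fs, wt, "sel")
    em <- compute_enrichment(n, s)
    # scale invariance: k x both libraries
    em_k <- compute_enrichment(make_cm(fn * 7L, wt), make_cm(fs * 7L, wt),
                               min_count = 15 * 7)
    okb <- em$mask == "OK" & em_k$mask == "OK"
    expect_equal(em_k$E[okb], em$E[okb], tolerance = 1e-12)
    # antisymmetry
    em_sw <- compute_enrichment(s, n, min_count = 0)
    em_fw <- compute_enrichment(n, s, min_count = 0)
    ok2 <- em_sw$mask == "OK" & em_fw$mask == "OK"
    expect_equal(em_sw$E[ok2], -em_fw$E[ok2], tolerance = 1e-12)
  }
  # adding selected counts to one cell raises its E, weakly lowers others
  wt <- c("M", "K", "L")
  fn <- matrix(50L, 3, 21); fs <- matrix(50L, 3, 21)
  before <- compute_enrichment(make_cm(fn, wt), make_cm(fs, wt))
  fs2 <- fs; fs2[2, 2] <- fs2[2, 2] + 100L
  after <- compute_enrichment(make_cm(fn, wt), make_cm(fs2, wt))
  ok <- before$mask == "OK"
  expect_gt(after$E[2, 2], before$E[2, 2])
  others <- ok; others[2, 2] <- FALSE
  expect_true(all(after$E[others] <= before$E[others]))
})

test_that("render_heatmap writes TSVs that round-trip, plus the image", {
  wt <- c("M", "K", "L")
  fn <- matrix(0L, 3, 21); fs <- matrix(0L, 3, 21)
  fn[1, 3] <- 100L; fn[2, 4] <- 50L; fn[3, 5] <- 25L
  fs[1, 3] <- 200L; fs[2, 4] <- 25L; fs[3, 5] <- 25L
  em <- compute_enrichment(make_cm(fn, wt, "naive"), make_cm(fs, wt, "r1"))
  td <- withr::local_tempdir()
  out <- render_heatmap(em, file.path(td, "hm"))
  expect_true(all(file.exists(out$files)))
  back <- read_enrichment_tsv(file.path(td, "hm_E.tsv"))
  expect_equal(unname(back), unname(em$E))
  expect_equal(out$n_ok, 3L)

  # all-masked matrix: zero OK cells, all-NA numeric TSV, all-grey image
  em_all <- compute_enrichment(make_cm(fn, wt, "naive"),
                               make_cm(fs, wt, "r1"), min_count = 10000)
  out2 <- render_heatmap(em_all, file.path(td, "hm2"))
  expect_equal(out2$n_ok, 0L)
  expect_true(all(is.na(read_enrichment_tsv(file.path(td, "hm2_E.tsv")))))

  # single OK cell -> exactly one coloured cell reported
  fn1 <- matrix(0L, 3, 21); fs1 <- matrix(0L, 3, 21)
  fn1[2, 2] <- 100L; fs1[2, 2] <- 200L
  em1 <- compute_enrichment(make_cm(fn1, wt, "naive"), make_cm(fs1, wt, "r1"))
  out3 <- render_heatmap(em1, file.path(td, "hm3"))
  expect_equal(out3$n_ok, 1L)
})
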