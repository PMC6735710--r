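test_that("noiseless generation is the exact Gaussian mixture", {
  peaks <- data.frame(protein_id = c("A", "B", "B"),
                      center = c(10, 5, 15), width = c(2, 1.5, 2),
                      height = c(100, 50, 80))
  p <- generate_profile("s", c("A", "B", "C"), 20L, peaks,
                        noise_cv = 0, dropout_p = 0)
  expect_equal(p$intensities["A", 10], 100)          # peak value at center
  expect_equal(which.max(p$intensities["A", ]), c(slice_10 = 10L))
  expect_equal(unname(p$intensities["C", ]), rep(0, 20))
  # two peaks sum
  expect_equal(p$intensities["B", 5],
               50 + 80 * exp(-0.5 * (10 / 2)^2))
  expect_error(generate_profile("s", c("A"), 20L, peaks),
               "not in roster")
})

test_that("generation is seed-deterministic and dropout is calibrated", {
  peaks <- data.frame(protein_id = sprintf("P%d", 1:50),
                      center = rep(10, 50), width = rep(2, 50),
                      height = rep(100, 50))
  roster <- sprintf("P%d", 1:50)
  p1 <- generate_profile("s", roster, 20L, peaks, seed = 99L)
  p2 <- generate_profile("s", roster, 20L, peaks, seed = 99L)
  expect_identical(p1$intensities, p2$intensities)

  # dropout_p = 0.5 over 1000 cells: inside the binomial 99% CI
  pd <- generate_profile("s", roster, 20L, peaks, noise_cv = 0,
                         dropout_p = 0.5, seed = 4L)
  n_zero <- sum(pd$intensities == 0)
  ci <- qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gte(n_zero, ci[1])
  expect_lte(n_zero, ci[2])
})

test_that("apply_warp duplicates slices and scales the lane", {
  p <- toy_profile("s", 3L, 6L)
  expect_identical(apply_warp(p, integer(0), 1)$intensities,
                   {m <- p$intensities
                    colnames(m) <- sprintf("slice_%d", 1:6); m})
  w <- apply_warp(p, 4L, 2)
  expect_equal(ncol(w$intensities), 7L)
  expect_equal(unname(w$intensities[, 5]), unname(w$intensities[, 4]))
  expect_equal(unname(w$intensities[, 4]), unname(p$intensities[, 4]) * 2)
  expect_error(apply_warp(p, 9L), "out of range")
})

test_that("the aligner undoes a known warp", {
  peaks <- data.frame(protein_id = sprintf("P%d", 1:10),
                      center = seq(5, 25, length.out = 10),
                      width = rep(1.5, 10), height = rep(100, 10))
  roster <- sprintf("P%d", 1:10)
  x <- generate_profile("x", roster, 30L, peaks, noise_cv = 0, dropout_p = 0)
  y0 <- generate_profile("y", roster, 30L, peaks, noise_cv = 0, dropout_p = 0)

  # pure duplication (factor 1): exact zero cost, gap at the true site
  y <- apply_warp(y0, insert_at = 12L, factor = 1)
  pw <- dtw_align(x$intensities, y$intensities)
  expect_identical(pw$cost, 0)
  expect_length(pw$gaps_x, 1L)
  expect_equal(unname(pw$steps[pw$gaps_x, 1]), 12L)

  # with a gel factor, sum-normalization cancels it only up to the mass the
  # duplicated slice adds, so the cost is small relative to the lane total
  y2 <- apply_warp(y0, insert_at = 12L, factor = 2)
  norm <- normalize_sum(build_profile_set(list(x, y2)))$profile_set
  pw2 <- dtw_align(norm$profiles$x, norm$profiles$y)
  expect_lt(pw2$cost, 0.1 * sum(norm$profiles$x$intensities))
  expect_length(pw2$gaps_x, 1L)
  expect_lte(abs(pw2$steps[pw2$gaps_x, 1] - 12L), 1L)
})

test_that("generate_study produces a consistent labeled dataset", {
  st <- generate_study(n_case = 2L, n_control = 2L, n_proteins = 20L,
                       n_slices = 30L, n_affected = 3L, seed = 5L)
  expect_length(st$profiles, 4L)
  expect_identical(st$groups$case, c("case_1", "case_2"))
  expect_length(st$truth$affected, 3L)
  # warped lane lengths: n_slices + per-gel duplications
  for (s in names(st$profiles))
    expect_equal(ncol(st$profiles[[s]]$intensities),
                 30L + length(st$truth$warps[[s]]))
  # all profiles satisfy the container invariants (validator would stop)
  for (p in st$profiles) expect_s3_class(p, "cx_profile")

  st2 <- generate_study(n_case = 2L, n_control = 2L, n_proteins = 20L,
                        n_slices = 30L, n_affected = 3L, seed = 5L)
  expect_identical(lapply(st2$profiles, `[[`, "intensities"),
                   lapply(st$profiles, `[[`, "intensities"))
  expect_identical(st2$truth$affected, st$truth$affected)
})
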