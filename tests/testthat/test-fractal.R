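# box counting, offset averaging, scaling-window selection, FD fitting

test_that("count_boxes matches the aligned-grid examples and rejects bad input", {
  cube <- make_phantom("cube", size = 8)
  expect_identical(count_boxes(cube, 2), 64L)
  expect_identical(count_boxes(cube, 8), 1L)
  expect_identical(count_boxes(cube, 2, offset = c(1, 0, 0)), 80L)

  empty <- voxel_mask(array(FALSE, dim = c(4, 4, 4)))
  expect_error(count_boxes(empty, 2), class = "fracdem_empty_mask")
  expect_error(count_boxes(cube, 0.5), class = "fracdem_scale_error")
})

test_that("count_boxes equals the brute-force cell-hashing oracle", {
  set.seed(11)
  for (i in 1:12) {
    m <- random_mask(p = runif(1, 0.05, 0.6))
    s <- sample(c(1, 2, 3, 4, 8), 1)
    off <- if (i %% 2) c(0, 0, 0) else runif(3, 0, s)
    expect_identical(count_boxes(m, s, off), oracle_box_count(m, s, off))
  }
})

test_that("zero-offset counts are non-increasing over nested power-of-two grids", {
  set.seed(7)
  for (i in 1:5) {
    m <- random_mask(p = 0.3)
    counts <- vapply(c(1, 2, 4, 8), function(s) count_boxes(m, s),
                     integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("box_count_curve honors its contracts", {
  one <- voxel_mask(array(c(TRUE, rep(FALSE, 26)), dim = c(3, 3, 3)))
  ser <- box_count_curve(one, scales = c(1, 2, 4), seed = 5)
  expect_equal(ser$counts, c(1, 1, 1))

  cube <- make_phantom("cube", size = 64)
  ser <- box_count_curve(cube, scales = c(1, 2, 4, 8, 16, 32), seed = 9)
  expect_true(all(ser$counts >= (64 / ser$scales)^3 - 1e-9))
  expect_true(all(ser$counts <= (64 / ser$scales + 1)^3 + 1e-9))

  # determinism for a fixed seed; different seed perturbs a fractal's curve
  again <- box_count_curve(cube, scales = c(1, 2, 4, 8, 16, 32), seed = 9)
  expect_identical(ser, again)

  expect_error(box_count_curve(cube, scales = c(1, 2)),
               class = "fracdem_scale_error")
  expect_error(box_count_curve(cube, scales = c(4, 2, 1)),
               class = "fracdem_scale_error")
})

test_that("default_scales spans 1..E/2 and errors on tiny structures", {
  expect_equal(default_scales(make_phantom("cube", size = 64)), 1:32)
  expect_equal(default_scales(make_phantom("cube", size = 8)), 1:4)
  expect_equal(default_scales(make_phantom("cube", size = 64),
                              kind = "pow2"), c(1, 2, 4, 8, 16, 32))
  tiny <- voxel_mask(array(TRUE, dim = c(2, 2, 2)))
  expect_error(default_scales(tiny), class = "fracdem_scale_error")
})

test_that("scaling-window selection matches exact power laws and the oracle", {
  scales <- c(1, 2, 4, 8, 16, 32)
  ser <- scale_series_for_test(scales, 2048 * scales^-2)
  w <- select_scaling_window(ser)
  expect_equal(c(w$start_index, w$end_index), c(1L, 6L))
  expect_equal(w$radj2_rounded, 1)

  # broken power law: cubic decay then flat -> window confined to the decay
  counts <- c(4096 * c(1, 2, 4, 8)^-3, 8, 8)
  wb <- select_scaling_window(scale_series_for_test(scales, counts))
  orc <- oracle_select_window(scales, counts)
  expect_equal(c(wb$start_index, wb$end_index), c(orc$start, orc$end))
  expect_lte(wb$end_index, 4L)

  # 3-point series: the only window
  w3 <- select_scaling_window(scale_series_for_test(c(1, 2, 4), c(9, 4, 2)))
  expect_equal(c(w3$start_index, w3$end_index), c(1L, 3L))

  expect_error(select_scaling_window(
    structure(list(scales = c(1, 2), counts = c(2, 1)),
              class = "scale_series")),
    class = "fracdem_series_error")
})

test_that("window selection equals the independent oracle on varied curves", {
  set.seed(23)
  for (i in 1:40) {
    n <- sample(5:10, 1)
    scales <- sort(sample(1:64, n))
    kind <- i %% 3
    counts <- if (kind == 0) {
      5000 * scales^-runif(1, 1, 3)                     # pure power law
    } else if (kind == 1) {
      brk <- scales[ceiling(n / 2)]                     # broken power law
      ifelse(scales <= brk, 5000 * scales^-2.5,
             5000 * brk^-2.5 * (scales / brk)^-0.5)
    } else {
      5000 * scales^-2 * exp(rnorm(n, 0, 0.15))         # noisy
    }
    counts <- pmax(counts, 1)
    w <- select_scaling_window(scale_series_for_test(scales, counts))
    orc <- oracle_select_window(scales, counts)
    expect_equal(c(w$start_index, w$end_index), c(orc$start, orc$end),
                 info = paste("curve", i))
  }
})

test_that("fit_fd recovers slopes exactly", {
  scales <- c(1, 2, 4, 8, 16)
  ser <- scale_series_for_test(scales, exp(12 - 2.5 * log(scales)))
  w <- select_scaling_window(ser)
  expect_equal(fit_fd(ser, w)$fd, 2.5, tolerance = 1e-10)

  flat <- scale_series_for_test(scales, rep(1, 5))
  expect_equal(fit_fd(flat, select_scaling_window(flat))$fd, 0)

  bad <- structure(list(start_index = 4L, end_index = 5L,
                        radj2_rounded = 1),
                   class = "scaling_window")
  expect_error(fit_fd(ser, bad), class = "fracdem_series_error")
})

test_that("FD is invariant under integer translation of the mask", {
  set.seed(3)
  occ <- array(FALSE, dim = c(40, 40, 40))
  occ[5:20, 5:20, 5:20] <- array(runif(16^3) < 0.4, dim = c(16, 16, 16))
  base <- voxel_mask(occ)
  shifted <- voxel_mask(array(FALSE, dim = c(40, 40, 40)))
  shifted$occupancy[12:27, 3:18, 9:24] <- occ[5:20, 5:20, 5:20]
  fd1 <- compute_fd(base, seed = 21)$fd
  fd2 <- compute_fd(shifted, seed = 21)$fd
  expect_equal(fd1, fd2, tolerance = 0.02)
})

test_that("hemispheric_average averages FD values", {
  expect_equal(hemispheric_average(2.34, 2.34), 2.34)
  expect_equal(hemispheric_average(2.30, 2.38), 2.34)
  expect_equal(hemispheric_average(0, 3), 1.5)
  fd <- compute_fd(make_phantom("cube", size = 8), seed = 1)
  expect_equal(hemispheric_average(fd, fd), fd$fd)
  expect_error(hemispheric_average("a", 2), class = "fracdem_series_error")
})
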