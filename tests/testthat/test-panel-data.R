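test_that("construction validates shape, uniqueness and balance", {
  arr <- array(rnorm(6 * 9 * 8), dim = c(6, 9, 8))
  long <- long_from_array(arr)
  expect_equal(nrow(long), 432L)
  p <- panel_dataset(long)
  expect_s3_class(p, "panel_dataset")
  expect_equal(p$n_subjects, 6L)
  expect_equal(unname(p$n_times), 9L)
  expect_length(p$variables, 8L)

  # one deleted row breaks balance, and the error names the gap
  expect_error(panel_dataset(long[-5, ]), "unbalanced.*S05.*missing time 0")
  # duplicated cell
  expect_error(panel_dataset(rbind(long, long[1, ])), "duplicate")
  # non-finite value
  bad <- long; bad$value[3] <- NA_real_
  expect_error(panel_dataset(bad), "non-finite")
  # minimum sizes
  tiny <- long_from_array(array(rnorm(1 * 9 * 2), dim = c(1, 9, 2)))
  expect_error(panel_dataset(tiny), "2 subjects")
  short <- long_from_array(array(rnorm(6 * 3 * 2), dim = c(6, 3, 2)))
  expect_error(panel_dataset(short), "4 time points")
})

test_that("ordinal time is assigned by sort order of the declared times", {
  arr <- array(rnorm(2 * 4 * 1), dim = c(2, 4, 1))
  long <- long_from_array(arr)
  long$time <- c(0, 4, 8, 10)[long$time + 1L]  # uneven clock times
  shuffled <- long[sample.int(nrow(long)), ]
  p <- panel_dataset(shuffled)
  expect_equal(sort(unique(p$data$time)), 0:3)
  expect_equal(p$meta$time_labels[["all"]], c(0, 4, 8, 10))
  pa <- panel_array(p)  # subjects are kept in order of appearance
  expect_equal(unname(pa[match(c("S01", "S02"), rownames(pa)), , 1]), arr[, , 1])
})

test_that("write_panel / read_panel round-trips cell-for-cell in all layouts", {
  arr <- array(rnorm(3 * 5 * 2), dim = c(3, 5, 2))
  p <- panel_dataset(long_from_array(arr, condition = "low"))
  for (layout in c("long", "wide")) {
    for (ext in c("csv", "tsv")) {
      path <- file.path(withr::local_tempdir(), paste0("panel.", ext))
      write_panel(p, path, layout = layout)
      q <- read_panel(path, layout = layout)
      expect_identical(panel_array(q, "low"), panel_array(p, "low"),
                       label = paste(layout, ext))
      expect_equal(q$conditions, "low")
    }
  }
  # long layout written file carries a condition column
  path <- file.path(withr::local_tempdir(), "panel.tsv")
  write_panel(p, path, "long")
  expect_true("condition" %in% names(read.delim(path)))
})

test_that("read_panel reports non-numeric cells and missing columns", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.csv")
  arr <- array(rnorm(2 * 4 * 1), dim = c(2, 4, 1))
  long <- long_from_array(arr)
  long$value <- as.character(long$value)
  long$value[4] <- "oops"
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  expect_error(read_panel(path), "non-numeric.*row")
  expect_error(read_panel(file.path(dir, "absent.csv")), "not found")
  long2 <- long_from_array(arr)
  names(long2)[names(long2) == "value"] <- "conc"
  write.csv(long2, path, row.names = FALSE, quote = FALSE)
  expect_error(read_panel(path), "not in file")
  expect_s3_class(read_panel(path, schema = list(value = "conc")), "panel_dataset")
})

test_that("calcium correction follows the albumin formula and is affine", {
  expect_equal(correct_calcium(2.30, 40.0), 2.30)
  expect_equal(correct_calcium(2.10, 47.0), 1.96)
  expect_equal(correct_calcium(2.00, 30.0), 2.20)
  # affine: the adjustment does not depend on the calcium level
  ca <- runif(20, 1.5, 3); alb <- runif(20, 25, 55)
  expect_equal(correct_calcium(ca, alb) - ca, correct_calcium(0 * ca, alb))
  expect_error(correct_calcium(NA_real_, 40), "finite")
  expect_error(correct_calcium(2.1, -3), "positive")
})

test_that("difference shrinks T, preserves balance, and inverts by cumsum", {
  withr::local_seed(1)
  N <- 4; T_ <- 9
  lin <- outer(rnorm(N, 5), rep(1, T_)) + outer(rnorm(N, 1), 0:(T_ - 1))
  other <- matrix(rnorm(N * T_), N)
  p <- two_var_panel(lin, other, names = c("lin", "other"))
  d <- difference(p, "lin", 1L)
  expect_equal(unname(d$n_times), T_ - 1L)
  expect_equal(d$n_subjects, N)
  expect_length(d$variables, 2L)
  # linear-in-time series differences to a constant (the slope)
  darr <- panel_array(d)
  expect_equal(unname(darr[, , "lin"]), outer(lin[, 2] - lin[, 1], rep(1, T_ - 1L)))
  # other variable truncated, not altered
  expect_equal(unname(darr[, , "other"]), other[, -1])
  # cumulative sum restores the original up to the lost first point
  rec <- t(apply(cbind(lin[, 1], darr[, , "lin"]), 1, cumsum))
  expect_equal(unname(rec), unname(lin))
  expect_error(difference(p, "lin", T_), "smaller than T")
  expect_match(d$meta$transformations[[1]], "difference\\(lin")
})
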