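test_that("pairwise deprivation follows the shortfall definition", {
  expect_equal(rd_pairwise(40, 10), 30)
  expect_equal(rd_pairwise(10, 10), 0)
  expect_equal(rd_pairwise(5, 10), 0)
  expect_equal(rd_pairwise(c(40, 10, 5), 10), c(30, 0, 0))
  expect_error(rd_pairwise(Inf, 1), "finite")
  expect_error(rd_pairwise(1, NA_real_), "finite")
})

test_that("index hand computations match worked examples", {
  x <- c(10, 20, 30, 40)
  expect_equal(rd_yitzhaki(x), c(15, 7.5, 2.5, 0))
  expect_equal(rd_deaton(x), c(0.6, 0.3, 0.1, 0))
  expect_equal(rd_podder(x)[1], (log(2) + log(3) + log(4)) / 4)
  expect_equal(rd_podder(c(1, exp(1), exp(2)))[1], 1.0)
  expect_equal(rd_percentile(x), c(0, 100 / 3, 200 / 3, 100))
  # ties contribute zero to the shortfall sums and average their ranks
  expect_equal(rd_yitzhaki(c(10, 10, 20)), c(10 / 3, 10 / 3, 0))
  expect_equal(rd_percentile(c(10, 10, 20)), c(25, 25, 100))
})

test_that("the richest member is undeprived and scaling leaves Deaton alone", {
  x <- c(3, 17, 120, 120)
  expect_equal(rd_yitzhaki(x)[3:4], c(0, 0))
  expect_equal(rd_deaton(x)[3:4], c(0, 0))
  expect_equal(rd_podder(x)[3:4], c(0, 0))
  expect_equal(rd_deaton(x * 1000), rd_deaton(x))
  expect_equal(rd_deaton(c(10, 20, 30, 40) * 1000)[1], 0.6)
})

test_that("all four indices agree with the pairwise brute-force oracle", {
  set.seed(101)
  for (v in 1:50) {
    n <- sample(2:50, 1)
    x <- exp(rnorm(n, 9, 1))
    if (v %% 3 == 0) x[sample(n, min(3, n))] <- x[1] # inject ties
    o <- oracle_indices(x)
    expect_equal(rd_yitzhaki(x), o$yitzhaki, tolerance = 1e-12)
    expect_equal(rd_deaton(x), o$deaton, tolerance = 1e-12)
    expect_equal(rd_podder(x), o$podder, tolerance = 1e-12)
    expect_equal(rd_percentile(x), o$percentile, tolerance = 1e-12)
    # compact identity: (1/n) sum (xk - xi) = gamma+ * (mu+ - xi)
    expect_equal(rd_yitzhaki(x), oracle_compact_yitzhaki(x), tolerance = 1e-12)
  }
})

test_that("indices are monotone in income within a group", {
  set.seed(202)
  for (rep in 1:20) {
    x <- sort(exp(rnorm(12, 9, 0.8)))
    expect_true(all(diff(rd_yitzhaki(x)) <= 1e-12))
    expect_true(all(diff(rd_deaton(x)) <= 1e-12))
    expect_true(all(diff(rd_podder(x)) <= 1e-12))
    expect_true(all(diff(rd_percentile(x)) >= -1e-12))
  }
})

test_that("translation shifts affect the indices as expected", {
  set.seed(303)
  x <- exp(rnorm(10, 9, 0.8))
  shift <- 5000
  expect_equal(rd_yitzhaki(x + shift), rd_yitzhaki(x))
  d0 <- rd_deaton(x); d1 <- rd_deaton(x + shift)
  non_top <- x < max(x)
  expect_true(all(d1[non_top] < d0[non_top]))
  expect_false(isTRUE(all.equal(rd_podder(x + shift), rd_podder(x))))
})

test_that("Deaton index stays within [0, 1) on valid income vectors", {
  set.seed(404)
  for (rep in 1:200) {
    n <- sample(2:40, 1)
    x <- exp(rnorm(n, sample(5:12, 1), runif(1, 0.1, 2)))
    d <- rd_deaton(x)
    expect_true(all(d >= 0 & d < 1))
  }
})

test_that("Podder excludes nonpositive incomes with a warning", {
  x <- c(-5, 10, 20, 40)
  expect_warning(p <- rd_podder(x), "nonpositive")
  expect_true(is.na(p[1]))
  expect_equal(p[-1], rd_podder(c(10, 20, 40)))
  expect_warning(p2 <- rd_podder(c(-1, -2, 7)), "Fewer than 2")
  expect_true(all(is.na(p2)))
})

test_that("add_rd_indices computes per village and standardizes over the sample", {
  df <- tibble::tibble(
    village_id = rep(c("a", "b"), each = 4),
    income = rep(c(10, 20, 30, 40), 2)
  )
  out <- add_rd_indices(df)
  expect_s3_class(out, "tbl_df")
  # identical income pattern => identical scores in both villages
  expect_equal(out$rd_deaton[1:4], out$rd_deaton[5:8])
  expect_equal(out$rd_deaton[1], 0.6)
  expect_equal(out$rd_percentile[5:8], c(0, 100 / 3, 200 / 3, 100))
  expect_equal(mean(out$rd_deaton_z), 0, tolerance = 1e-12)
  expect_equal(sd(out$rd_deaton_z), 1, tolerance = 1e-12)
})

test_that("add_rd_indices flags singletons and handles empty/bad input", {
  df <- tibble::tibble(village_id = c(1, 1, 2), income = c(10, 20, 30))
  expect_warning(out <- add_rd_indices(df), "singleton")
  expect_true(is.na(out$rd_deaton[3]))
  expect_false(anyNA(out$rd_deaton[1:2]))
  empty <- add_rd_indices(tibble::tibble(village_id = integer(), income = numeric()))
  expect_equal(nrow(empty), 0)
  expect_true("rd_deaton" %in% names(empty))
  expect_error(add_rd_indices(tibble::tibble(income = 1:3)), "village_id")
  expect_error(add_rd_indices(tibble::tibble(village_id = 1:2, income = c(1, Inf))),
               "non-finite")
})

test_that("large-group indices match the oracle (consistency at survey scale)", {
  set.seed(505)
  x <- exp(rnorm(500, 9.3, 0.9))
  o <- oracle_indices(x)
  expect_equal(rd_yitzhaki(x), o$yitzhaki, tolerance = 1e-12)
  expect_equal(rd_podder(x), o$podder, tolerance = 1e-12)
})
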