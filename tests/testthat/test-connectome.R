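test_that("delimited round-trip reproduces matrices exactly", {
  conn <- synthetic_connectome(12, density = 0.4, seed = 5)
  dir <- withr::local_tempdir()
  write_connectome(conn, dir)
  back <- read_connectome(file.path(dir, "weights.csv"),
                          file.path(dir, "distances.csv"))
  expect_identical(back$weights, conn$weights)
  expect_identical(back$distances, conn$distances)
  expect_equal(back$n_nodes, 12)
})

test_that("asymmetric weights are rejected unless symmetrize averages them", {
  dir <- withr::local_tempdir()
  w <- matrix(c(0, 0.4, 0.2, 0), 2, 2, byrow = TRUE)
  d <- matrix(c(0, 10, 10, 0), 2, 2)
  wp <- file.path(dir, "w.csv"); dp <- file.path(dir, "d.csv")
  write.table(w, wp, sep = ",", row.names = FALSE, col.names = FALSE)
  write.table(d, dp, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_error(read_connectome(wp, dp), "not symmetric")
  conn <- read_connectome(wp, dp, symmetrize = TRUE)
  expect_equal(conn$weights[1, 2], 0.3)
  expect_equal(conn$weights[2, 1], 0.3)
})

test_that("malformed matrix input fails with descriptive errors", {
  dir <- withr::local_tempdir()
  wp <- file.path(dir, "w.csv"); dp <- file.path(dir, "d.csv")
  write.table(matrix(1:6, 2, 3), wp, sep = ",", row.names = FALSE,
              col.names = FALSE)
  write.table(matrix(0, 2, 3), dp, sep = ",", row.names = FALSE,
              col.names = FALSE)
  expect_error(read_connectome(wp, dp), "not square")
  expect_error(read_connectome(wp, dp, format = "hdf5"), "unsupported format")
  expect_error(connectome(matrix(c(0, -1, -1, 0), 2, 2),
                          matrix(c(0, 1, 1, 0), 2, 2)), "negative")
  expect_error(connectome(matrix(c(0, 1, 1, 0), 2, 2), matrix(0, 3, 3)),
               "same dimensions")
})

test_that("synthetic connectomes are seed-deterministic with target density", {
  a <- synthetic_connectome(90, density = 0.3, seed = 1)
  b <- synthetic_connectome(90, density = 0.3, seed = 1)
  expect_identical(a$weights, b$weights)
  expect_identical(a$distances, b$distances)
  expect_false(identical(a$weights,
                         synthetic_connectome(90, density = 0.3,
                                              seed = 2)$weights))
  dens <- mean(a$weights[upper.tri(a$weights)] > 0)
  expect_lt(abs(dens - 0.3), 0.05 * 0.3 + 1e-9)
})

test_that("two-node synthetic connectome is a single connected pair", {
  conn <- synthetic_connectome(2, density = 1, seed = 3)
  expect_gt(conn$weights[1, 2], 0)
  expect_equal(conn$weights[1, 2], conn$weights[2, 1])
  expect_error(synthetic_connectome(1), "at least 2")
  expect_error(synthetic_connectome(10, density = 0), "density")
})

test_that("synthetic connectomes satisfy every invariant across seeds", {
  for (seed in 1:100) {
    conn <- synthetic_connectome(20, density = 0.4, seed = seed)
    w <- conn$weights; d <- conn$distances
    expect_identical(w, t(w))
    expect_identical(d, t(d))
    expect_true(all(diag(w) == 0))
    expect_true(all(w >= 0) && all(d >= 0))
    expect_true(all(d[w > 0] > 0))
  }
  # weight distribution is heavy-tailed: skewness of nonzero weights
  conn <- synthetic_connectome(90, density = 0.35, seed = 1)
  wnz <- conn$weights[upper.tri(conn$weights) & conn$weights > 0]
  expect_gt(mean(wnz) / median(wnz), 1.2)
  # delay distribution right-skewed and unimodal-ish: mean above mode region
  dnz <- conn$distances[upper.tri(conn$distances) & conn$weights > 0]
  expect_gt(mean(dnz), median(dnz) * 0.95)
})

test_that("scaled_coupling applies the chosen normalization then K", {
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1
  w[1, 3] <- w[3, 1] <- 2; w[2, 3] <- w[3, 2] <- 3
  d <- matrix(10, 3, 3); diag(d) <- 0
  conn <- connectome(w, d)
  g <- scaled_coupling(conn, 10, normalize = "mean_nonzero")
  expect_equal(sort(unique(g[g > 0])), c(5, 10, 15))
  expect_equal(scaled_coupling(conn, 0), matrix(0, 3, 3))
  # mean-1 weights are unchanged at K = 1
  expect_equal(scaled_coupling(conn, 1, normalize = "mean_nonzero"),
               w / 2)
  # mean_all: mean over off-diagonal entries becomes K
  g2 <- scaled_coupling(conn, 10, normalize = "mean_all")
  offd <- row(g2) != col(g2)
  expect_equal(mean(g2[offd]), 10)
  expect_true(all(g2[w == 0] == 0))
  conn0 <- connectome(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_error(scaled_coupling(conn0, 1), "all zero")
})

test_that("delay_matrix rescales connected distances to the target mean", {
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1
  w[1, 3] <- w[3, 1] <- 1; w[2, 3] <- w[3, 2] <- 1
  d <- matrix(0, 3, 3); d[1, 2] <- d[2, 1] <- 1
  d[1, 3] <- d[3, 1] <- 2; d[2, 3] <- d[3, 2] <- 3
  conn <- connectome(w, d)
  tau <- delay_matrix(conn, 0.003)
  expect_equal(sort(unique(tau[tau > 0])), c(1.5, 3, 4.5) / 1000)
  expect_equal(delay_matrix(conn, 0), matrix(0, 3, 3))
})

test_that("unconnected pairs are excluded from the delay mean and get zero", {
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1
  d <- matrix(0, 3, 3); d[1, 2] <- d[2, 1] <- 2
  d[1, 3] <- d[3, 1] <- 100; d[2, 3] <- d[3, 2] <- 100
  conn <- connectome(w, d)
  tau <- delay_matrix(conn, 0.005)
  expect_equal(tau[1, 2], 0.005)   # only connected pair carries the mean
  expect_equal(tau[1, 3], 0)
  expect_error(delay_matrix(connectome(matrix(0, 2, 2), matrix(0, 2, 2)),
                            0.003), "no connected pairs")
})

test_that("delay mean over connected pairs is exact across random cases", {
  for (seed in 1:25) {
    conn <- synthetic_connectome(15, density = 0.5, seed = seed)
    tau <- delay_matrix(conn, 0.0042)
    mask <- conn$weights > 0
    expect_equal(mean(tau[mask]), 0.0042, tolerance = 1e-12)
  }
})

test_that("tidy.connectome lists each connected pair once", {
  conn <- synthetic_connectome(10, density = 0.4, seed = 2)
  td <- tidy(conn)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), sum(conn$weights[upper.tri(conn$weights)] > 0))
  expect_true(all(td$weight > 0))
  expect_true(all(td$distance > 0))
})
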