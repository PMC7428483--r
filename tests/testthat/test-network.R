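toy_adjacency <- function() {
  # links {1-2, 2-3, 3-4} on 4 nodes
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 1] <- 1L
  A[2, 3] <- A[3, 2] <- 1L
  A[3, 4] <- A[4, 3] <- 1L
  structure(A, link_count = 3L, class = c("adjacency_matrix", "matrix", "array"))
}

toy_parc <- function(labels) {
  parcellation(sprintf("n%d", seq_along(labels)), seq_along(labels), 0, 0, labels)
}

test_that("correlation_matrix matches direct covariance computation", {
  # 3-node toy series of length 5, checked against sum-of-products by hand
  m <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 1, 4, 3, 7), c = c(5, 4, 3, 2, 1))
  C <- correlation_matrix(roi_timeseries(m))
  direct <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(C["a", "b"], direct(m[, 1], m[, 2]))
  expect_equal(C["a", "c"], direct(m[, 1], m[, 3]))
  expect_equal(diag(unclass(C)), c(a = 1, b = 1, c = 1))
  expect_equal(unclass(C), t(unclass(C)))

  dup <- roi_timeseries(cbind(x = m[, 1], y = m[, 1], z = -m[, 1] + 10))
  Cd <- correlation_matrix(dup)
  expect_equal(Cd["x", "y"], 1)
  expect_equal(Cd["x", "z"], -1)

  flat <- roi_timeseries(cbind(ok = rnorm(10), bad = rep(2, 10)))
  expect_error(correlation_matrix(flat), "bad")
  expect_error(correlation_matrix(roi_timeseries(m[1:2, ])), "3 volumes")
})

test_that("proportional threshold keeps exactly the top-ranked link budget", {
  # 4-node matrix with known upper-triangle values; p = 0.25 keeps only the
  # single largest (floor(0.25 * 6) = 1)
  C <- diag(4)
  vals <- c(.9, .8, .1, .05, -.2, -.4)
  C[upper.tri(C)] <- vals
  C <- C + t(C); diag(C) <- 1
  A <- proportional_threshold(C, 0.25)
  expect_equal(attr(A, "link_count"), 1L)
  expect_equal(sum(unclass(A)), 2L)
  expect_equal(unclass(A)[1, 2], 1L)  # the 0.9 pair (column-major upper tri)

  # p = 1: complete graph
  A1 <- proportional_threshold(C, 1)
  expect_equal(attr(A1, "link_count"), 6L)
  expect_true(all(unclass(A1)[upper.tri(C)] == 1L))
  expect_true(all(diag(unclass(A1)) == 0L))

  expect_error(proportional_threshold(C, 0), "0, 1")
  expect_error(proportional_threshold(C, 1.2), "0, 1")

  # absolute ranking promotes strong negative correlations
  Aabs <- proportional_threshold(C, 1 / 6, ranking = "absolute")
  expect_equal(unclass(Aabs)[1, 2], 1L)
  C2 <- C; C2[1, 2] <- C2[2, 1] <- -0.95
  expect_equal(unclass(proportional_threshold(C2, 1 / 6, ranking = "absolute"))[1, 2], 1L)
  expect_equal(unclass(proportional_threshold(C2, 1 / 6, ranking = "signed"))[1, 2], 0L)
})

test_that("the 264-node default keeps exactly floor(0.25 * 264 * 263 / 2) links", {
  set.seed(8)
  m <- matrix(rnorm(300 * 264), 300, 264)
  A <- proportional_threshold(correlation_matrix(roi_timeseries(m)), 0.25)
  expect_equal(attr(A, "link_count"), 8679L)
  expect_equal(sum(unclass(A)) / 2, 8679)
  expect_equal(sum(node_degrees(A)), 2 * 8679)
})

test_that("degree and subnetwork statistics match hand counts on the toy graph", {
  A <- toy_adjacency()
  expect_equal(unname(node_degrees(A)), c(1L, 2L, 2L, 1L))
  parc <- toy_parc(c("DMN", "DMN", "FPN", "FPN"))
  # within: mean full degree over members {1,2} = (1 + 2) / 2
  expect_equal(within_network_connectivity(A, parc, "DMN"), 1.5)
  expect_equal(within_network_connectivity(A, parc, "FPN"), 1.5)
  # between: only link 2-3 crosses
  expect_equal(between_network_connectivity(A, parc, "DMN", "FPN"), 1L)

  empty <- structure(matrix(0L, 4, 4), link_count = 0L,
                     class = c("adjacency_matrix", "matrix", "array"))
  expect_equal(unname(node_degrees(empty)), rep(0L, 4))
  expect_equal(within_network_connectivity(empty, parc, "DMN"), 0)
  expect_equal(between_network_connectivity(empty, parc, "DMN", "FPN"), 0L)

  full <- structure(1L - diag(1L, 5), link_count = 10L,
                    class = c("adjacency_matrix", "matrix", "array"))
  parc5 <- toy_parc(c("DMN", "DMN", "DMN", "FPN", "FPN"))
  expect_equal(unname(node_degrees(full)), rep(4L, 5))
  expect_equal(within_network_connectivity(full, parc5, "DMN"), 4)
  expect_equal(between_network_connectivity(full, parc5, "DMN", "FPN"), 6L)

  expect_error(within_network_connectivity(A, parc, "nope"), "unknown|empty")
  expect_error(between_network_connectivity(A, parc, "DMN", "DMN"), "distinct")
})

test_that("all graph metrics agree with brute-force oracles on random instances", {
  set.seed(9)
  for (rep in 1:20) {
    C <- correlation_matrix(roi_timeseries(matrix(rnorm(30 * 10), 30, 10)))
    p <- sample(c(0.1, 0.25, 0.5, 1), 1)
    A <- proportional_threshold(C, p)
    O <- oracle_threshold(unclass(C), p)
    expect_equal(unclass(A), O, ignore_attr = TRUE)
    expect_equal(unname(node_degrees(A)), oracle_degrees(O))
    labels <- sample(c("DMN", "FPN", "other"), 10, replace = TRUE)
    labels[1:2] <- c("DMN", "FPN")  # both present
    parc <- toy_parc(labels)
    expect_equal(within_network_connectivity(A, parc, "DMN"),
                 oracle_within(O, which(labels == "DMN")))
    expect_equal(between_network_connectivity(A, parc, "DMN", "FPN"),
                 oracle_between(O, which(labels == "DMN"), which(labels == "FPN")))
  }
})

test_that("raising a correlation never removes that pair's link", {
  set.seed(10)
  C <- unclass(correlation_matrix(roi_timeseries(matrix(rnorm(40 * 8), 40, 8))))
  A <- unclass(proportional_threshold(C, 0.3))
  for (q in 1:10) {
    i <- sample(7, 1)
    j <- if (i == 7) 8L else sample((i + 1):8, 1)
    C2 <- C
    C2[i, j] <- C2[j, i] <- min(0.999, C[i, j] + runif(1, 0, 0.5))
    A2 <- unclass(proportional_threshold(C2, 0.3))
    if (A[i, j] == 1L) expect_equal(A2[i, j], 1L)
  }
})

test_that("subject_condition_metrics yields equal link budgets and label invariance", {
  set.seed(11)
  n <- 12
  labels <- rep(c("DMN", "FPN", "other"), c(4, 3, 5))
  parc <- toy_parc(labels)
  ts_list <- list(
    s1 = list(rest = roi_timeseries(matrix(rnorm(40 * n), 40, n)),
              task = roi_timeseries(matrix(rnorm(40 * n), 40, n))),
    s2 = list(rest = roi_timeseries(matrix(rnorm(40 * n), 40, n)),
              task = roi_timeseries(matrix(rnorm(40 * n), 40, n))))
  m <- subject_condition_metrics(ts_list, parc, p = 0.25)
  expect_equal(nrow(m), 2 * 2 * 3)  # 2 subjects x 2 conditions x 3 metrics
  expect_setequal(unique(m$metric), c("within_DMN", "within_FPN", "between_DMN_FPN"))

  # permuting node order leaves every metric value unchanged
  perm <- sample(n)
  ts_perm <- lapply(ts_list, function(bc) lapply(bc, function(ts)
    roi_timeseries(unclass(ts)[, perm], node_ids = colnames(ts)[perm])))
  parc_perm <- toy_parc(labels[perm])
  m2 <- subject_condition_metrics(ts_perm, parc_perm, p = 0.25)
  expect_equal(m2$value, m$value)

  bad <- ts_list
  bad$s1$rest <- roi_timeseries(matrix(rnorm(40 * 5), 40, 5))
  expect_error(subject_condition_metrics(bad, parc), "parcellation")
})
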