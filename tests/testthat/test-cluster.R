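make_summary <- function(alpha, ids = names(alpha)) {
  # minimal fit-summary stand-in for clustering inputs
  structure(list(nodes = data.frame(id = ids, alpha_mean = alpha,
                                    stringsAsFactors = FALSE)),
            class = "p2_fit_summary")
}

test_that("sociality distances are absolute mean differences", {
  sm <- make_summary(c(A = 0, B = 3))
  D <- sociality_distance(sm)
  expect_equal(D["A", "B"], 3)
  expect_equal(D["B", "A"], 3)
  expect_equal(unname(diag(D)), c(0, 0))

  set.seed(90)
  alpha <- rnorm(10)
  names(alpha) <- paste0("n", 1:10)
  D10 <- sociality_distance(make_summary(alpha))
  expect_equal(unname(D10), abs(outer(alpha, alpha, `-`)),
               ignore_attr = TRUE)
})

test_that("complete linkage reproduces hand-traced merges", {
  x <- c(a = 0, b = 0.1, c = 10, d = 10.1)
  hc <- complete_linkage(as.matrix(dist(x)))
  expect_equal(hc$height, c(0.1, 0.1, 10.1), tolerance = 1e-12)

  same <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  hc0 <- complete_linkage(same)
  expect_equal(hc0$height, c(0, 0))

  expect_error(complete_linkage(matrix(0, 1, 1)), "at least 2")
})

test_that("complete linkage agrees with the brute-force oracle", {
  set.seed(91)
  for (rep in 1:5) {
    x <- rnorm(7)
    names(x) <- paste0("p", 1:7)
    D <- as.matrix(dist(x))
    hc <- complete_linkage(D)
    oracle <- bf_complete_linkage(D, k = 3)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-12)
    expect_true(all(diff(hc$height) >= 0))  # monotone merges
    labels <- cut_clusters(hc, k = 3)
    expect_equal(partition_id(unname(labels[paste0("p", 1:7)])),
                 partition_id(oracle$labels))
  }
})

test_that("cutting the dendrogram yields ordered sociality clusters", {
  x <- c(a = 0, b = 0.1, c = 10, d = 10.1)
  hc <- complete_linkage(as.matrix(dist(x)))
  expect_equal(unname(cut_clusters(hc, k = 1)), rep(1L, 4))
  expect_equal(sort(unname(cut_clusters(hc, k = 4))), 1:4)

  two <- cut_clusters(hc, k = 2)
  expect_equal(unname(two[c("a", "b")]), rep(two[["a"]], 2))
  expect_equal(unname(two[c("c", "d")]), rep(two[["c"]], 2))
  expect_false(two[["a"]] == two[["c"]])

  # cluster 1 = highest mean sociality
  relab <- cut_clusters(hc, k = 2, alpha = x)
  expect_equal(unname(relab[c("c", "d")]), c(1L, 1L))
  expect_equal(unname(relab[c("a", "b")]), c(2L, 2L))

  expect_error(cut_clusters(hc, k = 0), "between")
  expect_error(cut_clusters(hc, k = 5), "between")
})

test_that("cluster reports count sizes, degree ranges and edge flows", {
  # two clusters, all edges between them
  net <- p2_network(c("a", "b", "c", "d"),
                    rbind(c("a", "c"), c("a", "d"), c("b", "c")))
  labels <- c(a = 1L, b = 1L, c = 2L, d = 2L)
  rep1 <- cluster_report(labels, net)
  expect_equal(rep1$flows["1", "2"], 100)
  expect_equal(rep1$flows["1", "1"], 0)
  expect_equal(sum(rep1$flows), 100)
  expect_equal(rep1$clusters$size, c(2L, 2L))

  # toy 6-node network, hand-counted flows
  net6 <- p2_network(letters[1:6],
                     rbind(c("a", "b"), c("a", "c"), c("b", "c"),
                           c("c", "d"), c("d", "e"), c("e", "f")))
  lab6 <- c(a = 1L, b = 1L, c = 1L, d = 2L, e = 2L, f = 2L)
  rep6 <- cluster_report(lab6, net6, make_summary(c(a = 2, b = 2, c = 2,
                                                    d = 0, e = 0, f = 0)))
  # within cluster 1: ab, ac, bc = 3/6; between: cd = 1/6; within 2: de, ef
  expect_equal(rep6$flows["1", "1"], 50)
  expect_equal(rep6$flows["1", "2"], 100 / 6, tolerance = 1e-12)
  expect_equal(rep6$flows["2", "2"], 100 / 3, tolerance = 1e-12)
  expect_equal(sum(rep6$flows), 100, tolerance = 1e-9)
  expect_equal(rep6$clusters$degree_min, c(2L, 1L))
  expect_equal(rep6$clusters$degree_max, c(3L, 2L))
  expect_equal(rep6$clusters$alpha_mean, c(2, 0))

  expect_error(cluster_report(lab6[-1], net6), "missing for node")

  # flows always sum to 100 on random labelings of random graphs
  set.seed(92)
  for (i in 1:20) {
    net_r <- simulate_network(0, rnorm(10))
    if (n_edges(net_r) == 0) next
    lab_r <- setNames(sample(1:3, 10, replace = TRUE), net_r$nodes)
    expect_equal(sum(cluster_report(lab_r, net_r)$flows), 100,
                 tolerance = 1e-9)
  }
})

test_that("cluster exports write the two documented CSVs", {
  net <- p2_network(letters[1:4],
                    rbind(c("a", "b"), c("c", "d"), c("a", "c")))
  labels <- c(a = 1L, b = 1L, c = 2L, d = 2L)
  dir <- tempfile()
  write_clusters(cluster_report(labels, net), dir)
  cs <- read.csv(file.path(dir, "cluster_summary.csv"))
  fl <- read.csv(file.path(dir, "flows.csv"))
  expect_equal(names(cs), c("cluster", "size", "degree_min", "degree_max"))
  expect_equal(sum(fl$percent), 100)
})
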