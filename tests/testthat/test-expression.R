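test_that("fold-change counting is thresholded and antisymmetric", {
  set.seed(2)
  m <- cbind(a = c(rnorm(5, 0, 0.1), 2.5, 2.6, 2.7, -3, -3.1),
             b = rep(0, 10))
  rownames(m) <- sprintf("g%02d", 1:10)
  fc <- foldChangeCounts(m, "a", "b")
  expect_identical(fc$nUp, 3L)
  expect_identical(fc$nDown, 2L)
  expect_identical(fc$n, 5L)
  # sorted by |fold change| decreasing
  expect_identical(fc$down, c("g10", "g09"))
  # identity comparison
  same <- foldChangeCounts(m, "a", "a")
  expect_identical(same$n, 0L)
  # antisymmetry: up(a, b) = down(b, a)
  rev <- foldChangeCounts(m, "b", "a")
  expect_identical(sort(fc$up), sort(rev$down))
  expect_identical(sort(fc$down), sort(rev$up))
  # boundary is inclusive (>= log2 fold)
  m2 <- cbind(a = c(g1 = 1), b = c(g1 = 0))
  expect_identical(foldChangeCounts(m2, "a", "b")$nUp, 1L)
  expect_error(foldChangeCounts(m, "a", "zz"), "unknown sample")
})

test_that("Venn partitions are exact, disjoint and sum to the union", {
  v <- vennPartition(list(A = c("a", "b"), B = "c"))
  expect_identical(sort(v$A), c("a", "b"))
  expect_identical(v$B, "c")
  expect_identical(length(v[["A&B"]]), 0L)

  # identical sets: everything in the full intersection
  v2 <- vennPartition(list(A = c("x", "y"), B = c("x", "y"), C = c("x", "y")))
  expect_identical(length(v2[["A&B&C"]]), 2L)
  expect_true(all(lengths(v2[setdiff(names(v2), "A&B&C")]) == 0))

  # constructed three-set arithmetic: 2 triple, 7 extra per pairwise overlap
  tri <- sprintf("t%d", 1:2)
  ab <- sprintf("ab%d", 1:7); ac <- sprintf("ac%d", 1:7); bc <- sprintf("bc%d", 1:7)
  onlyA <- sprintf("a%d", 1:4)
  sets <- list(A = c(tri, ab, ac, onlyA), B = c(tri, ab, bc), C = c(tri, ac, bc))
  v3 <- vennPartition(sets)
  expect_identical(lengths(v3)[c("A&B&C", "A&B", "A&C", "B&C", "A")],
                   c(`A&B&C` = 2L, `A&B` = 7L, `A&C` = 7L, `B&C` = 7L, A = 4L))
  expect_identical(sum(lengths(v3)), length(unique(unlist(sets))))
  # regions are disjoint
  expect_false(anyDuplicated(unlist(v3)) > 0)
})

test_that("average-linkage correlation clustering matches a brute-force oracle", {
  set.seed(7)
  m <- matrix(rnorm(200), 50, 4,
              dimnames = list(NULL, c("s1", "s2", "s3", "s4")))
  m[, 2] <- m[, 1] + rnorm(50, 0, 0.3)
  out <- correlationAndCluster(m, bootstraps = 0)
  D <- 1 - cor(m)

  # exhaustive agglomeration on 4 leaves, average linkage
  clusters <- as.list(colnames(m))
  d <- function(c1, c2) mean(D[c1, c2])
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      dij <- d(clusters[[i]], clusters[[j]])
      if (dij < best[1]) best <- c(dij, j, i)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  expect_equal(out$hclust$height, heights, tolerance = 1e-12)

  # duplicated sample columns: correlation 1, distance 0, joined first
  m2 <- cbind(m, s5 = m[, "s3"])
  out2 <- correlationAndCluster(m2, bootstraps = 0)
  expect_equal(out2$correlation["s3", "s5"], 1)
  expect_equal(out2$hclust$height[1], 0, tolerance = 1e-12)
  first <- out2$hclust$labels[-out2$hclust$merge[1, ]]
  expect_identical(sort(first), c("s3", "s5"))

  expect_error(correlationAndCluster(cbind(m, flat = 1), bootstraps = 0),
               "zero-variance")
})

test_that("clustering is invariant to sample-column permutation", {
  set.seed(9)
  m <- matrix(rnorm(300), 60, 5, dimnames = list(NULL, sprintf("s%d", 1:5)))
  o1 <- correlationAndCluster(m, bootstraps = 0)
  o2 <- correlationAndCluster(m[, c(4, 1, 5, 2, 3)], bootstraps = 0)
  expect_equal(sort(o1$hclust$height), sort(o2$hclust$height), tolerance = 1e-12)
  expect_identical(sort(unlist(o1$splits)), sort(unlist(o2$splits)))
})

test_that("a planted sample partition gets high bootstrap support", {
  set.seed(3)
  n <- 400
  g1 <- rnorm(n); g2 <- rnorm(n)
  noise <- function(sd) rnorm(n, 0, sd)
  # within-group correlation ~0.95, between ~0.5
  shared <- sqrt(0.5) * (g1 + g2) / sqrt(2)
  m <- cbind(x1 = g1 + noise(0.3), x2 = g1 + noise(0.3),
             y1 = g2 + noise(0.3), y2 = g2 + noise(0.3))
  m <- m + 0.8 * cbind(shared, shared, shared, shared)
  out <- correlationAndCluster(m, bootstraps = 200, seed = 4)
  planted <- which(out$splits == "x1|x2" | out$splits == "y1|y2")
  expect_true(length(planted) >= 1)
  expect_true(all(out$bp[planted] >= 0.95))
  # the newick string carries the tree
  expect_match(out$newick, "x1")
})

test_that("xenograft area follows the ellipse formula", {
  expect_equal(xenograftArea(2, 2), pi)
  expect_equal(xenograftArea(20, 10), 50 * pi)  # ~157.08 mm^2
  expect_equal(xenograftArea(20, 10), xenograftArea(10, 20))
  expect_error(xenograftArea(0, 1), "positive")
})

test_that("expression matrices load with replicate averaging and checks", {
  d <- data.frame(gene = c("g1", "g2"),
                  `2D7d_1` = c(1, 2), `2D7d_2` = c(3, 4),
                  xenograft = c(5, 6), check.names = FALSE)
  f <- tempfile(fileext = ".tsv")
  write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- readExpressionMatrix(f)
  expect_identical(colnames(m), c("2D7d", "xenograft"))
  expect_equal(unname(m[, "2D7d"]), c(2, 3))   # replicate averages

  d2 <- d; d2$gene <- c("g1", "g1")
  write.table(d2, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readExpressionMatrix(f), "duplicated")
  d3 <- d; names(d3)[4] <- "mystery"
  write.table(d3, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readExpressionMatrix(f), "unknown sample")
})
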