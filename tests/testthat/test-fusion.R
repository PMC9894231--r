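test_that("pairwise distances follow the squared-Euclidean and (1-r)/2 conventions", {
  x <- rbind(a = c(0, 0), b = c(3, 4), c = c(0, 0))
  d <- pairwise_distance(x, "sq_euclidean")
  expect_equal(d$d["a", "b"], 25)
  expect_equal(d$d["a", "c"], 0)
  expect_equal(diag(d$d), setNames(rep(0, 3), rownames(x)))

  y <- rbind(u = c(1, 2, 3), v = c(3, 2, 1), w = c(1, 1.5, 3.5))
  dp <- pairwise_distance(y, "pearson_distance")
  expect_equal(dp$d["u", "v"], 1)          # r = -1 -> (1-r)/2 = 1
  expect_equal(dp$d["u", "u"], 0)
  z <- rbind(u = c(1, 1, 1), v = c(1, 2, 3), w = c(2, 1, 0))
  expect_error(pairwise_distance(z, "pearson_distance"), "u")
})

test_that("affinity kernel matches the hand-computed locally scaled exponential", {
  # points on a line at 0, 1, 3: squared distances 1, 4, 9
  x <- matrix(c(0, 1, 3), dimnames = list(c("p1", "p2", "p3"), NULL))
  d <- pairwise_distance(x, "sq_euclidean")
  w <- affinity_kernel(d, k = 1, mu = 0.5)
  # eps(1,2) = (1 + 1 + 1)/3 = 1 -> W = exp(-1 / 0.5) = exp(-2)
  expect_equal(w$w["p1", "p2"], exp(-2))
  # eps(1,3) = (1 + 4 + 9)/3 -> W = exp(-9/(0.5 * 14/3))
  expect_equal(w$w["p1", "p3"], exp(-9 / (0.5 * 14 / 3)))
  expect_equal(diag(w$w), setNames(rep(1, 3), rownames(x)))

  # scale invariance: multiplying all distances by c leaves W unchanged
  w2 <- affinity_kernel(structure(list(d = d$d * 7.3, metric = d$metric,
                                       ids = d$ids),
                                  class = "distance_matrix"), k = 1, mu = 0.5)
  expect_equal(w2$w, w$w, tolerance = 1e-12)
  expect_error(affinity_kernel(d, k = 3, mu = 0.5), "k")
  expect_error(affinity_kernel(d, k = 1, mu = 0), "mu")
})

test_that("snf diffusion keeps transition normalization and the self-fusion fixed point", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    x <- matrix(rnorm(n * 3), n)
    rownames(x) <- paste0("p", seq_len(n))
    d <- pairwise_distance(x, "sq_euclidean")
    k <- sample(2:(n - 2), 1)
    w <- affinity_kernel(d, k = k)
    # fusing a dataset with a byte-identical copy equals direct single-network
    # diffusion (independent reference recursion)
    fused <- snf_fuse(list(w, w), t = 20)
    ref <- reference_self_diffusion(w$w, k, 20)
    expect_lt(max(abs(fused - ref)), 1e-8)
  }

  # intermediate transition matrices: off-diagonal row sums 1/2, diagonal 1/2
  p <- snfmap:::p_normalize(affinity_kernel(
    pairwise_distance(matrix(rnorm(30), 10), "sq_euclidean"), k = 3)$w)
  expect_equal(unname(diag(p)), rep(0.5, 10))
  expect_equal(unname(rowSums(p) - diag(p)), rep(0.5, 10))

  expect_error(snf_fuse(list(affinity_kernel(d, k = 2)), t = 20), ">= 2")
  expect_error(snf_fuse(list(w, w), t = 0), "t must")
})

test_that("fusion preserves block structure when one dataset is uninformative", {
  # two tight triples far apart in dataset A; dataset B all-equal affinities
  xa <- rbind(p1 = c(0, 0), p2 = c(0.1, 0), p3 = c(0.05, 0.1),
              p4 = c(10, 10), p5 = c(10.1, 10), p6 = c(10.05, 10.1))
  da <- pairwise_distance(xa, "sq_euclidean")
  wa <- affinity_kernel(da, k = 2)
  wb <- wa
  wb$w <- matrix(0.5, 6, 6, dimnames = dimnames(wa$w))
  diag(wb$w) <- 1
  fused <- snf_fuse(list(wa, wb), t = 20)
  blocks <- rep(1:2, each = 3)
  same <- outer(blocks, blocks, "==") & upper.tri(fused)
  diff <- (!outer(blocks, blocks, "==")) & upper.tri(fused)
  expect_gt(min(fused[same]), max(fused[diff]))
})

test_that("the k sweep produces floor(n/2) - 1 matrices and a (0,1]-bounded aggregate", {
  set.seed(33)
  mk <- function(n, p, platform) {
    z <- matrix(rnorm(n * p), n, dimnames = list(paste0("p", 1:n), NULL))
    profile_matrix(z, platform = platform)
  }
  pa10 <- mk(10, 5, "FUSION"); pb10 <- mk(10, 8, "CP")
  net10 <- ksweep_aggregate(pa10, pb10)
  expect_identical(net10$params$k_range, 2:5)       # 4 fused matrices (n/2 - 1)
  expect_length(net10$params$k_range, 4L)

  pa4 <- mk(4, 5, "FUSION"); pb4 <- mk(4, 8, "CP")
  net4 <- ksweep_aggregate(pa4, pb4)
  expect_identical(net4$params$k_range, 2L)         # degenerate sweep
  off4 <- net4$w_agg[row(net4$w_agg) != col(net4$w_agg)]
  expect_equal(max(off4), 1)                        # single normalized matrix

  off10 <- net10$w_agg[row(net10$w_agg) != col(net10$w_agg)]
  expect_true(all(off10 > 0 & off10 <= 1))
  expect_lt(max(abs(net10$w_agg - t(net10$w_agg))), 1e-12)
  # per-dataset aggregates obey the same bounds
  for (m in net10$per_dataset_agg) {
    offm <- m[row(m) != col(m)]
    expect_true(all(offm > 0 & offm <= 1))
  }

  z3 <- matrix(rnorm(9), 3, dimnames = list(paste0("p", 1:3), NULL))
  expect_error(ksweep_aggregate(profile_matrix(z3, platform = "FUSION"),
                                profile_matrix(z3, platform = "CP")),
               "n >= 4")
})

test_that("the fused aggregate is equivariant under perturbagen permutation", {
  set.seed(55)
  n <- 8
  za <- matrix(rnorm(n * 4), n, dimnames = list(paste0("p", 1:n), NULL))
  zb <- matrix(rnorm(n * 6), n, dimnames = list(paste0("p", 1:n), NULL))
  net <- ksweep_aggregate(profile_matrix(za, platform = "FUSION"),
                          profile_matrix(zb, platform = "CP"),
                          per_dataset = FALSE)
  perm <- sample(n)
  netp <- ksweep_aggregate(profile_matrix(za[perm, ], platform = "FUSION"),
                           profile_matrix(zb[perm, ], platform = "CP"),
                           per_dataset = FALSE)
  expect_equal(netp$w_agg[rownames(net$w_agg), colnames(net$w_agg)],
               net$w_agg, tolerance = 1e-10)
})

test_that("signal dominance: agreeing two-block data fuses into two blocks", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 12
    block <- rep(c(0, 4), each = n / 2)
    za <- matrix(rnorm(n * 5, mean = block), n)
    zb <- matrix(rnorm(n * 7, mean = block), n)
    rownames(za) <- rownames(zb) <- paste0("p", 1:n)
    net <- ksweep_aggregate(profile_matrix(za, platform = "FUSION"),
                            profile_matrix(zb, platform = "CP"),
                            per_dataset = FALSE)
    same <- outer(block, block, "==") & upper.tri(net$w_agg)
    diff <- (!outer(block, block, "==")) & upper.tri(net$w_agg)
    expect_gt(mean(net$w_agg[same]), mean(net$w_agg[diff]))
  }
})

test_that("log transform floors, network distances match direct formulas", {
  m <- matrix(c(1, 0.1, 1e-15, 0.1, 1, 0.5, 1e-15, 0.5, 1), 3)
  lt <- log_transform(m)
  expect_equal(lt[1, 1], 0)
  expect_equal(lt[1, 2], -1)
  expect_equal(lt[1, 3], -12)   # clipped at the 1e-12 floor

  set.seed(8)
  w <- matrix(rnorm(9), 3); w <- (w + t(w)) / 2
  dimnames(w) <- list(letters[1:3], letters[1:3])
  nd <- network_distance(w, "euclidean")
  expect_equal(nd$d["a", "b"], sqrt(sum((w["a", ] - w["b", ])^2)))
  expect_equal(unname(diag(nd$d)), rep(0, 3))
  np <- network_distance(w, "pearson")
  expect_equal(np["a", "b"], cor(w["a", ], w["b", ]))
  expect_equal(unname(diag(np)), rep(1, 3))
  # identical rows -> distance 0, correlation 1
  w2 <- matrix(c(1, 1, 2, 1, 1, 2, 2, 2, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(network_distance(w2, "euclidean")$d["a", "b"], 0)
  expect_equal(network_distance(w2, "pearson")["a", "b"], 1)
  expect_error(network_distance(matrix(1:6, 2), "euclidean"), "square")
})

test_that("fused networks round-trip through the directory serialization", {
  sim <- small_screen()
  net <- ksweep_aggregate(sim$profile_a, sim$profile_b)
  dir <- withr::local_tempdir()
  write_fused_network(net, dir)
  back <- read_fused_network(dir)
  expect_equal(back$w_agg, net$w_agg)
  expect_identical(back$params$k_range, net$params$k_range)
  expect_identical(names(back$per_dataset_agg), names(net$per_dataset_agg))
  expect_equal(back$per_dataset_agg$FUSION, net$per_dataset_agg$FUSION)
})
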