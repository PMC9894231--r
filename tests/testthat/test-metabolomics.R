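obs_row <- function(sample, replicate, mz, rt, ccs = NA_real_, intensity = 100) {
  data.frame(sample = sample, replicate = replicate, mz = mz, rt = rt,
             ccs = ccs, intensity = intensity, stringsAsFactors = FALSE)
}

test_that("replicate consensus keeps 2-of-3 features and pairs greedily by nearest m/z", {
  tol <- tolerance_spec()
  # present in replicates 1 and 3 only -> kept; single-replicate -> dropped
  obs <- rbind(obs_row("s1", 1, 300.1000, 2.00, intensity = 50),
               obs_row("s1", 3, 300.1030, 2.05, intensity = 80),
               obs_row("s1", 2, 500.2000, 5.00))
  cons <- replicate_consensus(obs, tol)
  expect_identical(nrow(cons), 1L)
  expect_equal(cons$mz, mean(c(300.1000, 300.1030)))
  expect_equal(cons$rt, mean(c(2.00, 2.05)))
  expect_equal(cons$intensity, 80)       # max across members
  expect_identical(cons$n_replicates, 2L)

  # two features in one replicate both within tolerance of one feature in
  # another: only one match is consumed; the leftover same-replicate feature
  # stays single-replicate and is dropped
  obs2 <- rbind(obs_row("s1", 1, 400.0000, 3.00),
                obs_row("s1", 1, 400.0080, 3.00),
                obs_row("s1", 2, 400.0070, 3.00))
  cons2 <- replicate_consensus(obs2, tol)
  expect_identical(nrow(cons2), 1L)
  expect_identical(cons2$n_replicates, 2L)
  # ascending-m/z processing pairs the replicate-2 observation with the
  # already-open group it can still join (400.0000)
  expect_equal(cons2$mz, mean(c(400.0000, 400.0070)))

  # with several open candidate groups, the nearest m/z wins
  obs3 <- rbind(obs_row("s1", 1, 400.0000, 3.00),
                obs_row("s1", 1, 400.0090, 3.00),
                obs_row("s1", 2, 400.0095, 3.00))
  cons3 <- replicate_consensus(obs3, tol)
  expect_identical(nrow(cons3), 1L)
  expect_equal(cons3$mz, mean(c(400.0090, 400.0095)))

  expect_identical(nrow(replicate_consensus(obs[0, ], tol)), 0L)
  expect_error(replicate_consensus(rbind(obs_row("s1", 1, 1, 1),
                                         obs_row("s2", 1, 1, 1)), tol),
               "single sample")
})

test_that("basketing single-links across samples and is idempotent", {
  tol <- tolerance_spec(mz_tol = 0.01, rt_tol = 0.2)
  # the same feature in three samples -> one basket with all three
  f <- rbind(
    data.frame(sample = "extA", mz = 303.1712, rt = 3.13, ccs = NA,
               intensity = 10, n_replicates = 3),
    data.frame(sample = "extB", mz = 303.1718, rt = 3.10, ccs = NA,
               intensity = 12, n_replicates = 3),
    data.frame(sample = "extC", mz = 303.1707, rt = 3.16, ccs = NA,
               intensity = 9, n_replicates = 2))
  b <- basket_features(f, tol)
  expect_identical(nrow(b), 1L)
  expect_setequal(b$samples[[1]], c("extA", "extB", "extC"))
  expect_equal(b$mz, mean(f$mz))
  expect_equal(b$max_intensity, 12)

  # chain a-b-c merges under single linkage though a-c exceeds tolerance
  chain <- rbind(
    data.frame(sample = "sA", mz = 200.000, rt = 1, ccs = NA, intensity = 1,
               n_replicates = 2),
    data.frame(sample = "sB", mz = 200.008, rt = 1, ccs = NA, intensity = 1,
               n_replicates = 2),
    data.frame(sample = "sC", mz = 200.016, rt = 1, ccs = NA, intensity = 1,
               n_replicates = 2))
  bc <- basket_features(chain, tol)
  expect_identical(nrow(bc), 1L)
  expect_identical(bc$n_members, 3L)

  # a lone feature baskets as a singleton
  single <- data.frame(sample = "sA", mz = 999, rt = 9, ccs = NA,
                       intensity = 1, n_replicates = 3)
  expect_identical(basket_features(single, tol)$n_samples, 1L)

  # idempotence: re-basketing the consensus list reproduces the baskets
  cons <- data.frame(sample = vapply(bc$samples, `[`, "", 1L), mz = bc$mz,
                     rt = bc$rt, ccs = bc$ccs, intensity = bc$max_intensity,
                     n_replicates = 2)
  again <- basket_features(rbind(cons, f[0, ]), tol)
  expect_equal(again$mz, bc$mz)
  expect_identical(nrow(again), nrow(bc))
})

test_that("snf_score equals the brute-force submatrix mean and is monotone under mixing", {
  set.seed(31)
  n <- 20
  w <- matrix(runif(n * n, 0.05, 1), n)
  w <- (w + t(w)) / 2
  diag(w) <- 1
  ids <- sprintf("frac_%02d", 1:n)
  dimnames(w) <- list(ids, ids)

  for (i in 1:100) {
    sz <- sample(2:6, 1)
    samp <- sample(ids, sz)
    expect_equal(snf_score(samp, w), snf_score_brute(samp, w),
                 tolerance = 1e-12)
  }
  # a basket in exactly 2 fractions scores the single pairwise similarity
  expect_equal(snf_score(ids[c(3, 7)], w), w[3, 7])
  # singletons score 0; missing ids are dropped with a warning
  expect_equal(snf_score(ids[1], w), 0)
  expect_warning(s <- snf_score(c(ids[1:3], "ghost"), w), "missing")
  expect_equal(s, snf_score_brute(ids[1:3], w))

  # adding a fraction whose similarities to members all exceed the current
  # score strictly increases the score
  for (rep_i in 1:20) {
    samp <- sample(ids, 3)
    cur <- snf_score(samp, w)
    cand <- setdiff(ids, samp)
    gains <- vapply(cand, function(c2) all(w[c2, samp] > cur), logical(1))
    if (any(gains)) {
      c2 <- cand[which(gains)[1]]
      expect_gt(snf_score(c(samp, c2), w), cur)
    }
  }
})

test_that("basket descriptors match hand arithmetic on a printed toy", {
  # 3 fractions, 2-feature fingerprints in platform A, 3-feature in B
  za <- rbind(f1 = c(1, 2), f2 = c(2, 4), f3 = c(4, 0))
  zb <- rbind(f1 = c(1, 0, 1), f2 = c(-1, 0, -1), f3 = c(0, 2, 0))
  w <- matrix(c(1, .8, .4, .8, 1, .6, .4, .6, 1), 3,
              dimnames = list(rownames(za), rownames(za)))
  pa <- profile_matrix(za, platform = "FUSION")
  pb <- profile_matrix(zb, platform = "CP")
  b <- basket_features(data.frame(sample = rownames(za), mz = 300, rt = 1,
                                  ccs = NA, intensity = 1, n_replicates = 3),
                       tolerance_spec())
  sc <- score_baskets(b, w, pa, pb)
  expect_equal(sc$snf_cluster_score, mean(c(.8, .4, .6)))
  ra <- cor(t(za))
  expect_equal(sc$fusion_cluster_score,
               mean(ra[upper.tri(ra)]))
  mean_fp_a <- colMeans(za)
  expect_equal(sc$fusion_activity_score, sqrt(sum(mean_fp_a^2)) / sqrt(2))
  mean_fp_b <- colMeans(zb)
  expect_equal(sc$cp_activity_score, sqrt(sum(mean_fp_b^2)) / sqrt(3))
  # perfectly correlated fingerprints in A -> cluster score 1
  expect_equal(cor(za["f1", ], za["f2", ]), 1)
  b12 <- b; b12$samples <- list(c("f1", "f2"))
  expect_equal(score_baskets(b12, w, pa, pb)$fusion_cluster_score, 1)
  # all-zero fingerprints -> activity score 0
  z0 <- rbind(f1 = c(0, 0), f2 = c(0, 0), f3 = c(0, 0))
  suppressWarnings(
    expect_equal(score_baskets(b, w, profile_matrix(z0, platform = "FUSION"),
                               pb)$fusion_activity_score, 0))
  expect_equal(sc$snf_percentile, 100)
})

test_that("active-basket selection uses nearest-rank percentiles and strict thresholds", {
  b <- basket_features(data.frame(sample = "s", mz = 100 + (1:100),
                                  rt = 1, ccs = NA, intensity = 1,
                                  n_replicates = 3), tolerance_spec())
  b$snf_cluster_score <- (1:100) / 100
  sel <- select_active(b, percentile = 95)
  expect_identical(nrow(sel), 5L)            # 100 distinct scores -> top 5
  expect_true(all(sel$snf_cluster_score >= 0.95))
  thr <- select_active(b, threshold = 0.06)
  expect_identical(nrow(thr), sum(b$snf_cluster_score > 0.06))
  expect_false(0.06 %in% thr$snf_cluster_score)   # strict >
  # all-equal scores at the cutoff: ties kept
  b$snf_cluster_score <- rep(0.5, 100)
  expect_identical(nrow(select_active(b, percentile = 95)), 100L)
  expect_identical(nrow(select_active(b[0, ], percentile = 95)), 0L)
})

test_that("basket tables round-trip through CSV", {
  sim <- small_screen()
  obs <- simulate_metabolome(sim$truth, seed = 12)
  per <- lapply(split(obs, obs$sample), replicate_consensus)
  b <- basket_features(per)
  net <- ksweep_aggregate(sim$profile_a, sim$profile_b, per_dataset = FALSE)
  sc <- score_baskets(b, net, sim$profile_a, sim$profile_b)
  path <- withr::local_tempfile(fileext = ".csv")
  write_baskets(sc, path)
  back <- read_baskets(path)
  expect_identical(nrow(back), nrow(sc))
  expect_equal(back$snf_cluster_score, sc$snf_cluster_score)
  expect_identical(back$samples, sc$samples)
})
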