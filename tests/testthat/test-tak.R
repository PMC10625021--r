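random_seq_matrix <- function(K, Tw, n_states = 3L) {
  matrix(sample(0:n_states, K * Tw, replace = TRUE,
                prob = c(0.7, rep(0.3 / n_states, n_states))),
         K, Tw)
}

test_that("Hamming matrix matches the nested-loop oracle", {
  expect_equal(hamming_matrix(rbind(rep(1L, 10), rep(1L, 10)))[1, 2], 0)
  expect_equal(hamming_matrix(rbind(rep(0L, 10), rep(1L, 10)))[1, 2], 10)
  set.seed(7)
  for (rep in 1:5) {
    m <- random_seq_matrix(sample(5:50, 1), sample(5:50, 1))
    expect_equal(hamming_matrix(m), naive_hamming_matrix(m))
  }
  expect_error(hamming_matrix(matrix(0L, 2, 5), matrix(0L, 2, 6)), "length")
})

test_that("unit-weight linkage coincides with hclust ward.D2", {
  set.seed(11)
  m <- random_seq_matrix(20, 40)
  D <- hamming_matrix(m)
  model <- ward_cluster(D, NULL, C = 3)
  ref <- hclust(as.dist(D), method = "ward.D2")
  expect_equal(sort(model$tree$height), sort(ref$height), tolerance = 1e-8)
  expect_equal(cophenetic(model$tree), cophenetic(ref), tolerance = 1e-8)
  for (k in 2:6)
    expect_equal(adjusted_rand_index(cutree(model$tree, k), cutree(ref, k)), 1)
})

test_that("weighted merges equal the from-scratch quadratic oracle (K <= 12)", {
  set.seed(19)
  for (rep in 1:4) {
    K <- sample(5:12, 1)
    m <- random_seq_matrix(K, 30)
    D <- hamming_matrix(m)
    w <- sample(1:9, K, replace = TRUE)
    model <- ward_cluster(D, w, C = 2)
    oracle <- naive_ward(D, w)
    expect_equal(model$tree$height, oracle$heights, tolerance = 1e-8)
    for (s in seq_len(K - 2)) {
      impl_part <- cutree(model$tree, k = K - s)
      expect_equal(adjusted_rand_index(impl_part, oracle$partitions[[s]]), 1,
                   label = sprintf("partition after merge %d (rep %d)", s, rep))
    }
  }
})

test_that("merge heights are monotone and K = 2 behaves trivially", {
  set.seed(23)
  m <- random_seq_matrix(15, 25)
  w <- sample(1:20, 15, replace = TRUE)
  model <- ward_cluster(hamming_matrix(m), w, C = 4)
  expect_true(all(diff(model$tree$height) >= -1e-9))
  expect_equal(sum(model$patient_counts), sum(w))

  two <- ward_cluster(hamming_matrix(m[1:2, ]), c(3L, 5L), C = 2)
  expect_identical(two$labels, c(1L, 2L))
  one <- ward_cluster(hamming_matrix(m[1:2, ]), c(3L, 5L), C = 1)
  expect_identical(one$labels, c(1L, 1L))
  expect_error(ward_cluster(matrix(c(0, 1, 2, 0), 2), NULL, 1), "symmetric")
})

test_that("two well-separated groups are recovered exactly at C = 2", {
  set.seed(29)
  Tw <- 60
  base1 <- integer(Tw); base1[1:30] <- 1L
  base2 <- integer(Tw); base2[31:60] <- 3L
  jitter1 <- t(sapply(1:8, function(i) { s <- base1; s[sample(Tw, 2)] <- 2L; s }))
  jitter2 <- t(sapply(1:8, function(i) { s <- base2; s[sample(Tw, 2)] <- 2L; s }))
  m <- rbind(jitter1, jitter2)
  model <- ward_cluster(hamming_matrix(m), NULL, C = 2)
  expect_equal(adjusted_rand_index(model$labels, rep(1:2, each = 8)), 1)
})

test_that("silhouette matches the naive per-point oracle, weighted via expansion", {
  # two tight, separated clusters collapse to the limit value 1
  D <- matrix(10, 4, 4); D[1:2, 1:2] <- 0; D[3:4, 3:4] <- 0; diag(D) <- 0
  expect_equal(silhouette_score(D, c(1, 1, 2, 2)), 1)

  set.seed(31)
  for (rep in 1:4) {
    K <- sample(6:12, 1)
    m <- random_seq_matrix(K, 30)
    D <- hamming_matrix(m)
    labels <- sample(1:3, K, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(1L, 2L)
    w <- sample(1:4, K, replace = TRUE)
    exp_ <- expand_by_counts(D, labels, w)
    expect_equal(silhouette_score(D, labels, w),
                 naive_silhouette(exp_$d, exp_$labels), tolerance = 1e-10)
  }
  expect_error(silhouette_score(D, rep(1, 4)), "2 clusters")
  expect_error(silhouette_score(diag(0, 3), 1:3, c(1L, 1L, 1L)), "singleton")
})

test_that("random labels on a homogeneous blob give silhouette near zero", {
  set.seed(37)
  vals <- replicate(50, {
    m <- random_seq_matrix(30, 40)
    silhouette_score(hamming_matrix(m), sample(1:2, 30, replace = TRUE))
  })
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("severity ordering sorts by exacerbation episodes, then days", {
  Tw <- 365
  mk <- function(days, code = 1L) { s <- integer(Tw); s[days + Tw + 1] <- code; s }
  # medoids: A has 2 episodes, B has none, C has 1
  seqs <- rbind(mk(c(-50:-45, -20:-15)), mk(integer(0)), mk(-30:-25))
  assignment <- c(1L, 1L, 2L, 3L, 3L)[c(1, 2, 3, 4, 5)]
  seqs_pat <- seqs[assignment, ]
  model <- list(labels = c(1L, 2L, 3L), C = 3L,
                patient_counts = c(2, 1, 2),
                tree = list(order = 1:3))
  class(model) <- "traj_clusters"
  out <- order_by_severity(model, seqs_pat, assignment)
  # episode means: medoid1 -> 2, medoid2 -> 0, medoid3 -> 1  => order 2,3,1
  expect_identical(out$labels, c(3L, 1L, 2L))
  expect_true(all(diff(out$severity$mean_exac_episodes) >= 0))

  # tie on episodes broken by hospitalised days
  seqs2 <- rbind(mk(-10:-8), mk(-30:-1))    # 1 episode each: 3 vs 30 days
  model2 <- list(labels = c(1L, 2L), C = 2L, patient_counts = c(1, 1),
                 tree = list(order = 1:2))
  class(model2) <- "traj_clusters"
  out2 <- order_by_severity(model2, seqs2, c(1L, 2L))
  expect_identical(out2$labels, c(1L, 2L))
  # reversed day means flip the labels
  out3 <- order_by_severity(model2, seqs2[2:1, ], c(1L, 2L))
  expect_identical(out3$labels, c(2L, 1L))

  # already ordered input is left unchanged
  expect_identical(order_by_severity(out2, seqs2, c(1L, 2L))$labels,
                   out2$labels)
})

test_that("visualization raster conserves patients and groups clusters", {
  co <- shared_cohort()
  ms <- compress_sequences(co$sequences, 40L, rng_seed = 5)
  model <- ward_cluster(hamming_matrix(ms$medoids), ms$member_counts, 4)
  raster <- visualization_matrix(model, ms$medoids, ms$member_counts)
  expect_identical(nrow(raster), nrow(co$sequences))
  cl <- attr(raster, "cluster")
  expect_identical(cl, sort(cl))                  # contiguous cluster blocks
  # a medoid with count c yields c identical adjacent rows
  j <- which(ms$member_counts >= 3)[1]
  rows <- which(apply(raster, 1, function(r) all(r == ms$medoids[j, ])))
  expect_gte(length(rows), ms$member_counts[j])
})
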