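# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance suites.  Oracles deliberately use naive nested loops
# and from-scratch recomputation, not the package's algorithms.

naive_hamming <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- 0L
  for (t in seq_along(a)) if (a[t] != b[t]) n <- n + 1L
  n
}

naive_hamming_matrix <- function(m) {
  K <- nrow(m)
  D <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    D[i, j] <- naive_hamming(m[i, ], m[j, ])
  D
}

# From-scratch Ward agglomeration: at every step, the cost of merging two
# clusters is recomputed from the full pairwise distance matrix via the
# centroid identity on squared distances (weights = member counts), with
# the same smallest-leaf-pair tie-break as the implementation.
naive_ward <- function(d, w = rep(1, nrow(d))) {
  K <- nrow(d)
  clusters <- as.list(seq_len(K))      # member leaf sets
  heights <- numeric(0)
  partitions <- list()
  S <- function(A, B) sum(outer(w[A], w[B]) * d[A, B, drop = FALSE]^2)
  cost <- function(A, B) {
    WA <- sum(w[A]); WB <- sum(w[B])
    cen2 <- S(A, B) / (WA * WB) - S(A, A) / (2 * WA^2) - S(B, B) / (2 * WB^2)
    WA * WB / (WA + WB) * cen2
  }
  while (length(clusters) > 1L) {
    best <- NULL; best_cost <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      cc <- cost(clusters[[i]], clusters[[j]])
      better <- cc < best_cost - 1e-9
      tie <- abs(cc - best_cost) <= 1e-9 && !is.null(best) &&
        (min(clusters[[i]]) < min(clusters[[best[1]]]) ||
           (min(clusters[[i]]) == min(clusters[[best[1]]]) &&
              min(clusters[[j]]) < min(clusters[[best[2]]])))
      if (better || tie) { best_cost <- cc; best <- c(i, j) }
    }
    heights <- c(heights, sqrt(2 * best_cost))
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
    lab <- integer(K)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1L]] <- lab
  }
  list(heights = heights, partitions = partitions)
}

# Plain unweighted silhouette by per-point loops.
naive_silhouette <- function(d, labels) {
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    mates <- which(labels == own & seq_len(n) != i)
    if (length(mates) == 0L) { s[i] <- 0; next }
    a <- mean(d[i, mates])
    b <- Inf
    for (l in setdiff(unique(labels), own))
      b <- min(b, mean(d[i, labels == l]))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Expand a weighted medoid-level problem into per-patient copies (distance
# zero between copies of the same medoid); lets the unweighted naive
# silhouette act as the oracle for the weighted one.
expand_by_counts <- function(d, labels, w) {
  idx <- rep(seq_len(nrow(d)), times = w)
  list(d = d[idx, idx, drop = FALSE], labels = labels[idx])
}

# Event-table builder for encoding/selection tests.
ev <- function(id, type, start, end = start) {
  data.frame(patient_id = id, event_type = type,
             start_day = start, end_day = end, stringsAsFactors = FALSE)
}

# One shared mid-size synthetic cohort, generated once per test run.
.fixture_env <- new.env(parent = emptyenv())
shared_cohort <- function(n = 800L, seed = 101L) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(.fixture_env[[key]])) {
    co <- generate_cohort(generator_config(n_patients = n, rng_seed = seed))
    co$sequences <- encode_cohort(co$events, co$covariates$patient_id)
    .fixture_env[[key]] <- co
  }
  .fixture_env[[key]]
}
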