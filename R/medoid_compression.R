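#' Trajectory meta-features
#'
#' Summarises each daily state sequence by, for every non-none state:
#' total days spent in the state, number of distinct episodes (maximal
#' runs of consecutive days), and the day of last occurrence (negative
#' day index in [-T, -1], or the sentinel -T-1 when the state never
#' occurs).  These are the features the K-means compression stage runs
#' on; recency and episode count let temporally distinct trajectories
#' (early vs late exacerbations) separate even when total days match.
#'
#' @param sequences integer matrix (patients x T) from [encode_cohort()],
#'   or a single integer vector.
#' @param n_states number of non-none states (defaults to the maximum code
#'   present, at least 1).
#' @param days_only if TRUE, return only the total-days features.
#' @return numeric matrix (patients x 3*n_states) with columns
#'   \code{days_s}, \code{episodes_s}, \code{last_s} per state s.
#' @export
meta_features <- function(sequences, n_states = NULL, days_only = FALSE) {
  if (is.vector(sequences)) sequences <- matrix(sequences, nrow = 1L)
  Tw <- ncol(sequences)
  if (is.null(n_states)) n_states <- max(1L, max(sequences))
  out <- matrix(0, nrow(sequences), 3L * n_states)
  colnames(out) <- as.vector(t(outer(seq_len(n_states), c("days", "episodes",
                                                          "last"),
                                     function(s, f) paste0(f, "_", s))))
  sentinel <- -Tw - 1L
  for (i in seq_len(nrow(sequences))) {
    r <- rle(as.integer(sequences[i, ]))
    run_end <- cumsum(r$lengths)            # 1-based end position of run
    for (s in seq_len(n_states)) {
      sel <- r$values == s
      days <- sum(r$lengths[sel])
      eps <- sum(sel)
      last <- if (eps > 0L) max(run_end[sel]) - Tw - 1L else sentinel
      out[i, (s - 1L) * 3L + 1:3] <- c(days, eps, last)
    }
  }
  if (days_only) out <- out[, grep("^days_", colnames(out)), drop = FALSE]
  out
}

# Feature collisions between distinct sequences can leave K-means with
# fewer than k non-empty partitions; split multi-sequence partitions
# (deterministically) until all k indices are populated.  Always possible
# because k never exceeds the number of distinct sequences.
fill_empty_partitions <- function(part, k, key) {
  repeat {
    counts <- tabulate(part, k)
    empty <- which(counts == 0L)
    if (length(empty) == 0L) return(part)
    j <- empty[1L]
    donor <- NA_integer_
    for (p in order(-counts)) {
      if (counts[p] > 0L && length(unique(key[part == p])) > 1L) {
        donor <- p; break
      }
    }
    if (is.na(donor)) stop("internal error: cannot populate all partitions")
    keys <- key[part == donor]
    move_key <- sort(unique(keys))[1L]
    part[part == donor & key == move_key] <- j
  }
}

# Lloyd K-means with deterministic seeding and farthest-point reseeding of
# empty clusters; several restarts, best within-cluster sum of squares
# kept.  Returns integer assignment.
kmeans_lloyd <- function(x, k, n_init = 5L, max_iter = 100L) {
  n <- nrow(x)
  best <- NULL; best_wss <- Inf
  for (run in seq_len(n_init)) {
    centers <- x[sample.int(n, k), , drop = FALSE]
    assign_old <- integer(n)
    for (it in seq_len(max_iter)) {
      # squared distances to centers via the expansion trick
      d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
        2 * tcrossprod(x, centers)
      assign_new <- max.col(-d2, ties.method = "first")
      empty <- setdiff(seq_len(k), unique(assign_new))
      for (e in empty) {
        # reseed from the point farthest from its current center
        far <- which.max(d2[cbind(seq_len(n), assign_new)])
        centers[e, ] <- x[far, ]
        assign_new[far] <- e
      }
      for (j in unique(assign_new))
        centers[j, ] <- colMeans(x[assign_new == j, , drop = FALSE])
      if (identical(assign_new, assign_old)) break
      assign_old <- assign_new
    }
    wss <- sum((x - centers[assign_new, , drop = FALSE])^2)
    if (wss < best_wss) { best_wss <- wss; best <- assign_new }
  }
  list(assignment = best, wss = best_wss)
}

#' Compress sequences into patient-medoids
#'
#' Stage one of the TAK-medoids procedure: K-means (Euclidean, on
#' standardised meta-features) partitions the cohort into K groups, and
#' each group is represented by its medoid -- the member sequence with the
#' smallest summed Hamming distance to all group members.  Every patient
#' is assigned to its group's medoid, and per-patient homogeneity scores
#' (percentage agreement with the representing medoid) are recorded.
#'
#' When \code{k} equals the number of distinct sequences the partition is
#' the identity on distinct sequences, so every patient is represented by
#' its own sequence and mean homogeneity is exactly 100.
#'
#' @param sequences integer matrix (patients x T).
#' @param k target number of medoids (must not exceed the number of
#'   distinct sequences).
#' @param n_init number of K-means restarts (best inertia kept).
#' @param rng_seed seed making the compression deterministic.
#' @param days_only use only total-days meta-features.
#' @return object of class \code{medoid_set}: list(k, medoids (k x T),
#'   assignment (patient -> medoid index), member_counts, homogeneity
#'   (per patient), mean_homogeneity, sd_homogeneity, wss).
#' @export
compress_sequences <- function(sequences, k, n_init = 5L,
                               rng_seed = 1L, days_only = FALSE) {
  n <- nrow(sequences)
  key <- apply(sequences, 1L, paste, collapse = ",")
  n_distinct <- length(unique(key))
  if (k > n_distinct)
    stop(sprintf("k (%d) exceeds number of distinct sequences (%d)",
                 k, n_distinct))
  if (k == n_distinct) {
    part <- as.integer(factor(key, levels = unique(key)))
  } else {
    feats <- meta_features(sequences, days_only = days_only)
    sds <- apply(feats, 2L, stats::sd)
    sds[sds == 0] <- 1                    # constant feature: leave centred
    z <- scale(feats, scale = sds)
    set.seed(rng_seed)
    part <- kmeans_lloyd(z, k, n_init = n_init)$assignment
    part <- fill_empty_partitions(part, k, key)
  }

  medoids <- matrix(0L, k, ncol(sequences))
  assignment <- integer(n)
  for (j in seq_len(k)) {
    members <- which(part == j)
    sub <- sequences[members, , drop = FALSE]
    if (length(unique(key[members])) == 1L) {
      med_row <- 1L
    } else {
      D <- hamming_matrix(sub)
      med_row <- which.min(rowSums(D))    # first minimiser: deterministic
    }
    medoids[j, ] <- sub[med_row, ]
    assignment[members] <- j
  }
  hom <- homogeneity(sequences, medoids[assignment, , drop = FALSE])
  structure(list(k = k, medoids = medoids, assignment = assignment,
                 member_counts = tabulate(assignment, k),
                 homogeneity = hom,
                 mean_homogeneity = mean(hom),
                 sd_homogeneity = stats::sd(hom)),
            class = "medoid_set")
}

#' Homogeneity score between sequences and their medoids
#'
#' Percentage agreement: \code{100 * (1 - hamming(seq, medoid) / T)},
#' so 100 means identical and 0 means the sequences differ everywhere.
#'
#' @param seqs integer matrix (or vector) of sequences.
#' @param medoids matching matrix (or vector) of representing medoids.
#' @return numeric vector of scores in [0, 100].
#' @export
homogeneity <- function(seqs, medoids) {
  if (is.vector(seqs)) seqs <- matrix(seqs, nrow = 1L)
  if (is.vector(medoids)) medoids <- matrix(medoids, nrow = 1L)
  if (!all(dim(seqs) == dim(medoids)))
    stop("sequence and medoid dimensions differ")
  100 * (1 - rowSums(seqs != medoids) / ncol(seqs))
}

#' @export
print.medoid_set <- function(x, ...) {
  cat(sprintf(
    "medoid_set: %d medoids for %d patients; mean homogeneity %.1f (sd %.1f)\n",
    x$k, length(x$assignment), x$mean_homogeneity, x$sd_homogeneity))
  invisible(x)
}
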