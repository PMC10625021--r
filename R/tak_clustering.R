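#' Pairwise Hamming distance matrix
#'
#' Number of positions at which two equal-length categorical sequences
#' differ.  Computed state-by-state with indicator cross-products so the
#' cost is a handful of BLAS calls rather than a nested loop.  Member
#' counts do not enter the metric (they weight the linkage instead).
#'
#' @param sequences integer matrix (sequences x T).
#' @param sequences2 optional second matrix; when supplied the result is
#'   the rectangular cross-distance matrix.
#' @return matrix of raw Hamming distances (entries in [0, T]).
#' @export
hamming_matrix <- function(sequences, sequences2 = NULL) {
  if (is.vector(sequences)) sequences <- matrix(sequences, nrow = 1L)
  cross <- !is.null(sequences2)
  if (cross && ncol(sequences) != ncol(sequences2))
    stop("sequence lengths differ")
  Tw <- ncol(sequences)
  B <- if (cross) sequences2 else sequences
  codes <- sort(unique(c(sequences, B)))
  eq <- matrix(0, nrow(sequences), nrow(B))
  for (s in codes)
    eq <- eq + tcrossprod((sequences == s) * 1, (B == s) * 1)
  D <- Tw - eq
  if (!cross) { diag(D) <- 0; D <- (D + t(D)) / 2 }
  D
}

#' Weighted Ward agglomerative clustering of medoids
#'
#' Stage two of the TAK-medoids procedure: hierarchical agglomeration of
#' the patient-medoids using Ward's criterion applied to the (squared)
#' Hamming distances through the Lance-Williams recurrence, with each
#' medoid carrying its member count as an observation weight so the cut
#' reflects patient mass rather than medoid count.  Ties in the minimum
#' merge cost are broken by the lexicographically smallest pair of leaf
#' indices, making runs reproducible.  Since the Hamming matrix is not
#' Euclidean, Ward's variance interpretation is approximate here; the
#' recurrence itself is exact.
#'
#' Merge heights are reported on the \code{ward.D2} scale
#' (\code{sqrt(2 * cost)}), so with unit weights the tree coincides with
#' \code{hclust(d, "ward.D2")}.
#'
#' @param dist square symmetric Hamming distance matrix over medoids.
#' @param member_counts observation weights (patients per medoid);
#'   \code{NULL} for unit weights.
#' @param C number of clusters to cut the tree into (>= 1).
#' @return object of class \code{traj_clusters}: list(tree (an
#'   \code{hclust} object), C, labels (medoid -> cluster in 1..C),
#'   member_counts, patient_counts (per cluster), silhouette (weighted
#'   mean, NA when C < 2), dist).
#' @export
ward_cluster <- function(dist, member_counts = NULL, C = 4L) {
  K <- nrow(dist)
  if (ncol(dist) != K || any(abs(dist - t(dist)) > 1e-8))
    stop("distance matrix must be square and symmetric")
  if (any(diag(dist) != 0)) stop("distance matrix must have zero diagonal")
  if (C < 1L || C > K) stop("C must be in 1..K")
  if (is.null(member_counts)) member_counts <- rep(1L, K)
  if (length(member_counts) != K || any(member_counts < 1))
    stop("member_counts must be positive, one per medoid")

  w <- as.numeric(member_counts)
  A <- outer(w, w) / outer(w, w, "+") * dist^2   # initial Ward merge costs
  diag(A) <- Inf
  active <- rep(TRUE, K)
  cl_id <- -seq_len(K)          # hclust convention: negative = leaf
  rep_leaf <- seq_len(K)        # smallest original index, for tie-breaks
  merge <- matrix(0L, K - 1L, 2L)
  height <- numeric(K - 1L)

  for (s in seq_len(K - 1L)) {
    act <- which(active)
    sub <- A[act, act, drop = FALSE]
    m <- min(sub)
    cand <- which(sub <= m + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pr <- cbind(rep_leaf[act[cand[, 1L]]], rep_leaf[act[cand[, 2L]]])
    pick <- order(pmin(pr[, 1L], pr[, 2L]), pmax(pr[, 1L], pr[, 2L]))[1L]
    i <- act[min(cand[pick, ])]; j <- act[max(cand[pick, ])]

    height[s] <- sqrt(2 * A[i, j])
    mi <- cl_id[i]; mj <- cl_id[j]
    merge[s, ] <- if (mi < mj) c(mi, mj) else c(mj, mi)

    # Lance-Williams Ward update, weights = member counts
    others <- act[act != i & act != j]
    if (length(others) > 0L) {
      Anew <- ((w[i] + w[others]) * A[i, others] +
               (w[j] + w[others]) * A[j, others] -
               w[others] * A[i, j]) / (w[i] + w[j] + w[others])
      A[i, others] <- Anew; A[others, i] <- Anew
    }
    w[i] <- w[i] + w[j]
    active[j] <- FALSE
    A[j, ] <- Inf; A[, j] <- Inf
    cl_id[i] <- s
    rep_leaf[i] <- min(rep_leaf[i], rep_leaf[j])
  }

  tree <- structure(list(merge = merge, height = height,
                         order = dendrogram_order(merge),
                         labels = rownames(dist),
                         method = "ward.weighted",
                         dist.method = "hamming",
                         call = match.call()),
                    class = "hclust")
  labels <- if (C == 1L) rep(1L, K) else
    as.integer(stats::cutree(tree, k = C))
  pc <- vapply(seq_len(C),
               function(cc) sum(member_counts[labels == cc]), numeric(1))
  sil <- if (C >= 2L) silhouette_score(dist, labels, member_counts) else NA_real_
  structure(list(tree = tree, C = as.integer(C), labels = labels,
                 member_counts = member_counts, patient_counts = pc,
                 silhouette = sil, dist = dist),
            class = "traj_clusters")
}

# Leaf order by left-to-right traversal of the merge matrix (the order an
# index plot should draw the leaves in).
dendrogram_order <- function(merge) {
  unpack <- function(node) {
    if (node < 0L) return(-node)
    c(unpack(merge[node, 1L]), unpack(merge[node, 2L]))
  }
  unpack(nrow(merge))
}

#' Mean silhouette index from a distance matrix with observation weights
#'
#' Standard silhouette s(i) = (b - a) / max(a, b), where a is the mean
#' distance to the object's own cluster and b the smallest mean distance
#' to another cluster, evaluated at the patient level by treating each
#' medoid as \code{member_counts} coincident patients (distance zero
#' between patients sharing a medoid).  The weighted mean over patients is
#' returned; a patient alone in its cluster scores 0 by convention.
#'
#' @param dist square distance matrix over medoids.
#' @param labels cluster label per medoid.
#' @param member_counts patients per medoid (NULL for unit weights).
#' @return weighted mean silhouette in [-1, 1].
#' @export
silhouette_score <- function(dist, labels, member_counts = NULL) {
  K <- nrow(dist)
  if (is.null(member_counts)) member_counts <- rep(1L, K)
  w <- as.numeric(member_counts)
  labs <- unique(labels)
  if (length(labs) < 2L) stop("silhouette needs at least 2 clusters")
  Wc <- vapply(labs, function(cc) sum(w[labels == cc]), numeric(1))
  if (all(Wc == 1)) stop("all clusters are singletons")
  s <- numeric(K)
  for (i in seq_len(K)) {
    own <- labels[i]
    W_own <- Wc[match(own, labs)]
    if (W_own <= 1) { s[i] <- 0; next }
    a <- sum(w[labels == own] * dist[i, labels == own]) / (W_own - 1)
    b <- min(vapply(labs[labs != own], function(cc)
      sum(w[labels == cc] * dist[i, labels == cc]) / Wc[match(cc, labs)],
      numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  sum(w * s) / sum(w)
}

#' Relabel clusters from least to most severe
#'
#' Permutes cluster labels so the mean per-patient number of severe
#' exacerbation episodes (maximal runs of the exacerbation state in the
#' daily sequence) is non-decreasing in the label; ties are broken by the
#' mean total number of hospitalised (non-zero) days.
#'
#' @param model a [ward_cluster()] fit.
#' @param sequences patient daily-state matrix.
#' @param assignment patient -> medoid index (from [compress_sequences()]).
#' @param exac_code alphabet code of the exacerbation state (default 1).
#' @return the model with \code{labels}, \code{patient_counts} permuted and
#'   a \code{severity} data.frame (cluster, mean_exac_episodes,
#'   mean_hosp_days) attached.
#' @export
order_by_severity <- function(model, sequences, assignment, exac_code = 1L) {
  pat_cluster <- model$labels[assignment]
  feats <- meta_features(sequences)
  ep <- feats[, paste0("episodes_", exac_code)]
  hosp_days <- rowSums(sequences != 0L)
  C <- model$C
  mean_ep <- vapply(seq_len(C), function(cc) mean(ep[pat_cluster == cc]),
                    numeric(1))
  mean_days <- vapply(seq_len(C),
                      function(cc) mean(hosp_days[pat_cluster == cc]),
                      numeric(1))
  perm <- order(mean_ep, mean_days)       # perm[new label] = old label
  new_of_old <- match(seq_len(C), perm)
  model$labels <- new_of_old[model$labels]
  model$patient_counts <- model$patient_counts[perm]
  model$severity <- data.frame(cluster = seq_len(C),
                               mean_exac_episodes = mean_ep[perm],
                               mean_hosp_days = mean_days[perm])
  model
}

#' Patient-level raster for trajectory visualization
#'
#' Expands the medoid matrix back to patient scale for the classic index
#' plot: each medoid row is repeated once per represented patient, rows are
#' grouped by cluster (1..C) and ordered within cluster by dendrogram leaf
#' order, so archetype blocks appear contiguous.
#'
#' @param model a [ward_cluster()] fit.
#' @param medoids medoid sequence matrix (K x T).
#' @param member_counts patients per medoid (defaults to the model's).
#' @return integer matrix (total patients x T) with the row's cluster label
#'   in attribute \code{cluster}.
#' @export
visualization_matrix <- function(model, medoids,
                                 member_counts = model$member_counts) {
  ord <- model$tree$order
  rows <- integer(0); row_cluster <- integer(0)
  for (cc in seq_len(model$C)) {
    leaves <- ord[model$labels[ord] == cc]
    rows <- c(rows, rep(leaves, times = member_counts[leaves]))
    row_cluster <- c(row_cluster, rep(cc, sum(member_counts[leaves])))
  }
  out <- medoids[rows, , drop = FALSE]
  attr(out, "cluster") <- row_cluster
  out
}

#' @export
print.traj_clusters <- function(x, ...) {
  cat(sprintf("traj_clusters: %d medoids cut into %d clusters\n",
              length(x$labels), x$C))
  cat("patients per cluster:", paste(x$patient_counts, collapse = ", "), "\n")
  if (!is.na(x$silhouette))
    cat(sprintf("weighted mean silhouette: %.3f\n", x$silhouette))
  invisible(x)
}
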