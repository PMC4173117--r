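# Agglomerative clustering of rows or columns. The production path wraps
# stats::hclust; naive_linkage is an independent O(n^3) from-definition
# agglomerator used as the correctness oracle.

LINKAGE_METHODS <- c("single", "complete", "average", "ward",
                     "centroid", "median", "weighted")
DISTANCE_METRICS <- c("euclidean", "manhattan", "correlation", "cosine",
                      "hamming")

# Pairwise dissimilarities between the rows of a plain numeric matrix.
pairwise_distance <- function(m, metric) {
  metric <- match.arg(metric, DISTANCE_METRICS)
  switch(metric,
    euclidean = stats::dist(m),
    manhattan = stats::dist(m, method = "manhattan"),
    correlation = {
      sds <- apply(m, 1L, stats::sd)
      if (any(!is.finite(sds)) || any(sds == 0)) {
        stop("correlation distance is undefined for a constant vector")
      }
      stats::as.dist(1 - stats::cor(t(m)))
    },
    cosine = {
      nrm <- sqrt(rowSums(m^2))
      if (any(nrm == 0)) stop("cosine distance is undefined for a zero vector")
      stats::as.dist(1 - tcrossprod(m / nrm))
    },
    hamming = {
      n <- nrow(m)
      d <- matrix(0, n, n)
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          d[i, j] <- d[j, i] <- mean(m[i, ] != m[j, ])
        }
      }
      stats::as.dist(d)
    })
}

axis_matrix <- function(data, axis) {
  axis <- match.arg(axis, c("row", "column"))
  if (axis == "row") data$values else t(data$values)
}

# A merge sequence: n-1 rows of (left, right, height, size) with original
# observations numbered 0..n-1 and merge i creating cluster n+i.
new_merge_sequence <- function(left, right, height, size, n_leaves) {
  structure(data.frame(left = as.integer(left), right = as.integer(right),
                       height = as.numeric(height), size = as.integer(size)),
            n_leaves = as.integer(n_leaves),
            class = c("merge_sequence", "data.frame"))
}

#' Number of leaves of a merge sequence
#' @param merges a `merge_sequence`.
#' @return Integer leaf count.
#' @export
n_leaves <- function(merges) attr(merges, "n_leaves")

# Orient each merge so the member containing the smallest original leaf index
# comes first; this makes left/right deterministic.
orient_merges <- function(left, right, height, n) {
  k <- length(left)
  minleaf <- c(0:(n - 1L), integer(k))
  size <- c(rep(1L, n), integer(k))
  for (i in seq_len(k)) {
    a <- left[i]; b <- right[i]
    if (minleaf[b + 1L] < minleaf[a + 1L]) { tmp <- a; a <- b; b <- tmp }
    left[i] <- a; right[i] <- b
    minleaf[n + i] <- min(minleaf[a + 1L], minleaf[b + 1L])
    size[n + i] <- size[a + 1L] + size[b + 1L]
  }
  new_merge_sequence(left, right, height, size[(n + 1L):(n + k)], n)
}

hclust_to_merges <- function(hc) {
  n <- nrow(hc$merge) + 1L
  conv <- function(x) ifelse(x < 0, -x - 1L, x + n - 1L)
  orient_merges(conv(hc$merge[, 1L]), conv(hc$merge[, 2L]),
                pmax(hc$height, 0), n)
}

#' Hierarchical clustering of a data matrix axis
#'
#' Agglomerates rows (or columns, after transposition) and returns the merge
#' sequence. Heights follow the convention in which two singletons merge at
#' their plain (unsquared) dissimilarity for every method, so Ward's first
#' merge of two points equals their Euclidean distance. Centroid and median
#' linkage are computed on squared distances with square-rooted heights,
#' which is the same convention; their height sequences may contain
#' inversions, which are reported as a warning.
#'
#' @param data a [data_matrix].
#' @param axis `"row"` (default) or `"column"`.
#' @param linkage one of `single`, `complete`, `average`, `ward`, `centroid`,
#'   `median`, `weighted`.
#' @param distance one of `euclidean`, `manhattan`, `correlation`, `cosine`,
#'   `hamming`.
#' @return A `merge_sequence`: a data frame with columns `left`, `right`,
#'   `height`, `size` (0-based member indices; merge *i* creates cluster
#'   *n + i*), with attribute `n_leaves`.
#' @export
compute_linkage <- function(data, axis = c("row", "column"),
                            linkage = "ward", distance = "euclidean") {
  stopifnot(inherits(data, "data_matrix"))
  axis <- match.arg(axis)
  linkage <- match.arg(linkage, LINKAGE_METHODS)
  m <- axis_matrix(data, axis)
  if (nrow(m) < 2L) {
    stop(sprintf("need at least 2 items on the %s axis to cluster", axis))
  }
  d <- pairwise_distance(m, distance)
  method <- switch(linkage, ward = "ward.D2", weighted = "mcquitty", linkage)
  if (linkage %in% c("centroid", "median")) {
    hc <- stats::hclust(d^2, method = method)
    hc$height <- sqrt(pmax(hc$height, 0))
  } else {
    hc <- stats::hclust(d, method = method)
  }
  merges <- hclust_to_merges(hc)
  if (linkage %in% c("centroid", "median") &&
      any(diff(merges$height) < -1e-9)) {
    warning(sprintf("%s linkage produced height inversions", linkage))
  }
  merges
}

#' Naive from-definition agglomerative clustering (test oracle)
#'
#' Direct O(n^3) agglomeration: at every step all inter-cluster distances are
#' recomputed from their definitions over the current cluster members
#' (min / max / mean of pairwise dissimilarities for single, complete and
#' average; centroid geometry for ward, centroid and median; the recursive
#' midpoint average for weighted) and the closest pair is merged. Ties are
#' broken deterministically: among minimal-distance pairs the one with the
#' lexicographically smallest (smaller index, larger index) cluster-index
#' pair wins. Ward, centroid and median require the Euclidean metric, since
#' their definitions are geometric.
#'
#' Intended for small n; it is the independent reference that
#' [compute_linkage] is checked against.
#'
#' @inheritParams compute_linkage
#' @return A `merge_sequence`.
#' @export
naive_linkage <- function(data, axis = c("row", "column"),
                          linkage = "ward", distance = "euclidean") {
  stopifnot(inherits(data, "data_matrix"))
  axis <- match.arg(axis)
  linkage <- match.arg(linkage, LINKAGE_METHODS)
  m <- axis_matrix(data, axis)
  n <- nrow(m)
  if (n < 2L) stop(sprintf("need at least 2 items on the %s axis to cluster", axis))
  geometric <- linkage %in% c("ward", "centroid", "median")
  if (geometric && distance != "euclidean") {
    stop(sprintf("naive %s linkage is defined for the euclidean metric only",
                 linkage))
  }
  D <- as.matrix(pairwise_distance(m, distance))

  members <- c(as.list(seq_len(n)), vector("list", n - 1L)) # by id+1, 1-based rows
  centers <- matrix(NA_real_, 2L * n - 1L, ncol(m))
  centers[seq_len(n), ] <- m
  active <- 0:(n - 1L)
  # WPGMA distances are defined recursively, so they are carried along.
  wd <- if (linkage == "weighted") {
    W <- matrix(NA_real_, 2L * n - 1L, 2L * n - 1L)
    W[seq_len(n), seq_len(n)] <- D
    W
  } else NULL

  cluster_dist <- function(a, b) {
    switch(linkage,
      single = min(D[members[[a + 1L]], members[[b + 1L]]]),
      complete = max(D[members[[a + 1L]], members[[b + 1L]]]),
      average = mean(D[members[[a + 1L]], members[[b + 1L]]]),
      weighted = wd[a + 1L, b + 1L],
      centroid = ,
      median = sqrt(sum((centers[a + 1L, ] - centers[b + 1L, ])^2)),
      ward = {
        na <- length(members[[a + 1L]]); nb <- length(members[[b + 1L]])
        sqrt(2 * na * nb / (na + nb)) *
          sqrt(sum((centers[a + 1L, ] - centers[b + 1L, ])^2))
      })
  }

  left <- integer(n - 1L); right <- integer(n - 1L); height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- Inf; bi <- NA_integer_; bj <- NA_integer_
    na_ <- length(active)
    for (p in seq_len(na_ - 1L)) {
      for (q in (p + 1L):na_) {
        dpq <- cluster_dist(active[p], active[q])
        if (dpq < best) { best <- dpq; bi <- active[p]; bj <- active[q] }
      }
    }
    new_id <- n + step - 1L
    ma <- members[[bi + 1L]]; mb <- members[[bj + 1L]]
    members[[new_id + 1L]] <- c(ma, mb)
    if (geometric) {
      centers[new_id + 1L, ] <- if (linkage == "median") {
        (centers[bi + 1L, ] + centers[bj + 1L, ]) / 2
      } else {
        colMeans(m[members[[new_id + 1L]], , drop = FALSE])
      }
    }
    if (!is.null(wd)) {
      for (k in setdiff(active, c(bi, bj))) {
        wd[new_id + 1L, k + 1L] <- wd[k + 1L, new_id + 1L] <-
          (wd[bi + 1L, k + 1L] + wd[bj + 1L, k + 1L]) / 2
      }
    }
    active <- c(setdiff(active, c(bi, bj)), new_id)
    left[step] <- bi; right[step] <- bj; height[step] <- best
  }
  orient_merges(left, right, height, n)
}

# Canonical form for comparing two merge sequences when merge order between
# equal-height merges may differ: every merge as (sorted leaf set, height),
# the list sorted by (height, smallest leaf).
canonical_merges <- function(merges) {
  n <- n_leaves(merges)
  leafset <- c(lapply(0:(n - 1L), identity), vector("list", n - 1L))
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    s <- sort(c(leafset[[merges$left[i] + 1L]],
                leafset[[merges$right[i] + 1L]]))
    leafset[[n + i]] <- s
    out[[i]] <- list(set = s, height = merges$height[i])
  }
  ord <- order(vapply(out, `[[`, 0, "height"),
               vapply(out, function(x) x$set[1L], 0))
  out[ord]
}

# TRUE when two merge sequences describe the same hierarchy with heights
# agreeing within tol.
same_hierarchy <- function(a, b, tol = 1e-9) {
  if (!identical(n_leaves(a), n_leaves(b))) return(FALSE)
  ca <- canonical_merges(a); cb <- canonical_merges(b)
  for (i in seq_along(ca)) {
    if (!identical(ca[[i]]$set, cb[[i]]$set)) return(FALSE)
    if (abs(ca[[i]]$height - cb[[i]]$height) > tol) return(FALSE)
  }
  TRUE
}
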