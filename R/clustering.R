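# Standardization, 2-D embedding and fuzzy c-means soft clustering.
#
# FCM is implemented from scratch (it is the analytical core of the
# repertoire analysis): alternate membership updates
#   u_ik = [ sum_j (d_ik / d_jk)^(2/(mu-1)) ]^(-1)
# with Euclidean d, and u^mu-weighted centroid means, until the maximum
# membership change falls below `tol` or `max_iter` is reached.

#' Z-score standardization of a feature matrix
#'
#' Centers and scales each column to mean 0 and standard deviation 1 so the
#' differing measurement units of the acoustic parameters do not bias the
#' embedding or clustering. Uses the population-sd convention (divide by n)
#' by default.
#'
#' @param x numeric matrix or data frame (at least 2 rows).
#' @param population logical; population (n) or sample (n-1) sd.
#' @return standardized matrix with `center`/`scale` attributes.
#' @export
zscore_standardize <- function(x, population = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to standardize")
  if (any(!is.finite(x))) stop("non-finite values in feature matrix")
  mu <- colMeans(x)
  denom <- if (population) nrow(x) else nrow(x) - 1
  sdv <- sqrt(colSums(sweep(x, 2, mu)^2) / denom)
  if (any(sdv < 1e-12)) {
    bad <- colnames(x)[sdv < 1e-12] %||% which(sdv < 1e-12)
    stop("constant column cannot be standardized: ",
         paste(bad, collapse = ", "))
  }
  out <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
  attr(out, "center") <- mu
  attr(out, "scale") <- sdv
  out
}

#' Two-dimensional UMAP embedding of the standardized feature table
#'
#' Uniform Manifold Approximation and Projection as a pre-processing step
#' before clustering; preserves local and global structure of the acoustic
#' parameter space in two coordinates (UMAP1, UMAP2). Backed by
#' \pkg{uwot} restricted to one thread so that a fixed seed reproduces the
#' coordinates exactly.
#'
#' @param x standardized numeric matrix.
#' @param n_neighbors,min_dist UMAP hyperparameters (defaults 15 and 0.1;
#'   the canonical defaults, documented as choices rather than reproductions
#'   of any published setting).
#' @param seed integer seed.
#' @return list of class `call_embedding`: `coords` (n x 2, columns UMAP1,
#'   UMAP2) and `params`.
#' @export
embed_2d <- function(x, n_neighbors = 15, min_dist = 0.1, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < n_neighbors + 1) {
    stop("need at least n_neighbors + 1 = ", n_neighbors + 1, " rows, got ",
         nrow(x))
  }
  if (any(!is.finite(x))) stop("non-finite values in embedding input")
  coords <- withr::with_seed(as.integer(seed),
    uwot::umap(x, n_neighbors = n_neighbors, min_dist = min_dist,
               n_components = 2, n_threads = 1, n_sgd_threads = 0))
  if (any(!is.finite(coords))) stop("embedding produced non-finite values")
  colnames(coords) <- c("UMAP1", "UMAP2")
  structure(list(coords = coords,
                 params = list(n_neighbors = n_neighbors,
                               min_dist = min_dist, seed = seed)),
            class = "call_embedding")
}

#' Fuzzy c-means soft clustering
#'
#' Soft-clusters `x` into `c` clusters with fuzzifier `mu` (> 1). Instead of
#' a crisp partition, every observation receives a membership value per
#' cluster (rows of the membership matrix sum to 1); hard labels are the
#' row-wise argmax. Centroids are initialized by sampling `c` distinct
#' points under the given seed. A point coincident with a centroid receives
#' full membership there. The objective sum_ik u_ik^mu d_ik^2 is recorded
#' per iteration and is non-increasing.
#'
#' @param x numeric matrix (rows = calls; the 2-D embedding by default in
#'   the pipeline, or the standardized feature table).
#' @param c number of clusters (>= 2; the repertoire analysis uses 3).
#' @param fuzzifier degree of fuzzification mu (> 1; default 2).
#' @param max_iter maximum iterations (default 100).
#' @param tol stop when the largest membership change falls below this.
#' @param seed seed for centroid initialization.
#' @param init optional c x d matrix of initial centroids (overrides the
#'   seeded sampling).
#' @return object of class `fcm_clustering`: `centroids`, `membership`,
#'   `hard_labels`, `objective_trace`, `iterations`, `converged`,
#'   `n_clusters`, `fuzzifier`.
#' @export
fcm_cluster <- function(x, c = 3, fuzzifier = 2, max_iter = 100,
                        tol = 1e-6, seed = 1L, init = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (c < 2) stop("need at least 2 clusters")
  if (fuzzifier <= 1) stop("fuzzifier must exceed 1")
  if (n <= c) stop("need more points (", n, ") than clusters (", c, ")")
  ux <- unique(x)
  if (nrow(ux) < c) stop("all points identical (or fewer distinct points than clusters)")
  centroids <- if (!is.null(init)) {
    stopifnot(nrow(init) == c, ncol(init) == ncol(x))
    as.matrix(init)
  } else {
    withr::with_seed(as.integer(seed),
                     ux[sample.int(nrow(ux), c), , drop = FALSE])
  }
  U <- matrix(0, n, c)
  trace <- numeric(0)
  expo <- 1 / (fuzzifier - 1)
  sqdist <- function(cent) {
    d2 <- vapply(seq_len(nrow(cent)), function(k) {
      rowSums(sweep(x, 2, cent[k, ])^2)
    }, numeric(n))
    matrix(d2, nrow = n)
  }
  memberships <- function(d2) {
    inv <- d2^(-expo)
    u <- inv / rowSums(inv)
    zero <- which(d2 < 1e-300, arr.ind = TRUE)
    if (nrow(zero) > 0) {
      for (i in unique(zero[, 1])) {
        hits <- d2[i, ] < 1e-300
        u[i, ] <- 0
        u[i, hits] <- 1 / sum(hits)
      }
    }
    u
  }
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    U_new <- memberships(sqdist(centroids))
    W <- U_new^fuzzifier
    centroids <- (t(W) %*% x) / colSums(W)
    trace <- c(trace, sum(W * sqdist(centroids)))
    delta <- max(abs(U_new - U))
    U <- U_new
    if (delta < tol) { converged <- TRUE; break }
  }
  # close with a membership update so the returned memberships satisfy the
  # closed-form equation against the returned centroids
  d2_final <- sqdist(centroids)
  U <- memberships(d2_final)
  trace <- c(trace, sum(U^fuzzifier * d2_final))
  dimnames(U) <- list(NULL, paste0("u", seq_len(c)))
  structure(list(centroids = centroids, membership = U,
                 hard_labels = hard_assign(U, quiet = TRUE),
                 objective_trace = trace, iterations = it,
                 converged = converged, n_clusters = c,
                 fuzzifier = fuzzifier, tol = tol, seed = seed),
            class = "fcm_clustering")
}

#' @export
print.fcm_clustering <- function(x, ...) {
  cat("Fuzzy c-means clustering: ", nrow(x$membership), " calls, ",
      x$n_clusters, " clusters, mu = ", x$fuzzifier, "\n", sep = "")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  cat("  final objective:", utils::tail(x$objective_trace, 1), "\n")
  print(table(cluster = x$hard_labels))
  invisible(x)
}

#' Hard cluster labels from a membership matrix
#'
#' Row-wise argmax of the membership matrix; ties are broken toward the
#' lowest cluster index and reported via a message and the `"ties"`
#' attribute.
#'
#' @param U membership matrix (rows sum to 1, entries in \[0, 1\]).
#' @param quiet suppress the tie message.
#' @return integer vector of cluster labels with attribute `ties` (row
#'   indices that were tied).
#' @export
hard_assign <- function(U, quiet = FALSE) {
  U <- as.matrix(U)
  if (any(U < -1e-9) || any(U > 1 + 1e-9)) {
    stop("membership values must lie in [0, 1]")
  }
  if (any(abs(rowSums(U) - 1) > 1e-6)) {
    stop("membership rows must sum to 1")
  }
  labels <- max.col(U, ties.method = "first")
  rmax <- U[cbind(seq_len(nrow(U)), labels)]
  ties <- which(rowSums(abs(U - rmax) < 1e-12) > 1)
  if (length(ties) > 0 && !quiet) {
    message(length(ties), " call(s) tied between clusters; ",
            "assigned to the lowest cluster index")
  }
  attr(labels, "ties") <- ties
  labels
}
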