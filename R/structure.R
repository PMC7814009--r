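#' Pairwise distances between samples on the dosage matrix
#'
#' Distances between dosage vectors with pairwise-complete handling of the
#' missing code: for each sample pair only sites with observed dosage in
#' both are compared, with no rescaling, so that under the Manhattan metric
#' a difference of one dosage unit at one site contributes exactly 1 (the
#' total allele-count difference).
#'
#' @param mat A `genotype_matrix` (samples x sites).
#' @param metric `"euclidean"` (default) or `"manhattan"`.
#' @return A symmetric `dist`-convertible matrix of class
#'   `c("distance_matrix", "matrix")` with zero diagonal.
#' @export
pairwise_distance <- function(mat, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 2L) stop("need at least 2 samples", call. = FALSE)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      diff <- mat[i, ] - mat[j, ]
      diff <- diff[!is.na(diff)]
      d[i, j] <- d[j, i] <- switch(metric,
        euclidean = sqrt(sum(diff^2)),
        manhattan = sum(abs(diff)))
    }
  }
  structure(d, metric = metric, class = c("distance_matrix", "matrix"))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou–Nei agglomeration (via [ape::nj()], the standard
#' implementation with default parameters).  Negative branch lengths, which
#' NJ can produce on non-additive input, are clamped to zero for display
#' while the raw estimates are retained in `attr(tree, "raw_edge_length")`.
#'
#' @param d A symmetric distance matrix (`distance_matrix`, `matrix` or
#'   `dist`) over at least 3 samples.
#' @return An unrooted [ape::phylo] tree (leaf set = sample set).
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d))
  if (nrow(d) < 3L) stop("need at least 3 samples for a tree", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  tree <- ape::nj(as.dist(d))
  raw <- tree$edge.length
  tree$edge.length <- pmax(raw, 0)
  attr(tree, "raw_edge_length") <- raw
  tree
}

#' Write a tree in Newick format
#'
#' @param tree An [ape::phylo] object (e.g. from [nj_tree()]).
#' @param path Output file path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Principal component analysis of the dosage matrix
#'
#' Column-mean centering without unit-variance scaling, decomposed exactly
#' by singular values (via [stats::prcomp()]).  Missing dosage codes are
#' mean-imputed per site before centering.  Scores are returned for
#' `min(samples - 1, sites)` components, and the sign of each component is
#' fixed so that its largest-magnitude loading is positive, making runs
#' reproducible.
#'
#' @param mat A `genotype_matrix` (samples x sites).
#' @return A list of class `dosage_pca`: `scores` (samples x components),
#'   `loadings` (sites x components), `variance_explained` (non-increasing
#'   fractions summing to at most 1), `center` (site means).
#' @export
dosage_pca <- function(mat) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 2L) stop("need at least 2 samples", call. = FALSE)
  x <- apply(mat, 2L, function(col) {
    if (anyNA(col)) col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  x <- matrix(as.numeric(x), nrow = nrow(mat), dimnames = dimnames(mat))
  total_var <- sum(apply(x, 2L, stats::var))
  if (total_var == 0) {
    warning("all sites are constant: zero-variance PCA result")
    k <- min(nrow(mat) - 1L, ncol(mat))
    return(structure(list(
      scores = matrix(0, nrow(mat), k, dimnames = list(rownames(mat), NULL)),
      loadings = matrix(0, ncol(mat), k, dimnames = list(colnames(mat), NULL)),
      variance_explained = rep(0, k),
      center = colMeans(x)), class = "dosage_pca"))
  }
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(nrow(mat) - 1L, ncol(mat), ncol(p$rotation))
  scores <- p$x[, seq_len(k), drop = FALSE]
  loadings <- p$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    l <- loadings[, j]
    sign(l[which.max(abs(l))]) < 0
  }, logical(1))
  scores[, flip] <- -scores[, flip, drop = FALSE]
  loadings[, flip] <- -loadings[, flip, drop = FALSE]
  ve <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve[seq_len(k)], center = p$center),
            class = "dosage_pca")
}

#' @method print dosage_pca
#' @export
print.dosage_pca <- function(x, ...) {
  cat(sprintf("Dosage-matrix PCA: %d samples, %d components\n",
              nrow(x$scores), ncol(x$scores)))
  ve <- utils::head(x$variance_explained, 5)
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(ve), 100 * ve),
            collapse = ", "), "\n")
  invisible(x)
}

#' @method plot dosage_pca
#' @export
plot.dosage_pca <- function(x, groups = NULL, ...) {
  col <- if (is.null(groups)) "black" else
    as.integer(factor(groups[rownames(x$scores)])) + 1L
  plot(x$scores[, 1], x$scores[, 2], col = col, pch = 19,
       xlab = sprintf("PC1 (%.1f%%)", 100 * x$variance_explained[1]),
       ylab = sprintf("PC2 (%.1f%%)", 100 * x$variance_explained[2]), ...)
  invisible(x)
}

# Deterministic k-means++ seeding (used for reproducible site aggregation).
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1L] <- sample.int(n, 1L, prob = prob)
    d2_new <- rowSums((x - matrix(x[centers[j + 1L], ], n, ncol(x),
                                  byrow = TRUE))^2)
    d2 <- pmin(d2, d2_new)
  }
  x[centers, , drop = FALSE]
}

#' Aggregate sites into k-means centroid rows for heatmap display
#'
#' Sites (columns of the dosage matrix) are clustered with Lloyd's k-means
#' (k-means++ initialisation, fixed seed, at most 100 iterations); the
#' output is the k centroid rows — the average dosage per site cluster —
#' ordered by hierarchical clustering of the centroids, the order a heatmap
#' of SNV patterns displays.
#'
#' @param mat A `genotype_matrix` (samples x sites).
#' @param k Number of site clusters (default 200; must not exceed the
#'   number of sites).
#' @param seed Integer seed for the initialisation.
#' @return A k x samples matrix of class `aggregated_matrix` with
#'   attributes `assignment` (cluster of each site) and `sizes`.  When the
#'   matrix holds fewer distinct site patterns than `k`, one centroid per
#'   distinct pattern is returned instead.
#' @export
kmeans_row_aggregate <- function(mat, k = 200L, seed = 1L) {
  stopifnot(is.matrix(mat))
  k <- check_count(k)
  x <- t(mat)                       # sites in rows
  x[is.na(x)] <- 0
  if (k > nrow(x)) stop("k exceeds the number of sites", call. = FALSE)
  with_seed(seed, {
    key <- apply(x, 1L, paste, collapse = "\r")
    ukey <- unique(key)
    ux <- x[match(ukey, key), , drop = FALSE]
    fit <- if (k == nrow(x)) {
      list(centers = x, cluster = seq_len(nrow(x)),
           size = rep(1L, nrow(x)))
    } else if (k >= nrow(ux)) {
      # fewer distinct site patterns than requested clusters: each
      # pattern is its own centroid
      cl <- match(key, ukey)
      list(centers = ux, cluster = cl, size = tabulate(cl, nrow(ux)))
    } else {
      # k-means++ seeding over the distinct patterns keeps the initial
      # centers distinct, so no Lloyd cluster starts empty
      init <- kmeanspp_init(ux, k)
      fit <- tryCatch(
        suppressWarnings(kmeans(x, centers = init, iter.max = 100L,
                                algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(fit) || anyNA(fit$centers)) {
        # rare degenerate Lloyd run: fall back to one assignment step
        d2 <- as.matrix(dist(rbind(init, x)))[-(1:k), 1:k, drop = FALSE]
        cl <- max.col(-d2)
        centers <- t(vapply(seq_len(k), function(j) {
          colMeans(x[cl == j, , drop = FALSE])
        }, numeric(ncol(x))))
        centers[is.nan(centers)] <- 0
        fit <- list(centers = centers, cluster = cl,
                    size = tabulate(cl, k))
      }
      fit
    }
    centers <- fit$centers
    ord <- if (nrow(centers) > 2L) {
      hclust(dist(centers))$order
    } else seq_len(nrow(centers))
    out <- centers[ord, , drop = FALSE]
    rownames(out) <- paste0("cluster", seq_len(nrow(out)))
    structure(out, assignment = match(fit$cluster, ord),
              sizes = fit$size[ord],
              class = c("aggregated_matrix", "matrix"))
  })
}
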