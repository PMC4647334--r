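# Clustering machinery: sequential self-organizing map with Gauss
# neighborhood and Euclidean distance, k-means seeded from the SOM codebook,
# and agglomerative hierarchical clustering with heatmap leaf ordering.

grid_coordinates <- function(grid) {
  as.matrix(expand.grid(row = seq_len(grid[1]), col = seq_len(grid[2])))
}

#' Best-matching unit of each item
#'
#' Index of the codebook vector at minimal Euclidean distance; ties go to
#' the lowest neuron index.
#'
#' @param model a \code{som_model} (or any codebook matrix).
#' @param data items x features matrix.
#' @return integer vector of neuron indices, one per item.
#' @export
best_matching_unit <- function(model, data) {
  codebook <- if (inherits(model, "som_model")) model$codebook else model
  apply(data, 1, function(x) {
    d2 <- rowSums(sweep(codebook, 2, x)^2)
    which.min(d2)  # which.min takes the first (lowest index) on ties
  })
}

#' Train a self-organizing map
#'
#' Sequential (online) training: at each step one item is drawn at random,
#' its best-matching unit (BMU) is found by Euclidean distance, and every
#' codebook vector w is moved by
#' \code{w <- w + alpha(t) * h(BMU, u, sigma(t)) * (x - w)} with the Gauss
#' neighborhood \code{h = exp(-d_grid^2 / (2 sigma^2))}. The neighborhood
#' width sigma decays linearly from half the grid diagonal to 0.5 and the
#' learning rate alpha from 0.05 to 0.01. The codebook is initialized from
#' randomly drawn items with a small jitter. Deterministic under seed.
#'
#' @param data items x features numeric matrix (finite values).
#' @param grid c(rows, cols) of the neuron grid; 5x5 is the conventional
#'   choice for small descriptor matrices, 4x6 (24 neurons) for GO count
#'   matrices.
#' @param iterations training steps (default 4000).
#' @param seed integer seed.
#' @param alpha_range learning-rate schedule (start, floor).
#' @param sigma_range neighborhood-width schedule (start, floor); the
#'   default start is half the grid diagonal.
#' @return object of class \code{som_model}: codebook (neurons x features),
#'   grid, grid coordinates, iterations, seed.
#' @export
train_som <- function(data, grid = c(5, 5), iterations = 4000, seed = 1L,
                      alpha_range = c(0.05, 0.01), sigma_range = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("SOM input must be finite")
  if (nrow(data) < 1 || prod(grid) < 1) stop("need >= 1 item and >= 1 neuron")
  coords <- grid_coordinates(grid)
  n_neurons <- nrow(coords)
  if (is.null(sigma_range)) {
    sigma_range <- c(max(0.5, sqrt(sum((grid - 1)^2)) / 2), 0.5)
  }
  with_seed(seed, {
    init_rows <- sample(nrow(data), n_neurons, replace = TRUE)
    codebook <- data[init_rows, , drop = FALSE] +
      matrix(stats::rnorm(n_neurons * ncol(data),
                          sd = 0.01 * max(stats::sd(data), .Machine$double.eps)),
             nrow = n_neurons)
    grid_d2 <- as.matrix(stats::dist(coords))^2
    for (t in seq_len(iterations)) {
      frac <- if (iterations > 1) (t - 1) / (iterations - 1) else 1
      alpha <- alpha_range[1] + frac * (alpha_range[2] - alpha_range[1])
      sigma <- sigma_range[1] + frac * (sigma_range[2] - sigma_range[1])
      x <- data[sample(nrow(data), 1), ]
      bmu <- which.min(rowSums(sweep(codebook, 2, x)^2))
      h <- exp(-grid_d2[bmu, ] / (2 * sigma^2))
      codebook <- codebook + alpha * h * sweep(codebook, 2, x, `-`) * -1
    }
    dimnames(codebook) <- list(paste0("n", seq_len(n_neurons)), colnames(data))
    structure(list(codebook = codebook, grid = grid, coords = coords,
                   iterations = iterations, seed = seed,
                   alpha_range = alpha_range, sigma_range = sigma_range),
              class = "som_model")
  })
}

#' @export
print.som_model <- function(x, ...) {
  cat("som_model:", x$grid[1], "x", x$grid[2], "grid,",
      ncol(x$codebook), "features,", x$iterations, "iterations\n")
  invisible(x)
}

# k-means++ selection of k distinct rows from a candidate matrix.
kmeanspp_centers <- function(candidates, k) {
  candidates <- unique(candidates)
  if (k > nrow(candidates)) {
    stop("k exceeds the number of distinct candidate centers")
  }
  idx <- integer(k)
  idx[1] <- sample(nrow(candidates), 1)
  if (k > 1) {
    d2 <- rowSums(sweep(candidates, 2, candidates[idx[1], ])^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / nrow(candidates),
                                                     nrow(candidates))
      idx[j] <- sample(nrow(candidates), 1, prob = prob)
      d2 <- pmin(d2, rowSums(sweep(candidates, 2, candidates[idx[j], ])^2))
    }
  }
  candidates[idx, , drop = FALSE]
}

#' k-means clustering seeded from a SOM codebook
#'
#' Selects k initial centers among the trained codebook vectors by
#' k-means++ and runs Lloyd k-means (via \code{stats::kmeans}) on the
#' original items, capped at 4000 iterations. The k-means++ draw and Lloyd
#' run are restarted \code{n_start} times and the solution with the lowest
#' within-cluster sum of squares is kept (single restarts of Lloyd are
#' well known to stick in local optima). Items are labeled by their final
#' nearest center.
#'
#' @param som a \code{som_model}.
#' @param data the original items x features matrix.
#' @param k number of clusters (default 3).
#' @param seed integer seed.
#' @param n_start number of k-means++ restarts (default 10).
#' @return object of class \code{cluster_assignment}: \code{cluster} (named
#'   integer vector), \code{k}, \code{inertia} (total within-cluster sum of
#'   squares), \code{centers}.
#' @export
som_kmeans <- function(som, data, k = 3, seed = 1L, n_start = 10) {
  data <- as.matrix(data)
  if (k > nrow(data)) stop("k exceeds the number of items")
  if (k == nrow(data)) {
    cl <- stats::setNames(seq_len(nrow(data)), rownames(data))
    return(structure(list(cluster = cl, k = k, inertia = 0, centers = data),
                     class = "cluster_assignment"))
  }
  with_seed(seed, {
    best <- NULL
    for (attempt in seq_len(n_start)) {
      centers <- kmeanspp_centers(som$codebook, k)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(data, centers = centers,
                                       iter.max = 4000,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(fit) || length(unique(fit$cluster)) != k) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) {
      # degenerate codebook: fall back to k-means++ over the items themselves
      best <- stats::kmeans(data, centers = kmeanspp_centers(data, k),
                            iter.max = 4000, algorithm = "Lloyd")
    }
    structure(list(cluster = stats::setNames(best$cluster, rownames(data)),
                   k = k, inertia = best$tot.withinss,
                   centers = best$centers),
              class = "cluster_assignment")
  })
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment: k =", x$k, ", inertia =",
      format(x$inertia, digits = 6), "\n")
  print(x$cluster)
  invisible(x)
}

#' Agglomerative hierarchical clustering with heatmap leaf order
#'
#' Standard agglomerative merge tree (\code{stats::hclust} over
#' \code{stats::dist}); the leaf order is emitted for heatmap rendering and
#' the tree can be exported as Newick.
#'
#' @param m items x features matrix (>= 2 items).
#' @param metric distance metric for \code{stats::dist}.
#' @param linkage linkage method for \code{stats::hclust}.
#' @return list with \code{hclust}, \code{leaf_order} (item names in
#'   dendrogram order) and \code{newick} (tree string).
#' @export
hierarchical_cluster <- function(m, metric = "euclidean",
                                 linkage = "average") {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need >= 2 items")
  if (is.null(rownames(m))) rownames(m) <- paste0("item", seq_len(nrow(m)))
  d <- stats::dist(m, method = metric)
  if (any(!is.finite(d))) stop("distance undefined on data")
  h <- stats::hclust(d, method = linkage)
  phy <- ape::as.phylo(h)
  list(hclust = h,
       leaf_order = h$labels[h$order],
       newick = ape::write.tree(phy))
}

#' Silhouette sweep over candidate k (optional utility)
#'
#' Mean silhouette width of \code{som_kmeans} assignments for each k.
#'
#' @param som a \code{som_model}.
#' @param data items x features matrix.
#' @param ks candidate cluster counts.
#' @param seed seed passed to \code{som_kmeans}.
#' @return data.frame k / mean_silhouette.
#' @export
silhouette_sweep <- function(som, data, ks = 2:5, seed = 1L) {
  d <- as.matrix(stats::dist(data))
  res <- vapply(ks, function(k) {
    cl <- som_kmeans(som, data, k = k, seed = seed)$cluster
    mean(vapply(seq_len(nrow(data)), function(i) {
      own <- cl[i]
      a <- mean(d[i, cl == own & seq_along(cl) != i])
      if (!is.finite(a)) a <- 0
      b <- min(vapply(setdiff(unique(cl), own), function(g)
        mean(d[i, cl == g]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1)))
  }, numeric(1))
  data.frame(k = ks, mean_silhouette = res)
}
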