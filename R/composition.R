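#' Hellinger transform of a catch matrix
#'
#' Each cell becomes the square root of the species' share of its year's
#' total biomass, so Euclidean distances between transformed year profiles
#' are Hellinger distances — low weight on rare species, no double-zero
#' problem. Zero rows stay zero, with a warning.
#'
#' @param matrix a [catch_matrix()] or non-negative numeric matrix.
#' @return numeric matrix of class `hellinger_matrix`, same dimnames; each
#'   nonzero row has unit sum of squares.
#' @examples
#' hellinger_transform(rbind(c(1, 4, 4)))
#' @export
hellinger_transform <- function(matrix) {
  m <- unclass(as.matrix(matrix))
  if (any(m < 0)) stop("negative input")
  totals <- rowSums(m)
  if (any(totals == 0)) warning("zero row(s) left as zeros")
  out <- sqrt(sweep(m, 1, ifelse(totals == 0, 1, totals), "/"))
  structure(out, class = c("hellinger_matrix", class(out)))
}

#' Pairwise dissimilarity between years
#'
#' Two metrics: `"hellinger"` (Euclidean distance between
#' Hellinger-transformed rows; pass the transformed matrix) and
#' `"percentage_difference"` (the abundance-based Bray-Curtis-type index
#' (B + C) / (2A + B + C), computed on raw biomass, where A is the summed
#' shared biomass and B and C the summed exclusive biomass of each year).
#'
#' @param matrix a matrix whose rows are years: Hellinger-transformed for
#'   `metric = "hellinger"`, raw biomass for `"percentage_difference"`.
#' @param metric dissimilarity to compute.
#' @return symmetric matrix of class `dist_matrix` with zero diagonal and
#'   attribute `metric`.
#' @export
distance_matrix <- function(matrix,
                            metric = c("hellinger", "percentage_difference")) {
  metric <- match.arg(metric)
  m <- unclass(as.matrix(matrix))
  if (metric == "hellinger") {
    if (!inherits(matrix, "hellinger_matrix")) {
      stop("hellinger metric expects a Hellinger-transformed matrix; ",
           "call hellinger_transform() first")
    }
    d <- as.matrix(stats::dist(m, method = "euclidean"))
  } else {
    if (inherits(matrix, "hellinger_matrix")) {
      stop("percentage difference operates on raw biomass, not a ",
           "Hellinger-transformed matrix")
    }
    if (any(m < 0)) stop("negative input")
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (u in seq_len(n - 1)) {
      for (v in (u + 1):n) {
        a <- sum(pmin(m[u, ], m[v, ]))
        b <- sum(pmax(m[u, ] - m[v, ], 0))
        cc <- sum(pmax(m[v, ] - m[u, ], 0))
        den <- 2 * a + b + cc
        d[u, v] <- d[v, u] <- if (den == 0) 0 else (b + cc) / den
      }
    }
  }
  structure(d, metric = metric, class = c("dist_matrix", "matrix"))
}

#' Principal Coordinates Analysis
#'
#' Classical metric ordination: Gower double-centering of -d^2/2 followed by
#' eigen-decomposition. Coordinates are eigenvectors scaled by the square
#' root of their (non-negative) eigenvalues, so inter-point Euclidean
#' distances in the full coordinate space reproduce the input distances
#' whenever the matrix is Euclidean-embeddable. Negative eigenvalues are
#' reported, never corrected; Hellinger distances produce none.
#'
#' @param dist a symmetric distance matrix (e.g. from [distance_matrix()]).
#' @param tol eigenvalues within `tol * max(|eigenvalue|)` of zero are
#'   treated as null and dropped from the coordinates.
#' @return list of class `pcoa_result`: `eigenvalues` (all, descending),
#'   `coordinates` (rows = objects, columns = axes with positive
#'   eigenvalues), `proportion` (variance share per retained axis, relative
#'   to the sum of positive eigenvalues), `negative_eigenvalues`.
#' @export
pcoa <- function(dist, tol = 1e-9) {
  d <- unclass(as.matrix(dist))
  if (!isSymmetric(d, tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(d)
  g <- -0.5 * d^2
  # sequential sweeps give a_ij - rowmean_i - colmean_j + grandmean
  g <- sweep(g, 1, rowMeans(g))
  g <- sweep(g, 2, colMeans(g))
  eg <- eigen((g + t(g)) / 2, symmetric = TRUE)
  ev <- eg$values
  scale0 <- max(abs(ev), 1e-300)
  pos <- ev > tol * scale0
  coords <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]),
                                                     nrow = sum(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(
    eigenvalues = ev,
    coordinates = coords,
    proportion = ev[pos] / sum(ev[pos]),
    negative_eigenvalues = ev[ev < -tol * scale0]
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- min(2, length(x$proportion))
  cat(sprintf("PCoA: %d positive axes; first %d explain %.1f%%\n",
              ncol(x$coordinates), k, 100 * sum(x$proportion[seq_len(k)])))
  invisible(x)
}
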