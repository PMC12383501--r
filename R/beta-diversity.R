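#' Total beta diversity and its year / species decomposition
#'
#' Centres each species column on its mean, squares the deviations, and
#' partitions the total sum of squares (SStotal) into relative contributions
#' of years (YCBD, the local contributions) and species (SCBD). Total beta
#' diversity is BDtotal = SStotal / (n - 1), the total community variance.
#' Equivalent, by the Gower identity, to (1/n) times the sum of squared
#' Euclidean inter-year distances — computing it on a Hellinger-transformed
#' matrix (the default workflow) makes it Hellinger-based.
#'
#' @param transformed matrix whose rows are years (typically from
#'   [hellinger_transform()]).
#' @return list of class `beta_div_result`: `ss_total`, `bd_total`, `scbd`
#'   (named per-species proportions summing to 1), `ycbd` (named per-year
#'   proportions summing to 1), `n`. For a constant matrix `bd_total` is 0
#'   and the contributions are `NA` (undefined).
#' @export
beta_decompose <- function(transformed) {
  m <- unclass(as.matrix(transformed))
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least 2 years and 2 species")
  dev2 <- sweep(m, 2, colMeans(m))^2
  ss_total <- sum(dev2)
  n <- nrow(m)
  if (ss_total == 0) {
    scbd <- stats::setNames(rep(NA_real_, ncol(m)), colnames(m))
    ycbd <- stats::setNames(rep(NA_real_, nrow(m)), rownames(m))
  } else {
    scbd <- stats::setNames(colSums(dev2) / ss_total, colnames(m))
    ycbd <- stats::setNames(rowSums(dev2) / ss_total, rownames(m))
  }
  structure(list(ss_total = ss_total, bd_total = ss_total / (n - 1),
                 scbd = scbd, ycbd = ycbd, n = n),
            class = "beta_div_result")
}

#' @export
print.beta_div_result <- function(x, ...) {
  cat(sprintf("beta_div_result: SStotal = %.5g, BDtotal = %.5g (n = %d)\n",
              x$ss_total, x$bd_total, x$n))
  invisible(x)
}

#' Permutation test of year contributions to beta diversity
#'
#' Each permutation independently shuffles the values within every species
#' column, breaking year structure while preserving species abundance
#' distributions, and recomputes YCBD. The p-value for year y is
#' (number of permuted YCBD_y >= observed + 1) / (n_perm + 1).
#'
#' @param transformed matrix whose rows are years.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed; results are reproducible given the seed.
#' @return list of class `ycbd_test`: `ycbd` (observed), `p_values` (named,
#'   in (0, 1]), `n_perm`, `seed`.
#' @export
ycbd_permutation_test <- function(transformed, n_perm = 999, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  m <- unclass(as.matrix(transformed))
  obs <- beta_decompose(m)
  n <- nrow(m); p <- ncol(m)
  if (anyNA(obs$ycbd)) {
    return(structure(list(ycbd = obs$ycbd,
                          p_values = obs$ycbd, n_perm = n_perm, seed = seed),
                     class = "ycbd_test"))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, "ycbd-perm"))
  count <- rep(0L, n)
  col_offset <- (seq_len(p) - 1L) * n
  for (b in seq_len(n_perm)) {
    idx <- vapply(seq_len(p), function(j) sample.int(n), integer(n))
    pm <- matrix(m[as.vector(idx) + rep(col_offset, each = n)], n)
    dev2 <- sweep(pm, 2, colMeans(pm))^2
    perm_ycbd <- rowSums(dev2) / sum(dev2)
    count <- count + (perm_ycbd >= obs$ycbd)
  }
  p_values <- stats::setNames((count + 1) / (n_perm + 1), rownames(m))
  structure(list(ycbd = obs$ycbd, p_values = p_values,
                 n_perm = n_perm, seed = seed),
            class = "ycbd_test")
}

#' Temporal beta-diversity indices between all year pairs
#'
#' For every pair of years u < v, the biomass shared between the two years
#' (A), lost from u to v (B) and gained (C) are combined into the
#' percentage-difference components: loss share B' = B / (2A + B + C), gain
#' share C' = C / (2A + B + C), dissimilarity D = B' + C', and the signed
#' index S = C' - B' in [-1, 1], positive when gains dominate. Operates on
#' raw biomass.
#'
#' @param matrix a [catch_matrix()] or non-negative matrix, rows = years.
#' @return list of class `tbi_result` with years-by-years matrices `A`,
#'   `B`, `C`, `denominator`, `loss_share`, `gain_share`, `D`, `S` (upper
#'   and lower triangles filled; `S` antisymmetric, read row u -> column v).
#' @examples
#' tbi_pairwise(rbind(`1` = c(1, 0), `2` = c(1, 2)))
#' @export
tbi_pairwise <- function(matrix) {
  m <- unclass(as.matrix(matrix))
  if (nrow(m) < 2) stop("need at least 2 years")
  if (any(m < 0)) stop("negative biomass")
  n <- nrow(m)
  nm <- list(rownames(m), rownames(m))
  A <- B <- C <- den <- bshare <- cshare <- D <- S <-
    matrix(0, n, n, dimnames = nm)
  for (u in seq_len(n - 1)) {
    for (v in (u + 1):n) {
      a <- sum(pmin(m[u, ], m[v, ]))
      b <- sum(pmax(m[u, ] - m[v, ], 0))
      cc <- sum(pmax(m[v, ] - m[u, ], 0))
      dd <- 2 * a + b + cc
      bs <- if (dd == 0) 0 else b / dd
      cs <- if (dd == 0) 0 else cc / dd
      A[u, v] <- A[v, u] <- a
      B[u, v] <- B[v, u] <- b
      C[u, v] <- C[v, u] <- cc
      den[u, v] <- den[v, u] <- dd
      bshare[u, v] <- bshare[v, u] <- bs
      cshare[u, v] <- cshare[v, u] <- cs
      D[u, v] <- D[v, u] <- bs + cs
      S[u, v] <- cs - bs
      S[v, u] <- bs - cs
    }
  }
  structure(list(A = A, B = B, C = C, denominator = den,
                 loss_share = bshare, gain_share = cshare, D = D, S = S),
            class = "tbi_result")
}

#' @export
print.tbi_result <- function(x, ...) {
  up <- upper.tri(x$D)
  cat(sprintf(
    "tbi_result: %d year pairs; mean D = %.4f; gains dominate in %d pairs, losses in %d\n",
    sum(up), mean(x$D[up]), sum(x$S[up] > 0), sum(x$S[up] < 0)
  ))
  invisible(x)
}

#' Long-format table of pairwise TBI components
#'
#' @param x a `tbi_result`.
#' @return data.frame with one row per year pair (u < v): `year_u`,
#'   `year_v`, `A`, `B`, `C`, `loss_share`, `gain_share`, `D`, `S`.
#' @export
tbi_long <- function(x) {
  up <- which(upper.tri(x$D), arr.ind = TRUE)
  up <- up[order(up[, 1], up[, 2]), , drop = FALSE]
  data.frame(
    year_u = rownames(x$D)[up[, 1]], year_v = colnames(x$D)[up[, 2]],
    A = x$A[up], B = x$B[up], C = x$C[up],
    loss_share = x$loss_share[up], gain_share = x$gain_share[up],
    D = x$D[up], S = x$S[up]
  )
}

#' Paired test of biomass gains versus losses
#'
#' Across a selection of year pairs (by default all pairs u < v; typically
#' the pairs spanning two composition groups), tests whether gain shares C'
#' systematically exceed loss shares B' with a paired two-sided t test, and
#' reports the dominant direction.
#'
#' @param result a `tbi_result` from [tbi_pairwise()].
#' @param pairs optional two-column matrix or data.frame of year labels
#'   (u, v) selecting the pairs; default all pairs u < v.
#' @return list of class `tbi_test`: `mean_difference` (mean C' - B'), `t`,
#'   `p_value`, `df`, `n_pairs`, `direction` (`"gains"`, `"losses"` or
#'   `"balanced"`), `exact_equality` (TRUE when differences have zero
#'   variance, in which case no t statistic is produced).
#' @export
tbi_gain_loss_test <- function(result, pairs = NULL) {
  if (is.null(pairs)) {
    up <- which(upper.tri(result$D), arr.ind = TRUE)
    gains <- result$gain_share[up]
    losses <- result$loss_share[up]
  } else {
    pairs <- as.matrix(pairs)
    if (nrow(pairs) < 2) stop("need at least 2 selected pairs")
    iu <- match(as.character(pairs[, 1]), rownames(result$D))
    iv <- match(as.character(pairs[, 2]), colnames(result$D))
    if (anyNA(iu) || anyNA(iv)) stop("pair labels not found among years")
    gains <- result$gain_share[cbind(iu, iv)]
    losses <- result$loss_share[cbind(iu, iv)]
  }
  diffs <- gains - losses
  md <- mean(diffs)
  direction <- if (md > 0) "gains" else if (md < 0) "losses" else "balanced"
  if (stats::sd(diffs) == 0) {
    return(structure(list(mean_difference = md, t = NA_real_,
                          p_value = NA_real_, df = NA_real_,
                          n_pairs = length(diffs), direction = direction,
                          exact_equality = TRUE),
                     class = "tbi_test"))
  }
  tt <- stats::t.test(gains, losses, paired = TRUE)
  structure(list(mean_difference = unname(tt$estimate), t = unname(tt$statistic),
                 p_value = tt$p.value, df = unname(tt$parameter),
                 n_pairs = length(diffs), direction = direction,
                 exact_equality = FALSE),
            class = "tbi_test")
}

#' @export
print.tbi_test <- function(x, ...) {
  cat(sprintf(
    "tbi_test over %d pairs: mean(C' - B') = %.4f, direction %s%s\n",
    x$n_pairs, x$mean_difference, x$direction,
    if (x$exact_equality) " (exact equality, no t statistic)"
    else sprintf(" (t = %.3f, p = %.4g)", x$t, x$p_value)
  ))
  invisible(x)
}
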