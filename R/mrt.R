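# Multivariate regression tree over time: recursive binary partitioning of
# a multivariate community response on the single ordered predictor "year".
# Because the predictor is ordered, every tree is a set of year thresholds
# cutting the series into contiguous blocks.

node_ss <- function(Y, rows) {
  if (length(rows) <= 1) return(0)
  sub <- Y[rows, , drop = FALSE]
  sum(sweep(sub, 2, colMeans(sub))^2)
}

# Best single split of a node (rows sorted by year). Ties in SS reduction
# break toward the earliest year.
best_split <- function(Y, years, rows) {
  if (length(rows) < 2) return(NULL)
  ord <- rows[order(years[rows])]
  sub <- Y[ord, , drop = FALSE]
  n <- nrow(sub)
  parent <- node_ss(Y, rows)
  csum <- apply(sub, 2, cumsum)
  tot <- csum[n, ]
  best <- NULL
  for (i in seq_len(n - 1)) {
    if (years[ord[i]] == years[ord[i + 1]]) next
    left <- csum[i, ]
    ss_left <- sum(sub[seq_len(i), , drop = FALSE]^2) - sum(left^2) / i
    right <- tot - left
    ss_right <- sum(sub[(i + 1):n, , drop = FALSE]^2) - sum(right^2) / (n - i)
    red <- parent - (ss_left + ss_right)
    if (is.null(best) || red > best$reduction + 1e-12) {
      best <- list(
        threshold = (years[ord[i]] + years[ord[i + 1]]) / 2,
        reduction = red,
        left = ord[seq_len(i)], right = ord[(i + 1):n]
      )
    }
  }
  best
}

# Best-first greedy growth: repeatedly split the leaf offering the largest
# SS reduction, producing a nested sequence of trees of sizes 1..max_size.
# Returns the ordered threshold sequence and per-size training SS.
grow_thresholds <- function(Y, years, rows, max_size, tol) {
  leaves <- list(list(rows = rows, cand = best_split(Y, years, rows)))
  thresholds <- numeric(0)
  train_ss <- node_ss(Y, rows)
  ss_seq <- train_ss
  while (length(leaves) < max_size) {
    reds <- vapply(leaves, function(l) {
      if (is.null(l$cand)) -Inf else l$cand$reduction
    }, numeric(1))
    starts <- vapply(leaves, function(l) min(years[l$rows]), numeric(1))
    reds[reds <= tol] <- -Inf
    if (all(is.infinite(reds))) break
    # earliest-year tie-break among (numerically) equal reductions
    top <- which(reds >= max(reds) - 1e-12)
    pick <- top[which.min(starts[top])]
    cand <- leaves[[pick]]$cand
    thresholds <- c(thresholds, cand$threshold)
    ss_seq <- c(ss_seq, ss_seq[length(ss_seq)] - cand$reduction)
    leaves <- c(leaves[-pick],
                list(list(rows = cand$left,
                          cand = best_split(Y, years, cand$left)),
                     list(rows = cand$right,
                          cand = best_split(Y, years, cand$right))))
  }
  list(thresholds = thresholds, ss = ss_seq)
}

predict_blocks <- function(Y, years, train_rows, thresholds, new_years) {
  grp_train <- findInterval(years[train_rows], sort(thresholds))
  grp_new <- findInterval(new_years, sort(thresholds))
  out <- matrix(NA_real_, length(new_years), ncol(Y))
  for (g in unique(grp_new)) {
    tr <- train_rows[grp_train == g]
    if (length(tr) == 0) {  # empty block: fall back to nearest block mean
      tr <- train_rows[which.min(abs(grp_train - g))]
      tr <- train_rows[grp_train == grp_train[match(tr, train_rows)]]
    }
    out[grp_new == g, ] <- rep(colMeans(Y[tr, , drop = FALSE]),
                               each = sum(grp_new == g))
  }
  out
}

#' Multivariate regression tree of community composition on year
#'
#' Chronological recursive partitioning: the Hellinger-transformed
#' year-by-species matrix is the multivariate response and calendar year the
#' single explanatory variable, so the tree cuts the series into contiguous
#' blocks of years with homogeneous composition. Splits maximally reduce
#' the total within-group sum of squared deviations; candidate cut points
#' are midpoints between consecutive years. Tree size is selected by V-fold
#' cross-validation (contiguous block folds by default, respecting serial
#' structure) under the minimum-CV-error rule, with a one-standard-error
#' option favouring parsimony.
#'
#' @param transformed matrix whose rows are years (typically from
#'   [hellinger_transform()]).
#' @param years numeric years, defaulting to the rownames.
#' @param max_size largest number of leaves considered; `NULL` (default)
#'   uses `min(10, n_years - 1)`. Explicitly requesting more leaves than
#'   years is an error.
#' @param cv_folds number of cross-validation folds (default 10).
#' @param cv_type `"block"` (contiguous, default) or `"random"` folds.
#' @param size_rule `"min"` (default) or `"1se"`.
#' @param seed integer seed for random folds (recorded either way).
#' @return list of class `mrt_result`: `splits` (selected year thresholds,
#'   ascending), `groups` (per-year group index, contiguous blocks),
#'   `cv_table` (size, training relative error, CV relative error, CV SE),
#'   `selected_size`, `size_rule`, `seed`.
#' @export
fit_mrt <- function(transformed, years = NULL, max_size = NULL,
                    cv_folds = 10, cv_type = c("block", "random"),
                    size_rule = c("min", "1se"), seed = 1L) {
  cv_type <- match.arg(cv_type)
  size_rule <- match.arg(size_rule)
  Y <- unclass(as.matrix(transformed))
  if (is.null(years)) years <- as.numeric(rownames(Y))
  if (anyNA(years)) stop("years must be supplied or present as rownames")
  n <- nrow(Y)
  if (n < 4) stop("need at least 4 years")
  if (is.null(max_size)) max_size <- min(10, n - 1)
  if (max_size > n) stop("cannot request more leaves than years")
  ord <- order(years)
  Y <- Y[ord, , drop = FALSE]; years <- years[ord]
  total_ss <- node_ss(Y, seq_len(n))
  tol <- 1e-12 * max(total_ss, 1)
  full <- grow_thresholds(Y, years, seq_len(n), max_size, tol)
  sizes <- seq_along(full$ss)

  cv_folds <- min(cv_folds, n)
  fold_id <- if (cv_type == "block") {
    sort(rep_len(seq_len(cv_folds), n))
  } else {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(substream_seed(seed, "mrt-cv"))
    sample(rep_len(seq_len(cv_folds), n))
  }
  fold_err <- matrix(NA_real_, cv_folds, length(sizes))
  for (f in seq_len(cv_folds)) {
    train <- which(fold_id != f); test <- which(fold_id == f)
    if (length(train) < 2 || length(test) == 0) next
    gf <- grow_thresholds(Y, years, train, max_size, tol)
    for (s in sizes) {
      th <- gf$thresholds[seq_len(min(s - 1, length(gf$thresholds)))]
      pred <- predict_blocks(Y, years, train, th, years[test])
      fold_err[f, s] <- sum((Y[test, , drop = FALSE] - pred)^2)
    }
  }
  cv_err <- colSums(fold_err, na.rm = TRUE) / max(total_ss, 1e-300)
  per_fold_rel <- fold_err / max(total_ss, 1e-300)
  cv_se <- apply(per_fold_rel, 2, function(e) {
    e <- e[!is.na(e)]
    stats::sd(e) * sqrt(length(e))
  })
  best <- which.min(cv_err)
  selected <- if (size_rule == "min") sizes[best] else {
    sizes[min(which(cv_err <= cv_err[best] + cv_se[best]))]
  }
  splits <- sort(full$thresholds[seq_len(selected - 1)])
  groups <- findInterval(years, splits) + 1L
  structure(list(
    splits = splits,
    groups = stats::setNames(groups, years),
    cv_table = data.frame(size = sizes,
                          rel_error = full$ss / max(total_ss, 1e-300),
                          cv_error = cv_err, cv_se = cv_se),
    selected_size = selected,
    size_rule = size_rule,
    seed = seed,
    total_ss = total_ss
  ), class = "mrt_result")
}

#' @export
print.mrt_result <- function(x, ...) {
  cat(sprintf("mrt_result: %d group(s)%s\n", x$selected_size,
              if (length(x$splits) == 0) "" else
                paste0("; splits at ", paste(x$splits, collapse = ", "))))
  invisible(x)
}
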