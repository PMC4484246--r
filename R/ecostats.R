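# Comparative ecology layer: diversity, ordination, cluster testing,
# environmental regression, fold contrasts and LC-MS feature filtering.

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over the positive proportions of a count (or
#' abundance) vector. Natural log by default; zero-count taxa never change
#' the value.
#'
#' @param counts Nonnegative abundance vector with at least one positive
#'   entry.
#' @param base Logarithm base; `exp(1)` (nats, default) or `2`.
#' @return Shannon index, a scalar `>= 0`.
#' @export
shannon_index <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("all counts are zero: H undefined", call. = FALSE)
  p <- counts / sum(counts)
  -sum(p * log(p, base = base))
}

#' Between-sample distance matrix
#'
#' `bray_curtis` on raw (or relative) abundances for community ordination;
#' `euclidean_hellinger` (Euclidean distance between Hellinger-transformed
#' rows) for catabolic family percentages. Both delegate the arithmetic to
#' vegan.
#'
#' @param table Numeric matrix, samples in rows, features (OTUs/families) in
#'   columns; nonnegative.
#' @param metric `"bray_curtis"` or `"euclidean_hellinger"`.
#' @return Full symmetric distance matrix with a zero diagonal.
#' @export
community_distance <- function(table, metric = c("bray_curtis", "euclidean_hellinger")) {
  metric <- match.arg(metric)
  if (nrow(table) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(table < 0)) stop("negative abundances", call. = FALSE)
  d <- switch(metric,
    bray_curtis = vegan::vegdist(table, method = "bray"),
    euclidean_hellinger = stats::dist(vegan::decostand(table, method = "hellinger"))
  )
  as.matrix(d)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers the squared distance matrix (`B = -0.5 * J * D^2 * J`),
#' eigendecomposes it, and returns sample coordinates on the axes with
#' positive eigenvalues, scaled by the square roots of the eigenvalues.
#' Negative eigenvalues (possible for semi-metric dissimilarities like
#' Bray-Curtis) are reported but excluded from the percent-explained
#' denominator.
#'
#' @param d Square symmetric distance matrix with zero diagonal.
#' @param eps Eigenvalues with `|lambda| < eps * max(lambda)` are treated as
#'   numerically zero.
#' @return A `deg_pcoa`: `points` (samples x axes, columns `MDS1`, `MDS2`,
#'   ...), `eigenvalues` (all, sorted decreasing), `percent_explained`
#'   (positive axes only, non-increasing).
#' @export
pcoa_ordination <- function(d, eps = 1e-9) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix must be square and symmetric", call. = FALSE)
  }
  if (max(abs(diag(d))) > 1e-12) stop("distance matrix must have a zero diagonal", call. = FALSE)
  n <- nrow(d)
  a <- -0.5 * d^2
  b <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen(b, symmetric = TRUE)
  lambda <- e$values
  tol <- eps * max(abs(lambda), 1)
  pos <- which(lambda > tol)
  pts <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lambda[pos]), length(pos))
  colnames(pts) <- paste0("MDS", seq_along(pos))
  rownames(pts) <- rownames(d)
  structure(list(
    points = pts,
    eigenvalues = lambda,
    percent_explained = 100 * lambda[pos] / sum(lambda[pos])
  ), class = "deg_pcoa")
}

#' @export
print.deg_pcoa <- function(x, ...) {
  cat(sprintf(
    "<deg_pcoa> %d samples, %d positive axes; MDS1 explains %.2f%%\n",
    nrow(x$points), ncol(x$points), x$percent_explained[1]
  ))
  invisible(x)
}

#' Best contiguous two-cluster split along an ordination axis
#'
#' Sorts samples by their coordinate on the chosen axis and evaluates every
#' contiguous bipartition with at least two samples per side by a Welch
#' t-test on the coordinates; the split with the smallest p-value wins, ties
#' broken toward the more balanced split. A degenerate axis (all
#' coordinates equal) reports p = 1.
#'
#' @param ord A `deg_pcoa` (or any matrix-bearing list with `points`).
#' @param axis Axis number (1 = MDS1) or name.
#' @return A `cluster_split`: `groups` (two character vectors of sample
#'   ids, ordered along the axis), `axis`, `statistic` (Welch t), `p_value`.
#' @export
split_on_axis <- function(ord, axis = 1) {
  coord <- ord$points[, axis]
  n <- length(coord)
  if (n < 4) stop("need at least 4 samples to split", call. = FALSE)
  ord_idx <- order(coord)
  x <- coord[ord_idx]
  ids <- names(coord)[ord_idx] %||% as.character(ord_idx)
  if (max(x) - min(x) < .Machine$double.eps^0.5) {
    half <- seq_len(n %/% 2)
    return(structure(list(
      groups = list(ids[half], ids[-half]),
      axis = axis, statistic = 0, p_value = 1
    ), class = "cluster_split"))
  }
  best <- NULL
  for (cut in 2:(n - 2)) {
    g1 <- x[seq_len(cut)]
    g2 <- x[(cut + 1):n]
    tt <- tryCatch(stats::t.test(g1, g2, var.equal = FALSE),
      error = function(e) list(statistic = c(t = 0), p.value = 1)
    )
    cand <- list(
      cut = cut, statistic = unname(tt$statistic), p_value = tt$p.value,
      balance = abs(cut - (n - cut))
    )
    if (is.null(best) ||
      cand$p_value < best$p_value ||
      (cand$p_value == best$p_value && cand$balance < best$balance)) {
      best <- cand
    }
  }
  structure(list(
    groups = list(ids[seq_len(best$cut)], ids[(best$cut + 1):n]),
    axis = axis, statistic = best$statistic, p_value = best$p_value
  ), class = "cluster_split")
}

#' @export
print.cluster_split <- function(x, ...) {
  cat(sprintf(
    "<cluster_split> axis %s: {%s} vs {%s}, Welch t = %.3f, P = %.4g\n",
    as.character(x$axis), paste(x$groups[[1]], collapse = ","),
    paste(x$groups[[2]], collapse = ","), x$statistic, x$p_value
  ))
  invisible(x)
}

#' Ordinary least-squares regression of a response on one covariate
#'
#' @param y Per-sample response (e.g. DEGgp percent, Shannon index).
#' @param x Per-sample covariate (e.g. temperature, deg C).
#' @return A `regression_fit`: `slope`, `intercept`, `r_squared`, `p_value`
#'   (two-sided slope test), `n`, `slope_se`.
#' @export
regress_on <- function(y, x) {
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]
  x <- x[ok]
  if (length(y) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0) stop("covariate is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    slope_se = sm$coefficients[2, 2],
    n = length(y)
  ), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "<regression_fit> slope = %.4g (SE %.3g), r^2 = %.3f, P = %.3g, n = %d\n",
    x$slope, x$slope_se, x$r_squared, x$p_value, x$n
  ))
  invisible(x)
}

#' Fold change between two groups with a Welch t-test
#'
#' `fold = mean(a) / mean(b)`; the p-value is a two-sided Welch
#' (unequal-variance) two-sample t-test. Single observations per group give
#' the fold with `p_value = NA`; a zero denominator mean sets the
#' `infinite` flag instead of raising.
#'
#' @param a,b Numeric value vectors (e.g. family percentages across
#'   samples).
#' @return A `fold_test`: `fold`, `p_value`, `n` (group sizes), `infinite`.
#' @export
fold_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be nonempty", call. = FALSE)
  mb <- mean(b)
  infinite <- mb == 0
  fold <- if (infinite) Inf else mean(a) / mb
  p <- NA_real_
  if (length(a) >= 2 && length(b) >= 2) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      p <- if (mean(a) == mean(b)) 1 else 0
    } else {
      p <- stats::t.test(a, b, var.equal = FALSE)$p.value
    }
  }
  structure(list(
    fold = fold, p_value = p, n = c(length(a), length(b)),
    infinite = infinite
  ), class = "fold_test")
}

#' @export
print.fold_test <- function(x, ...) {
  cat(sprintf(
    "<fold_test> fold = %.3g (n = %d vs %d), Welch P = %.3g\n",
    x$fold, x$n[1], x$n[2], x$p_value
  ))
  invisible(x)
}

#' Filter LC-MS features by full within-group presence and a Welch t-test
#'
#' Two-step rule: (1) keep only features detected (nonzero) in 100% of the
#' replicates of at least one group; (2) among those, keep features with a
#' two-sided Welch t-test p-value strictly below `alpha` between the two
#' groups. No multiplicity correction by default, matching the raw
#' `P < 0.05` screen; Benjamini-Hochberg is available via `adjust = "BH"`.
#'
#' @param mat Feature x replicate abundance matrix (0 = not detected); row
#'   names identify features.
#' @param groups Factor/character of length `ncol(mat)` with exactly two
#'   levels, each with `>= 2` replicates.
#' @param alpha Significance cutoff (strict `<`). Default 0.05.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame of retained features: `feature`, `p_value`,
#'   `mean_a`, `mean_b`.
#' @export
filter_mass_features <- function(mat, groups, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(groups) < 2)) stop("each group needs at least 2 replicates", call. = FALSE)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("f", seq_len(nrow(mat)))
  ga <- groups == levels(groups)[1]
  gb <- !ga
  present <- apply(mat, 1, function(v) all(v[ga] > 0) || all(v[gb] > 0))
  cand <- mat[present, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(data.frame(
      feature = character(), p_value = numeric(),
      mean_a = numeric(), mean_b = numeric()
    ))
  }
  p <- apply(cand, 1, function(v) {
    if (stats::sd(v[ga]) == 0 && stats::sd(v[gb]) == 0) {
      return(if (mean(v[ga]) == mean(v[gb])) 1 else 0)
    }
    stats::t.test(v[ga], v[gb], var.equal = FALSE)$p.value
  })
  p_adj <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  keep <- p_adj < alpha
  data.frame(
    feature = rownames(cand)[keep],
    p_value = unname(p[keep]),
    mean_a = unname(rowMeans(cand[keep, ga, drop = FALSE])),
    mean_b = unname(rowMeans(cand[keep, gb, drop = FALSE])),
    row.names = NULL
  )
}

#' Summarize metabolomics confirmation of predicted degradation
#'
#' @param predicted Chemical codes predicted degradable (nonempty).
#' @param confirmed Chemical codes with metabolomic confirmation.
#' @return List `n_confirmed`, `n_predicted`, `percent` (integer-rounded
#'   percentage of predicted chemicals that were confirmed).
#' @export
validation_summary <- function(predicted, confirmed) {
  predicted <- unique(predicted)
  confirmed <- unique(confirmed)
  if (length(predicted) == 0) stop("empty predicted set: percent undefined", call. = FALSE)
  n_conf <- length(intersect(predicted, confirmed))
  list(
    n_confirmed = n_conf,
    n_predicted = length(predicted),
    percent = round(100 * n_conf / length(predicted))
  )
}

#' Adjusted Rand index between two labelings
#'
#' Used to score recovery of planted cluster structure; 1.0 means identical
#' partitions up to label permutation.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) {
    return(1)
  }
  (sum_ij - expected) / (max_idx - expected)
}
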