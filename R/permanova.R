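#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: partitions the sum of
#' squared inter-point distances into between- and within-group components
#' and assesses the pseudo-F statistic by randomly permuting group labels.
#' For `a` groups and `N` observations,
#' `SS_total = sum(d_ij^2) / N` over `i < j`,
#' `SS_within = sum_g sum(d_ij^2 within g) / n_g`, and
#' `F = (SS_between / (a - 1)) / (SS_within / (N - a))`.
#' The p-value uses the add-one estimator `(1 + #{F_perm >= F_obs}) /
#' (1 + n_perm)`, counting ties as exceedances.
#'
#' @param d distance matrix (`dist` or symmetric matrix, zero diagonal).
#' @param groups factor (or coercible) of group labels, >= 2 groups with
#'   >= 2 members each.
#' @param n_perm number of label permutations (default 9999).
#' @param seed integer seed driving the permutations (recorded in the
#'   result); `NULL` uses the current RNG state.
#' @return object of class `permanova_result` with fields `SS_between`,
#'   `SS_within`, `SS_total`, `df_between`, `df_within`, `F`, `R2`,
#'   `p_value`, `n_perm`, `seed`.
#' @export
permanova_oneway <- function(d, groups, n_perm = 9999, seed = NULL) {
  D2 <- check_distance_matrix(d)^2
  groups <- droplevels(as.factor(groups))
  n <- nrow(D2)
  stopifnot(length(groups) == n)
  if (nlevels(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 members", call. = FALSE)
  a <- nlevels(groups)
  ss_total <- sum(D2) / (2 * n)
  ss_within_of <- function(g) {
    s <- 0
    for (lv in levels(groups)) {
      idx <- which(g == lv)
      s <- s + sum(D2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  ss_w <- ss_within_of(groups)
  ss_b <- ss_total - ss_w
  f_obs <- (ss_b / (a - 1)) / (ss_w / (n - a))

  if (!is.null(seed)) set.seed(seed)
  f_perm <- permanova_perm_f(D2, groups, n_perm)
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
  structure(list(SS_between = ss_b, SS_within = ss_w, SS_total = ss_total,
                 df_between = a - 1L, df_within = n - a,
                 F = f_obs, R2 = ss_b / ss_total, p_value = p,
                 n_perm = as.integer(n_perm), seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("One-way PERMANOVA\n")
  cat(sprintf("  SS between %.4f (df %d), SS within %.4f (df %d)\n",
              x$SS_between, x$df_between, x$SS_within, x$df_within))
  cat(sprintf("  pseudo-F = %.4f, R2 = %.4f, p = %.4g (%d permutations)\n",
              x$F, x$R2, x$p_value, x$n_perm))
  invisible(x)
}

# Vectorised permutation distribution of the pseudo-F.
# For indicator u of one group, u' D2 u = colSums(U * (D2 %*% U)); the
# all-ones quadratic form gives the complement without a second multiply.
permanova_perm_f <- function(D2, groups, n_perm) {
  n <- nrow(D2)
  a <- nlevels(groups)
  ss_total <- sum(D2) / (2 * n)
  perm_labels <- vapply(seq_len(n_perm),
                        function(i) as.integer(groups)[sample.int(n)],
                        integer(n))
  ss_w <- numeric(n_perm)
  for (lv in seq_len(a)) {
    U <- perm_labels == lv
    storage.mode(U) <- "double"
    q <- colSums(U * (D2 %*% U))
    ss_w <- ss_w + q / (2 * sum(as.integer(groups) == lv))
  }
  ss_b <- ss_total - ss_w
  (ss_b / (a - 1)) / (ss_w / (n - a))
}

check_distance_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8 ||
      max(abs(diag(d))) > 1e-8)
    stop("d must be a symmetric distance matrix with zero diagonal",
         call. = FALSE)
  d
}

#' Pairwise post-hoc PERMANOVA between all group pairs
#'
#' Runs [permanova_oneway()] on every pair of groups (Euclidean distances of
#' the supplied ilr coordinates) and adjusts the p-values for multiplicity.
#'
#' @param ilr_data n x k matrix of real coordinates (e.g. ilr images).
#' @param groups group labels.
#' @param n_perm permutations per pair.
#' @param seed integer seed; pair `i` uses `seed + i` so pairs are
#'   independent but reproducible.
#' @param adjust p-adjustment method (see [stats::p.adjust()]); default
#'   Benjamini-Hochberg FDR.
#' @return list of class `pairwise_permanova` with matrices `p_raw` and
#'   `p_adjusted` (lower triangle filled), `F` values, and `method`.
#' @export
pairwise_permanova <- function(ilr_data, groups, n_perm = 999, seed = NULL,
                               adjust = "BH") {
  x <- as.matrix(ilr_data)
  groups <- droplevels(as.factor(groups))
  lv <- levels(groups)
  if (length(lv) < 2L) stop("need at least 2 groups", call. = FALSE)
  pairs <- utils::combn(lv, 2L)
  p_raw <- f_mat <- matrix(NA_real_, length(lv), length(lv),
                           dimnames = list(lv, lv))
  p_vec <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
    keep <- groups %in% c(g1, g2)
    res <- permanova_oneway(stats::dist(x[keep, , drop = FALSE]),
                            groups[keep], n_perm = n_perm,
                            seed = if (is.null(seed)) NULL else seed + i)
    p_vec[i] <- res$p_value
    p_raw[g2, g1] <- res$p_value
    f_mat[g2, g1] <- res$F
  }
  p_adj_vec <- stats::p.adjust(p_vec, method = adjust)
  p_adj <- p_raw
  for (i in seq_len(ncol(pairs)))
    p_adj[pairs[2L, i], pairs[1L, i]] <- p_adj_vec[i]
  structure(list(p_raw = p_raw, p_adjusted = p_adj, F = f_mat,
                 method = adjust, n_perm = as.integer(n_perm), seed = seed),
            class = "pairwise_permanova")
}

#' Permutation test of homogeneity of multivariate dispersions
#'
#' Embeds the distance matrix by principal-coordinates analysis, measures
#' each point's distance to its own group centroid in that space (with the
#' standard real/imaginary correction for negative eigenvalues), computes
#' the one-way ANOVA F on those distances, and obtains the p-value by
#' permuting the distances across groups.
#'
#' @inheritParams permanova_oneway
#' @param n_perm number of permutations (default 999).
#' @return object of class `dispersion_result` with `group_means` (mean
#'   distance-to-centroid per group), `SS_between`, `SS_within`, `F`,
#'   `p_value`, `n_perm`, `seed`, `distances`.
#' @export
dispersion_test <- function(d, groups, n_perm = 999, seed = NULL) {
  D <- check_distance_matrix(d)
  groups <- droplevels(as.factor(groups))
  n <- nrow(D)
  stopifnot(length(groups) == n)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 members", call. = FALSE)

  # PCoA: double-centred Gower matrix
  G <- -0.5 * D^2
  G <- sweep(G, 1L, rowMeans(G))
  G <- sweep(G, 2L, colMeans(G))
  G <- G + mean(-0.5 * D^2)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  pos <- e$values > tol
  neg <- e$values < -tol
  A_pos <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                                   sum(pos))
  A_neg <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]),
                                                   sum(neg))
  z <- numeric(n)
  for (lv in levels(groups)) {
    idx <- which(groups == lv)
    cp <- colMeans(A_pos[idx, , drop = FALSE])
    d2 <- colSums((t(A_pos[idx, , drop = FALSE]) - cp)^2)
    if (ncol(A_neg) > 0L) {
      cn <- colMeans(A_neg[idx, , drop = FALSE])
      d2 <- d2 - colSums((t(A_neg[idx, , drop = FALSE]) - cn)^2)
    }
    z[idx] <- sqrt(pmax(0, d2))
  }
  f_of <- function(zz, g) {
    gm <- tapply(zz, g, mean)
    ng <- tabulate(g)
    ssb <- sum(ng * (gm - mean(zz))^2)
    ssw <- sum((zz - gm[as.integer(g)])^2)
    (ssb / (nlevels(groups) - 1)) / (ssw / (n - nlevels(groups)))
  }
  gi <- as.integer(groups)
  f_obs <- f_of(z, gi)
  if (!is.null(seed)) set.seed(seed)
  f_perm <- vapply(seq_len(n_perm),
                   function(i) f_of(z[sample.int(n)], gi), numeric(1))
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
  gm <- tapply(z, groups, mean)
  gmeans <- stats::setNames(as.numeric(gm), levels(groups))
  ng <- tabulate(gi)
  ssb <- sum(ng * (as.numeric(gm) - mean(z))^2)
  ssw <- sum((z - as.numeric(gm)[gi])^2)
  structure(list(group_means = gmeans, SS_between = ssb, SS_within = ssw,
                 F = f_obs, p_value = p, n_perm = as.integer(n_perm),
                 seed = seed, distances = z),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("Homogeneity of multivariate dispersions (permutation test)\n")
  cat("  mean distance to centroid:",
      paste(sprintf("%s %.4f", names(x$group_means), x$group_means),
            collapse = ", "), "\n")
  cat(sprintf("  F = %.4f, p = %.4g (%d permutations)\n",
              x$F, x$p_value, x$n_perm))
  invisible(x)
}
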