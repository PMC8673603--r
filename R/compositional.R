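#' Isometric log-ratio (ilr) transform of 3-part compositions
#'
#' Maps (BPI, LPI, PII) compositions from the simplex to R^2 using the
#' orthonormal balance basis of the sequential binary partition
#' {BPI} | {LPI, PII}, then {LPI} | {PII}: the first coordinate contrasts
#' buccal phase I against the geometric mean of the other two parts, the
#' second contrasts lingual phase I against phase II. The map is an isometry
#' between Aitchison geometry on the simplex and Euclidean geometry, so all
#' distance-based tests downstream are independent of the basis choice.
#'
#' @param comps numeric vector (one composition) or matrix (rows =
#'   compositions) of strictly positive parts; each row is closed to sum 1.
#' @param basis 3 x 2 orthonormal clr basis matrix; default
#'   [ilr_basis_default()].
#' @return n x 2 matrix of ilr coordinates with the basis attached as
#'   attribute `basis`.
#' @export
ilr_transform <- function(comps, basis = ilr_basis_default()) {
  x <- as_composition_matrix(comps)
  if (any(x <= 0))
    stop("compositions must be strictly positive; apply replace_zeros() ",
         "(multiplicative replacement) to boundary compositions first",
         call. = FALSE)
  x <- x / rowSums(x)
  lx <- log(x)
  clr <- lx - rowMeans(lx)
  y <- clr %*% basis
  dimnames(y) <- list(rownames(x), c("ilr1", "ilr2"))
  attr(y, "basis") <- basis
  y
}

#' @rdname ilr_transform
#' @param coords n x 2 matrix of ilr coordinates.
#' @return `ilr_inverse`: matrix of compositions (rows sum to 1).
#' @export
ilr_inverse <- function(coords, basis = ilr_basis_default()) {
  y <- if (is.null(dim(coords))) matrix(coords, ncol = 2L) else as.matrix(coords)
  clr <- y %*% t(basis)
  x <- exp(clr)
  x <- x / rowSums(x)
  colnames(x) <- c("bpi", "lpi", "pii")
  x
}

#' @rdname ilr_transform
#' @export
ilr_basis_default <- function() {
  cbind(c(sqrt(2 / 3), -sqrt(1 / 6), -sqrt(1 / 6)),
        c(0, sqrt(1 / 2), -sqrt(1 / 2)))
}

as_composition_matrix <- function(comps) {
  x <- if (is.null(dim(comps))) matrix(as.numeric(comps), nrow = 1L)
       else as.matrix(comps)
  if (ncol(x) != 3L) stop("expected 3-part compositions", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Multiplicative zero replacement for boundary compositions
#'
#' Replaces zero parts by `frac` (default 0.1%) of the smallest observed
#' nonzero share across the dataset, rescaling the nonzero parts of affected
#' rows so each row still sums to 1. Replacements are reported via
#' `message()`.
#'
#' @param comps matrix or vector of compositions (rows sum to 1).
#' @param frac replacement value as a fraction of the smallest nonzero share.
#' @return matrix of strictly positive closed compositions.
#' @export
replace_zeros <- function(comps, frac = 0.001) {
  x <- as_composition_matrix(comps)
  x <- x / rowSums(x)
  if (!any(x == 0)) return(x)
  delta <- frac * min(x[x > 0])
  n_rows <- sum(apply(x == 0, 1L, any))
  for (i in seq_len(nrow(x))) {
    z <- x[i, ] == 0
    if (any(z)) {
      x[i, z] <- delta
      x[i, !z] <- x[i, !z] * (1 - sum(z) * delta)
    }
  }
  message(sprintf("replaced zeros in %d composition(s) with delta = %.3g",
                  n_rows, delta))
  x
}

#' Compositional center of a set of compositions
#'
#' `"geometric"` (the compositional centre): component-wise geometric means
#' re-closed to sum 1, i.e. the inverse-ilr of the mean ilr coordinate.
#' `"arithmetic"`: the plain mean of the proportions. Both appear in wear
#' studies ("centre" vs "mean" compositions); they differ for dispersed data.
#'
#' @param comps matrix of compositions (rows).
#' @param mode `"geometric"` or `"arithmetic"`.
#' @return a single closed composition (length-3 vector).
#' @export
compositional_center <- function(comps, mode = c("geometric", "arithmetic")) {
  mode <- match.arg(mode)
  x <- as_composition_matrix(comps)
  x <- x / rowSums(x)
  if (mode == "arithmetic") return(colMeans(x) / sum(colMeans(x)))
  if (any(x <= 0)) x <- replace_zeros(x)
  g <- exp(colMeans(log(x)))
  g / sum(g)
}

#' Aitchison distance between compositions
#'
#' Euclidean distance between clr (equivalently ilr) images; used as the
#' oracle for the ilr isometry property.
#'
#' @param a,b strictly positive compositions (length-3 vectors).
#' @return distance (numeric scalar).
#' @export
aitchison_distance <- function(a, b) {
  ca <- log(a) - mean(log(a))
  cb <- log(b) - mean(log(b))
  sqrt(sum((ca - cb)^2))
}

#' Ternary-plot coordinates of compositions
#'
#' Barycentric-to-Cartesian map into the unit equilateral triangle with
#' vertices (0,0), (1,0) and (1/2, sqrt(3)/2) for parts 1 (BPI), 2 (LPI) and
#' 3 (PII) respectively.
#'
#' @param comps composition vector or matrix (rows).
#' @return n x 2 matrix of (x, y) plot coordinates.
#' @export
ternary_coordinates <- function(comps) {
  x <- as_composition_matrix(comps)
  x <- x / rowSums(x)
  verts <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  out <- x %*% verts
  colnames(out) <- c("x", "y")
  out
}
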