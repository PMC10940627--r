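# Principal coordinates analysis ---------------------------------------------

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling of a `morph_dist` (or plain symmetric matrix):
#' the squared distances are double-centred and eigendecomposed, and
#' coordinates are eigenvectors scaled by the square roots of their
#' eigenvalues. MORD matrices are generally non-Euclidean, so the default
#' applies the Cailliez correction: the smallest constant is added to all
#' off-diagonal distances that makes the centred matrix positive
#' semi-definite. Axes are retained while their eigenvalue exceeds
#' `1e-8 *` the largest eigenvalue; the threshold is recorded in the result.
#'
#' The numerical engine is `stats::cmdscale()` (with `add = TRUE` for
#' Cailliez).
#'
#' @param dm A `morph_dist` from [distance_matrix()], or a symmetric numeric
#'   matrix with zero diagonal.
#' @param correction `"cailliez"` (default) or `"none"`.
#' @return Object of class `ordination`: `labels`, `coords` (points x axes,
#'   columns `PC1..PCn`), `eigenvalues` (descending, retained axes only),
#'   `variance_fraction` (share of the positive-eigenvalue sum),
#'   `correction`, `cailliez_constant`, `all_eigenvalues`.
#' @export
pcoa <- function(dm, correction = c("cailliez", "none")) {
  correction <- match.arg(correction)
  d <- if (inherits(dm, "morph_dist")) dm$d else as.matrix(dm)
  if (nrow(d) < 2L) stop("need at least 2 points")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix is not symmetric")
  if (anyNA(d)) stop("distance matrix has undefined entries")
  n <- nrow(d)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = n - 1L, eig = TRUE,
                    add = (correction == "cailliez"))
  )
  eig <- fit$eig
  emax <- max(eig)
  if (emax <= 0) {
    coords <- matrix(0, n, 0, dimnames = list(rownames(d), NULL))
    return(structure(list(labels = rownames(d), coords = coords,
                          eigenvalues = numeric(0), variance_fraction = numeric(0),
                          correction = correction,
                          cailliez_constant = if (correction == "cailliez") fit$ac else NA_real_,
                          all_eigenvalues = eig, threshold = 1e-8),
                     class = "ordination"))
  }
  keep <- which(eig > 1e-8 * emax)
  keep <- keep[keep <= ncol(fit$points)]
  coords <- fit$points[, keep, drop = FALSE]
  colnames(coords) <- paste0("PC", seq_along(keep))
  rownames(coords) <- rownames(d)
  structure(list(
    labels = rownames(d),
    coords = coords,
    eigenvalues = eig[keep],
    variance_fraction = eig[keep] / sum(eig[eig > 0]),
    correction = correction,
    cailliez_constant = if (correction == "cailliez") fit$ac else NA_real_,
    all_eigenvalues = eig,
    threshold = 1e-8
  ), class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("ordination:", nrow(x$coords), "points,", ncol(x$coords),
      "retained axes, correction =", x$correction, "\n")
  invisible(x)
}

#' Cumulative variance fraction of the leading axes
#'
#' @param ord An [pcoa()] result.
#' @param k Number of leading axes (1..number of retained axes).
#' @return Sum of the first `k` eigenvalues over the sum of all positive
#'   eigenvalues, in `[0, 1]`.
#' @export
scree <- function(ord, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > length(ord$eigenvalues))
    stop("'k' must be in 1..", length(ord$eigenvalues))
  sum(ord$eigenvalues[seq_len(k)]) / sum(ord$all_eigenvalues[ord$all_eigenvalues > 0])
}

#' Export ordination coordinates and eigenvalues as CSV
#' @param ord An `ordination`.
#' @param coords_path,eigen_path Output paths (either may be `NULL`).
#' @export
write_ordination_csv <- function(ord, coords_path = NULL, eigen_path = NULL) {
  if (!is.null(coords_path))
    utils::write.csv(ord$coords, coords_path, row.names = TRUE)
  if (!is.null(eigen_path))
    utils::write.csv(
      data.frame(axis = seq_along(ord$eigenvalues),
                 eigenvalue = ord$eigenvalues,
                 variance_fraction = ord$variance_fraction),
      eigen_path, row.names = FALSE)
  invisible(NULL)
}
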