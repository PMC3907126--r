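#' Exploratory factor analysis by principal-axis factoring
#'
#' Extracts factors from the item correlation matrix with iterated
#' communalities: the diagonal is replaced by communality estimates
#' (initialised from squared multiple correlations), the reduced matrix is
#' eigendecomposed, loadings are formed from the leading eigenpairs, and the
#' implied communalities are fed back until they change by less than `tol`
#' (or `max_iter` passes). Factors are ordered by eigenvalue;
#' `variance_explained` is eigenvalue / number of items. A varimax rotation
#' of the loadings is returned alongside the unrotated solution.
#'
#' The automatic factor count is the number of eigenvalues of the initial
#' reduced correlation matrix at or above their mean — a parametrisation of
#' the scree-plot judgment, overridable via `n_factors`.
#'
#' @param item_matrix Subjects x items numeric matrix (items as columns).
#' @param n_factors Number of factors, or "auto".
#' @param rotate "varimax" (default) or "none".
#' @param max_iter Maximum communality iterations (default 100).
#' @param tol Convergence tolerance on communalities (default 1e-6).
#' @return A list of class `factor_solution`: `eigenvalues` (descending, of
#'   the final reduced matrix), `loadings` (items x factors, unrotated),
#'   `rotated` (varimax loadings, or NULL), `variance_explained`,
#'   `n_factors`, `communalities`, `converged`, `degenerate`.
#' @export
principal_factor_analysis <- function(item_matrix, n_factors = "auto",
                                      rotate = c("varimax", "none"),
                                      max_iter = 100L, tol = 1e-6) {
  rotate <- match.arg(rotate)
  m <- as.matrix(item_matrix)
  storage.mode(m) <- "numeric"
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 3L) stop("need at least 3 items", call. = FALSE)
  if (nrow(m) <= k) stop("need more subjects than items", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance item(s): ",
         paste(colnames(m)[sds == 0] %||% which(sds == 0), collapse = ", "),
         call. = FALSE)
  }
  R <- stats::cor(m)
  degenerate <- FALSE
  # initial communalities: squared multiple correlations
  h2 <- tryCatch({
    Rinv <- solve(R)
    1 - 1 / diag(Rinv)
  }, error = function(e) NULL)
  if (is.null(h2)) {
    degenerate <- TRUE
    h2 <- apply(R - diag(k), 2, function(col) max(abs(col)))
  }
  h2 <- pmin(pmax(h2, 0), 1)

  reduced <- R; diag(reduced) <- h2
  eig0 <- sort(eigen(reduced, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
  if (identical(n_factors, "auto")) {
    n_factors <- max(1L, sum(eig0 >= mean(eig0)))
  }
  n_factors <- as.integer(n_factors)
  if (n_factors < 1L || n_factors >= k) {
    stop("n_factors must be in [1, n_items - 1]", call. = FALSE)
  }

  converged <- FALSE
  loadings <- NULL
  eigvals <- eig0
  for (iter in seq_len(max_iter)) {
    reduced <- R; diag(reduced) <- h2
    ed <- eigen(reduced, symmetric = TRUE)
    eigvals <- ed$values
    lam <- pmax(eigvals[seq_len(n_factors)], 0)
    loadings <- ed$vectors[, seq_len(n_factors), drop = FALSE] %*%
      diag(sqrt(lam), n_factors)
    h2_new <- pmin(rowSums(loadings^2), 1)
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      converged <- TRUE
      break
    }
    h2 <- h2_new
  }
  rownames(loadings) <- colnames(m) %||% paste0("item_", seq_len(k))
  colnames(loadings) <- paste0("F", seq_len(n_factors))
  # sign convention: each factor's largest loading is positive
  for (j in seq_len(n_factors)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
    }
  }
  rotated <- NULL
  if (rotate == "varimax" && n_factors > 1L) {
    rotated <- unclass(stats::varimax(loadings, normalize = TRUE)$loadings)
    class(rotated) <- "matrix"
    for (j in seq_len(n_factors)) {
      if (rotated[which.max(abs(rotated[, j])), j] < 0) {
        rotated[, j] <- -rotated[, j]
      }
    }
  } else if (rotate == "varimax") {
    rotated <- loadings
  }
  structure(
    list(eigenvalues = eigvals,
         loadings = loadings,
         rotated = rotated,
         variance_explained = pmax(eigvals[seq_len(n_factors)], 0) / k,
         n_factors = n_factors,
         communalities = stats::setNames(h2, rownames(loadings)),
         converged = converged,
         degenerate = degenerate),
    class = "factor_solution"
  )
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("principal-axis solution: %d factor(s), variance explained %s\n",
              x$n_factors,
              paste(sprintf("%.1f%%", 100 * x$variance_explained),
                    collapse = ", ")))
  invisible(x)
}

# Tucker's congruence coefficient between two loading vectors.
tucker_congruence <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Best-match absolute congruence of each reference factor against the
# columns of a recovered loading matrix (greedy over permutations).
match_congruence <- function(recovered, reference) {
  stopifnot(ncol(recovered) >= ncol(reference))
  used <- logical(ncol(recovered))
  out <- numeric(ncol(reference))
  for (j in seq_len(ncol(reference))) {
    phi <- vapply(seq_len(ncol(recovered)), function(c) {
      if (used[c]) return(-Inf)
      abs(tucker_congruence(recovered[, c], reference[, j]))
    }, numeric(1))
    best <- which.max(phi)
    used[best] <- TRUE
    out[j] <- phi[best]
  }
  out
}
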