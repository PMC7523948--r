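# Non-metric multidimensional scaling by iterated monotone regression.

#' Non-metric multidimensional scaling (nMDS)
#'
#' Finds a k-dimensional configuration whose inter-point distances preserve
#' the rank order of the input dissimilarities, minimising Kruskal stress-1
#' `sqrt(sum (d - dhat)^2 / sum d^2)` where `dhat` is the monotone (isotonic)
#' regression of configuration distances on the dissimilarity order. Each
#' iteration alternates an isotonic fit (primary tie treatment: ties may
#' untie) with a Guttman majorisation step, which can not increase stress.
#' The best of `restarts` starts is returned (the first start is the metric
#' principal-coordinate solution, the rest random); the final configuration is
#' centred and rotated to its principal axes for determinism. As a rule of
#' thumb, 2-D solutions with stress above 0.2 should not be trusted.
#'
#' @param d `resemblance`, `dist`, or dissimilarity matrix
#' @param k embedding dimension (k < n)
#' @param restarts number of starting configurations
#' @param max_iter iterations per start
#' @param tol convergence tolerance on the stress decrease
#' @param seed RNG seed for the random restarts
#' @return object of class `nmds_fw`: `points` (n x k), `stress`, `converged`,
#'   `restarts`
#' @export
nmds <- function(d, k = 2, restarts = 20, max_iter = 300, tol = 1e-7,
                 seed = NULL) {
  D <- as_dissimilarity(d)
  n <- nrow(D)
  if (k >= n) stop("k must be smaller than the number of points", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lt <- lower.tri(D)
  dv <- D[lt]

  run <- function(X) {
    stress <- Inf
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      dd <- as.matrix(stats::dist(X))
      dvec <- dd[lt]
      ord <- order(dv, dvec) # within tied dissimilarities, follow current d
      fit <- stats::isoreg(seq_along(ord), dvec[ord])
      dhat <- numeric(length(dvec))
      dhat[ord] <- fit$yf
      denom <- sum(dvec^2)
      s <- if (denom > 0) sqrt(sum((dvec - dhat)^2) / denom) else 0
      if (is.finite(stress) && stress - s < tol) { stress <- min(stress, s); conv <- TRUE; break }
      stress <- s
      if (s < 1e-12) { conv <- TRUE; break }
      # Guttman transform with the fitted disparities
      Dhat <- matrix(0, n, n); Dhat[lt] <- dhat; Dhat <- Dhat + t(Dhat)
      ratio <- ifelse(dd > 0, Dhat / dd, 0)
      B <- -ratio
      diag(B) <- -rowSums(B)
      X <- B %*% X / n
    }
    list(X = X, stress = stress, converged = conv)
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    X0 <- if (r == 1L) {
      pc <- suppressWarnings(stats::cmdscale(D, k = k))
      if (ncol(pc) < k) pc <- cbind(pc, matrix(0, n, k - ncol(pc)))
      pc + matrix(stats::rnorm(n * k, sd = 1e-8), n, k)
    } else matrix(stats::rnorm(n * k), n, k)
    fit <- run(X0)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }

  X <- scale(best$X, center = TRUE, scale = FALSE)
  if (n > 1L) {
    sv <- svd(X)
    X <- sv$u %*% diag(sv$d, k, k)
    # deterministic sign: largest-magnitude loading positive per axis
    for (j in seq_len(k)) {
      i0 <- which.max(abs(X[, j]))
      if (X[i0, j] < 0) X[, j] <- -X[, j]
    }
  }
  rownames(X) <- rownames(D)
  structure(list(points = X, stress = best$stress, converged = best$converged,
                 restarts = restarts, k = k),
            class = "nmds_fw")
}

#' @export
print.nmds_fw <- function(x, ...) {
  cat(sprintf("nMDS: %d points in %d dimensions, stress-1 = %.5f%s\n",
              nrow(x$points), x$k, x$stress,
              if (x$stress > 0.2 && x$k == 2) " (> 0.2: interpret with caution)" else ""))
  invisible(x)
}

#' @export
plot.nmds_fw <- function(x, groups = NULL, ...) {
  pts <- x$points
  col <- if (is.null(groups)) 1L else as.integer(factor(groups))
  graphics::plot(pts[, 1L], pts[, 2L], col = col, pch = 19,
                 xlab = "nMDS 1", ylab = "nMDS 2",
                 main = sprintf("stress = %.3f", x$stress), ...)
  invisible(x)
}
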