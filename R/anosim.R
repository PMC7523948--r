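# Analysis of similarities and similarity-percentage decomposition.

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of group separation on a dissimilarity matrix. All
#' n(n-1)/2 pairwise dissimilarities are ranked (mid-ranks for ties) and
#' R = (mean between-group rank - mean within-group rank) / (M / 2),
#' M = n(n-1)/2, so R lies in \\[-1, 1\\] with 1 meaning all between-group
#' dissimilarities exceed all within-group ones. Significance is obtained by
#' permuting group labels; the P estimator includes the observed statistic.
#'
#' @param d `resemblance`, `dist`, or dissimilarity matrix
#' @param groups grouping vector (>= 2 groups, not all singletons)
#' @param n_perm number of label permutations
#' @param seed RNG seed
#' @return object of class `anosim_fw` with `statistic` (R), `p_value`,
#'   `n_perm`
#' @export
anosim <- function(d, groups, n_perm = 999, seed = NULL) {
  D <- as_dissimilarity(d)
  groups <- as.character(groups)
  n <- nrow(D)
  if (length(unique(groups)) < 2L) stop("need at least two groups", call. = FALSE)
  if (all(table(groups) == 1L))
    stop("all groups are singletons; R is undefined", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  lt <- lower.tri(D)
  dv <- D[lt]
  rk <- rank(dv) # mid-ranks for ties
  same <- outer(groups, groups, "==")[lt]
  M <- n * (n - 1) / 2

  r_of <- function(same_vec) {
    (mean(rk[!same_vec]) - mean(rk[same_vec])) / (M / 2)
  }
  R <- r_of(same)
  Rstar <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    gp <- groups[sample.int(n)]
    Rstar[p] <- r_of(outer(gp, gp, "==")[lt])
  }
  P <- (sum(Rstar >= R - 1e-12) + 1) / (n_perm + 1)
  structure(list(statistic = R, p_value = P, n_perm = n_perm, groups = groups),
            class = "anosim_fw")
}

#' @export
print.anosim_fw <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, P = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' Similarity percentages (SIMPER)
#'
#' Decomposes the average Bray-Curtis dissimilarity between two groups into
#' per-taxon contributions: for taxon j the contribution is the mean over all
#' between-group sample pairs of 100 |x1j - x2j| / sum_k(x1k + x2k). The
#' contributions sum to the average between-group dissimilarity. Rows are
#' sorted by decreasing contribution; those contributing at least `cutoff_pct`
#' percentage points of dissimilarity are flagged for reporting.
#'
#' @param x abundance matrix or `assemblage` (already transformed if desired)
#' @param groups grouping vector with exactly two levels represented
#' @param cutoff_pct reporting cutoff in percentage points of dissimilarity
#' @return object of class `simper_fw`: data frame with per-group mean
#'   abundances, `contribution` (percentage points), `contribution_pct`
#'   (share of total), `cumulative_pct`, `reported`
#' @export
simper <- function(x, groups, cutoff_pct = 2) {
  m <- .as_abund(x)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L) stop("simper() compares exactly two groups", call. = FALSE)
  i1 <- which(groups == lev[1L]); i2 <- which(groups == lev[2L])
  ntax <- ncol(m)
  contrib <- numeric(ntax)
  npair <- 0L
  for (a in i1) for (b in i2) {
    den <- sum(m[a, ] + m[b, ])
    if (den == 0) next
    contrib <- contrib + 100 * abs(m[a, ] - m[b, ]) / den
    npair <- npair + 1L
  }
  if (npair == 0L) stop("no valid between-group pair", call. = FALSE)
  contrib <- contrib / npair
  total <- sum(contrib)
  out <- data.frame(taxon = colnames(m),
                    mean_1 = colMeans(m[i1, , drop = FALSE]),
                    mean_2 = colMeans(m[i2, , drop = FALSE]),
                    contribution = contrib,
                    contribution_pct = if (total > 0) 100 * contrib / total else 0,
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("mean_", lev)
  out <- out[order(-out$contribution), , drop = FALSE]
  out$cumulative_pct <- cumsum(out$contribution_pct)
  out$reported <- out$contribution >= cutoff_pct
  rownames(out) <- NULL
  structure(out, class = c("simper_fw", "data.frame"),
            average_dissimilarity = total, groups = lev,
            cutoff_pct = cutoff_pct)
}

#' @export
print.simper_fw <- function(x, ...) {
  cat(sprintf("SIMPER %s vs %s: average dissimilarity %.2f (cutoff %.3g)\n",
              attr(x, "groups")[1L], attr(x, "groups")[2L],
              attr(x, "average_dissimilarity"), attr(x, "cutoff_pct")))
  print(as.data.frame(x)[x$reported, , drop = FALSE], row.names = FALSE,
        digits = 4)
  invisible(x)
}
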