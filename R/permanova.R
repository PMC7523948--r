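# Distance-based permutational multivariate ANOVA.
#
# The machinery follows the partitioning of a Gower-centered inner-product
# matrix G built from squared dissimilarities: for a hat matrix H,
# tr(H G H) = tr(H G) is the sum of squares explained by the corresponding
# model. Type III (partial) SS for a term is the trace reduction between the
# full model and the model omitting only that term; significance comes from
# Freedman-Lane permutation of residuals under the reduced model.

# residual SS that is zero up to rounding (perfectly separated groups) must
# not come out as a tiny negative number and flip the sign of pseudo-F
.zap_ss <- function(ss, ss_tot) {
  if (ss < 0 && -ss <= 1e-8 * max(ss_tot, 1)) 0 else ss
}

.proj <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

#' Permutational multivariate analysis of variance
#'
#' One-way or two-way crossed fixed-factor PERMANOVA on a dissimilarity
#' matrix. Uses Type III partial sums of squares (each term adjusted for all
#' others, sum-to-zero contrasts) and permutation of residuals under the
#' reduced model (Freedman-Lane): for each term, residuals of the model
#' containing every other term are permuted and the pseudo-F recomputed. The
#' reported P value includes the observed statistic, (b + 1) / (m + 1); ties
#' in permuted F values count as exceedances. When the full set of n!
#' relabelings is no larger than `n_perm` they are enumerated exhaustively and
#' the P value is exact.
#'
#' The ECV column is the signed square root of the estimated component of
#' variation for each fixed term, (MS_term - MS_residual) / q with q the
#' expected-mean-squares coefficient (n divided by the term's number of level
#' combinations; the average cell size is used for unbalanced designs).
#'
#' @param d `resemblance`, `dist`, or dissimilarity matrix
#' @param data data frame of factors, rows aligned with `d`
#' @param formula right-hand-side formula over columns of `data`, e.g.
#'   `~ year` or `~ year * section`
#' @param n_perm number of permutations (>= 99)
#' @param seed RNG seed for the permutations
#' @return object of class `permanova` with an `aov.tab` data frame
#'   (df, SS (Type III), ECV, unique permutations, pseudo-F, P)
#' @export
permanova <- function(d, data, formula, n_perm = 9999, seed = NULL) {
  D <- as_dissimilarity(d)
  n <- nrow(D)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  stopifnot(nrow(data) == n, n_perm >= 99)
  if (!is.null(seed)) set.seed(seed)

  tl <- attr(stats::terms(formula), "term.labels")
  vars <- all.vars(formula)
  if (length(vars) > 2L)
    stop("only one-way or two-way crossed designs are supported", call. = FALSE)
  for (v in vars) {
    data[[v]] <- factor(data[[v]])
    if (nlevels(data[[v]]) < 2L)
      stop("factor '", v, "' has fewer than 2 levels", call. = FALSE)
  }
  contr <- lapply(vars, function(v) "contr.sum")
  names(contr) <- vars
  X <- stats::model.matrix(formula, data, contrasts.arg = contr)
  asn <- attr(X, "assign")

  G <- gower_center(D)
  ss_tot <- sum(diag(G))
  H_f <- .proj(X)
  rank_f <- qr(X)$rank
  ss_full <- sum(H_f * G)
  df_res <- n - rank_f
  ss_res <- .zap_ss(ss_tot - ss_full, ss_tot)
  ms_res <- ss_res / df_res

  # exhaustive enumeration when feasible
  exhaustive <- FALSE
  n_total <- suppressWarnings(factorial(n))
  if (is.finite(n_total) && n_total <= n_perm) {
    perm_mat <- .all_perms(n)
    exhaustive <- TRUE
  }

  res <- vector("list", length(tl))
  for (ti in seq_along(tl)) {
    keep <- asn != ti
    X_r <- X[, keep, drop = FALSE]
    H_r <- .proj(X_r)
    rank_r <- qr(X_r)$rank
    df_t <- rank_f - rank_r
    ss_t <- ss_full - sum(H_r * G)
    F_t <- (ss_t / df_t) / ms_res

    if (!exhaustive)
      perm_mat <- t(replicate(n_perm, sample.int(n)))
    m <- nrow(perm_mat)
    R_r <- diag(n) - H_r
    Fstar <- numeric(m)
    for (p in seq_len(m)) {
      M <- H_r + R_r[perm_mat[p, ], , drop = FALSE]
      Gs <- M %*% G %*% t(M)
      ss_full_s <- sum(H_f * Gs)
      ss_t_s <- ss_full_s - sum(H_r * Gs)
      ss_res_s <- .zap_ss(sum(diag(Gs)) - ss_full_s, ss_tot)
      Fstar[p] <- (ss_t_s / df_t) / (ss_res_s / df_res)
    }
    P <- if (exhaustive) mean(Fstar >= F_t - 1e-12)
    else (sum(Fstar >= F_t - 1e-12) + 1) / (m + 1)
    uniq <- nrow(unique(perm_mat))

    # expected-mean-squares coefficient for this fixed term
    L <- prod(vapply(strsplit(tl[ti], ":", fixed = TRUE)[[1L]],
                     function(v) nlevels(data[[v]]), 1L))
    q <- n / L
    comp <- (ss_t / df_t - ms_res) / q
    ecv <- sign(comp) * sqrt(abs(comp))

    res[[ti]] <- data.frame(term = tl[ti], df = df_t, SS = ss_t, ECV = ecv,
                            perm = uniq, pseudo_F = F_t, P = P,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, res)
  tab <- rbind(tab,
               data.frame(term = "Residual", df = df_res, SS = ss_res,
                          ECV = sqrt(ms_res), perm = NA, pseudo_F = NA, P = NA,
                          stringsAsFactors = FALSE),
               data.frame(term = "Total", df = n - 1L, SS = ss_tot,
                          ECV = NA, perm = NA, pseudo_F = NA, P = NA,
                          stringsAsFactors = FALSE))
  rownames(tab) <- NULL
  structure(list(aov.tab = tab, formula = formula, n = n, n_perm = n_perm,
                 exhaustive = exhaustive, seed = seed),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (Type III SS, residual permutation under reduced model)\n")
  cat("design:", deparse(x$formula), "  n =", x$n,
      if (x$exhaustive) " [exhaustive]" else sprintf(" [%d permutations]", x$n_perm),
      "\n")
  tab <- x$aov.tab
  tab$SS <- signif(tab$SS, 6)
  tab$ECV <- signif(tab$ECV, 4)
  tab$pseudo_F <- signif(tab$pseudo_F, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

# moment-matched gamma reference for small-permutation P values: fit the
# first two moments of the permutation F distribution and integrate the tail
.monte_carlo_p <- function(Fstar, F_obs) {
  mu <- mean(Fstar)
  v <- stats::var(Fstar)
  if (!is.finite(v) || v <= 0) return(if (F_obs > mu) 0 else 1)
  shape <- mu^2 / v
  rate <- mu / v
  p <- stats::pgamma(F_obs, shape = shape, rate = rate, lower.tail = FALSE)
  min(1, max(p, .Machine$double.eps))
}

#' Pairwise PERMANOVA comparisons
#'
#' All pairwise one-way tests between levels of a factor, reporting the
#' pseudo-t (signed square root of the two-group pseudo-F; negative values
#' can arise for semi-metric measures), the number of unique
#' possible permutations (the binomial coefficient of the two group sizes),
#' and a permutational P value. When fewer than `mc_threshold` unique
#' permutations exist the permutation distribution is too coarse, and an
#' asymptotic Monte Carlo P value from a moment-matched gamma reference is
#' reported instead (flagged). Significance is judged against a
#' Bonferroni-adjusted level, `alpha_family` divided by the number of
#' comparisons.
#'
#' @param d `resemblance`, `dist`, or dissimilarity matrix
#' @param groups factor over the rows of `d`
#' @param n_perm permutations for large pairs
#' @param seed RNG seed
#' @param alpha_family family-wise alpha to be Bonferroni-split
#' @param mc_threshold minimum unique permutations for a pure permutation P
#' @return object of class `pairwise_permanova`, a data frame per pair with
#'   `df`, `perm`, `pseudo_t`, `P`, `monte_carlo`, `adjusted_alpha`,
#'   `significant`
#' @export
pairwise_permanova <- function(d, groups, n_perm = 9999, seed = NULL,
                               alpha_family = 0.05, mc_threshold = 40) {
  D <- as_dissimilarity(d)
  groups <- factor(groups)
  if (!is.null(seed)) set.seed(seed)
  lev <- levels(groups)
  prs <- utils::combn(lev, 2L)
  n_comp <- ncol(prs)
  adj <- alpha_family / n_comp
  out <- vector("list", n_comp)
  for (i in seq_len(n_comp)) {
    a <- prs[1L, i]; b <- prs[2L, i]
    sel <- groups %in% c(a, b)
    Dp <- D[sel, sel, drop = FALSE]
    g <- droplevels(groups[sel])
    n1 <- sum(g == a); n2 <- sum(g == b); np <- n1 + n2
    uniq_possible <- choose(np, n1)

    G <- gower_center(Dp)
    X <- stats::model.matrix(~g, contrasts.arg = list(g = "contr.sum"))
    H <- .proj(X)
    ss_tot <- sum(diag(G))
    ss_b <- sum(H * G) # intercept part vanishes on centered G
    df_t <- 1L; df_res <- np - 2L
    if (df_res < 1L) {
      out[[i]] <- data.frame(group1 = a, group2 = b, df = NA, perm = uniq_possible,
                             pseudo_t = NA, P = NA, monte_carlo = FALSE,
                             adjusted_alpha = adj, significant = NA)
      next
    }
    F_obs <- (ss_b / df_t) / (.zap_ss(ss_tot - ss_b, ss_tot) / df_res)

    # permutation distribution over distinct two-group relabelings
    if (uniq_possible <= max(n_perm, mc_threshold)) {
      assigns <- utils::combn(np, n1)
      m <- ncol(assigns)
      Fstar <- numeric(m)
      for (p in seq_len(m)) {
        gp <- factor(ifelse(seq_len(np) %in% assigns[, p], a, b), levels = c(a, b))
        Xp <- stats::model.matrix(~gp, contrasts.arg = list(gp = "contr.sum"))
        Hp <- .proj(Xp)
        ssb <- sum(Hp * G)
        Fstar[p] <- (ssb / df_t) / (.zap_ss(ss_tot - ssb, ss_tot) / df_res)
      }
      P_perm <- mean(Fstar >= F_obs - 1e-12)
    } else {
      m <- n_perm
      Fstar <- numeric(m)
      for (p in seq_len(m)) {
        gp <- g[sample.int(np)]
        Xp <- stats::model.matrix(~gp, contrasts.arg = list(gp = "contr.sum"))
        Hp <- .proj(Xp)
        ssb <- sum(Hp * G)
        Fstar[p] <- (ssb / df_t) / (.zap_ss(ss_tot - ssb, ss_tot) / df_res)
      }
      P_perm <- (sum(Fstar >= F_obs - 1e-12) + 1) / (m + 1)
    }
    mc <- uniq_possible < mc_threshold
    P <- if (mc) .monte_carlo_p(Fstar, F_obs) else P_perm
    # signed root: a (rare) negative pseudo-F from a semi-metric measure maps
    # to a negative pseudo-t instead of NaN
    out[[i]] <- data.frame(group1 = a, group2 = b, df = df_res,
                           perm = uniq_possible,
                           pseudo_t = sign(F_obs) * sqrt(abs(F_obs)),
                           P = P, monte_carlo = mc, adjusted_alpha = adj,
                           significant = !is.na(P) & P <= adj,
                           stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  structure(tab, class = c("pairwise_permanova", "data.frame"))
}

#' @export
print.pairwise_permanova <- function(x, ...) {
  cat("Pairwise PERMANOVA (Bonferroni-adjusted alpha =",
      signif(x$adjusted_alpha[1L], 3), "; Monte Carlo P flagged)\n")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
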