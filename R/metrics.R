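# Univariate sample and diet metrics, group summaries, percent change, and
# the classical ANOVA / Tukey HSD contract used on those metrics.

#' Per-sample univariate metrics
#'
#' Numeric density (count / effort), energy density (see
#' [sample_energy_density()] for units), taxa richness (unique taxa at the
#' finest identified level) and the terrestrial percentage of the sample on a
#' count or energy basis. Samples with zero total abundance get a terrestrial
#' percentage of 0 and are flagged.
#'
#' @param x a `sample_set` (energy-annotated if `basis_for_terrestrial` or the
#'   energy density is wanted)
#' @param basis_for_terrestrial `"count"` or `"energy"`
#' @return data frame, one row per sample, with the sample metadata plus
#'   `numeric_density`, `energy_density`, `richness`, `terrestrial_pct`,
#'   `zero_total`
#' @export
sample_metrics <- function(x, basis_for_terrestrial = c("count", "energy")) {
  basis_for_terrestrial <- match.arg(basis_for_terrestrial)
  obs <- x$observations
  s <- x$samples
  has_energy <- "joules" %in% names(obs)
  if (basis_for_terrestrial == "energy" && !has_energy)
    stop("energy basis requires annotate_energy() first", call. = FALSE)

  counts <- tapply(obs$count, obs$sample_id, sum)
  nd <- unname(counts[s$sample_id]); nd[is.na(nd)] <- 0
  nd <- nd / s$effort

  ed <- rep(NA_real_, nrow(s))
  if (has_energy) ed <- sample_energy_density(x)$energy_density

  rich <- tapply(obs$taxon_id[obs$count > 0], obs$sample_id[obs$count > 0],
                 function(v) length(unique(v)))
  ri <- unname(rich[s$sample_id]); ri[is.na(ri)] <- 0

  origin <- x$taxa$origin[match(obs$taxon_id, x$taxa$taxon_id)]
  w <- if (basis_for_terrestrial == "count") obs$count else obs$joules
  terr <- tapply(w * (origin == "terrestrial"), obs$sample_id, sum)
  tot <- tapply(w, obs$sample_id, sum)
  tp <- unname(terr[s$sample_id]) / unname(tot[s$sample_id]) * 100
  zero <- is.na(tp) | unname(tot[s$sample_id]) == 0
  tp[zero | is.na(tp)] <- 0

  cbind(s,
        data.frame(numeric_density = nd, energy_density = ed, richness = ri,
                   terrestrial_pct = tp, zero_total = zero))
}

#' Per-stomach diet metrics
#'
#' For each fish: total prey items, unique prey taxa, total prey energy (KJ)
#' and the terrestrial percentage of total energy. Diet observations are keyed
#' to the fish's diet sample; when several fish share one diet sample the
#' observations must carry a `fish_id` column.
#'
#' @param x a `sample_set` with `$fish` and energy-annotated observations
#' @return data frame, one row per fish
#' @export
diet_metrics <- function(x) {
  if (is.null(x$fish)) stop("sample set has no fish records", call. = FALSE)
  obs <- x$observations
  if (!"joules" %in% names(obs))
    stop("run annotate_energy() first", call. = FALSE)
  fish <- x$fish
  key <- if ("fish_id" %in% names(obs)) obs$fish_id else obs$sample_id
  fkey <- if ("fish_id" %in% names(obs)) fish$fish_id else fish$sample_id

  tot_n <- tapply(obs$count, key, sum)
  rich <- tapply(obs$taxon_id[obs$count > 0], key[obs$count > 0],
                 function(v) length(unique(v)))
  tot_j <- tapply(obs$joules, key, sum)
  origin <- x$taxa$origin[match(obs$taxon_id, x$taxa$taxon_id)]
  terr_j <- tapply(obs$joules * (origin == "terrestrial"), key, sum)

  g <- function(tab) { v <- unname(tab[fkey]); v[is.na(v)] <- 0; v }
  prey_items <- g(tot_n); prey_richness <- g(rich)
  prey_kj <- g(tot_j) / 1000
  tp <- ifelse(g(tot_j) > 0, g(terr_j) / g(tot_j) * 100, 0)
  prey_items[fish$empty] <- 0; prey_richness[fish$empty] <- 0
  prey_kj[fish$empty] <- 0; tp[fish$empty] <- 0
  cbind(fish,
        data.frame(age_class = age_class(fish$fork_length_mm),
                   prey_items = prey_items, prey_richness = prey_richness,
                   prey_energy_kj = prey_kj, terrestrial_pct = tp))
}

#' Group means and standard deviations
#'
#' Unweighted arithmetic mean and sample standard deviation (n - 1
#' denominator) per group; groups of size one report the SD as `NA`. Empty
#' groups are omitted.
#'
#' @param values numeric vector
#' @param by data frame (or list) of grouping variables, same length
#' @return data frame with the group keys, `n`, `mean`, `sd`
#' @export
group_summary <- function(values, by) {
  by <- as.data.frame(by, stringsAsFactors = FALSE)
  key <- interaction(by, drop = TRUE, lex.order = TRUE, sep = "\r")
  lev <- levels(key)
  n <- as.vector(table(key))
  mu <- tapply(values, key, mean)
  sd_ <- tapply(values, key, function(v) if (length(v) > 1L) stats::sd(v) else NA_real_)
  parts <- do.call(rbind, strsplit(lev, "\r", fixed = TRUE))
  out <- as.data.frame(parts, stringsAsFactors = FALSE)
  names(out) <- names(by)
  out$n <- n
  out$mean <- as.numeric(mu[lev])
  out$sd <- as.numeric(sd_[lev])
  rownames(out) <- NULL
  out
}

#' Percent decline between two means
#'
#' `100 * (1 - during / pre)`; positive values are declines. With
#' `digits = 0` the result is rounded to the nearest whole percent for
#' reporting; `digits = NULL` returns the exact value.
#'
#' @param pre_mean baseline mean (> 0)
#' @param during_mean mean during the disturbance
#' @param digits rounding for reporting, or `NULL` for the exact value
#' @return percent decline
#' @export
percent_change <- function(pre_mean, during_mean, digits = NULL) {
  if (any(pre_mean <= 0))
    stop("percent change is undefined for a non-positive baseline mean",
         call. = FALSE)
  pc <- 100 * (1 - during_mean / pre_mean)
  if (!is.null(digits)) pc <- round(pc, digits)
  pc
}

#' ANOVA with Tukey HSD letters
#'
#' One-way or two-way (crossed, with interaction) fixed-factor ANOVA on a
#' univariate metric, with an optional variance-stabilising transformation
#' applied first, followed by all-pairs Tukey HSD and a compact letter display
#' whenever a term is significant at `alpha`.
#'
#' @param values numeric response
#' @param factors data frame with one or two grouping columns
#' @param transform `"none"`, `"log10"` (log10(x + c)) or `"asin_sqrt"`
#'   (arcsine square root of a proportion in \\[0, 1\\])
#' @param log_const the c in log10(x + c)
#' @param alpha significance level for the HSD letters
#' @return list of class `anova_tukey`: `table` (term F and p values),
#'   `tukey` (per significant term: TukeyHSD table and letters)
#' @export
anova_tukey <- function(values, factors, transform = c("none", "log10", "asin_sqrt"),
                        log_const = 1, alpha = 0.05) {
  transform <- match.arg(transform)
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  if (!ncol(factors) %in% 1:2)
    stop("one or two factors supported", call. = FALSE)
  y <- switch(transform,
              none = values,
              log10 = log10(values + log_const),
              asin_sqrt = asin(sqrt(values)))
  dat <- factors
  dat[] <- lapply(dat, factor)
  dat$.y <- y
  fml <- if (ncol(factors) == 1L)
    stats::as.formula(paste(".y ~", names(factors)[1L]))
  else
    stats::as.formula(paste(".y ~", names(factors)[1L], "*", names(factors)[2L]))
  fit <- stats::aov(fml, data = dat)
  sm <- summary(fit)[[1L]]
  aliased <- is.na(stats::coef(fit))
  if (any(aliased))
    stop("singular design: aliased coefficient(s) ",
         paste(names(aliased)[aliased], collapse = ", "), call. = FALSE)
  terms_ <- trimws(rownames(sm))
  tab <- data.frame(term = terms_, df = sm$Df, ss = sm$`Sum Sq`,
                    F = sm$`F value`, p = sm$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  tukey <- list()
  sig <- tab$term[!is.na(tab$p) & tab$p < alpha]
  for (tm in sig) {
    hs <- stats::TukeyHSD(fit, which = tm)[[tm]]
    groups <- levels(interaction(dat[strsplit(tm, ":", fixed = TRUE)[[1L]]],
                                 drop = TRUE, sep = ":"))
    pm <- matrix(1, length(groups), length(groups),
                 dimnames = list(groups, groups))
    prs <- strsplit(rownames(hs), "-", fixed = TRUE)
    for (i in seq_along(prs)) {
      a <- prs[[i]][1L]; b <- prs[[i]][2L]
      if (a %in% groups && b %in% groups)
        pm[a, b] <- pm[b, a] <- hs[i, "p adj"]
    }
    tukey[[tm]] <- list(hsd = hs, letters = cld_letters(pm, alpha))
  }
  structure(list(table = tab, tukey = tukey, transform = transform,
                 alpha = alpha), class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat("ANOVA (transform:", x$transform, ")\n")
  print(x$table, row.names = FALSE)
  for (tm in names(x$tukey)) {
    cat("\nTukey HSD letters for", tm, "(alpha =", x$alpha, "):\n")
    print(x$tukey[[tm]]$letters)
  }
  invisible(x)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Standard insert-and-absorb letter merging: groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param pmat symmetric matrix of pairwise p values with group names
#' @param alpha significance level
#' @return named character vector of letter codes
#' @export
cld_letters <- function(pmat, alpha = 0.05) {
  g <- rownames(pmat)
  k <- length(g)
  # start with one column (letter) containing everything
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    if (pmat[i, j] >= alpha) next  # not significantly different
    for (ci in seq_along(cols)) {
      if (cols[[ci]][i] && cols[[ci]][j]) {
        # split this letter: one copy without i, one without j
        a <- cols[[ci]]; b <- cols[[ci]]
        a[i] <- FALSE; b[j] <- FALSE
        cols[[ci]] <- a
        cols[[length(cols) + 1L]] <- b
      }
    }
    # absorb columns that are subsets of others
    keep <- rep(TRUE, length(cols))
    for (u in seq_along(cols)) for (v in seq_along(cols)) {
      if (u != v && keep[u] && keep[v] &&
          all(!cols[[u]] | cols[[v]]) && any(cols[[v]] & !cols[[u]]))
        keep[u] <- FALSE
      else if (u < v && keep[u] && keep[v] &&
               identical(cols[[u]], cols[[v]]))
        keep[v] <- FALSE
    }
    cols <- cols[keep]
  }
  lab <- rep("", k)
  for (ci in seq_along(cols))
    lab[cols[[ci]]] <- paste0(lab[cols[[ci]]], letters[ci])
  names(lab) <- g
  lab
}
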