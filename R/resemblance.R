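# Bray-Curtis resemblance and its plumbing: abundance transformations, the
# dummy species that keeps empty samples defined, diet-availability overlap,
# and centroid distance matrices in principal-coordinate space.

.as_abund <- function(x) {
  if (inherits(x, "assemblage")) x$abund else as.matrix(x)
}

.set_abund <- function(x, m) {
  if (inherits(x, "assemblage")) { x$abund <- m; x } else m
}

#' Abundance transformation
#'
#' Elementwise square root or fourth root, balancing the contribution of
#' common and rare taxa before resemblance computation. The usual convention
#' in this kind of study is square root for drift data and fourth root for
#' everything else.
#'
#' @param x abundance matrix or `assemblage` (non-negative cells)
#' @param kind `"none"`, `"sqrt"` or `"fourth_root"`
#' @return transformed object of the same type
#' @export
transform_abundance <- function(x, kind = c("none", "sqrt", "fourth_root")) {
  kind <- match.arg(kind)
  m <- .as_abund(x)
  if (any(m < 0)) stop("negative abundance cell", call. = FALSE)
  m <- switch(kind, none = m, sqrt = sqrt(m), fourth_root = m^0.25)
  .set_abund(x, m)
}

#' Add a dummy species
#'
#' Appends one column with a constant small abundance to every sample so that
#' Bray-Curtis coefficients are defined even between empty samples. Added to
#' the raw abundances, before transformation.
#'
#' @param x abundance matrix or `assemblage`
#' @param value dummy abundance (default 0.1)
#' @param name dummy column name
#' @return object of the same type with the extra column
#' @export
add_dummy <- function(x, value = 0.1, name = "dummy") {
  m <- .as_abund(x)
  if (name %in% colnames(m))
    stop("column '", name, "' already present", call. = FALSE)
  m <- cbind(m, matrix(value, nrow(m), 1L, dimnames = list(NULL, name)))
  .set_abund(x, m)
}

#' @rdname add_dummy
#' @export
drop_dummy <- function(x, name = "dummy") {
  m <- .as_abund(x)
  if (!name %in% colnames(m)) stop("no '", name, "' column", call. = FALSE)
  .set_abund(x, m[, colnames(m) != name, drop = FALSE])
}

#' Bray-Curtis resemblance matrix
#'
#' Similarity between samples i and j is
#' `100 * (1 - sum |x_i - x_j| / sum (x_i + x_j))`, from 0 (no overlap) to 100
#' (identical); dissimilarity is its complement. A pair of all-zero samples is
#' undefined and raises an error — add a dummy species first if empty samples
#' can occur.
#'
#' @param x abundance matrix or `assemblage` (rows = samples)
#' @param as `"similarity"` or `"dissimilarity"`
#' @return a `resemblance` object: square matrix in \\[0, 100\\] with
#'   provenance attributes
#' @export
bray_curtis <- function(x, as = c("similarity", "dissimilarity")) {
  as <- match.arg(as)
  m <- .as_abund(x)
  if (any(m < 0)) stop("negative abundance cell", call. = FALSE)
  n <- nrow(m)
  if (n < 2L) stop("need at least two samples", call. = FALSE)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    den <- sum(m[i, ] + m[j, ])
    if (den == 0)
      stop(sprintf("Bray-Curtis undefined for all-zero pair (%s, %s); add a dummy species",
                   rownames(m)[i], rownames(m)[j]), call. = FALSE)
    d <- 100 * sum(abs(m[i, ] - m[j, ])) / den
    out[i, j] <- out[j, i] <- d
  }
  if (as == "similarity") out <- 100 - out
  resemblance(out, type = as)
}

#' @rdname bray_curtis
#' @param mat square numeric matrix
#' @param type `"similarity"` or `"dissimilarity"`
#' @export
resemblance <- function(mat, type = c("similarity", "dissimilarity")) {
  type <- match.arg(type)
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (max(abs(mat - t(mat))) > 1e-8) stop("matrix must be symmetric", call. = FALSE)
  diag(mat) <- if (type == "similarity") 100 else 0
  structure(mat, type = type, class = c("resemblance", "matrix", "array"))
}

#' @export
print.resemblance <- function(x, ...) {
  cat("Bray-Curtis", attr(x, "type"), "matrix,", nrow(x), "samples\n")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))], digits = 4)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Convert a resemblance to 0-100 dissimilarity form
#'
#' @param x `resemblance`, `dist`, or plain square matrix (assumed
#'   dissimilarity)
#' @return plain numeric dissimilarity matrix
#' @export
as_dissimilarity <- function(x) {
  if (inherits(x, "resemblance")) {
    m <- unclass(x)
    if (attr(x, "type") == "similarity") m <- 100 - m
    attr(m, "type") <- NULL
    diag(m) <- 0
    return(m)
  }
  if (inherits(x, "dist")) return(as.matrix(x))
  m <- as.matrix(x)
  if (max(abs(m - t(m))) > 1e-8) stop("dissimilarity matrix must be symmetric",
                                      call. = FALSE)
  m
}

#' Diet-availability overlap per sampling event
#'
#' For each site sampling event, compares the fish-diet assemblage (mean over
#' fish of the event) against the paired environmental assemblage using
#' Bray-Curtis similarity. Because counts per stomach and densities per m2/m3
#' are incomparable, both assemblages are standardized to relative abundance
#' (rows summing to 1) first. Events without a pairing are skipped with a
#' message.
#'
#' @param diet abundance matrix or `assemblage`, rows = individual fish
#' @param env abundance matrix or `assemblage`, rows = environmental samples
#'   (rownames = sample ids)
#' @param diet_events vector assigning each diet row to an event id
#' @param pairing named character vector: event id -> environmental sample id
#' @param dummy dummy abundance added to both standardized assemblages before
#'   comparison (`NULL` to disable); keeps pairs of empty assemblages defined
#' @return data frame with `event`, `env_sample`, `similarity`
#' @export
diet_availability_overlap <- function(diet, env, diet_events, pairing,
                                      dummy = 0.1) {
  dm <- .as_abund(diet); em <- .as_abund(env)
  events <- unique(diet_events)
  res <- list()
  for (ev in events) {
    if (!ev %in% names(pairing)) {
      message("event '", ev, "' has no paired environmental sample; skipped")
      next
    }
    es <- pairing[[ev]]
    if (!es %in% rownames(em)) {
      message("environmental sample '", es, "' not found; event '", ev,
              "' skipped")
      next
    }
    dsub <- dm[diet_events == ev, , drop = FALSE]
    # standardize each stomach, then average over fish of the event
    rs <- rowSums(dsub)
    dstd <- dsub[rs > 0, , drop = FALSE] / rs[rs > 0]
    dvec <- if (nrow(dstd)) colMeans(dstd) else colSums(dsub) * 0
    evec <- em[es, ]
    if (sum(evec) > 0) evec <- evec / sum(evec)
    taxa <- union(names(dvec), names(evec))
    two <- matrix(0, 2L, length(taxa), dimnames = list(c("diet", "env"), taxa))
    two["diet", names(dvec)] <- dvec
    two["env", names(evec)] <- evec
    if (!is.null(dummy)) two <- add_dummy(two, dummy)
    s <- bray_curtis(two)["diet", "env"]
    res[[length(res) + 1L]] <- data.frame(event = ev, env_sample = es,
                                          similarity = s,
                                          stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(event = character(), env_sample = character(),
                      similarity = numeric()))
  do.call(rbind, res)
}

# Gower-centered inner-product matrix from a dissimilarity matrix.
gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' Distances between group centroids
#'
#' Centroids are taken in the principal-coordinate embedding of the
#' dissimilarity matrix. Distances are computed directly from the
#' Gower-centered inner-product matrix, which retains negative eigenvalues;
#' squared centroid distances that come out (numerically) negative are
#' truncated at zero, the standard correction for semi-metric resemblance
#' measures.
#'
#' @param d a `resemblance` or dissimilarity matrix
#' @param groups grouping vector (or data frame whose columns are combined)
#' @return a `resemblance` dissimilarity matrix over group labels
#' @export
centroid_matrix <- function(d, groups) {
  D <- as_dissimilarity(d)
  if (is.data.frame(groups))
    groups <- interaction(groups, drop = TRUE, lex.order = TRUE, sep = ":")
  groups <- as.character(groups)
  G <- gower_center(D)
  labs <- unique(groups)
  k <- length(labs)
  block_mean <- function(a, b) mean(G[groups == a, groups == b, drop = FALSE])
  out <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    d2 <- block_mean(labs[i], labs[i]) + block_mean(labs[j], labs[j]) -
      2 * block_mean(labs[i], labs[j])
    out[i, j] <- out[j, i] <- sqrt(max(0, d2))
  }
  resemblance(out, type = "dissimilarity")
}

#' Centroid trajectories through time
#'
#' Orders the group centroids of `centroid_matrix()` by period within section,
#' giving the step lengths of each section's multivariate trajectory.
#'
#' @param d a `resemblance` or dissimilarity matrix over samples
#' @param section,period grouping vectors aligned with the rows of `d`
#' @return list per section: ordered period labels and the centroid distance
#'   of each consecutive step
#' @export
centroid_trajectory <- function(d, section, period) {
  cm <- centroid_matrix(d, data.frame(section = section, period = period))
  per_order <- .PERIODS[.PERIODS %in% unique(period)]
  out <- list()
  for (s in unique(section)) {
    pres <- per_order[paste(s, per_order, sep = ":") %in% rownames(cm)]
    labs <- paste(s, pres, sep = ":")
    steps <- if (length(labs) > 1L)
      vapply(seq_len(length(labs) - 1L),
             function(i) cm[labs[i], labs[i + 1L]], 0)
    else numeric()
    out[[s]] <- list(periods = pres, step = steps)
  }
  out
}
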