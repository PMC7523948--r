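# Length -> dry mass -> energy conversion with taxonomic fallback.
#
# Conversion entries are keyed by a rank-path prefix (class, order, family,
# genus, species; trailing levels empty) plus a life stage. Lookup returns the
# most specific matching entry, falling back species -> genus -> family ->
# order -> class, and at each level preferring the exact life stage before
# stage "unknown". Tables must carry class-level defaults so resolution never
# dead-ends for catalogued taxa.

#' Read a conversion-coefficient table
#'
#' The CSV mirrors the usual literature compilation: one row per taxon key and
#' life stage with length-to-dry-mass power-law coefficients and dry-mass-to-
#' energy factors. Columns: `class,order,family,genus,species,life_stage,
#' metric,a,b,ED,pDM,ed_basis,default_joules`. `a` (mg mm^-b) and `b` define
#' DM = a L^b; `ED` is energy density in J per mg (dry mass by default, wet
#' mass when `ed_basis = "wet"`, in which case `pDM` converts dry to wet);
#' `default_joules` is an optional per-individual fallback energy for taxa
#' that are never measured (heavily digested prey).
#'
#' @param path CSV file
#' @return a `conversion_table`
#' @export
read_conversions <- function(path) {
  df <- .read_csv(path, numeric_cols = c("a", "b", "ED", "pDM",
                                         "default_joules"))
  conversion_table(df)
}

#' @rdname read_conversions
#' @param df data frame with the columns documented above
#' @export
conversion_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (cc in c(.RANKS, "life_stage", "metric"))
    if (!cc %in% names(df)) df[[cc]] <- ""
  df$life_stage[!nzchar(df$life_stage)] <- "unknown"
  for (cc in c("a", "b", "ED", "pDM", "default_joules"))
    if (!cc %in% names(df)) df[[cc]] <- NA_real_
  if (!"ed_basis" %in% names(df)) df$ed_basis <- "dry"
  df$ed_basis[!nzchar(df$ed_basis)] <- "dry"
  if (any(!is.na(df$a) & df$a <= 0) || any(!is.na(df$b) & df$b <= 0))
    stop("regression coefficients a and b must be positive", call. = FALSE)
  if (any(!is.na(df$ED) & df$ED <= 0))
    stop("energy densities must be positive", call. = FALSE)
  if (any(!is.na(df$pDM) & (df$pDM <= 0 | df$pDM > 1)))
    stop("percent dry mass must be in (0, 1]", call. = FALSE)
  df$.depth <- apply(df[.RANKS], 1L, function(r) max(c(0L, which(nzchar(r)))))
  if (any(df$.depth == 0L))
    stop("conversion entries must name at least a class", call. = FALSE)
  # canonical order: resolution is independent of the file's row order
  key <- do.call(paste, c(df[c(.RANKS, "life_stage", "metric")], sep = "\r"))
  df <- df[order(key), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("conversion_table", "data.frame"))
}

# does entry (row e of tab) key-match the taxon rank path at its own depth?
.prefix_match <- function(tab, path) {
  d <- tab$.depth
  ok <- rep(TRUE, nrow(tab))
  for (i in seq_along(.RANKS)) {
    lev <- .RANKS[i]
    ok <- ok & (d < i | tab[[lev]] == path[[i]])
  }
  ok
}

#' Resolve conversion factors for a taxon
#'
#' Returns the most specific mass regression and energy factor whose key is a
#' prefix of the taxon's rank path, falling back through coarser ranks, and at
#' each rank preferring the matching life stage before stage `"unknown"`.
#' Regression and energy factor are resolved independently (an entry may carry
#' either or both). The fallback rank actually used is recorded.
#'
#' @param taxon one row of a taxon catalog (or a list with `class`..`species`
#'   and `life_stage`)
#' @param table a `conversion_table`
#' @param metric restrict the mass regression to this body measurement type
#'   (`"total_length"` or `"head_capsule_width"`); `NULL` accepts any
#' @param life_stage overrides the taxon's life stage if given
#' @return list with `regression` (row or NULL), `energy` (row or NULL),
#'   `regression_rank`, `energy_rank`
#' @export
resolve_factors <- function(taxon, table, metric = NULL, life_stage = NULL) {
  stopifnot(inherits(table, "conversion_table"))
  path <- lapply(.RANKS, function(r) as.character(taxon[[r]]))
  names(path) <- .RANKS
  stage <- if (is.null(life_stage)) as.character(taxon[["life_stage"]]) else life_stage
  if (!length(stage) || !nzchar(stage)) stage <- "unknown"

  match_all <- .prefix_match(table, path)
  pick <- function(candidates) {
    if (!any(candidates)) return(NULL)
    sub <- table[candidates, , drop = FALSE]
    taxon_depth <- max(c(0L, which(nzchar(unlist(path)))))
    for (d in seq(taxon_depth, 1L)) {
      for (st in unique(c(stage, "unknown"))) {
        hit <- sub$.depth == d & sub$life_stage == st
        if (any(hit)) return(sub[which(hit)[1L], , drop = FALSE])
      }
    }
    NULL
  }
  reg_ok <- match_all & !is.na(table$a) & !is.na(table$b)
  if (!is.null(metric)) reg_ok <- reg_ok & table$metric == metric
  en_ok <- match_all & !is.na(table$ED)
  reg <- pick(reg_ok)
  en <- pick(en_ok)
  list(regression = reg, energy = en,
       regression_rank = if (is.null(reg)) NA_character_ else .RANKS[reg$.depth],
       energy_rank = if (is.null(en)) NA_character_ else .RANKS[en$.depth])
}

#' Energy content of one measured individual
#'
#' Dry mass follows the standard invertebrate length-mass power law
#' DM = a L^b (mg, L in mm); energy is DM x ED (J per mg dry mass), or
#' wet mass x ED when the energy density is expressed per wet mass
#' (wet mass = DM / pDM).
#'
#' @param length_mm body measurement in mm (> 0)
#' @param regression one-row regression entry (needs `a`, `b`, optionally
#'   `metric` and a `valid_min`/`valid_max` range)
#' @param energy one-row energy entry (needs `ED`, `ed_basis`, `pDM`)
#' @param metric measurement type of `length_mm`; checked against the
#'   regression's metric when both are non-empty
#' @return list with `dry_mass_mg` and `joules`
#' @export
individual_energy <- function(length_mm, regression, energy, metric = NULL) {
  if (any(length_mm <= 0)) stop("measurement must be positive", call. = FALSE)
  if (!is.null(metric) && nzchar(regression$metric) && nzchar(metric) &&
      regression$metric != metric)
    stop(sprintf("measurement metric '%s' does not match regression metric '%s'",
                 metric, regression$metric), call. = FALSE)
  if (!is.null(regression$valid_min) && !is.na(regression$valid_min) &&
      any(length_mm < regression$valid_min | length_mm > regression$valid_max))
    warning("measurement outside the regression's valid range; extrapolating")
  dm <- regression$a * length_mm^regression$b
  ed <- energy$ED
  j <- if (identical(energy$ed_basis, "wet")) {
    if (is.na(energy$pDM))
      stop("wet-mass energy density requires pDM", call. = FALSE)
    (dm / energy$pDM) * ed
  } else dm * ed
  list(dry_mass_mg = dm, joules = j)
}

#' Annotate a sample set with energy content
#'
#' Computes total joules per observation: measured individuals through the
#' length-mass-energy chain, unmeasured individuals by imputation (mean
#' per-individual energy of measured conspecifics in the same sample, else the
#' taxon-level mean across all samples, else the order-level mean, else the
#' table's `default_joules`). Errors if a counted taxon's energy can not be
#' established at all.
#'
#' @param x a `sample_set`
#' @param table a `conversion_table`
#' @return `x` with a `joules` column added to `$observations` and an
#'   `imputed_n` column counting individuals whose energy was imputed
#' @export
annotate_energy <- function(x, table) {
  obs <- x$observations
  taxa <- x$taxa
  lens <- parse_lengths(obs$lengths_mm)
  n <- nrow(obs)
  measured_j <- numeric(n)     # total J from measured individuals
  measured_n <- integer(n)
  per_ind <- rep(NA_real_, n)  # mean per-individual J among measured
  for (i in seq_len(n)) {
    li <- lens[[i]]
    measured_n[i] <- length(li)
    if (!length(li)) next
    tx <- taxa[match(obs$taxon_id[i], taxa$taxon_id), , drop = FALSE]
    fac <- resolve_factors(tx, table, metric = if (nzchar(obs$metric[i])) obs$metric[i] else NULL)
    if (is.null(fac$regression) || is.null(fac$energy))
      stop("no conversion entry resolves for taxon '", obs$taxon_id[i],
           "' (metric ", obs$metric[i], ")", call. = FALSE)
    e <- individual_energy(li, fac$regression, fac$energy,
                           metric = obs$metric[i])
    measured_j[i] <- sum(e$joules)
    per_ind[i] <- mean(e$joules)
  }

  # imputation pools
  ord <- taxa$order[match(obs$taxon_id, taxa$taxon_id)]
  taxon_mean <- tapply(per_ind, obs$taxon_id, mean, na.rm = TRUE)
  order_mean <- tapply(per_ind, ord, mean, na.rm = TRUE)

  joules <- numeric(n); imputed_n <- integer(n)
  for (i in seq_len(n)) {
    miss <- obs$count[i] - measured_n[i]
    imputed_n[i] <- miss
    if (miss == 0) { joules[i] <- measured_j[i]; next }
    # same sample, same taxon first
    same <- which(obs$sample_id == obs$sample_id[i] &
                    obs$taxon_id == obs$taxon_id[i] & !is.na(per_ind))
    e1 <- if (length(same)) mean(per_ind[same]) else NA_real_
    if (is.na(e1)) e1 <- unname(taxon_mean[obs$taxon_id[i]])
    if (is.na(e1) && !is.na(ord[i])) e1 <- unname(order_mean[ord[i]])
    if (is.na(e1)) {
      tx <- taxa[match(obs$taxon_id[i], taxa$taxon_id), , drop = FALSE]
      fac <- resolve_factors(tx, table)
      if (!is.null(fac$energy) && !is.na(fac$energy$default_joules))
        e1 <- fac$energy$default_joules
    }
    if (is.na(e1))
      stop("no measured individuals and no default energy for taxon '",
           obs$taxon_id[i], "'", call. = FALSE)
    joules[i] <- measured_j[i] + miss * e1
  }
  x$observations$joules <- joules
  x$observations$imputed_n <- imputed_n
  x
}

#' Per-sample energy density
#'
#' Total joules divided by effort, reported as KJ per m2 for areal gears
#' (benthic and fallout), J per m3 for drift, and J per fish for diets.
#'
#' @param x an energy-annotated `sample_set`
#' @return data frame with `sample_id`, `energy_density` and `unit`
#' @export
sample_energy_density <- function(x) {
  obs <- x$observations
  if (!"joules" %in% names(obs))
    stop("run annotate_energy() first", call. = FALSE)
  tot <- tapply(obs$joules, obs$sample_id, sum)
  s <- x$samples
  j <- unname(tot[s$sample_id]); j[is.na(j)] <- 0
  dens <- j / s$effort
  unit <- ifelse(s$effort_unit == "m2", "KJ/m2",
                 ifelse(s$effort_unit == "m3", "J/m3", "J/fish"))
  dens[s$effort_unit == "m2"] <- dens[s$effort_unit == "m2"] / 1000
  data.frame(sample_id = s$sample_id, energy_density = dens, unit = unit,
             stringsAsFactors = FALSE)
}
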