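# Energy-based Index of Relative Importance and prey-selectivity analysis.
#
# IRI = F (N + J): frequency of occurrence percentage times the sum of the
# numerical and energetic percentages, computed per invertebrate order within
# each section x season x period group, and normalised to %IRI (0-100) by the
# group total. Prey energy stands in for the volumetric term of the classic
# index. Plotting diet %IRI against environmental %IRI on log10 axes puts
# positively selected orders above the 1:1 line.

#' Index of Relative Importance table
#'
#' For each group (default section x season x period) and invertebrate order:
#' F = percentage of sampling units containing the order (environmental
#' samples for `source = "environment"`, individual stomachs for
#' `source = "diet"`, empty stomachs excluded from the denominator by
#' default); N = the order's percentage of total individuals; J = its
#' percentage of total joules; IRI = F (N + J); %IRI = 100 IRI / group total.
#'
#' @param x an energy-annotated `sample_set`
#' @param source `"environment"` (non-diet gears) or `"diet"`
#' @param group_by sample metadata columns defining the groups
#' @param rank taxonomic rank for the index (order, as conventional)
#' @param include_empty count empty stomachs in the diet F denominator
#' @return object of class `iri_table`: a data frame with the group columns
#'   plus `taxon`, `F`, `N`, `J`, `IRI`, `pct_IRI`
#' @export
iri <- function(x, source = c("environment", "diet"),
                group_by = c("section", "season", "period"),
                rank = "order", include_empty = FALSE) {
  source <- match.arg(source)
  obs <- x$observations
  if (!"joules" %in% names(obs))
    stop("run annotate_energy() first", call. = FALSE)
  s <- x$samples
  sel <- if (source == "diet") s$gear == "diet" else s$gear != "diet"
  s <- s[sel, , drop = FALSE]
  obs <- obs[obs$sample_id %in% s$sample_id, , drop = FALSE]

  lab <- .taxon_label_at_rank(x$taxa, rank)
  obs$taxon <- lab$label[match(obs$taxon_id, x$taxa$taxon_id)]

  # occurrence unit: environmental sample, or individual stomach for diets
  if (source == "diet") {
    if (is.null(x$fish)) stop("diet IRI requires fish records", call. = FALSE)
    fish <- x$fish[x$fish$sample_id %in% s$sample_id, , drop = FALSE]
    if (!include_empty) fish <- fish[!fish$empty, , drop = FALSE]
    if ("fish_id" %in% names(obs)) {
      obs <- obs[obs$fish_id %in% fish$fish_id, , drop = FALSE]
      obs$unit <- obs$fish_id
      units <- data.frame(unit = fish$fish_id,
                          sample_id = fish$sample_id,
                          stringsAsFactors = FALSE)
    } else {
      obs$unit <- obs$sample_id
      units <- data.frame(unit = fish$fish_id, sample_id = fish$sample_id,
                          stringsAsFactors = FALSE)
      units$unit <- units$sample_id
      units <- unique(units)
    }
  } else {
    obs$unit <- obs$sample_id
    units <- data.frame(unit = s$sample_id, sample_id = s$sample_id,
                        stringsAsFactors = FALSE)
  }
  units <- cbind(units, s[match(units$sample_id, s$sample_id), group_by,
                          drop = FALSE])
  obs <- cbind(obs, s[match(obs$sample_id, s$sample_id), group_by,
                      drop = FALSE])
  gkey_u <- interaction(units[group_by], drop = TRUE, sep = "\r")
  gkey_o <- interaction(obs[group_by], drop = TRUE, sep = "\r")

  res <- list()
  for (g in levels(gkey_u)) {
    u <- units[gkey_u == g, , drop = FALSE]
    o <- obs[as.character(gkey_o) == g & obs$count > 0, , drop = FALSE]
    n_units <- nrow(u)
    tot_n <- sum(o$count); tot_j <- sum(o$joules)
    if (n_units == 0L || (tot_n == 0 && tot_j == 0)) next
    taxa <- sort(unique(o$taxon))
    Fo <- vapply(taxa, function(tx)
      100 * length(unique(o$unit[o$taxon == tx])) / n_units, 0)
    No <- vapply(taxa, function(tx)
      if (tot_n > 0) 100 * sum(o$count[o$taxon == tx]) / tot_n else 0, 0)
    Jo <- vapply(taxa, function(tx)
      if (tot_j > 0) 100 * sum(o$joules[o$taxon == tx]) / tot_j else 0, 0)
    iri_v <- Fo * (No + Jo)
    pct <- if (sum(iri_v) > 0) 100 * iri_v / sum(iri_v) else iri_v
    gk <- u[1L, group_by, drop = FALSE]
    res[[length(res) + 1L]] <-
      cbind(gk[rep(1L, length(taxa)), , drop = FALSE],
            data.frame(taxon = taxa, F = Fo, N = No, J = Jo, IRI = iri_v,
                       pct_IRI = pct, stringsAsFactors = FALSE))
  }
  if (!length(res))
    stop("no non-empty group; IRI undefined", call. = FALSE)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("iri_table", "data.frame"),
            source = source, group_by = group_by)
}

#' Paired log-scale selectivity coordinates
#'
#' Joins environmental and diet %IRI tables by group and order and returns
#' log10 coordinates: x = log10(environmental %IRI), y = log10(diet %IRI), so
#' 100% maps to +2. Percentages below the floor (default 0.1%, including
#' absences from the diet) are set to the fixed display value `floor_value`
#' (default -2), placing them below every unclamped coordinate. Orders
#' consumed by fish but absent from the environmental samples are excluded.
#'
#' @param env_table,diet_table `iri_table`s over the same groups
#' @param floor_pct clamping floor in percent
#' @param floor_value coordinate assigned to clamped percentages
#' @return data frame with the group columns plus `taxon`, `env_pct`,
#'   `diet_pct`, `x`, `y`
#' @export
selectivity_coords <- function(env_table, diet_table, floor_pct = 0.1,
                               floor_value = -2) {
  gb <- attr(env_table, "group_by")
  if (!identical(gb, attr(diet_table, "group_by")))
    stop("environment and diet tables use different group keys", call. = FALSE)
  ke <- interaction(env_table[gb], drop = TRUE, sep = "\r")
  kd <- interaction(diet_table[gb], drop = TRUE, sep = "\r")
  common <- intersect(levels(ke), levels(kd))
  if (!length(common))
    stop("no common group between environment and diet tables", call. = FALSE)
  lf <- floor_value
  res <- list()
  for (g in common) {
    e <- env_table[ke == g, , drop = FALSE]
    dd <- diet_table[kd == g, , drop = FALSE]
    # keep orders present in the environment; fish-only orders are excluded
    taxa <- e$taxon
    dp <- dd$pct_IRI[match(taxa, dd$taxon)]
    dp[is.na(dp)] <- 0
    ep <- e$pct_IRI
    clamp <- function(p) ifelse(p < floor_pct, lf, log10(p))
    gk <- e[rep(1L, length(taxa)), gb, drop = FALSE]
    res[[length(res) + 1L]] <-
      cbind(gk, data.frame(taxon = taxa, env_pct = ep, diet_pct = dp,
                           x = clamp(ep), y = clamp(dp),
                           stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Classify prey selection from log-scale coordinates
#'
#' Orders above the 1:1 line (diet importance exceeding environmental
#' importance) are selected, below it avoided, on it neutral.
#'
#' @param coords output of [selectivity_coords()]
#' @param epsilon half-width of the neutral band around the 1:1 line
#' @return `coords` with a `selection` column
#'   (`"selected"` / `"neutral"` / `"avoided"`)
#' @export
classify_selection <- function(coords, epsilon = 0) {
  sel <- ifelse(coords$y > coords$x + epsilon, "selected",
                ifelse(coords$y < coords$x - epsilon, "avoided", "neutral"))
  coords$selection <- sel
  coords
}
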