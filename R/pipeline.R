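# End-to-end orchestration: ingest or simulate, annotate energy, univariate
# metrics + ANOVA, resemblance, PERMANOVA main + pairwise, ANOSIM pooling
# checks, SIMPER, nMDS + centroid trajectories, IRI selectivity.

#' Pipeline configuration
#'
#' Either `paths` (named list with `taxa`, `samples`, `obs`, `conversions`,
#' optionally `fish`) or `sim` (a [sim_params()] object) must be supplied.
#'
#' @param paths input CSV paths, or `NULL` to simulate
#' @param sim [sim_params()] for simulated input
#' @param transform abundance transformation for resemblance
#'   (square root is the drift convention, fourth root otherwise)
#' @param dummy dummy-species abundance (NULL to disable)
#' @param rank taxonomic rank for assemblage matrices
#' @param design right-hand-side formula for the main PERMANOVA
#' @param pairwise_factor factor for pairwise comparisons
#' @param n_perm permutations
#' @param alpha significance level
#' @param seed mandatory seed, recorded in every output
#' @return a `run_config` list
#' @export
run_config <- function(paths = NULL, sim = NULL,
                       transform = c("sqrt", "fourth_root", "none"),
                       dummy = 0.1, rank = "family",
                       design = ~ period * section,
                       pairwise_factor = "period",
                       n_perm = 999, alpha = 0.05, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (is.null(paths) && is.null(sim))
    stop("either paths or sim must be given", call. = FALSE)
  structure(list(paths = paths, sim = sim, transform = match.arg(transform),
                 dummy = dummy, rank = rank, design = design,
                 pairwise_factor = pairwise_factor,
                 n_perm = n_perm, alpha = alpha, seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the standard sequence on ingested or simulated data: energy
#' annotation; univariate metric tables (group mean +/- SD) with two-way
#' ANOVA; percent declines of section means relative to the baseline period;
#' Bray-Curtis resemblance (dummy species, transformation); PERMANOVA main
#' test and pairwise comparisons; ANOSIM age-class pooling check when fish are
#' present; SIMPER between the baseline and each later period; nMDS and
#' centroid trajectories; and environment/diet IRI selectivity tables. All
#' seeds and permutation counts are recorded in `$log`. The result is a pure
#' function of (inputs, config): rerunning with the same config reproduces it
#' bit for bit.
#'
#' @param config a [run_config()]
#' @return list of class `foodweb_pipeline`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  log <- list(seed = config$seed, n_perm = config$n_perm,
              transform = config$transform, warnings = character())

  # --- stage: input -----------------------------------------------------
  if (!is.null(config$sim)) {
    com <- simulate_community(config$sim)
    com <- simulate_diets(com)
    data <- com$data
    conv <- com$conversions
    truth <- com$truth
    pairing <- com$pairing
  } else {
    pp <- config$paths
    data <- tryCatch(
      load_tables(pp$taxa, pp$samples, pp$obs, pp$fish),
      error = function(e) stop("stage ingest failed: ", conditionMessage(e),
                               call. = FALSE))
    conv <- read_conversions(pp$conversions)
    truth <- NULL; pairing <- NULL
  }

  data <- tryCatch(annotate_energy(data, conv),
                   error = function(e) stop("stage energetics failed: ",
                                            conditionMessage(e), call. = FALSE))

  # --- stage: univariate metrics ---------------------------------------
  env_ids <- data$samples$sample_id[data$samples$gear != "diet"]
  env <- data
  env$samples <- data$samples[data$samples$gear != "diet", , drop = FALSE]
  env$observations <- data$observations[data$observations$sample_id %in% env_ids, ,
                                        drop = FALSE]
  env$fish <- NULL
  sm <- sample_metrics(env)
  metric_tables <- list()
  anova_tables <- list()
  two_way <- length(unique(sm$section)) > 1L && length(unique(sm$period)) > 1L
  for (v in c("numeric_density", "energy_density", "richness",
              "terrestrial_pct")) {
    metric_tables[[v]] <- group_summary(sm[[v]], sm[c("section", "season",
                                                      "period")])
    anova_tables[[v]] <- tryCatch(
      if (two_way) anova_tukey(sm[[v]], sm[c("period", "section")],
                               alpha = config$alpha)
      else anova_tukey(sm[[v]], sm["period"], alpha = config$alpha),
      error = function(e) { log$warnings <<- c(log$warnings, conditionMessage(e)); NULL })
  }

  # headline percent declines of section means vs the baseline period
  base_per <- .PERIODS[.PERIODS %in% sm$period][1L]
  gs <- group_summary(sm$numeric_density, sm[c("section", "period")])
  declines <- list()
  for (sec in unique(gs$section)) {
    pre <- gs$mean[gs$section == sec & gs$period == base_per]
    if (!length(pre) || pre <= 0) next
    for (per in setdiff(unique(gs$period[gs$section == sec]), base_per)) {
      dur <- gs$mean[gs$section == sec & gs$period == per]
      declines[[length(declines) + 1L]] <- data.frame(
        section = sec, period = per,
        percent_decline = percent_change(pre, dur), stringsAsFactors = FALSE)
    }
  }
  declines <- if (length(declines)) do.call(rbind, declines) else NULL

  # --- stage: resemblance ----------------------------------------------
  mat <- build_matrix(env, basis = "count_density", rank = config$rank)
  m <- mat$abund
  if (!is.null(config$dummy)) m <- add_dummy(m, config$dummy)
  m <- transform_abundance(m, config$transform)
  bc <- bray_curtis(m, as = "dissimilarity")

  # --- stage: permanova -------------------------------------------------
  meta <- mat$meta
  vars <- all.vars(config$design)
  design <- config$design
  for (v in vars) if (length(unique(meta[[v]])) < 2L) {
    design <- stats::as.formula(paste("~", setdiff(vars, v)[1L]))
    log$warnings <- c(log$warnings,
                      paste0("factor '", v, "' constant; design reduced"))
  }
  main <- permanova(bc, meta, design, n_perm = config$n_perm,
                    seed = config$seed + 1L)
  pw <- pairwise_permanova(bc, meta[[config$pairwise_factor]],
                           n_perm = config$n_perm, seed = config$seed + 2L,
                           alpha_family = config$alpha)

  # --- stage: anosim pooling checks ------------------------------------
  anosim_checks <- list()
  diet_bc <- NULL; diet_meta <- NULL
  if (!is.null(data$fish)) {
    dmat <- build_matrix(data, basis = "count", rank = config$rank,
                         gear = "diet")
    dm <- dmat$abund
    if (!is.null(config$dummy)) dm <- add_dummy(dm, config$dummy)
    dm <- transform_abundance(dm, "fourth_root")
    diet_bc <- bray_curtis(dm, as = "dissimilarity")
    diet_meta <- dmat$meta
    # age-class pooling: mean fork length per diet sample
    fl <- tapply(data$fish$fork_length_mm, data$fish$sample_id, stats::median)
    ac <- age_class(unname(fl[dmat$meta$sample_id]))
    if (length(unique(ac)) == 2L)
      anosim_checks$age_class <- anosim(diet_bc, ac, n_perm = config$n_perm,
                                        seed = config$seed + 3L)
  }

  # --- stage: simper ----------------------------------------------------
  simper_tables <- list()
  pers <- unique(meta$period)
  if (base_per %in% pers) for (per in setdiff(pers, base_per)) {
    sel <- meta$period %in% c(base_per, per)
    simper_tables[[paste(base_per, per, sep = "_vs_")]] <-
      simper(m[sel, , drop = FALSE], meta$period[sel])
  }

  # --- stage: ordination ------------------------------------------------
  ord <- nmds(bc, k = 2, restarts = 10, seed = config$seed + 4L)
  traj <- centroid_trajectory(bc, meta$section, meta$period)

  # --- stage: selectivity ----------------------------------------------
  iri_env <- NULL; iri_diet <- NULL; selection <- NULL; overlap <- NULL
  if (!is.null(data$fish)) {
    iri_env <- tryCatch(iri(data, "environment"), error = function(e) NULL)
    iri_diet <- tryCatch(iri(data, "diet"), error = function(e) NULL)
    if (!is.null(iri_env) && !is.null(iri_diet)) {
      co <- selectivity_coords(iri_env, iri_diet)
      selection <- classify_selection(co)
    }
    if (!is.null(pairing)) {
      dmat2 <- build_matrix(data, basis = "count", rank = config$rank,
                            gear = "diet")
      events <- pairing[dmat2$meta$sample_id]
      overlap <- diet_availability_overlap(
        dmat2$abund,
        build_matrix(env, basis = "count_density", rank = config$rank)$abund,
        diet_events = unname(events),
        pairing = stats::setNames(unname(pairing), unname(pairing)),
        dummy = config$dummy)
    }
  }

  structure(list(metrics = metric_tables, anova = anova_tables,
                 declines = declines, resemblance = bc,
                 permanova = main, pairwise = pw,
                 anosim_checks = anosim_checks, simper = simper_tables,
                 nmds = ord, trajectories = traj,
                 iri_env = iri_env, iri_diet = iri_diet,
                 selection = selection, overlap = overlap,
                 truth = truth, log = log, config = config),
            class = "foodweb_pipeline")
}

#' @export
print.foodweb_pipeline <- function(x, ...) {
  cat("food-web analysis pipeline (seed", x$log$seed, ")\n")
  cat("\nheadline percent declines vs baseline:\n")
  if (!is.null(x$declines)) print(x$declines, row.names = FALSE, digits = 3)
  cat("\n")
  print(x$permanova)
  invisible(x)
}
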