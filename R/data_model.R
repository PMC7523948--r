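#' @keywords internal
"_PACKAGE"

# -- controlled vocabularies -------------------------------------------------

.SECTIONS <- c("Estuary", "LE", "ME", "TR", "LME")
.SEASONS <- c("spring", "summer")
.PERIODS <- c("Pre", "2012", "2013", "2014")
.HABITATS <- c("mainstem", "floodplain", "estuary", "tributary")
.GEARS <- c("benthic", "fallout", "drift", "diet")
.ORIGINS <- c("aquatic", "terrestrial")
.STAGES <- c("larva", "pupa", "adult", "unknown")
.RANKS <- c("class", "order", "family", "genus", "species")
.METRICS <- c("total_length", "head_capsule_width")

# expected effort unit per gear
.GEAR_UNIT <- c(benthic = "m2", fallout = "m2", drift = "m3", diet = "per_fish")

#' Assemble and validate a sample set
#'
#' A `sample_set` bundles the four long-format tables the package works from:
#' a taxon catalog, sample (collection event) metadata, per-taxon observations,
#' and optionally individual fish records for diet samples. Referential
#' integrity is enforced: every observation must resolve to a catalogued taxon
#' and a known sample.
#'
#' @param taxa data frame with columns `taxon_id`, `class`, `order`, `family`,
#'   `genus`, `species` (trailing ranks may be empty strings), `origin`
#'   (`"aquatic"` or `"terrestrial"`) and `life_stage`
#'   (`"larva"`, `"pupa"`, `"adult"`, `"unknown"`).
#' @param samples data frame with columns `sample_id`, `section`, `season`,
#'   `period`, `habitat`, `gear`, `effort` (positive number) and `effort_unit`
#'   (`"m2"`, `"m3"`, or `"per_fish"`). Benthic and fallout gears are sampled
#'   per m2, drift per m3 of filtered water, diets per fish.
#' @param observations data frame with columns `sample_id`, `taxon_id`,
#'   `count` (non-negative integer), `metric` (body measurement type, may be
#'   empty) and `lengths_mm` (semicolon-separated mm values for measured
#'   individuals, may be empty). The number of measurements can not exceed
#'   `count`.
#' @param fish optional data frame with columns `fish_id`, `sample_id`,
#'   `species`, `fork_length_mm`, `mass_g`, `empty` (logical). The age class
#'   (`YOY` for fork length <= 70 mm, else `1+`) is derived, not stored.
#' @return An object of class `sample_set`.
#' @export
sample_set <- function(taxa, samples, observations, fish = NULL) {
  taxa <- as.data.frame(taxa, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  observations <- as.data.frame(observations, stringsAsFactors = FALSE)
  if (!is.null(fish)) fish <- as.data.frame(fish, stringsAsFactors = FALSE)
  x <- structure(list(taxa = taxa, samples = samples,
                      observations = observations, fish = fish),
                 class = "sample_set")
  validate_sample_set(x)
  x
}

#' @rdname sample_set
#' @param x a `sample_set`
#' @export
validate_sample_set <- function(x) {
  taxa <- x$taxa; samples <- x$samples; obs <- x$observations
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s table is missing column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  need(taxa, c("taxon_id", .RANKS, "origin", "life_stage"), "taxon")
  need(samples, c("sample_id", "section", "season", "period", "habitat",
                  "gear", "effort", "effort_unit"), "sample")
  need(obs, c("sample_id", "taxon_id", "count"), "observation")

  if (anyDuplicated(taxa$taxon_id))
    stop("duplicate taxon_id in catalog: ",
         paste(unique(taxa$taxon_id[duplicated(taxa$taxon_id)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "),
         call. = FALSE)

  .check_enum(taxa$origin, .ORIGINS, "taxon origin")
  .check_enum(taxa$life_stage, .STAGES, "taxon life_stage")
  bad <- apply(taxa[.RANKS], 1L, function(r) all(r == "" | is.na(r)))
  if (any(bad))
    stop("taxon row(s) with empty rank path: ",
         paste(taxa$taxon_id[bad], collapse = ", "), call. = FALSE)

  .check_enum(samples$section, .SECTIONS, "section")
  .check_enum(samples$season, .SEASONS, "season")
  .check_enum(samples$period, .PERIODS, "period")
  .check_enum(samples$habitat, .HABITATS, "habitat")
  .check_enum(samples$gear, .GEARS, "gear")
  if (any(!is.finite(samples$effort) | samples$effort <= 0))
    stop("effort must be a positive number for every sample", call. = FALSE)
  exp_unit <- .GEAR_UNIT[samples$gear]
  off <- samples$effort_unit != exp_unit
  if (any(off))
    stop(sprintf("sample %s: gear '%s' requires effort unit '%s', got '%s'",
                 samples$sample_id[off][1L], samples$gear[off][1L],
                 exp_unit[off][1L], samples$effort_unit[off][1L]), call. = FALSE)

  unk_t <- !(obs$taxon_id %in% taxa$taxon_id)
  if (any(unk_t))
    stop(sprintf("observation row %d references unknown taxon_id '%s'",
                 which(unk_t)[1L], obs$taxon_id[which(unk_t)[1L]]), call. = FALSE)
  unk_s <- !(obs$sample_id %in% samples$sample_id)
  if (any(unk_s))
    stop(sprintf("observation row %d references unknown sample_id '%s'",
                 which(unk_s)[1L], obs$sample_id[which(unk_s)[1L]]), call. = FALSE)
  if (any(!is.finite(obs$count) | obs$count < 0 | obs$count != round(obs$count)))
    stop("observation counts must be non-negative integers", call. = FALSE)
  nm <- vapply(parse_lengths(obs$lengths_mm), length, 1L)
  if (any(nm > obs$count))
    stop(sprintf("observation row %d has more measurements than counted individuals",
                 which(nm > obs$count)[1L]), call. = FALSE)
  lens <- unlist(parse_lengths(obs$lengths_mm))
  if (length(lens) && any(lens <= 0))
    stop("all body measurements must be positive (mm)", call. = FALSE)

  if (!is.null(x$fish)) {
    fish <- x$fish
    need(fish, c("fish_id", "sample_id", "species", "fork_length_mm",
                 "mass_g", "empty"), "fish")
    unk_f <- !(fish$sample_id %in% samples$sample_id)
    if (any(unk_f))
      stop(sprintf("fish row %d references unknown sample_id '%s'",
                   which(unk_f)[1L], fish$sample_id[which(unk_f)[1L]]), call. = FALSE)
    # empty stomach implies no observations for that (diet) sample... checked
    # at the sample level: a diet sample whose fish are all empty carries none.
    empty_s <- tapply(fish$empty, fish$sample_id, all)
    all_empty <- names(empty_s)[empty_s]
    viol <- obs$sample_id %in% all_empty & obs$count > 0
    if (any(viol))
      stop("diet sample(s) flagged all-empty carry prey observations: ",
           paste(unique(obs$sample_id[viol]), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

.check_enum <- function(v, allowed, what) {
  bad <- !(v %in% allowed)
  if (any(bad))
    stop(sprintf("invalid %s '%s' (allowed: %s)", what, v[bad][1L],
                 paste(allowed, collapse = ", ")), call. = FALSE)
}

#' @export
print.sample_set <- function(x, ...) {
  cat("sample_set:", nrow(x$samples), "samples,", nrow(x$taxa), "taxa,",
      nrow(x$observations), "observations")
  if (!is.null(x$fish)) cat(",", nrow(x$fish), "fish")
  cat("\n")
  invisible(x)
}

# split semicolon-separated mm strings into numeric vectors
parse_lengths <- function(s) {
  s[is.na(s)] <- ""
  lapply(strsplit(as.character(s), ";", fixed = TRUE), function(v) {
    v <- v[nzchar(v)]
    as.numeric(v)
  })
}

format_lengths <- function(lst) {
  vapply(lst, function(v) paste(format(v, trim = TRUE, scientific = FALSE),
                                collapse = ";"), "")
}

#' Derived fish age class
#'
#' Young-of-year (YOY) fish are defined by fork length <= 70 mm; larger fish
#' are age 1+.
#'
#' @param fork_length_mm numeric vector of fork lengths in mm
#' @return character vector, `"YOY"` or `"1+"`
#' @export
age_class <- function(fork_length_mm) {
  ifelse(fork_length_mm <= 70, "YOY", "1+")
}

# -- readers / writers -------------------------------------------------------

.read_csv <- function(path, numeric_cols = character(), logical_cols = character()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        na.strings = NULL)
  df[] <- lapply(df, function(v) { v[is.na(v)] <- ""; v })
  for (cc in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- !is.na(df[[cc]]) & nzchar(df[[cc]]) & is.na(v)
    if (any(bad))
      stop(sprintf("%s: malformed numeric '%s' in column '%s' (line %d)",
                   basename(path), df[[cc]][bad][1L], cc,
                   which(bad)[1L] + 1L), call. = FALSE)
    v[!nzchar(df[[cc]])] <- NA_real_
    df[[cc]] <- v
  }
  for (cc in intersect(logical_cols, names(df))) {
    v <- toupper(trimws(df[[cc]])) %in% c("TRUE", "T", "1", "YES")
    df[[cc]] <- v
  }
  df
}

#' Read the long-format input tables
#'
#' Reads the four CSV tables (UTF-8, comma-separated, header row required,
#' empty string for missing) and assembles a validated [sample_set()].
#'
#' @param taxon_path,sample_path,observation_path,fish_path file paths;
#'   `fish_path` is optional.
#' @return a `sample_set`
#' @export
load_tables <- function(taxon_path, sample_path, observation_path,
                        fish_path = NULL) {
  taxa <- .read_csv(taxon_path)
  samples <- .read_csv(sample_path, numeric_cols = "effort")
  obs <- .read_csv(observation_path, numeric_cols = "count")
  if (!"metric" %in% names(obs)) obs$metric <- ""
  if (!"lengths_mm" %in% names(obs)) obs$lengths_mm <- ""
  fish <- NULL
  if (!is.null(fish_path))
    fish <- .read_csv(fish_path, numeric_cols = c("fork_length_mm", "mass_g"),
                      logical_cols = "empty")
  sample_set(taxa, samples, obs, fish)
}

#' Write a sample set back to CSV
#'
#' Inverse of [load_tables()]; round-trips all records through the documented
#' CSV dialect.
#'
#' @param x a `sample_set`
#' @param dir output directory (created if absent)
#' @return invisibly, the paths written
#' @export
write_tables <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(taxa = file.path(dir, "taxa.csv"),
             samples = file.path(dir, "samples.csv"),
             observations = file.path(dir, "observations.csv"))
  utils::write.csv(x$taxa, paths["taxa"], row.names = FALSE, quote = TRUE)
  utils::write.csv(x$samples, paths["samples"], row.names = FALSE, quote = TRUE)
  utils::write.csv(x$observations, paths["observations"], row.names = FALSE,
                   quote = TRUE)
  if (!is.null(x$fish)) {
    paths <- c(paths, fish = file.path(dir, "fish.csv"))
    utils::write.csv(x$fish, paths["fish"], row.names = FALSE, quote = TRUE)
  }
  invisible(paths)
}

# -- assemblage matrices -----------------------------------------------------

# finest identified rank label for each taxon row, e.g. genus when species is
# empty; partially identified taxa keep their coarse label (flagged unresolved
# when a finer rank was requested)
.taxon_label_at_rank <- function(taxa, rank) {
  if (rank == "finest") {
    lab <- rep("", nrow(taxa))
    for (r in .RANKS) {
      has <- nzchar(taxa[[r]])
      lab[has] <- taxa[[r]][has]
    }
    return(list(label = lab, unresolved = rep(FALSE, nrow(taxa))))
  }
  ri <- match(rank, .RANKS)
  lab <- taxa[[rank]]
  unresolved <- !nzchar(lab)
  # taxa observed only at a coarser rank keep their own (finest) label
  if (any(unresolved)) {
    fin <- .taxon_label_at_rank(taxa, "finest")$label
    lab[unresolved] <- fin[unresolved]
  }
  list(label = lab, unresolved = unresolved)
}

#' Build a samples-by-taxa assemblage matrix
#'
#' Aggregates long-format observations into a wide abundance matrix at a
#' stated taxonomic rank and basis. Density bases divide by sampling effort;
#' energy bases require joules annotation from [annotate_energy()]. Rows with
#' zero total abundance are retained.
#'
#' Taxa identified only at a rank coarser than `rank` (e.g. unidentifiable
#' fragments kept at order level) are retained as their own column under
#' their finest label and flagged in `attr(, "unresolved")`.
#'
#' @param x a `sample_set`
#' @param basis one of `"count"`, `"count_density"`, `"energy"`,
#'   `"energy_density"`
#' @param rank `"class"`, `"order"`, `"family"`, `"genus"`, `"species"` or
#'   `"finest"`
#' @param gear optional gear filter (e.g. `"drift"`)
#' @return an object of class `assemblage`: a list with the abundance matrix
#'   (`abund`), row metadata (`meta`), and the `basis`, `rank` and `unit` tags
#' @export
build_matrix <- function(x, basis = c("count", "count_density", "energy",
                                      "energy_density"),
                         rank = "family", gear = NULL) {
  basis <- match.arg(basis)
  stopifnot(rank %in% c(.RANKS, "finest"))
  samples <- x$samples
  if (!is.null(gear)) samples <- samples[samples$gear %in% gear, , drop = FALSE]
  obs <- x$observations[x$observations$sample_id %in% samples$sample_id, ,
                        drop = FALSE]
  if (grepl("^energy", basis) && !"joules" %in% names(obs))
    stop("energy basis requires annotate_energy() first", call. = FALSE)

  lab <- .taxon_label_at_rank(x$taxa, rank)
  tl <- lab$label[match(obs$taxon_id, x$taxa$taxon_id)]
  cols <- sort(unique(lab$label))
  m <- matrix(0, nrow(samples), length(cols),
              dimnames = list(samples$sample_id, cols))
  val <- if (grepl("^energy", basis)) obs$joules else obs$count
  if (nrow(obs)) {
    agg <- tapply(val, list(obs$sample_id, tl), sum)
    ri <- match(rownames(agg), rownames(m))
    ci <- match(colnames(agg), colnames(m))
    agg[is.na(agg)] <- 0
    m[ri, ci] <- agg
  }
  # drop taxa never observed in the selected samples
  m <- m[, colSums(m) > 0 | colnames(m) %in% tl, drop = FALSE]

  unit <- "count"
  if (basis %in% c("count_density", "energy_density")) {
    eu <- unique(samples$effort_unit)
    if (length(eu) > 1L)
      stop("density basis requires a single effort unit across samples; got: ",
           paste(eu, collapse = ", "), call. = FALSE)
    m <- m / samples$effort
    if (basis == "count_density") {
      unit <- paste0("count/", eu)
    } else {
      # energy density conventions: KJ/m2 for areal gears, J/m3 for drift
      if (eu == "m2") { m <- m / 1000; unit <- "KJ/m2" } else
        unit <- if (eu == "m3") "J/m3" else "J/fish"
    }
  } else if (basis == "energy") unit <- "J"

  unresolved <- colnames(m) %in% lab$label[lab$unresolved]
  structure(list(abund = m,
                 meta = samples,
                 basis = basis, rank = rank, unit = unit,
                 unresolved = colnames(m)[unresolved]),
            class = "assemblage")
}

#' @export
print.assemblage <- function(x, ...) {
  cat(sprintf("assemblage matrix: %d samples x %d taxa (rank %s, basis %s, unit %s)\n",
              nrow(x$abund), ncol(x$abund), x$rank, x$basis, x$unit))
  if (length(x$unresolved))
    cat("unresolved (coarser-rank) columns:",
        paste(x$unresolved, collapse = ", "), "\n")
  invisible(x)
}

#' Pool sections into a combined label
#'
#' Relabels row metadata only; abundance values are untouched. Used e.g. to
#' pool the two mainstem river sections into one category in seasons with low
#' replication.
#'
#' @param x an `assemblage`
#' @param mapping named character vector, `c(LE = "LME", ME = "LME")`
#' @param seasons optional: restrict the relabeling to these seasons
#' @return the relabeled `assemblage`
#' @export
pool_sections <- function(x, mapping, seasons = NULL) {
  stopifnot(inherits(x, "assemblage"))
  sec <- x$meta$section
  hit <- sec %in% names(mapping)
  if (!is.null(seasons)) hit <- hit & x$meta$season %in% seasons
  collide <- sec %in% mapping & !hit
  if (any(collide) && any(hit))
    stop("pooled label collides with an existing unpooled section: ",
         paste(unique(sec[collide]), collapse = ", "), call. = FALSE)
  sec[hit] <- mapping[sec[hit]]
  x$meta$section <- sec
  x
}

#' Export an assemblage matrix as TSV
#'
#' Sample metadata columns come first, then one column per taxon.
#'
#' @param x an `assemblage`
#' @param path output file
#' @export
write_matrix <- function(x, path) {
  out <- cbind(x$meta, as.data.frame(x$abund, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
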