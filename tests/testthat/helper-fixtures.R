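# Fixtures built in code: tiny hand-written tables and random generators.

tiny_taxa <- function() {
  data.frame(
    taxon_id = c("baetis", "chiro", "formica"),
    class = "Insecta",
    order = c("Ephemeroptera", "Diptera", "Hymenoptera"),
    family = c("Baetidae", "Chironomidae", "Formicidae"),
    genus = c("Baetis", "", ""),
    species = "",
    origin = c("aquatic", "aquatic", "terrestrial"),
    life_stage = c("larva", "larva", "adult"),
    stringsAsFactors = FALSE)
}

tiny_samples <- function() {
  data.frame(
    sample_id = c("s1", "s2"),
    section = c("LE", "LE"),
    season = "summer",
    period = c("Pre", "2013"),
    habitat = "mainstem",
    gear = "drift",
    effort = c(2, 4),
    effort_unit = "m3",
    stringsAsFactors = FALSE)
}

tiny_obs <- function() {
  data.frame(
    sample_id = c("s1", "s1", "s2"),
    taxon_id = c("baetis", "formica", "chiro"),
    count = c(3, 1, 4),
    metric = "total_length",
    lengths_mm = c("3;4;5", "6", "2;2;3;3"),
    stringsAsFactors = FALSE)
}

tiny_set <- function() sample_set(tiny_taxa(), tiny_samples(), tiny_obs())

tiny_conversions <- function() {
  conversion_table(data.frame(
    class = c("Insecta", "Insecta", "Insecta"),
    order = c("", "Ephemeroptera", ""),
    family = c("", "Baetidae", ""),
    genus = "", species = "",
    life_stage = c("unknown", "larva", "unknown"),
    metric = "total_length",
    a = c(0.005, 0.003, 0.005), b = c(2.8, 2.7, 2.8),
    ED = c(23, 20, 23), pDM = c(0.25, 0.2, 0.25),
    ed_basis = "dry", default_joules = c(5, NA, 5),
    stringsAsFactors = FALSE)[c(1, 2), ])
}

# one-group sample set with fixed per-order counts and joules, for IRI tests
sel_fixture <- function(counts, joules, n_samples = 4) {
  orders <- names(counts)
  taxa <- data.frame(taxon_id = paste0("t_", orders), class = "Insecta",
                     order = orders, family = paste0(orders, "idae"),
                     genus = "", species = "", origin = "aquatic",
                     life_stage = "unknown", stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = paste0("s", seq_len(n_samples)),
                        section = "LE", season = "summer", period = "Pre",
                        habitat = "mainstem", gear = "drift", effort = 1,
                        effort_unit = "m3", stringsAsFactors = FALSE)
  obs <- data.frame(sample_id = "s1", taxon_id = paste0("t_", orders),
                    count = unname(counts), metric = "", lengths_mm = "",
                    stringsAsFactors = FALSE)
  x <- sample_set(taxa, samples, obs)
  x$observations$joules <- unname(joules)
  x$observations$imputed_n <- 0L
  x
}

# random abundance matrix (counts), no all-zero rows unless allowed
random_counts <- function(n, p, lambda = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n * p, lambda), n, p,
              dimnames = list(paste0("s", seq_len(n)), paste0("t", seq_len(p))))
  zero <- rowSums(m) == 0
  m[zero, 1L] <- 1
  m
}

# independent Bray-Curtis oracle for one pair
brute_bray_sim <- function(a, b) 100 * (1 - sum(abs(a - b)) / sum(a + b))

# independent one-way pseudo-F from raw distance sums (no Gower matrices)
brute_pseudoF <- function(D, groups) {
  n <- nrow(D)
  lev <- unique(groups)
  a <- length(lev)
  sst <- sum(D[lower.tri(D)]^2) / n
  ssw <- 0
  for (g in lev) {
    idx <- which(groups == g)
    sub <- D[idx, idx, drop = FALSE]
    ssw <- ssw + sum(sub[lower.tri(sub)]^2) / length(idx)
  }
  ssa <- sst - ssw
  (ssa / (a - 1)) / (ssw / (n - a))
}

# independent ANOSIM R via explicit rank bookkeeping
brute_anosim_R <- function(D, groups) {
  n <- nrow(D)
  rk <- matrix(0, n, n)
  rk[lower.tri(rk)] <- rank(D[lower.tri(D)])
  rb <- c(); rw <- c()
  for (i in 2:n) for (j in 1:(i - 1)) {
    if (groups[i] == groups[j]) rw <- c(rw, rk[i, j]) else rb <- c(rb, rk[i, j])
  }
  M <- n * (n - 1) / 2
  (mean(rb) - mean(rw)) / (M / 2)
}

# exhaustive-scan oracle for conversion-table resolution: longest matching
# prefix, preferring the exact life stage over "unknown"
brute_resolve <- function(taxon, tab, field) {
  ranks <- c("class", "order", "family", "genus", "species")
  best <- NULL; best_key <- NULL
  for (i in seq_len(nrow(tab))) {
    e <- tab[i, ]
    if (is.na(e[[field]])) next
    d <- max(c(0, which(nzchar(unlist(e[ranks])))))
    ok <- TRUE
    for (r in seq_len(d)) if (e[[ranks[r]]] != taxon[[ranks[r]]]) ok <- FALSE
    if (!ok) next
    if (!e$life_stage %in% c(taxon$life_stage, "unknown")) next
    stage_pref <- as.integer(e$life_stage == taxon$life_stage)
    key <- c(d, stage_pref)
    if (is.null(best) || key[1] > best_key[1] ||
        (key[1] == best_key[1] && key[2] > best_key[2])) {
      best <- e; best_key <- key
    }
  }
  best
}
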