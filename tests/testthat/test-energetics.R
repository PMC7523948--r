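test_that("individual_energy follows the power law and the wet-mass path", {
  reg <- data.frame(a = 1, b = 2, metric = "total_length")
  en <- data.frame(ED = 1, ed_basis = "dry", pDM = NA_real_)
  expect_equal(individual_energy(3, reg, en)$dry_mass_mg, 9)
  expect_equal(individual_energy(3, reg, en)$joules, 9)

  reg2 <- data.frame(a = 0.001, b = 3, metric = "total_length")
  en2 <- data.frame(ED = 23, ed_basis = "dry", pDM = 0.2)
  expect_equal(individual_energy(10, reg2, en2)$joules, 23)

  # wet-mass basis: wet mass = DM / pDM
  en3 <- data.frame(ED = 5, ed_basis = "wet", pDM = 0.2)
  expect_equal(individual_energy(10, reg2, en3)$joules, (1 / 0.2) * 5)

  expect_error(individual_energy(0, reg, en), "positive")
  expect_error(individual_energy(3, reg, en, metric = "head_capsule_width"),
               "does not match")

  # log-space oracle over random coefficients
  set.seed(7)
  for (i in 1:200) {
    a <- exp(runif(1, -7, -2)); b <- runif(1, 1.5, 3.5)
    ED <- runif(1, 5, 40); L <- runif(1, 0.5, 50)
    got <- individual_energy(L, data.frame(a = a, b = b, metric = ""),
                             data.frame(ED = ED, ed_basis = "dry",
                                        pDM = NA_real_))$joules
    want <- exp(log(a) + b * log(L) + log(ED))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("resolve_factors walks the taxonomy and matches an exhaustive scan", {
  tab <- tiny_conversions()
  baetis <- tiny_taxa()[1, ]   # Baetidae larva: family entry wins
  f <- resolve_factors(baetis, tab, metric = "total_length")
  expect_equal(f$regression$a, 0.003)
  expect_equal(f$regression_rank, "family")
  formica <- tiny_taxa()[3, ]  # only the class default matches
  f2 <- resolve_factors(formica, tab, metric = "total_length")
  expect_equal(f2$regression$a, 0.005)
  expect_equal(f2$regression_rank, "class")
  expect_equal(f2$energy$default_joules, 5)

  # exact life stage beats stage "unknown" at the same rank
  tab2 <- conversion_table(data.frame(
    class = "Insecta", order = "Diptera", family = "", genus = "", species = "",
    life_stage = c("unknown", "larva"), metric = "total_length",
    a = c(0.004, 0.006), b = 2.8, ED = 23, pDM = 0.25, ed_basis = "dry",
    default_joules = NA_real_, stringsAsFactors = FALSE))
  chiro <- tiny_taxa()[2, ]
  expect_equal(resolve_factors(chiro, tab2)$regression$a, 0.006)

  # randomized tables: resolution equals the brute-force exhaustive scan
  set.seed(11)
  orders <- c("O1", "O2"); fams <- c("F1", "F2"); gens <- c("G1", "G2")
  for (rep in 1:100) {
    depth <- sample(1:4, 6, replace = TRUE)
    rows <- lapply(depth, function(d) {
      data.frame(class = "C1",
                 order = if (d >= 2) sample(orders, 1) else "",
                 family = if (d >= 3) sample(fams, 1) else "",
                 genus = if (d >= 4) sample(gens, 1) else "",
                 species = "",
                 life_stage = sample(c("larva", "unknown"), 1),
                 metric = "total_length",
                 a = runif(1, 0.001, 0.01), b = runif(1, 2, 3),
                 ED = runif(1, 10, 30), pDM = 0.25, ed_basis = "dry",
                 default_joules = NA_real_, stringsAsFactors = FALSE)
    })
    df <- unique(do.call(rbind, rows))
    # drop duplicate keys so the expected winner is unambiguous
    key <- do.call(paste, df[c("class", "order", "family", "genus", "species",
                               "life_stage")])
    df <- df[!duplicated(key), , drop = FALSE]
    tabr <- conversion_table(df)
    taxon <- list(class = "C1", order = sample(orders, 1),
                  family = sample(fams, 1), genus = sample(gens, 1),
                  species = "", life_stage = "larva")
    got <- resolve_factors(taxon, tabr)
    want <- brute_resolve(taxon, tabr, "a")
    if (is.null(want)) {
      expect_null(got$regression)
    } else {
      expect_equal(got$regression$a, want$a)
      expect_equal(got$regression$life_stage, want$life_stage)
    }
  }
})

test_that("resolution is independent of conversion-table row order", {
  df <- data.frame(
    class = "Insecta",
    order = c("", "Ephemeroptera", "Ephemeroptera"),
    family = c("", "", "Baetidae"), genus = "", species = "",
    life_stage = "unknown", metric = "total_length",
    a = c(0.005, 0.004, 0.003), b = 2.8, ED = c(23, 21, 20), pDM = 0.25,
    ed_basis = "dry", default_joules = NA_real_, stringsAsFactors = FALSE)
  baetis <- tiny_taxa()[1, ]
  for (perm in list(1:3, 3:1, c(2, 3, 1))) {
    f <- resolve_factors(baetis, conversion_table(df[perm, ]))
    expect_equal(f$regression$a, 0.003)
    expect_equal(f$energy$ED, 20)
  }
})

test_that("annotate_energy sums measured individuals and imputes the rest", {
  x <- annotate_energy(tiny_set(), tiny_conversions())
  obs <- x$observations
  # hand-computed: baetis lengths 3,4,5 via family entry a=.003 b=2.7 ED=20
  want_baetis <- sum(0.003 * c(3, 4, 5)^2.7 * 20)
  expect_equal(obs$joules[1], want_baetis, tolerance = 1e-12)
  # formica length 6 via class default a=.005 b=2.8 ED=23
  expect_equal(obs$joules[2], 0.005 * 6^2.8 * 23, tolerance = 1e-12)
  expect_equal(obs$imputed_n, c(0L, 0L, 0L))

  # unmeasured individuals take the same-sample conspecific mean
  obs2 <- tiny_obs(); obs2$count[1] <- 5  # 3 measured, 2 imputed
  x2 <- annotate_energy(sample_set(tiny_taxa(), tiny_samples(), obs2),
                        tiny_conversions())
  per_ind <- mean(0.003 * c(3, 4, 5)^2.7 * 20)
  expect_equal(x2$observations$joules[1], want_baetis + 2 * per_ind,
               tolerance = 1e-12)
  expect_equal(x2$observations$imputed_n[1], 2L)

  # no measurements anywhere falls through to default_joules
  obs3 <- tiny_obs(); obs3$lengths_mm[2] <- ""
  x3 <- annotate_energy(sample_set(tiny_taxa(), tiny_samples(), obs3),
                        tiny_conversions())
  expect_equal(x3$observations$joules[2], 5) # 1 individual x default 5 J

  # and errors when even the default is missing
  tab_nd <- tiny_conversions()
  tab_nd$default_joules <- NA_real_
  expect_error(annotate_energy(sample_set(tiny_taxa(), tiny_samples(), obs3),
                               conversion_table(as.data.frame(tab_nd))),
               "no measured individuals and no default")
})

test_that("annotated totals match a per-individual brute-force sum", {
  set.seed(23)
  com <- simulate_community(sim_params(n_taxa_aquatic = 5,
                                       n_taxa_terrestrial = 2,
                                       sections = "LE", periods = "Pre",
                                       n_samples = c(LE = 4), seed = 23))
  x <- annotate_energy(com$data, com$conversions)
  obs <- x$observations
  for (i in seq_len(nrow(obs))) {
    tx <- x$taxa[match(obs$taxon_id[i], x$taxa$taxon_id), ]
    fac <- resolve_factors(tx, com$conversions, metric = obs$metric[i])
    lens <- parse_lengths(obs$lengths_mm[i])[[1]]
    if (length(lens) < obs$count[i]) next # imputation covered above
    want <- sum(fac$regression$a * lens^fac$regression$b * fac$energy$ED)
    expect_equal(obs$joules[i], want, tolerance = 1e-9)
  }
  # energy is monotone in body length
  tx <- x$taxa[1, ]
  fac <- resolve_factors(tx, com$conversions, metric = "total_length")
  e <- vapply(c(1, 2, 5, 10, 20),
              function(L) individual_energy(L, fac$regression, fac$energy)$joules, 0)
  expect_true(all(diff(e) > 0))
})
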