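test_that("sample_metrics computes densities, richness and terrestrial share", {
  x <- annotate_energy(tiny_set(), tiny_conversions())
  sm <- sample_metrics(x)
  expect_equal(sm$numeric_density, c(4 / 2, 4 / 4))
  expect_equal(sm$richness, c(2, 1))
  # s1: 1 terrestrial of 4 individuals
  expect_equal(sm$terrestrial_pct, c(25, 0))
  expect_false(any(sm$zero_total))
  # energy density agrees with sample_energy_density (J/m3 for drift)
  expect_equal(sm$energy_density, sample_energy_density(x)$energy_density)

  # zero-total sample flagged, terrestrial share defined as 0
  samples <- rbind(tiny_samples(),
                   data.frame(sample_id = "s3", section = "TR",
                              season = "summer", period = "Pre",
                              habitat = "tributary", gear = "drift",
                              effort = 1, effort_unit = "m3"))
  x2 <- annotate_energy(sample_set(tiny_taxa(), samples, tiny_obs()),
                        tiny_conversions())
  sm2 <- sample_metrics(x2)
  expect_true(sm2$zero_total[sm2$sample_id == "s3"])
  expect_equal(sm2$terrestrial_pct[sm2$sample_id == "s3"], 0)
})

test_that("group_summary matches a two-pass oracle; singletons give NA sd", {
  g <- group_summary(c(2, 4), data.frame(a = c("x", "x")))
  expect_equal(g$mean, 3)
  expect_equal(g$sd, sqrt(2))
  g1 <- group_summary(5, data.frame(a = "x"))
  expect_true(is.na(g1$sd))

  set.seed(5)
  v <- rnorm(60)
  by <- data.frame(s = sample(c("LE", "ME"), 60, TRUE),
                   p = sample(c("Pre", "2012", "2013"), 60, TRUE))
  gs <- group_summary(v, by)
  for (i in seq_len(nrow(gs))) {
    sel <- by$s == gs$s[i] & by$p == gs$p[i]
    expect_equal(gs$n[i], sum(sel))
    mu <- sum(v[sel]) / sum(sel)
    expect_equal(gs$mean[i], mu, tolerance = 1e-12)
    expect_equal(gs$sd[i], sqrt(sum((v[sel] - mu)^2) / (sum(sel) - 1)),
                 tolerance = 1e-12)
  }
  expect_equal(sum(gs$n), 60)
})

test_that("percent_change reproduces worked values and basic properties", {
  expect_equal(percent_change(9.27, 1.36, digits = 0), 85)
  expect_equal(percent_change(11.09, 6.14, digits = 0), 45)
  expect_equal(percent_change(9.27, 0.33, digits = 0), 96)
  expect_equal(percent_change(21.60, 1.56, digits = 0), 93)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(5, 0), 100)
  expect_equal(percent_change(5, 10), -100)
  expect_error(percent_change(0, 1), "non-positive")
  # strictly decreasing in the during mean
  set.seed(2)
  pre <- runif(1, 1, 10)
  dd <- sort(runif(10, 0, 20))
  expect_true(all(diff(percent_change(pre, dd)) < 0))
})

test_that("anova_tukey matches a textbook sum-of-squares oracle", {
  set.seed(13)
  # balanced 2x3, strong section effect
  fac <- expand.grid(period = c("Pre", "2012", "2013"),
                     section = c("LE", "TR"), rep = 1:6,
                     stringsAsFactors = FALSE)[, 1:2]
  y <- rnorm(nrow(fac)) + ifelse(fac$section == "LE", 3, 0)
  fit <- anova_tukey(y, fac)
  tab <- fit$table

  # textbook decomposition for the balanced two-way crossed design
  cellm <- tapply(y, fac, mean)
  gm <- mean(y)
  n_cell <- nrow(fac) / length(cellm)
  a_m <- rowMeans(cellm); b_m <- colMeans(cellm)
  ss_a <- n_cell * ncol(cellm) * sum((a_m - gm)^2)
  ss_b <- n_cell * nrow(cellm) * sum((b_m - gm)^2)
  ss_ab <- n_cell * sum((sweep(sweep(cellm, 1, a_m), 2, b_m) + gm)^2)
  ss_res <- sum((y - cellm[cbind(fac$period, fac$section)])^2)
  df_res <- nrow(fac) - length(cellm)
  expect_equal(tab$ss[tab$term == "period"], ss_a, tolerance = 1e-9)
  expect_equal(tab$ss[tab$term == "section"], ss_b, tolerance = 1e-9)
  expect_equal(tab$ss[tab$term == "period:section"], ss_ab, tolerance = 1e-9)
  expect_equal(tab$F[tab$term == "section"],
               (ss_b / 1) / (ss_res / df_res), tolerance = 1e-9)
  expect_true("section" %in% names(fit$tukey))

  # transforms are applied before fitting
  f_log <- anova_tukey(y - min(y), fac, transform = "log10")
  man <- anova_tukey(log10(y - min(y) + 1), fac)
  expect_equal(f_log$table$F, man$table$F, tolerance = 1e-12)
})

test_that("Tukey letters separate clearly different groups", {
  set.seed(3)
  fac <- data.frame(period = rep(c("Pre", "2012", "2013"), each = 8))
  y <- rnorm(24, sd = 0.1) + rep(c(0, 5, 5), each = 8)
  fit <- anova_tukey(y, fac)
  lt <- fit$tukey$period$letters
  expect_false(lt["Pre"] == lt["2012"])
  expect_equal(lt["2012"], lt["2013"], ignore_attr = TRUE)

  # all-equal groups share one letter via a direct p-matrix
  pm <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unname(cld_letters(pm)), rep("a", 3))
  pm2 <- pm; pm2["a", "c"] <- pm2["c", "a"] <- 0.001
  l2 <- cld_letters(pm2)
  expect_false(any(strsplit(l2["a"], "")[[1]] %in% strsplit(l2["c"], "")[[1]]))
})

test_that("diet_metrics keys observations to fish and zeroes empty stomachs", {
  set.seed(31)
  com <- simulate_diets(simulate_community(
    sim_params(n_taxa_aquatic = 5, n_taxa_terrestrial = 2, sections = "LE",
               periods = "Pre", n_samples = c(LE = 3), seed = 31)))
  x <- annotate_energy(com$data, com$conversions)
  dm <- diet_metrics(x)
  expect_equal(nrow(dm), nrow(x$fish))
  expect_true(all(dm$prey_items[dm$empty] == 0))
  expect_true(all(dm$prey_energy_kj[dm$empty] == 0))
  # totals agree with a direct per-fish tally
  obs <- x$observations[!is.na(x$observations$fish_id), ]
  for (fid in sample(dm$fish_id[!dm$empty], 5)) {
    expect_equal(dm$prey_items[dm$fish_id == fid],
                 sum(obs$count[obs$fish_id == fid]))
    expect_equal(dm$prey_energy_kj[dm$fish_id == fid],
                 sum(obs$joules[obs$fish_id == fid]) / 1000, tolerance = 1e-12)
  }
  expect_true(all(dm$age_class %in% c("YOY", "1+")))
  expect_equal(age_class(c(70, 70.1)), c("YOY", "1+"))
})
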