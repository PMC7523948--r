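test_that("transformations and the dummy species behave as documented", {
  m <- matrix(c(16, 0, 81, 1), 2, 2, dimnames = list(c("a", "b"), c("t1", "t2")))
  expect_equal(transform_abundance(m, "sqrt"), sqrt(m))
  expect_equal(transform_abundance(m, "fourth_root"), m^0.25)
  set.seed(9)
  r <- matrix(runif(20, 0, 50), 4, 5)
  expect_equal(transform_abundance(r, "fourth_root"),
               sqrt(sqrt(r)), tolerance = 1e-12)
  expect_error(transform_abundance(matrix(-1, 1, 2), "sqrt"), "negative")

  d <- add_dummy(m, 0.1)
  expect_equal(ncol(d), 3)
  expect_true(all(d[, "dummy"] == 0.1))
  expect_identical(drop_dummy(d), m)
  expect_error(add_dummy(d), "already present")
})

test_that("bray_curtis reproduces hand values, bounds and identities", {
  two <- rbind(a = c(1, 2, 3), b = c(2, 2, 2))
  s <- bray_curtis(two)
  expect_equal(s["a", "b"], 100 * (1 - 2 / 12)) # = 83.33...
  expect_equal(unclass(s)["a", "b"], 250 / 3, tolerance = 1e-12)

  expect_equal(bray_curtis(rbind(a = 1:3, b = 1:3))["a", "b"], 100)
  expect_equal(bray_curtis(rbind(a = c(1, 0), b = c(0, 2)))["a", "b"], 0)
  # scale invariance
  expect_equal(unclass(bray_curtis(two)), unclass(bray_curtis(7 * two)))

  # undefined all-zero pair errors, names the samples, dummy rescues it
  z <- rbind(s1 = c(0, 0), s2 = c(0, 0), s3 = c(1, 2))
  expect_error(bray_curtis(z), "all-zero pair \\(s1, s2\\)")
  zd <- bray_curtis(add_dummy(z))
  expect_equal(zd["s1", "s2"], 100) # two empty samples are identical

  set.seed(17)
  m <- random_counts(7, 10)
  sim <- bray_curtis(m, as = "similarity")
  dis <- bray_curtis(m, as = "dissimilarity")
  expect_true(all(sim >= 0 & sim <= 100))
  expect_equal(unclass(sim) + unclass(dis),
               matrix(100, 7, 7, dimnames = dimnames(sim)),
               ignore_attr = TRUE)
  expect_equal(diag(unclass(dis)), rep(0, 7), ignore_attr = TRUE)
  expect_equal(unclass(dis), t(unclass(dis)))
  # each pair against the scalar oracle
  for (i in 1:6) for (j in (i + 1):7)
    expect_equal(unclass(sim)[i, j], brute_bray_sim(m[i, ], m[j, ]),
                 tolerance = 1e-12)
})

test_that("bray_curtis agrees with the vegan reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(29)
  for (rep in 1:5) {
    m <- random_counts(8, 12)
    ours <- as_dissimilarity(bray_curtis(m, as = "dissimilarity")) / 100
    ref <- as.matrix(vegan::vegdist(m, method = "bray"))
    expect_equal(ours, ref, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("diet-availability overlap standardizes, pairs and ranks sensibly", {
  env <- rbind(e1 = c(10, 30, 60), e2 = c(5, 5, 90))
  colnames(env) <- c("t1", "t2", "t3")
  # two fish whose mean standardized diet equals e1's composition exactly
  diet <- rbind(f1 = c(1, 3, 6), f2 = c(2, 6, 12))
  colnames(diet) <- colnames(env)
  ov <- diet_availability_overlap(diet, env, diet_events = c("d1", "d1"),
                                  pairing = c(d1 = "e1"))
  expect_equal(ov$similarity, 100)

  # disjoint compositions, no dummy: similarity exactly 0
  diet2 <- rbind(f1 = c(1, 0, 0))
  colnames(diet2) <- colnames(env)
  env2 <- rbind(e1 = c(0, 1, 1)); colnames(env2) <- colnames(env)
  ov2 <- diet_availability_overlap(diet2, env2, "d1", c(d1 = "e1"),
                                   dummy = NULL)
  expect_equal(ov2$similarity, 0)

  # unpaired events are skipped with a message
  expect_message(
    ov3 <- diet_availability_overlap(diet, env, c("d1", "dX"),
                                     c(d1 = "e1")),
    "no paired environmental sample")
  expect_equal(nrow(ov3), 1)

  # fish feeding in proportion to availability overlap more than skewed
  # feeders, on average over simulated events
  base <- sim_params(n_taxa_aquatic = 6, n_taxa_terrestrial = 2,
                     sections = "LE", periods = c("Pre", "2013"),
                     n_samples = c(LE = 6), seed = 77)
  com <- simulate_community(base)
  run_overlap <- function(w, seed) {
    p2 <- base; p2$selectivity_weights <- w
    com2 <- com; com2$params <- p2
    com2 <- simulate_diets(com2, seed = seed)
    d <- build_matrix(com2$data, basis = "count", rank = "family",
                      gear = "diet")
    e <- build_matrix(com2$data, basis = "count_density", rank = "family",
                      gear = "drift")
    ev <- com2$pairing[d$meta$sample_id]
    mean(diet_availability_overlap(
      d$abund, e$abund, unname(ev),
      stats::setNames(unname(com2$pairing), unname(com2$pairing)))$similarity)
  }
  ords <- unique(com$data$taxa$order)
  w_flat <- stats::setNames(rep(1, length(ords)), ords)
  w_skew <- w_flat; w_skew[1] <- 50
  expect_gt(run_overlap(w_flat, 101), run_overlap(w_skew, 101))
})

test_that("centroid distances match an explicit eigen-embedding oracle", {
  set.seed(37)
  m <- random_counts(10, 8)
  D <- as_dissimilarity(bray_curtis(m, as = "dissimilarity"))
  groups <- rep(c("g1", "g2", "g3"), c(3, 3, 4))
  cm <- centroid_matrix(D, groups)

  # oracle: full eigendecomposition of the Gower matrix, signed squared
  # distances between group centroids across all axes
  G <- foodwebkit:::gower_center(D)
  ee <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- abs(ee$values) > 1e-9
  X <- ee$vectors[, keep, drop = FALSE] %*% diag(sqrt(abs(ee$values[keep])))
  sgn <- sign(ee$values[keep])
  for (a in c("g1", "g2")) for (b in setdiff(unique(groups), a)) {
    ca <- colMeans(X[groups == a, , drop = FALSE])
    cb <- colMeans(X[groups == b, , drop = FALSE])
    d2 <- sum(sgn * (ca - cb)^2)
    expect_equal(unclass(cm)[a, b], sqrt(max(0, d2)), tolerance = 1e-8)
  }

  # duplicated composition gives a zero centroid distance
  m2 <- rbind(m[1:2, ], m[1:2, ])
  rownames(m2) <- paste0("s", 1:4)
  D2 <- as_dissimilarity(bray_curtis(m2, as = "dissimilarity"))
  cm2 <- centroid_matrix(D2, c("a", "a", "b", "b"))
  expect_equal(unclass(cm2)["a", "b"], 0, tolerance = 1e-8)

  # singleton groups: centroid distance is the sample dissimilarity
  cm3 <- centroid_matrix(D[1:2, 1:2], c("x", "y"))
  expect_equal(unclass(cm3)["x", "y"], D[1, 2], tolerance = 1e-8)
})

test_that("centroid_trajectory orders periods and returns step lengths", {
  set.seed(43)
  m <- random_counts(12, 6)
  D <- as_dissimilarity(bray_curtis(m, as = "dissimilarity"))
  section <- rep("LE", 12)
  period <- rep(c("2013", "Pre", "2012"), each = 4) # unordered on purpose
  tr <- centroid_trajectory(D, section, period)
  expect_equal(tr$LE$periods, c("Pre", "2012", "2013"))
  expect_length(tr$LE$step, 2)
  cm <- centroid_matrix(D, data.frame(section = section, period = period))
  expect_equal(tr$LE$step[1], unclass(cm)["LE:Pre", "LE:2012"])
})
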