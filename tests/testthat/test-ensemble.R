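make_long <- function(distances, state = "apo", pair = "51-223",
                      triplet = "lobe_closure") {
  data.frame(structure_id = sprintf("S%02d", seq_along(distances)),
             chain_id = "A", state = state, triplet = triplet, pair = pair,
             distance = distances, stringsAsFactors = FALSE)
}

test_that("summary cells use linearly interpolated quartiles", {
  s <- summarize_distances(make_long(c(1, 2, 3, 4, 5)))
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$n, 5L)
  expect_equal(s$average, 3)
  expect_equal(s$std_dev, sd(1:5))
})

test_that("a singleton cell degenerates to the value itself", {
  s <- summarize_distances(make_long(7.3))
  expect_true(all(unlist(s[c("min", "q1", "q2", "q3", "max")]) == 7.3))
  expect_equal(s$std_dev, 0)
  expect_equal(s$n, 1L)
})

test_that("missing values are dropped per pair so N differs across pairs", {
  long <- rbind(make_long(c(10, 11, NA, 12), pair = "328-52"),
                make_long(c(20, 21, 22, 23), pair = "52-127"))
  s <- summarize_distances(long)
  expect_equal(s$n[s$pair == "328-52"], 3L)
  expect_equal(s$n[s$pair == "52-127"], 4L)
})

test_that("summary ordering invariants hold on generated corpora", {
  corp <- small_corpus()
  rec <- measure_corpus(corp$models, states = corp$states)
  s <- summarize_distances(distances_long(rec))
  ok <- s$n > 0
  expect_true(all(s$min[ok] <= s$q1[ok] + 1e-12))
  expect_true(all(s$q1[ok] <= s$q2[ok] + 1e-12))
  expect_true(all(s$q2[ok] <= s$q3[ok] + 1e-12))
  expect_true(all(s$q3[ok] <= s$max[ok] + 1e-12))
  expect_equal(s$q2[ok], s$median[ok])
})

fake_profile <- function(id, values, residues = seq_along(values) + 39L) {
  p <- list(structure_id = id, chain_id = "A", selection = "backbone",
            residues = data.frame(residue_seq = residues,
                                  insertion_code = "", residue_name = "ALA",
                                  b_prime = values, stringsAsFactors = FALSE),
            report = NULL)
  class(p) <- "bprime_profile"
  p
}

test_that("identical profiles give a zero-width confidence band", {
  v <- sin(seq(0, 3, length.out = 50))
  profs <- lapply(1:5, function(i) fake_profile(paste0("P", i), v))
  sp <- state_profile(profs, seed = 4L)
  expect_equal(sp$mean, v, tolerance = 1e-12)
  expect_equal(sp$lower, v, tolerance = 1e-12)
  expect_equal(sp$upper, v, tolerance = 1e-12)
})

test_that("bootstrap CI width approximates the t-interval on Gaussian data", {
  set.seed(99)
  n <- 30L
  profs <- lapply(seq_len(n), function(i) {
    fake_profile(sprintf("G%02d", i), rnorm(40, 0, 1))
  })
  sp <- state_profile(profs, n_boot = 2000L, seed = 12L)
  mat <- vapply(profs, function(p) p$residues$b_prime, numeric(40))
  t_width <- 2 * qt(0.975, n - 1) * apply(mat, 1, sd) / sqrt(n)
  boot_width <- sp$upper - sp$lower
  expect_lt(median(abs(boot_width - t_width) / t_width), 0.25)
})

test_that("the band is bit-reproducible under a fixed seed and shrinks with n", {
  profs <- lapply(1:10, function(i) {
    set.seed(100 + i); fake_profile(sprintf("R%02d", i), rnorm(30))
  })
  a <- state_profile(profs, seed = 7L)
  b <- state_profile(profs, seed = 7L)
  expect_identical(a, b)
  # quadruple the sample -> roughly half the width
  profs4 <- lapply(1:40, function(i) {
    set.seed(500 + i); fake_profile(sprintf("Q%02d", i), rnorm(30))
  })
  w1 <- median(a$upper - a$lower)
  w4 <- median(state_profile(profs4, seed = 7L)$upper -
                 state_profile(profs4, seed = 7L)$lower)
  expect_lt(w4, w1 * 0.75)
})

test_that("residues seen in under two profiles keep a mean but lose the CI", {
  p1 <- fake_profile("A1", c(0.5, 1.0), residues = c(40L, 41L))
  p2 <- fake_profile("A2", 0.7, residues = 40L)
  sp <- state_profile(list(p1, p2), seed = 1L)
  r41 <- sp[sp$residue_seq == 41L, ]
  expect_equal(r41$mean, 1.0)
  expect_true(is.na(r41$lower) && is.na(r41$upper))
})

test_that("identical profiles have an all-zero PCA spectrum", {
  v <- cos(seq(0, 5, length.out = 30))
  profs <- lapply(1:4, function(i) fake_profile(paste0("I", i), v))
  pc <- pca_profiles(profs)
  expect_true(all(abs(pc$explained_variance) < 1e-12 |
                    is.nan(pc$explained_variance)))
  expect_equal(unname(pc$x), matrix(0, 4, 4), tolerance = 1e-9)
})

test_that("PCA recovers a planted flexible block on PC1 and separates groups", {
  sim <- simulate_bprime_profiles(n_per_group = 15L, seed = 42L)
  pc <- pca_profiles(sim$profiles)
  l1 <- pc$loadings[, 1]
  mass <- sum(l1[as.character(sim$block)]^2) / sum(l1^2)
  expect_gt(mass, 0.8)
  s1 <- pc$scores[, 1]
  g1 <- s1[sim$group == 1]; g2 <- s1[sim$group == 2]
  expect_true(max(g1) < min(g2) || min(g1) > max(g2))
})

test_that("loadings are orthonormal and reconstruction is exact", {
  sim <- simulate_bprime_profiles(n_per_group = 6L, noise_sd = 0.5,
                                  seed = 9L)
  pc <- pca_profiles(sim$profiles)
  rot <- pc$rotation
  expect_equal(t(rot) %*% rot, diag(ncol(rot)), tolerance = 1e-8,
               ignore_attr = TRUE)
  centred <- sweep(pc$x %*% t(rot), 2, pc$center, "+")
  mat <- t(vapply(sim$profiles, function(p) p$residues$b_prime,
                  numeric(100)))
  expect_equal(unname(centred), unname(mat), tolerance = 1e-8)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  expect_lte(sum(pc$explained_variance), 1 + 1e-9)
})

test_that("PCA restricts to the common residue set and can fail loudly", {
  p1 <- fake_profile("C1", rnorm(10), residues = 40:49)
  p2 <- fake_profile("C2", rnorm(10), residues = 45:54)
  p3 <- fake_profile("C3", rnorm(10), residues = 45:54)
  pc <- pca_profiles(list(p1, p2, p3), n_components = 2L)
  expect_equal(pc$residue_index, 45:49)
  p4 <- fake_profile("C4", rnorm(5), residues = 80:84)
  expect_error(pca_profiles(list(p1, p2, p4)), "residue")
})

test_that("projection of a fitted profile reproduces its own scores", {
  sim <- simulate_bprime_profiles(n_per_group = 5L, seed = 3L)
  pc <- pca_profiles(sim$profiles)
  proj <- project_profiles(pc, sim$profiles[1:3])
  expect_equal(unname(proj), unname(pc$x[1:3, seq_len(ncol(proj))]),
               tolerance = 1e-9)
})

test_that("KDE integrates to one and recovers a planted mode", {
  set.seed(77)
  x <- rnorm(500, 20, 1)
  k <- kde_state(x)
  grid <- seq(10, 30, length.out = 4000)
  integral <- sum(k$eval(grid)) * diff(grid[1:2])
  expect_equal(integral, 1, tolerance = 1e-3)
  expect_lt(abs(k$peak - 20), 0.2)
  # far-negative support carries essentially no mass
  expect_lt(k$eval(-5), 1e-12)
  # two points still normalise
  k2 <- kde_state(c(19, 21))
  g2 <- seq(0, 40, length.out = 8000)
  expect_equal(sum(k2$eval(g2)) * diff(g2[1:2]), 1, tolerance = 1e-3)
  expect_error(kde_state(c(5, 5)), "distinct")
})

test_that("Scott's-rule bandwidth is deterministic given the data", {
  x <- c(18.2, 19.5, 20.1, 21.7, 22.0)
  k <- kde_state(x)
  expect_equal(k$bw, sd(x) * 5^(-1 / 5))
  expect_equal(kde_state(x)$peak, k$peak)
})

test_that("mutant placement names the nearest density peak", {
  set.seed(5)
  d19 <- kde_state(rnorm(200, 19, 0.3))
  d21 <- kde_state(rnorm(200, 21, 0.3))
  pl <- place_mutant(20.9, list(low = d19, high = d21))
  expect_equal(pl$nearest_peak, "high")
  expect_equal(nrow(pl$table), 2L)
  expect_true(all(pl$table$density >= 0))
  # exactly at a peak
  pl2 <- place_mutant(d19$peak, list(low = d19, high = d21))
  expect_equal(pl2$nearest_peak, "low")
  # missing distance propagates
  pl3 <- place_mutant(NA_real_, list(low = d19, high = d21))
  expect_true(is.na(pl3$nearest_peak))
  expect_error(place_mutant(20, list(only = d19)), "two states")
})
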