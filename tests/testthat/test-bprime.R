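test_that("modified z-scores reproduce the hand-computed fixture", {
  b <- c(8, 9, 10, 11, 12, 100)
  m <- modified_zscores(b)
  # median 10.5, MAD 1.5
  expect_equal(m[6], 0.6745 * 89.5 / 1.5, tolerance = 1e-12)  # ~40.25
  expect_equal(m[1], 0.6745 * 2.5 / 1.5, tolerance = 1e-12)   # ~1.12
  expect_equal(modified_zscores(rep(7, 5)), rep(0, 5))
  expect_error(modified_zscores(numeric(0)), "empty")
})

test_that("modified z-scores are invariant under positive affine transforms", {
  set.seed(11)
  for (i in 1:20) {
    b <- rnorm(50, 20, 4)
    a <- runif(1, 0.1, 5); c0 <- runif(1, -10, 10)
    expect_equal(modified_zscores(a * b + c0), modified_zscores(b),
                 tolerance = 1e-9)
  }
})

test_that("outlier exclusion reproduces the hand-computed fixture", {
  b <- c(8, 9, 10, 11, 12, 100)
  ex <- exclude_outliers(b)
  expect_equal(ex$report$excluded, 6L)
  expect_equal(ex$report$mean_b, 10)
  expect_equal(ex$report$sd_b, sd(8:12))       # sample sd ~1.5811
  expect_equal(ex$report$n_included, 5L)
  # MAD = 0 excludes nothing
  ex0 <- exclude_outliers(c(10, 10, 10, 10))
  expect_equal(length(ex0$report$excluded), 0L)
  expect_error(exclude_outliers(5), "at least two")
})

test_that("clean Gaussian data suffers < 2% false exclusion", {
  set.seed(2024)
  b <- rnorm(1000, 20, 3)
  ex <- exclude_outliers(b)
  expect_lt(length(ex$report$excluded) / 1000, 0.02)
})

test_that("atom-level B' of included atoms has mean 0 and sd 1", {
  corp <- small_corpus()
  m <- corp$models[[1L]]
  for (sel in c("backbone", "all_atom", "calpha")) {
    p <- normalize_chain(m, "A", selection = sel)
    bp <- p$atoms$b_prime[p$atoms$included]
    expect_equal(mean(bp), 0, tolerance = 1e-9)
    expect_equal(sd(bp), 1, tolerance = 1e-9)
  }
})

test_that("mass-weighted residue aggregation matches the hand-computed value", {
  # residue 1 backbone engineered so its atom-level B' are exactly
  # N=+1, CA=0, C=-1, O=+0.5 (chain mean 10, sample sd 2, no exclusions)
  lines <- c(
    pdb_line(serial = 1, name = "N", resno = 1, b = 12, element = "N"),
    pdb_line(serial = 2, name = "CA", resno = 1, x = 1, b = 10),
    pdb_line(serial = 3, name = "C", resno = 1, x = 2, b = 8),
    pdb_line(serial = 4, name = "O", resno = 1, x = 3, b = 11,
             element = "O"),
    pdb_line(serial = 5, name = "N", resno = 2, y = 1, b = 7, element = "N"),
    pdb_line(serial = 6, name = "CA", resno = 2, x = 1, y = 1, b = 13),
    pdb_line(serial = 7, name = "C", resno = 2, x = 2, y = 1, b = 9),
    pdb_line(serial = 8, name = "O", resno = 2, x = 3, y = 1, b = 10,
             element = "O"))
  m <- read_structure(write_pdb_fixture(lines))
  p <- normalize_chain(m, "A", selection = "backbone")
  expect_equal(p$report$mean_b, 10)
  expect_equal(p$report$sd_b, 2)
  expected <- (14.007 * 1 + 12.011 * 0 + 12.011 * -1 + 15.999 * 0.5) /
    (14.007 + 12.011 + 12.011 + 15.999)
  expect_equal(p$residues$b_prime[1], expected, tolerance = 1e-4)
  expect_equal(round(expected, 4), 0.1850)
})

test_that("C-alpha selection equals the CA atom's B' exactly", {
  corp <- small_corpus()
  m <- corp$models[[2L]]
  p <- normalize_chain(m, "A", selection = "calpha")
  ca <- p$atoms[p$atoms$atom_name == "CA" & p$atoms$included, ]
  expect_equal(p$residues$b_prime[match(ca$residue_seq,
                                        p$residues$residue_seq)],
               ca$b_prime, tolerance = 1e-12)
})

test_that("the full pipeline is invariant under positive affine B transforms", {
  corp <- small_corpus()
  m <- corp$models[[3L]]
  p0 <- normalize_chain(m, "A")
  m2 <- m
  m2$atoms$b_factor <- 2.5 * m$atoms$b_factor + 7
  expect_warning(p1 <- normalize_chain(m2, "A"), NA)
  expect_equal(which(p1$atoms$included), which(p0$atoms$included))
  expect_equal(p1$residues$b_prime, p0$residues$b_prime, tolerance = 1e-9)
})

test_that("altloc conformer order does not change the profile", {
  spec <- synthetic_spec(
    structure_id = "ALT", seed = 17L,
    altloc_spec = list(list(residue_seq = 60L, atom_name = "CA",
                            occupancy = c(0.7, 0.3), b = c(18, 26))))
  dir <- tempdir()
  man <- generate_structure(spec, file.path(dir, "alt.pdb"))
  m <- read_structure(file.path(dir, "alt.pdb"))
  p <- normalize_chain(m, "A")
  i60 <- p$atoms$residue_seq == 60 & p$atoms$atom_name == "CA"
  expect_equal(p$atoms$b_eff[i60], man$altloc_effective_b[["60 CA"]])
  # permute the two conformer rows in the atom table
  m2 <- m
  rows <- which(m2$atoms$residue_seq == 60 & m2$atoms$atom_name == "CA")
  m2$atoms[rows, ] <- m2$atoms[rev(rows), ]
  p2 <- normalize_chain(m2, "A")
  expect_equal(p2$residues$b_prime, p$residues$b_prime, tolerance = 1e-12)
})

test_that("injected outliers are excluded and recorded region ordering holds", {
  spec <- synthetic_spec(
    structure_id = "REG", seed = 23L, b_base_mean = 10, b_noise_sd = 2,
    b_regions = list(list(range = c(40L, 140L), mean = 20)),
    outliers = list(list(residue_seq = 200L, atom_name = "CA",
                         value = 120)))
  dir <- tempdir()
  generate_structure(spec, file.path(dir, "reg.pdb"))
  m <- read_structure(file.path(dir, "reg.pdb"))
  p <- normalize_chain(m, "A")
  out_atom <- p$atoms$residue_seq == 200 & p$atoms$atom_name == "CA"
  expect_false(p$atoms$included[out_atom])
  # region with doubled raw B mean has the higher mean B'
  in_a <- p$residues$residue_seq <= 140
  expect_gt(mean(p$residues$b_prime[in_a], na.rm = TRUE),
            mean(p$residues$b_prime[!in_a], na.rm = TRUE))
})

test_that("degenerate chains raise errors rather than profiles", {
  lines <- c(pdb_line(serial = 1, resno = 1, b = 10),
             pdb_line(serial = 2, resno = 2, x = 1, b = 10),
             pdb_line(serial = 3, resno = 3, x = 2, b = 10))
  m <- read_structure(write_pdb_fixture(lines))
  expect_error(normalize_chain(m, "A"), "zero variance")
  expect_error(normalize_chain(m, "Q"), "not found")
})

test_that("the squared-deviation MAD variant is available and differs", {
  b <- c(8, 9, 10, 11, 12, 100)
  m_abs <- modified_zscores(b, "absolute")
  m_sq <- modified_zscores(b, "squared")
  expect_false(isTRUE(all.equal(m_abs, m_sq)))
  # squared variant still flags the gross outlier
  expect_gt(m_sq[6], 3.5)
})
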