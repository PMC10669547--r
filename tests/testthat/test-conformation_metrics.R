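test_that("the built-in triplet set matches the conventional probe residues", {
  tl <- builtin_triplets()
  expect_length(tl, 6L)
  expect_false(anyDuplicated(names(tl)) > 0)
  expect_setequal(names(tl), c("lobe_closure", "lobe_closure_s53",
                               "dfg_spine", "ctail_gloop", "cspine_gloop",
                               "nlobe_core"))
  dfg <- tl$dfg_spine$probes
  expect_equal(dfg$residue_seq, c(72L, 185L, 95L))
  expect_equal(dfg$atom_name, c("CA", "CZ", "CA"))
  ct <- tl$ctail_gloop$probes
  expect_equal(ct$residue_seq, c(328L, 52L, 127L))
  expect_true(all(ct$atom_name == "CA"))
  expect_equal(tl$lobe_closure$probes$residue_seq, c(51L, 87L, 223L))
})

test_that("euclidean_dist agrees with an independent oracle", {
  expect_equal(euclidean_dist(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(euclidean_dist(c(0, 0, 0), c(3, 4, 12)), 13)
  set.seed(7)
  for (i in 1:100) {
    a <- runif(3, -50, 50); b <- runif(3, -50, 50)
    expect_equal(euclidean_dist(a, b),
                 as.numeric(dist(rbind(a, b))), tolerance = 1e-12)
  }
  # symmetry
  expect_equal(euclidean_dist(c(1, 2, 3), c(-4, 0, 9)),
               euclidean_dist(c(-4, 0, 9), c(1, 2, 3)))
})

test_that("measured distances match the generator manifest at PDB precision", {
  dir <- tempdir()
  mp <- default_marker_positions()
  mp[["51"]] <- c(0, 0, 0); mp[["87"]] <- c(60, 0, 0)
  mp[["223"]] <- c(25, 0, 0)
  spec <- synthetic_spec(structure_id = "EX", marker_positions = mp,
                         seed = 5L)
  man <- generate_structure(spec, file.path(dir, "ex.pdb"))
  m <- read_structure(file.path(dir, "ex.pdb"))
  r <- measure_triplet(m, "A", builtin_triplets()$lobe_closure)
  expect_equal(r$d13, 25, tolerance = 1e-3)   # T51-A223 planted at 25.000
  md <- man$marker_distances
  expect_equal(md$distance[md$res_i == 51 & md$res_j == 223][1], 25)
})

test_that("missing probes yield missing distances, not dropped records", {
  p <- write_pdb_fixture(c(
    pdb_line(serial = 1, resno = 52, x = 0, y = 0, z = 0),
    pdb_line(serial = 2, resno = 127, x = 5, y = 0, z = 0)))
  m <- read_structure(p)   # no residue 328
  r <- measure_triplet(m, "A", builtin_triplets()$ctail_gloop)
  expect_true(is.na(r$d12) && is.na(r$d13))
  expect_equal(r$d23, 5)
})

test_that("corpus measurement emits chains x triplets records in stable order", {
  dir <- file.path(tempdir(), "mc")
  specs <- list(
    synthetic_spec("S1", n_chains = 2L, seed = 1L),
    synthetic_spec("S2", n_chains = 2L, seed = 2L))
  files <- file.path(dir, c("S1.pdb", "S2.pdb"))
  dir.create(dir, showWarnings = FALSE)
  mans <- Map(generate_structure, specs, files)
  models <- lapply(files, read_structure)
  rec <- measure_corpus(models)
  expect_equal(nrow(rec), 2L * 2L * 6L)
  expect_equal(rec, rec[order(rec$structure_id, rec$chain_id, rec$triplet), ],
               ignore_attr = TRUE)
  # both asymmetric-unit copies yield the same internal geometry
  a <- rec[rec$structure_id == "S1" & rec$triplet == "dfg_spine", ]
  expect_equal(a$d13[a$chain_id == "A"], a$d13[a$chain_id == "B"],
               tolerance = 1e-9)
})

test_that("distances are invariant under rigid-body motion", {
  f <- fixture_kinase()
  m <- read_structure(f)
  rec0 <- measure_corpus(list(m))
  # rotate about z by 71 degrees, then translate
  th <- 71 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(R)
  m2 <- m
  m2$atoms$x <- xyz[, 1] + 13.7
  m2$atoms$y <- xyz[, 2] - 42.1
  m2$atoms$z <- xyz[, 3] + 5.5
  rec1 <- measure_corpus(list(m2))
  for (col in c("d12", "d13", "d23")) {
    expect_equal(rec1[[col]], rec0[[col]], tolerance = 1e-6)
  }
})

test_that("triangle inequality holds for every complete triplet record", {
  corp <- small_corpus()
  rec <- measure_corpus(corp$models, states = corp$states)
  full <- rec[stats::complete.cases(rec[, c("d12", "d13", "d23")]), ]
  expect_gt(nrow(full), 0)
  expect_true(all(full$d12 <= full$d13 + full$d23 + 1e-9))
  expect_true(all(full$d13 <= full$d12 + full$d23 + 1e-9))
  expect_true(all(full$d23 <= full$d12 + full$d13 + 1e-9))
})

test_that("probe order permutation only relabels the distances", {
  f <- fixture_kinase()
  m <- read_structure(f)
  t1 <- distance_triplet("t", c(51, 87, 223))
  t2 <- distance_triplet("t", c(223, 51, 87))
  r1 <- measure_triplet(m, "A", t1)
  r2 <- measure_triplet(m, "A", t2)
  expect_equal(sort(c(r1$d12, r1$d13, r1$d23)),
               sort(c(r2$d12, r2$d13, r2$d23)), tolerance = 1e-12)
})

test_that("numbering offset relocates probes", {
  p <- write_pdb_fixture(c(
    pdb_line(serial = 1, resno = 61, x = 0),
    pdb_line(serial = 2, resno = 97, x = 3),
    pdb_line(serial = 3, resno = 233, x = 7)))
  m <- read_structure(p)
  r <- measure_triplet(m, "A", builtin_triplets()$lobe_closure,
                       numbering_offset = 10L)
  expect_equal(c(r$d12, r$d13, r$d23), c(3, 7, 4))
})
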