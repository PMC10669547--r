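# Fixed-width PDB writer over bio3d, taking the package's uniform atom table.
.write_pdb_table <- function(df, path) {
  xyz <- as.numeric(t(as.matrix(df[, c("x", "y", "z")])))
  pdb <- list(
    atom = data.frame(
      type = df$record, eleno = df$serial, elety = df$atom_name,
      alt = ifelse(df$altloc == "", NA, df$altloc),
      resid = df$residue_name, chain = df$chain_id, resno = df$residue_seq,
      insert = ifelse(df$insertion_code == "", NA, df$insertion_code),
      x = df$x, y = df$y, z = df$z, o = df$occupancy, b = df$b_factor,
      segid = NA, elesy = df$element, charge = NA,
      stringsAsFactors = FALSE),
    xyz = bio3d::as.xyz(matrix(xyz, nrow = 1)),
    calpha = df$atom_name == "CA" & df$record == "ATOM")
  class(pdb) <- "pdb"
  bio3d::write.pdb(pdb, file = path)
  invisible(path)
}

# Place a triangle with given side lengths d12, d13, d23 at an offset:
# p1 at origin, p2 on +x, p3 in the xy plane.
.triangle <- function(d12, d13, d23, offset = c(0, 0, 0)) {
  x3 <- (d12^2 + d13^2 - d23^2) / (2 * d12)
  y3 <- sqrt(max(0, d13^2 - x3^2))
  rbind(p1 = offset,
        p2 = offset + c(d12, 0, 0),
        p3 = offset + c(x3, y3, 0))
}

#' Default marker positions for the synthetic kinase
#'
#' Places the sixteen probe residues of the built-in triplets at coordinates
#' whose within-triplet distances match typical closed-state (substrate/
#' product) values of the real enzyme, so the generator's ground truth is
#' realistic on the scale that matters. Triplet groups live in disjoint
#' regions of space (only within-triplet distances are ever measured), and
#' the two inter-lobe metrics share their H87/A223 edge as in the real
#' protein.
#'
#' @return Named list mapping residue number to a 3-vector (Angstrom),
#'   coordinates rounded to PDB precision. Residue 185's marker positions
#'   its C-zeta probe; all others position C-alpha.
#' @export
default_marker_positions <- function() {
  pos <- list()
  # inter-lobe group: H87, A223 shared; T51 and S53 placed off the 87-223 edge
  t1 <- .triangle(19.4, 14.6, 19.0)           # 87-223, 87-51, 223-51
  pos[["87"]] <- t1["p1", ]; pos[["223"]] <- t1["p2", ]
  pos[["51"]] <- t1["p3", ]
  t1b <- .triangle(19.4, 13.5, 19.5)          # 87-223, 87-53, 223-53
  pos[["53"]] <- t1b["p3", ] * c(1, -1, 1)    # opposite side of the edge
  # regulatory-spine group (K72 CA, F185 CZ, L95 CA)
  t2 <- .triangle(14.4, 12.5, 5.8, offset = c(100, 0, 0))  # 72-185,72-95,185-95
  pos[["72"]] <- t2["p1", ]; pos[["185"]] <- t2["p2", ]; pos[["95"]] <- t2["p3", ]
  # C-tail / G-loop group (D328, G52, E127)
  t3 <- .triangle(13.4, 9.6, 12.9, offset = c(200, 0, 0))  # 328-52,328-127,52-127
  pos[["328"]] <- t3["p1", ]; pos[["52"]] <- t3["p2", ]; pos[["127"]] <- t3["p3", ]
  # C-spine / G-loop group (F54, F154, L173)
  t4 <- .triangle(25.3, 19.2, 16.0, offset = c(300, 0, 0)) # 54-154,54-173,154-173
  pos[["54"]] <- t4["p1", ]; pos[["154"]] <- t4["p2", ]; pos[["173"]] <- t4["p3", ]
  # N-lobe core group (V104, K81, N113)
  t5 <- .triangle(27.2, 26.4, 16.4, offset = c(400, 0, 0)) # 81-104,81-113,104-113
  pos[["81"]] <- t5["p1", ]; pos[["104"]] <- t5["p2", ]; pos[["113"]] <- t5["p3", ]
  lapply(pos, function(p) round(unname(p), 3))
}

#' Specification of one synthetic structure
#'
#' Collects every knob of the generator: marker geometry, catalytic state
#' (which drives ligand/peptide emission), the B-factor model, alternate
#' locations and injected outliers. The seed fully determines the output
#' bytes.
#'
#' @param structure_id Label written into the manifest and file name.
#' @param state One of [state_labels()]; emits ATP for substrate/product,
#'   AMP-PNP (`ANP`) for inhibitor, an extra short chain for peptide, and
#'   nothing for apo.
#' @param n_chains Number of kinase copies in the asymmetric unit (chains
#'   A, B, ...), each a translated copy with identical internal geometry.
#' @param marker_positions Named list residue -> 3-vector; see
#'   [default_marker_positions()].
#' @param residue_range First and last residue of the kinase chain; must
#'   cover the marker residues.
#' @param include_peptide Emit a bound peptide chain in addition to the
#'   state's ligand (always `TRUE` for the peptide state).
#' @param peptide_length Residue count of the peptide chain.
#' @param b_base_mean,b_noise_sd Base mean and Gaussian noise (truncated at
#'   a small positive floor) of atomic B-factors, Angstrom^2.
#' @param b_regions List of `list(range = c(lo, hi), mean = m)` overrides of
#'   the regional B mean.
#' @param outliers List of `list(residue_seq, atom_name, value)` B-factor
#'   outliers to inject.
#' @param altloc_spec List of `list(residue_seq, atom_name, occupancy =
#'   c(...), b = c(...))` atoms to split into alternate locations
#'   (occupancies must sum to 1).
#' @param seed Integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(structure_id = "SYN001", state = "apo",
                           n_chains = 1L,
                           marker_positions = default_marker_positions(),
                           residue_range = c(40L, 340L),
                           include_peptide = FALSE, peptide_length = 20L,
                           b_base_mean = 20, b_noise_sd = 2,
                           b_regions = list(), outliers = list(),
                           altloc_spec = list(), seed = 1L) {
  state <- match.arg(state, state_labels())
  mp <- lapply(marker_positions, function(p) round(as.numeric(p), 3))
  pm <- do.call(rbind, mp)
  if (anyDuplicated(pm)) stop("synthetic_spec: marker positions collide")
  mr <- as.integer(names(mp))
  if (any(mr < residue_range[1] | mr > residue_range[2])) {
    stop("synthetic_spec: residue_range must cover all marker residues")
  }
  for (al in altloc_spec) {
    if (abs(sum(al$occupancy) - 1) > 1e-9) {
      stop("synthetic_spec: altloc occupancies must sum to 1 (residue ",
           al$residue_seq, " ", al$atom_name, ")")
    }
  }
  structure(list(
    structure_id = structure_id, state = state, n_chains = as.integer(n_chains),
    marker_positions = mp, residue_range = as.integer(residue_range),
    include_peptide = isTRUE(include_peptide) || state == "peptide",
    peptide_length = as.integer(peptide_length),
    b_base_mean = b_base_mean, b_noise_sd = b_noise_sd,
    b_regions = b_regions, outliers = outliers, altloc_spec = altloc_spec,
    seed = as.integer(seed)), class = "synthetic_spec")
}

# regional mean for each residue number
.region_mean <- function(resno, base, regions) {
  m <- rep(base, length(resno))
  for (rg in regions) {
    hit <- resno >= rg$range[1] & resno <= rg$range[2]
    m[hit] <- rg$mean
  }
  m
}

#' Generate one synthetic PDB structure with a ground-truth manifest
#'
#' Writes a well-formed fixed-width PDB file: a kinase-like chain (ideal
#' helix trace for filler residues, probe atoms pinned at the marker
#' positions), state-appropriate ligand/peptide content, Gaussian B-factors
#' with configurable regional means, injected outliers and alternate
#' locations. The manifest records every planted quantity so each pipeline
#' stage can be checked against known truth.
#'
#' @param spec A `synthetic_spec`.
#' @param path Output PDB path.
#' @return Manifest list: `structure_id`, `path`, `state`, `chains`,
#'   `marker_distances` (data frame `chain`, `res_i`, `res_j`, `distance`),
#'   `marker_positions`, `true_region_means`, `outliers`,
#'   `altloc_effective_b`, `seed`.
#' @export
generate_structure <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  resnos <- seq(spec$residue_range[1], spec$residue_range[2])
  nres <- length(resnos)
  markers <- spec$marker_positions
  chain_ids <- LETTERS[seq_len(spec$n_chains)]

  # backbone offsets relative to CA; arbitrary but fixed (geometry of filler
  # and non-probe atoms is irrelevant to every measurement)
  bnames <- c("N", "CA", "C", "O")
  boff <- rbind(N = c(-0.9, 0.6, 0.0), CA = c(0, 0, 0),
                C = c(0.9, 0.7, 0.0), O = c(1.3, 1.8, 0.3))
  belem <- c(N = "N", CA = "C", C = "C", O = "O")

  # C-alpha trace: ideal helix for filler residues, marker positions pinned
  # (residue 185 keeps its helix CA; its C-zeta probe carries the marker)
  k <- seq_len(nres)
  ca <- cbind(round(2.3 * cos(k * 100 * pi / 180) - 50, 3),
              round(-80 + 1.5 * k, 3),
              round(2.3 * sin(k * 100 * pi / 180), 3))
  for (r in names(markers)) {
    if (r != "185") ca[match(as.integer(r), resnos), ] <- markers[[r]]
  }

  mean_b <- .region_mean(resnos, spec$b_base_mean, spec$b_regions)
  trunc_b <- function(mu, sd = spec$b_noise_sd) {
    pmax(0.01, round(rnorm(length(mu), mu, sd), 2))
  }
  one_chain <- function(ch, shift_z) {
    n <- nres * 4L
    xyz <- ca[rep(seq_len(nres), each = 4L), , drop = FALSE] +
      boff[rep(1:4, nres), , drop = FALSE]
    df <- data.frame(
      record = "ATOM", serial = 0L,
      atom_name = rep(bnames, nres), altloc = "",
      residue_name = "ALA", chain_id = ch,
      residue_seq = rep(resnos, each = 4L), insertion_code = "",
      x = round(xyz[, 1], 3), y = round(xyz[, 2], 3),
      z = round(xyz[, 3], 3) + shift_z,
      occupancy = 1.00, b_factor = trunc_b(rep(mean_b, each = 4L)),
      element = rep(unname(belem), nres), stringsAsFactors = FALSE)
    if ("185" %in% names(markers) && 185L %in% resnos) {
      cz <- markers[["185"]]
      i <- max(which(df$residue_seq == 185L))
      df[df$residue_seq == 185L, "residue_name"] <- "PHE"
      df <- rbind(df[1:i, ],
                  data.frame(record = "ATOM", serial = 0L, atom_name = "CZ",
                             altloc = "", residue_name = "PHE",
                             chain_id = ch, residue_seq = 185L,
                             insertion_code = "", x = cz[1], y = cz[2],
                             z = cz[3] + shift_z, occupancy = 1.00,
                             b_factor = trunc_b(mean_b[match(185L, resnos)]),
                             element = "C", stringsAsFactors = FALSE),
                  df[(i + 1L):nrow(df), ])
    }
    df
  }
  chains <- lapply(seq_along(chain_ids), function(ci) {
    one_chain(chain_ids[ci], (ci - 1) * 500)   # AU copies: translated clones
  })
  df <- do.call(rbind, chains)

  # inject outliers (every chain, same atom identity)
  for (o in spec$outliers) {
    hit <- df$residue_seq == o$residue_seq & df$atom_name == o$atom_name
    df$b_factor[hit] <- o$value
  }
  # split selected atoms of the first chain into alternate locations
  manifest_alt <- list()
  for (al in spec$altloc_spec) {
    i <- which(df$chain_id == chain_ids[1L] &
                 df$residue_seq == al$residue_seq &
                 df$atom_name == al$atom_name)[1L]
    if (is.na(i)) next
    conf <- do.call(rbind, lapply(seq_along(al$occupancy), function(j) {
      r <- df[i, ]
      r$altloc <- LETTERS[j]
      r$x <- r$x + 0.2 * (j - 1)
      r$occupancy <- al$occupancy[j]
      r$b_factor <- al$b[j]
      r
    }))
    df <- rbind(df[seq_len(i - 1L), ], conf,
                df[seq(i + 1L, nrow(df)), ])
    manifest_alt[[paste(al$residue_seq, al$atom_name)]] <-
      sum(al$occupancy * al$b)
  }
  # active-site ligand + solvent/ion records classification must ignore
  lig <- switch(spec$state, substrate_product = "ATP", inhibitor = "ANP",
                NULL)
  het <- list()
  if (!is.null(lig)) {
    lat <- rbind(c("PA", "P"), c("PB", "P"), c("N9", "N"), c("C8", "C"),
                 c("O2A", "O"))
    if (lig == "ATP") lat <- rbind(lat, c("PG", "P"))
    j <- seq_len(nrow(lat))
    het$lig <- data.frame(
      record = "HETATM", serial = 0L, atom_name = lat[, 1], altloc = "",
      residue_name = lig, chain_id = chain_ids[1L], residue_seq = 401L,
      insertion_code = "", x = round(50 + 1.3 * j, 3),
      y = round(0.4 * j, 3), z = 0, occupancy = 1.00,
      b_factor = trunc_b(rep(spec$b_base_mean, nrow(lat))),
      element = lat[, 2], stringsAsFactors = FALSE)
  }
  het$solvent <- data.frame(
    record = "HETATM", serial = 0L, atom_name = c("O", "MG"), altloc = "",
    residue_name = c("HOH", "MG"), chain_id = chain_ids[1L],
    residue_seq = c(501L, 502L), insertion_code = "",
    x = c(60, 61), y = c(5, 6), z = 0, occupancy = 1.00,
    b_factor = c(trunc_b(30, 5), trunc_b(25, 5)),
    element = c("O", "MG"), stringsAsFactors = FALSE)
  # bound peptide chain
  if (spec$include_peptide) {
    pk <- seq_len(spec$peptide_length)
    pca <- cbind(round(30 + 2.3 * cos(pk * 100 * pi / 180), 3),
                 round(-150 + 1.5 * pk, 3),
                 round(2.3 * sin(pk * 100 * pi / 180), 3))
    pxyz <- pca[rep(pk, each = 4L), , drop = FALSE] +
      boff[rep(1:4, spec$peptide_length), , drop = FALSE]
    het$peptide <- data.frame(
      record = "ATOM", serial = 0L,
      atom_name = rep(bnames, spec$peptide_length), altloc = "",
      residue_name = "GLY", chain_id = LETTERS[spec$n_chains + 1L],
      residue_seq = rep(pk, each = 4L), insertion_code = "",
      x = round(pxyz[, 1], 3), y = round(pxyz[, 2], 3),
      z = round(pxyz[, 3], 3), occupancy = 1.00,
      b_factor = trunc_b(rep(spec$b_base_mean, spec$peptide_length * 4L)),
      element = rep(unname(belem), spec$peptide_length),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, c(list(df), unname(het)))
  df$serial <- seq_len(nrow(df))
  rownames(df) <- NULL
  .write_pdb_table(df, path)

  mres <- as.integer(names(markers))
  pairs <- t(combn(seq_along(mres), 2))
  mdist <- do.call(rbind, lapply(chain_ids, function(ch) {
    data.frame(chain = ch,
               res_i = pmin(mres[pairs[, 1]], mres[pairs[, 2]]),
               res_j = pmax(mres[pairs[, 1]], mres[pairs[, 2]]),
               distance = apply(pairs, 1, function(ij) {
                 euclidean_dist(markers[[ij[1]]], markers[[ij[2]]])
               }),
               stringsAsFactors = FALSE)
  }))
  list(structure_id = spec$structure_id, path = path, state = spec$state,
       chains = chain_ids,
       marker_distances = mdist,
       marker_positions = markers,
       true_region_means = list(base = spec$b_base_mean,
                                regions = spec$b_regions),
       outliers = spec$outliers,
       altloc_effective_b = manifest_alt,
       seed = spec$seed)
}

#' Default per-state marker displacements for the synthetic corpus
#'
#' Apo structures open the inter-lobe metric: marker T51 is moved 4 Angstrom
#' further from A223 along the 223-to-51 direction, reproducing the
#' open-state increase in the T51-A223 distance that separates apo
#' structures from ligand-bound ones.
#'
#' @return Named list state -> list of displacement rules
#'   (`residue`, `away_from`, `delta`).
#' @export
default_displacements <- function() {
  list(apo = list(list(residue = 51L, away_from = 223L, delta = 4)))
}

#' Default per-state B-factor region rules for the synthetic corpus
#'
#' Apo structures carry an elevated B mean over residues 120-139 (the
#' alpha-D helix and adjacent region), emulating the state-specific
#' flexibility increase seen in open-state ensembles; all other states use
#' the base mean there. The elevation (+5 Angstrom^2 over a base of 20, i.e.
#' +2.5 noise standard deviations) is deliberately moderate: like the real
#' signal it must survive the single-pass modified z-score filter, which
#' would excise a grossly inflated region as outliers.
#'
#' @return Named list state -> list of region overrides.
#' @export
default_b_rules <- function() {
  list(apo = list(list(range = c(120L, 139L), mean = 25)))
}

#' Generate a synthetic corpus emulating the study's composition
#'
#' Writes `sum(counts)` PDB files (default 37 substrate/product,
#' 60 inhibitor, 15 apo, 3 peptide = 115 structures) with per-state marker
#' displacements, per-state B-region rules, per-structure Gaussian jitter of
#' the marker coordinates, occasional two-copy asymmetric units and
#' occasional bound peptides in the substrate/product state. The manifest
#' records every planted quantity.
#'
#' @param out_dir Output directory (created).
#' @param counts Named integer vector of structures per state.
#' @param base_spec Template `synthetic_spec` supplying geometry and
#'   B-model defaults.
#' @param displacement_rules See [default_displacements()].
#' @param b_rules See [default_b_rules()].
#' @param jitter_sd Per-coordinate Gaussian jitter of marker positions
#'   (Angstrom), the corpus's conformational noise. Default 0.2.
#' @param multi_chain_every Every k-th structure gets a two-copy asymmetric
#'   unit (0 disables).
#' @param seed Corpus seed; drives all per-structure seeds.
#' @return List with `files`, `manifests` (per structure), `states` (named
#'   vector of planted labels), `planted` (displacement/B rules, jitter),
#'   `seed`.
#' @export
generate_corpus <- function(out_dir,
                            counts = c(substrate_product = 37L,
                                       inhibitor = 60L, apo = 15L,
                                       peptide = 3L),
                            base_spec = synthetic_spec(),
                            displacement_rules = default_displacements(),
                            b_rules = default_b_rules(),
                            jitter_sd = 0.2, multi_chain_every = 5L,
                            seed = 1L) {
  stopifnot(all(names(counts) %in% state_labels()), all(counts >= 0))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  states <- rep(names(counts), counts)
  n <- length(states)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  files <- character(n)
  manifests <- vector("list", n)
  ids <- sprintf("SYN%03d", seq_len(n))
  for (i in seq_len(n)) {
    st <- states[i]
    mp <- base_spec$marker_positions
    # planted per-state displacement, then per-structure jitter
    for (rule in displacement_rules[[st]]) {
      a <- as.character(rule$residue); b <- as.character(rule$away_from)
      u <- mp[[a]] - mp[[b]]
      u <- u / sqrt(sum(u^2))
      mp[[a]] <- mp[[a]] + rule$delta * u
    }
    mp <- lapply(mp, function(p) round(p + rnorm(3, 0, jitter_sd), 3))
    regions <- base_spec$b_regions
    for (rg in b_rules[[st]]) regions <- c(regions, list(rg))
    spec <- synthetic_spec(
      structure_id = ids[i], state = st,
      n_chains = if (multi_chain_every > 0 && i %% multi_chain_every == 0L)
        2L else 1L,
      marker_positions = mp,
      residue_range = base_spec$residue_range,
      include_peptide = st == "peptide" ||
        (st == "substrate_product" && i %% 2L == 0L),
      peptide_length = base_spec$peptide_length,
      b_base_mean = base_spec$b_base_mean,
      b_noise_sd = base_spec$b_noise_sd,
      b_regions = regions, outliers = base_spec$outliers,
      altloc_spec = base_spec$altloc_spec, seed = seeds[i])
    files[i] <- file.path(out_dir, paste0(ids[i], ".pdb"))
    manifests[[i]] <- generate_structure(spec, files[i])
  }
  st_vec <- states
  names(st_vec) <- ids
  res <- list(files = files, manifests = manifests, states = st_vec,
              planted = list(displacements = displacement_rules,
                             b_rules = b_rules, jitter_sd = jitter_sd),
              counts = counts, seed = seed)
  jsonlite::write_json(
    list(states = as.list(st_vec), seed = seed,
         planted = res$planted, files = basename(files)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  res
}

#' Simulate B' profile sets with a planted flexible block
#'
#' Constructs `bprime_profile` objects directly (no file round trip) for
#' experiments on the ensemble statistics: two groups of structures whose
#' profiles differ by `effect` over a contiguous residue block, plus
#' i.i.d. Gaussian noise elsewhere. Used to verify that the profile PCA
#' concentrates its leading component on the planted block and separates
#' the groups.
#'
#' @param n_per_group Structures per group (two groups).
#' @param residues Integer vector of residue numbers.
#' @param block Integer vector of residue numbers carrying the effect.
#' @param effect Mean profile offset of group 2 over the block.
#' @param noise_sd Residual noise standard deviation.
#' @param seed Integer seed.
#' @return List with `profiles` (list of `bprime_profile`), `group`
#'   (integer vector), `block`.
#' @export
simulate_bprime_profiles <- function(n_per_group = 15L,
                                     residues = 40:139,
                                     block = 80:89,
                                     effect = 2, noise_sd = 0.3,
                                     seed = 1L) {
  set.seed(seed)
  profiles <- list()
  group <- integer(0)
  for (g in 1:2) {
    for (i in seq_len(n_per_group)) {
      v <- rnorm(length(residues), 0, noise_sd)
      if (g == 2L) v[residues %in% block] <- v[residues %in% block] + effect
      id <- sprintf("SIM_G%d_%02d", g, i)
      p <- list(structure_id = id, chain_id = "A", selection = "backbone",
                residues = data.frame(residue_seq = residues,
                                      insertion_code = "",
                                      residue_name = "ALA", b_prime = v,
                                      stringsAsFactors = FALSE),
                report = NULL)
      class(p) <- "bprime_profile"
      profiles[[id]] <- p
      group <- c(group, g)
    }
  }
  list(profiles = profiles, group = group, block = block)
}
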