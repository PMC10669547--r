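#' Per-state summary of distance records
#'
#' Summarises each (state, triplet, pair) cell of a long distance table with
#' the statistics used in per-state report tables: mean, median, sample
#' standard deviation, N, minimum, quartiles and maximum. Quartiles use
#' linear interpolation between order statistics. Missing distances are
#' dropped per pair, so N can legitimately differ between the pairs of one
#' triplet within one state (unresolved residues affect only their own
#' pairs).
#'
#' @param long Long distance table from [distances_long()].
#' @return Data frame with one row per (state, triplet, pair) and columns
#'   `average`, `median`, `std_dev`, `n`, `min`, `q1`, `q2`, `q3`, `max`.
#' @export
summarize_distances <- function(long) {
  stopifnot(all(c("state", "triplet", "pair", "distance") %in% names(long)))
  key <- interaction(long$state, long$triplet, long$pair, drop = TRUE)
  cells <- split(long, key)
  rows <- lapply(cells, function(g) {
    x <- g$distance[!is.na(g$distance)]
    base <- data.frame(state = g$state[1L], triplet = g$triplet[1L],
                       pair = g$pair[1L], stringsAsFactors = FALSE)
    if (length(x) == 0L) {
      return(cbind(base, average = NA_real_, median = NA_real_,
                   std_dev = NA_real_, n = 0L, min = NA_real_, q1 = NA_real_,
                   q2 = NA_real_, q3 = NA_real_, max = NA_real_))
    }
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
    cbind(base,
          average = mean(x), median = median(x),
          std_dev = if (length(x) > 1L) sd(x) else 0,
          n = length(x),
          min = min(x), q1 = q[1], q2 = q[2], q3 = q[3], max = max(x))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$state, out$triplet, out$pair), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-residue mean and bootstrap confidence band of B' profiles
#'
#' For a set of profiles belonging to one state, computes the per-residue
#' mean over the structures that resolve that residue, and a percentile
#' bootstrap confidence interval obtained by resampling structures (not
#' residues). Residues resolved in fewer than two profiles keep their mean
#' but get a missing interval.
#'
#' @param profiles List of `bprime_profile` objects (one state).
#' @param level Confidence level, default 0.95.
#' @param n_boot Number of bootstrap resamples, default 1000.
#' @param seed Integer seed making the band reproducible.
#' @return Data frame `residue_seq`, `mean`, `lower`, `upper`, `n`.
#' @export
state_profile <- function(profiles, level = 0.95, n_boot = 1000L,
                          seed = 1L) {
  if (length(profiles) < 2L) stop("state_profile: need at least two profiles")
  mat <- .profile_matrix(profiles, common_only = FALSE)
  set.seed(seed)
  n <- nrow(mat)
  alpha <- (1 - level) / 2
  boot_means <- matrix(NA_real_, n_boot, ncol(mat))
  for (b in seq_len(n_boot)) {
    i <- sample.int(n, n, replace = TRUE)
    boot_means[b, ] <- colMeans(mat[i, , drop = FALSE], na.rm = TRUE)
  }
  n_res <- colSums(!is.na(mat))
  lower <- apply(boot_means, 2, quantile, probs = alpha, na.rm = TRUE)
  upper <- apply(boot_means, 2, quantile, probs = 1 - alpha, na.rm = TRUE)
  lower[n_res < 2L] <- NA_real_
  upper[n_res < 2L] <- NA_real_
  data.frame(residue_seq = as.integer(colnames(mat)),
             mean = colMeans(mat, na.rm = TRUE),
             lower = lower, upper = upper, n = n_res,
             row.names = NULL)
}

# structures x residues matrix of B' values; colnames are residue numbers.
# common_only = TRUE restricts to residues resolved (non-NA) in every profile.
.profile_matrix <- function(profiles, common_only = TRUE) {
  res <- lapply(profiles, function(p) {
    v <- p$residues$b_prime
    names(v) <- p$residues$residue_seq
    v[!is.na(v)]
  })
  all_res <- sort(unique(as.integer(unlist(lapply(res, names)))))
  mat <- matrix(NA_real_, length(res), length(all_res),
                dimnames = list(names(profiles), all_res))
  for (i in seq_along(res)) {
    mat[i, names(res[[i]])] <- res[[i]]
  }
  if (common_only) {
    keep <- colSums(is.na(mat)) == 0L
    if (!any(keep)) {
      stop("no residue is resolved in every profile; restrict the residue ",
           "range or relax the profile set")
    }
    mat <- mat[, keep, drop = FALSE]
  }
  mat
}

#' Principal component analysis of B' profiles
#'
#' Builds the structures x residues matrix over the intersection of residues
#' resolved in every included profile (imputation would fabricate flexibility
#' signal), mean-centres each residue column without variance scaling (the
#' values are already z-scored within chains) and eigendecomposes the
#' covariance. Loadings map back to residues for structure painting; score
#' signs are arbitrary up to the usual PCA sign convention.
#'
#' @param profiles List of `bprime_profile` objects, one per structure
#'   (use `first_chain_only = TRUE` in [profile_corpus()] to apply the
#'   first-molecule rule for multi-copy asymmetric units).
#' @param n_components Number of leading components to report, default 3.
#' @return Object of class `bprime_pca`: `residue_index`, `loadings`
#'   (residues x components, orthonormal), `explained_variance` (fractions,
#'   all components), `scores` (structures x `n_components`), `center`,
#'   plus the full `rotation` and `x` for reconstruction.
#' @export
pca_profiles <- function(profiles, n_components = 3L) {
  if (length(profiles) < 3L) stop("pca_profiles: need at least three profiles")
  mat <- .profile_matrix(profiles, common_only = TRUE)
  pc <- prcomp(mat, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- if (sum(ev) > 0) ev / sum(ev) else ev
  k <- min(n_components, ncol(pc$rotation))
  out <- list(
    residue_index = as.integer(colnames(mat)),
    loadings = pc$rotation[, seq_len(k), drop = FALSE],
    explained_variance = frac,
    scores = pc$x[, seq_len(k), drop = FALSE],
    center = pc$center,
    rotation = pc$rotation,
    x = pc$x,
    n_structures = nrow(mat)
  )
  class(out) <- "bprime_pca"
  out
}

#' @export
print.bprime_pca <- function(x, ...) {
  cat("<bprime_pca> ", x$n_structures, " structures x ",
      length(x$residue_index), " residues\n", sep = "")
  k <- ncol(x$loadings)
  cat("  explained variance: ",
      paste(sprintf("PC%d %.1f%%", seq_len(k),
                    100 * x$explained_variance[seq_len(k)]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Project new B' profiles onto a fitted profile PCA
#'
#' @param pca A `bprime_pca`.
#' @param profiles List of `bprime_profile`s; each must resolve every residue
#'   of the PCA's residue set.
#' @return Matrix of scores (profiles x components).
#' @export
project_profiles <- function(pca, profiles) {
  stopifnot(inherits(pca, "bprime_pca"))
  rows <- t(vapply(profiles, function(p) {
    v <- p$residues$b_prime
    names(v) <- p$residues$residue_seq
    vals <- v[as.character(pca$residue_index)]
    if (anyNA(vals)) {
      stop("profile ", p$structure_id, ".", p$chain_id,
           " does not resolve every residue of the PCA residue set")
    }
    vals
  }, numeric(length(pca$residue_index))))
  scale(rows, center = pca$center, scale = FALSE) %*% pca$loadings
}

#' Gaussian kernel density estimate of one distance distribution
#'
#' Fixed-bandwidth Gaussian KDE with Scott's rule, h = sd(x) * n^(-1/5) --
#' deterministic given the data. The returned model is evaluable at
#' arbitrary distances and exposes its peak (global mode).
#'
#' @param x Numeric vector of distances (Angstrom), at least two distinct
#'   values.
#' @param bw Optional bandwidth override (Angstrom).
#' @param state Optional state label stored on the model.
#' @param pair Optional pair label stored on the model.
#' @return Object of class `state_density` with elements `eval` (vectorised
#'   density function), `peak` (mode, Angstrom), `bw`, `n`, `range`,
#'   `state`, `pair`.
#' @export
kde_state <- function(x, bw = NULL, state = NA_character_,
                      pair = NA_character_) {
  x <- x[!is.na(x)]
  if (length(unique(x)) < 2L) {
    stop("kde_state: need at least two distinct values")
  }
  if (is.null(bw)) bw <- sd(x) * length(x)^(-1 / 5)
  if (bw <= 0) stop("kde_state: bandwidth must be positive")
  xs <- x
  f <- function(q) {
    vapply(q, function(qi) mean(dnorm(qi, mean = xs, sd = bw)), numeric(1))
  }
  # locate the global mode: coarse grid then local refinement
  grid <- seq(min(xs) - 3 * bw, max(xs) + 3 * bw, length.out = 512L)
  dg <- f(grid)
  i0 <- which.max(dg)
  lo <- grid[max(1L, i0 - 1L)]
  hi <- grid[min(length(grid), i0 + 1L)]
  peak <- optimize(f, c(lo, hi), maximum = TRUE)$maximum
  out <- list(eval = f, peak = peak, bw = bw, n = length(xs),
              range = range(xs), state = state, pair = pair)
  class(out) <- "state_density"
  out
}

#' @export
print.state_density <- function(x, ...) {
  cat("<state_density>", if (!is.na(x$state)) x$state else "",
      if (!is.na(x$pair)) paste0("(", x$pair, ")") else "", "\n")
  cat(sprintf("  n = %d, bandwidth = %.3f A, peak at %.2f A\n",
              x$n, x$bw, x$peak))
  invisible(x)
}

#' Place a structure's distance against per-state density models
#'
#' Purely descriptive placement: reports the density of each state's
#' distance distribution at the observed value and names the state whose
#' density peak lies nearest. Used to ask whether a mutant structure adopts
#' the conformation typical of its own ligand state or of another.
#'
#' @param distance Observed distance (Angstrom); `NA` propagates to a
#'   missing placement.
#' @param densities Named list of `state_density` models (>= 2 states).
#' @return List with `distance`, `table` (data frame `state`, `density`,
#'   `peak`, `peak_offset`) and `nearest_peak` (state name or `NA`).
#' @export
place_mutant <- function(distance, densities) {
  if (length(densities) < 2L) {
    stop("place_mutant: need densities for at least two states")
  }
  states <- names(densities)
  if (is.null(states)) {
    states <- vapply(densities, function(d) d$state, character(1))
  }
  if (is.na(distance)) {
    return(list(distance = NA_real_,
                table = data.frame(state = states, density = NA_real_,
                                   peak = vapply(densities, `[[`, 0, "peak"),
                                   peak_offset = NA_real_),
                nearest_peak = NA_character_))
  }
  peaks <- vapply(densities, `[[`, numeric(1), "peak")
  dens <- vapply(densities, function(d) d$eval(distance), numeric(1))
  off <- abs(peaks - distance)
  list(distance = distance,
       table = data.frame(state = states, density = unname(dens),
                          peak = unname(peaks), peak_offset = unname(off),
                          stringsAsFactors = FALSE),
       nearest_peak = states[which.min(off)])
}

#' Export PCA loadings as a painted PDB
#'
#' Writes a copy of a structure with the B-factor column of one chain
#' overwritten by a component's per-residue loading (0 elsewhere), the
#' standard trick for putty/colour rendering of flexibility components in
#' molecular viewers.
#'
#' @param model A `structure_model`.
#' @param chain Chain to paint.
#' @param pca A `bprime_pca`.
#' @param component Component number (column of the loadings).
#' @param path Output PDB path.
#' @return Invisibly, the path.
#' @export
export_loading_pdb <- function(model, chain, pca, component = 1L, path) {
  stopifnot(inherits(pca, "bprime_pca"))
  load <- pca$loadings[, component]
  names(load) <- pca$residue_index
  a <- model$atoms
  b <- rep(0, nrow(a))
  sel <- a$chain_id == chain
  hit <- match(as.character(a$residue_seq), names(load))
  b[sel & !is.na(hit)] <- load[hit[sel & !is.na(hit)]]
  .write_pdb_table(data.frame(
    record = a$record, serial = a$serial, atom_name = a$atom_name,
    altloc = a$altloc, residue_name = a$residue_name, chain_id = a$chain_id,
    residue_seq = a$residue_seq, insertion_code = a$insertion_code,
    x = a$x, y = a$y, z = a$z, occupancy = a$occupancy, b_factor = b,
    element = a$element, stringsAsFactors = FALSE), path)
  invisible(path)
}
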