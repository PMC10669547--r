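# Standard atomic weights (heavy elements found in protein/ligand models).
.ATOMIC_MASS <- c(
  C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, MN = 54.938,
  NA. = 22.990, K = 39.098, CL = 35.45, CA = 40.078, BR = 79.904,
  I = 126.904
)

atomic_mass <- function(element) {
  el <- toupper(element)
  el[el == "NA"] <- "NA."
  m <- .ATOMIC_MASS[el]
  if (anyNA(m)) {
    stop("no atomic mass tabulated for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Modified z-scores of B-factors
#'
#' Median-based outlier scores: with median B~ and the median absolute
#' deviation MAD = median(|B_i - B~|), M(i) = 0.6745 |B_i - B~| / MAD. The
#' constant 0.6745 makes MAD consistent with the standard deviation for
#' Gaussian data, so M is comparable to an ordinary |z|. When MAD is zero
#' (constant or near-constant data) all scores are defined as 0, so nothing
#' is ever excluded from such a chain.
#'
#' @param b Numeric vector of (effective) B-factors, Angstrom^2.
#' @param mad_method `"absolute"` (standard; median of absolute deviations)
#'   or `"squared"` (median of squared deviations in the denominator), kept
#'   as an explicit variant because the two appear interchangeably in the
#'   B-factor literature's typography.
#' @return Numeric vector of non-negative modified z-scores.
#' @export
modified_zscores <- function(b, mad_method = c("absolute", "squared")) {
  mad_method <- match.arg(mad_method)
  if (length(b) == 0L) stop("modified_zscores: empty input")
  med <- median(b)
  dev <- abs(b - med)
  mad <- if (mad_method == "absolute") median(dev) else median(dev^2)
  if (mad <= 0) return(rep(0, length(b)))
  0.6745 * dev / mad
}

#' Exclude B-factor outliers by the modified z-score rule
#'
#' Single-pass filter: atoms with M(i) > `cutoff` are excluded, and the
#' post-exclusion mean and sample standard deviation are computed over the
#' survivors. The pass is not iterated.
#'
#' @param b Numeric vector of B-factors (length >= 2).
#' @param cutoff Exclusion threshold on the modified z-score; default 3.5.
#' @param mad_method Passed to [modified_zscores()].
#' @return List with `included` (logical vector) and `report`, a
#'   normalisation report holding `median_b`, `mad`, `mean_b`, `sd_b`
#'   (post-exclusion, sample sd), `n_included` and `excluded` indices.
#' @export
exclude_outliers <- function(b, cutoff = 3.5,
                             mad_method = c("absolute", "squared")) {
  mad_method <- match.arg(mad_method)
  if (length(b) < 2L) stop("exclude_outliers: need at least two values")
  med <- median(b)
  dev <- abs(b - med)
  mad <- if (mad_method == "absolute") median(dev) else median(dev^2)
  m <- modified_zscores(b, mad_method)
  included <- m <= cutoff
  if (!any(included)) {
    stop("exclude_outliers: all values excluded; data degenerate")
  }
  keep <- b[included]
  report <- list(
    median_b = med, mad = mad,
    mean_b = mean(keep),
    sd_b = if (sum(included) >= 2L) sd(keep) else NA_real_,
    n_included = sum(included),
    excluded = which(!included)
  )
  list(included = included, report = report)
}

# Collapse altloc conformers: one row per unique atom identity with
# occupancy-weighted effective B and the highest-occupancy conformer's
# element/name kept. Single-conformer atoms (the vast majority) pass through.
.collapse_altlocs <- function(atoms) {
  key <- paste(atoms$residue_seq, atoms$insertion_code, atoms$atom_name,
               sep = "\r")
  multi <- key %in% key[duplicated(key)]
  if (!any(multi)) return(atoms)
  singles <- atoms[!multi, , drop = FALSE]
  groups <- split(which(multi), key[multi])
  rows <- lapply(groups, function(i) {
    g <- atoms[i, , drop = FALSE]
    r <- g[order(-g$occupancy, g$altloc)[1L], , drop = FALSE]
    r$b_factor <- effective_b(g$b_factor, g$occupancy)
    r$occupancy <- sum(g$occupancy)
    r
  })
  out <- rbind(singles, do.call(rbind, rows))
  # restore first-appearance file order
  pos <- c(which(!multi), vapply(groups, min, integer(1)))
  out <- out[order(pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.SELECTIONS <- c("all_atom", "backbone", "calpha")
.BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Normalised B'-factor profile of one chain
#'
#' Converts raw crystallographic B-factors of a chain into a dimensionless
#' per-residue flexibility profile:
#' \enumerate{
#'   \item alternate-location conformers are collapsed into one effective B
#'     per atom by occupancy weighting ([effective_b()]);
#'   \item atoms are restricted to the chosen selection (all heavy atoms,
#'     backbone N/CA/C/O, or C-alpha only); all normalisation statistics are
#'     computed within that selection so each analysis mode is
#'     self-contained;
#'   \item outliers with modified z-score above `cutoff` are excluded in a
#'     single pass ([exclude_outliers()]);
#'   \item surviving atoms are z-scored, B'(a) = (B_a - mean) / sd;
#'   \item residue values are the atomic-mass-weighted mean of the residue's
#'     included atoms, B'(i) = sum_a M_a B'(a) / sum_a M_a.
#' }
#' Residues whose selected atoms were all excluded (or are absent) get `NA`.
#'
#' @param model A `structure_model`.
#' @param chain Chain identifier.
#' @param selection One of `"backbone"` (default, matching the headline
#'   analysis), `"all_atom"`, `"calpha"`.
#' @param cutoff Modified z-score exclusion threshold (default 3.5).
#' @param mad_method See [modified_zscores()].
#' @return Object of class `bprime_profile`: list with `structure_id`,
#'   `chain_id`, `selection`, `residues` (data frame `residue_seq`,
#'   `residue_name`, `b_prime`), `atoms` (per-atom table with `b_eff`,
#'   `b_prime`, `included`), and `report` (see [exclude_outliers()]).
#' @export
normalize_chain <- function(model, chain,
                            selection = c("backbone", "all_atom", "calpha"),
                            cutoff = 3.5,
                            mad_method = c("absolute", "squared")) {
  selection <- match.arg(selection)
  mad_method <- match.arg(mad_method)
  a <- chain_atoms(model, chain)
  if (nrow(a) == 0L) stop("normalize_chain: chain ", chain, " not found in ",
                          model$structure_id)
  a <- .collapse_altlocs(a)
  a <- switch(selection,
    all_atom = a,
    backbone = a[a$atom_name %in% .BACKBONE_ATOMS, , drop = FALSE],
    calpha = a[a$atom_name == "CA", , drop = FALSE]
  )
  if (nrow(a) < 2L) {
    stop("normalize_chain: fewer than two atoms in selection '", selection,
         "' for chain ", chain)
  }
  ex <- exclude_outliers(a$b_factor, cutoff = cutoff, mad_method = mad_method)
  rep <- ex$report
  if (is.na(rep$sd_b) || rep$sd_b <= 0) {
    stop("normalize_chain: zero variance after exclusion in chain ", chain,
         " of ", model$structure_id, "; profile undefined")
  }
  a$b_eff <- a$b_factor
  a$included <- ex$included
  a$b_prime <- ifelse(a$included, (a$b_eff - rep$mean_b) / rep$sd_b, NA_real_)

  rkey <- factor(paste(a$residue_seq, a$insertion_code, sep = "\r"),
                 levels = unique(paste(a$residue_seq, a$insertion_code,
                                       sep = "\r")))
  mass <- atomic_mass(a$element)
  w <- ifelse(a$included, mass, 0)
  num <- rowsum(ifelse(a$included, w * a$b_prime, 0), rkey)
  den <- rowsum(w, rkey)
  first <- !duplicated(rkey)
  res <- data.frame(residue_seq = a$residue_seq[first],
                    insertion_code = a$insertion_code[first],
                    residue_name = a$residue_name[first],
                    b_prime = ifelse(den[, 1] > 0, num[, 1] / den[, 1],
                                     NA_real_),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  out <- list(structure_id = model$structure_id, chain_id = chain,
              selection = selection, residues = res, atoms = a,
              report = rep)
  class(out) <- "bprime_profile"
  out
}

#' @export
print.bprime_profile <- function(x, ...) {
  cat("<bprime_profile> ", x$structure_id, " chain ", x$chain_id,
      " (", x$selection, ")\n", sep = "")
  cat(sprintf("  %d residues, %d atoms included, %d excluded\n",
              nrow(x$residues), x$report$n_included,
              length(x$report$excluded)))
  cat(sprintf("  raw B: median %.2f, MAD %.2f; post-exclusion mean %.2f, sd %.2f\n",
              x$report$median_b, x$report$mad, x$report$mean_b,
              x$report$sd_b))
  invisible(x)
}

#' B' profiles for every kinase chain of a corpus
#'
#' @param models List of `structure_model`s.
#' @param selection,cutoff,mad_method Passed to [normalize_chain()].
#' @param dict Ligand dictionary separating kinase chains from peptides.
#' @param first_chain_only If `TRUE`, keep only the first kinase chain of
#'   each structure (the rule used for the profile PCA).
#' @return Named list of `bprime_profile` objects (names
#'   `"<structure_id>.<chain>"`); chains whose profile is degenerate are
#'   skipped with a warning.
#' @export
profile_corpus <- function(models, selection = "backbone", cutoff = 3.5,
                           mad_method = "absolute",
                           dict = ligand_dictionary(),
                           first_chain_only = FALSE) {
  out <- list()
  for (model in models) {
    chains <- kinase_chains(model, dict)
    if (first_chain_only) chains <- chains[1L]
    for (ch in chains) {
      p <- tryCatch(
        normalize_chain(model, ch, selection = selection, cutoff = cutoff,
                        mad_method = mad_method),
        error = function(e) {
          warning("profile skipped for ", model$structure_id, " chain ", ch,
                  ": ", conditionMessage(e))
          NULL
        })
      if (!is.null(p)) out[[paste(model$structure_id, ch, sep = ".")]] <- p
    }
  }
  out
}
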