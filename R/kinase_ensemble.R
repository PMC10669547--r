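#' Fit the ensemble model of a kinase structure corpus
#'
#' The package's central fit: takes a corpus of crystal structures and
#' returns the full ensemble description --- catalytic-state labels,
#' per-chain distance records for every triplet, per-(state, pair) summary
#' statistics, per-state B' profile bands, a PCA of the B' profiles (first
#' molecule of each asymmetric unit only) and per-state kernel density
#' models of every distance pair.
#'
#' @param models List of `structure_model` objects (from [read_structure()])
#'   or a character vector of PDB file paths.
#' @param dict Ligand dictionary for state classification.
#' @param triplets Distance triplets to measure (default
#'   [builtin_triplets()]).
#' @param selection Atom selection for B' profiles: `"backbone"` (default),
#'   `"all_atom"` or `"calpha"`.
#' @param cutoff Modified z-score exclusion cutoff, default 3.5.
#' @param n_components Number of PCA components reported, default 3.
#' @param n_boot Bootstrap resamples for the confidence bands, default 1000.
#' @param ci Confidence level for the per-residue bands, default 0.95.
#' @param seed Seed for the bootstrap.
#' @param numbering_offset Residue-numbering offset(s) passed to
#'   [measure_corpus()].
#' @return Object of class `kinase_ensemble` with elements `states`,
#'   `records`, `long`, `summary`, `profiles`, `state_profiles`, `pca`,
#'   `densities` (nested list state -> pair -> `state_density`), `failures`
#'   (per-structure problems collected, not fatal), and the call settings.
#' @seealso [predict.kinase_ensemble()] for placing a new (e.g. mutant)
#'   structure against the fitted ensemble.
#' @export
kinase_ensemble <- function(models, dict = ligand_dictionary(),
                            triplets = builtin_triplets(),
                            selection = "backbone", cutoff = 3.5,
                            n_components = 3L, n_boot = 1000L, ci = 0.95,
                            seed = 1L, numbering_offset = 0L) {
  if (is.character(models)) {
    models <- lapply(models, read_structure)
  }
  failures <- list()
  states <- character(0)
  ok <- logical(length(models))
  for (i in seq_along(models)) {
    st <- tryCatch(classify_state(models[[i]], dict), error = function(e) e)
    if (inherits(st, "error")) {
      failures[[models[[i]]$structure_id]] <- conditionMessage(st)
    } else {
      states[models[[i]]$structure_id] <- st
      ok[i] <- TRUE
    }
  }
  if (!any(ok)) stop("kinase_ensemble: no structure could be classified")
  models <- models[ok]

  records <- measure_corpus(models, triplets, states = states, dict = dict,
                            numbering_offset = numbering_offset)
  long <- distances_long(records, triplets)
  summary_tab <- summarize_distances(long)

  profiles <- profile_corpus(models, selection = selection, cutoff = cutoff,
                             dict = dict, first_chain_only = FALSE)
  prof_state <- states[vapply(profiles, `[[`, "", "structure_id")]
  state_profiles <- list()
  for (st in unique(prof_state)) {
    ps <- profiles[prof_state == st]
    if (length(ps) >= 2L) {
      state_profiles[[st]] <- state_profile(ps, level = ci, n_boot = n_boot,
                                            seed = seed)
    }
  }

  # first-molecule rule for the PCA: keep the first kinase chain per structure
  first_keys <- vapply(models, function(m) {
    paste(m$structure_id, kinase_chains(m, dict)[1L], sep = ".")
  }, character(1))
  first_profiles <- profiles[intersect(first_keys, names(profiles))]
  pca <- if (length(first_profiles) >= 3L) {
    tryCatch(pca_profiles(first_profiles, n_components = n_components),
             error = function(e) {
               failures[["pca"]] <<- conditionMessage(e)
               NULL
             })
  } else NULL

  densities <- list()
  for (st in unique(long$state[!is.na(long$state)])) {
    sl <- long[long$state == st & !is.na(long$distance), ]
    for (pr in unique(sl$pair)) {
      x <- sl$distance[sl$pair == pr]
      if (length(unique(x)) >= 2L) {
        densities[[st]][[pr]] <- kde_state(x, state = st, pair = pr)
      }
    }
  }

  out <- list(states = states, records = records, long = long,
              summary = summary_tab, profiles = profiles,
              state_profiles = state_profiles, pca = pca,
              densities = densities, failures = failures,
              settings = list(selection = selection, cutoff = cutoff,
                              n_components = n_components, n_boot = n_boot,
                              ci = ci, seed = seed),
              dict = dict, triplets = triplets)
  class(out) <- "kinase_ensemble"
  out
}

#' @export
print.kinase_ensemble <- function(x, ...) {
  cat("<kinase_ensemble>\n")
  tab <- table(x$states)
  cat("  structures: ", length(x$states), " (",
      paste(names(tab), tab, sep = " = ", collapse = ", "), ")\n", sep = "")
  cat("  distance records:", nrow(x$records), "over",
      length(unique(x$records$triplet)), "triplets\n")
  cat("  B' profiles:", length(x$profiles), "chains, selection",
      x$settings$selection, "\n")
  if (!is.null(x$pca)) {
    ev <- x$pca$explained_variance
    k <- ncol(x$pca$loadings)
    cat("  profile PCA: ",
        paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * ev[seq_len(k)]),
              collapse = ", "), "\n", sep = "")
  }
  if (length(x$failures)) {
    cat("  failures:", length(x$failures), "structure(s); see $failures\n")
  }
  invisible(x)
}

#' Per-state distance summary of a fitted ensemble
#'
#' @param object A `kinase_ensemble`.
#' @param triplet Optional triplet name to restrict the table.
#' @param digits Rounding applied to the distance columns for display
#'   (default 0.1 Angstrom resolution, i.e. 1 digit; `NULL` for full
#'   precision).
#' @param ... Unused.
#' @return Data frame of per-(state, triplet, pair) statistics.
#' @export
summary.kinase_ensemble <- function(object, triplet = NULL, digits = 2L,
                                    ...) {
  s <- object$summary
  if (!is.null(triplet)) s <- s[s$triplet %in% triplet, , drop = FALSE]
  if (!is.null(digits)) {
    num <- c("average", "median", "std_dev", "min", "q1", "q2", "q3", "max")
    s[num] <- lapply(s[num], round, digits = digits)
  }
  s
}

#' Place a new structure against a fitted ensemble
#'
#' Classifies the structure, measures the requested distance pair on its
#' first kinase chain, evaluates every state's kernel density at that value
#' and reports the state whose density peak is nearest
#' ([place_mutant()]). If the ensemble has a profile PCA and the structure
#' resolves the PCA residue set, its B' profile is also projected onto the
#' fitted components.
#'
#' @param object A `kinase_ensemble`.
#' @param newdata A `structure_model` or a PDB file path.
#' @param triplet Triplet name containing the pair of interest (default
#'   `"cspine_gloop"`).
#' @param pair Pair label (default `"54-173"`, the G-loop-to-C-spine
#'   distance used for mutant placement; pass `NULL` for the triplet's first
#'   pair).
#' @param chain Chain to measure; default the first kinase chain.
#' @param ... Unused.
#' @return List with `structure_id`, `state` (the structure's own
#'   ligand-defined state), `pair`, `placement` (see [place_mutant()]), and
#'   `pc_scores` (or `NULL`).
#' @export
predict.kinase_ensemble <- function(object, newdata,
                                    triplet = "cspine_gloop",
                                    pair = "54-173",
                                    chain = NULL, ...) {
  model <- if (is.character(newdata)) read_structure(newdata) else newdata
  stopifnot(inherits(model, "structure_model"))
  st <- tryCatch(classify_state(model, object$dict),
                 error = function(e) NA_character_)
  tp <- object$triplets[[triplet]]
  if (is.null(tp)) stop("unknown triplet: ", triplet)
  if (is.null(chain)) chain <- kinase_chains(model, object$dict)[1L]
  rec <- measure_triplet(model, chain, tp)
  labs <- .pair_labels(tp)
  if (is.null(pair)) pair <- labs[1L]
  d <- c(rec$d12, rec$d13, rec$d23)[match(pair, labs)]
  dens <- lapply(object$densities, function(byp) byp[[pair]])
  dens <- dens[!vapply(dens, is.null, logical(1))]
  placement <- if (length(dens) >= 2L) place_mutant(d, dens) else NULL
  pc <- NULL
  if (!is.null(object$pca)) {
    prof <- tryCatch(
      normalize_chain(model, chain, selection = object$settings$selection,
                      cutoff = object$settings$cutoff),
      error = function(e) NULL)
    if (!is.null(prof)) {
      pc <- tryCatch(project_profiles(object$pca, list(prof)),
                     error = function(e) NULL)
    }
  }
  list(structure_id = model$structure_id, state = st, pair = pair,
       distance = d, placement = placement, pc_scores = pc)
}

#' Plot a fitted kinase ensemble
#'
#' `type = "profile"` draws the per-state mean B' bands with their
#' confidence envelopes; `type = "pca"` draws the structure scores on the
#' first two components, coloured by state; `type = "density"` draws the
#' per-state kernel densities of one distance pair.
#'
#' @param x A `kinase_ensemble`.
#' @param type One of `"profile"`, `"pca"`, `"density"`.
#' @param pair Pair label for `type = "density"`.
#' @param ... Passed to the underlying plotting calls.
#' @return Invisibly, `x`.
#' @export
plot.kinase_ensemble <- function(x, type = c("profile", "pca", "density"),
                                 pair = "54-173", ...) {
  type <- match.arg(type)
  cols <- c(substrate_product = "#E69F00", inhibitor = "#9450A8",
            apo = "#009E73", peptide = "#0072B2")
  if (type == "profile") {
    sps <- x$state_profiles
    if (!length(sps)) stop("no state profiles fitted")
    xl <- range(unlist(lapply(sps, `[[`, "residue_seq")))
    yl <- range(unlist(lapply(sps, function(s) c(s$lower, s$mean, s$upper))),
                na.rm = TRUE)
    plot(NA, xlim = xl, ylim = yl, xlab = "residue",
         ylab = "B' (normalised)", main = "Per-residue B' by state", ...)
    for (st in names(sps)) {
      s <- sps[[st]]
      okci <- !is.na(s$lower)
      graphics::polygon(c(s$residue_seq[okci], rev(s$residue_seq[okci])),
                        c(s$lower[okci], rev(s$upper[okci])),
                        col = grDevices::adjustcolor(cols[[st]], 0.25),
                        border = NA)
      graphics::lines(s$residue_seq, s$mean, col = cols[[st]], lwd = 1.5)
    }
    graphics::legend("topright", legend = names(sps), col = cols[names(sps)],
                     lwd = 2, bty = "n")
  } else if (type == "pca") {
    if (is.null(x$pca)) stop("no PCA fitted")
    sc <- x$pca$scores
    ids <- sub("\\.[^.]*$", "", rownames(sc))
    st <- x$states[ids]
    plot(sc[, 1], sc[, 2], col = cols[st], pch = 19,
         xlab = sprintf("PC1 (%.1f%%)", 100 * x$pca$explained_variance[1]),
         ylab = sprintf("PC2 (%.1f%%)", 100 * x$pca$explained_variance[2]),
         main = "B' profile PCA", ...)
    graphics::legend("topright", legend = unique(st),
                     col = cols[unique(st)], pch = 19, bty = "n")
  } else {
    found <- FALSE
    xs <- seq(0, 1, length.out = 2)
    dens <- lapply(x$densities, function(byp) byp[[pair]])
    dens <- dens[!vapply(dens, is.null, logical(1))]
    if (!length(dens)) stop("no density fitted for pair ", pair)
    xl <- range(unlist(lapply(dens, `[[`, "range"))) + c(-2, 2)
    grid <- seq(xl[1], xl[2], length.out = 256)
    ys <- lapply(dens, function(d) d$eval(grid))
    plot(NA, xlim = xl, ylim = c(0, max(unlist(ys))),
         xlab = paste0("distance ", pair, " (Å)"), ylab = "density",
         main = "Per-state distance densities", ...)
    for (st in names(dens)) {
      graphics::lines(grid, ys[[st]], col = cols[[st]], lwd = 1.5)
    }
    graphics::legend("topright", legend = names(dens),
                     col = cols[names(dens)], lwd = 2, bty = "n")
  }
  invisible(x)
}
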