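#' Run the full ensemble pipeline over a directory of structures
#'
#' End-to-end orchestration: read every PDB file, classify states, measure
#' the distance triplets, compute B' profiles, fit per-state bands, PCA and
#' densities ([kinase_ensemble()]), and write a reproducible artifact tree:
#' \preformatted{
#'   out_dir/
#'     config.json          run settings + input list (provenance)
#'     states.tsv           per-structure state labels
#'     distances.tsv        tidy long distance table
#'     summary_tables.tsv   per-(state, triplet, pair) statistics
#'     bprime/<id>.<chain>.tsv   per-residue B' profiles
#'     state_profiles.tsv   per-state mean + CI bands
#'     pca_scores.tsv, pca_loadings.tsv, pca_variance.tsv
#'     failures.tsv         structures that could not be processed
#' }
#' Identical inputs, settings and seed reproduce the outputs exactly.
#' Per-structure failures are collected; the run fails only when no
#' structure can be processed at all.
#'
#' @param input Directory containing `.pdb` files, or a character vector of
#'   file paths.
#' @param out_dir Output directory (created).
#' @param dict Ligand dictionary, or path to a JSON dictionary config.
#' @param selection,cutoff,n_components,n_boot,ci,seed,triplets Passed to
#'   [kinase_ensemble()].
#' @return Invisibly, the fitted `kinase_ensemble`.
#' @export
run_pipeline <- function(input, out_dir, dict = ligand_dictionary(),
                         triplets = builtin_triplets(),
                         selection = "backbone", cutoff = 3.5,
                         n_components = 3L, n_boot = 1000L, ci = 0.95,
                         seed = 1L) {
  files <- if (length(input) == 1L && dir.exists(input)) {
    list.files(input, pattern = "\\.(pdb|ent)$", full.names = TRUE)
  } else input
  if (!length(files)) stop("run_pipeline: no input structures")
  files <- sort(files)
  if (is.character(dict)) dict <- read_ligand_dictionary(dict)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  read_fail <- list()
  models <- list()
  for (f in files) {
    m <- tryCatch(read_structure(f), error = function(e) e)
    if (inherits(m, "error")) {
      read_fail[[basename(f)]] <- conditionMessage(m)
    } else {
      models[[length(models) + 1L]] <- m
    }
  }
  if (!length(models)) {
    stop("run_pipeline: no structure could be read (",
         length(read_fail), " failures)")
  }
  fit <- kinase_ensemble(models, dict = dict, triplets = triplets,
                         selection = selection, cutoff = cutoff,
                         n_components = n_components, n_boot = n_boot,
                         ci = ci, seed = seed)

  jsonlite::write_json(
    list(inputs = basename(files), selection = selection, cutoff = cutoff,
         n_components = n_components, n_boot = n_boot, ci = ci, seed = seed,
         ligand_dictionary = unclass(dict),
         triplets = lapply(triplets, function(t) {
           list(name = t$name, residues = t$probes$residue_seq,
                atoms = t$probes$atom_name)
         })),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)

  tsv <- function(d, f) {
    write.table(d, file.path(out_dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(data.frame(structure_id = names(fit$states), state = fit$states,
                 row.names = NULL), "states.tsv")
  tsv(fit$long, "distances.tsv")
  tsv(fit$summary, "summary_tables.tsv")

  dir.create(file.path(out_dir, "bprime"), showWarnings = FALSE)
  for (nm in names(fit$profiles)) {
    p <- fit$profiles[[nm]]
    write.table(cbind(p$residues, selection = p$selection),
                file.path(out_dir, "bprime", paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(fit$state_profiles)) {
    sp <- do.call(rbind, lapply(names(fit$state_profiles), function(st) {
      cbind(state = st, fit$state_profiles[[st]])
    }))
    tsv(sp, "state_profiles.tsv")
  }
  if (!is.null(fit$pca)) {
    tsv(data.frame(profile = rownames(fit$pca$scores), fit$pca$scores,
                   row.names = NULL), "pca_scores.tsv")
    tsv(data.frame(residue_seq = fit$pca$residue_index, fit$pca$loadings,
                   row.names = NULL), "pca_loadings.tsv")
    tsv(data.frame(component = seq_along(fit$pca$explained_variance),
                   fraction = fit$pca$explained_variance), "pca_variance.tsv")
  }
  fails <- c(read_fail, fit$failures)
  tsv(data.frame(structure = names(fails),
                 problem = unlist(fails, use.names = FALSE)
                 %||% character(0)), "failures.tsv")
  invisible(fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-structure distance grid for named entries
#'
#' Builds the wide per-structure table used to compare individual (e.g.
#' mutant) structures: rows are distance pairs, columns are
#' structure/chain entries.
#'
#' @param models List of `structure_model`s or PDB paths.
#' @param chains Optional character vector (parallel to `models`) naming the
#'   chain to report per structure; default: first kinase chain.
#' @param triplets Triplets to measure.
#' @param dict Ligand dictionary.
#' @param digits Rounding of reported distances (default 1, i.e. 0.1
#'   Angstrom as in report tables).
#' @return Data frame: first column `pair`, one column per structure entry.
#' @export
structure_grid <- function(models, chains = NULL,
                           triplets = builtin_triplets(),
                           dict = ligand_dictionary(), digits = 1L) {
  if (is.character(models)) models <- lapply(models, read_structure)
  cols <- list()
  pair_names <- unlist(lapply(triplets, .pair_labels), use.names = FALSE)
  for (i in seq_along(models)) {
    m <- models[[i]]
    ch <- if (!is.null(chains)) chains[i] else kinase_chains(m, dict)[1L]
    v <- unlist(lapply(triplets, function(tp) {
      r <- measure_triplet(m, ch, tp)
      c(r$d12, r$d13, r$d23)
    }), use.names = FALSE)
    cols[[paste0(m$structure_id, ".", ch)]] <-
      if (is.null(digits)) v else round(v, digits)
  }
  data.frame(pair = pair_names, cols, check.names = FALSE,
             row.names = NULL)
}
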