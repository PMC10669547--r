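#' @importFrom stats median sd quantile prcomp dnorm rnorm runif qt optimize
#' @importFrom utils write.table read.table head tail
NULL

# Het codes treated as solvent/buffer and ignored during classification and
# ligand listing. Extendable through the ligand dictionary's ignore_codes.
.WATER_CODES <- c("HOH", "WAT", "DOD")

#' Read a crystal structure from a PDB file
#'
#' Parses ATOM and HETATM records of the first MODEL into a uniform atom
#' table. Alternate-location conformers are retained as distinct rows sharing
#' the same atom name and residue; waters are kept separable from other
#' heteroatom groups. Polymer chain order follows file order, which matters
#' downstream for the "first molecule" rule in the profile PCA.
#'
#' @param path Path to a PDB-format file.
#' @param structure_id Identifier stored on the returned model; defaults to
#'   the file name without extension.
#' @return An object of class `structure_model`: a list with elements
#'   `structure_id`, `atoms` (data frame of polymer ATOM records), `het`
#'   (non-water HETATM records), `waters`, and `chains` (polymer chain ids in
#'   file order). Atom columns: `serial`, `atom_name`, `altloc`,
#'   `residue_name`, `chain_id`, `residue_seq`, `insertion_code`, `x`, `y`,
#'   `z`, `occupancy`, `b_factor`, `element`.
#' @details Occupancy or B-factor fields that cannot be parsed raise an error
#'   naming the offending record; negative B-factors are retained but flagged
#'   with a warning (exclusion is the job of the outlier filter, not the
#'   parser). Hydrogens are dropped. Only the first MODEL is kept.
#' @export
read_structure <- function(path, structure_id = NULL) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0L) stop("no ATOM/HETATM records in ", path)
  if (is.null(structure_id)) {
    structure_id <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path))
  }
  bad <- which(is.na(at$o) | is.na(at$b))
  if (length(bad)) {
    stop("missing occupancy/B-factor on record serial ", at$eleno[bad[1]],
         " (", at$resid[bad[1]], " ", at$resno[bad[1]], " ",
         at$elety[bad[1]], ") in ", path)
  }
  atoms <- data.frame(
    record = at$type,
    serial = at$eleno,
    atom_name = at$elety,
    altloc = ifelse(is.na(at$alt), "", at$alt),
    residue_name = at$resid,
    chain_id = ifelse(is.na(at$chain), "", at$chain),
    residue_seq = at$resno,
    insertion_code = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = at$o,
    b_factor = at$b,
    element = ifelse(is.na(at$elesy), "", at$elesy),
    stringsAsFactors = FALSE
  )
  # drop hydrogens/deuteriums; absent from the crystal structures analysed
  h <- toupper(atoms$element) %in% c("H", "D")
  atoms <- atoms[!h, , drop = FALSE]
  if (any(atoms$b_factor < 0)) {
    warning("negative B-factor(s) in ", structure_id,
            " retained and flagged (", sum(atoms$b_factor < 0), " atoms)")
  }
  is_water <- atoms$residue_name %in% .WATER_CODES
  is_het <- atoms$record == "HETATM" & !is_water
  poly <- atoms$record == "ATOM"
  out <- list(
    structure_id = structure_id,
    atoms = atoms[poly, , drop = FALSE],
    het = atoms[is_het, , drop = FALSE],
    waters = atoms[is_water & atoms$record == "HETATM", , drop = FALSE],
    chains = unique(atoms$chain_id[poly])
  )
  rownames(out$atoms) <- NULL
  rownames(out$het) <- NULL
  class(out) <- "structure_model"
  out
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", x$structure_id, "\n", sep = "")
  nres <- vapply(x$chains, function(ch) {
    a <- x$atoms[x$atoms$chain_id == ch, ]
    nrow(unique(a[, c("residue_seq", "insertion_code")]))
  }, integer(1))
  cat("  polymer chains: ",
      paste0(x$chains, " (", nres, " res)", collapse = ", "), "\n", sep = "")
  hets <- unique(x$het$residue_name)
  cat("  het groups: ", if (length(hets)) paste(hets, collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

#' Atoms of one polymer chain
#'
#' @param model A `structure_model`.
#' @param chain Chain identifier.
#' @return Data frame of ATOM records for that chain, file order preserved.
#' @export
chain_atoms <- function(model, chain) {
  stopifnot(inherits(model, "structure_model"))
  model$atoms[model$atoms$chain_id == chain, , drop = FALSE]
}

#' Number of residues in a polymer chain
#' @inheritParams chain_atoms
#' @return Integer count of distinct (residue_seq, insertion_code) pairs.
#' @export
chain_length <- function(model, chain) {
  a <- chain_atoms(model, chain)
  nrow(unique(a[, c("residue_seq", "insertion_code")]))
}

#' Occupancy-weighted effective B-factor of an atom
#'
#' For an atom modelled in several alternate locations I with occupancies
#' pi_I, the effective temperature factor is sum_I pi_I * B(I). With a single
#' fully occupied conformer this is the plain B-factor.
#'
#' @param b_factor Numeric vector of conformer B-factors (Angstrom^2).
#' @param occupancy Numeric vector of conformer occupancies, same length.
#' @return The occupancy-weighted B (Angstrom^2).
#' @details If the occupancies do not sum to 1 the weighted sum is used as
#'   given (no renormalisation) and a warning is emitted; partial-occupancy
#'   models are legitimate in deposited structures.
#' @export
effective_b <- function(b_factor, occupancy) {
  if (length(b_factor) == 0L) stop("effective_b: no conformers supplied")
  if (length(b_factor) != length(occupancy)) {
    stop("effective_b: b_factor and occupancy lengths differ")
  }
  if (any(occupancy <= 0)) stop("effective_b: occupancies must be > 0")
  s <- sum(occupancy)
  if (abs(s - 1) > 1e-6 && length(b_factor) > 1L) {
    warning("altloc occupancies sum to ", format(s), ", not 1; using as given")
  }
  sum(occupancy * b_factor)
}

#' Select a single atom conformer from a structure
#'
#' Resolves alternate locations by the highest-occupancy rule (ties broken by
#' alphabetically first altloc, blank sorting first). Missing residues or
#' atoms yield `NULL` rather than an error: unresolved residues are data, not
#' failures, and downstream distance records carry them as missing values.
#'
#' @param model A `structure_model`.
#' @param chain Chain identifier.
#' @param residue_seq Residue sequence number (author numbering).
#' @param atom_name PDB atom name, e.g. `"CA"`, `"CZ"`.
#' @return A one-row data frame (one conformer) or `NULL` if unresolved.
#' @export
select_atom <- function(model, chain, residue_seq, atom_name) {
  a <- model$atoms
  hit <- a$chain_id == chain & a$residue_seq == residue_seq &
    a$atom_name == atom_name
  if (!any(hit)) return(NULL)
  cand <- a[hit, , drop = FALSE]
  ord <- order(-cand$occupancy, cand$altloc)
  cand[ord[1L], , drop = FALSE]
}

#' Het group codes present in a structure
#'
#' @param model A `structure_model`.
#' @param ignore Character vector of codes to drop (waters are always
#'   excluded).
#' @return Character vector of distinct non-water het codes.
#' @export
het_codes <- function(model, ignore = character()) {
  setdiff(unique(model$het$residue_name), ignore)
}

#' Fetch a PDB entry from the RCSB (explicit, cached)
#'
#' Convenience download helper; requires network access and is never invoked
#' implicitly by any analysis function or test.
#'
#' @param id Four-character PDB identifier.
#' @param dir Cache directory; the file is reused if already present.
#' @return Path to the cached PDB file.
#' @export
fetch_structure <- function(id, dir = file.path(tempdir(), "pdb_cache")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(dir, paste0(tolower(id), ".pdb"))
  if (!file.exists(dest)) {
    url <- paste0("https://files.rcsb.org/download/", toupper(id), ".pdb")
    utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  }
  dest
}
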