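#' Catalytic-state labels
#'
#' The four ligand-defined states of the kinase catalytic cycle used
#' throughout the package.
#' @return Character vector of the valid state labels.
#' @export
state_labels <- function() {
  c("substrate_product", "inhibitor", "apo", "peptide")
}

#' Ligand dictionary for catalytic-state classification
#'
#' Maps active-site het codes to catalytic states. `sp_codes` are hydrolysable
#' nucleotides (ATP/ADP); `inhibitor_codes` seed the non-hydrolysable
#' analogue / Type-I ATP-competitive inhibitor list (AMP-PNP plus common
#' co-crystallised inhibitors) and are expected to be extended per corpus;
#' `ignore_codes` are solvent, ions and cryoprotectants that never define a
#' state. Waters are always ignored.
#'
#' @param sp_codes Het codes implying the substrate/product state.
#' @param inhibitor_codes Het codes implying the inhibitor state.
#' @param extra_inhibitors Additional inhibitor codes appended to the seed
#'   list.
#' @param ignore_codes Het codes carrying no state information.
#' @param extra_ignore Additional ignored codes.
#' @param peptide_max_length Maximum residue count of a polymer chain still
#'   treated as a bound peptide rather than a kinase molecule. Substrate
#'   peptides and pseudo-substrate inhibitor peptides run ~5-25 residues while
#'   the kinase chain is ~350, so the default of 30 is unambiguous.
#' @return An object of class `ligand_dictionary`.
#' @export
ligand_dictionary <- function(sp_codes = c("ATP", "ADP"),
                              inhibitor_codes = c("ANP", "STU", "BAL", "IQB",
                                                  "H52", "SKE"),
                              extra_inhibitors = character(),
                              ignore_codes = c("MG", "MN", "ZN", "CA", "NA",
                                               "K", "CL", "IOD", "BR", "SO4",
                                               "PO4", "GOL", "EDO", "ACT",
                                               "MPD", "PEG", "PG4", "TRS",
                                               "MES", "EPE", "FMT", "NO3",
                                               "DTT", "BME", "MYR", "SEP",
                                               "TPO"),
                              extra_ignore = character(),
                              peptide_max_length = 30L) {
  dict <- list(
    sp_codes = unique(toupper(sp_codes)),
    inhibitor_codes = unique(toupper(c(inhibitor_codes, extra_inhibitors))),
    ignore_codes = unique(toupper(c(ignore_codes, extra_ignore, .WATER_CODES))),
    peptide_max_length = as.integer(peptide_max_length)
  )
  if (length(intersect(dict$sp_codes, dict$inhibitor_codes))) {
    stop("ligand dictionary invalid: substrate/product and inhibitor code ",
         "sets overlap: ",
         paste(intersect(dict$sp_codes, dict$inhibitor_codes), collapse = ", "))
  }
  class(dict) <- "ligand_dictionary"
  dict
}

#' Read a ligand dictionary from a JSON config file
#'
#' Keys `sp_codes`, `inhibitor_codes`, `ignore_codes`, `peptide_max_length`;
#' missing keys fall back to the defaults of [ligand_dictionary()].
#'
#' @param path Path to a JSON file.
#' @return A `ligand_dictionary`.
#' @export
read_ligand_dictionary <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- ligand_dictionary()
  ligand_dictionary(
    sp_codes = if (!is.null(cfg$sp_codes)) cfg$sp_codes else defaults$sp_codes,
    inhibitor_codes = if (!is.null(cfg$inhibitor_codes)) cfg$inhibitor_codes
      else defaults$inhibitor_codes,
    ignore_codes = if (!is.null(cfg$ignore_codes)) cfg$ignore_codes
      else defaults$ignore_codes,
    peptide_max_length = if (!is.null(cfg$peptide_max_length))
      cfg$peptide_max_length else defaults$peptide_max_length
  )
}

#' Classify a structure into a catalytic state
#'
#' Assigns one of the four ligand-defined catalytic states from the
#' structure's active-site contents, with the priority
#' substrate/product > inhibitor > peptide > apo:
#' a hydrolysable nucleotide (ATP/ADP) always wins regardless of any bound
#' peptide; otherwise a known inhibitor code wins; otherwise a short polymer
#' chain (length <= `dict$peptide_max_length`) marks the peptide-only state;
#' otherwise the structure is apo. Waters, ions and other ignored codes never
#' affect the outcome, nor does chain order.
#'
#' @param model A `structure_model`.
#' @param dict A `ligand_dictionary`.
#' @return A single character state label.
#' @details A het code found in none of the dictionary's sets raises an
#'   "unclassifiable" error naming the code: the user must extend the
#'   dictionary rather than let the classifier guess.
#' @export
classify_state <- function(model, dict = ligand_dictionary()) {
  stopifnot(inherits(model, "structure_model"),
            inherits(dict, "ligand_dictionary"))
  if (length(model$chains) == 0L) {
    stop("classify_state: ", model$structure_id, " has no polymer chain")
  }
  codes <- toupper(het_codes(model, ignore = dict$ignore_codes))
  unknown <- setdiff(codes, c(dict$sp_codes, dict$inhibitor_codes))
  if (length(unknown)) {
    stop("unclassifiable structure ", model$structure_id,
         ": het code(s) not in ligand dictionary: ",
         paste(sort(unknown), collapse = ", "),
         " (extend inhibitor_codes or ignore_codes)")
  }
  if (any(codes %in% dict$sp_codes)) return("substrate_product")
  if (any(codes %in% dict$inhibitor_codes)) return("inhibitor")
  lens <- vapply(model$chains, function(ch) chain_length(model, ch),
                 integer(1))
  if (any(lens <= dict$peptide_max_length)) return("peptide")
  "apo"
}

#' Kinase (non-peptide) chains of a structure
#'
#' Polymer chains longer than the peptide threshold, in file order. These are
#' the molecules measured and profiled; short peptide chains are ligands.
#'
#' @param model A `structure_model`.
#' @param dict A `ligand_dictionary`.
#' @return Character vector of chain ids.
#' @export
kinase_chains <- function(model, dict = ligand_dictionary()) {
  lens <- vapply(model$chains, function(ch) chain_length(model, ch),
                 integer(1))
  keep <- model$chains[lens > dict$peptide_max_length]
  if (length(keep) == 0L) keep <- model$chains  # peptide-only corpus edge case
  keep
}
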