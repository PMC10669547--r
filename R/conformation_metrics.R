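#' Define a named distance triplet
#'
#' A triplet names three probe atoms (residue number + atom name, default
#' C-alpha) whose three pairwise distances summarise one conformational
#' feature of the kinase domain.
#'
#' @param name Triplet name.
#' @param residues Integer vector of three residue sequence numbers.
#' @param atoms Character vector of three PDB atom names (recycled from
#'   `"CA"`).
#' @return An object of class `distance_triplet`.
#' @export
distance_triplet <- function(name, residues, atoms = "CA") {
  residues <- as.integer(residues)
  atoms <- rep_len(atoms, 3L)
  if (length(residues) != 3L) stop("a triplet needs exactly three residues")
  key <- paste(residues, atoms)
  if (anyDuplicated(key)) stop("triplet probes must be distinct")
  structure(list(name = name,
                 probes = data.frame(residue_seq = residues,
                                     atom_name = atoms,
                                     stringsAsFactors = FALSE)),
            class = "distance_triplet")
}

#' Built-in kinase distance triplets
#'
#' The named conformational metrics of the PKA catalytic subunit, in its
#' conventional residue numbering:
#' \describe{
#'   \item{lobe_closure}{T51 (G-loop), H87 (alpha-C helix), A223 (alpha-F
#'     helix): inter-lobe opening/closing. T51 replaces the historically used
#'     S53 to deconvolute lobe motion from G-loop tip inversions.}
#'   \item{lobe_closure_s53}{the S53 variant of the same metric, kept for
#'     comparison with earlier work.}
#'   \item{dfg_spine}{K72 C-alpha, F185 C-zeta (DFG phenylalanine), L95
#'     C-alpha: regulatory-spine assembly / DFG-in vs DFG-out tendency.}
#'   \item{ctail_gloop}{D328 (C-tail FDDY motif), G52 (G-loop), E127
#'     (catalytic spine): C-tail tethering and G-loop conformation.}
#'   \item{cspine_gloop}{F54 (G-loop), F154 (alpha-E helix), L173 (C-spine):
#'     G-loop orientation relative to the active site.}
#'   \item{nlobe_core}{V104 (core/shield), K81 (alpha-B helix), N113
#'     (beta4-beta5 loop): N-lobe hydrophobic core.}
#' }
#'
#' @return Named list of six `distance_triplet` objects.
#' @export
builtin_triplets <- function() {
  tl <- list(
    lobe_closure = distance_triplet("lobe_closure", c(51, 87, 223)),
    lobe_closure_s53 = distance_triplet("lobe_closure_s53", c(53, 87, 223)),
    dfg_spine = distance_triplet("dfg_spine", c(72, 185, 95),
                                 c("CA", "CZ", "CA")),
    ctail_gloop = distance_triplet("ctail_gloop", c(328, 52, 127)),
    cspine_gloop = distance_triplet("cspine_gloop", c(54, 154, 173)),
    nlobe_core = distance_triplet("nlobe_core", c(104, 81, 113))
  )
  tl
}

#' Euclidean distance between two points
#'
#' @param a,b Numeric 3-vectors (Angstrom).
#' @return Distance in Angstrom.
#' @export
euclidean_dist <- function(a, b) {
  stopifnot(length(a) == 3L, length(b) == 3L,
            all(is.finite(a)), all(is.finite(b)))
  sqrt(sum((a - b)^2))
}

# pair labels "51-223" etc. for the three distances of a triplet
.pair_labels <- function(triplet) {
  r <- triplet$probes$residue_seq
  c(paste0(r[1], "-", r[2]), paste0(r[1], "-", r[3]), paste0(r[2], "-", r[3]))
}

#' Measure one distance triplet on one chain
#'
#' Computes the three pairwise probe distances. A probe that is unresolved in
#' the chain (missing residue or atom) leaves its two distances `NA`; the
#' record is still emitted, because unresolved residues are informative data
#' and per-pair sample sizes legitimately differ downstream.
#'
#' @param model A `structure_model`.
#' @param chain Chain identifier.
#' @param triplet A `distance_triplet`.
#' @param numbering_offset Integer added to the triplet's residue numbers
#'   before lookup, for files whose author numbering is shifted relative to
#'   the conventional numbering. Default 0.
#' @return One-row data frame: `structure_id`, `chain_id`, `triplet`,
#'   `d12`, `d13`, `d23` (Angstrom, `NA` when a probe is missing).
#' @export
measure_triplet <- function(model, chain, triplet, numbering_offset = 0L) {
  stopifnot(inherits(triplet, "distance_triplet"))
  pr <- triplet$probes
  at <- lapply(seq_len(3L), function(i) {
    select_atom(model, chain, pr$residue_seq[i] + numbering_offset,
                pr$atom_name[i])
  })
  xyz <- lapply(at, function(a) if (is.null(a)) NULL else c(a$x, a$y, a$z))
  pd <- function(i, j) {
    if (is.null(xyz[[i]]) || is.null(xyz[[j]])) NA_real_
    else euclidean_dist(xyz[[i]], xyz[[j]])
  }
  data.frame(structure_id = model$structure_id, chain_id = chain,
             triplet = triplet$name,
             d12 = pd(1, 2), d13 = pd(1, 3), d23 = pd(2, 3),
             stringsAsFactors = FALSE)
}

#' Measure distance triplets across a corpus
#'
#' One record per (structure, kinase chain, triplet); structures with several
#' kinase molecules in the asymmetric unit contribute every molecule as an
#' individual entry. Output is deterministically ordered by structure id,
#' chain id and triplet name.
#'
#' @param models List of `structure_model` objects.
#' @param triplets List of `distance_triplet`s (default [builtin_triplets()]).
#' @param states Optional named character vector of state labels per
#'   structure id (e.g. from [classify_state()]); attached as a `state`
#'   column, `NA` where missing.
#' @param dict Ligand dictionary used to separate kinase chains from bound
#'   peptide chains.
#' @param numbering_offset Integer or named integer vector (per structure id)
#'   of residue-numbering offsets.
#' @return Data frame of distance records (long by triplet, wide by pair).
#' @export
measure_corpus <- function(models, triplets = builtin_triplets(),
                           states = NULL, dict = ligand_dictionary(),
                           numbering_offset = 0L) {
  rows <- list()
  for (model in models) {
    off <- if (length(numbering_offset) > 1L || !is.null(names(numbering_offset))) {
      o <- numbering_offset[model$structure_id]
      if (is.na(o)) 0L else o
    } else numbering_offset
    for (ch in kinase_chains(model, dict)) {
      a <- chain_atoms(model, ch)
      if (!any(a$atom_name == "CA")) {
        warning("chain ", ch, " of ", model$structure_id,
                " has no C-alpha atoms; skipped")
        next
      }
      for (tp in triplets) {
        rows[[length(rows) + 1L]] <- measure_triplet(model, ch, tp, off)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(structure_id = character(), chain_id = character(),
                      triplet = character(), d12 = numeric(), d13 = numeric(),
                      d23 = numeric(), state = character(),
                      stringsAsFactors = FALSE))
  }
  rec <- do.call(rbind, rows)
  rec$state <- if (is.null(states)) NA_character_
    else unname(states[rec$structure_id])
  rec <- rec[order(rec$structure_id, rec$chain_id, rec$triplet), ,
             drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Reshape distance records to one row per pair
#'
#' Converts the wide (d12/d13/d23) record layout into a tidy long table with
#' a `pair` label such as `"51-223"`, suitable for grouped summaries, KDEs
#' and TSV export. Missing distances are kept as `NA` rows so per-pair sample
#' sizes remain visible.
#'
#' @param records Data frame from [measure_corpus()].
#' @param triplets The triplet definitions used (for pair labels).
#' @return Long data frame: `structure_id`, `chain_id`, `state`, `triplet`,
#'   `pair`, `distance`.
#' @export
distances_long <- function(records, triplets = builtin_triplets()) {
  labs <- lapply(triplets, .pair_labels)
  names(labs) <- vapply(triplets, `[[`, "", "name")
  out <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    lab <- labs[[r$triplet]]
    if (is.null(lab)) lab <- c("d12", "d13", "d23")
    data.frame(structure_id = r$structure_id, chain_id = r$chain_id,
               state = r$state, triplet = r$triplet, pair = lab,
               distance = c(r$d12, r$d13, r$d23), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
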