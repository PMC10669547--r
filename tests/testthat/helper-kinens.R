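# Test-side PDB line formatter, independent of the package's writer, so
# round-trip tests do not validate the writer against itself.
pdb_line <- function(record = "ATOM", serial = 1L, name = "CA", alt = "",
                     resname = "ALA", chain = "A", resno = 1L, icode = "",
                     x = 0, y = 0, z = 0, occ = 1.00, b = 20.00,
                     element = "C") {
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, ifelse(alt == "", " ", alt), resname, chain,
          resno, ifelse(icode == "", " ", icode), x, y, z, occ, b, element)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# A minimal kinase-like model: a long chain with all probe residues plus an
# optional ligand and peptide, written through the test-side formatter.
fixture_kinase <- function(path = tempfile(fileext = ".pdb"),
                           het = NULL, peptide = FALSE, n_res = 40L) {
  markers <- default_marker_positions()
  lines <- character(0)
  serial <- 0L
  resnos <- sort(unique(c(seq(40L, 40L + n_res - 1L),
                          as.integer(names(markers)))))
  for (r in resnos) {
    mk <- markers[[as.character(r)]]
    ca <- if (!is.null(mk) && r != 185L) mk else c(r * 1.5, -50, 0)
    serial <- serial + 1L
    lines <- c(lines, pdb_line(serial = serial, name = "CA", resno = r,
                               x = ca[1], y = ca[2], z = ca[3]))
    if (r == 185L) {
      serial <- serial + 1L
      cz <- markers[["185"]]
      lines <- c(lines, pdb_line(serial = serial, name = "CZ",
                                 resname = "PHE", resno = r, x = cz[1],
                                 y = cz[2], z = cz[3]))
    }
  }
  if (!is.null(het)) {
    serial <- serial + 1L
    lines <- c(lines, pdb_line(record = "HETATM", serial = serial,
                               name = "PA", resname = het, resno = 401L,
                               x = 50, y = 0, z = 0, element = "P"))
  }
  if (peptide) {
    for (k in 1:12) {
      serial <- serial + 1L
      lines <- c(lines, pdb_line(serial = serial, name = "CA", chain = "P",
                                 resno = k, x = 30 + k, y = -80, z = 0))
    }
  }
  write_pdb_fixture(lines, path)
}

# small corpus used by several test files; cached per test run
small_corpus <- local({
  cache <- NULL
  function(seed = 101L) {
    if (!is.null(cache)) return(cache)
    dir <- file.path(tempdir(), paste0("kinens_corpus_", seed))
    corp <- generate_corpus(
      dir, counts = c(substrate_product = 6L, inhibitor = 6L, apo = 5L,
                      peptide = 3L), seed = seed)
    corp$models <- lapply(corp$files, read_structure)
    cache <<- corp
    corp
  }
})
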