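# Internal molecule representation: a V2000 connection table parsed into
# atoms/bonds plus the raw molblock lines, so subgraphs can be cut out while
# preserving every atom-level field (charges, isotopes) verbatim.

OB_OPTS_NOSTEREO <- "b"  # placeholder; stereo is stripped at the text level

#' @keywords internal
mc_strip_stereo <- function(smiles) {
  # '@' occurs only as a chirality marker, '/' and '\' only as cis/trans bond
  # markers; removing them leaves a valid achiral SMILES.
  gsub("[@/\\\\]", "", smiles)
}

# Convert text between chemical formats through OpenBabel; returns "" on
# failure (OpenBabel reports parse errors on stderr and emits nothing).
mc_convert <- function(from, to, text) {
  if (!endsWith(text, "\n")) text <- paste0(text, "\n")
  out <- suppressWarnings(ChemmineOB::convertFormat(from, to, text))
  if (is.null(out)) "" else out
}

# SMILES text (one per line) -> character vector of canonical SMILES, NA for
# lines OpenBabel cannot parse. Tries one batch call first; falls back to
# per-molecule calls only when some line failed (a failed line aborts the
# OpenBabel batch stream).
mc_canonical_batch <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  batch <- mc_convert("SMI", "CAN", paste(smiles, collapse = "\n"))
  lines <- strsplit(batch, "\n", fixed = TRUE)[[1]]
  lines <- sub("[\t ].*$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == n) return(lines)
  vapply(smiles, function(s) {
    one <- mc_convert("SMI", "CAN", s)
    one <- sub("[\t ].*$", "", strsplit(one, "\n", fixed = TRUE)[[1]][1])
    if (is.na(one) || !nzchar(one)) NA_character_ else one
  }, character(1), USE.NAMES = FALSE)
}

# Parse one SMILES into the internal molecule structure, or NULL on failure.
# Stereo is stripped; if largest_fragment, only the largest covalent
# component is kept (salt handling).
mc_parse_smiles <- function(smiles, largest_fragment = FALSE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(trimws(smiles))) return(NULL)
  sdf <- mc_convert("SMI", "SDF", mc_strip_stereo(trimws(smiles)))
  if (!nzchar(sdf)) return(NULL)
  mol <- mc_from_molblock(sdf)
  if (is.null(mol)) return(NULL)
  if (largest_fragment) mol <- mc_largest_fragment(mol)
  mol
}

# Parse a V2000 molblock (possibly with $$$$ terminator) into the internal
# structure. ChemmineR does the connection-table parsing; the raw lines are
# retained for verbatim subsetting.
mc_from_molblock <- function(molblock) {
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
  end <- which(lines == "M  END")
  if (length(end) == 0L) return(NULL)
  lines <- lines[seq_len(end[1])]
  sdfstr <- ChemmineR::read.SDFstr(textConnection(c(lines, "$$$$")))
  sdf <- tryCatch(ChemmineR::read.SDFset(sdfstr)[[1]], error = function(e) NULL)
  if (is.null(sdf)) return(NULL)
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  symbols <- sub("_[0-9]+$", "", rownames(ab))
  atoms <- data.frame(
    symbol = symbols,
    x = unname(ab[, 1]), y = unname(ab[, 2]),
    stringsAsFactors = FALSE
  )
  if (is.null(bb) || nrow(bb) == 0L) {
    bonds <- data.frame(from = integer(0), to = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(
      from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
      order = as.integer(bb[, 3])
    )
  }
  # M-block atom properties that must be renumbered when subsetting
  mlines <- grep("^M  (CHG|ISO|RAD)", lines, value = TRUE)
  props <- do.call(rbind, lapply(mlines, function(l) {
    tag <- substr(l, 4, 6)
    flds <- as.integer(strsplit(trimws(substr(l, 10, nchar(l))), "[ ]+")[[1]])
    k <- flds[1]
    data.frame(tag = tag,
               atom = flds[seq(2, by = 2, length.out = k)],
               value = flds[seq(3, by = 2, length.out = k)])
  }))
  if (is.null(props)) {
    props <- data.frame(tag = character(0), atom = integer(0), value = integer(0))
  }
  structure(
    list(atoms = atoms, bonds = bonds, props = props,
         atom_lines = lines[4L + seq_len(n)]),
    class = "mc_mol"
  )
}

mc_natoms <- function(mol) nrow(mol$atoms)

# igraph view of the heavy-atom skeleton
mc_graph <- function(mol) {
  g <- igraph::make_empty_graph(n = mc_natoms(mol), directed = FALSE)
  if (nrow(mol$bonds) > 0L) {
    g <- igraph::add_edges(g, rbind(mol$bonds$from, mol$bonds$to))
  }
  igraph::set_edge_attr(g, "order",
                        value = if (nrow(mol$bonds)) mol$bonds$order else integer(0))
}

mc_largest_fragment <- function(mol) {
  comp <- igraph::components(mc_graph(mol))
  if (comp$no <= 1L) return(mol)
  big <- which.max(comp$csize)  # ties: first component, deterministic
  mc_subset(mol, which(comp$membership == big))
}

# Extract the induced subgraph on `keep` (original atom indices) as a new
# mc_mol. Optional extra dummy atoms (symbol "*") can be appended, each
# bonded to one kept atom; used for substituent attachment points.
# Atom lines are copied verbatim so charges/isotopes survive untouched.
mc_subset <- function(mol, keep, dummy_attach = integer(0)) {
  keep <- sort(unique(as.integer(keep)))
  idx <- match(seq_len(mc_natoms(mol)), keep)  # old -> new index or NA
  nkeep <- length(keep)
  ndum <- length(dummy_attach)
  b <- mol$bonds
  bkeep <- b[!is.na(idx[b$from]) & !is.na(idx[b$to]), , drop = FALSE]
  atom_lines <- mol$atom_lines[keep]
  if (ndum > 0L) {
    at <- mol$atoms[dummy_attach, , drop = FALSE]
    atom_lines <- c(atom_lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      at$x + 0.5, at$y + 0.5, 0, "*"))
  }
  bond_lines <- character(0)
  if (nrow(bkeep) > 0L) {
    bond_lines <- sprintf("%3d%3d%3d  0  0  0  0",
                          idx[bkeep$from], idx[bkeep$to], bkeep$order)
  }
  if (ndum > 0L) {
    bond_lines <- c(bond_lines, sprintf("%3d%3d%3d  0  0  0  0",
                                        nkeep + seq_len(ndum),
                                        idx[dummy_attach], 1L))
  }
  p <- mol$props[mol$props$atom %in% keep, , drop = FALSE]
  prop_lines <- character(0)
  if (nrow(p) > 0L) {
    prop_lines <- vapply(split(p, p$tag), function(pp) {
      sprintf("M  %s%3d%s", pp$tag[1], nrow(pp),
              paste0(sprintf("%4d%4d", idx[pp$atom], pp$value), collapse = ""))
    }, character(1))
  }
  block <- paste(c(
    "", "  moleculecloud", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
            nkeep + ndum, length(bond_lines)),
    atom_lines, bond_lines, prop_lines, "M  END", "$$$$", ""
  ), collapse = "\n")
  mc_from_molblock(block)
}

# Canonical SMILES of an internal molecule via OpenBabel.
mc_to_smiles <- function(mol) {
  block <- paste(c(
    "", "  moleculecloud", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
            mc_natoms(mol), nrow(mol$bonds)),
    mol$atom_lines,
    if (nrow(mol$bonds)) sprintf("%3d%3d%3d  0  0  0  0",
                                 mol$bonds$from, mol$bonds$to, mol$bonds$order),
    if (nrow(mol$props)) vapply(split(mol$props, mol$props$tag), function(pp) {
      sprintf("M  %s%3d%s", pp$tag[1], nrow(pp),
              paste0(sprintf("%4d%4d", pp$atom, pp$value), collapse = ""))
    }, character(1)),
    "M  END", "$$$$", ""
  ), collapse = "\n")
  out <- mc_convert("SDF", "CAN", block)
  smi <- sub("[\t ].*$", "", strsplit(out, "\n", fixed = TRUE)[[1]][1])
  if (is.na(smi) || !nzchar(smi)) NA_character_ else smi
}

mc_is_hetero <- function(symbol) !(symbol %in% c("C", "H", "*"))
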