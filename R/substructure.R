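#' Canonicalize SMILES strings
#'
#' Converts SMILES to a single canonical form so that identical molecular
#' graphs aggregate under one key. Canonicalization is delegated to
#' OpenBabel's canonical SMILES writer; stereochemistry markers are stripped
#' beforehand so stereoisomeric cores collapse to the same flat 2D key (the
#' cloud displays flat depictions). Charges and isotopes are preserved.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES; `NA` where a string could
#'   not be parsed.
#' @examples
#' canonicalize_smiles(c("C1=CC=CC=C1", "c1ccccc1", "OCC"))
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  mc_canonical_batch(mc_strip_stereo(trimws(smiles)))
}

# Ring-atom membership: an atom is in a ring iff it is incident to at least
# one edge that is not a bridge.
mc_ring_atoms <- function(g) {
  ne <- igraph::ecount(g)
  if (ne == 0L) return(integer(0))
  br <- igraph::bridges(g)
  ring_edges <- setdiff(seq_len(ne), as.integer(br))
  if (length(ring_edges) == 0L) return(integer(0))
  unique(as.integer(igraph::ends(g, ring_edges, names = FALSE)))
}

# Atom indices forming the Murcko framework: ring atoms plus linkers,
# obtained by iteratively pruning non-ring terminal atoms; optionally atoms
# attached to the framework by a multiple bond (exocyclic =O and friends)
# are retained.
mc_scaffold_atoms <- function(mol, keep_exocyclic = TRUE) {
  g <- mc_graph(mol)
  ring <- mc_ring_atoms(g)
  if (length(ring) == 0L) return(integer(0))
  keep <- rep(TRUE, mc_natoms(mol))
  is_ring <- seq_along(keep) %in% ring
  b <- mol$bonds
  repeat {
    deg <- tabulate(c(b$from[keep[b$from] & keep[b$to]],
                      b$to[keep[b$from] & keep[b$to]]),
                    nbins = length(keep))
    prune <- keep & !is_ring & deg <= 1L
    if (!any(prune)) break
    keep[prune] <- FALSE
  }
  core <- which(keep)
  if (keep_exocyclic) {
    multi <- b[b$order >= 2L, , drop = FALSE]
    extra <- c(multi$to[multi$from %in% core & !(multi$to %in% core)],
               multi$from[multi$to %in% core & !(multi$from %in% core)])
    core <- sort(unique(c(core, extra)))
  }
  core
}

#' Extract the Murcko scaffold of a molecule
#'
#' Reduces a molecule to its framework: all ring atoms plus the linker atoms
#' lying on paths between rings, with every other substituent atom removed.
#' By the usual Murcko-framework convention, atoms attached to the framework
#' by a double or triple bond (such as the oxygen of a ring-attached
#' carbonyl) are retained; set `keep_exocyclic = FALSE` for the pure pruned
#' framework.
#'
#' @param smiles a single SMILES string.
#' @param keep_exocyclic keep atoms multiple-bonded to the framework.
#' @return canonical SMILES of the scaffold, or `NA` if the molecule has no
#'   rings (caller should fall back to [extract_major_chain()]).
#' @examples
#' extract_scaffold("Cc1ccccc1")        # toluene -> benzene
#' extract_scaffold("CCCCCC")           # acyclic -> NA
#' @export
extract_scaffold <- function(smiles, keep_exocyclic = TRUE) {
  mol <- mc_parse_smiles(smiles, largest_fragment = TRUE)
  if (is.null(mol)) stop("unparseable SMILES: ", smiles)
  core <- mc_scaffold_atoms(mol, keep_exocyclic)
  if (length(core) == 0L) return(NA_character_)
  mc_to_smiles(mc_subset(mol, core))
}

#' Extract the major chain of an acyclic molecule
#'
#' For ring-free molecules the cloud displays the major chain: the longest
#' simple path through the heavy atoms; among equally long paths, the one
#' containing the most heteroatoms; any remaining tie is broken by taking
#' the path whose canonical SMILES sorts first (C locale), which makes the
#' result deterministic across platforms.
#'
#' @param smiles a single SMILES string of a ring-free molecule.
#' @return canonical SMILES of the major chain.
#' @examples
#' extract_major_chain("CCC(C)C")  # 2-methylbutane -> butane
#' @export
extract_major_chain <- function(smiles) {
  mol <- mc_parse_smiles(smiles, largest_fragment = TRUE)
  if (is.null(mol)) stop("unparseable SMILES: ", smiles)
  g <- mc_graph(mol)
  if (length(mc_ring_atoms(g)) > 0L)
    stop("molecule contains rings; use extract_scaffold()")
  n <- mc_natoms(mol)
  if (n == 1L) return(mc_to_smiles(mol))
  het <- mc_is_hetero(mol$atoms$symbol)
  best_len <- -1L; best_het <- -1L; best_paths <- list()
  # acyclic connected graph is a tree: the path between any two atoms is
  # unique, and every maximal simple path runs between two leaves
  deg <- igraph::degree(g)
  leaves <- which(deg <= 1L)
  for (i in seq_along(leaves)) {
    sp <- igraph::shortest_paths(g, from = leaves[i],
                                 to = leaves[leaves > leaves[i]])$vpath
    for (p in sp) {
      v <- as.integer(p)
      len <- length(v); nh <- sum(het[v])
      if (len > best_len || (len == best_len && nh > best_het)) {
        best_len <- len; best_het <- nh; best_paths <- list(v)
      } else if (len == best_len && nh == best_het) {
        best_paths <- c(best_paths, list(v))
      }
    }
  }
  smis <- vapply(best_paths, function(v) mc_to_smiles(mc_subset(mol, v)),
                 character(1))
  sort(smis, method = "radix")[1]
}

#' Extract substituents of a molecule
#'
#' Cuts every single bond connecting a scaffold atom (ring or linker atom)
#' to a non-scaffold atom. Each detached fragment with at most `max_atoms`
#' heavy atoms is returned with its attachment point marked by a dummy atom
#' (`*`). The dummy is not counted against `max_atoms`. Ring-free molecules
#' have no scaffold and therefore yield no substituents.
#'
#' @param smiles a single SMILES string.
#' @param max_atoms maximum heavy-atom count of a reported fragment.
#' @param keep_exocyclic treat atoms multiple-bonded to the framework as
#'   scaffold atoms (so a ring carbonyl oxygen is not a substituent).
#' @return character vector of canonical substituent SMILES (one entry per
#'   occurrence; duplicates preserved), empty when there are none.
#' @examples
#' extract_substituents("Cc1ccccc1")  # toluene -> "*C"
#' @export
extract_substituents <- function(smiles, max_atoms = 15L,
                                 keep_exocyclic = TRUE) {
  stopifnot(max_atoms >= 1L)
  mol <- mc_parse_smiles(smiles, largest_fragment = TRUE)
  if (is.null(mol)) stop("unparseable SMILES: ", smiles)
  core <- mc_scaffold_atoms(mol, keep_exocyclic)
  if (length(core) == 0L) return(character(0))
  rest <- setdiff(seq_len(mc_natoms(mol)), core)
  if (length(rest) == 0L) return(character(0))
  g <- mc_graph(mol)
  sub <- igraph::induced_subgraph(g, rest)
  comp <- igraph::components(sub)
  b <- mol$bonds
  out <- character(0)
  for (k in seq_len(comp$no)) {
    frag <- rest[comp$membership == k]
    if (length(frag) > max_atoms) next
    # bonds tying this fragment to the scaffold
    att <- b[(b$from %in% frag & b$to %in% core) |
             (b$to %in% frag & b$from %in% core), , drop = FALSE]
    if (nrow(att) != 1L || att$order[1] != 1L) next  # only single-bond cuts
    anchor <- if (att$from[1] %in% frag) att$from[1] else att$to[1]
    out <- c(out, mc_to_smiles(mc_subset(mol, frag, dummy_attach = anchor)))
  }
  sort(out, method = "radix")
}

#' Reduce a molecule collection to aggregated substructure records
#'
#' The workhorse of the pipeline: each parseable molecule is reduced to its
#' scaffold (or, if it has no rings, its major chain), or to its set of
#' substituents, and identical canonical cores are aggregated with their
#' frequencies. Activity flags and target-class labels, when supplied, are
#' aggregated per record: `activity_ratio` is the fraction of contributing
#' molecules flagged active, and per-class fractions are tallied into
#' `class_*` columns. Unparseable SMILES are skipped and counted.
#'
#' @param smiles character vector of SMILES strings.
#' @param mode `"scaffold"` (scaffold with major-chain fallback) or
#'   `"substituent"`.
#' @param is_active optional logical vector, one flag per molecule.
#' @param target_class optional character vector of class labels per
#'   molecule (`NA` = unannotated).
#' @param max_atoms substituent size cutoff (heavy atoms), mode
#'   `"substituent"` only.
#' @param keep_exocyclic see [extract_scaffold()].
#' @return a `data.frame` with columns `canonical_smiles`, `kind`
#'   (`scaffold`/`chain`/`substituent`), `frequency`, and, when annotations
#'   were given, `activity_ratio` and/or `class_<label>` fraction columns.
#'   Rows are ordered by decreasing frequency (ties by canonical SMILES).
#'   The attribute `"report"` carries `parsed` and `failed` counts.
#' @export
reduce_collection <- function(smiles, mode = c("scaffold", "substituent"),
                              is_active = NULL, target_class = NULL,
                              max_atoms = 15L, keep_exocyclic = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is.character(smiles))
  if (!is.null(is_active)) stopifnot(length(is_active) == length(smiles))
  if (!is.null(target_class)) stopifnot(length(target_class) == length(smiles))
  keys <- vector("list", length(smiles))
  kinds <- vector("list", length(smiles))
  failed <- 0L
  for (i in seq_along(smiles)) {
    mol <- mc_parse_smiles(smiles[i], largest_fragment = TRUE)
    if (is.null(mol)) { failed <- failed + 1L; next }
    if (mode == "scaffold") {
      core <- mc_scaffold_atoms(mol, keep_exocyclic)
      if (length(core) > 0L) {
        keys[[i]] <- mc_to_smiles(mc_subset(mol, core))
        kinds[[i]] <- "scaffold"
      } else {
        keys[[i]] <- extract_major_chain(mc_to_smiles(mol))
        kinds[[i]] <- "chain"
      }
    } else {
      frs <- extract_substituents(mc_to_smiles(mol), max_atoms = max_atoms,
                                  keep_exocyclic = keep_exocyclic)
      if (length(frs) > 0L) {
        keys[[i]] <- frs
        kinds[[i]] <- rep("substituent", length(frs))
      }
    }
  }
  contrib <- rep.int(seq_along(smiles), lengths(keys))
  key <- unlist(keys, use.names = FALSE)
  kind <- unlist(kinds, use.names = FALSE)
  parsed <- length(smiles) - failed
  if (length(key) == 0L) {
    rec <- data.frame(canonical_smiles = character(0), kind = character(0),
                      frequency = integer(0))
    attr(rec, "report") <- list(parsed = parsed, failed = failed)
    return(rec)
  }
  freq <- tapply(seq_along(key), key, length)
  rec <- data.frame(canonical_smiles = names(freq),
                    kind = as.vector(tapply(kind, key, `[`, 1L)),
                    frequency = as.integer(freq),
                    stringsAsFactors = FALSE)
  if (!is.null(is_active)) {
    act <- as.logical(is_active)[contrib]
    nact <- tapply(ifelse(is.na(act), 0L, as.integer(act)), key, sum)
    rec$activity_ratio <- as.numeric(nact[rec$canonical_smiles]) / rec$frequency
  }
  if (!is.null(target_class)) {
    cls <- as.character(target_class)[contrib]
    for (lab in sort(unique(cls[!is.na(cls)]), method = "radix")) {
      cnt <- tapply(!is.na(cls) & cls == lab, key, sum)
      rec[[paste0("class_", lab)]] <-
        as.numeric(cnt[rec$canonical_smiles]) / rec$frequency
    }
  }
  rec <- rec[order(-rec$frequency, rec$canonical_smiles,
                   method = "radix"), , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "report") <- list(parsed = parsed, failed = failed)
  rec
}
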