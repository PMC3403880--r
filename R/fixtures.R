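# Synthetic fixtures emulating the structure of real compound collections:
# a long-tailed (power-law) rank-frequency distribution over drug-like ring
# systems, optional bioactivity and target-class annotations, and random
# acyclic molecules for chain analysis. Everything is deterministic under a
# seed so the whole pipeline is testable offline.

# run expr with a local RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Built-in library of common drug-like ring systems. Every entry begins with
# a carbon atom with a free valence, so a chain prefix pasted in front of
# the SMILES forms a valid substituted molecule whose scaffold is the entry
# itself (validated in the test suite).
MC_SCAFFOLD_LIBRARY <- c(
  "c1ccccc1",                 # benzene
  "c1ccncc1",                 # pyridine
  "c1ccc2ccccc2c1",           # naphthalene
  "c1ccc2[nH]ccc2c1",         # indole (1H)
  "c1ccc2ncccc2c1",           # quinoline
  "c1ccc2occc2c1",            # benzofuran
  "c1ccc2sccc2c1",            # benzothiophene
  "c1ccc2nccnc2c1",           # quinoxaline
  "c1ccc(-c2ccccc2)cc1",      # biphenyl
  "c1cncnc1",                 # pyrimidine
  "c1ccsc1",                  # thiophene
  "c1ccoc1",                  # furan
  "c1cc[nH]c1",               # pyrrole
  "c1c[nH]cn1",               # imidazole
  "c1cn[nH]c1",               # pyrazole
  "c1nc[nH]n1",               # 1,2,4-triazole
  "c1csnn1",                  # thiadiazole-like
  "c1ocnc1",                  # oxazole
  "c1scnc1",                  # thiazole
  "c1cnncn1",                 # triazine-like
  "C1CCCCC1",                 # cyclohexane
  "C1CCCC1",                  # cyclopentane
  "C1CCNCC1",                 # piperidine
  "C1CNCCN1",                 # piperazine
  "C1COCCN1",                 # morpholine
  "C1CSCCN1",                 # thiomorpholine
  "C1CCOC1",                  # tetrahydrofuran
  "C1CCNC1",                  # pyrrolidine
  "C1CCOCC1",                 # tetrahydropyran
  "C1CCCCCC1",                # cycloheptane
  "C1CC1",                    # cyclopropane
  "C1CCC2CCCCC2C1",           # decalin
  "C1Cc2ccccc2C1",            # indane
  "C1CCc2ccccc2C1",           # tetralin
  "C1COc2ccccc2O1",           # benzodioxine
  "C1Cc2ccccc2N1",            # indoline
  "C1CNc2ccccc2C1",           # tetrahydroquinoline
  "C1COc2ccccc2N1",           # benzoxazine
  "c1nc2[nH]cnc2cn1",         # purine-like
  "c1cnc2[nH]ccc2c1",         # azaindole
  "c1ccc2c(c1)oc1ccccc12",    # dibenzofuran
  "c1ccc2c(c1)sc1ccccc12",    # dibenzothiophene
  "c1ccc2c(c1)[nH]c1ccccc12", # carbazole
  "c1ccc2c(c1)ncc1ccccc12",   # acridine-like
  "C1CN2CCC1CC2",             # quinuclidine
  "c1ccc(-c2ccncc2)cc1",      # phenylpyridine
  "c1ccc(-c2cncnc2)cc1",      # phenylpyrimidine
  "c1ccc(-n2cccc2)cc1"        # N-phenylpyrrole
)

# Scaffold SMILES for ranks beyond the built-in library: two ring systems
# joined by an alkyl linker of increasing length (the linker is part of the
# framework, so each variant is its own scaffold).
mc_composed_scaffolds <- function(n_extra, existing) {
  heads <- c("C1CCCCC1", "c1ccccc1", "C1CCNCC1", "C1COCCN1", "C1CCCC1")
  out <- character(0)
  seen <- existing
  for (j in seq_len(25L)) {
    cand <- as.vector(outer(paste0(heads, strrep("C", j)),
                            MC_SCAFFOLD_LIBRARY, paste0))
    can <- canonicalize_smiles(cand)
    keep <- !is.na(can) & !duplicated(can) & !(can %in% seen)
    out <- c(out, cand[keep])
    seen <- c(seen, can[keep])
    if (length(out) >= n_extra) return(out[seq_len(n_extra)])
  }
  stop("cannot compose enough distinct scaffolds")
}

# Integer frequencies following frequency(rank) ~ rank^(-exponent), summing
# exactly to n_molecules, each at least 1 (largest-remainder rounding).
mc_powerlaw_counts <- function(n_scaffolds, exponent, n_molecules) {
  stopifnot(n_scaffolds >= 1L, exponent > 0, n_molecules >= n_scaffolds)
  w <- seq_len(n_scaffolds)^(-exponent)
  target <- n_molecules * w / sum(w)
  f <- floor(target)
  rem <- n_molecules - sum(f)
  if (rem > 0) {
    extra <- order(target - f, decreasing = TRUE)[seq_len(rem)]
    f[extra] <- f[extra] + 1L
  }
  short <- f < 1L
  if (any(short)) {
    need <- sum(1L - f[short])
    f[short] <- 1L
    donors <- order(f, decreasing = TRUE)
    i <- 1L
    while (need > 0L) {
      d <- donors[i]
      give <- min(need, f[d] - 1L)
      f[d] <- f[d] - give
      need <- need - give
      i <- i + 1L
    }
  }
  as.integer(f)
}

#' Generate a synthetic power-law scaffold table
#'
#' Produces aggregated scaffold records whose rank-frequency curve follows
#' `frequency(rank) ~ rank^(-exponent)` — the long-tail distribution that
#' scaffold counts in real compound databases follow — with total frequency
#' `n_molecules`. Scaffold SMILES are drawn from a built-in library of
#' common ring systems; when more are requested than the library holds,
#' additional distinct scaffolds are composed as linker-joined ring pairs.
#'
#' @param n_scaffolds number of distinct scaffold records.
#' @param exponent power-law exponent (> 0); 1.5 is typical of scaffold
#'   counts in large collections.
#' @param n_molecules total frequency mass (>= `n_scaffolds`).
#' @param seed integer seed; the output is a deterministic function of the
#'   arguments.
#' @param annotate `"none"`, `"activity"` (adds `activity_ratio` in
#'   \[0,1\]), or `"target_class"` (adds `class_*` fraction columns over the
#'   six standard target classes, with a dominant class for most scaffolds).
#' @return a `data.frame` of substructure records (see
#'   [reduce_collection()]), ordered by decreasing frequency.
#' @export
generate_powerlaw_fixture <- function(n_scaffolds, exponent = 1.5,
                                      n_molecules = 100L * n_scaffolds,
                                      seed = 1L,
                                      annotate = c("none", "activity",
                                                   "target_class")) {
  annotate <- match.arg(annotate)
  f <- mc_powerlaw_counts(n_scaffolds, exponent, n_molecules)
  lib <- canonicalize_smiles(MC_SCAFFOLD_LIBRARY)
  if (n_scaffolds > length(lib)) {
    extra <- mc_composed_scaffolds(n_scaffolds - length(lib), lib)
    lib <- c(lib, canonicalize_smiles(extra))
  }
  smis <- lib[seq_len(n_scaffolds)]
  rec <- data.frame(canonical_smiles = smis, kind = "scaffold",
                    frequency = f, stringsAsFactors = FALSE)
  with_seed(seed, {
    if (annotate == "activity") {
      rec$activity_ratio <- round(stats::runif(n_scaffolds), 3)
    } else if (annotate == "target_class") {
      classes <- names(MC_CLASS_PALETTE)
      dominant <- sample(classes, n_scaffolds, replace = TRUE)
      # ~70% of scaffolds get a clear dominant class, the rest mixed
      share <- ifelse(stats::runif(n_scaffolds) < 0.7,
                      stats::runif(n_scaffolds, 0.75, 1),
                      stats::runif(n_scaffolds, 0.3, 0.65))
      for (cl in classes) {
        rest <- stats::runif(n_scaffolds)
        rec[[paste0("class_", cl)]] <- round(ifelse(
          dominant == cl, share, (1 - share) * rest / 5), 3)
      }
    }
  })
  attr(rec, "report") <- list(parsed = n_molecules, failed = 0L)
  rec
}

#' Generate a synthetic raw-molecule fixture
#'
#' Emits individual molecules (SMILES plus optional activity flag and
#' target-class label) whose scaffold composition follows a power law over
#' the built-in ring-system library: each molecule is a library scaffold
#' decorated with a small random substituent. Feeding the output through
#' [reduce_collection()] recovers the scaffold distribution, which makes
#' this the end-to-end fixture for the full pipeline.
#'
#' @param n_molecules number of molecules.
#' @param n_scaffolds number of distinct parent scaffolds (<= library size
#'   unless composition kicks in).
#' @param exponent power-law exponent for scaffold sampling weights.
#' @param seed integer seed.
#' @param annotate as in [generate_powerlaw_fixture()].
#' @return a `data.frame` with columns `smiles`, `name`, and optionally
#'   `is_active` / `target_class`.
#' @export
generate_molecule_fixture <- function(n_molecules, n_scaffolds = 30L,
                                      exponent = 1.5, seed = 1L,
                                      annotate = c("none", "activity",
                                                   "target_class")) {
  annotate <- match.arg(annotate)
  stopifnot(n_molecules >= 1L)
  lib <- MC_SCAFFOLD_LIBRARY
  if (n_scaffolds > length(lib)) {
    lib <- c(lib, mc_composed_scaffolds(n_scaffolds - length(lib),
                                        canonicalize_smiles(lib)))
  }
  lib <- lib[seq_len(n_scaffolds)]
  prefixes <- c("", "C", "CC", "CCC", "CC(C)", "O", "OC", "N", "NC",
                "CO", "CN", "OCC", "CCO")
  with_seed(seed, {
    w <- seq_len(n_scaffolds)^(-exponent)
    sc <- sample.int(n_scaffolds, n_molecules, replace = TRUE, prob = w)
    pre <- sample(prefixes, n_molecules, replace = TRUE)
    df <- data.frame(
      smiles = paste0(pre, lib[sc]),
      name = sprintf("MOL%05d", seq_len(n_molecules)),
      stringsAsFactors = FALSE
    )
    if (annotate == "activity") {
      p_act <- stats::runif(n_scaffolds)           # scaffold-level propensity
      df$is_active <- stats::runif(n_molecules) < p_act[sc]
    } else if (annotate == "target_class") {
      classes <- names(MC_CLASS_PALETTE)
      dominant <- sample(classes, n_scaffolds, replace = TRUE)
      purity <- stats::runif(n_scaffolds, 0.5, 1)
      pick_dom <- stats::runif(n_molecules) < purity[sc]
      alt <- sample(classes, n_molecules, replace = TRUE)
      df$target_class <- ifelse(pick_dom, dominant[sc], alt)
    }
    df
  })
}

#' Generate random acyclic molecules
#'
#' Builds random heavy-atom trees over C/N/O/S respecting standard valences
#' and returns their SMILES. Used to exercise major-chain extraction against
#' exhaustive path enumeration.
#'
#' @param n number of molecules.
#' @param min_atoms,max_atoms heavy-atom count range.
#' @param seed integer seed.
#' @return character vector of SMILES.
#' @export
random_acyclic_smiles <- function(n, min_atoms = 2L, max_atoms = 12L,
                                  seed = 1L) {
  stopifnot(min_atoms >= 1L, max_atoms >= min_atoms)
  valence <- c(C = 4L, N = 3L, O = 2L, S = 2L)
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      na <- sample(min_atoms:max_atoms, 1L)
      sym <- sample(names(valence), na, replace = TRUE,
                    prob = c(0.6, 0.15, 0.15, 0.1))
      from <- integer(0); to <- integer(0)
      used <- integer(na)  # bonds consumed per atom
      for (v in seq_len(na)[-1]) {
        open <- which(seq_len(na) < v & used < valence[sym][seq_len(na)])
        u <- if (length(open) == 1L) open else sample(open, 1L)
        from <- c(from, u); to <- c(to, v)
        used[u] <- used[u] + 1L; used[v] <- used[v] + 1L
      }
      block <- paste(c(
        "", "  moleculecloud", "",
        sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, na - 1L),
        sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                seq_len(na), 0, 0, sym),
        if (na > 1L) sprintf("%3d%3d  1  0  0  0  0", from, to),
        "M  END", "$$$$", ""
      ), collapse = "\n")
      out <- mc_convert("SDF", "CAN", block)
      sub("[\t ].*$", "", strsplit(out, "\n", fixed = TRUE)[[1]][1])
    }, character(1))
  })
}
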