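test_that("scaffold extraction matches the Murcko reduction rule", {
  can <- canonicalize_smiles
  # single substituent removed
  expect_identical(extract_scaffold("Cc1ccccc1"), can("c1ccccc1"))
  # inter-ring bond is part of the core, tail removed
  expect_identical(extract_scaffold("CCCc1ccccc1-c2ccccc2"),
                   can("c1ccc(-c2ccccc2)cc1"))
  # linker nitrogen stays only while it connects rings; here it does not
  expect_identical(extract_scaffold("NCCN1CCOCC1"), can("C1COCCN1"))
  # no rings -> NA, signalling major-chain fallback
  expect_identical(extract_scaffold("CCCCCC"), NA_character_)
})

test_that("exocyclic multiple bonds follow the Murcko convention", {
  can <- canonicalize_smiles
  expect_identical(extract_scaffold("O=C1CCCCC1"), can("O=C1CCCCC1"))
  expect_identical(extract_scaffold("O=C1CCCCC1", keep_exocyclic = FALSE),
                   can("C1CCCCC1"))
  # a carbonyl in the side chain is removed either way
  expect_identical(extract_scaffold("CC(=O)c1ccccc1"), can("c1ccccc1"))
  expect_identical(extract_scaffold("N#Cc1ccccc1"), can("c1ccccc1"))
})

test_that("scaffold extraction is idempotent and pruned to rings + linkers", {
  mols <- c("Cc1cc2ccccc2[nH]1", "CCN1CCN(c2ccccc2)CC1", "O=C1CCCCC1",
            "CC(=O)Oc1ccccc1C(=O)O", "c1ccccc1COCc1ccccc1",
            "CC1CCCC12CCCCC2", "Cn1cnc2c1c(=O)n(C)c(=O)n2C")
  for (m in mols) {
    for (exo in c(TRUE, FALSE)) {
      sc <- extract_scaffold(m, keep_exocyclic = exo)
      expect_identical(extract_scaffold(sc, keep_exocyclic = exo), sc,
                       label = paste("idempotence", m))
      # graph check: every scaffold atom is a ring atom, or a linker (degree
      # >= 2 among scaffold atoms), or retained by an exocyclic multiple bond
      g <- oracle_graph(sc)
      br <- igraph::bridges(g)
      ring_e <- setdiff(seq_len(igraph::ecount(g)), as.integer(br))
      ring_v <- unique(as.integer(igraph::ends(g, ring_e, names = FALSE)))
      deg <- igraph::degree(g)
      terminal <- setdiff(which(deg <= 1), ring_v)
      if (!exo) {
        expect_length(terminal, 0)
      } else {
        # any terminal atom must hang off the core by a multiple bond
        mol <- moleculecloud:::mc_parse_smiles(sc)
        b <- mol$bonds
        for (v in terminal) {
          expect_true(any((b$from == v | b$to == v) & b$order >= 2L),
                      label = paste("exocyclic terminal atom in", sc))
        }
      }
    }
  }
})

test_that("major chain is the longest path, heteroatoms break length ties", {
  can <- canonicalize_smiles
  expect_identical(extract_major_chain("CCOCC"), can("CCOCC"))
  expect_identical(extract_major_chain("CCC(C)C"), can("CCCC"))
  # O-C-C-N (length 4, 2 heteroatoms) beats the carbon-heavy alternatives
  expect_identical(extract_major_chain("CC(N)CO"), can("NCCO"))
  # symmetric tie: all maximal paths identical
  expect_identical(extract_major_chain("CC(C)C"), can("CCC"))
  expect_error(extract_major_chain("c1ccccc1"), "ring")
})

test_that("major chain equals brute-force path enumeration on random acyclic molecules", {
  smis <- random_acyclic_smiles(40, min_atoms = 2, max_atoms = 10, seed = 42)
  for (s in smis) {
    expect_identical(extract_major_chain(s), oracle_major_chain(s),
                     label = paste("major chain of", s))
  }
})

test_that("substituent extraction cuts single bonds at the scaffold boundary", {
  expect_identical(extract_substituents("Cc1ccccc1"),
                   canonicalize_smiles("[*]C"))
  expect_identical(extract_substituents("c1ccccc1"), character(0))
  # size filter: a 20-atom tail is not reported at the 15-atom cutoff
  expect_identical(
    extract_substituents(paste0(strrep("C", 20), "c1ccccc1"), max_atoms = 15),
    character(0))
  # acyclic molecules have no scaffold, hence no substituents
  expect_identical(extract_substituents("CCCCCC"), character(0))
  # two substituents, reported per occurrence
  subs <- extract_substituents("Cc1ccccc1CCO")
  expect_length(subs, 2)
  expect_true(canonicalize_smiles("[*]C") %in% subs)
  expect_true(canonicalize_smiles("[*]CCO") %in% subs)
  # exocyclic =O is part of the scaffold, not a substituent
  expect_identical(extract_substituents("O=C1CCCCC1"), character(0))
})

test_that("canonicalization is idempotent and representation-independent", {
  expect_identical(canonicalize_smiles("c1ccccc1"),
                   canonicalize_smiles("C1=CC=CC=C1"))
  expect_identical(canonicalize_smiles("OCC"), canonicalize_smiles("CCO"))
  x <- canonicalize_smiles(c("CC(N)CO", "c1ccc2ncccc2c1", "C[n+]1ccccc1"))
  expect_identical(canonicalize_smiles(x), x)
  # stereo collapses to one flat key
  expect_identical(canonicalize_smiles("C[C@H](N)C(=O)O"),
                   canonicalize_smiles("C[C@@H](N)C(=O)O"))
  expect_identical(canonicalize_smiles("not_a_smiles(("), NA_character_)
})

test_that("reduce_collection aggregates per-molecule cores and annotations", {
  rec <- reduce_collection(c("Cc1ccccc1", "CCc1ccccc1", "c1ccccc1"))
  expect_equal(nrow(rec), 1L)
  expect_identical(rec$canonical_smiles, canonicalize_smiles("c1ccccc1"))
  expect_equal(rec$frequency, 3L)
  expect_identical(rec$kind, "scaffold")

  rec <- reduce_collection("CCCCCC")
  expect_identical(rec$kind, "chain")
  expect_equal(rec$frequency, 1L)

  # activity ratio = fraction of contributing molecules flagged active
  smis <- rep("Cc1ccccc1", 10)
  rec <- reduce_collection(smis, is_active = c(rep(TRUE, 4), rep(FALSE, 6)))
  expect_equal(rec$activity_ratio, 0.4)

  # unparseable SMILES are skipped and counted, not fatal
  rec <- reduce_collection(c("Cc1ccccc1", "xxx((", "CCO"))
  rep_ <- attr(rec, "report")
  expect_equal(rep_$parsed, 2L)
  expect_equal(rep_$failed, 1L)
  expect_equal(sum(rec$frequency), rep_$parsed)
})

test_that("aggregation conserves counts and is order-independent", {
  mf <- generate_molecule_fixture(120, n_scaffolds = 12, seed = 11,
                                  annotate = "activity")
  rec <- reduce_collection(mf$smiles, is_active = mf$is_active)
  expect_equal(sum(rec$frequency), attr(rec, "report")$parsed)

  perm <- withr::with_seed(99, sample.int(nrow(mf)))
  rec2 <- reduce_collection(mf$smiles[perm], is_active = mf$is_active[perm])
  expect_identical(rec, rec2, ignore_attr = TRUE)
})

test_that("target-class tallies become per-class fractions", {
  smis <- rep("Cc1ccccc1", 10)
  cls <- c(rep("kinase", 7), rep("GPCR", 2), NA)
  rec <- reduce_collection(smis, target_class = cls)
  expect_equal(rec$class_kinase, 0.7)
  expect_equal(rec$class_GPCR, 0.2)
})
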