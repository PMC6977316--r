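# Molecule parsing, canonicalization, preprocessing, matching, compound I/O.

test_that("parse_structure reads SMILES and perceives aromaticity", {
  b <- parse_structure("c1ccccc1")
  expect_equal(nrow(b$atoms), 6)
  expect_true(all(b$atoms$aromatic))
  expect_equal(ring_count(b), 1L)

  kek <- parse_structure("C1=CC=CC=C1")
  expect_identical(canonical_form(kek), canonical_form(b))

  expect_error(parse_structure("c1ccc", id = "bad"), class = "ncmfp_parse_error")
  expect_error(parse_structure(""), class = "ncmfp_parse_error")
})

test_that("parse_structure reads SDF records", {
  sdf <- ncmfp:::ob_convert("SMI", "SDF", "Oc1ccccc1 phenol\n")
  m <- parse_structure(sdf, format = "sdf")
  expect_identical(canonical_form(m), canonical_form(parse_structure("Oc1ccccc1")))
})

test_that("canonical form is invariant under atom relabelling", {
  withr::with_seed(11, {
    for (name in c("toluene", "quinoline", "cyclohexanone", "coumarin")) {
      m <- fixture_mol(name)
      ref <- canonical_form(m)
      forms <- replicate(25, canonical_form(reparse_permuted(m)))
      expect_identical(unique(forms), ref, label = name)
    }
  })
  expect_identical(canonical_form(parse_structure("C")),
                   canonical_form(parse_structure("C")))
})

test_that("preprocess adds hydrogens, weight and Hill formula; idempotent", {
  p <- preprocess(parse_structure("CCO"))
  expect_equal(nrow(p$atoms), 9) # 2 C + 1 O + 6 H
  expect_equal(p$formula, "C2H6O")
  expect_equal(p$mw, 46.07, tolerance = 0.01)

  b <- preprocess(fixture_mol("benzene"))
  expect_equal(p$formula, "C2H6O")
  expect_equal(nrow(b$atoms), 12)
  expect_equal(b$formula, "C6H6")

  expect_identical(preprocess(p), p)
})

test_that("match_substructure enumerates all embeddings, aromatic-strict", {
  b <- fixture_mol("benzene")
  expect_length(match_substructure(b, preprocess(fixture_mol("toluene"))), 12)
  expect_length(match_substructure(b, preprocess(fixture_mol("cyclohexane"))), 0)
  expect_length(match_substructure(b, preprocess(b)), 12)
  mp <- match_substructure(b, preprocess(fixture_mol("toluene")))[[1]]
  expect_named(mp, c("pattern_atom", "target_atom"))
  expect_false(any(duplicated(mp$target_atom)))
})

test_that("match_substructure agrees with a brute-force enumerator", {
  pairs <- list(
    c("benzene", "toluene"), c("benzene", "benzene"),
    c("benzene", "naphthalene"), c("benzene", "biphenyl"),
    c("benzene", "cyclohexane"), c("cyclohexane", "spiro_decane"),
    c("pyridine", "quinoline"), c("toluene", "p_terphenyl"),
    c("cyclohexanone", "cyclohexanone"), c("benzene", "phenyl_cyclohexane")
  )
  for (pr in pairs) {
    p <- fixture_mol(pr[1]); t <- preprocess(fixture_mol(pr[2]))
    got <- ncmfp:::match_heavy(ncmfp:::mol_graph_heavy(p), ncmfp:::mol_graph_heavy(t))
    want <- bf_match(p, t)
    key <- function(maps) sort(vapply(maps, paste, character(1), collapse = ","))
    expect_identical(key(got), key(want), label = paste(pr, collapse = " in "))
  }
})

test_that("read_compound_set applies the ring filter and accounting holds", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1\tbenzene", "Cc1ccccc1\ttoluene", "CCO\tethanol"), f)
  expect_warning(res <- read_compound_set(f), class = "ncmfp_ring_filter_warning")
  expect_equal(nrow(res), 2)
  expect_equal(attr(res, "n_acyclic"), 1)
  expect_equal(nrow(res) + attr(res, "n_malformed") + attr(res, "n_acyclic"),
               attr(res, "n_input"))

  f2 <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1\ta", "c1ccc\tbroken", "Oc1ccccc1\tb"), f2)
  expect_warning(res2 <- read_compound_set(f2), class = "ncmfp_skip_warning")
  expect_equal(nrow(res2), 2)
  expect_equal(attr(res2, "n_malformed"), 1)

  f3 <- withr::local_tempfile(fileext = ".smi")
  writeLines(character(0), f3)
  expect_warning(res3 <- read_compound_set(f3), class = "ncmfp_empty_warning")
  expect_equal(nrow(res3), 0)
})

test_that("read_compound_set reads delimited tables and keeps metadata", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles,class,ic50",
               "a,Cc1ccccc1,alpha,5",
               "b,Oc1ccccc1,beta,20"), f)
  res <- read_compound_set(f)
  expect_equal(res$class, c("alpha", "beta"))
  expect_equal(res$ic50, c(5, 20))
})

test_that("salts are reduced to the largest covalent component", {
  m <- parse_structure("C[N+]1(C)CCCCC1.[Cl-]")
  lc <- ncmfp:::largest_component(m)
  expect_false("Cl" %in% lc$atoms$element)
  expect_equal(ring_count(lc), 1L)
})
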