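# Framework extraction, ring pruning, level enumeration, library construction.

test_that("murcko_framework removes side chains and keeps double bonds", {
  b <- fixture_mol("benzene")
  expect_identical(canonical_form(murcko_framework(b)), canonical_form(b))

  eb <- parse_structure("CCc1ccccc1")
  expect_identical(canonical_form(murcko_framework(eb)), canonical_form(b))

  keto <- fixture_mol("cyclohexanone")
  expect_identical(canonical_form(murcko_framework(keto)), canonical_form(keto))

  # acetyl side chain goes entirely; only ring-attached double bonds stay
  acet <- parse_structure("CC(=O)c1ccccc1")
  expect_identical(canonical_form(murcko_framework(acet)), canonical_form(b))

  expect_error(murcko_framework(parse_structure("CCO")),
               class = "ncmfp_no_scaffold_error")
})

test_that("murcko_framework is idempotent", {
  for (name in c("toluene", "decorated_naphthalene", "cyclohexanone",
                 "diphenylmethane", "coumarin")) {
    fw <- murcko_framework(fixture_mol(name))
    expect_identical(canonical_form(ncmfp:::bm_cleanup(fw)), canonical_form(fw),
                     label = name)
  }
})

test_that("prune_one_ring removes peripheral rings and terminates", {
  benz <- canonical_form(fixture_mol("benzene"))
  expect_identical(names(prune_one_ring(fixture_mol("biphenyl"))), benz)
  expect_identical(names(prune_one_ring(fixture_mol("naphthalene"))), benz)
  expect_length(prune_one_ring(fixture_mol("benzene")), 0)
  kids <- prune_one_ring(fixture_mol("indole"))
  expect_setequal(names(kids), c(benz, canonical_form(parse_structure("c1cc[nH]c1"))))
})

test_that("enumerate_levels builds the pruning hierarchy with level = rings - 1", {
  lv <- enumerate_levels(fixture_mol("benzene"))
  expect_equal(lv$level, 0L)

  dpm <- enumerate_levels(fixture_mol("diphenylmethane"))
  expect_equal(sort(unique(dpm$level)), c(0L, 1L))
  expect_equal(sum(dpm$level == 0), 1) # both rings collapse to benzene

  tp <- enumerate_levels(fixture_mol("p_terphenyl"))
  expect_equal(sort(unique(tp$level)), c(0L, 1L, 2L))
  expect_identical(
    tp$smiles[tp$level == 1],
    canonical_form(fixture_mol("biphenyl"))
  )

  for (row in seq_len(nrow(tp))) {
    expect_equal(ring_count(tp$mol[[row]]), tp$level[row] + 1L)
  }
})

test_that("every level-0 scaffold is a single ring and a substructure of a parent", {
  for (name in c("p_terphenyl", "anthracene", "decorated_naphthalene", "quinoline")) {
    lv <- enumerate_levels(fixture_mol(name))
    l0 <- lv[lv$level == 0, ]
    expect_gt(nrow(l0), 0)
    expect_true(all(vapply(l0$mol, ring_count, integer(1)) == 1L), label = name)
    top <- max(lv$level)
    for (j in seq_len(top)) {
      lower <- lv[lv$level == j - 1, ]
      upper <- lv[lv$level == j, ]
      for (s in lower$mol) {
        hit <- any(vapply(upper$mol, function(u) {
          length(match_substructure(s, u)) > 0
        }, logical(1)))
        expect_true(hit, label = paste(name, "level", j - 1))
      }
    }
  }
})

test_that("enumerate_levels matches the ring-subset brute-force enumerator", {
  fixtures <- c(
    "benzene", "naphthalene", "biphenyl", "diphenylmethane", "p_terphenyl",
    "indole", "quinoline", "anthracene", "spiro_decane", "norbornane",
    "coumarin", "decorated_naphthalene", "phenyl_cyclohexane"
  )
  for (name in fixtures) {
    got <- enumerate_levels(fixture_mol(name))[, c("level", "smiles")]
    want <- bf_enumerate_levels(fixture_mol(name))
    expect_equal(as.data.frame(got), as.data.frame(want), label = name)
  }
})

test_that("build_library pools, deduplicates and orders per class and level", {
  comps <- tibble::tibble(
    id = c("t", "p"), smiles = c("Cc1ccccc1", "Oc1ccccc1"), class = "A"
  )
  lib <- build_library(comps, levels = 0)
  expect_s3_class(lib, "scaffold_library")
  expect_equal(nrow(lib$scaffolds), 1)
  expect_identical(lib$scaffolds$smiles, canonical_form(fixture_mol("benzene")))
  expect_equal(lib$scaffolds$index, 1L)

  two <- tibble::tibble(
    id = c("a", "b"),
    smiles = c("Cc1ccccc1", "CC1CCNCC1"),
    class = c("aromatic", "saturated")
  )
  lib2 <- build_library(two, levels = 0)
  sc <- tidy(lib2)
  expect_equal(length(intersect(
    sc$smiles[sc$class == "aromatic"], sc$smiles[sc$class == "saturated"]
  )), 0)

  bad <- tibble::tibble(id = "x", smiles = "c1ccccc1", class = NA_character_)
  expect_error(build_library(bad), class = "ncmfp_label_error")
})

test_that("scaffold library JSON round-trips", {
  comps <- tibble::tibble(
    id = c("a", "b"), smiles = c("Cc1ccc2ccccc2c1", "Oc1ccccc1"),
    class = c("fused", "simple")
  )
  lib <- build_library(comps, levels = 0:1)
  f <- withr::local_tempfile(fileext = ".json")
  write_scaffold_library(lib, f)
  lib2 <- read_scaffold_library(f)
  expect_equal(tidy(lib2), tidy(lib))
  expect_equal(lib2$classes, lib$classes)
  expect_equal(lib2$levels, lib$levels)
})
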