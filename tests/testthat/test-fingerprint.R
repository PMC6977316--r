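# Feature dictionary construction and six-step fingerprint generation.

test_that("toy dictionary has the expected 4-bit layout", {
  dict <- toy_dictionary()
  expect_equal(dict$n_bits, 4L)
  expect_equal(nrow(dict$scaffolds), 1)
  expect_equal(nrow(dict$sfcp), 1)
  expect_equal(dict$sfcp$position, 0L)
  # methyl (15.03 Da) indexed before hydroxyl (17.01 Da)
  expect_equal(dict$fragments$smiles, c("*C", "*O"))
  expect_equal(dict$fragments$index, 1:2)
  expect_equal(dict$fragments$mw, c(15.03, 17.01), tolerance = 1e-3)
})

test_that("an empty reference gives a scaffold-only dictionary", {
  lib <- build_library(
    tibble::tibble(id = "b", smiles = "c1ccccc1", class = "A"),
    levels = 0
  )
  dict <- build_feature_dictionary(lib)
  expect_equal(dict$n_bits, nrow(lib$scaffolds))
  expect_equal(nrow(dict$sfcp), 0)
  expect_equal(nrow(dict$fragments), 0)
})

test_that("match_scaffolds respects the ring precondition and aromaticity", {
  dict <- toy_dictionary()
  ms <- match_scaffolds(parse_structure("c1ccccc1"), dict)
  expect_equal(nrow(ms), 1)
  expect_length(ms$mapping[[1]], 6)

  expect_gt(nrow(match_scaffolds(parse_structure("Cc1ccccc1"), dict)), 0)

  fp <- compute_ncmfp(parse_structure("C1CCCCC1"), dict)
  expect_true(fp$flags$no_scaffold_match)
  expect_equal(sum(fp$bits), 0)

  expect_error(match_scaffolds(parse_structure("CCO"), dict),
               class = "ncmfp_ring_error")
  expect_error(compute_ncmfp(parse_structure("CCO"), dict),
               class = "ncmfp_ring_error")
})

test_that("generate_fragments cuts, marks, deduplicates and sorts by weight", {
  dict <- toy_dictionary()
  tol <- parse_structure("Cc1ccccc1")
  mp <- match_scaffolds(tol, dict)$mapping[[1]]
  fr <- generate_fragments(tol, mp)
  expect_equal(fr$smiles, "*C")
  expect_equal(fr$mw, 15.03, tolerance = 1e-3)
  expect_equal(fr$count, 1L)

  benz <- parse_structure("c1ccccc1")
  mp0 <- match_scaffolds(benz, dict)$mapping[[1]]
  expect_equal(nrow(generate_fragments(benz, mp0)), 0)

  mx <- parse_structure("Cc1cccc(C)c1")
  mpx <- match_scaffolds(mx, dict)$mapping[[1]]
  frx <- generate_fragments(mx, mpx)
  expect_equal(frx$smiles, "*C")
  expect_equal(frx$count, 2L)

  # anisole: marker keeps methoxy distinct from methanol-like fragments
  ani <- parse_structure("COc1ccccc1")
  fra <- generate_fragments(ani, match_scaffolds(ani, dict)$mapping[[1]])
  expect_equal(nrow(fra), 1)
  expect_equal(fra$mw, 31.03, tolerance = 1e-2) # OCH3 without the marker
})

test_that("assign_sfcp reduces positions over scaffold automorphisms", {
  dict <- toy_dictionary()
  tol <- parse_structure("Cc1ccccc1")
  sf <- assign_sfcp(tol, dict$scaffolds$smiles[1],
                    match_scaffolds(tol, dict)$mapping[[1]])
  expect_equal(sf$position, 0L) # all benzene atoms are equivalent

  benz <- parse_structure("c1ccccc1")
  sf0 <- assign_sfcp(benz, dict$scaffolds$smiles[1],
                     match_scaffolds(benz, dict)$mapping[[1]])
  expect_equal(nrow(sf0), 0)

  mx <- parse_structure("Cc1cccc(C)c1")
  sfx <- assign_sfcp(mx, dict$scaffolds$smiles[1],
                     match_scaffolds(mx, dict)$mapping[[1]])
  expect_equal(nrow(sfx), 2)
  expect_equal(sfx$position, c(0L, 2L)) # meta pair, minimal index tuple
})

test_that("identify_fragment is an exact lookup with unknowns preserved", {
  dict <- toy_dictionary()
  expect_equal(identify_fragment("*C", dict), 1L)
  expect_equal(identify_fragment("*O", dict), 2L)
  expect_true(is.na(identify_fragment("*CC", dict)))

  # unknown fragments leave the bit string length unchanged and are counted
  fp <- compute_ncmfp(parse_structure("CCc1ccccc1"), dict)
  expect_equal(length(fp$bits), 4)
  expect_equal(fp$flags$unknown_fragments, 1L)
  expect_equal(as.character(fp), "1100")
})

test_that("compute_ncmfp reproduces the worked toy examples", {
  dict <- toy_dictionary()
  expect_equal(as.character(compute_ncmfp(parse_structure("c1ccccc1"), dict)), "1000")
  expect_equal(as.character(compute_ncmfp(parse_structure("Cc1ccccc1"), dict)), "1110")
  expect_equal(as.character(compute_ncmfp(parse_structure("Oc1ccccc1"), dict)), "1101")
})

test_that("set bits equal matched features exactly (provenance audit)", {
  spec <- make_toy_spec(4, seed = 9)
  ds <- generate_dataset(spec, 24)
  lib <- build_library(ds, levels = 0)
  dict <- build_feature_dictionary(lib, ds)
  for (i in seq_len(nrow(ds))) {
    fp <- compute_ncmfp(ds$mol[[i]], dict)
    expect_equal(sum(fp$bits), nrow(fp$provenance))
    expect_equal(fp$set_positions, fp$provenance$bit)
    expect_false(any(duplicated(fp$provenance$bit)))
  }
})

test_that("fingerprints are invariant under atom reordering", {
  dict <- toy_dictionary()
  withr::with_seed(21, {
    for (smi in c("Cc1ccccc1", "Oc1ccccc1", "Cc1cccc(C)c1", "CCc1ccccc1O")) {
      m <- parse_structure(smi)
      ref <- as.character(compute_ncmfp(m, dict))
      for (k in 1:30) {
        fp <- as.character(compute_ncmfp(reparse_permuted(m), dict))
        expect_identical(fp, ref, label = smi)
      }
    }
  })
})

test_that("a query identical to a dictionary scaffold sets only its scaffold bit", {
  spec <- make_toy_spec(4, seed = 9)
  ds <- generate_dataset(spec, 24)
  dict <- build_feature_dictionary(build_library(ds, levels = 0), ds)
  for (smi in spec$classes$scaffold) {
    fp <- compute_ncmfp(parse_structure(smi), dict)
    expect_equal(nrow(fp$provenance), 1)
    expect_equal(fp$provenance$kind, "scaffold")
    expect_equal(fp$provenance$feature, smi)
  }
})

test_that("fingerprint length is constant for a fixed dictionary", {
  spec <- make_toy_spec(3, seed = 4)
  ds <- generate_dataset(spec, 15)
  dict <- build_feature_dictionary(build_library(ds, levels = 0), ds)
  fps <- ncmfp_fingerprints(ds, dict)
  expect_equal(unique(nchar(fps$bits)), dict$n_bits)
})

test_that("single-scaffold mode uses only the largest matched scaffold", {
  comps <- tibble::tibble(
    id = c("a", "b"),
    smiles = c("Cc1ccccc1", "Cc1ccc2ccccc2c1"),
    class = c("mono", "fused")
  )
  lib <- build_library(comps, levels = 0:1)
  dict <- build_feature_dictionary(lib, comps)
  q <- parse_structure("Cc1ccc2ccccc2c1")
  multi <- compute_ncmfp(q, dict)
  single <- compute_ncmfp(q, dict, mode = "single")
  expect_gt(sum(multi$bits), sum(single$bits))
  sc <- single$provenance[single$provenance$kind == "scaffold", ]
  expect_equal(nrow(sc), 1)
  expect_equal(sc$feature, canonical_form(parse_structure("c1ccc2ccccc2c1")))
})

test_that("fp_hex packs bit strings with zero padding", {
  expect_equal(fp_hex("1110"), "e")
  expect_equal(fp_hex("11101"), "e8")
  expect_equal(fp_hex(rep(0L, 8)), "00")
})

test_that("feature dictionary JSON round-trips with checksum", {
  dict <- toy_dictionary()
  f <- withr::local_tempfile(fileext = ".json")
  write_feature_dictionary(dict, f)
  d2 <- read_feature_dictionary(f)
  expect_equal(d2$n_bits, dict$n_bits)
  expect_equal(d2$checksum, dict$checksum)
  expect_equal(
    as.character(compute_ncmfp(parse_structure("Cc1ccccc1"), d2)),
    "1110"
  )
})
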