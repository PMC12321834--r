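quiet_opts()

write_demo_csv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(rows, path, progress = FALSE)
  path
}

test_that("compound tables load in file order with kept/dropped tallies", {
  path <- write_demo_csv(tibble::tibble(smiles = c("C", "O"), label = c(1, 0)))
  d <- read_compounds(path)
  expect_equal(nrow(d), 2)
  expect_equal(attr(d, "n_dropped"), 0)
  expect_equal(d$smiles, c("C", "O"))
  expect_equal(d$label, c(1, 0))

  path2 <- write_demo_csv(tibble::tibble(smiles = c("C", "not_a_smiles"),
                                         label = c(1, 0)))
  d2 <- read_compounds(path2)
  expect_equal(nrow(d2), 1)
  expect_equal(attr(d2, "n_kept"), 1)
  expect_equal(attr(d2, "n_dropped"), 1)
})

test_that("loader errors carry their failure kinds", {
  expect_error(read_compounds(file.path(tempdir(), "no_such_file.csv")),
               class = "cmpnntox_input_error")
  path <- write_demo_csv(tibble::tibble(smiles = "C", label = 1))
  expect_error(read_compounds(path, label_col = "toxicity"),
               class = "cmpnntox_schema_error")
  bad <- write_demo_csv(tibble::tibble(smiles = c("xx", "zz"),
                                       label = c(1, 0)))
  expect_error(read_compounds(bad), class = "cmpnntox_empty_error")
  lbl <- write_demo_csv(tibble::tibble(smiles = c("C", "O"), label = c(1, 7)))
  expect_error(read_compounds(lbl), class = "cmpnntox_schema_error")
})

test_that("datasets round-trip through write/reload unchanged", {
  d <- generate_compounds(n = 20, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_compounds(d, path)
  d2 <- read_compounds(path)
  expect_equal(d2$smiles, d$smiles)
  expect_equal(d2$label, d$label)
  expect_equal(d2$identifier, d$identifier)
})

test_that("fingerprints are deterministic, spelling-invariant and 2048 bits", {
  fp <- compute_fingerprints(tibble::tibble(
    smiles = c("CCO", "CCO", "OCC", "C", "CCCCCCCC")))
  m <- fingerprint_matrix(fp)
  expect_equal(ncol(m), 2048)
  expect_true(all(m %in% c(0L, 1L)))
  expect_identical(m[1, ], m[2, ])           # repeated computation
  expect_identical(m[1, ], m[3, ])           # canonical-form invariance
  expect_false(identical(m[4, ], m[5, ]))    # methane vs octane differ
  expect_gte(sum(m[4, ]), 1)
  expect_lte(sum(m[4, ]), 2048)
})

test_that("fingerprint folding preserves bit counts and validates inputs", {
  fp <- compute_fingerprints(tibble::tibble(smiles = "CCO"), n_bits = 256)
  expect_length(fp$fingerprint[[1]], 256)
  expect_error(compute_fingerprints(tibble::tibble(smiles = "CCO"),
                                    n_bits = 100),
               class = "cmpnntox_config_error")
  expect_error(compute_fingerprints(tibble::tibble(smiles = "CCO"),
                                    radius = 5),
               class = "cmpnntox_config_error")
  expect_error(compute_fingerprints(tibble::tibble(smiles = "qq")),
               class = "cmpnntox_parse_error")
})

test_that("descriptors reproduce independently computed reference values", {
  d <- compute_descriptors(tibble::tibble(smiles = c(
    "CC", "c1ccccc1", "O", "CCCCCCCC", "CC(=O)Oc1ccccc1C(=O)O",
    "COC(=O)c1ccccc1C(=O)OC", "CCO")))
  # frozen values from an independent cheminformatics toolkit
  expect_equal(d$weight, c(30.07, 78.114, 18.015, 114.232, 180.159,
                           194.186, 46.069), tolerance = 1e-3)
  expect_equal(d$tpsa[c(2, 5, 6, 7)], c(0, 63.60, 52.60, 20.23),
               tolerance = 1e-3)
  expect_equal(d$logp[c(2, 4, 5, 6, 7)],
               c(1.6866, 3.3668, 1.3101, 1.2598, -0.0014), tolerance = 1e-3)
  expect_equal(d$rot_bonds, c(0L, 0L, 0L, 5L, 2L, 2L, 0L))
  expect_true(all(d$weight > 0))
  expect_true(all(d$tpsa >= 0))
  expect_true(all(d$hbd >= 0 & d$hba >= 0))
})

test_that("descriptors are invariant to SMILES spelling", {
  d <- compute_descriptors(tibble::tibble(smiles = c("CCO", "OCC", "C(O)C")))
  for (col in c("weight", "tpsa", "logp", "hbd", "hba", "rot_bonds")) {
    expect_equal(d[[col]][1], d[[col]][2])
    expect_equal(d[[col]][1], d[[col]][3])
  }
})

test_that("descriptor summaries use order-statistic medians per class", {
  fake <- tibble::tibble(
    label = c(1, 1, 1, 0, 0),
    weight = c(1, 2, 100, 10, 20), tpsa = c(0, 0, 0, 5, 5),
    logp = c(1, 1, 1, 2, 2), hbd = c(0, 1, 2, 0, 0),
    hba = c(0, 0, 0, 1, 3), rot_bonds = c(0, 0, 0, 0, 0))
  s <- summarize_descriptors(fake)
  get <- function(cls, desc) s$median[s$class == cls & s$descriptor == desc]
  expect_equal(get(1, "weight"), 2)        # odd n: member of the multiset
  expect_equal(get(0, "weight"), 15)       # even n: midpoint convention
  expect_equal(get(0, "hba"), 2)
  expect_true(all(s$n[s$class == 1] == 3))
  # median bounded by class extremes
  expect_true(all(s$median >= s$q1 & s$median <= s$q3))
  expect_error(summarize_descriptors(dplyr::mutate(fake, label = 1)),
               class = "cmpnntox_degenerate_class_error")
  expect_error(summarize_descriptors(dplyr::mutate(fake, label = NA)),
               class = "cmpnntox_schema_error")
})

test_that("largest-fragment reduction is optional and off by default", {
  path <- write_demo_csv(tibble::tibble(smiles = "CCO.[Na+]", label = 1))
  asis <- read_compounds(path)
  expect_match(asis$canonical_smiles, "Na", fixed = TRUE)
  reduced <- read_compounds(path, keep_largest_fragment = TRUE)
  expect_false(grepl("Na", reduced$canonical_smiles, fixed = TRUE))
})
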