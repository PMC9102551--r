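test_that("toy pose generation is deterministic and noise-free at zero jitter", {
  spec0 <- toy_complex_spec(jitter_sd = 0, n_poses = 2, seed = 9)
  poses <- gen_toy_poses(spec0)
  expect_identical(write_structure(poses[[1]]), write_structure(poses[[2]]))

  spec <- toy_complex_spec(n_poses = 3, seed = 12)
  a <- gen_toy_poses(spec)
  b <- gen_toy_poses(spec)
  expect_identical(lapply(a, `[[`, "atoms"), lapply(b, `[[`, "atoms"))
  # different seeds move the jittered residues
  c_ <- gen_toy_poses(toy_complex_spec(n_poses = 3, seed = 13))
  expect_false(identical(a[[1]]$atoms$x, c_[[1]]$atoms$x))
})

test_that("planted residues are in the interface set of every pose", {
  spec <- toy_complex_spec(n_res_receptor = 32, n_res_ligand = 32,
                           planted_receptor = 8, planted_ligand = 24,
                           n_poses = 3, seed = 2)
  poses <- gen_toy_poses(spec)
  partners <- attr(poses, "partners")
  for (p in poses) {
    iface <- interface_residues(p, partners)
    expect_true("A:8" %in% iface$receptor)
    expect_true("B:24" %in% iface$ligand)
  }
})

test_that("impossible toy geometries are rejected", {
  expect_error(toy_complex_spec(n_res_receptor = 8), "at least 16")
  expect_error(toy_complex_spec(planted_receptor = c(1, 50)), "outside")
  expect_error(toy_complex_spec(planted_receptor = 1:10), "impossible geometry")
  expect_error(toy_complex_spec(jitter_sd = -1), "jitter_sd")
  expect_error(toy_complex_spec(n_poses = 0), "n_poses")
})

test_that("mutation tables follow the seeded Poisson policy and watch lists", {
  genes <- data.frame(name = "G1", length_aa = 500)
  empty <- gen_mutation_table(cohort_spec(genes, 50, c(G1 = 0), seed = 3))
  expect_equal(nrow(empty$mutations), 0)

  # forced watch entry round-trips through the protein-change parser
  spec <- cohort_spec(data.frame(name = "TRPM8", length_aa = 1104), 10,
                      c(TRPM8 = 0),
                      watch_codons = list(TRPM8 = data.frame(
                        position = 207, ref = "E", alt = "D")), seed = 4)
  tab <- gen_mutation_table(spec)
  expect_equal(tab$mutations$protein_change, "p.E207D")
  parsed <- parse_protein_change(tab$mutations$protein_change)
  expect_equal(parsed$ref_aa, "E")
  expect_equal(parsed$position, 207L)
  expect_equal(parsed$alt_aa, "D")

  # total count equals an independent Poisson draw under the same seed policy
  one <- cohort_spec(data.frame(name = "G1", length_aa = 300), 100,
                     c(G1 = 0.1), seed = 77)
  got <- gen_mutation_table(one)
  expected_n <- local({ set.seed(77); rpois(1, 100 * 0.1) })
  expect_equal(nrow(got$mutations), expected_n)
  expect_true(all(parse_protein_change(got$mutations$protein_change)$position
                  <= 300))
})

test_that("clinical metadata exercises every labeling rule exactly", {
  meta <- gen_clinical_metadata(1)
  expect_equal(nrow(meta), 5)
  lab <- label_sample(meta)
  counts <- table(lab$label)
  expect_equal(counts[["metastatic"]], 3)
  expect_equal(counts[["healthy"]], 1)
  expect_equal(counts[["not_metastatic"]], 1)
  expect_setequal(lab$rule, c("gtex", "ajcc_m", "ajcc_stage_iv",
                              "figo_iii_iv", "fallback"))

  empty <- gen_clinical_metadata(0)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("sample_id", "source_cohort") %in% names(empty)))

  dup <- rbind(meta, meta[1, ])
  expect_error(validate_metadata(dup), "duplicated")
})

test_that("trace generator plants a known step and tracks a known speed", {
  flat <- gen_roi_traces(n_cells = 2, response_amplitude = 0, noise_sd = 0,
                         seed = 5)
  s <- cell_translocation_series(flat)
  expect_equal(s$R, rep(attr(flat, "truth")$baseline_r, nrow(s)),
               tolerance = 1e-12)

  tr <- gen_tracks(n_cells = 4, true_speed = 1.2, dt = 10, seed = 6)
  expect_equal(migration_rate(tr)$rate, rep(1.2, 4), tolerance = 1e-9)

  expect_equal(nrow(gen_roi_traces(n_cells = 0)), 0)
  expect_equal(nrow(gen_tracks(n_cells = 0)), 0)
  expect_warning(gen_roi_traces(n_cells = 1, n_roi_pairs = 3, seed = 1),
                 "fewer than 4")
})
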