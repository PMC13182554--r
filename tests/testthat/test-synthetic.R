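test_that("generation is deterministic under the seed and yields unique, valid SMILES", {
  cfg <- generator_config(n_molecules = 50, seed = 7)
  a <- generate_molecules(cfg)
  b <- generate_molecules(cfg)
  expect_identical(a, b)
  expect_length(unique(a), 50L)
  expect_false(anyNA(canonicalize_smiles(a)))
})

test_that("generated molecules span a wide molecular-weight range", {
  cfg <- generator_config(n_molecules = 200, seed = 1)
  mw <- descriptors(generate_molecules(cfg))$values[, "MW"]
  expect_gte(diff(range(mw)), 150)
})

test_that("requests beyond the grammar capacity are rejected", {
  expect_error(generate_molecules(generator_config(n_molecules = 1e7)),
               "capacity")
})

test_that("config invariants are enforced", {
  expect_error(generator_config(source_mix = list(A = c(1, 1, 0, 0) / 3,
                                                  B = rep(0.25, 4))),
               "summing to 1")
  expect_error(generator_config(thresholds = c(1, 1, 2)), "strictly")
  expect_error(generator_config(label_noise = 1), "label_noise")
})

test_that("a constant latent score between tau2 and tau3 labels everything medium", {
  mols <- fixture_molecules(30, seed = 7)
  cfg <- generator_config(
    n_molecules = 30, seed = 7,
    latent_params = list(beta0 = 2.4, beta_mw = 0, beta_logp = 0,
                         beta_polarity = 0, mu_mw = 0, mu_logp = 0,
                         noise_sd = 0))
  ds <- assign_labels(mols, cfg)
  expect_true(all(ds$true_labels == 2L))
})

test_that("labels are the deterministic thresholding of the latent score", {
  cfg <- generator_config(n_molecules = 60, seed = 3)
  mols <- generate_molecules(cfg)
  ds <- assign_labels(mols, cfg)
  ds2 <- assign_labels(mols, cfg)
  expect_identical(ds$true_labels, ds2$true_labels)
  expect_identical(ds$true_labels,
                   as.integer(findInterval(ds$latent_scores, cfg$thresholds)))
})

test_that("label frequencies match a Monte-Carlo oracle of the latent model", {
  cfg <- generator_config(n_molecules = 1000, seed = 5)
  mols <- generate_molecules(cfg)
  ds <- assign_labels(mols, cfg)
  # oracle: integrate the latent model over the generated molecule population
  # by drawing molecules uniformly and noise from its stated distribution
  lp <- cfg$latent_params
  d <- ds$descriptors$values
  det <- lp$beta0 - lp$beta_mw * abs(d[, "MW"] - lp$mu_mw) -
    lp$beta_logp * abs(d[, "logP"] - lp$mu_logp) +
    lp$beta_polarity * (d[, "HBD"] + d[, "HBA1"])
  set.seed(123)
  draws <- sample(det, 1e5, replace = TRUE) + rnorm(1e5, 0, lp$noise_sd)
  p_oracle <- tabulate(findInterval(draws, cfg$thresholds) + 1L, 4) / 1e5
  p_emp <- tabulate(ds$true_labels + 1L, 4) / length(ds$true_labels)
  expect_true(all(abs(p_emp - p_oracle) <= 0.05))
})

test_that("two-source emission respects overlap and noise settings", {
  cfg0 <- generator_config(n_molecules = 80, seed = 11, label_noise = 0,
                           overlap_fraction = 1)
  ds <- fixture_dataset(80, seed = 11)
  ds0 <- assign_labels(fixture_molecules(80, seed = 11), cfg0)
  rec <- emit_two_source_dataset(ds0, cfg0)
  # full overlap, no noise: both sources agree perfectly
  a <- rec[rec$source == "A", ]
  b <- rec[rec$source == "B", ]
  expect_setequal(a$smiles, b$smiles)
  expect_equal(kappa_quadratic(a$label_observed[match(b$smiles, a$smiles)],
                               b$label_observed), 1)
  # zero overlap: no molecule is annotated twice
  cfg2 <- generator_config(n_molecules = 80, seed = 11, overlap_fraction = 0)
  rec2 <- emit_two_source_dataset(ds0, cfg2)
  expect_length(intersect(rec2$smiles[rec2$source == "A"],
                          rec2$smiles[rec2$source == "B"]), 0L)
})

test_that("emission is deterministic and observed labels stay adjacent to truth", {
  cfg <- generator_config(n_molecules = 100, seed = 13)
  ds <- assign_labels(generate_molecules(cfg), cfg)
  r1 <- emit_two_source_dataset(ds, cfg)
  r2 <- emit_two_source_dataset(ds, cfg)
  expect_identical(r1, r2)
  expect_true(all(abs(r1$label_observed - r1$label_true) <= 1))
  expect_true(all(r1$label_observed %in% 0:3))
})

test_that("increasing label noise lowers the measured overlap agreement", {
  cfg_base <- generator_config(n_molecules = 500, seed = 17,
                               overlap_fraction = 0.8)
  ds <- assign_labels(generate_molecules(cfg_base), cfg_base)
  kappas <- vapply(c(0, 0.15, 0.35), function(p) {
    cfg <- generator_config(n_molecules = 500, seed = 17,
                            overlap_fraction = 0.8, label_noise = p)
    rec <- emit_two_source_dataset(ds, cfg)
    ov <- intersect(rec$smiles[rec$source == "A"], rec$smiles[rec$source == "B"])
    a <- rec$label_observed[rec$source == "A"][match(ov, rec$smiles[rec$source == "A"])]
    b <- rec$label_observed[rec$source == "B"][match(ov, rec$smiles[rec$source == "B"])]
    kappa_quadratic(a, b)
  }, numeric(1))
  expect_equal(kappas[1], 1)
  expect_true(all(diff(kappas) < 0))
})
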