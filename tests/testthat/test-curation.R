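test_that("description mapping is ordered first-match substring scan", {
  tab <- data.frame(keyword = c("odorless", "strong"), category = c(0L, 3L))
  expect_identical(map_description("Colorless, odorless gas.", tab), 0L)
  expect_identical(map_description("has a strong pungent smell", tab), 3L)
  expect_identical(map_description("pleasant fruity aroma", tab), NA_integer_)
  # table order decides conflicts
  tab2 <- data.frame(keyword = c("strong", "odorless"), category = c(3L, 0L))
  expect_identical(map_description("strong but odorless?", tab2), 3L)
  expect_identical(map_description("strong but odorless?", tab), 0L)
})

test_that("keyword tables are validated", {
  expect_error(validate_keyword_table(
    data.frame(keyword = c("a", "a"), category = c(0L, 1L))), "duplicate")
  expect_error(validate_keyword_table(
    data.frame(keyword = "", category = 0L)), "empty")
  expect_error(validate_keyword_table(
    data.frame(keyword = "x", category = 7L)), "codes")
})

.raw_records <- function() {
  data.frame(
    smiles = c("CCO", "OCC", "CC(=O)[O-].[Na+]", "C(", "CCC", "CCCC", "CCCC"),
    source = c("A", "B", "A", "B", "A", "B", "B"),
    description = c("", "faint sweet smell", "", "weak odor", "", "strong", "strong"),
    strength = c("very high", NA, "medium", NA, "nonsense", NA, NA),
    stringsAsFactors = FALSE)
}

test_that("filters remove dots, invalid SMILES and source-B duplicates, and reclassify very high", {
  prep <- prepare_records(.raw_records())
  fa <- apply_filters(prep[prep$source == "A", , drop = FALSE])
  fb <- apply_filters(prep[prep$source == "B", , drop = FALSE])
  # A: CCO kept (very high -> 3), dot salt removed, unmapped word removed
  expect_identical(fa$retained$strength_code, 3L)
  expect_true(grepl("reclassified_very_high", fa$retained$audit_flags))
  expect_equal(unname(fa$audit[["dot_smiles"]]), 1)
  expect_equal(unname(fa$audit[["unmapped_description"]]), 1)
  # B: invalid "C(" removed, duplicated butane collapsed to first
  expect_equal(unname(fb$audit[["invalid_smiles"]]), 1)
  expect_equal(unname(fb$audit[["duplicate"]]), 1)
  expect_equal(nrow(fb$retained), 2L)
  # audit conservation: input = retained + removals
  for (f in list(fa, fb)) {
    removals <- sum(f$audit[c("invalid_smiles", "dot_smiles", "duplicate",
                              "unmapped_description")])
    expect_equal(unname(f$audit[["input"]]),
                 unname(f$audit[["retained"]]) + removals)
  }
})

test_that("filtering already-filtered records changes nothing", {
  prep <- prepare_records(.raw_records())
  f1 <- apply_filters(prep[prep$source == "B", , drop = FALSE])
  f2 <- apply_filters(f1$retained)
  expect_identical(f1$retained$smiles_canonical, f2$retained$smiles_canonical)
  expect_identical(f1$retained$strength_code, f2$retained$strength_code)
  expect_equal(unname(f2$audit[["input"]]), unname(f2$audit[["retained"]]))
})

test_that("merging applies precedence and records the overlap", {
  a <- data.frame(smiles_canonical = c("CCO", "CCC"), strength_code = c(2L, 1L))
  b <- data.frame(smiles_canonical = c("CCO", "CCCC"), strength_code = c(3L, 0L))
  m <- merge_sources(a, b, precedence = "A")
  expect_equal(nrow(m$merged), 3L)
  expect_equal(m$merged$strength_code[m$merged$smiles_canonical == "CCO"], 2L)
  expect_equal(m$overlap$label_A, 2L)
  expect_equal(m$overlap$label_B, 3L)
  m2 <- merge_sources(a, b, precedence = "B")
  expect_equal(m2$merged$strength_code[m2$merged$smiles_canonical == "CCO"], 3L)
  # disjoint inputs: union of sizes; empty A: identity on B
  d <- merge_sources(a, data.frame(smiles_canonical = "CCCCC",
                                   strength_code = 1L))
  expect_equal(nrow(d$merged), 3L)
  e <- merge_sources(a[0, ], b)
  expect_identical(sort(e$merged$smiles_canonical), sort(b$smiles_canonical))
})

test_that("weighted kappa reproduces worked values and the brute-force oracle", {
  expect_equal(kappa_quadratic(0:3, 0:3), 1)
  # observed weighted disagreement 1, expected 0.5 -> kappa = -1
  expect_equal(kappa_quadratic(c(0, 0, 3, 3), c(3, 3, 0, 0)), -1)
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    a <- sample(0:3, n, replace = TRUE)
    b <- sample(0:3, n, replace = TRUE)
    ko <- oracle_kappa(a, b)
    kp <- kappa_quadratic(a, b)
    if (is.na(ko)) expect_true(is.na(kp)) else expect_equal(as.numeric(kp), ko)
  }
  # symmetry
  a <- c(0, 1, 2, 3, 3, 2); b <- c(1, 1, 2, 2, 3, 0)
  expect_equal(kappa_quadratic(a, b), kappa_quadratic(b, a))
  # degenerate single-category input is flagged undefined
  k <- kappa_quadratic(c(2, 2), c(2, 2))
  expect_true(is.na(k) && attr(k, "undefined"))
})

test_that("ordinal alpha matches the brute-force coincidence oracle", {
  r <- rbind(c(0, 0), c(1, 1), c(2, 3))
  expect_equal(krippendorff_alpha_ordinal(r), oracle_alpha_ordinal(r))
  set.seed(7)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    r <- cbind(sample(0:3, n, replace = TRUE), sample(0:3, n, replace = TRUE))
    r[sample(n, 2), 2] <- NA  # missing annotations allowed
    ao <- oracle_alpha_ordinal(r)
    ap <- krippendorff_alpha_ordinal(r)
    if (is.na(ao)) expect_true(is.na(ap)) else expect_equal(as.numeric(ap), ao)
  }
  expect_equal(krippendorff_alpha_ordinal(cbind(0:3, 0:3)), 1)
})

test_that("the full curation pipeline reports agreement near the generator target", {
  cfg <- generator_config(n_molecules = 300, seed = 19, overlap_fraction = 0.5)
  rec <- emit_two_source_dataset(assign_labels(generate_molecules(cfg), cfg), cfg)
  cu <- curate(rec)
  expect_s3_class(cu$agreement, "agreement_report")
  expect_equal(sum(cu$agreement$contingency), cu$agreement$n_overlap)
  expect_gt(cu$agreement$kappa_quadratic, 0.6)
  expect_gt(cu$agreement$krippendorff_alpha, 0.6)
  # curated output is one label per canonical SMILES
  expect_false(anyDuplicated(cu$curated$smiles_canonical) > 0)
  expect_true(all(cu$curated$strength_code %in% 0:3))
})
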