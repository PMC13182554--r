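# Synthetic two-source ordinal odor-strength data.
#
# Molecules come from a fragment grammar (alkyl/alkenyl backbones decorated
# with common functional groups), the ordinal label from a latent
# mass-transport score: strength peaks at an optimum of molecular weight and
# lipophilicity (volatile enough to reach the nose, lipophilic enough to
# cross the mucosa) and rises with H-bonding polarity, plus Gaussian noise.
# Two annotation sources with different class profiles then observe the true
# label through an adjacent-category noise channel.

# internal seed-derivation offsets so each stage is independently reproducible
.SEED_OFFSETS <- c(generate = 0L, labels = 1L, emit = 2L)

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic dataset generator
#'
#' Defaults encode the study conditions the generator emulates: a
#' medium-majority, low-minority (~12%) class structure; one source skewed
#' toward medium/high strengths and one toward odorless/low; a 30% molecule
#' overlap between sources; and adjacent-category label noise of 0.2 per
#' annotation, which puts the chance-corrected agreement on the overlap
#' near 0.8 (quadratically weighted kappa about 0.85, ordinal alpha about
#' 0.81).
#'
#' @param n_molecules number of unique molecules to generate.
#' @param seed integer seed; identical config + seed gives identical output.
#' @param source_mix list with elements `A` and `B`, each a 4-vector of
#'   target class probabilities (odorless, low, medium, high) summing to 1.
#' @param overlap_fraction fraction in \[0, 1\] of molecules annotated by
#'   both sources.
#' @param label_noise probability in \[0, 1) of an adjacent-category flip
#'   per annotation (boundary categories flip inward).
#' @param latent_params list with coefficients `beta0`, `beta_mw` (per Da),
#'   `beta_logp`, `beta_polarity`; optima `mu_mw` (Da), `mu_logp`; and
#'   `noise_sd` (> 0 unless exactly 0 for deterministic labels).
#' @param thresholds strictly increasing cutpoints `c(tau1, tau2, tau3)` on
#'   the latent score.
#' @return validated object of class `generator_config`.
#' @export
generator_config <- function(n_molecules = 1000L,
                             seed = 1L,
                             source_mix = list(A = c(0.05, 0.10, 0.50, 0.35),
                                               B = c(0.40, 0.30, 0.20, 0.10)),
                             overlap_fraction = 0.3,
                             label_noise = 0.2,
                             latent_params = list(beta0 = 3.2,
                                                  beta_mw = 0.012,
                                                  beta_logp = 0.55,
                                                  beta_polarity = 0.12,
                                                  mu_mw = 140,
                                                  mu_logp = 2.5,
                                                  noise_sd = 0.15),
                             thresholds = c(1.69, 2.03, 2.80)) {
  stopifnot(is.numeric(n_molecules), length(n_molecules) == 1L, n_molecules >= 1,
            is.numeric(seed), length(seed) == 1L,
            is.list(source_mix), setequal(names(source_mix), c("A", "B")),
            overlap_fraction >= 0, overlap_fraction <= 1,
            label_noise >= 0, label_noise < 1,
            length(thresholds) == 3L)
  for (s in c("A", "B")) {
    p <- source_mix[[s]]
    if (length(p) != .K || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("source_mix$", s, " must be 4 non-negative probabilities summing to 1")
  }
  if (!(thresholds[1] < thresholds[2] && thresholds[2] < thresholds[3]))
    stop("thresholds must satisfy tau1 < tau2 < tau3 strictly")
  need <- c("beta0", "beta_mw", "beta_logp", "beta_polarity",
            "mu_mw", "mu_logp", "noise_sd")
  if (!all(need %in% names(latent_params)))
    stop("latent_params must contain: ", paste(need, collapse = ", "))
  if (latent_params$noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(n_molecules = as.integer(n_molecules), seed = as.integer(seed),
                 source_mix = source_mix, overlap_fraction = overlap_fraction,
                 label_noise = label_noise, latent_params = latent_params,
                 thresholds = as.numeric(thresholds)),
            class = "generator_config")
}

# ---- fragment grammar -------------------------------------------------------

# substituents attachable to a backbone carbon (at most one per carbon, which
# keeps every generated structure within carbon's valence)
.GRAMMAR_GROUPS <- c(alcohol = "(O)", aldehyde = "(C=O)", ketone = "(C(C)=O)",
                     ester = "(C(=O)OC)", ether = "(OC)", acid = "(C(=O)O)",
                     amine = "(N)", nitrile = "(C#N)", thiol = "(S)",
                     aromatic = "(c1ccccc1)")
.GRAMMAR_CHAIN <- 2:12

# loose upper bound on distinct structures the grammar can emit; requests
# beyond half of it are rejected because rejection sampling of unique
# canonical forms would stall
.grammar_capacity <- function() {
  cap <- 0
  for (L in .GRAMMAR_CHAIN) {
    db <- L                              # no double bond, or one of L-1 sites
    combos <- sum(vapply(0:3, function(g) choose(L, g) * 10^g, numeric(1)))
    cap <- cap + db * combos
  }
  cap
}

.random_smiles <- function() {
  L <- sample(.GRAMMAR_CHAIN, 1L)
  db <- if (L >= 3 && stats::runif(1) < 0.3) sample(L - 1L, 1L) else 0L
  n_groups <- min(sample(0:3, 1L, prob = c(0.15, 0.4, 0.3, 0.15)), L)
  pos <- if (n_groups > 0) sample(L, n_groups) else integer(0)
  grp <- if (n_groups > 0) sample(.GRAMMAR_GROUPS, n_groups, replace = TRUE)
         else character(0)
  atoms <- rep("C", L)
  for (k in seq_along(pos)) atoms[pos[k]] <- paste0("C", grp[k])
  bonds <- rep("", L - 1L)
  if (db > 0) bonds[db] <- "="
  paste0(atoms[1], paste0(bonds, atoms[-1], collapse = ""), collapse = "")
}

#' Generate unique synthetic molecules
#'
#' Draws molecules from the fragment grammar: a linear carbon backbone of
#' 2-12 atoms, optionally with one C=C double bond, decorated with 0-3
#' substituents from \{alcohol, aldehyde, ketone, ester, ether, carboxylic
#' acid, amine, nitrile, thiol, phenyl\}. All outputs are syntactically
#' valid, canonicalized and unique, spanning roughly 30-400 Da so the latent
#' strength model has signal.
#'
#' @param config a [generator_config()].
#' @return character vector of `n_molecules` unique canonical SMILES.
#' @export
generate_molecules <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_molecules
  if (n > .grammar_capacity() / 2)
    stop("n_molecules = ", n, " exceeds the unique-structure capacity of the ",
         "fragment grammar (about ", floor(.grammar_capacity() / 2),
         " reliably reachable structures)")
  .with_seed(config$seed + .SEED_OFFSETS[["generate"]], {
    seen <- character(0)
    attempts <- 0L
    max_attempts <- 200L * n
    while (length(seen) < n && attempts < max_attempts) {
      batch_n <- max(64L, n - length(seen))
      raw <- vapply(seq_len(batch_n), function(i) .random_smiles(), character(1))
      attempts <- attempts + batch_n
      can <- canonicalize_smiles(raw)
      can <- can[!is.na(can)]
      new <- setdiff(can, seen)
      seen <- c(seen, new)
    }
    if (length(seen) < n)
      stop("could not generate ", n, " unique molecules from the grammar")
    seen[seq_len(n)]
  })
}

# ---- latent labels ----------------------------------------------------------

.latent_score <- function(desc, lp, noise) {
  mw <- desc[, "MW"]; logp <- desc[, "logP"]
  pol <- desc[, "HBD"] + desc[, "HBA1"]
  lp$beta0 - lp$beta_mw * abs(mw - lp$mu_mw) -
    lp$beta_logp * abs(logp - lp$mu_logp) + lp$beta_polarity * pol + noise
}

.threshold_labels <- function(s, tau) {
  findInterval(s, tau)  # 0..3
}

#' Assign latent scores and true ordinal labels
#'
#' The latent strength score is
#' `beta0 - beta_mw*|MW - mu_mw| - beta_logp*|logP - mu_logp| +
#' beta_polarity*(HBD + HBA) + Normal(0, noise_sd)`; the true label is its
#' deterministic thresholding at `tau1 < tau2 < tau3`. Descriptors come from
#' [descriptors()].
#'
#' @param molecules character vector of canonical SMILES.
#' @param config a [generator_config()].
#' @return object of class `synthetic_dataset`: list with `smiles`,
#'   `latent_scores`, `true_labels` (codes 0..3), and the descriptor
#'   [feature_matrix()] used (`descriptors`).
#' @export
assign_labels <- function(molecules, config) {
  stopifnot(inherits(config, "generator_config"), is.character(molecules))
  desc <- descriptors(molecules)
  if (length(desc$encoder_params$failed_smiles))
    stop("featurization failed for: ",
         paste(desc$encoder_params$failed_smiles, collapse = ", "))
  lp <- config$latent_params
  noise <- .with_seed(config$seed + .SEED_OFFSETS[["labels"]],
                      stats::rnorm(nrow(desc$values), 0, lp$noise_sd))
  s <- .latent_score(desc$values, lp, noise)
  structure(list(smiles = desc$row_keys, latent_scores = as.numeric(s),
                 true_labels = as.integer(.threshold_labels(s, config$thresholds)),
                 descriptors = desc),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d molecules; label counts: %s\n",
              length(x$smiles),
              paste(tabulate(x$true_labels + 1L, .K), collapse = "/")))
  invisible(x)
}

# adjacent-category noise channel: flip to a neighbor with probability p,
# boundary categories flip inward only
.flip_adjacent <- function(y, p) {
  n <- length(y)
  do_flip <- stats::runif(n) < p
  dir <- ifelse(y == 0L, 1L, ifelse(y == .K - 1L, -1L,
                                    ifelse(stats::runif(n) < 0.5, -1L, 1L)))
  ifelse(do_flip, y + dir, y)
}

#' Emit the two-source annotated record table
#'
#' Assigns each molecule to source A, source B, or both (the overlap), and
#' observes the true label through the adjacent-flip noise channel
#' independently per annotation. Which non-overlap molecules each source
#' annotates is steered by rejection-resampling weights
#' `target_mix[class] / empirical_freq[class]`, so the per-source class
#' profiles approach `source_mix` while the latent ground truth stays common
#' to both sources. Source A reports a categorical strength word; source B
#' reports a free-text odor description built from the default keyword
#' phrases, leaving the strength column empty (so curation has to map it).
#'
#' @param dataset a `synthetic_dataset` from [assign_labels()].
#' @param config the same [generator_config()].
#' @return data.frame with one row per annotation: `smiles`, `source`
#'   (`"A"`/`"B"`), `description`, `strength` (word or `NA`),
#'   `label_observed` (noisy code), `label_true`.
#' @export
emit_two_source_dataset <- function(dataset, config) {
  stopifnot(inherits(dataset, "synthetic_dataset"),
            inherits(config, "generator_config"))
  n <- length(dataset$smiles)
  y <- dataset$true_labels
  .with_seed(config$seed + .SEED_OFFSETS[["emit"]], {
    n_both <- round(config$overlap_fraction * n)
    both <- sample(n, n_both)
    rest <- setdiff(seq_len(n), both)
    freq <- (tabulate(y + 1L, .K) + 0.5) / (n + 2)
    wA <- config$source_mix$A[y + 1L] / freq[y + 1L]
    wB <- config$source_mix$B[y + 1L] / freq[y + 1L]
    pA <- wA / (wA + wB)
    to_A <- rest[stats::runif(length(rest)) < pA[rest]]
    to_B <- setdiff(rest, to_A)
    idx_A <- sort(c(both, to_A))
    idx_B <- sort(c(both, to_B))
    obs_A <- .flip_adjacent(y[idx_A], config$label_noise)
    obs_B <- .flip_adjacent(y[idx_B], config$label_noise)
    rbind(
      data.frame(smiles = dataset$smiles[idx_A], source = "A",
                 description = "",
                 strength = strength_label(obs_A),
                 label_observed = obs_A, label_true = y[idx_A],
                 stringsAsFactors = FALSE),
      data.frame(smiles = dataset$smiles[idx_B], source = "B",
                 description = .describe_strength(obs_B),
                 strength = NA_character_,
                 label_observed = obs_B, label_true = y[idx_B],
                 stringsAsFactors = FALSE)
    )
  })
}

# phrase templates whose keywords round-trip through the default keyword table
.DESCRIPTION_TEMPLATES <- list(
  c("Colorless, odorless gas.", "An odorless crystalline solid.",
    "Practically odorless liquid."),
  c("Faint, slightly sweet odor.", "Weak characteristic smell.",
    "Mild ethereal odor."),
  c("Moderate fruity odor.", "Distinct aromatic smell.",
    "Noticeable characteristic odor."),
  c("Strong pungent smell.", "Intense penetrating odor.",
    "Powerful aromatic odor.")
)

.describe_strength <- function(codes) {
  vapply(codes, function(cd) {
    opts <- .DESCRIPTION_TEMPLATES[[cd + 1L]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
}

#' Write synthetic records and the hidden-truth sidecar
#'
#' `write_records_csv()` writes the standard record table
#' (smiles, source, description, strength); `write_truth_csv()` writes the
#' hidden ground truth (smiles, latent_score, true_label) used only by tests
#' and audits.
#'
#' @param records data.frame from [emit_two_source_dataset()].
#' @param dataset a `synthetic_dataset`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records[, c("smiles", "source", "description", "strength")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_records_csv
#' @export
write_truth_csv <- function(dataset, path) {
  utils::write.csv(data.frame(smiles = dataset$smiles,
                              latent_score = dataset$latent_scores,
                              true_label = dataset$true_labels),
                   path, row.names = FALSE)
  invisible(path)
}
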