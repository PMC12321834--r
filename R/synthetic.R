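# Synthetic SMILES datasets with a planted, noisy structure-toxicity rule.
#
# Molecules are assembled by concatenating valence-safe SMILES fragments
# (every vocabulary fragment starts and ends with an atom that can accept
# one more bond, so plain string concatenation always yields a valid
# molecule). The positive class is defined by substructure: a molecule
# containing any toxicophore pattern is toxic. Ground truth comes from
# SMARTS matching on the assembled molecule - not from the construction
# path - so accidental matches in "non-toxic" draws are caught and
# resampled. Labels are then flipped independently with the noise rate.

# link-safe fragments: first and last written atoms keep a spare valence
SYN_NEUTRAL_FRAGS <- c(
  "C", "CC", "CCC", "CCCC", "CC(C)C", "CCO", "CCOC", "CCN", "CCSC",
  "c1ccccc1", "Cc1ccccc1", "C1CCCCC1", "CC(Cl)", "CC(Br)", "CC(F)",
  "CC(=O)C", "CC(C)O", "CCC(=O)N"
)
# decoys: share motifs with the toxicophores without matching them
SYN_DECOY_FRAGS <- c(
  "c1ccc(C(=O)OCC)cc1",       # lone aromatic ester (not an ortho pair)
  "CC([N+](=O)[O-])",         # aliphatic nitro
  "c1ccc(N)cc1",              # aniline
  "CC(=O)OC"                  # aliphatic ester
)
SYN_TOXICOPHORE_FRAGS <- c(
  nitroaromatic = "c1ccc([N+](=O)[O-])cc1",
  phthalate_diester = "c1ccc(C(=O)OCC)c(C(=O)OCC)c1"
)
SYN_TOXICOPHORE_SMARTS <- c(
  nitroaromatic = "c[N+](=O)[O-]",
  phthalate_diester = "O=C(O[#6])c1ccccc1C(=O)O[#6]"
)

#' Match toxicophore patterns
#'
#' Counts matches of the planted toxicophore SMARTS patterns in each
#' molecule.
#'
#' @param smiles character vector of valid SMILES.
#' @param patterns named character vector of SMARTS (defaults to the
#'   planted nitroaromatic and ortho-phthalate-diester patterns).
#' @return a logical vector: any pattern present.
#' @export
matches_toxicophore <- function(smiles, patterns = SYN_TOXICOPHORE_SMARTS) {
  hit <- rep(FALSE, length(smiles))
  for (p in patterns) {
    hit <- hit | ob_smarts_count(smiles, p) > 0
  }
  hit
}

#' Generate a synthetic compound dataset
#'
#' Draws molecules from the fragment grammar, plants the toxicophore rule,
#' steers the pre-noise class balance to `round(n * toxic_fraction)`
#' positives, and flips each label independently with probability `noise`.
#' Deterministic under `seed`.
#'
#' @param n number of compounds (>= 10; default 500).
#' @param toxic_fraction target positive fraction before noise
#'   (default 0.5, emulating a near-balanced screening collection).
#' @param noise label-noise rate in `[0, 0.5)` (default 0.05).
#' @param seed RNG seed.
#' @param max_frags fragments per molecule are drawn uniformly from
#'   2..`max_frags` (default 4), plus the toxicophore for positives.
#' @return a tibble with `identifier`, `smiles`, `canonical_smiles`,
#'   `label` (noisy), `label_clean` (rule label) and `toxicophore`
#'   (which pattern, `NA` for clean negatives). The rule record (patterns,
#'   rates, seed) is attached as attribute `rule`.
#' @export
generate_compounds <- function(n = 500L, toxic_fraction = 0.5,
                               noise = 0.05, seed = 1L, max_frags = 4L) {
  if (n < 10) stop_cmpnntox("n must be at least 10", "cmpnntox_config_error")
  if (noise < 0 || noise >= 0.5) {
    stop_cmpnntox("noise must be in [0, 0.5)", "cmpnntox_config_error")
  }
  if (toxic_fraction <= 0 || toxic_fraction >= 1) {
    stop_cmpnntox("toxic_fraction must be in (0, 1)", "cmpnntox_config_error")
  }
  set.seed(seed)
  n_pos <- round(n * toxic_fraction)
  n_neg <- n - n_pos
  draw_body <- function(pool) {
    k <- sample(2:max_frags, 1)
    paste0(sample(pool, k, replace = TRUE), collapse = "")
  }
  pos_smiles <- character(n_pos)
  pos_which <- character(n_pos)
  for (i in seq_len(n_pos)) {
    frags <- sample(c(SYN_NEUTRAL_FRAGS, SYN_DECOY_FRAGS),
                    sample(1:(max_frags - 1L), 1), replace = TRUE)
    tox_i <- sample(length(SYN_TOXICOPHORE_FRAGS), 1)
    pieces <- append(frags, SYN_TOXICOPHORE_FRAGS[[tox_i]],
                     after = sample(0:length(frags), 1))
    pos_smiles[i] <- paste0(pieces, collapse = "")
    pos_which[i] <- names(SYN_TOXICOPHORE_FRAGS)[tox_i]
  }
  neg_smiles <- character(n_neg)
  filled <- 0L
  guard <- 0L
  while (filled < n_neg) {
    guard <- guard + 1L
    if (guard > 50L) {
      stop_cmpnntox("fragment grammar failed to reach the target balance",
                    "cmpnntox_generation_error")
    }
    need <- n_neg - filled
    cand <- vapply(seq_len(need), function(i)
      draw_body(c(SYN_NEUTRAL_FRAGS, SYN_DECOY_FRAGS)), "")
    ok <- !matches_toxicophore(cand)
    keep <- cand[ok]
    if (length(keep)) {
      neg_smiles[(filled + 1L):(filled + length(keep))] <- keep
      filled <- filled + length(keep)
    }
  }
  smiles <- c(pos_smiles, neg_smiles)
  tox_name <- c(pos_which, rep(NA_character_, n_neg))
  # ground truth from the rule itself, not the construction path
  label_clean <- as.numeric(matches_toxicophore(smiles))
  stopifnot(all(label_clean == rep(c(1, 0), c(n_pos, n_neg))))
  ord <- sample.int(n)
  smiles <- smiles[ord]; label_clean <- label_clean[ord]
  tox_name <- tox_name[ord]
  flip <- stats::rbinom(n, 1, noise) == 1
  label <- ifelse(flip, 1 - label_clean, label_clean)
  can <- canonical_smiles(smiles)
  stopifnot(!anyNA(can))
  out <- tibble::tibble(
    identifier = sprintf("syn_%05d", seq_len(n)),
    smiles = smiles, canonical_smiles = can,
    label = label, label_clean = label_clean, toxicophore = tox_name
  )
  attr(out, "rule") <- list(
    toxicophore_smarts = SYN_TOXICOPHORE_SMARTS, noise = noise, seed = seed,
    toxic_fraction = toxic_fraction, n_positive_clean = n_pos
  )
  out
}

#' Tiny fixture molecules with known graph sizes
#'
#' A fixed set of named molecules with hand-counted atom and directed-edge
#' counts, for graph-construction checks.
#'
#' @return a tibble with `name`, `smiles`, `n_atoms`, `n_edges`.
#' @export
fixture_molecules <- function() {
  tibble::tibble(
    name = c("methane", "water", "ethanol", "benzene", "dimethyl_phthalate"),
    smiles = c("C", "O", "CCO", "c1ccccc1", "COC(=O)c1ccccc1C(=O)OC"),
    n_atoms = c(1L, 1L, 3L, 6L, 14L),
    n_edges = c(0L, 0L, 4L, 12L, 28L)
  )
}
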