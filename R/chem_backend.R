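# Low-level cheminformatics backend.
#
# All structure handling delegates to OpenBabel through ChemmineOB:
# canonical SMILES, explicit-hydrogen SDF topology, physicochemical
# properties, SMARTS matching and ECFP fingerprints. Atom-level flags that
# the R bindings do not expose (aromaticity, formal charge, chirality tag)
# are recovered by scanning the atom tokens of the *canonical* SMILES, whose
# atom order OpenBabel preserves into SDF output; the two sources are
# aligned 1:1 and cross-checked by element symbol.

# standard atomic masses (Da) for common organic/elemental species
ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.086, P = 30.974, S = 32.06,
  Cl = 35.453, K = 39.098, Ca = 40.078, Zn = 65.38, As = 74.922,
  Se = 78.971, Br = 79.904, Sn = 118.71, I = 126.904, Hg = 200.59,
  Pb = 207.2
)

atomic_mass <- function(element) {
  m <- ATOMIC_MASS[element]
  m[is.na(m)] <- 0
  unname(m)
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form. Strings that do not parse
#' under the SMILES grammar come back as `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where invalid.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  ok <- which(!is.na(smiles) & nzchar(smiles) & !grepl("[[:space:]]", smiles))
  # OpenBabel aborts the input stream at the first unparseable molecule, so
  # convert in passes, marking the offender and resuming after it
  pending <- ok
  while (length(pending)) {
    ids <- paste0("m", pending)
    src <- paste0(smiles[pending], " ", ids, "\n", collapse = "")
    res <- ChemmineOB::convertFormat("SMI", "CAN", src)
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    n_done <- 0L
    if (length(lines)) {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      can <- vapply(parts, `[`, "", 1L)
      ttl <- vapply(parts, function(p) if (length(p) > 1) p[2] else "", "")
      idx <- as.integer(sub("^m", "", ttl))
      keep <- nzchar(can) & !is.na(idx)
      out[idx[keep]] <- can[keep]
      n_done <- length(lines)
    }
    if (n_done >= length(pending)) break
    pending <- pending[-seq_len(n_done + 1L)]  # skip the failing molecule
  }
  out
}

# --- canonical-SMILES atom token scan --------------------------------------

# Returns, for one canonical SMILES, a data.frame with one row per heavy atom
# in string order: element, aromatic, charge, chirality, explicit H count
# (bracket atoms only, NA otherwise).
scan_atom_tokens <- function(smiles) {
  pat <- "\\[[^]]+\\]|Br|Cl|b|c|n|o|p|s|B|C|N|O|P|S|F|I"
  m <- gregexpr(pat, smiles)[[1]]
  if (m[1] == -1) {
    return(data.frame(element = character(), aromatic = logical(),
                      charge = integer(), chirality = character(),
                      h_explicit = integer()))
  }
  toks <- regmatches(smiles, gregexpr(pat, smiles))[[1]]
  parse_tok <- function(tok) {
    if (startsWith(tok, "[")) {
      body <- substr(tok, 2, nchar(tok) - 1)
      body <- sub("^\\d+", "", body)                       # isotope
      sym <- regmatches(body, regexpr("^[A-Za-z][a-z]?", body))
      # two-letter match may swallow aromatic marker or H: element symbols in
      # brackets are e.g. "Cl", "Br", "Se", "se", "nH" must split
      if (nchar(sym) == 2 && substr(sym, 2, 2) == "H" ||
          !(sym %in% c(names(ATOMIC_MASS), tolower(names(ATOMIC_MASS)),
                       "se", "as", "te"))) {
        sym <- substr(sym, 1, 1)
      }
      rest <- substr(body, nchar(sym) + 1, nchar(body))
      aromatic <- sym == tolower(sym)
      element <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      chir_pat <- "^(@@|@(TH|AL|SP|TB|OH)\\d+|@)"
      chir <- regmatches(rest, regexpr(chir_pat, rest))
      chirality <- if (length(chir) == 0) "none"
        else if (chir == "@") "ccw" else if (chir == "@@") "cw" else "other"
      rest <- sub(chir_pat, "", rest)
      hm <- regmatches(rest, regexpr("H\\d*", rest))
      h_explicit <- if (length(hm) == 0) 0L
        else if (hm == "H") 1L else as.integer(substr(hm, 2, nchar(hm)))
      cm <- regmatches(rest, regexpr("[+-]+\\d*", rest))
      charge <- 0L
      if (length(cm) == 1) {
        sign <- if (substr(cm, 1, 1) == "+") 1L else -1L
        digits <- gsub("[+-]", "", cm)
        charge <- if (nzchar(digits)) sign * as.integer(digits)
          else sign * nchar(gsub("\\d", "", cm))
      }
      data.frame(element = element, aromatic = aromatic, charge = charge,
                 chirality = chirality, h_explicit = h_explicit)
    } else {
      aromatic <- tok == tolower(tok)
      element <- paste0(toupper(substr(tok, 1, 1)), substring(tok, 2))
      data.frame(element = element, aromatic = aromatic, charge = 0L,
                 chirality = "none", h_explicit = NA_integer_)
    }
  }
  do.call(rbind, lapply(toks, parse_tok))
}

# --- topology from explicit-hydrogen SDF -----------------------------------

# Parses a batch of *canonical* SMILES into per-molecule topology lists:
#   atoms: tibble(element, aromatic, charge, chirality, n_h, degree,
#                 hybridization, mass)
#   bonds: tibble(a1, a2, order, aromatic, conjugated, in_ring)
# Invalid input is an error here; validation happens upstream.
parse_molecules <- function(can_smiles) {
  stopifnot(length(can_smiles) >= 1, !anyNA(can_smiles))
  src <- paste0(can_smiles, " m", seq_along(can_smiles), "\n", collapse = "")
  sdf_txt <- suppressWarnings(ChemmineOB::convertFormat(
    "SMI", "SDF", src, options = data.frame(names = "h", args = "")
  ))
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(sdf_txt, tf)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(tf))
  if (length(sdfs) != length(can_smiles)) {
    stop_cmpnntox("SMILES failed to parse during topology extraction",
                  "cmpnntox_parse_error")
  }
  lapply(seq_along(can_smiles), function(i) {
    build_topology(sdfs[[i]], can_smiles[i])
  })
}

build_topology <- function(sdf, can) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  is_h <- elements == "H"
  n_all <- length(elements)
  heavy_ids <- which(!is_h)
  n <- length(heavy_ids)
  tok <- scan_atom_tokens(can)
  if (nrow(tok) != n || !all(tok$element == elements[heavy_ids])) {
    stop_cmpnntox(
      paste0("atom alignment failure between canonical SMILES and SDF for: ", can),
      "cmpnntox_parse_error")
  }
  b1 <- integer(0); b2 <- integer(0); bo <- integer(0)
  if (!is.null(bb) && NROW(bb) > 0 && NCOL(bb) >= 3) {
    bm <- matrix(as.integer(as.matrix(bb)[, 1:3, drop = FALSE]), ncol = 3)
    real <- bm[, 1] > 0 & bm[, 2] > 0  # bond-free molecules get a dummy row
    b1 <- bm[real, 1]; b2 <- bm[real, 2]; bo <- bm[real, 3]
  }
  # hydrogen and heavy-neighbour counts
  n_h <- integer(n); degree <- integer(n)
  remap <- integer(n_all); remap[heavy_ids] <- seq_len(n)
  heavy_bond <- !is_h[b1] & !is_h[b2]
  for (k in which(!heavy_bond)) {
    hv <- if (is_h[b1[k]]) b2[k] else b1[k]
    if (!is_h[hv]) n_h[remap[hv]] <- n_h[remap[hv]] + 1L
  }
  a1 <- remap[b1[heavy_bond]]; a2 <- remap[b2[heavy_bond]]
  order <- bo[heavy_bond]
  tabd <- tabulate(c(a1, a2), nbins = n)
  degree <- tabd
  # ring perception: a bond is in a ring iff it is not a bridge
  in_ring <- rep(FALSE, length(a1))
  if (length(a1)) {
    g <- igraph::graph_from_edgelist(cbind(a1, a2), directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    br <- igraph::bridges(g)
    in_ring <- !(seq_along(a1) %in% as.integer(br))
  }
  aromatic_bond <- in_ring & tok$aromatic[a1] & tok$aromatic[a2]
  # hybridization from bond multiplicities (aromatic counts as sp2)
  n_double <- tabulate(c(a1[order == 2], a2[order == 2]), nbins = n)
  n_triple <- tabulate(c(a1[order == 3], a2[order == 3]), nbins = n)
  hyb <- ifelse(n_triple > 0 | n_double >= 2, "sp",
         ifelse(tok$aromatic | n_double == 1, "sp2", "sp3"))
  # convention: a bond is conjugated when aromatic, or when both end atoms
  # carry unsaturation (part of a double/triple/aromatic system)
  unsat <- tok$aromatic | n_double > 0 | n_triple > 0
  conjugated <- aromatic_bond | (unsat[a1] & unsat[a2])
  list(
    smiles = can,
    atoms = tibble::tibble(
      element = tok$element, aromatic = tok$aromatic, charge = tok$charge,
      chirality = tok$chirality, n_h = n_h, degree = degree,
      hybridization = hyb, mass = atomic_mass(tok$element)
    ),
    bonds = tibble::tibble(
      a1 = a1, a2 = a2, order = order, aromatic = aromatic_bond,
      conjugated = conjugated, in_ring = in_ring
    )
  )
}

# --- OpenBabel-backed whole-molecule computations --------------------------

# Apply fn over molecules of a batch of valid SMILES, returning a list.
ob_for_each <- function(smiles, fn) {
  src <- paste0(smiles, " m", seq_along(smiles), "\n", collapse = "")
  ChemmineOB::forEachMol("SMILES", src, fn)
}

ob_properties <- function(smiles) {
  props <- ob_for_each(smiles, function(m) ChemmineOB::prop_OB(m))
  dplyr::bind_rows(props)
}

ob_ecfp4 <- function(smiles) {
  fps <- ob_for_each(smiles, function(m)
    ChemmineOB::fingerprint_OB(list(m), "ECFP4"))
  do.call(rbind, fps)
}

# count of unique SMARTS matches per molecule
ob_smarts_count <- function(smiles, smarts) {
  hits <- ob_for_each(smiles, function(m)
    ChemmineOB::smartsSearch_OB(list(m), smarts, uniqueMatches = TRUE))
  vapply(hits, function(h) as.numeric(h[[1]]), 0)
}
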