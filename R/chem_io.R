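# Compound-table I/O, Morgan fingerprints and physicochemical descriptors.

#' Read a compound table from delimited text
#'
#' Reads a CSV with a header row containing at least a SMILES column and,
#' unless `label_col = NULL`, a binary label column (1 = toxic, 0 =
#' non-toxic). Rows whose SMILES do not parse are dropped with a message;
#' the kept/dropped tallies are attached as attributes `n_kept` and
#' `n_dropped`.
#'
#' @param path path to a CSV file.
#' @param smiles_col,label_col column names (defaults `"smiles"`,
#'   `"label"`). Set `label_col = NULL` for unlabelled prediction input.
#' @param id_col optional identifier column; when absent, identifiers
#'   `cmpd_<row>` are generated.
#' @param keep_largest_fragment if `TRUE`, multi-fragment SMILES (salts,
#'   mixtures) are reduced to their largest fragment by heavy-atom count.
#'   Off by default: structures are taken as written.
#' @return a tibble with columns `identifier`, `smiles`,
#'   `canonical_smiles` and (if requested) `label`, in file order.
#' @export
read_compounds <- function(path, smiles_col = "smiles", label_col = "label",
                           id_col = NULL, keep_largest_fragment = FALSE) {
  if (!file.exists(path)) {
    stop_cmpnntox(paste0("input file not found: ", path), "cmpnntox_input_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_compound_table(raw, smiles_col = smiles_col, label_col = label_col,
                    id_col = id_col,
                    keep_largest_fragment = keep_largest_fragment)
}

#' Validate an in-memory compound table
#'
#' The data-frame counterpart of [read_compounds()]: checks columns,
#' validates SMILES and labels, drops unparseable rows with a message.
#'
#' @inheritParams read_compounds
#' @param data a data frame with SMILES (and optionally label) columns.
#' @return a tibble as in [read_compounds()].
#' @export
as_compound_table <- function(data, smiles_col = "smiles",
                              label_col = "label", id_col = NULL,
                              keep_largest_fragment = FALSE) {
  stopifnot(is.data.frame(data))
  if (is.null(id_col) && "identifier" %in% names(data)) id_col <- "identifier"
  for (col in c(smiles_col, label_col, id_col)) {
    if (!is.null(col) && !col %in% names(data)) {
      stop_cmpnntox(paste0("column not found in input: ", col),
                    "cmpnntox_schema_error")
    }
  }
  smiles <- as.character(data[[smiles_col]])
  if (keep_largest_fragment) smiles <- largest_fragment(smiles)
  can <- canonical_smiles(smiles)
  keep <- !is.na(can)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform_quiet("dropped ", n_dropped, " row(s) with unparseable SMILES")
  }
  if (!any(keep)) {
    stop_cmpnntox("no valid SMILES rows in input", "cmpnntox_empty_error")
  }
  ids <- if (!is.null(id_col)) as.character(data[[id_col]])
         else sprintf("cmpd_%05d", seq_along(smiles))
  out <- tibble::tibble(identifier = ids[keep], smiles = smiles[keep],
                        canonical_smiles = can[keep])
  if (!is.null(label_col)) {
    lab <- data[[label_col]][keep]
    if (!is_binary_label(lab[!is.na(lab)])) {
      stop_cmpnntox("labels must be 0 or 1", "cmpnntox_schema_error")
    }
    out$label <- as.numeric(lab)
  }
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- n_dropped
  out
}

# naive dot-split largest fragment (heavy atoms counted by token scan)
largest_fragment <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !grepl(".", s, fixed = TRUE)) return(s)
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    sizes <- vapply(frags, function(f) nrow(scan_atom_tokens(f)), 0L)
    frags[which.max(sizes)]
  }, "", USE.NAMES = FALSE)
}

#' Write a compound table to CSV
#'
#' @param data a compound tibble (as from [read_compounds()]).
#' @param path output path.
#' @return `data`, invisibly.
#' @export
write_compounds <- function(data, path) {
  cols <- intersect(c("identifier", "smiles", "canonical_smiles", "label"),
                    names(data))
  readr::write_csv(data[cols], path, progress = FALSE)
  invisible(data)
}

#' Morgan (ECFP) fingerprints
#'
#' Appends a `fingerprint` list-column of binary vectors to a compound
#' table. Circular ECFP fingerprints of the requested radius (default 2,
#' i.e. ECFP4) are computed by OpenBabel and folded to `n_bits` by OR-ing
#' equal-length segments.
#'
#' @param data a data frame with a SMILES column.
#' @param smiles_col SMILES column name.
#' @param radius circular-neighbourhood radius (0--3; default 2 = ECFP4).
#' @param n_bits folded length (default 2048; must divide 4096).
#' @return `data` with an added `fingerprint` list-column of 0/1 integer
#'   vectors of length `n_bits`.
#' @export
compute_fingerprints <- function(data, smiles_col = "smiles", radius = 2,
                                 n_bits = 2048) {
  stopifnot(is.data.frame(data), smiles_col %in% names(data))
  if (!radius %in% 0:3) {
    stop_cmpnntox("radius must be 0, 1, 2 or 3", "cmpnntox_config_error")
  }
  if (4096 %% n_bits != 0) {
    stop_cmpnntox("n_bits must divide 4096", "cmpnntox_config_error")
  }
  can <- require_valid_smiles(data[[smiles_col]])
  raw <- ob_ecfp4_any(can, radius)
  folded <- fold_fingerprints(raw, n_bits)
  data <- tibble::as_tibble(data)
  data$fingerprint <- lapply(seq_len(nrow(folded)), function(i)
    as.integer(folded[i, ]))
  data
}

ob_ecfp4_any <- function(smiles, radius) {
  name <- paste0("ECFP", 2L * radius)
  fps <- ob_for_each(smiles, function(m)
    ChemmineOB::fingerprint_OB(list(m), name))
  do.call(rbind, fps)
}

fold_fingerprints <- function(raw, n_bits) {
  k <- ncol(raw) / n_bits
  out <- matrix(0L, nrow(raw), n_bits)
  for (j in seq_len(k)) {
    seg <- raw[, ((j - 1) * n_bits + 1):(j * n_bits), drop = FALSE]
    out <- pmax(out, (seg != 0) * 1L)
  }
  out
}

#' Extract the fingerprint list-column as a matrix
#'
#' @param data a tibble with a `fingerprint` list-column
#'   (from [compute_fingerprints()]).
#' @return an integer matrix, one row per compound.
#' @export
fingerprint_matrix <- function(data) {
  stopifnot("fingerprint" %in% names(data))
  do.call(rbind, data$fingerprint)
}

require_valid_smiles <- function(smiles) {
  can <- canonical_smiles(as.character(smiles))
  if (anyNA(can)) {
    bad <- which(is.na(can))
    stop_cmpnntox(paste0("unparseable SMILES at row(s): ",
                         paste(utils::head(bad, 5), collapse = ", ")),
                  "cmpnntox_parse_error")
  }
  can
}

#' Physicochemical descriptors
#'
#' Appends the six descriptor columns used throughout the package:
#' molecular weight (`weight`, Da), topological polar surface area (`tpsa`,
#' Ertl scheme, squared angstroms), Wildman--Crippen atom-contribution
#' `logp`, hydrogen-bond donor and acceptor counts (`hbd`, `hba`;
#' OpenBabel's Lipinski-type SMARTS definitions) and the rotatable-bond
#' count (`rot_bonds`; non-ring single bonds between non-terminal atoms,
#' excluding triple-bond atoms and carbonyl--O/N linkages).
#'
#' @param data a data frame with a SMILES column.
#' @param smiles_col SMILES column name.
#' @return `data` with the six descriptor columns appended. The descriptor
#'   provenance (scheme names) is attached as attribute
#'   `descriptor_schemes`.
#' @export
compute_descriptors <- function(data, smiles_col = "smiles") {
  stopifnot(is.data.frame(data), smiles_col %in% names(data))
  can <- require_valid_smiles(data[[smiles_col]])
  pr <- ob_properties(can)
  topo <- parse_molecules(can)
  data <- tibble::as_tibble(data)
  data$weight <- as.numeric(pr$MW)
  data$tpsa <- as.numeric(pr$TPSA)
  data$logp <- as.numeric(pr$logP)
  data$hbd <- as.integer(pr$HBD)
  data$hba <- as.integer(pr$HBA2)
  data$rot_bonds <- vapply(topo, count_rotatable_bonds, 0L)
  attr(data, "descriptor_schemes") <- c(
    weight = "standard atomic masses (OpenBabel)",
    tpsa = "Ertl TPSA (OpenBabel)",
    logp = "Wildman-Crippen atom contributions (OpenBabel)",
    hbd = "OpenBabel HBD SMARTS", hba = "OpenBabel HBA2 SMARTS",
    rot_bonds = "graph rule: acyclic single bonds, non-terminal, no triple/amide-ester"
  )
  data
}

count_rotatable_bonds <- function(topo) {
  b <- topo$bonds
  if (nrow(b) == 0) return(0L)
  a <- topo$atoms
  in_triple <- rep(FALSE, nrow(a))
  tr <- b$order == 3
  in_triple[c(b$a1[tr], b$a2[tr])] <- TRUE
  # carbonyl carbons: C double-bonded to O
  dbl_o <- (b$order == 2 & !b$aromatic) &
    ((a$element[b$a1] == "C" & a$element[b$a2] == "O") |
     (a$element[b$a2] == "C" & a$element[b$a1] == "O"))
  carbonyl <- rep(FALSE, nrow(a))
  carbonyl[c(b$a1[dbl_o], b$a2[dbl_o])[
    a$element[c(b$a1[dbl_o], b$a2[dbl_o])] == "C"]] <- TRUE
  cand <- b$order == 1 & !b$aromatic & !b$in_ring &
    a$degree[b$a1] >= 2 & a$degree[b$a2] >= 2 &
    !in_triple[b$a1] & !in_triple[b$a2]
  ester_like <- (carbonyl[b$a1] & a$element[b$a2] %in% c("O", "N")) |
                (carbonyl[b$a2] & a$element[b$a1] %in% c("O", "N"))
  sum(cand & !ester_like)
}

#' Per-class descriptor summary
#'
#' Medians and quartiles of the six descriptors, by toxicity class. The
#' median of an even-sized class is the midpoint of the two central order
#' statistics.
#'
#' @param data a compound tibble with `label` and descriptor columns (run
#'   [compute_descriptors()] first; it is called here if the columns are
#'   missing).
#' @return a tibble with columns `class`, `descriptor`, `q1`, `median`,
#'   `q3`, `n`.
#' @export
summarize_descriptors <- function(data) {
  stopifnot(is.data.frame(data))
  if (!"label" %in% names(data) || anyNA(data$label)) {
    stop_cmpnntox("every record needs a 0/1 label", "cmpnntox_schema_error")
  }
  desc_cols <- c("weight", "tpsa", "logp", "hbd", "hba", "rot_bonds")
  if (!all(desc_cols %in% names(data))) data <- compute_descriptors(data)
  if (length(unique(data$label)) < 2) {
    stop_cmpnntox("a toxicity class has zero members",
                  "cmpnntox_degenerate_class_error")
  }
  data |>
    dplyr::select(dplyr::all_of(c("label", desc_cols))) |>
    tidyr::pivot_longer(dplyr::all_of(desc_cols), names_to = "descriptor",
                        values_to = "value") |>
    dplyr::group_by(class = .data$label, .data$descriptor) |>
    dplyr::summarise(
      q1 = stats::quantile(.data$value, 0.25, names = FALSE),
      median = stats::median(.data$value),
      q3 = stats::quantile(.data$value, 0.75, names = FALSE),
      n = dplyr::n(), .groups = "drop"
    )
}
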