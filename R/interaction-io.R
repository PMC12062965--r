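#' Bondi van der Waals radius table
#'
#' Default atomic radii (Angstrom) used by the clash filter. Values are the
#' Bondi set for the elements that occur in predicted protein models.
#'
#' @param overrides Optional named numeric vector of element -> radius to add
#'   or replace entries.
#' @return Named numeric vector of radii.
#' @export
#' @examples
#' vdw_radii()[["C"]] # 1.70
vdw_radii <- function(overrides = NULL) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
  if (!is.null(overrides)) {
    if (any(overrides <= 0)) abort("Radii must be positive.")
    r[names(overrides)] <- overrides
  }
  r
}

#' Read a van der Waals radius table
#'
#' @param path TSV with columns `element`, `radius` (Angstrom).
#' @return Named numeric vector usable wherever [vdw_radii()] is.
#' @export
read_vdw_radii <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(df, c("element", "radius"), "radius table")
  vdw_radii(stats::setNames(df$radius, df$element))
}

infer_element <- function(atom_name) {
  # PDB atom names may start with a digit (e.g. "1HB"); element is the first
  # alphabetic character (two-letter elements are not produced by the
  # generators and come from columns 77-78 when present)
  toupper(substr(gsub("[^A-Za-z].*$|^[^A-Za-z]+", "", paste0(atom_name, "")), 1, 1))
}

#' Load a predicted two-chain complex
#'
#' Reads a PDB file holding one bait/prey complex and attaches its pTM and
#' ipTM confidences. Chains are mapped to roles by chain id; residue indices
#' are renumbered sequentially from 1 within each chain so downstream
#' profiles are indexed consistently. Elements come from PDB columns 77-78
#' when present and are inferred from the atom name otherwise; an element
#' missing from the radius table is an error naming the atom.
#'
#' @param pdb_path PDB file with exactly two chains.
#' @param ptm,iptm Confidence scores in `[0, 1]`.
#' @param bait_id,prey_id Identifiers for the two partners.
#' @param bait_chain,prey_chain Chain ids carrying bait and prey (default
#'   `"A"` / `"B"`).
#' @param radii Radius table used to validate elements.
#' @return An object of class `complex_model`: list with `bait_id`,
#'   `prey_id`, `ptm`, `iptm` and an `atoms` tibble (`atom_id`, `role`,
#'   `chain`, `residue_index`, `residue_name`, `atom_name`, `element`,
#'   `x`, `y`, `z`).
#' @export
read_complex <- function(pdb_path, ptm, iptm,
                         bait_id = "bait", prey_id = "prey",
                         bait_chain = "A", prey_chain = "B",
                         radii = vdw_radii()) {
  pdb <- bio3d::read.pdb(pdb_path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  chains <- unique(at$chain)
  if (length(chains) != 2) {
    abort(sprintf("Complex must have exactly 2 chains, found %d (%s).",
                  length(chains), paste(chains, collapse = ", ")))
  }
  if (!all(c(bait_chain, prey_chain) %in% chains)) {
    abort(sprintf("Chains %s/%s not found in file (has %s).",
                  bait_chain, prey_chain, paste(chains, collapse = ", ")))
  }
  elem <- ifelse(is.na(at$elesy) | at$elesy == "",
                 infer_element(at$elety), trimws(at$elesy))
  unknown <- which(!elem %in% names(radii))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown element '%s' for atom %s %d %s.",
                  elem[unknown[1]], at$elety[unknown[1]],
                  at$resno[unknown[1]], at$chain[unknown[1]]))
  }
  atoms <- tibble(
    role = if_else(at$chain == bait_chain, "bait", "prey"),
    chain = at$chain,
    resno = at$resno,
    residue_name = at$resid,
    atom_name = at$elety,
    element = elem,
    x = at$x, y = at$y, z = at$z) |>
    group_by(.data$role) |>
    mutate(residue_index = match(.data$resno, unique(.data$resno))) |>
    ungroup() |>
    mutate(atom_id = sprintf("%s:%d:%s:%d", .data$role, .data$residue_index,
                             .data$atom_name, row_number())) |>
    select("atom_id", "role", "chain", "residue_index", "residue_name",
           "atom_name", "element", "x", "y", "z")
  new_complex_model(bait_id, prey_id, atoms, ptm, iptm)
}

new_complex_model <- function(bait_id, prey_id, atoms, ptm, iptm) {
  if (!all(c("bait", "prey") %in% atoms$role)) {
    abort("Both bait and prey chains must be non-empty.")
  }
  structure(list(bait_id = bait_id, prey_id = prey_id, atoms = atoms,
                 ptm = ptm, iptm = iptm),
            class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  cat(sprintf("<complex_model> %s / %s: %d atoms (%d bait, %d prey), pTM %.2f, ipTM %.2f\n",
              x$bait_id, x$prey_id, nrow(x$atoms),
              sum(x$atoms$role == "bait"), sum(x$atoms$role == "prey"),
              x$ptm, x$iptm))
  invisible(x)
}

#' Write a complex back to PDB
#'
#' Coordinates survive a write/read cycle bit-identically at PDB's 3-decimal
#' precision.
#'
#' @param model A `complex_model`.
#' @param path Output PDB path.
#' @param bait_chain,prey_chain Chain ids to emit.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(model, path, bait_chain = "A", prey_chain = "B") {
  a <- model$atoms
  # residue numbering must be global-per-chain for bio3d
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(a)),
    resno = a$residue_index,
    resid = a$residue_name,
    eleno = seq_len(nrow(a)),
    elety = a$atom_name,
    chain = if_else(a$role == "bait", bait_chain, prey_chain),
    elesy = a$element)
  invisible(path)
}

#' Read the benchmark label table
#'
#' The curated library of labelled interactor / noninteractor pairs with the
#' model confidences obtained for them, used for ROC analysis and threshold
#' selection.
#'
#' @param path TSV with columns `pair_id`, `label` (one of `interactor`,
#'   `noninteractor`), `ptm`, `iptm`.
#' @return Tibble of benchmark pairs.
#' @export
read_benchmark <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(df, c("pair_id", "label", "ptm", "iptm"), "benchmark table")
  bad <- setdiff(unique(df$label), c("interactor", "noninteractor"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown benchmark label(s): %s", paste(bad, collapse = ", ")))
  }
  as_tibble(df)
}

#' Read a screen confidence table
#'
#' @param path TSV with columns `bait`, `prey`, `ptm`, `iptm`.
#' @return Tibble with columns `bait_id`, `prey_id`, `ptm`, `iptm`.
#' @export
read_confidence <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(df, c("bait", "prey", "ptm", "iptm"), "confidence table")
  df |> rename(bait_id = "bait", prey_id = "prey")
}

#' Read a bait domain map
#'
#' @param path TSV with columns `bait`, `domain_label`, `start_res`,
#'   `end_res` (1-based inclusive residue ranges).
#' @return Tibble with columns `bait_id`, `domain_label`, `start_res`,
#'   `end_res`.
#' @export
read_domain_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(df, c("bait", "domain_label", "start_res", "end_res"),
                 "domain map")
  if (any(df$start_res > df$end_res)) abort("Domain map has start_res > end_res.")
  df |> rename(bait_id = "bait")
}
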