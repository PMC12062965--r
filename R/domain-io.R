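#' Read curated domain-set lists
#'
#' Loads the two curated lists of InterPro accessions that drive the
#' co-occurrence screen: domains characteristic of eukaryotic multicopy gene
#' families (F-box, ankyrin repeats, BTB/POZ, kinases, ...) and domains derived
#' from transposable elements or viruses (transposases, integrases,
#' reverse-transcriptases, ...).
#'
#' @param path TSV with columns `accession`, `category` (one of `multicopy`,
#'   `te_viral`) and optionally `description`.
#' @return A tibble with columns `accession`, `category`, `description`.
#'   The two categories must be disjoint; an accession listed under both is an
#'   error, since a domain cannot be simultaneously host-multicopy and
#'   TE/viral in this screen.
#' @export
read_domain_sets <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(df, c("accession", "category"), "domain-set table")
  if (!"description" %in% names(df)) df$description <- NA_character_
  bad <- setdiff(unique(df$category), c("multicopy", "te_viral"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown domain-set category: %s", paste(bad, collapse = ", ")))
  }
  overlap <- df |>
    distinct(.data$accession, .data$category) |>
    count(.data$accession) |>
    filter(n > 1)
  if (nrow(overlap) > 0) {
    abort(sprintf(
      "Domain sets must be disjoint; accession(s) in both: %s",
      paste(overlap$accession, collapse = ", ")))
  }
  df |>
    distinct(.data$accession, .keep_all = TRUE) |>
    select("accession", "category", "description")
}

#' Read a protein domain-annotation table
#'
#' Reads an InterPro/UniProt-style export: one row per domain annotation on a
#' protein, with 1-based inclusive amino-acid coordinates. Each annotation is
#' categorised as `multicopy`, `te_viral` or `other` purely by membership in
#' the curated domain sets.
#'
#' @param path TSV with header columns `protein_id`, `taxon_id`, `length`,
#'   `accession`, `start`, `end`.
#' @param domain_sets Tibble from [read_domain_sets()].
#' @return A tibble with one row per domain annotation and an added `category`
#'   column. Raises an error on duplicated annotations, coordinates outside
#'   `[1, length]`, `start > end`, or inconsistent protein lengths; error
#'   messages carry the offending row numbers.
#' @export
read_domain_table <- function(path, domain_sets) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(df, c("protein_id", "taxon_id", "length", "accession",
                       "start", "end"), "domain table")
  as_domain_table(df, domain_sets)
}

#' Categorise an in-memory domain table
#'
#' Same validation and categorisation as [read_domain_table()], for tables
#' built programmatically (e.g. by [sim_domain_table()]).
#'
#' @param df Data frame with columns `protein_id`, `taxon_id`, `length`,
#'   `accession`, `start`, `end`.
#' @inheritParams read_domain_table
#' @return A categorised domain-annotation tibble.
#' @export
as_domain_table <- function(df, domain_sets) {
  df <- as_tibble(df)
  dup <- duplicated(df[c("protein_id", "accession", "start", "end")])
  if (any(dup)) {
    abort(sprintf("Duplicate domain annotation row(s): %s",
                  paste(which(dup), collapse = ", ")))
  }
  bad_coord <- which(df$start > df$end | df$start < 1 | df$end > df$length)
  if (length(bad_coord) > 0) {
    abort(sprintf("Domain coordinates outside [1, length] at row(s): %s",
                  paste(bad_coord, collapse = ", ")))
  }
  len_chk <- df |>
    group_by(.data$protein_id) |>
    summarise(nlen = n_distinct(.data$length),
              ntax = n_distinct(.data$taxon_id), .groups = "drop")
  if (any(len_chk$nlen > 1) || any(len_chk$ntax > 1)) {
    abort(sprintf(
      "Inconsistent length/taxon for protein(s): %s",
      paste(len_chk$protein_id[len_chk$nlen > 1 | len_chk$ntax > 1],
            collapse = ", ")))
  }
  df |>
    left_join(select(domain_sets, "accession", "category"), by = "accession") |>
    mutate(category = dplyr::coalesce(.data$category, "other"))
}

#' Read a taxonomy lineage table
#'
#' @param path Long-format TSV with columns `taxon_id`, `rank`, `clade_name`;
#'   one row per (taxon, rank).
#' @return A tibble of lineages. Within a taxon each rank may appear at most
#'   once.
#' @export
read_taxonomy <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(df, c("taxon_id", "rank", "clade_name"), "taxonomy table")
  dup <- df |> count(.data$taxon_id, .data$rank) |> filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("Rank repeated within lineage for taxon(s): %s",
                  paste(unique(dup$taxon_id), collapse = ", ")))
  }
  as_tibble(df)
}
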