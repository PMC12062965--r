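#' Read gene models and their PFAM domain content
#'
#' Genes come from a GFF3 annotation (1-based inclusive, converted once at
#' this boundary to the package's internal 0-based half-open convention);
#' PFAM content from a two-column map. Genes absent from the map carry no
#' domains and therefore contribute to no family.
#'
#' @param gff_path GFF3 file containing `gene` features with an `ID`
#'   attribute.
#' @param pfam_map_path TSV with columns `gene_id`, `pfam_id`.
#' @return A tibble with one row per gene: `gene_id`, `scaffold`, `start`,
#'   `end` (0-based half-open), `strand`, and list-column `pfam_domains`
#'   (character vector, possibly empty). PFAM rows whose `gene_id` is not in
#'   the GFF are skipped with a warning and returned in the
#'   `skipped_pfam_rows` attribute.
#' @export
read_gene_models <- function(gff_path, pfam_map_path = NULL) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  genes <- tibble(
    gene_id = as.character(gr$ID),
    scaffold = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,   # to 0-based half-open
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)))
  if (anyNA(genes$gene_id)) abort("GFF gene feature without an ID attribute.")

  pfam <- if (is.null(pfam_map_path)) {
    tibble(gene_id = character(), pfam_id = character())
  } else {
    readr::read_tsv(pfam_map_path, show_col_types = FALSE, progress = FALSE)
  }
  stopifnot_cols(pfam, c("gene_id", "pfam_id"), "PFAM map")
  skipped <- anti_join(pfam, genes, by = "gene_id")
  if (nrow(skipped) > 0) {
    warn(sprintf("%d PFAM map row(s) reference genes absent from the GFF; skipped.",
                 nrow(skipped)))
  }
  pfam_by_gene <- pfam |>
    dplyr::semi_join(genes, by = "gene_id") |>
    distinct(.data$gene_id, .data$pfam_id) |>
    tidyr::nest(.by = "gene_id", .key = "pf")
  out <- genes |>
    left_join(pfam_by_gene, by = "gene_id") |>
    mutate(pfam_domains = purrr::map(.data$pf, ~ if (is.null(.x)) character() else .x$pfam_id)) |>
    select(-"pf")
  attr(out, "skipped_pfam_rows") <- skipped
  out
}

#' Read TE annotations, keeping classified copies only
#'
#' TE copies come from an EDTA-style annotation in GFF3 (classification in a
#' `classification=` attribute, falling back to the feature type) or BED
#' (classification in the name column). Copies with an empty, missing or
#' `"Unknown"` classification are unclassified and removed, mirroring the
#' filtering applied before enrichment testing; the number removed is
#' recorded in the `n_removed` attribute.
#'
#' @param path Annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @return A tibble of classified TE copies: `scaffold`, `start`, `end`
#'   (0-based half-open), `strand`, `classification`.
#' @export
read_te_annotations <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = format)
  cls <- if (format == "bed") {
    as.character(gr$name %||% rep(NA_character_, length(gr)))
  } else {
    cl <- gr$classification %||% rep(NA_character_, length(gr))
    ifelse(is.na(cl) | cl == "", as.character(gr$type), as.character(cl))
  }
  tes <- tibble(
    scaffold = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    classification = cls)
  keep <- !is.na(tes$classification) & tes$classification != "" &
    tes$classification != "Unknown"
  out <- tes[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Read scaffold lengths
#'
#' Accepts either a two-column TSV (`scaffold`, `length`, with header) or a
#' samtools faidx index (`.fai`: name, length, ... without header).
#'
#' @param path Path to the table.
#' @return Tibble with columns `scaffold`, `length`.
#' @export
read_scaffold_lengths <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("scaffold", first, fixed = TRUE)
  df <- readr::read_tsv(path, col_names = has_header,
                        show_col_types = FALSE, progress = FALSE)
  if (!has_header) {
    df <- df[, 1:2]
    names(df) <- c("scaffold", "length")
  }
  stopifnot_cols(df, c("scaffold", "length"), "scaffold length table")
  df |>
    mutate(scaffold = as.character(.data$scaffold),
           length = as.integer(.data$length)) |>
    select("scaffold", "length")
}
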