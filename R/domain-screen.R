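#' Screen proteins for co-occurrence of multicopy and TE/viral domains
#'
#' The core of the domain-capture screen: a protein is a co-occurrence hit if
#' it carries at least one domain from the curated multicopy set and at least
#' one from the TE/viral set. Such architectures are the molecular signature
#' of a TE- or virus-derived coding segment captured by a host gene family.
#'
#' @param domains Categorised domain-annotation tibble
#'   (see [read_domain_table()]).
#' @return A tibble with one row per hit protein: `protein_id`, `taxon_id`,
#'   `length`, `n_multicopy`, `n_te`, `n_te_distinct` (distinct TE/viral
#'   accessions), and list-columns `multicopy_hits` / `te_hits` holding the
#'   qualifying annotations.
#' @export
screen_cooccurrence <- function(domains) {
  empty <- tibble(
    protein_id = character(), taxon_id = character(), length = integer(),
    n_multicopy = integer(), n_te = integer(), n_te_distinct = integer(),
    multicopy_hits = list(), te_hits = list())
  if (nrow(domains) == 0) return(empty)

  cat_rows <- domains[domains$category %in% c("multicopy", "te_viral"), ]
  keep <- intersect(
    unique(cat_rows$protein_id[cat_rows$category == "multicopy"]),
    unique(cat_rows$protein_id[cat_rows$category == "te_viral"]))
  if (length(keep) == 0) return(empty)

  cat_rows[cat_rows$protein_id %in% keep, ] |>
    tidyr::nest(.by = c("protein_id", "taxon_id", "length"),
                .key = "hits") |>
    mutate(
      multicopy_hits = purrr::map(.data$hits,
        function(h) h[h$category == "multicopy", , drop = FALSE]),
      te_hits = purrr::map(.data$hits,
        function(h) h[h$category == "te_viral", , drop = FALSE]),
      n_multicopy = purrr::map_int(.data$multicopy_hits, nrow),
      n_te = purrr::map_int(.data$te_hits, nrow),
      n_te_distinct = purrr::map_int(.data$te_hits,
        function(h) length(unique(h$accession)))) |>
    select("protein_id", "taxon_id", "length", "n_multicopy", "n_te",
           "n_te_distinct", "multicopy_hits", "te_hits") |>
    arrange(.data$protein_id)
}

#' Partition co-occurrence hits by number of distinct TE/viral domains
#'
#' Splits screen hits into proteins fused to a single TE/viral domain versus
#' proteins carrying several distinct TE/viral domains, the latter suggesting
#' more complex fusions (e.g. several domains of one element captured
#' together).
#'
#' @param cooc Tibble from [screen_cooccurrence()].
#' @return The input with an added factor column `te_architecture`
#'   (`"single"` / `"multiple"`), partitioning on the count of distinct
#'   TE/viral accessions (1 vs >= 2).
#' @export
partition_by_te_count <- function(cooc) {
  cooc |>
    mutate(te_architecture = factor(
      if_else(.data$n_te_distinct >= 2L, "multiple", "single"),
      levels = c("single", "multiple")))
}

#' Group co-occurrence hits by (multicopy, TE/viral) domain pair
#'
#' A protein carrying several multicopy and/or TE/viral domains contributes to
#' every (multicopy accession, TE accession) pair it hosts, so groups count
#' shared architectures rather than proteins. Clade membership is tallied at
#' every rank present in the taxonomy; taxa absent from the taxonomy are kept
#' under the clade `"unclassified"` so totals are conserved.
#'
#' @param cooc Tibble from [screen_cooccurrence()].
#' @param taxonomy Lineage tibble from [read_taxonomy()], or `NULL` to skip
#'   clade counting.
#' @return A tibble with one row per observed pair: `multicopy_accession`,
#'   `te_accession`, `n_members`, list-column `members` (protein ids) and
#'   list-column `clade_counts` (tibble `rank`, `clade_name`, `n` per group),
#'   sorted by `n_members` descending.
#' @export
group_by_domain_pair <- function(cooc, taxonomy = NULL) {
  if (nrow(cooc) == 0) {
    return(tibble(multicopy_accession = character(), te_accession = character(),
                  n_members = integer(), members = list(), clade_counts = list()))
  }
  pairs <- cooc |>
    mutate(
      mc_acc = purrr::map(.data$multicopy_hits, ~ unique(.x$accession)),
      te_acc = purrr::map(.data$te_hits, ~ unique(.x$accession))) |>
    select("protein_id", "taxon_id", "mc_acc", "te_acc") |>
    tidyr::unnest_longer("mc_acc") |>
    tidyr::unnest_longer("te_acc") |>
    rename(multicopy_accession = "mc_acc", te_accession = "te_acc")

  ranks <- if (is.null(taxonomy)) character() else unique(taxonomy$rank)
  clade_of <- function(members_tax) {
    if (length(ranks) == 0) {
      return(tibble(rank = character(), clade_name = character(), n = integer()))
    }
    tidyr::expand_grid(taxon_id = members_tax, rank = ranks) |>
      left_join(taxonomy, by = c("taxon_id", "rank")) |>
      mutate(clade_name = dplyr::coalesce(.data$clade_name, "unclassified")) |>
      count(.data$rank, .data$clade_name, name = "n")
  }

  pairs |>
    tidyr::nest(.by = c("multicopy_accession", "te_accession"), .key = "prot") |>
    mutate(
      members = purrr::map(.data$prot, ~ sort(unique(.x$protein_id))),
      n_members = purrr::map_int(.data$members, length),
      clade_counts = purrr::map(.data$prot, ~ clade_of(.x$taxon_id))) |>
    select(-"prot") |>
    arrange(desc(.data$n_members), .data$multicopy_accession, .data$te_accession)
}

#' Fraction of a co-occurrence group falling in one clade
#'
#' Reports, for each domain-pair group, how many member proteins belong to a
#' given clade at a given rank — e.g. 808/828 (97.6%) of BTB/POZ-integrase
#' fusions in the phylum Chordata.
#'
#' @param groups Tibble from [group_by_domain_pair()].
#' @param rank Taxonomic rank to interrogate (e.g. `"phylum"`).
#' @param clade Clade name at that rank.
#' @return A tibble per group: pair accessions, `count`, `total`
#'   (= group size) and `percent` (half-up, one decimal).
#' @export
clade_fraction <- function(groups, rank, clade) {
  groups |>
    mutate(
      count = purrr::map_int(.data$clade_counts, function(cc) {
        hit <- cc$n[cc$rank == rank & cc$clade_name == clade]
        if (length(hit) == 0) 0L else as.integer(hit[1])
      }),
      total = .data$n_members,
      percent = percent_of(.data$count, .data$total)) |>
    select("multicopy_accession", "te_accession", "count", "total", "percent")
}

#' Ranked taxonomic spread of a co-occurrence group
#'
#' @param groups Tibble from [group_by_domain_pair()].
#' @param rank Rank at which to summarise.
#' @param top_n Maximum number of clades per group (>= 1); ties in count are
#'   broken lexicographically by clade name.
#' @return Long tibble: pair accessions, `clade_name`, `n`, `rank_order`.
#' @export
summarize_taxonomic_spread <- function(groups, rank, top_n = 10L) {
  if (top_n < 1) abort("`top_n` must be >= 1.")
  groups |>
    mutate(spread = purrr::map(.data$clade_counts, function(cc) {
      cc |>
        filter(.data$rank == !!rank) |>
        arrange(desc(.data$n), .data$clade_name) |>
        slice_head(n = top_n) |>
        mutate(rank_order = row_number()) |>
        select("clade_name", "n", "rank_order")
    })) |>
    select("multicopy_accession", "te_accession", "spread") |>
    tidyr::unnest("spread")
}

#' Positional bias of TE/viral domains within host proteins
#'
#' Tests whether captured TE/viral domains sit N-terminally of their multicopy
#' partner domains. For each hit protein the leftmost TE/viral and leftmost
#' multicopy annotations are reduced to relative midpoints
#' ((start + end) / 2 / length); a protein is an N-terminal case if the TE
#' midpoint is strictly left of the multicopy midpoint. Exact midpoint ties
#' are excluded, and the sign test is an exact two-sided binomial against 0.5.
#'
#' @param cooc Tibble from [screen_cooccurrence()].
#' @return An object of class `positional_bias` with the per-protein relative
#'   positions, the N-terminal fraction among non-tied proteins, and the
#'   binomial p-value. Use [tidy()] for per-protein positions and [glance()]
#'   for the one-row summary.
#' @export
positional_bias <- function(cooc) {
  if (nrow(cooc) == 0) abort("No usable proteins for positional bias.")
  leftmost_mid <- function(hits) {
    h <- hits[order(hits$start, hits$end), , drop = FALSE]
    (h$start[1] + h$end[1]) / 2
  }
  pos <- cooc |>
    mutate(
      te_midpoint_rel = purrr::map_dbl(.data$te_hits, leftmost_mid) / .data$length,
      multicopy_midpoint_rel =
        purrr::map_dbl(.data$multicopy_hits, leftmost_mid) / .data$length,
      te_nterminal = dplyr::case_when(
        .data$te_midpoint_rel < .data$multicopy_midpoint_rel ~ TRUE,
        .data$te_midpoint_rel > .data$multicopy_midpoint_rel ~ FALSE,
        TRUE ~ NA)) |>
    select("protein_id", "te_midpoint_rel", "multicopy_midpoint_rel",
           "te_nterminal")
  usable <- !is.na(pos$te_nterminal)
  n_used <- sum(usable)
  if (n_used == 0) abort("No usable proteins (all midpoint ties).")
  k <- sum(pos$te_nterminal[usable])
  structure(list(
    positions = pos,
    n_proteins = nrow(pos),
    n_used = n_used,
    n_ties = nrow(pos) - n_used,
    fraction_te_nterminal = k / n_used,
    binomial_p = binom.test(k, n_used, p = 0.5,
                            alternative = "two.sided")$p.value
  ), class = "positional_bias")
}

#' @export
print.positional_bias <- function(x, ...) {
  cat(sprintf(
    "Positional bias: %d proteins (%d ties excluded)\n  TE/viral domain N-terminal in %.1f%% (exact binomial p = %.3g)\n",
    x$n_proteins, x$n_ties, 100 * x$fraction_te_nterminal, x$binomial_p))
  invisible(x)
}

#' @rdname positional_bias
#' @param x A `positional_bias` object.
#' @param ... Unused.
#' @method tidy positional_bias
#' @export
tidy.positional_bias <- function(x, ...) x$positions

#' @rdname positional_bias
#' @method glance positional_bias
#' @export
glance.positional_bias <- function(x, ...) {
  tibble(n_proteins = x$n_proteins, n_used = x$n_used, n_ties = x$n_ties,
         fraction_te_nterminal = x$fraction_te_nterminal,
         binomial_p = x$binomial_p)
}

#' Association between multicopy family size and TE-domain diversity
#'
#' Large host domain families offer more opportunities for capture, so family
#' size (number of proteins carrying a multicopy domain anywhere in the table)
#' should correlate with the number of distinct TE/viral domains found fused
#' to it. Quantified by Spearman's rank correlation, which is robust to the
#' heavy-tailed family-size distribution.
#'
#' @param domains Full categorised domain table (for family sizes).
#' @param groups Tibble from [group_by_domain_pair()] (for partner counts).
#' @return One-row tibble: `n_families`, `rho`, `p_value`, `undefined`
#'   (TRUE when a variable is constant and the correlation does not exist),
#'   plus a `by_family` list-column with the underlying per-family table.
#' @export
family_size_association <- function(domains, groups) {
  fam <- groups |>
    group_by(multicopy_accession = .data$multicopy_accession) |>
    summarise(n_te_partners = n_distinct(.data$te_accession), .groups = "drop")
  sizes <- domains |>
    filter(.data$category == "multicopy") |>
    group_by(accession = .data$accession) |>
    summarise(family_size = n_distinct(.data$protein_id), .groups = "drop")
  tab <- inner_join(fam, sizes,
                    by = c(multicopy_accession = "accession"))
  if (nrow(tab) < 3) abort("Need at least 3 multicopy families.")
  if (n_distinct(tab$family_size) == 1 || n_distinct(tab$n_te_partners) == 1) {
    return(tibble(n_families = nrow(tab), rho = NA_real_, p_value = NA_real_,
                  undefined = TRUE, by_family = list(tab)))
  }
  ct <- suppressWarnings(
    stats::cor.test(tab$family_size, tab$n_te_partners,
                    method = "spearman", exact = FALSE))
  tibble(n_families = nrow(tab), rho = unname(ct$estimate),
         p_value = ct$p.value, undefined = FALSE, by_family = list(tab))
}

#' Percentage of a focal class in a count table
#'
#' Reporting helper for count summaries of the form "12/30 A2 genes (40.0%)":
#' each class supplies its own numerator and denominator.
#'
#' @param counts Named numeric vector of per-class numerators.
#' @param totals Named numeric vector of per-class denominators.
#' @param focal Class to report.
#' @return The percentage (half-up, one decimal). Zero denominator errors.
#' @seealso [summarize_counts()] for the row-wise table version.
#' @export
class_fraction <- function(counts, totals, focal) {
  if (!focal %in% names(counts) || !focal %in% names(totals)) {
    abort(sprintf("Class '%s' absent from counts/totals.", focal))
  }
  if (totals[[focal]] == 0) abort("Zero denominator.")
  percent_of(counts[[focal]], totals[[focal]])
}
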