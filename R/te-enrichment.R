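#' Count classified TE copies near each gene
#'
#' For each gene, the window is the gene body extended by `flank` bp on both
#' sides (clipped at scaffold bounds) and the count is the number of TE
#' copies overlapping the window by at least 1 bp, capped at `cap` — i.e. "up
#' to `cap` TE copies closest to the gene", since every overlapping copy is at
#' distance 0. A TE copy overlapping the windows of several genes counts for
#' each of them.
#'
#' @param genes Gene tibble from [read_gene_models()] (0-based half-open).
#' @param tes Classified TE tibble from [read_te_annotations()].
#' @param scaffold_lengths Tibble from [read_scaffold_lengths()].
#' @param flank Window extension in bp on each side (default 500).
#' @param cap Maximum count per gene (default 10).
#' @return Tibble `gene_id`, `n_te`.
#' @export
count_te_near_gene <- function(genes, tes, scaffold_lengths,
                               flank = 500L, cap = 10L) {
  len <- scaffold_lengths$length[match(genes$scaffold, scaffold_lengths$scaffold)]
  if (anyNA(len)) {
    abort(sprintf("Gene scaffold(s) missing from scaffold_lengths: %s",
                  paste(unique(genes$scaffold[is.na(len)]), collapse = ", ")))
  }
  win_start <- pmax(0L, genes$start - flank)
  win_end <- pmin(len, genes$end + flank)
  # internal 0-based half-open -> IRanges 1-based inclusive
  win <- GenomicRanges::GRanges(genes$scaffold,
                                IRanges::IRanges(win_start + 1L, win_end))
  te_gr <- GenomicRanges::GRanges(tes$scaffold,
                                  IRanges::IRanges(tes$start + 1L, tes$end))
  n <- GenomicRanges::countOverlaps(win, te_gr, minoverlap = 1L,
                                    ignore.strand = TRUE)
  tibble(gene_id = genes$gene_id, n_te = pmin(as.integer(cap), as.integer(n)))
}

#' Sum per-gene TE counts by PFAM family
#'
#' Each PFAM family's observed statistic is the sum of capped per-gene TE
#' counts over the genes carrying that PFAM; a gene with several PFAM domains
#' contributes its count to each of them.
#'
#' @param per_gene Tibble `gene_id`, `n_te` from [count_te_near_gene()].
#' @param genes Gene tibble with `pfam_domains` list-column.
#' @return Tibble `pfam_id`, `observed`, covering every PFAM present on any
#'   gene (including zero totals).
#' @export
aggregate_by_pfam <- function(per_gene, genes) {
  long <- genes |>
    select("gene_id", "pfam_domains") |>
    tidyr::unnest_longer("pfam_domains", values_to = "pfam_id") |>
    filter(!is.na(.data$pfam_id))
  long |>
    left_join(per_gene, by = "gene_id") |>
    group_by(pfam_id = .data$pfam_id) |>
    summarise(observed = sum(.data$n_te), .groups = "drop") |>
    arrange(.data$pfam_id)
}

#' Shuffle TE positions across scaffolds
#'
#' Builds one replicate of the bootstrap null: every TE copy keeps its length
#' and classification but is independently re-placed, choosing a scaffold
#' with probability proportional to the number of legal start positions
#' (scaffold length - TE length + 1) and a start uniformly among them.
#' Shuffled copies may overlap each other and genes; no exclusion zones are
#' applied.
#'
#' @param tes Classified TE tibble.
#' @param scaffold_lengths Tibble `scaffold`, `length`.
#' @param replicate_seed Integer seed; identical seeds give identical
#'   placements.
#' @return A TE tibble of the same shape with new `scaffold`, `start`, `end`.
#' @export
shuffle_te_positions <- function(tes, scaffold_lengths, replicate_seed) {
  lens <- tes$end - tes$start
  too_long <- lens > max(scaffold_lengths$length)
  if (any(too_long)) {
    abort(sprintf("TE copy longer than every scaffold (first at row %d, length %d).",
                  which(too_long)[1], lens[which(too_long)[1]]))
  }
  out <- tes
  n <- length(lens)
  # legal-placement weight of scaffold s for copy i: length_s - len_i + 1
  W <- pmax(outer(rep(1, n), scaffold_lengths$length) - lens + 1, 0)
  cumW <- W %*% upper.tri(diag(ncol(W)), diag = TRUE)
  with_seed(replicate_seed, {
    u <- runif(n) * cumW[, ncol(cumW)]
    sc <- 1L + as.integer(rowSums(cumW < u))
    # uniform integer start in [0, scaffold_length - len]
    start <- floor(runif(n) * W[cbind(seq_len(n), sc)])
    out$scaffold <- scaffold_lengths$scaffold[sc]
    out$start <- as.integer(start)
    out$end <- as.integer(start + lens)
  })
  out
}

#' ECDF empirical p-values with add-one correction
#'
#' Tail probabilities of the observed statistic under the bootstrap null,
#' from the empirical cumulative distribution of the replicate values. The
#' add-one (pseudo-count) form counts the observation itself as one
#' replicate, so no p-value can be zero at finite replicate number: the
#' smallest attainable value is 1/(B + 1).
#'
#' @param observed Observed statistic (scalar).
#' @param null_values Numeric vector of B >= 1 replicate statistics.
#' @return One-row tibble `p_enrich`, `p_deplete` where
#'   `p_enrich = (1 + #\{null >= observed\}) / (1 + B)` and `p_deplete`
#'   symmetric on the lower tail.
#' @export
empirical_p <- function(observed, null_values) {
  B <- length(null_values)
  if (B < 1) abort("Empty null distribution.")
  tibble(
    p_enrich = (1 + sum(null_values >= observed)) / (1 + B),
    p_deplete = (1 + sum(null_values <= observed)) / (1 + B))
}

#' Multiple-testing correction for empirical p-values
#'
#' @param ps Numeric vector of p-values in (0, 1].
#' @param method `"BH"` (Benjamini-Hochberg step-up, default) or
#'   `"bonferroni"`.
#' @return Adjusted p-values, monotone non-decreasing in `ps`, in (0, 1].
#' @export
correct_pvalues <- function(ps, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(ps <= 0 | ps > 1 | is.na(ps))) abort("p-values must lie in (0, 1].")
  p.adjust(ps, method = method)
}

#' TE-proximity enrichment test for PFAM gene families
#'
#' The full bootstrap procedure: observed per-family TE counts (capped window
#' counts summed per PFAM), `replicates` shuffled-null re-computations, ECDF
#' empirical p-values on both tails, Benjamini-Hochberg (or Bonferroni)
#' correction of the enrichment p across families, and a signed
#' `-log10(q)` score (positive where the family sits above its null mean).
#' With `stratify_class = TRUE` the whole procedure is re-run per TE
#' classification prefix (text before the first `/`, e.g. `DNA`, `LTR`,
#' `RC`, `LINE`).
#'
#' @inheritParams count_te_near_gene
#' @param replicates Number of bootstrap replicates B (default 1000).
#' @param seed Master seed; replicate b uses seed XOR b so each replicate is
#'   individually reproducible.
#' @param correction Multiple-testing method, see [correct_pvalues()].
#' @param stratify_class Also test each TE class prefix separately.
#' @return Tibble with one row per (PFAM, stratum): `pfam_id`, `stratum`
#'   (`"all"` or a class prefix), `observed`, `null_mean`, `null_sd`,
#'   `p_enrich`, `p_deplete`, `q`, `score`.
#' @export
run_te_enrichment <- function(genes, tes, scaffold_lengths,
                              flank = 500L, cap = 10L, replicates = 1000L,
                              seed = 1L, correction = c("BH", "bonferroni"),
                              stratify_class = FALSE) {
  correction <- match.arg(correction)
  if (!any(lengths(genes$pfam_domains) > 0)) {
    abort("No PFAM-bearing genes; nothing to test.")
  }
  # fixed per-run structures: gene windows and the gene -> PFAM expansion
  len <- scaffold_lengths$length[match(genes$scaffold, scaffold_lengths$scaffold)]
  if (anyNA(len)) abort("Gene scaffold(s) missing from scaffold_lengths.")
  win <- GenomicRanges::GRanges(
    genes$scaffold,
    IRanges::IRanges(pmax(0L, genes$start - flank) + 1L,
                     pmin(len, genes$end + flank)))
  pfam_long <- genes |>
    select("gene_id", "pfam_domains") |>
    tidyr::unnest_longer("pfam_domains", values_to = "pfam_id") |>
    filter(!is.na(.data$pfam_id))
  gene_idx <- match(pfam_long$gene_id, genes$gene_id)
  pfam_ids <- sort(unique(pfam_long$pfam_id), method = "radix")
  by_pfam <- function(te_tbl) {
    n <- GenomicRanges::countOverlaps(
      win, GenomicRanges::GRanges(te_tbl$scaffold,
                                  IRanges::IRanges(te_tbl$start + 1L, te_tbl$end)),
      minoverlap = 1L, ignore.strand = TRUE)
    capped <- pmin(as.integer(cap), as.integer(n))
    as.vector(rowsum(capped[gene_idx], pfam_long$pfam_id)[pfam_ids, ])
  }
  one_stratum <- function(te_sub, stratum) {
    obs <- tibble(pfam_id = pfam_ids, observed = by_pfam(te_sub))
    null_mat <- vapply(seq_len(replicates), function(b) {
      by_pfam(shuffle_te_positions(te_sub, scaffold_lengths,
                                   replicate_seed(seed, b)))
    }, numeric(nrow(obs)))
    null_mat <- matrix(null_mat, nrow = nrow(obs))
    ps <- purrr::map(seq_len(nrow(obs)),
                     ~ empirical_p(obs$observed[.x], null_mat[.x, ])) |>
      bind_rows()
    obs |>
      mutate(
        stratum = stratum,
        null_mean = rowMeans(null_mat),
        null_sd = apply(null_mat, 1, sd),
        p_enrich = ps$p_enrich,
        p_deplete = ps$p_deplete,
        q = correct_pvalues(ps$p_enrich, correction),
        score = if_else(.data$observed >= .data$null_mean, 1, -1) *
          -log10(.data$q)) |>
      select("pfam_id", "stratum", "observed", "null_mean", "null_sd",
             "p_enrich", "p_deplete", "q", "score")
  }
  res <- one_stratum(tes, "all")
  if (stratify_class) {
    prefixes <- sort(unique(sub("/.*$", "", tes$classification)))
    strata <- purrr::map(prefixes, function(px) {
      one_stratum(tes[sub("/.*$", "", tes$classification) == px, ], px)
    })
    res <- bind_rows(res, strata)
  }
  res
}
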