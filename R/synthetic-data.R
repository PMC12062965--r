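# Seeded generators emulating the statistical structure of each pipeline
# input: InterPro-style domain tables with planted co-occurring pairs,
# genomes with background-uniform TEs plus enrichment planted near chosen
# gene families, benchmark score sets from truncated-normal models, and toy
# two-chain complexes with controlled contact geometry. Each generator is a
# pure function of its arguments (seed included) and returns a truth record
# sufficient to score recovery.

#' Simulate a protein domain-annotation table with planted co-occurrences
#'
#' Background proteins carry uncategorised decoy domains and, at most, one
#' domain from a single curated category — never both, so every co-occurrence
#' hit is a planted carrier. Each planted pair places its TE/viral domain at
#' a controlled relative position: `nterm` draws the relative midpoint from
#' U(0.05, 0.30) with the multicopy partner C-terminal, `cterm` mirrors
#' this, and `uniform` draws both independently.
#'
#' @param n_proteins Total number of proteins (background + carriers).
#' @param planted_pairs Tibble with columns `multicopy_accession`,
#'   `te_accession`, `n_carriers`, `te_position_mode` (one of `nterm`,
#'   `cterm`, `uniform`). May have zero rows.
#' @param n_taxa Number of distinct taxa, assigned cyclically and mapped to
#'   clades in the returned taxonomy.
#' @param seed Integer seed.
#' @return List: `domains` (categorised annotation tibble), `sets` (domain
#'   set tibble), `taxonomy` (lineage tibble at rank `"phylum"`), `truth`
#'   (tibble of planted carriers).
#' @export
sim_domain_table <- function(n_proteins, planted_pairs = NULL, n_taxa = 5L,
                             seed = 1L) {
  if (is.null(planted_pairs)) {
    planted_pairs <- tibble(multicopy_accession = character(),
                            te_accession = character(),
                            n_carriers = integer(),
                            te_position_mode = character())
  }
  n_planted <- sum(planted_pairs$n_carriers)
  if (n_planted > n_proteins) {
    abort("Planted carriers exceed n_proteins.")
  }
  decoy_mc <- sprintf("IPRM%04d", 1:8)
  decoy_te <- sprintf("IPRT%04d", 1:8)
  decoy_other <- sprintf("IPRX%04d", 1:20)
  sets <- bind_rows(
    tibble(accession = unique(c(planted_pairs$multicopy_accession, decoy_mc)),
           category = "multicopy"),
    tibble(accession = unique(c(planted_pairs$te_accession, decoy_te)),
           category = "te_viral")) |>
    mutate(description = paste("synthetic", .data$category, "domain"))
  taxa <- sprintf("taxon%02d", seq_len(n_taxa))
  taxonomy <- tibble(taxon_id = taxa, rank = "phylum",
                     clade_name = sprintf("Clade%02d", ((seq_len(n_taxa) - 1) %% 3) + 1))

  with_seed(seed, {
    prot <- tibble(
      protein_id = sprintf("P%06d", seq_len(n_proteins)),
      taxon_id = taxa[((seq_len(n_proteins) - 1L) %% n_taxa) + 1L],
      length = sample(200:1200, n_proteins, replace = TRUE))
    carrier_idx <- if (n_planted > 0) seq_len(n_planted) else integer()
    rows <- list()
    # background decoy domains on every protein
    for (i in seq_len(n_proteins)) {
      L <- prot$length[i]
      k <- sample(1:2, 1)
      st <- sample.int(max(1L, L - 60L), k, replace = TRUE)
      rows[[length(rows) + 1L]] <- tibble(
        protein_id = prot$protein_id[i], accession = sample(decoy_other, k),
        start = st, end = pmin(L, st + 49L))
      if (!(i %in% carrier_idx)) {
        # at most one categorised domain, never both categories
        u <- runif(1)
        acc <- if (u < 0.3) sample(decoy_mc, 1) else if (u < 0.45) sample(decoy_te, 1) else NA
        if (!is.na(acc)) {
          s <- sample.int(max(1L, L - 60L), 1)
          rows[[length(rows) + 1L]] <- tibble(
            protein_id = prot$protein_id[i], accession = acc,
            start = s, end = min(L, s + 49L))
        }
      }
    }
    # planted carriers
    truth <- list()
    at <- 1L
    place <- function(L, mid_rel, width = 60L) {
      mid <- mid_rel * L
      s <- max(1L, as.integer(round(mid - width / 2)))
      e <- min(L, s + width - 1L)
      c(s, e)
    }
    for (j in seq_len(nrow(planted_pairs))) {
      pp <- planted_pairs[j, ]
      for (k in seq_len(pp$n_carriers)) {
        i <- at; at <- at + 1L
        L <- prot$length[i]
        te_mid <- switch(pp$te_position_mode,
                         nterm = runif(1, 0.05, 0.30),
                         cterm = runif(1, 0.70, 0.95),
                         uniform = runif(1, 0.05, 0.95),
                         abort("Unknown te_position_mode."))
        mc_mid <- switch(pp$te_position_mode,
                         nterm = runif(1, 0.70, 0.95),
                         cterm = runif(1, 0.05, 0.30),
                         uniform = runif(1, 0.05, 0.95))
        te_se <- place(L, te_mid); mc_se <- place(L, mc_mid)
        rows[[length(rows) + 1L]] <- tibble(
          protein_id = prot$protein_id[i],
          accession = c(pp$te_accession, pp$multicopy_accession),
          start = c(te_se[1], mc_se[1]), end = c(te_se[2], mc_se[2]))
        truth[[length(truth) + 1L]] <- tibble(
          protein_id = prot$protein_id[i],
          multicopy_accession = pp$multicopy_accession,
          te_accession = pp$te_accession,
          te_position_mode = pp$te_position_mode)
      }
    }
    domains <- bind_rows(rows) |>
      left_join(prot, by = "protein_id") |>
      select("protein_id", "taxon_id", "length", "accession", "start", "end") |>
      distinct(.data$protein_id, .data$accession, .data$start, .data$end,
               .keep_all = TRUE)
    list(domains = as_domain_table(domains, sets),
         sets = sets, taxonomy = taxonomy,
         truth = if (length(truth) > 0) bind_rows(truth) else
           tibble(protein_id = character(), multicopy_accession = character(),
                  te_accession = character(), te_position_mode = character()))
  })
}

#' Simulate a genome with background TEs and planted enrichment
#'
#' Genes are placed without overlap, uniformly across scaffolds; background
#' TE copies follow the same placement model as the bootstrap null
#' (scaffold chosen length-proportionally, start uniform). Each gene carries
#' one PFAM family; the focal family gets `n_focal_genes` genes and, when
#' `lambda > 0`, Poisson(lambda) additional TE copies planted inside each
#' focal gene's +/- `flank` window.
#'
#' @param n_genes,n_tes Numbers of genes and background TE copies.
#' @param n_pfams Number of PFAM families (genes are split across them).
#' @param focal_pfam Name of the focal family (default `"PF_focal"`).
#' @param n_focal_genes Genes assigned to the focal family.
#' @param lambda Mean planted TE copies per focal-gene window (0 = null).
#' @param n_scaffolds,scaffold_length Genome shape.
#' @param gene_length Fixed gene length in bp.
#' @param te_length_range Background TE length range in bp.
#' @param flank Window half-width used for planting (match the test's).
#' @param seed Integer seed.
#' @return List: `genes` (tibble with `pfam_domains` list-column), `tes`,
#'   `scaffold_lengths`, `truth` (list with `focal_pfam`, `lambda`,
#'   `n_planted`).
#' @export
sim_genome_with_tes <- function(n_genes = 100L, n_tes = 500L, n_pfams = 20L,
                                focal_pfam = "PF_focal", n_focal_genes = 5L,
                                lambda = 0, n_scaffolds = 3L,
                                scaffold_length = 1e6L, gene_length = 1000L,
                                te_length_range = c(100L, 500L),
                                flank = 500L, seed = 1L) {
  if (n_focal_genes > n_genes) abort("n_focal_genes exceeds n_genes.")
  scaffold_lengths <- tibble(
    scaffold = sprintf("scaf%02d", seq_len(n_scaffolds)),
    length = as.integer(rep(scaffold_length, n_scaffolds)))
  with_seed(seed, {
    # non-overlapping uniform gene placement, rejection sampling
    placed <- tibble(scaffold = character(), start = integer(), end = integer())
    for (i in seq_len(n_genes)) {
      ok <- FALSE
      for (attempt in 1:1000) {
        sc <- sample(scaffold_lengths$scaffold, 1,
                     prob = scaffold_lengths$length)
        L <- scaffold_lengths$length[scaffold_lengths$scaffold == sc]
        s <- sample.int(L - gene_length + 1L, 1) - 1L
        e <- s + gene_length
        hit <- placed$scaffold == sc & placed$start < e & placed$end > s
        if (!any(hit)) {
          placed <- bind_rows(placed, tibble(scaffold = sc, start = s, end = e))
          ok <- TRUE
          break
        }
      }
      if (!ok) abort("Infeasible gene packing after 1000 attempts.")
    }
    other_pfams <- sprintf("PF%05d", seq_len(n_pfams - 1L))
    pfam_assign <- c(rep(focal_pfam, n_focal_genes),
                     rep(other_pfams, length.out = n_genes - n_focal_genes))
    genes <- placed |>
      mutate(gene_id = sprintf("gene%05d", seq_len(n_genes)),
             strand = "+",
             pfam_domains = as.list(sample(pfam_assign))) |>
      select("gene_id", "scaffold", "start", "end", "strand", "pfam_domains")

    # background TEs via the null placement model
    te_len <- sample(te_length_range[1]:te_length_range[2], n_tes,
                     replace = TRUE)
    cls_pool <- c("DNA/TcMar", "DNA/hAT", "LTR/Gypsy", "RC/Helitron", "LINE/L1")
    proto <- tibble(scaffold = scaffold_lengths$scaffold[1], start = 0L,
                    end = te_len, strand = ".",
                    classification = sample(cls_pool, n_tes, replace = TRUE))
    tes <- shuffle_te_positions(proto, scaffold_lengths,
                                replicate_seed(seed, 999983L))

    # planted enrichment inside focal windows
    n_planted <- 0L
    if (lambda > 0) {
      focal_genes <- genes |>
        filter(purrr::map_lgl(.data$pfam_domains, ~ focal_pfam %in% .x))
      extra <- list()
      for (i in seq_len(nrow(focal_genes))) {
        g <- focal_genes[i, ]
        L <- scaffold_lengths$length[scaffold_lengths$scaffold == g$scaffold]
        k <- rpois(1, lambda)
        if (k == 0) next
        w_start <- max(0L, g$start - flank)
        w_end <- min(L, g$end + flank)
        plen <- 100L
        s <- w_start + floor(runif(k) * (w_end - w_start - plen))
        extra[[length(extra) + 1L]] <- tibble(
          scaffold = g$scaffold, start = as.integer(s),
          end = as.integer(s + plen), strand = ".",
          classification = sample(cls_pool, k, replace = TRUE))
        n_planted <- n_planted + k
      }
      if (length(extra) > 0) tes <- bind_rows(tes, extra)
    }
    list(genes = genes, tes = tes, scaffold_lengths = scaffold_lengths,
         truth = list(focal_pfam = focal_pfam, lambda = lambda,
                      n_planted = n_planted, flank = flank))
  })
}

#' Write a simulated genome to standard files
#'
#' Emits the gene models as GFF3, the TE annotation as GFF3 (with a
#' `classification` attribute), the PFAM map and the scaffold lengths as
#' TSV — the formats the loaders consume.
#'
#' @param sim List from [sim_genome_with_tes()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_genome_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genes = file.path(dir, "genes.gff3"),
             tes = file.path(dir, "tes.gff3"),
             pfam = file.path(dir, "pfam_map.tsv"),
             lengths = file.path(dir, "scaffold_lengths.tsv"))
  seqinfo <- GenomeInfoDb::Seqinfo(sim$scaffold_lengths$scaffold,
                                   sim$scaffold_lengths$length)
  ggr <- GenomicRanges::GRanges(
    sim$genes$scaffold,
    IRanges::IRanges(sim$genes$start + 1L, sim$genes$end),
    strand = sim$genes$strand, seqinfo = seqinfo)
  ggr$type <- "gene"
  ggr$ID <- sim$genes$gene_id
  rtracklayer::export(ggr, paths[["genes"]], format = "gff3")
  tgr <- GenomicRanges::GRanges(
    sim$tes$scaffold,
    IRanges::IRanges(sim$tes$start + 1L, sim$tes$end), seqinfo = seqinfo)
  tgr$type <- "dispersed_repeat"
  tgr$classification <- sim$tes$classification
  rtracklayer::export(tgr, paths[["tes"]], format = "gff3")
  sim$genes |>
    select("gene_id", "pfam_domains") |>
    tidyr::unnest_longer("pfam_domains", values_to = "pfam_id") |>
    readr::write_tsv(paths[["pfam"]])
  readr::write_tsv(sim$scaffold_lengths, paths[["lengths"]])
  invisible(paths)
}

#' Simulate a benchmark score table
#'
#' Interactor and noninteractor pTM/ipTM scores drawn from truncated-normal
#' models on `[0, 1]`. Defaults emulate the size of the curated benchmark
#' library (255 interactor and 490 noninteractor pairs).
#'
#' @param n_pos,n_neg Numbers of interactor / noninteractor pairs.
#' @param pos_mean,neg_mean,sd Truncated-normal location and spread.
#' @param seed Integer seed.
#' @return Benchmark tibble: `pair_id`, `label`, `ptm`, `iptm`.
#' @export
sim_benchmark_scores <- function(n_pos = 255L, n_neg = 490L,
                                 pos_mean = 0.8, neg_mean = 0.3, sd = 0.1,
                                 seed = 1L) {
  if (sd <= 0) abort("sd must be positive.")
  rtnorm <- function(n, mean) {
    x <- rnorm(n, mean, sd)
    while (any(bad <- x < 0 | x > 1)) x[bad] <- rnorm(sum(bad), mean, sd)
    x
  }
  with_seed(seed, {
    tibble(
      pair_id = sprintf("pair%04d", seq_len(n_pos + n_neg)),
      label = rep(c("interactor", "noninteractor"), c(n_pos, n_neg)),
      ptm = c(rtnorm(n_pos, pos_mean), rtnorm(n_neg, neg_mean)),
      iptm = c(rtnorm(n_pos, pos_mean), rtnorm(n_neg, neg_mean)))
  })
}

#' Simulate a two-chain complex with a planted contact domain
#'
#' Builds a C-alpha-trace bait of three labelled segments (HTH, F-box, FTH)
#' laid out far apart, and a prey chain running parallel to the planted
#' domain at `prey_offset` Angstrom — so every planted-domain residue's
#' minimum prey distance is ~`prey_offset`, while the other domains sit two
#' orders of magnitude farther. Optionally injects one prey atom inside a
#' bait atom's van der Waals envelope to exercise the clash filter.
#'
#' @param contact_domain `"HTH"`, `"F-box"` or `"FTH"`.
#' @param prey_offset Planted contact distance in Angstrom; keep it above
#'   the carbon-carbon van der Waals sum (3.4) or the whole interface
#'   clashes.
#' @param n_res_per_domain Residues per bait segment.
#' @param inject_clash Add one clashing prey atom.
#' @param ptm,iptm Confidences attached to the model.
#' @param bait_id,prey_id Identifiers.
#' @param seed Integer seed (jitters prey atoms along the chain axis).
#' @return List: `model` (`complex_model`), `domain_map` tibble, `truth`
#'   (list with `contact_domain`, `prey_offset`, and `clash_pair` —
#'   the two injected atom ids, or `NULL`).
#' @export
sim_complex <- function(contact_domain = c("HTH", "F-box", "FTH"),
                        prey_offset = 4, n_res_per_domain = 10L,
                        inject_clash = FALSE, ptm = 0.9, iptm = 0.9,
                        bait_id = "bait1", prey_id = "prey1", seed = 1L) {
  contact_domain <- match.arg(contact_domain)
  domains <- c("HTH", "F-box", "FTH")
  nd <- n_res_per_domain
  spacing <- 3.8    # typical C-alpha step
  sep <- 500        # inter-domain offset, >> any contact distance
  with_seed(seed, {
    bait <- purrr::imap(domains, function(d, di) {
      tibble(role = "bait", chain = "A",
             residue_index = (di - 1L) * nd + seq_len(nd),
             residue_name = "GLY", atom_name = "CA", element = "C",
             x = spacing * seq_len(nd), y = 0, z = sep * (di - 1))
    }) |> bind_rows()
    di <- match(contact_domain, domains)
    jitter <- runif(nd, -0.3, 0.3)
    prey <- tibble(role = "prey", chain = "B",
                   residue_index = seq_len(nd),
                   residue_name = "GLY", atom_name = "CA", element = "C",
                   x = spacing * seq_len(nd) + jitter, y = prey_offset,
                   z = sep * (di - 1))
    clash_pair <- NULL
    if (inject_clash) {
      target <- bait[1, ]  # first residue of the first domain
      prey <- bind_rows(prey, tibble(
        role = "prey", chain = "B", residue_index = nd + 1L,
        residue_name = "GLY", atom_name = "CA", element = "C",
        x = target$x, y = target$y + 1.0, z = target$z))
    }
    atoms <- bind_rows(bait, prey) |>
      mutate(across(c("x", "y", "z"), ~ round(.x, 3)),
             atom_id = sprintf("%s:%d:%s:%d", .data$role, .data$residue_index,
                               .data$atom_name, row_number())) |>
      select("atom_id", "role", "chain", "residue_index", "residue_name",
             "atom_name", "element", "x", "y", "z")
    if (inject_clash) {
      clash_pair <- c(atoms$atom_id[1],
                      atoms$atom_id[nrow(atoms)])
    }
    domain_map <- tibble(
      bait_id = bait_id, domain_label = domains,
      start_res = (seq_along(domains) - 1L) * nd + 1L,
      end_res = seq_along(domains) * nd)
    list(model = new_complex_model(bait_id, prey_id, atoms, ptm, iptm),
         domain_map = domain_map,
         truth = list(contact_domain = contact_domain,
                      prey_offset = prey_offset, clash_pair = clash_pair))
  })
}
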