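test_that("gene models load from GFF3 with coordinates converted to half-open", {
  dir <- withr::local_tempdir()
  sim <- sim_genome_with_tes(n_genes = 50, n_tes = 100, n_pfams = 6,
                             n_focal_genes = 5, seed = 21)
  paths <- write_genome_files(sim, dir)
  genes <- read_gene_models(paths[["genes"]], paths[["pfam"]])
  # round trip: loader recovers the simulated 0-based half-open intervals
  expect_equal(
    genes |> select(gene_id, scaffold, start, end) |> arrange(gene_id),
    sim$genes |> select(gene_id, scaffold, start, end) |> arrange(gene_id),
    ignore_attr = TRUE)
  # gene/PFAM join equals an independent merge of the map file
  map <- readr::read_tsv(paths[["pfam"]], show_col_types = FALSE)
  for (i in sample(nrow(genes), 10)) {
    expect_setequal(genes$pfam_domains[[i]],
                    map$pfam_id[map$gene_id == genes$gene_id[i]])
  }
  # GFF gene written 1-based at 1..1000 loads as [0, 1000)
  one <- sim$genes[1, ]
  gff_line <- readr::read_lines(paths[["genes"]])
  expect_true(any(grepl(sprintf("\t%d\t%d\t", one$start + 1, one$end),
                        gff_line, fixed = TRUE)))

  # genes absent from the map get empty domain sets; orphan map rows warn
  genes0 <- read_gene_models(paths[["genes"]], NULL)
  expect_true(all(lengths(genes0$pfam_domains) == 0))
  orphan <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble(gene_id = c(genes$gene_id[1], "nope"),
                          pfam_id = "PFX"), orphan)
  expect_warning(g2 <- read_gene_models(paths[["genes"]], orphan), "skipped")
  expect_equal(nrow(attr(g2, "skipped_pfam_rows")), 1)
})

test_that("TE loader keeps classified copies only, from GFF3 or BED", {
  dir <- withr::local_tempdir()
  # 10 copies, 3 unclassified
  tes <- tibble(scaffold = "chr1", start = seq(0L, 900L, by = 100L),
                end = seq(50L, 950L, by = 100L), strand = ".",
                classification = c(rep("DNA/TcMar", 4), rep("Unknown", 3),
                                   rep("RC/Helitron", 3)))
  bed <- file.path(dir, "tes.bed")
  readr::write_tsv(tibble(chrom = tes$scaffold, start = tes$start,
                          end = tes$end, name = tes$classification),
                   bed, col_names = FALSE)
  got <- read_te_annotations(bed, "bed")
  expect_equal(nrow(got), 7)
  expect_equal(attr(got, "n_removed"), 3)
  # BED line "chr1 100 200 DNA/TcMar" -> [100, 200)
  one_line <- file.path(dir, "one.bed")
  writeLines("chr1\t100\t200\tDNA/TcMar", one_line)
  row <- read_te_annotations(one_line, "bed")
  expect_equal(row$start, 100L)
  expect_equal(row$end, 200L)
  expect_equal(row$classification, "DNA/TcMar")
  # retained set equals a brute-force filter
  expect_setequal(got$start, tes$start[tes$classification != "Unknown"])
})

test_that("window counts cap at ten and overlap by at least one bp", {
  sl <- tibble(scaffold = "chr1", length = 10000L)
  gene <- tibble(gene_id = "g1", scaffold = "chr1", start = 1000L,
                 end = 2000L, strand = "+", pfam_domains = list("PF1"))
  te_at <- function(s, e) tibble(scaffold = "chr1", start = s, end = e,
                                 strand = ".", classification = "DNA/TcMar")
  # window is [500, 2500): 1-bp overlap in, abutting out
  expect_equal(count_te_near_gene(gene, te_at(400L, 501L), sl)$n_te, 1L)
  expect_equal(count_te_near_gene(gene, te_at(2500L, 2600L), sl)$n_te, 0L)
  expect_equal(count_te_near_gene(gene, te_at(499L, 500L), sl)$n_te, 0L)
  # no TEs on the scaffold
  none <- te_at(integer(), integer())
  expect_equal(count_te_near_gene(gene, none, sl)$n_te, 0L)
  # 15 overlapping copies count as 10
  many <- te_at(seq(600L, 2000L, by = 100L), seq(650L, 2050L, by = 100L))
  expect_equal(nrow(many), 15)
  expect_equal(count_te_near_gene(gene, many, sl)$n_te, 10L)

  # random fixture equals brute-force interval intersection with cap
  sim <- sim_genome_with_tes(n_genes = 30, n_tes = 400, n_pfams = 5,
                             n_focal_genes = 3, n_scaffolds = 2,
                             scaffold_length = 50000L, seed = 5)
  got <- count_te_near_gene(sim$genes, sim$tes, sim$scaffold_lengths)
  oracle <- brute_window_count(sim$genes, sim$tes, sim$scaffold_lengths,
                               flank = 500, cap = 10)
  expect_equal(got, oracle)
})

test_that("per-PFAM aggregation sums gene counts into every family the gene carries", {
  genes <- tibble(gene_id = c("g1", "g2"), scaffold = "c", start = c(0L, 100L),
                  end = c(50L, 150L), strand = "+",
                  pfam_domains = list("PF1", c("PF1", "PF2")))
  counts <- tibble(gene_id = c("g1", "g2"), n_te = c(7L, 3L))
  agg <- aggregate_by_pfam(counts, genes)
  expect_equal(agg$observed[agg$pfam_id == "PF1"], 10L)
  expect_equal(agg$observed[agg$pfam_id == "PF2"], 3L)
  # conservation: sum over PFAMs = sum over genes of count x #PFAMs
  sim <- sim_genome_with_tes(n_genes = 40, n_tes = 200, seed = 9)
  pg <- count_te_near_gene(sim$genes, sim$tes, sim$scaffold_lengths)
  agg <- aggregate_by_pfam(pg, sim$genes)
  expect_equal(sum(agg$observed),
               sum(pg$n_te * lengths(sim$genes$pfam_domains)))
})

test_that("TE shuffling preserves copies and places them length-proportionally", {
  sl <- tibble(scaffold = c("s1", "s2"), length = c(1000L, 3000L))
  tes <- tibble(scaffold = "s1", start = 0L, end = 150L, strand = ".",
                classification = "DNA/TcMar")[rep(1, 50), ]
  a <- shuffle_te_positions(tes, sl, replicate_seed = 4)
  b <- shuffle_te_positions(tes, sl, replicate_seed = 4)
  expect_identical(a, b)  # same replicate seed, same placements
  expect_false(identical(a, shuffle_te_positions(tes, sl, 5)))
  expect_true(all(a$end - a$start == 150L))
  expect_equal(a$classification, tes$classification)
  lens <- sl$length[match(a$scaffold, sl$scaffold)]
  expect_true(all(a$start >= 0 & a$end <= lens))

  # TE exactly filling the single scaffold has one legal start
  snug <- shuffle_te_positions(
    tibble(scaffold = "s1", start = 0L, end = 1000L, strand = ".",
           classification = "X"),
    tibble(scaffold = "s1", length = 1000L), 99)
  expect_equal(snug$start, 0L)
  expect_error(shuffle_te_positions(
    tibble(scaffold = "s1", start = 0L, end = 2000L, strand = ".",
           classification = "X"),
    tibble(scaffold = "s1", length = 1000L), 1), "longer")

  # 1e4 1-bp copies over scaffolds 1000/3000: scaffold-2 fraction ~ 0.75
  one_bp <- tibble(scaffold = "s1", start = 0L, end = 1L, strand = ".",
                   classification = "X")[rep(1, 1e4), ]
  frac <- mean(shuffle_te_positions(one_bp, sl, 11)$scaffold == "s2")
  expect_lt(abs(frac - 3000 / 4001), 3 * sqrt(0.75 * 0.25 / 1e4))
})

test_that("ECDF empirical p-values use the add-one rule on both tails", {
  expect_equal(empirical_p(50, rep(1, 1000))$p_enrich, 1 / 1001)
  expect_equal(empirical_p(3, c(1, 2, 3, 4))$p_enrich, 0.6)  # (1+2)/5
  expect_equal(empirical_p(0, c(1, 2, 3, 4))$p_enrich, 1.0)
  expect_equal(empirical_p(0, c(1, 2, 3, 4))$p_deplete, 1 / 5)
  expect_error(empirical_p(1, numeric()), "Empty")
  # monotone non-increasing in observed, for fixed null
  null <- rpois(200, 5)
  ps <- vapply(0:15, function(o) empirical_p(o, null)$p_enrich, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("multiple-testing correction follows BH step-up / Bonferroni", {
  expect_equal(correct_pvalues(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))  # q_i = min_{j>=i} p_(j) * m / j
  expect_equal(correct_pvalues(0.03), 0.03)
  expect_equal(correct_pvalues(rep(0.01, 4), "bonferroni"), rep(0.04, 4))
  expect_error(correct_pvalues(c(0.5, 0)), "0, 1")
  expect_error(correct_pvalues(c(0.5, 1.2)), "0, 1")
  p <- runif(30, 0.001, 1)
  q <- correct_pvalues(p)
  expect_true(all(q[order(p)] == cummax(q[order(p)]) | diff(c(0, q[order(p)])) >= 0))
  expect_true(all(q >= p & q <= 1))
})

test_that("the full enrichment run is deterministic and coherent at tiny B", {
  sim <- sim_genome_with_tes(n_genes = 30, n_tes = 150, n_pfams = 5,
                             n_focal_genes = 3, seed = 12)
  r1 <- run_te_enrichment(sim$genes, sim$tes, sim$scaffold_lengths,
                          replicates = 20, seed = 7)
  r2 <- run_te_enrichment(sim$genes, sim$tes, sim$scaffold_lengths,
                          replicates = 20, seed = 7)
  expect_identical(r1, r2)
  expect_true(all(r1$p_enrich >= 1 / 21 & r1$q >= r1$p_enrich))
  expect_true(all(r1$score[r1$observed >= r1$null_mean] >= 0))

  # B = 1: the add-one rule only allows p in {0.5, 1}
  b1 <- run_te_enrichment(sim$genes, sim$tes, sim$scaffold_lengths,
                          replicates = 1, seed = 3)
  expect_true(all(b1$p_enrich %in% c(0.5, 1)))
  expect_true(all(b1$p_deplete %in% c(0.5, 1)))

  # stratified run covers each classification prefix plus "all"
  rs <- run_te_enrichment(sim$genes, sim$tes, sim$scaffold_lengths,
                          replicates = 5, seed = 7, stratify_class = TRUE)
  prefixes <- sort(unique(sub("/.*$", "", sim$tes$classification)))
  expect_setequal(unique(rs$stratum), c("all", prefixes))

  # observed column equals the unit-operation pipeline
  agg <- aggregate_by_pfam(
    count_te_near_gene(sim$genes, sim$tes, sim$scaffold_lengths), sim$genes) |>
    arrange(pfam_id)
  expect_equal(as.integer(r1$observed), as.integer(agg$observed))
  expect_error(run_te_enrichment(sim$genes |> mutate(pfam_domains = list(character())),
                                 sim$tes, sim$scaffold_lengths,
                                 replicates = 2, seed = 1), "PFAM")
})
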