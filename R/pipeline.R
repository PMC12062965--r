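#' Row-wise percentage summaries of a count table
#'
#' Reporting helper for fraction tables of the form "12/30 A2 genes
#' (40.0%)": every row supplies its own numerator and denominator.
#'
#' @param tables Data frame with a numerator column and a denominator
#'   column.
#' @param count,total Column names (default `"count"`, `"total"`).
#' @return The input with `percent` (half-up, one decimal) and a logical
#'   `zero_denominator` flag; zero-denominator rows are flagged, never
#'   dropped, and get `NA` percent.
#' @export
summarize_counts <- function(tables, count = "count", total = "total") {
  stopifnot_cols(tables, c(count, total), "count table")
  tables |>
    mutate(
      zero_denominator = .data[[total]] == 0,
      percent = if_else(.data$zero_denominator, NA_real_,
                        percent_of(.data[[count]],
                                   pmax(.data[[total]], 1))))
}

#' Run a multi-stage analysis from one config
#'
#' Orchestrates the pipelines (`simulate`, `screen`, `enrich`, `interact`)
#' from a single YAML config or equivalent list, executing the stages in
#' declared order and recording a manifest (parameters, per-stage seeds,
#' package version, md5 checksum of every file written). Per-stage seeds are
#' derived from the global seed by stage-name hashing, so reordering stages
#' does not reshuffle their randomness; a rerun with an identical config
#' reproduces identical outputs.
#'
#' @param config Path to a YAML file or a named list with elements `seed`,
#'   `out_dir`, `stages` (ordered character vector) and one parameter block
#'   per stage. See the package vignette for the block layouts.
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`). Any stage error aborts with a manifest of
#'   the completed stages.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (field in c("seed", "out_dir", "stages")) {
    if (is.null(config[[field]])) abort(sprintf("Config lacks `%s`.", field))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  known <- c("simulate", "screen", "enrich", "interact")
  bad <- setdiff(config$stages, known)
  if (length(bad) > 0) abort(sprintf("Unknown stage(s): %s", paste(bad, collapse = ", ")))

  # validate before any stage runs: every referenced input that the run
  # itself will not produce (i.e. not under out_dir) must already exist
  inputs <- unlist(purrr::map(setdiff(config$stages, "simulate"), function(st) {
    blk <- config[[st]]
    unlist(blk[names(blk) %in% c("domains", "sets", "taxonomy", "genes",
                                 "tes", "pfam", "lengths", "models_dir",
                                 "confidence", "benchmark", "domain_map",
                                 "radii")])
  }))
  inputs <- inputs %||% character()
  absolutize <- function(p) {
    ifelse(startsWith(p, "/") | grepl("^[A-Za-z]:", p), p,
           file.path(getwd(), p))
  }
  external <- inputs[!startsWith(absolutize(inputs),
                                 absolutize(out_dir))]
  missing <- external[!file.exists(external)]
  if (length(missing) > 0) {
    abort(sprintf("Input path(s) do not exist: %s",
                  paste(missing, collapse = ", ")))
  }

  manifest <- list(config = config,
                   package_version = as.character(utils::packageVersion("tecapture")),
                   stages = list())
  written <- character()
  finish <- function(status) {
    manifest$status <- status
    manifest$outputs <- purrr::map(written, ~ list(
      path = .x, md5 = unname(tools::md5sum(.x))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest
  }
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(df, path)
    written <<- c(written, path)
  }

  for (st in config$stages) {
    seed_st <- stage_seed(config$seed, st)
    blk <- config[[st]] %||% list()
    res <- tryCatch({
      switch(st,
        simulate = {
          sim_dir <- file.path(out_dir, "simulate")
          dir.create(sim_dir, showWarnings = FALSE)
          if (!is.null(blk$domains)) {
            pp <- if (is.null(blk$domains$planted_pairs)) NULL else
              bind_rows(purrr::map(blk$domains$planted_pairs, as_tibble))
            sim <- sim_domain_table(blk$domains$n_proteins, pp,
                                    n_taxa = blk$domains$n_taxa %||% 5L,
                                    seed = seed_st)
            for (nm in c("domains", "sets", "taxonomy", "truth")) {
              path <- file.path(sim_dir, paste0("domain_", nm, ".tsv"))
              out_tbl <- sim[[nm]]
              # category is derived by the loader, not part of the format
              if (nm == "domains") out_tbl <- select(out_tbl, -"category")
              readr::write_tsv(out_tbl, path)
              written <- c(written, path)
            }
          }
          if (!is.null(blk$genome)) {
            args <- blk$genome
            args$seed <- seed_st
            sim <- do.call(sim_genome_with_tes, args)
            paths <- write_genome_files(sim, sim_dir)
            written <- c(written, unname(paths))
          }
          if (!is.null(blk$benchmark)) {
            args <- blk$benchmark
            args$seed <- seed_st
            bench <- do.call(sim_benchmark_scores, args)
            path <- file.path(sim_dir, "benchmark.tsv")
            readr::write_tsv(bench, path)
            written <- c(written, path)
          }
          list(seed = seed_st)
        },
        screen = {
          sets <- read_domain_sets(blk$sets)
          domains <- read_domain_table(blk$domains, sets)
          taxonomy <- if (is.null(blk$taxonomy)) NULL else read_taxonomy(blk$taxonomy)
          cooc <- partition_by_te_count(screen_cooccurrence(domains))
          groups <- group_by_domain_pair(cooc, taxonomy)
          emit(cooc |> select(-"multicopy_hits", -"te_hits"),
               "cooccurrence.tsv")
          emit(groups |> select(-"members", -"clade_counts"), "groups.tsv")
          bias <- positional_bias(cooc)
          emit(glance(bias), "positional_bias.tsv")
          fam <- tryCatch(
            family_size_association(domains, groups) |> select(-"by_family"),
            error = function(e) tibble(n_families = NA, rho = NA,
                                       p_value = NA, undefined = NA))
          emit(fam, "family_size.tsv")
          list(seed = seed_st, n_hits = nrow(cooc))
        },
        enrich = {
          genes <- read_gene_models(blk$genes, blk$pfam)
          tes <- read_te_annotations(blk$tes, blk$format %||% "gff3")
          lens <- read_scaffold_lengths(blk$lengths)
          res <- run_te_enrichment(
            genes, tes, lens,
            flank = blk$flank %||% 500L, cap = blk$cap %||% 10L,
            replicates = blk$replicates %||% 1000L, seed = seed_st,
            correction = blk$correction %||% "BH",
            stratify_class = isTRUE(blk$stratify_class))
          emit(res, "enrichment.tsv")
          list(seed = seed_st, n_pfams = dplyr::n_distinct(res$pfam_id))
        },
        interact = {
          bench <- read_benchmark(blk$benchmark)
          conf <- read_confidence(blk$confidence)
          dmap <- read_domain_map(blk$domain_map)
          radii <- if (is.null(blk$radii)) vdw_radii() else read_vdw_radii(blk$radii)
          models <- purrr::pmap(conf, function(bait_id, prey_id, ptm, iptm) {
            read_complex(file.path(blk$models_dir,
                                   sprintf("%s__%s.pdb", bait_id, prey_id)),
                         ptm = ptm, iptm = iptm,
                         bait_id = bait_id, prey_id = prey_id, radii = radii)
          })
          rep <- screen_report(models, bench, dmap, radii = radii,
                               any_metric = isTRUE(blk$any_metric))
          emit(bind_rows(tidy(roc_analysis(bench, "ptm")) |> mutate(metric = "ptm"),
                         tidy(roc_analysis(bench, "iptm")) |> mutate(metric = "iptm")),
               "roc.tsv")
          emit(rep$thresholds, "thresholds.tsv")
          emit(rep$interactions, "high_confidence.tsv")
          profiles <- purrr::map(models, ~ min_distance_profile(
            .x, clash_filter(.x, radii))) |> bind_rows()
          emit(profiles, "distance_profiles.tsv")
          emit(rep$baits, "domain_summary.tsv")
          list(seed = seed_st, n_models = length(models))
        })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      finish("failed")
      abort(sprintf("Stage '%s' failed: %s", st, conditionMessage(res)))
    }
    manifest$stages[[st]] <- res
  }
  invisible(finish("ok"))
}
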