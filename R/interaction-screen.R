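#' ROC analysis of a confidence metric on the benchmark
#'
#' Evaluates how well a confidence metric (pTM or ipTM) separates the
#' labelled interactors from noninteractors. The classifier is
#' "score >= threshold => interactor", thresholds are the unique observed
#' scores, and the AUC is the trapezoidal integral of the curve — which
#' equals the Mann-Whitney U statistic divided by n_pos * n_neg, with tied
#' scores counted one half.
#'
#' @param benchmark Tibble from [read_benchmark()].
#' @param metric `"iptm"` (default) or `"ptm"`.
#' @return Object of class `roc_result`: `metric`, `points` (tibble
#'   `threshold`, `tpr`, `fpr`, sorted by threshold), `auc`, `n_pos`,
#'   `n_neg`. [tidy()] returns the points, [glance()] the one-row summary.
#' @export
roc_analysis <- function(benchmark, metric = c("iptm", "ptm")) {
  metric <- match.arg(metric)
  score <- benchmark[[metric]]
  pos <- score[benchmark$label == "interactor"]
  neg <- score[benchmark$label == "noninteractor"]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("Benchmark must contain both labels.")
  }
  thr <- sort(unique(score))
  points <- tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(pos >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(neg >= t), numeric(1)))
  # integrate over the full sweep: (fpr, tpr) from (1,1) at the lowest
  # threshold down to (0,0) past the highest
  fpr <- c(1, points$fpr, 0)
  tpr <- c(1, points$tpr, 0)
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) *
               (tpr[-length(tpr)] + tpr[-1]) / 2)
  structure(list(metric = metric, points = points, auc = auc,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> metric %s: AUC %.3f (%d interactors, %d noninteractors)\n",
              x$metric, x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @rdname roc_analysis
#' @param x A `roc_result`.
#' @param ... Unused.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$points

#' @rdname roc_analysis
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(metric = x$metric, auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Kolmogorov-Smirnov threshold selection
#'
#' Places the confidence cutoff where the empirical CDFs of noninteractor and
#' interactor scores are furthest apart:
#' `D(t) = ECDF_neg(t-) - ECDF_pos(t-)` over candidate thresholds t (the
#' unique observed scores), taking the smallest t attaining the maximum —
#' the most inclusive rule at equal separation. Scores are oriented
#' (interactors high), so the one-sided difference is used.
#'
#' @inheritParams roc_analysis
#' @return One-row tibble: `metric`, `threshold`, `ks_statistic`,
#'   `separable`. A benchmark where no threshold separates the labels
#'   (max D <= 0) is flagged `separable = FALSE` with `threshold = Inf`,
#'   so nothing passes.
#' @export
select_threshold_ks <- function(benchmark, metric = c("iptm", "ptm")) {
  metric <- match.arg(metric)
  score <- benchmark[[metric]]
  pos <- score[benchmark$label == "interactor"]
  neg <- score[benchmark$label == "noninteractor"]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("Benchmark must contain both labels.")
  }
  thr <- sort(unique(score))
  D <- vapply(thr, function(t) mean(neg < t) - mean(pos < t), numeric(1))
  Dmax <- max(D)
  if (Dmax <= 0) {
    return(tibble(metric = metric, threshold = Inf, ks_statistic = 0,
                  separable = FALSE))
  }
  tibble(metric = metric, threshold = thr[which(D == Dmax)[1]],
         ks_statistic = Dmax, separable = TRUE)
}

#' Call high-confidence interactors
#'
#' A pair passes when both confidence metrics reach their thresholds
#' (conjunction); `any_metric = TRUE` switches to the disjunction.
#'
#' @param confidence Tibble with columns `bait_id`, `prey_id`, `ptm`, `iptm`
#'   (e.g. from [read_confidence()]).
#' @param t_ptm,t_iptm Thresholds, typically from [select_threshold_ks()].
#' @param any_metric Pass on either metric instead of both.
#' @return The input tibble with a logical `high_confidence` column.
#' @export
classify_high_confidence <- function(confidence, t_ptm, t_iptm,
                                     any_metric = FALSE) {
  confidence |>
    mutate(high_confidence = if (any_metric) {
      .data$ptm >= t_ptm | .data$iptm >= t_iptm
    } else {
      .data$ptm >= t_ptm & .data$iptm >= t_iptm
    })
}

#' Van der Waals clash filter
#'
#' Flags atoms of the bait/prey interface that the predictor has placed
#' impossibly close: two atoms on opposite chains closer than the sum of
#' their van der Waals radii (strict inequality) are clashed, and both atoms
#' of every clashing pair are excluded from distance analysis. Intra-chain
#' pairs are not evaluated.
#'
#' @param model A `complex_model`.
#' @param radii Named radius vector, see [vdw_radii()].
#' @return Character vector of excluded `atom_id`s.
#' @export
clash_filter <- function(model, radii = vdw_radii()) {
  a <- model$atoms
  unknown <- setdiff(unique(a$element), names(radii))
  if (length(unknown) > 0) {
    abort(sprintf("Element(s) missing from radius table: %s",
                  paste(unknown, collapse = ", ")))
  }
  b <- a[a$role == "bait", ]
  p <- a[a$role == "prey", ]
  if (nrow(b) == 0 || nrow(p) == 0) return(character())
  d2 <- outer(b$x, p$x, "-")^2 + outer(b$y, p$y, "-")^2 +
    outer(b$z, p$z, "-")^2
  lim <- outer(radii[b$element], radii[p$element], "+")
  clash <- d2 < lim^2  # strict: touching pairs are retained
  hit_b <- rowSums(clash) > 0
  hit_p <- colSums(clash) > 0
  c(b$atom_id[hit_b], p$atom_id[hit_p])
}

#' Per-residue minimum distance profile of the bait
#'
#' For every bait residue, the minimum Euclidean distance (Angstrom) between
#' its non-excluded atoms and all non-excluded prey atoms — the per-residue
#' contact map of the interface. A residue with no eligible atom pair gets
#' `NA` ("no contact partner"), never 0.
#'
#' @param model A `complex_model`.
#' @param excluded Character vector of excluded atom ids, typically from
#'   [clash_filter()].
#' @return Tibble `bait_id`, `prey_id`, `residue_index`, `residue_name`,
#'   `min_dist` covering every bait residue.
#' @export
min_distance_profile <- function(model, excluded = character()) {
  a <- model$atoms |> filter(!.data$atom_id %in% excluded)
  b <- a[a$role == "bait", ]
  p <- a[a$role == "prey", ]
  all_res <- model$atoms |>
    filter(.data$role == "bait") |>
    distinct(.data$residue_index, .data$residue_name) |>
    arrange(.data$residue_index)
  if (nrow(p) == 0) {
    warn("All prey atoms excluded; every residue has no contact partner.")
    return(all_res |>
             mutate(bait_id = model$bait_id, prey_id = model$prey_id,
                    min_dist = NA_real_) |>
             select("bait_id", "prey_id", "residue_index", "residue_name",
                    "min_dist"))
  }
  mins <- if (nrow(b) == 0) {
    tibble(residue_index = integer(), min_dist = numeric())
  } else {
    d2 <- outer(b$x, p$x, "-")^2 + outer(b$y, p$y, "-")^2 +
      outer(b$z, p$z, "-")^2
    tibble(residue_index = b$residue_index,
           atom_min = sqrt(apply(d2, 1, min))) |>
      group_by(.data$residue_index) |>
      summarise(min_dist = min(.data$atom_min), .groups = "drop")
  }
  all_res |>
    left_join(mins, by = "residue_index") |>
    mutate(bait_id = model$bait_id, prey_id = model$prey_id) |>
    select("bait_id", "prey_id", "residue_index", "residue_name", "min_dist")
}

#' Summarise contact distances by bait domain
#'
#' Collapses a per-residue distance profile to one median per annotated bait
#' domain (residues outside every mapped range fall under `"other"`), and
#' names the domain the prey contacts preferentially — the argmin of the
#' medians. No-contact residues are excluded from medians; a domain with no
#' contact-bearing residue is excluded from the argmin with a warning; an
#' exact tie for the minimum gives `"ambiguous"`.
#'
#' @param profile Tibble from [min_distance_profile()].
#' @param domain_map Tibble with `domain_label`, `start_res`, `end_res`
#'   (1-based inclusive; e.g. from [read_domain_map()], filtered to the
#'   bait).
#' @return Object of class `domain_contact_summary`: `per_domain` tibble
#'   (`domain_label`, `median_dist`, `n_residues`, `n_used`) and
#'   `preferred_domain`. [tidy()] returns `per_domain`.
#' @export
domain_contact_summary <- function(profile, domain_map) {
  label_of <- function(res) {
    hit <- domain_map$domain_label[domain_map$start_res <= res &
                                     domain_map$end_res >= res]
    if (length(hit) == 0) "other" else hit[1]
  }
  labelled <- profile |>
    mutate(domain_label = purrr::map_chr(.data$residue_index, label_of))
  per_domain <- labelled |>
    group_by(domain_label = .data$domain_label) |>
    summarise(median_dist = median(.data$min_dist, na.rm = TRUE),
              n_residues = n(),
              n_used = sum(!is.na(.data$min_dist)), .groups = "drop") |>
    mutate(median_dist = if_else(.data$n_used == 0, NA_real_,
                                 .data$median_dist))
  if (any(per_domain$n_used == 0)) {
    warn(sprintf("Domain(s) with no contact-bearing residues: %s",
                 paste(per_domain$domain_label[per_domain$n_used == 0],
                       collapse = ", ")))
  }
  usable <- per_domain |> filter(!is.na(.data$median_dist))
  preferred <- if (nrow(usable) == 0) {
    NA_character_
  } else {
    best <- usable$median_dist == min(usable$median_dist)
    if (sum(best) > 1) "ambiguous" else usable$domain_label[best]
  }
  structure(list(per_domain = per_domain, preferred_domain = preferred),
            class = "domain_contact_summary")
}

#' @export
print.domain_contact_summary <- function(x, ...) {
  cat(sprintf("<domain_contact_summary> preferred domain: %s\n",
              x$preferred_domain))
  print(x$per_domain)
  invisible(x)
}

#' @rdname domain_contact_summary
#' @param x A `domain_contact_summary`.
#' @param ... Unused.
#' @method tidy domain_contact_summary
#' @export
tidy.domain_contact_summary <- function(x, ...) x$per_domain

#' @rdname domain_contact_summary
#' @method glance domain_contact_summary
#' @export
glance.domain_contact_summary <- function(x, ...) {
  tibble(preferred_domain = x$preferred_domain,
         n_domains = nrow(x$per_domain))
}

#' Full triage report for an interaction screen
#'
#' Runs the whole post-prediction triage: thresholds from the benchmark
#' (KS on both metrics), high-confidence calling over the supplied complex
#' models, clash filtering and distance profiling of each high-confidence
#' pair, the preferred contact domain per pair, and the modal preferred
#' domain per bait.
#'
#' @param models List of `complex_model` objects.
#' @param benchmark Tibble from [read_benchmark()].
#' @param domain_maps Tibble with `bait_id`, `domain_label`, `start_res`,
#'   `end_res` covering the baits.
#' @param radii Radius table for the clash filter.
#' @param any_metric Passed to [classify_high_confidence()].
#' @return Object of class `screen_report`: `thresholds` (two rows),
#'   `interactions` (per model: confidences, `high_confidence`,
#'   `preferred_domain`), `baits` (per bait: `n_high_confidence`,
#'   `modal_domain`).
#' @export
screen_report <- function(models, benchmark, domain_maps,
                          radii = vdw_radii(), any_metric = FALSE) {
  thr <- bind_rows(select_threshold_ks(benchmark, "ptm"),
                   select_threshold_ks(benchmark, "iptm"))
  confidence <- purrr::map(models, ~ tibble(
    bait_id = .x$bait_id, prey_id = .x$prey_id,
    ptm = .x$ptm, iptm = .x$iptm)) |> bind_rows()
  calls <- classify_high_confidence(
    confidence,
    t_ptm = thr$threshold[thr$metric == "ptm"],
    t_iptm = thr$threshold[thr$metric == "iptm"],
    any_metric = any_metric)
  preferred <- purrr::map2_chr(models, calls$high_confidence, function(m, hc) {
    if (!hc) return(NA_character_)
    dm <- domain_maps |> filter(.data$bait_id == m$bait_id)
    prof <- min_distance_profile(m, clash_filter(m, radii))
    domain_contact_summary(prof, dm)$preferred_domain
  })
  interactions <- calls |> mutate(preferred_domain = preferred)
  baits <- interactions |>
    group_by(bait_id = .data$bait_id) |>
    summarise(
      n_high_confidence = sum(.data$high_confidence),
      modal_domain = {
        pd <- .data$preferred_domain[!is.na(.data$preferred_domain)]
        if (length(pd) == 0) NA_character_ else {
          tab <- sort(table(pd), decreasing = TRUE)
          if (length(tab) > 1 && tab[1] == tab[2]) "ambiguous" else names(tab)[1]
        }
      },
      .groups = "drop")
  structure(list(thresholds = thr, interactions = interactions, baits = baits),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d models, %d high-confidence; thresholds pTM %.3g / ipTM %.3g\n",
              nrow(x$interactions), sum(x$interactions$high_confidence),
              x$thresholds$threshold[x$thresholds$metric == "ptm"],
              x$thresholds$threshold[x$thresholds$metric == "iptm"]))
  invisible(x)
}
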