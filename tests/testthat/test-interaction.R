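test_that("complexes round-trip through PDB at three-decimal precision", {
  cx <- sim_complex("HTH", seed = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_complex_pdb(cx$model, path)
  back <- read_complex(path, ptm = cx$model$ptm, iptm = cx$model$iptm,
                       bait_id = cx$model$bait_id, prey_id = cx$model$prey_id)
  expect_identical(back$atoms[, c("x", "y", "z")],
                   cx$model$atoms[, c("x", "y", "z")])
  expect_equal(back$atoms$role, cx$model$atoms$role)
  expect_equal(back$atoms$residue_index, cx$model$atoms$residue_index)
  expect_equal(back$atoms$element, cx$model$atoms$element)

  # minimal two-atom complex
  two <- withr::local_tempfile(fileext = ".pdb")
  bio3d::write.pdb(pdb = NULL, file = two,
                   xyz = c(0, 0, 0, 1, 1, 1), type = rep("ATOM", 2),
                   resno = c(1, 1), resid = rep("GLY", 2), eleno = 1:2,
                   elety = rep("CA", 2), chain = c("A", "B"),
                   elesy = rep("C", 2))
  m <- read_complex(two, ptm = 0.5, iptm = 0.5)
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$role, c("bait", "prey"))

  # three chains is an error
  three <- withr::local_tempfile(fileext = ".pdb")
  bio3d::write.pdb(pdb = NULL, file = three,
                   xyz = rep(0:2, each = 3), type = rep("ATOM", 3),
                   resno = rep(1, 3), resid = rep("GLY", 3), eleno = 1:3,
                   elety = rep("CA", 3), chain = c("A", "B", "C"),
                   elesy = rep("C", 3))
  expect_error(read_complex(three, ptm = 0.5, iptm = 0.5), "2 chains")
})

test_that("ROC analysis matches the Mann-Whitney U statistic with ties at one half", {
  perfect <- tibble(pair_id = as.character(1:4),
                    label = rep(c("interactor", "noninteractor"), each = 2),
                    ptm = c(0.9, 0.8, 0.1, 0.2),
                    iptm = c(0.9, 0.8, 0.1, 0.2))
  expect_equal(roc_analysis(perfect, "iptm")$auc, 1.0)

  ties <- perfect |> mutate(iptm = 0.5)
  expect_equal(roc_analysis(ties, "iptm")$auc, 0.5)

  for (seed in c(1, 2, 3)) {
    bench <- random_benchmark(30, seed)
    r <- roc_analysis(bench, "iptm")
    pos <- bench$iptm[bench$label == "interactor"]
    neg <- bench$iptm[bench$label == "noninteractor"]
    expect_equal(r$auc, brute_auc(pos, neg), tolerance = 1e-12)
    # complementarity under score negation
    flipped <- bench |> mutate(iptm = 1 - iptm)
    expect_equal(roc_analysis(flipped, "iptm")$auc, 1 - r$auc,
                 tolerance = 1e-12)
    # independent cross-check against pROC
    expect_equal(r$auc,
                 as.numeric(pROC::auc(pROC::roc(
                   bench$label, bench$iptm, levels = c("noninteractor", "interactor"),
                   direction = "<", quiet = TRUE))),
                 tolerance = 1e-12)
  }
  expect_error(roc_analysis(perfect |> filter(label == "interactor"), "iptm"),
               "both labels")
})

test_that("KS threshold selection maximises the ECDF gap, smallest threshold on ties", {
  disjoint <- tibble(pair_id = as.character(1:4),
                     label = rep(c("interactor", "noninteractor"), each = 2),
                     ptm = 0.5, iptm = c(0.8, 0.9, 0.1, 0.2))
  sel <- select_threshold_ks(disjoint, "iptm")
  expect_equal(sel$threshold, 0.8)
  expect_equal(sel$ks_statistic, 1.0)
  expect_true(sel$separable)

  identical_dist <- disjoint |> mutate(iptm = rep(c(0.4, 0.6), 2))
  sel2 <- select_threshold_ks(identical_dist, "iptm")
  expect_false(sel2$separable)
  expect_equal(sel2$threshold, Inf)

  for (seed in 4:6) {
    bench <- random_benchmark(40, seed)
    sel <- select_threshold_ks(bench, "iptm")
    oracle <- brute_ks_threshold(bench$iptm[bench$label == "interactor"],
                                 bench$iptm[bench$label == "noninteractor"])
    if (sel$separable) {
      expect_equal(sel$threshold, oracle$threshold)
      expect_equal(sel$ks_statistic, oracle$D)
    }
  }
})

test_that("high-confidence calls require both metrics unless any_metric is set", {
  conf <- tibble(bait_id = "b", prey_id = c("p1", "p2", "p3", "p4"),
                 ptm = c(0.8, 0.8, 0.4, 0.4), iptm = c(0.7, 0.3, 0.7, 0.3))
  both <- classify_high_confidence(conf, t_ptm = 0.5, t_iptm = 0.5)
  expect_equal(both$high_confidence, c(TRUE, FALSE, FALSE, FALSE))
  either <- classify_high_confidence(conf, 0.5, 0.5, any_metric = TRUE)
  expect_equal(either$high_confidence, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("clash filter applies the strict vdW-sum rule to inter-chain pairs", {
  mk <- function(d) {
    atoms <- tibble(role = c("bait", "prey"), chain = c("A", "B"),
                    residue_index = 1L, residue_name = "GLY",
                    atom_name = "CA", element = "C",
                    x = c(0, d), y = 0, z = 0) |>
      mutate(atom_id = sprintf("%s:1:CA:%d", role, dplyr::row_number()))
    tecapture:::new_complex_model("b", "p", atoms, 0.9, 0.9)
  }
  # two carbons: r = 1.70 each, so the limit is 3.40
  expect_length(clash_filter(mk(3.0)), 2)   # both atoms of the pair excluded
  expect_length(clash_filter(mk(3.5)), 0)
  expect_length(clash_filter(mk(3.4)), 0)   # strict inequality: touching kept

  for (seed in c(11, 12, 13)) {
    m <- random_complex(80, seed)
    expect_setequal(clash_filter(m), brute_clash(m))
    # symmetric under chain swap
    swapped <- m
    swapped$atoms$role <- ifelse(m$atoms$role == "bait", "prey", "bait")
    expect_setequal(sub("^[a-z]+", "", clash_filter(swapped)),
                    sub("^[a-z]+", "", clash_filter(m)))
  }
  bad <- mk(5); bad$atoms$element <- "Zz"
  expect_error(clash_filter(bad), "missing from radius table")
})

test_that("distance profiles take per-residue minima over non-excluded atoms", {
  atoms <- tibble(
    role = c("bait", "prey", "prey"), chain = c("A", "B", "B"),
    residue_index = c(1L, 1L, 2L), residue_name = "GLY",
    atom_name = "CA", element = "C",
    x = c(0, 3, 5), y = 0, z = 0) |>
    mutate(atom_id = sprintf("%s:%d:CA:%d", role, residue_index,
                             dplyr::row_number()))
  m <- tecapture:::new_complex_model("b", "p", atoms, 0.9, 0.9)
  expect_equal(min_distance_profile(m)$min_dist, 3.0)
  # nearest prey atom excluded as clashed -> minimum over the remaining
  expect_equal(min_distance_profile(m, excluded = atoms$atom_id[2])$min_dist,
               5.0)
  # all prey atoms excluded -> sentinel, with a warning
  expect_warning(
    prof <- min_distance_profile(m, excluded = atoms$atom_id[2:3]),
    "no contact")
  expect_true(is.na(prof$min_dist))

  for (seed in c(21, 22)) {
    m <- random_complex(60, seed)
    ex <- clash_filter(m)
    got <- min_distance_profile(m, ex)
    oracle <- brute_profile(m, ex)
    expect_equal(got$min_dist, oracle$min_dist, tolerance = 1e-12)
  }

  # removing a non-minimal prey atom never changes a residue minimum;
  # removing the minimal one never decreases it
  m <- random_complex(40, 31)
  base_prof <- min_distance_profile(m)
  prey_ids <- m$atoms$atom_id[m$atoms$role == "prey"]
  for (pid in prey_ids[1:5]) {
    dropped <- min_distance_profile(m, excluded = pid)
    expect_true(all(dropped$min_dist >= base_prof$min_dist - 1e-12,
                    na.rm = TRUE))
  }
})

test_that("geometry is invariant under rigid rotation and translation", {
  for (seed in c(41, 42)) {
    m <- random_complex(60, seed)
    mt <- rigid_transform(m, seed + 100)
    expect_setequal(clash_filter(m), clash_filter(mt))
    expect_equal(min_distance_profile(mt, clash_filter(mt))$min_dist,
                 min_distance_profile(m, clash_filter(m))$min_dist,
                 tolerance = 1e-6)
  }
})

test_that("domain contact summaries take per-domain medians and the argmin domain", {
  prof <- tibble(bait_id = "b", prey_id = "p",
                 residue_index = 1:20, residue_name = "GLY",
                 min_dist = c(rep(4, 10), rep(20, 10)))
  dm <- tibble(domain_label = c("HTH", "F-box"),
               start_res = c(1L, 11L), end_res = c(10L, 20L))
  s <- domain_contact_summary(prof, dm)
  expect_equal(s$preferred_domain, "HTH")
  expect_equal(s$per_domain$median_dist[s$per_domain$domain_label == "HTH"], 4)
  expect_equal(s$per_domain$median_dist[s$per_domain$domain_label == "F-box"], 20)

  # exact tie -> ambiguous
  tie <- domain_contact_summary(prof |> mutate(min_dist = 5), dm)
  expect_equal(tie$preferred_domain, "ambiguous")

  # odd/even residue counts: medians equal the sorted-middle rule
  set.seed(8)
  prof2 <- tibble(bait_id = "b", prey_id = "p", residue_index = 1:15,
                  residue_name = "GLY", min_dist = round(runif(15, 2, 30), 2))
  dm2 <- tibble(domain_label = c("A7", "B4"), start_res = c(1L, 8L),
                end_res = c(7L, 15L))
  s2 <- tidy(domain_contact_summary(prof2, dm2))
  mid <- function(v) { v <- sort(v); n <- length(v)
    if (n %% 2 == 1) v[(n + 1) / 2] else mean(v[n / 2 + 0:1]) }
  expect_equal(s2$median_dist[s2$domain_label == "A7"],
               mid(prof2$min_dist[1:7]))
  expect_equal(s2$median_dist[s2$domain_label == "B4"],
               mid(prof2$min_dist[8:15]))

  # unmapped residues fall under "other"; all-NA domain excluded with warning
  prof3 <- prof |> mutate(min_dist = replace(min_dist, 1:10, NA))
  expect_warning(s3 <- domain_contact_summary(prof3, dm), "no contact")
  expect_equal(s3$preferred_domain, "F-box")
})

test_that("screen reports recover planted contact domains per bait", {
  bench <- sim_benchmark_scores(n_pos = 40, n_neg = 60, pos_mean = 0.85,
                                neg_mean = 0.25, sd = 0.05, seed = 2)
  # two baits with disjoint planted contact domains, plus one low-confidence
  cx1 <- sim_complex("HTH", prey_offset = 4, bait_id = "baitA",
                     prey_id = "prey1", ptm = 0.9, iptm = 0.9, seed = 1)
  cx2 <- sim_complex("FTH", prey_offset = 5, bait_id = "baitB",
                     prey_id = "prey2", ptm = 0.88, iptm = 0.92, seed = 2)
  cx3 <- sim_complex("F-box", prey_offset = 4, bait_id = "baitA",
                     prey_id = "prey3", ptm = 0.1, iptm = 0.1, seed = 3)
  maps <- bind_rows(cx1$domain_map, cx2$domain_map |> # same layout per bait
                      mutate(bait_id = "baitB")) |> distinct()
  rep <- screen_report(list(cx1$model, cx2$model, cx3$model), bench, maps)
  expect_equal(nrow(rep$interactions), 3)
  expect_equal(sum(rep$interactions$high_confidence), 2)
  expect_equal(rep$baits$modal_domain[rep$baits$bait_id == "baitA"], "HTH")
  expect_equal(rep$baits$modal_domain[rep$baits$bait_id == "baitB"], "FTH")
  # low-confidence pair contributes no preferred domain
  expect_true(is.na(
    rep$interactions$preferred_domain[rep$interactions$prey_id == "prey3"]))

  # no high-confidence interactors: report still forms
  low <- sim_complex("HTH", bait_id = "baitZ", prey_id = "preyZ",
                     ptm = 0.01, iptm = 0.01, seed = 4)
  rep0 <- screen_report(list(low$model), bench, low$domain_map)
  expect_equal(sum(rep0$interactions$high_confidence), 0)
  expect_equal(rep0$baits$n_high_confidence, 0L)
  expect_true(is.na(rep0$baits$modal_domain))
})
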