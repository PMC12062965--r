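# Independent brute-force oracles and cheap random fixture builders.
# The oracles deliberately use naive loops / exhaustive enumeration and no
# package internals, so they stay independent of the code paths they check.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# ---- random fixtures --------------------------------------------------------

# vectorised random domain table; accession prefix encodes the category
random_domain_fixture <- function(n_proteins, seed,
                                  p_mc = 0.4, p_te = 0.3) {
  set.seed(seed)
  mc_pool <- sprintf("MC%03d", 1:12)
  te_pool <- sprintf("TE%03d", 1:12)
  other_pool <- sprintf("OT%03d", 1:20)
  sets <- bind_rows(
    tibble(accession = mc_pool, category = "multicopy"),
    tibble(accession = te_pool, category = "te_viral")) |>
    mutate(description = "fixture")
  prot <- tibble(protein_id = sprintf("P%05d", seq_len(n_proteins)),
                 taxon_id = sprintf("tax%02d", sample(1:6, n_proteins, TRUE)),
                 length = sample(300:900, n_proteins, TRUE))
  k <- sample(1:4, n_proteins, TRUE)
  rows <- tibble(
    protein_id = rep(prot$protein_id, k),
    accession = unlist(lapply(k, function(m) {
      pool <- c(sample(mc_pool, 2), sample(te_pool, 2), sample(other_pool, 3))
      sample(pool, m)
    })))
  rows <- rows |>
    left_join(prot, by = "protein_id") |>
    mutate(start = pmax(1L, as.integer(floor(runif(n()) * (length - 60)))),
           end = pmin(length, start + 49L)) |>
    distinct(protein_id, accession, start, end, .keep_all = TRUE) |>
    select(protein_id, taxon_id, length, accession, start, end)
  list(domains = as_domain_table(rows, sets), sets = sets)
}

random_benchmark <- function(n, seed) {
  set.seed(seed)
  tibble(pair_id = sprintf("p%03d", seq_len(n)),
         label = sample(c("interactor", "noninteractor"), n, TRUE,
                        prob = c(0.4, 0.6)),
         ptm = round(runif(n), 2),
         iptm = round(runif(n), 2))
}

# random two-chain complex in a tight box so clashes occur
random_complex <- function(n_atoms, seed, box = 12) {
  set.seed(seed)
  n_b <- max(2L, n_atoms %/% 2L)
  n_p <- max(2L, n_atoms - n_b)
  mk <- function(role, n) {
    tibble(role = role, chain = if (role == "bait") "A" else "B",
           residue_index = rep(seq_len(ceiling(n / 3)), each = 3)[seq_len(n)],
           residue_name = "GLY",
           atom_name = sample(c("CA", "CB", "N1", "O1"), n, TRUE),
           element = sample(c("C", "N", "O", "S"), n, TRUE),
           x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box))
  }
  atoms <- bind_rows(mk("bait", n_b), mk("prey", n_p)) |>
    mutate(across(c(x, y, z), ~ round(.x, 3)),
           atom_id = sprintf("%s:%d:%s:%d", role, residue_index, atom_name,
                             row_number()))
  tecapture:::new_complex_model("b1", "p1", atoms, 0.8, 0.8)
}

# random proper rotation + translation applied to every atom
rigid_transform <- function(model, seed) {
  set.seed(seed)
  qr_dec <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t_vec <- runif(3, -50, 50)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  model$atoms$x <- xyz[, 1] + t_vec[1]
  model$atoms$y <- xyz[, 2] + t_vec[2]
  model$atoms$z <- xyz[, 3] + t_vec[3]
  model
}

# ---- brute-force oracles ----------------------------------------------------

brute_screen <- function(domains) {
  ids <- unique(domains$protein_id)
  hits <- character()
  for (id in ids) {
    cats <- domains$category[domains$protein_id == id]
    if (any(cats == "multicopy") && any(cats == "te_viral")) hits <- c(hits, id)
  }
  sort(hits)
}

brute_te_partition <- function(domains) {
  hits <- brute_screen(domains)
  single <- multiple <- character()
  for (id in hits) {
    n_te <- length(unique(domains$accession[domains$protein_id == id &
                                              domains$category == "te_viral"]))
    if (n_te == 1) single <- c(single, id) else multiple <- c(multiple, id)
  }
  list(single = single, multiple = multiple)
}

brute_pair_groups <- function(domains) {
  hits <- brute_screen(domains)
  out <- list()
  for (id in hits) {
    mc <- unique(domains$accession[domains$protein_id == id &
                                     domains$category == "multicopy"])
    te <- unique(domains$accession[domains$protein_id == id &
                                     domains$category == "te_viral"])
    for (m in mc) for (t in te) {
      key <- paste(m, t, sep = "|")
      out[[key]] <- c(out[[key]], id)
    }
  }
  tibble(pair = names(out),
         n_members = unname(vapply(out, function(v) length(unique(v)),
                                   integer(1))))
}

brute_window_count <- function(genes, tes, scaffold_lengths, flank, cap) {
  counts <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    L <- scaffold_lengths$length[scaffold_lengths$scaffold == genes$scaffold[i]]
    ws <- max(0, genes$start[i] - flank)
    we <- min(L, genes$end[i] + flank)
    n <- 0L
    for (j in seq_len(nrow(tes))) {
      if (tes$scaffold[j] == genes$scaffold[i] &&
          tes$start[j] < we && tes$end[j] > ws) n <- n + 1L
    }
    counts[i] <- min(cap, n)
  }
  tibble(gene_id = genes$gene_id, n_te = counts)
}

brute_auc <- function(pos, neg) {
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

brute_ks_threshold <- function(pos, neg) {
  thr <- sort(unique(c(pos, neg)))
  D <- vapply(thr, function(t) mean(neg < t) - mean(pos < t), numeric(1))
  list(threshold = thr[which.max(D)], D = max(D))
}

brute_clash <- function(model, radii = vdw_radii()) {
  a <- model$atoms
  excluded <- character()
  for (i in which(a$role == "bait")) {
    for (j in which(a$role == "prey")) {
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                  (a$z[i] - a$z[j])^2)
      if (d < radii[[a$element[i]]] + radii[[a$element[j]]]) {
        excluded <- c(excluded, a$atom_id[i], a$atom_id[j])
      }
    }
  }
  sort(unique(excluded))
}

brute_profile <- function(model, excluded) {
  a <- model$atoms
  keep <- !(a$atom_id %in% excluded)
  res <- sort(unique(a$residue_index[a$role == "bait"]))
  out <- rep(NA_real_, length(res))
  for (r in seq_along(res)) {
    best <- Inf
    for (i in which(a$role == "bait" & a$residue_index == res[r] & keep)) {
      for (j in which(a$role == "prey" & keep)) {
        d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                    (a$z[i] - a$z[j])^2)
        best <- min(best, d)
      }
    }
    if (is.finite(best)) out[r] <- best
  }
  tibble(residue_index = res, min_dist = out)
}

# rank-then-Pearson Spearman, independent of stats::cor.test internals
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
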