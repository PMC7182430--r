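# Shared fixture builders: tiny in-code feature tables, PDB writers, and
# the brute-force deduplication oracle.

# minimal feature table; s / ctl are per-feature mean intensities
# replicated over 2 channels unless matrices are given
make_features <- function(mz, rt, s, ctl = rep(1, length(mz)),
                          id = sprintf("F%03d", seq_along(mz))) {
  data.frame(feature_id = id, mz = mz, rt_min = rt,
             sample_1 = s, sample_2 = s,
             control_1 = ctl, control_2 = ctl,
             stringsAsFactors = FALSE)
}

# PDB writer: atoms is a data.frame with x, y, z and optional element /
# residue; DUM rows mark leaflet planes like OPM files do
write_pdb_fixture <- function(path, atoms, dum_z = NULL) {
  fmt <- function(i, name, res, x, y, z, el) {
    sprintf("HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, name, res, i %% 10000, x, y, z, el)
  }
  lines <- character(0)
  k <- 0L
  for (i in seq_len(nrow(atoms))) {
    k <- k + 1L
    el <- if ("element" %in% names(atoms)) atoms$element[i] else "C"
    res <- if ("residue" %in% names(atoms)) atoms$residue[i] else "ALA"
    lines <- c(lines, fmt(k, el, res, atoms$x[i], atoms$y[i], atoms$z[i], el))
  }
  for (z in dum_z) {
    k <- k + 1L
    lines <- c(lines, fmt(k, "N", "DUM", 0, 0, z, "N"))
  }
  writeLines(c(lines, "END"), path)
  path
}

# ring of n carbon atoms at radius r in the z = plane slab
ring_atoms <- function(n, r, z) {
  th <- 2 * pi * (seq_len(n) - 0.5) / n
  data.frame(x = r * cos(th), y = r * sin(th), z = z, element = "C")
}

# ---- brute-force deduplication oracle -------------------------------
# Exhaustive fixpoint merger over all pairs, independent of the greedy
# pipeline implementation: first the isotope relation, then the
# adduct/dimer relation, each applied until no pair matches. Pair order
# is randomized to expose any order dependence. Returns the partition of
# feature ids (sorted member sets).
bruteforce_dedup <- function(features, cfg, shuffle_seed = 0) {
  n <- nrow(features)
  inten <- rowMeans(features[, grep("^sample_", names(features)), drop = FALSE])
  cluster <- as.list(seq_len(n))
  set.seed(shuffle_seed)
  tol <- function(mz) cfg$mz_tol_ppm * 1e-6 * mz
  # representative of a cluster: most intense member
  rep_of <- function(cl) cl[which.max(inten[cl])]
  merge_pass <- function(match_fun) {
    repeat {
      merged <- FALSE
      idx <- sample(seq_along(cluster))
      for (a in idx) for (b in sample(seq_along(cluster))) {
        if (a == b || a > length(cluster) || b > length(cluster)) next
        ra <- rep_of(cluster[[a]]); rb <- rep_of(cluster[[b]])
        if (match_fun(ra, rb)) {
          cluster[[a]] <<- c(cluster[[a]], cluster[[b]])
          cluster <<- cluster[-b]
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
  }
  iso <- function(ra, rb) {
    abs((features$mz[rb] - features$mz[ra]) - 1.0033548) <= tol(features$mz[rb]) &&
      abs(features$rt_min[rb] - features$rt_min[ra]) <= cfg$rt_tol_min &&
      inten[rb] / inten[ra] <= cfg$isotope_ratio_max
  }
  addim <- function(ra, rb) {
    if (abs(features$rt_min[rb] - features$rt_min[ra]) > cfg$rt_tol_min) return(FALSE)
    dm <- abs(features$mz[rb] - features$mz[ra])
    t <- tol(max(features$mz[ra], features$mz[rb]))
    abs(dm - 46.00547931) <= t ||
      abs(features$mz[rb] - (2 * features$mz[ra] + 1.00728)) <= t
  }
  environment(merge_pass) <- environment()
  merge_pass(iso)
  merge_pass(addim)
  parts <- lapply(cluster, function(cl) sort(features$feature_id[cl]))
  parts[order(vapply(parts, `[`, character(1), 1L))]
}

# partition of the pipeline's events, same normal form as the oracle
event_partition <- function(events) {
  parts <- lapply(strsplit(events$members, ";", fixed = TRUE), sort)
  parts[order(vapply(parts, `[`, character(1), 1L))]
}
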