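# Filtering cascade: control-enrichment, salt/solvent censoring, and
# collapse of redundant ion forms (isotopologues, alternate adducts,
# [2M-H]- dimers) into unique molecular events.

#' Filter configuration
#'
#' @param enrichment_fold Minimum mean sample / mean control intensity
#'   ratio (inclusive, "at least 10-fold").
#' @param pseudo_count Added to the control mean so features absent from
#'   the control do not divide by zero.
#' @param mz_tol_ppm m/z matching tolerance (ppm).
#' @param rt_tol_min Co-elution tolerance (minutes).
#' @param isotope_ratio_max Intensity ceiling for an M+1 isotopologue
#'   relative to its parent.
#' @param defect_slope Mass-defect censor: a feature is salt-like when its
#'   fractional mass is below `defect_slope x mz`.
#' @param salt_unit_masses Ladder spacings flagged as salt clusters
#'   (sodium formate, 67.98742 Da).
#' @param min_ladder_len Minimum chain length for a salt ladder.
#' @param censor_mz_range m/z window the censor analyzes; features outside
#'   pass through untouched.
#' @return Classed list of settings.
#' @export
filter_config <- function(enrichment_fold = 10, pseudo_count = 1,
                          mz_tol_ppm = 5, rt_tol_min = 0.1,
                          isotope_ratio_max = 0.6, defect_slope = 0.00045,
                          salt_unit_masses = 67.98742, min_ladder_len = 3L,
                          censor_mz_range = c(250, 1600)) {
  stopifnot(enrichment_fold >= 1, pseudo_count > 0, mz_tol_ppm > 0,
            rt_tol_min > 0, isotope_ratio_max > 0, defect_slope > 0,
            all(salt_unit_masses > 0), min_ladder_len >= 2L)
  structure(list(enrichment_fold = enrichment_fold,
                 pseudo_count = pseudo_count, mz_tol_ppm = mz_tol_ppm,
                 rt_tol_min = rt_tol_min,
                 isotope_ratio_max = isotope_ratio_max,
                 defect_slope = defect_slope,
                 salt_unit_masses = salt_unit_masses,
                 min_ladder_len = as.integer(min_ladder_len),
                 censor_mz_range = censor_mz_range),
            class = "filter_config")
}

.sample_cols <- function(tab) grep("^sample_", names(tab), value = TRUE)
.control_cols <- function(tab) grep("^control_", names(tab), value = TRUE)

.mean_intensity <- function(tab, cols) {
  if (length(cols) == 0L) stop("no intensity channels found")
  rowMeans(as.matrix(tab[, cols, drop = FALSE]))
}

.mz_tol <- function(mz, ppm) ppm * 1e-6 * mz

#' Enrichment filter against polymer-only controls
#'
#' Keeps a feature when its mean sample intensity is at least
#' `enrichment_fold` times the mean control intensity (a pseudo-count on
#' the control side guards features that are absent from the control).
#'
#' @param features Feature table (feature_id, mz, rt_min, sample_*,
#'   control_* columns).
#' @param cfg [filter_config()].
#' @return List: `kept` (features with an added `enrichment_ratio`
#'   column), `removed`, and `ratios` for all input features.
#' @export
enrichment_filter <- function(features, cfg = filter_config()) {
  s <- .mean_intensity(features, .sample_cols(features))
  ctl <- .mean_intensity(features, .control_cols(features))
  ratio <- s / (ctl + cfg$pseudo_count)
  keep <- ratio >= cfg$enrichment_fold
  kept <- features[keep, , drop = FALSE]
  kept$enrichment_ratio <- ratio[keep]
  list(kept = kept, removed = features[!keep, , drop = FALSE],
       ratios = ratio)
}

# Salt-cluster ladders: chains of >= min_len ions spaced by a repeat
# unit. A cluster family derives from one electrospray background
# species, so its members co-elute; the RT gate keeps coincidentally
# unit-spaced lipids (which elute according to their chain length) out.
.find_salt_ladders <- function(mz, rt, unit_masses, ppm, min_len, rt_tol) {
  n <- length(mz)
  in_ladder <- logical(n)
  if (n < min_len) return(in_ladder)
  ord <- order(mz)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  for (u in unit_masses) {
    for (a in seq_len(n - 1L)) {
      i <- ord[a]
      for (b in (a + 1L):n) {
        j <- ord[b]
        d <- mz[j] - mz[i]
        if (d > u + 1) break
        if (abs(d - u) <= .mz_tol(mz[j], ppm) &&
            abs(rt[j] - rt[i]) <= rt_tol) union2(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sizes <- table(roots)
  in_ladder <- sizes[as.character(roots)] >= min_len
  as.logical(in_ladder)
}

#' Censor salt clusters and solvent-like ions by mass defect
#'
#' Within the analyzed m/z window, a feature is censored when its
#' fractional mass falls below `defect_slope x mz` (inorganic clusters
#' have anomalously low mass defects for their size) or when it belongs
#' to a ladder of at least `min_ladder_len` features spaced by a salt
#' repeat unit. Features outside the window pass through untouched.
#'
#' @inheritParams enrichment_filter
#' @return List: `kept`, `censored`, `reasons` (character per censored
#'   feature: "low_defect", "salt_ladder", or both).
#' @export
mass_defect_censor <- function(features, cfg = filter_config()) {
  mz <- features$mz
  in_range <- mz >= cfg$censor_mz_range[1] & mz <= cfg$censor_mz_range[2]
  frac <- mz - floor(mz)
  low_defect <- in_range & (frac < cfg$defect_slope * mz)
  ladder <- logical(length(mz))
  if (any(in_range)) {
    ladder[in_range] <- .find_salt_ladders(mz[in_range],
                                           features$rt_min[in_range],
                                           cfg$salt_unit_masses,
                                           cfg$mz_tol_ppm,
                                           cfg$min_ladder_len,
                                           cfg$rt_tol_min)
  }
  censor <- low_defect | ladder
  reasons <- character(sum(censor))
  if (any(censor)) {
    reasons <- paste0(ifelse(low_defect[censor], "low_defect", ""),
                      ifelse(low_defect[censor] & ladder[censor], "+", ""),
                      ifelse(ladder[censor], "salt_ladder", ""))
  }
  list(kept = features[!censor, , drop = FALSE],
       censored = features[censor, , drop = FALSE],
       reasons = reasons)
}

# canonical deterministic processing order: descending mean sample
# intensity, ties by ascending m/z -- makes greedy collapse independent
# of input row order
.canonical_order <- function(features) {
  s <- .mean_intensity(features, .sample_cols(features))
  order(-s, features$mz)
}

.empty_events <- function() {
  data.frame(event_id = character(0), feature_id = character(0),
             mz = numeric(0), rt_min = numeric(0),
             intensity = numeric(0), members = character(0),
             n_members = integer(0), flags = character(0),
             stringsAsFactors = FALSE)
}

#' Collapse M+1 isotopologues into molecular events
#'
#' Greedy merge in descending intensity order: feature B is absorbed into
#' A when m/z(B) - m/z(A) matches +1.0033548 within tolerance, the two
#' co-elute within `rt_tol_min`, and B is at most `isotope_ratio_max`
#' times as intense as A.
#'
#' @inheritParams enrichment_filter
#' @return `molecular_events` data.frame: one row per event with the
#'   representative feature's id/mz/rt/mean intensity, a
#'   semicolon-joined `members` list and provenance `flags`.
#' @export
collapse_isotopes <- function(features, cfg = filter_config()) {
  n <- nrow(features)
  if (n == 0L) return(.empty_events())
  ord <- .canonical_order(features)
  f <- features[ord, , drop = FALSE]
  inten <- .mean_intensity(f, .sample_cols(f))
  assigned <- rep(NA_integer_, n)   # index of the absorbing representative
  for (a in seq_len(n)) {
    if (!is.na(assigned[a])) next
    assigned[a] <- a
    for (b in seq_len(n)) {
      if (b == a || !is.na(assigned[b])) next
      dm <- f$mz[b] - f$mz[a]
      if (abs(dm - .C13_DELTA) <= .mz_tol(f$mz[b], cfg$mz_tol_ppm) &&
          abs(f$rt_min[b] - f$rt_min[a]) <= cfg$rt_tol_min &&
          inten[b] / inten[a] <= cfg$isotope_ratio_max) {
        assigned[b] <- a
      }
    }
  }
  reps <- sort(unique(assigned))
  ev <- do.call(rbind, lapply(reps, function(r) {
    mem <- which(assigned == r)
    data.frame(event_id = NA_character_, feature_id = f$feature_id[r],
               mz = f$mz[r], rt_min = f$rt_min[r], intensity = inten[r],
               members = paste(f$feature_id[mem], collapse = ";"),
               n_members = length(mem),
               flags = if (length(mem) > 1L) "isotopes_collapsed" else "",
               stringsAsFactors = FALSE)
  }))
  ev <- ev[order(-ev$intensity, ev$mz), , drop = FALSE]
  ev$event_id <- sprintf("E%04d", seq_len(nrow(ev)))
  rownames(ev) <- NULL
  class(ev) <- c("molecular_events", "data.frame")
  ev
}

#' Collapse alternate adducts and remove dimers
#'
#' Co-eluting events whose m/z difference matches a registered adduct
#' spacing (formic acid, 46.00548 Da, for [M+HCOO]- vs [M-H]-) are
#' merged; the lower-m/z ([M-H]-) form becomes the representative.
#' Events at 2 x m/z(parent) + 1.00728 co-eluting with their parent are
#' absorbed as [2M-H]- dimers.
#'
#' @param events Output of [collapse_isotopes()].
#' @param cfg [filter_config()].
#' @return Reduced `molecular_events` data.frame.
#' @export
collapse_adducts_dimers <- function(events, cfg = filter_config()) {
  if (nrow(events) == 0L) return(events)
  ev <- events[order(-events$intensity, events$mz), , drop = FALSE]
  n <- nrow(ev)
  alive <- rep(TRUE, n)
  absorbed_into <- rep(NA_integer_, n)
  adduct_deltas <- .FORMIC_ACID_MASS
  for (a in seq_len(n)) {
    if (!alive[a]) next
    for (b in seq_len(n)) {
      if (b == a || !alive[b]) next
      if (abs(ev$rt_min[b] - ev$rt_min[a]) > cfg$rt_tol_min) next
      dm <- abs(ev$mz[b] - ev$mz[a])
      tol <- .mz_tol(max(ev$mz[a], ev$mz[b]), cfg$mz_tol_ppm)
      if (any(abs(dm - adduct_deltas) <= tol)) {
        alive[b] <- FALSE; absorbed_into[b] <- a
        ev$flags[a] <- paste0(ev$flags[a],
                              if (nzchar(ev$flags[a])) "+", "adduct_merged")
      } else if (abs(ev$mz[b] - (2 * ev$mz[a] + 1.00728)) <= tol) {
        alive[b] <- FALSE; absorbed_into[b] <- a
        ev$flags[a] <- paste0(ev$flags[a],
                              if (nzchar(ev$flags[a])) "+", "dimer_removed")
      }
    }
  }
  # fold members into absorbers; representative = lowest-m/z surviving form
  for (b in which(!alive)) {
    a <- absorbed_into[b]
    while (!alive[a]) a <- absorbed_into[a]
    ev$members[a] <- paste(ev$members[a], ev$members[b], sep = ";")
    ev$n_members[a] <- ev$n_members[a] + ev$n_members[b]
    # adduct merge: canonical representative is the lower-m/z form
    # (the [M-H]- ion); dimers never take over representation
    dm <- abs(ev$mz[b] - ev$mz[a])
    if (any(abs(dm - adduct_deltas) <=
            .mz_tol(max(ev$mz[a], ev$mz[b]), cfg$mz_tol_ppm)) &&
        ev$mz[b] < ev$mz[a]) {
      ev$mz[a] <- ev$mz[b]; ev$feature_id[a] <- ev$feature_id[b]
      ev$rt_min[a] <- ev$rt_min[b]
    }
  }
  out <- ev[alive, , drop = FALSE]
  out <- out[order(-out$intensity, out$mz), , drop = FALSE]
  out$event_id <- sprintf("E%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  class(out) <- c("molecular_events", "data.frame")
  out
}

#' Run the full filtering cascade
#'
#' Stages in order: control-enrichment, salt/solvent censoring, isotope
#' collapse, adduct/dimer collapse. The audit records the population at
#' each stage; counts are monotone non-increasing and kept + removed
#' equals the stage input everywhere.
#'
#' @param table Feature table.
#' @param cfg [filter_config()].
#' @return List: `events` (molecular events), `audit` (named counts:
#'   input, enriched, after_censor, after_dedup), and the per-stage
#'   intermediates (`enrichment`, `censor`).
#' @export
filter_pipeline <- function(table, cfg = filter_config()) {
  audit <- c(input = nrow(table))
  if (nrow(table) == 0L) {
    return(list(events = .empty_events(),
                audit = c(input = 0L, enriched = 0L, after_censor = 0L,
                          after_dedup = 0L),
                enrichment = NULL, censor = NULL))
  }
  enr <- enrichment_filter(table, cfg)
  audit["enriched"] <- nrow(enr$kept)
  cen <- mass_defect_censor(enr$kept, cfg)
  audit["after_censor"] <- nrow(cen$kept)
  ev <- collapse_isotopes(cen$kept, cfg)
  ev <- collapse_adducts_dimers(ev, cfg)
  audit["after_dedup"] <- nrow(ev)
  list(events = ev, audit = audit, enrichment = enr, censor = cen)
}

#' Score a filtering run against planted ground truth
#'
#' Sensitivity is the fraction of true species whose lead ion survives
#' inside some molecular event; artifact leakage is the fraction of
#' surviving events that contain no lead ion at all, i.e. events built
#' purely from planted artifacts or background.
#'
#' @param events Molecular events from [filter_pipeline()].
#' @param table Feature table carrying `true_role` / `species_id` truth
#'   columns.
#' @return List: `sensitivity`, `leakage`, `n_true`, `n_events`.
#' @export
score_against_truth <- function(events, table) {
  if (!"true_role" %in% names(table)) stop("table carries no ground truth")
  leads <- table$feature_id[table$true_role == "lead"]
  members <- strsplit(events$members, ";", fixed = TRUE)
  has_lead <- vapply(members, function(m) any(m %in% leads), logical(1))
  recovered <- sum(leads %in% unlist(members))
  list(sensitivity = recovered / length(leads),
       leakage = if (nrow(events)) sum(!has_lead) / nrow(events) else 0,
       n_true = length(leads), n_events = nrow(events))
}
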