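# Synthetic HPLC-ESI-QToF feature tables with known ground truth.
# Emulates the SMALP lipidomics experiment: true lipid ions of the yeast
# plasma-membrane classes with class-dependent reversed-phase retention,
# log-normal replicate noise, planted isotopologues / alternate adducts /
# [2M-H]- dimers, sodium-formate salt ladders and solvent background in
# both channels.

#' Simulation configuration
#'
#' @param n_replicates Sample channels (paper design: 3 independent
#'   purifications).
#' @param control_channels Polymer-only control channels (3).
#' @param noise_cv Coefficient of variation of log-normal multiplicative
#'   replicate noise (0.10 is typical QToF scatter).
#' @param enrichment_min,enrichment_max Range of the per-species
#'   sample/control enrichment factor (uniform draw; true lipid ions are
#'   at least `enrichment_min`-fold enriched before noise).
#' @param gradient_span_min Chromatographic run length in minutes (20 min
#'   gradient).
#' @param response_per_pmol Peak-intensity response factor (counts per
#'   pmol), one global value.
#' @param adduct_fraction Intensity of a planted alternate adduct relative
#'   to its lead ion.
#' @param dimer_fraction Intensity of a planted [2M-H]- dimer relative to
#'   its parent (dimers are planted for the top intensity decile only).
#' @return Classed list of settings.
#' @export
sim_config <- function(n_replicates = 3L, control_channels = 3L,
                       noise_cv = 0.10, enrichment_min = 50,
                       enrichment_max = 500, gradient_span_min = 20,
                       response_per_pmol = 2e5, adduct_fraction = 0.25,
                       dimer_fraction = 0.05) {
  stopifnot(n_replicates >= 1L, control_channels >= 1L, noise_cv >= 0,
            enrichment_min >= 1, enrichment_max >= enrichment_min,
            gradient_span_min > 0, response_per_pmol > 0)
  structure(list(n_replicates = as.integer(n_replicates),
                 control_channels = as.integer(control_channels),
                 noise_cv = noise_cv, enrichment_min = enrichment_min,
                 enrichment_max = enrichment_max,
                 gradient_span_min = gradient_span_min,
                 response_per_pmol = response_per_pmol,
                 adduct_fraction = adduct_fraction,
                 dimer_fraction = dimer_fraction),
            class = "sim_config")
}

# class-specific retention offsets (arbitrary but fixed); retention is
# linear in acyl carbons (+) and double bonds (-), the reversed-phase C18
# trend, then scaled into the gradient span
.RT_CLASS_OFFSET <- c(PC = 2.0, PE = 2.5, PS = 1.5, PI = 1.0, PG = 2.0,
                      PA = 2.2, CL = 6.0, DAG = 5.0, IPC = 3.0,
                      MIPC = 2.5, ERG = 8.0)

.species_rt <- function(class, carbons, double_bonds, span) {
  carbons <- ifelse(is.na(carbons), 28, carbons)
  double_bonds <- ifelse(is.na(double_bonds), 0, double_bonds)
  raw <- .RT_CLASS_OFFSET[class] + 0.25 * carbons - 0.6 * double_bonds
  pmin(pmax(raw * span / 24, 0.2), span - 0.2)
}

#' Default true lipid composition (mol%)
#'
#' Mirrors the reported yeast periprotein lipidome: PC ~40%, PI ~20%,
#' PE ~18%, PS ~16%, ergosterol ~4% with minor PG/PA/CL, plus small
#' sphingolipid (IPC/MIPC) and DAG fractions.
#'
#' @return Named numeric vector summing to 100.
#' @export
default_composition <- function() {
  c(PC = 37, PI = 18.5, PE = 16.5, PS = 15, ERG = 4, PG = 1, PA = 1,
    CL = 1, DAG = 2, IPC = 2, MIPC = 2)
}

#' Generate a ground-truth lipid panel
#'
#' Draws `n_species` distinct lipid species from the theoretical library
#' with class probabilities proportional to `composition`, assigns each a
#' true abundance (pmol, log-normal) and a sample/control enrichment
#' factor. Deterministic for a fixed seed.
#'
#' @param seed Integer RNG seed.
#' @param n_species Number of true species.
#' @param composition Named class -> mol% map (must sum to ~100).
#' @param cfg [sim_config()].
#' @param library Theoretical library; defaults to [build_library()].
#' @return `ground_truth` list: `species` data.frame (species_id, class,
#'   carbons, double_bonds, adduct, mz, rt, pmol, enrichment), `seed`,
#'   `cfg`.
#' @export
generate_ground_truth <- function(seed, n_species = 50L,
                                  composition = default_composition(),
                                  cfg = sim_config(),
                                  library = build_library()) {
  if (abs(sum(composition) - 100) > 1) {
    stop("composition must sum to ~100 mol%")
  }
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  # lead-adduct entries only: first configured adduct per class
  lead_adduct <- vapply(library_config()$adducts, `[`, character(1), 1L)
  lead <- library[library$adduct == lead_adduct[library$class], , drop = FALSE]
  lead <- lead[lead$class %in% names(composition), , drop = FALSE]
  if (n_species > nrow(lead)) {
    stop("n_species exceeds library size (", nrow(lead), ")")
  }
  withr_seed({
    w <- composition[lead$class]
    # weight within class is uniform; classes weighted by composition
    w <- w / ave(rep(1, nrow(lead)), lead$class, FUN = sum)
    idx <- sample.int(nrow(lead), n_species, prob = w)
    sp <- lead[idx, , drop = FALSE]
    sp$species_id <- sprintf("S%03d", seq_len(n_species))
    sp$rt <- .species_rt(sp$class, sp$carbons, sp$double_bonds,
                         cfg$gradient_span_min)
    # pmol scaled so that summed class abundances follow composition
    sp$pmol <- as.numeric(composition[sp$class]) / 10 *
      stats::rlnorm(n_species, 0, 0.5)
    sp$enrichment <- stats::runif(n_species, cfg$enrichment_min,
                                  cfg$enrichment_max)
    rownames(sp) <- NULL
    structure(list(species = sp, seed = as.integer(seed), cfg = cfg),
              class = "ground_truth")
  })
}

.lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.new_feature_row <- function(mz, rt, sample, control, role, parent, species) {
  d <- data.frame(mz = mz, rt_min = rt, stringsAsFactors = FALSE)
  for (i in seq_along(sample)) d[[paste0("sample_", i)]] <- sample[i]
  for (i in seq_along(control)) d[[paste0("control_", i)]] <- control[i]
  d$true_role <- role
  d$parent_species <- parent
  d$species_id <- species
  d
}

#' Render a feature table from ground truth
#'
#' Every true species contributes its monoisotopic lead ion at the library
#' m/z plus redundant forms: the M+1 isotopologue at +1.0033548 Da with
#' intensity fraction 0.0108 x nC, a co-eluting [M+HCOO]- alternate
#' adduct for the anionic ([M-H]-) classes,
#' and, for the top intensity decile, a [2M-H]- dimer at
#' 2 x m/z + 1.00728. Replicate intensities carry log-normal noise;
#' control channels are the sample signal divided by the species'
#' enrichment factor.
#'
#' @param truth [generate_ground_truth()] output.
#' @param cfg [sim_config()]; defaults to the one stored in `truth`.
#' @return `feature_table` data.frame: feature_id, mz, rt_min,
#'   sample_1..n, control_1..m, plus truth columns `true_role`
#'   (lead/isotope/adduct/dimer), `parent_species`, `species_id`.
#' @export
render_features <- function(truth, cfg = truth$cfg) {
  stopifnot(inherits(truth, "ground_truth"))
  sp <- truth$species
  set.seed(truth$seed + 1L)
  # anionic classes pick up a formate adduct alongside [M-H]-; the
  # zwitterionic/neutral classes (PC, DAG) only ever form the formate
  # ion, and protonated ergosterol has no negative-mode counterpart
  alt_adduct <- c("[M-H]-" = "[M+HCOO]-")
  rows <- vector("list", 0L)
  base <- sp$pmol * cfg$response_per_pmol
  dimer_cut <- stats::quantile(base, 0.9)
  for (i in seq_len(nrow(sp))) {
    nC <- parse_formula(sp$formula[i])[["C"]]
    s_lead <- base[i] * .lognormal_noise(cfg$n_replicates, cfg$noise_cv)
    c_lead <- base[i] / sp$enrichment[i] *
      .lognormal_noise(cfg$control_channels, cfg$noise_cv)
    rows[[length(rows) + 1L]] <- .new_feature_row(
      sp$mz[i], sp$rt[i], s_lead, c_lead, "lead", sp$species_id[i],
      sp$species_id[i])
    # M+1 isotopologue, first-order 13C binomial
    iso_frac <- 0.0108 * nC
    rows[[length(rows) + 1L]] <- .new_feature_row(
      sp$mz[i] + .C13_DELTA, sp$rt[i] + 0.01,
      s_lead * iso_frac, c_lead * iso_frac, "isotope",
      sp$species_id[i], NA_character_)
    # co-eluting alternate adduct (negative-mode classes only)
    if (sp$adduct[i] %in% names(alt_adduct)) {
      neutral <- monoisotopic_mass(sp$formula[i])
      amz <- ionize(neutral, alt_adduct[[sp$adduct[i]]])
      rows[[length(rows) + 1L]] <- .new_feature_row(
        amz, sp$rt[i] + 0.02, s_lead * cfg$adduct_fraction,
        c_lead * cfg$adduct_fraction, "adduct", sp$species_id[i],
        NA_character_)
      # [2M-H]- dimer for the brightest decile
      if (base[i] >= dimer_cut && sp$adduct[i] == "[M-H]-") {
        rows[[length(rows) + 1L]] <- .new_feature_row(
          2 * sp$mz[i] + 1.00728, sp$rt[i] + 0.01,
          s_lead * cfg$dimer_fraction, c_lead * cfg$dimer_fraction,
          "dimer", sp$species_id[i], NA_character_)
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab <- cbind(feature_id = sprintf("F%04d", seq_len(nrow(tab))), tab,
               stringsAsFactors = FALSE)
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Add salt ladders and solvent background
#'
#' Salt ladders are chains of at least three ions spaced by exactly
#' 67.98742 Da (sodium formate); solvent ions appear in sample and
#' control channels at comparable intensity, so the enrichment filter
#' removes them.
#'
#' @param table [render_features()] output (or empty `feature_table`).
#' @param seed RNG seed for the contaminant draw.
#' @param n_salt_ladders Number of ladders.
#' @param n_solvent Number of solvent background ions.
#' @param cfg [sim_config()].
#' @return Feature table with contaminant rows appended and feature ids
#'   reassigned; contaminants carry `true_role` "salt" / "solvent".
#' @export
add_contaminants <- function(table, seed, n_salt_ladders = 4L,
                             n_solvent = 12L, cfg = sim_config()) {
  stopifnot(n_salt_ladders >= 0L, n_solvent >= 0L)
  if (n_salt_ladders == 0L && n_solvent == 0L) return(table)
  set.seed(seed + 2L)
  rows <- list()
  for (k in seq_len(n_salt_ladders)) {
    start <- stats::runif(1, 260, 700)
    # salt clusters sit at low mass defect
    start <- floor(start) + stats::runif(1, 0.0, 0.12)
    len <- sample(3:6, 1)
    rt <- stats::runif(1, 0.3, cfg$gradient_span_min - 0.3)
    inten <- stats::rlnorm(1, log(5e5), 0.3)
    for (j in seq_len(len) - 1L) {
      s <- inten * .lognormal_noise(cfg$n_replicates, cfg$noise_cv)
      ctl <- inten * stats::runif(1, 0.7, 1.4) *
        .lognormal_noise(cfg$control_channels, cfg$noise_cv)
      rows[[length(rows) + 1L]] <- .new_feature_row(
        start + j * .SODIUM_FORMATE_MASS, rt, s, ctl,
        "salt", NA_character_, NA_character_)
    }
  }
  for (k in seq_len(n_solvent)) {
    mz <- stats::runif(1, 260, 1200)
    mz <- floor(mz) + stats::runif(1, 0.2, 0.9)
    inten <- stats::rlnorm(1, log(3e5), 0.5)
    s <- inten * .lognormal_noise(cfg$n_replicates, cfg$noise_cv)
    ctl <- inten * stats::runif(1, 0.7, 1.4) *
      .lognormal_noise(cfg$control_channels, cfg$noise_cv)
    rows[[length(rows) + 1L]] <- .new_feature_row(
      mz, stats::runif(1, 0.3, cfg$gradient_span_min - 0.3), s, ctl,
      "solvent", NA_character_, NA_character_)
  }
  extra <- do.call(rbind, rows)
  out <- rbind(table[, setdiff(names(table), "feature_id"), drop = FALSE],
               extra)
  out <- cbind(feature_id = sprintf("F%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Simulate a full SMALP lipidomics experiment
#'
#' Ground truth, rendered redundant ion forms, and contaminant background
#' in one call.
#'
#' @inheritParams generate_ground_truth
#' @inheritParams add_contaminants
#' @return List with `table` (feature table including truth columns) and
#'   `truth` (the ground-truth object).
#' @export
simulate_experiment <- function(seed, n_species = 50L,
                                composition = default_composition(),
                                cfg = sim_config(), n_salt_ladders = 4L,
                                n_solvent = 12L,
                                library = build_library()) {
  truth <- generate_ground_truth(seed, n_species, composition, cfg, library)
  tab <- render_features(truth, cfg)
  tab <- add_contaminants(tab, seed, n_salt_ladders, n_solvent, cfg)
  list(table = tab, truth = truth)
}

#' Simulate a standard series
#'
#' External series: areas from the spike grid only. Standard-addition
#' series: the endogenous analyte contributes to every point, so the
#' response line is area = slope x (spike + endogenous).
#'
#' @param kind "external" or "addition".
#' @param true_endogenous Endogenous concentration (pmol/ul), addition
#'   kind only.
#' @param slope Response factor (area per pmol/ul).
#' @param noise_cv CV of multiplicative log-normal area noise.
#' @param seed RNG seed.
#' @param spikes Spike grid (pmol/ul). The phospholipid protocol uses
#'   0, 0.5, 1.0, 1.5, 2.0; ergosterol uses 0, 1, 3, 5
#'   (`spikes = ergosterol_spike_grid()`).
#' @return `standard_series` data.frame: conc_pmol_per_ul, area; with
#'   attribute `kind`.
#' @export
simulate_standard_series <- function(kind = c("external", "addition"),
                                     true_endogenous = 0, slope = 200,
                                     noise_cv = 0, seed = 1L,
                                     spikes = c(0, 0.5, 1.0, 1.5, 2.0)) {
  kind <- match.arg(kind)
  if (slope <= 0) stop("slope must be positive")
  if (noise_cv < 0) stop("negative noise_cv")
  set.seed(seed)
  endog <- if (kind == "addition") true_endogenous else 0
  area <- slope * (spikes + endog) * .lognormal_noise(length(spikes), noise_cv)
  out <- data.frame(conc_pmol_per_ul = spikes, area = area)
  attr(out, "kind") <- kind
  class(out) <- c("standard_series", "data.frame")
  out
}

#' @rdname simulate_standard_series
#' @export
ergosterol_spike_grid <- function() c(0, 1, 3, 5)

#' Simulate sphingolipid/ergosterol peak areas for two membrane domains
#'
#' Generates triplicate IPC, MIPC and ergosterol peak areas for an
#' MCP-like group and an MCC-like group in which the true
#' sphingolipid/ergosterol ratio is `fold`-times lower. Used to test
#' recovery of the domain fold change.
#'
#' @param seed RNG seed.
#' @param fold True MCP/MCC ratio fold change.
#' @param cv Replicate CV.
#' @param n Replicates per group.
#' @return List of two data.frames (`mcp`, `mcc`) with columns ipc, mipc,
#'   erg.
#' @export
simulate_domain_ratios <- function(seed, fold = 4, cv = 0.10, n = 3L) {
  set.seed(seed)
  erg_area <- 1e6
  ipc_ratio_mcp <- 0.8
  mipc_ratio_mcp <- 0.5
  grp <- function(ipc_r, mipc_r) {
    data.frame(
      ipc = erg_area * ipc_r * .lognormal_noise(n, cv),
      mipc = erg_area * mipc_r * .lognormal_noise(n, cv),
      erg = erg_area * .lognormal_noise(n, cv))
  }
  list(mcp = grp(ipc_ratio_mcp, mipc_ratio_mcp),
       mcc = grp(ipc_ratio_mcp / fold, mipc_ratio_mcp / fold))
}

#' Write a feature table and its ground truth
#'
#' The CSV keeps only the measurement columns (feature_id, mz, rt_min,
#' sample/control channels); the truth sidecar (JSON) records roles and
#' parents for test oracles.
#'
#' @param table Feature table.
#' @param path CSV path.
#' @param truth_path Optional JSON sidecar path.
#' @return Invisibly, the CSV path.
#' @export
write_feature_table <- function(table, path, truth_path = NULL) {
  meas <- c("feature_id", "mz", "rt_min",
            grep("^(sample|control)_", names(table), value = TRUE))
  utils::write.csv(table[, meas, drop = FALSE], path, row.names = FALSE)
  if (!is.null(truth_path)) {
    truth_cols <- intersect(c("feature_id", "true_role", "parent_species",
                              "species_id"), names(table))
    jsonlite::write_json(table[, truth_cols, drop = FALSE], truth_path,
                         dataframe = "rows", na = "null")
  }
  invisible(path)
}
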