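# Homolog-series grouping (Kendrick-style CH2/H2 ladders) and
# accurate-mass identification of molecular events against the
# theoretical lipid library.

#' Kendrick coordinates of an ion
#'
#' Kendrick mass rescales m/z by 14 / 14.015650 so that CH2 homologs
#' share an identical Kendrick mass defect; plotting KMD against nominal
#' mass lines up chain-length series horizontally.
#'
#' @param mz m/z value(s), > 0.
#' @return data.frame with `kendrick_mass` and `kendrick_mass_defect`.
#' @examples
#' kendrick_coordinates(835.5342)
#' @export
kendrick_coordinates <- function(mz) {
  if (any(mz <= 0)) stop("m/z must be positive")
  km <- mz * 14 / .CH2_MASS
  data.frame(kendrick_mass = km, kendrick_mass_defect = km - floor(km))
}

#' Group molecular events into homolog series
#'
#' Builds an undirected graph with an edge between two events whose mass
#' difference matches k x CH2 + j x H2 (k = 0..10, |j| <= 6, not both
#' zero) within tolerance, provided their retention order is consistent
#' with the chain-length difference (more carbons elute later on a
#' reversed-phase column). Connected components are the series: lipids
#' sharing a head group with chain-length and unsaturation variants.
#'
#' @param events Molecular events (`mz`, `rt_min`, `event_id` columns).
#' @param mz_tol_ppm Mass tolerance (ppm).
#' @param rt_window Retention slack (minutes) allowed against the
#'   expected elution order.
#' @return List of `series_group` lists: `members` (event ids, by
#'   ascending m/z), `base` (lowest-mass member), `n`.
#' @export
group_series <- function(events, mz_tol_ppm = 5, rt_window = 0.1) {
  n <- nrow(events)
  if (n == 0L) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  steps <- expand.grid(k = 0:10, j = -6:6)
  steps <- steps[!(steps$k == 0 & steps$j == 0) & steps$k + steps$j >= 0, ]
  deltas <- steps$k * .CH2_MASS + steps$j * .H2_MASS
  pos <- deltas > 0
  steps <- steps[pos, ]; deltas <- deltas[pos]
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      light <- if (events$mz[a] <= events$mz[b]) a else b
      heavy <- if (light == a) b else a
      dm <- events$mz[heavy] - events$mz[light]
      tol <- .mz_tol(events$mz[heavy], mz_tol_ppm)
      hit <- which(abs(deltas - dm) <= tol)
      if (length(hit) == 0L) next
      k <- steps$k[hit[1]]
      # retention consistency: adding carbons (or saturating) must not
      # make the species elute earlier
      if (k >= 1 || steps$j[hit[1]] >= 1) {
        if (events$rt_min[heavy] < events$rt_min[light] - rt_window) next
      }
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(unique(roots), function(r) {
    mem <- which(roots == r)
    mem <- mem[order(events$mz[mem])]
    list(members = events$event_id[mem],
         base = events$event_id[mem[1]], n = length(mem))
  })
}

#' Identify molecular events by accurate mass
#'
#' Matches each event's representative m/z against the theoretical
#' library within a ppm tolerance. The best match (minimum absolute ppm
#' error) is reported as `identified`; candidates indistinguishable from
#' the best match (within 0.01 ppm, far below instrument resolution) are
#' reported as `ambiguous` with all candidates listed, ordered by class
#' priority PC > PE > PS > PI > PG > PA > CL > DAG > IPC > MIPC
#' (descending reported abundance); events with no match are
#' `unidentified`. Note that PC formate adducts are exactly isobaric
#' with the PS species three carbons up and one double bond down (the
#' ion compositions coincide), a known negative-mode overlap that
#' accurate mass alone cannot resolve; such events are always
#' ambiguous, with both candidates reported.
#'
#' @param events Molecular events.
#' @param library Theoretical library from [build_library()].
#' @param mz_tol_ppm Tolerance (default 5 ppm, covering the 0.2-3.5 ppm
#'   spread between measured and theoretical lead-ion masses).
#' @return `annotations` data.frame: event_id, mz, class, carbons,
#'   double_bonds, adduct, ppm, status, candidates.
#' @export
identify_species <- function(events, library = build_library(),
                             mz_tol_ppm = 5) {
  if (nrow(library) == 0L) stop("empty library")
  class_priority <- c("PC", "PE", "PS", "PI", "PG", "PA", "CL", "DAG",
                      "IPC", "MIPC", "ERG")
  out <- lapply(seq_len(nrow(events)), function(i) {
    mz <- events$mz[i]
    ppm <- ppm_error(mz, library$mz)
    hits <- which(abs(ppm) <= mz_tol_ppm)
    base <- data.frame(event_id = events$event_id[i], mz = mz,
                       class = NA_character_, carbons = NA_integer_,
                       double_bonds = NA_integer_, adduct = NA_character_,
                       ppm = NA_real_, status = "unidentified",
                       candidates = "", stringsAsFactors = FALSE)
    if (length(hits) == 0L) return(base)
    best_abs <- min(abs(ppm[hits]))
    # candidates indistinguishable from the best match; ordered by
    # class priority so exact isobars resolve deterministically
    ties <- hits[abs(ppm[hits]) - best_abs <= 0.01]
    ties <- ties[order(match(library$class[ties], class_priority),
                       abs(ppm[ties]))]
    best <- ties[1]
    base$class <- library$class[best]
    base$carbons <- library$carbons[best]
    base$double_bonds <- library$double_bonds[best]
    base$adduct <- library$adduct[best]
    base$ppm <- ppm[best]
    if (length(ties) > 1L) {
      base$status <- "ambiguous"
      base$candidates <- paste(sprintf("%s %d:%d %s", library$class[ties],
                                       library$carbons[ties],
                                       library$double_bonds[ties],
                                       library$adduct[ties]),
                               collapse = "|")
    } else {
      base$status <- "identified"
    }
    base
  })
  ann <- do.call(rbind, out)
  class(ann) <- c("annotations", "data.frame")
  ann
}

#' Targeted search for low-intensity species
#'
#' Rescue mode for species (such as IPC/MIPC) missed by the untargeted
#' cascade: looks for features matching user-supplied target m/z values
#' within tolerance, regardless of intensity filters.
#'
#' @param features Feature table.
#' @param target_mz Numeric vector of target m/z values (named vectors
#'   keep their names in the output).
#' @param mz_tol_ppm Tolerance (ppm).
#' @param rt_range Optional two-element retention window (minutes).
#' @return data.frame of matching features with `target` and `ppm`
#'   columns; zero rows when nothing matches.
#' @export
targeted_search <- function(features, target_mz, mz_tol_ppm = 5,
                            rt_range = NULL) {
  nm <- names(target_mz)
  if (is.null(nm)) nm <- sprintf("target_%g", target_mz)
  hits <- lapply(seq_along(target_mz), function(k) {
    ppm <- ppm_error(features$mz, target_mz[k])
    sel <- abs(ppm) <= mz_tol_ppm
    if (!is.null(rt_range)) {
      sel <- sel & features$rt_min >= rt_range[1] &
        features$rt_min <= rt_range[2]
    }
    if (!any(sel)) return(NULL)
    cbind(features[sel, , drop = FALSE],
          target = nm[k], ppm = ppm[sel], stringsAsFactors = FALSE)
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (length(hits) == 0L) {
    out <- features[0, , drop = FALSE]
    out$target <- character(0); out$ppm <- numeric(0)
    return(out)
  }
  do.call(rbind, hits)
}
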