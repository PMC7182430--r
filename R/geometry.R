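# Membrane geometry: SMALP lipid capacity, leaflet cross-sectional area
# by polar-wedge numerical integration of an OPM-positioned structure,
# and conformational lipid-displacement deltas.

#' Geometry parameters
#'
#' @param area_per_lipid Mean in-plane area of one lipid, in Angstrom^2
#'   (47.1 A^2 = 0.471 nm^2).
#' @param circle_radius Radius of the reference circle drawn around the
#'   protein center (35 A, i.e. a 70 A diameter spanning 1-2 lipid
#'   shells).
#' @param slab_half_width Half-width of the atom slab taken around each
#'   leaflet plane (A).
#' @param n_wedges Number of polar wedges for the area integration
#'   (80 wedges, 4.5 degrees each).
#' @param smalp_diameter_nm SMALP disc diameter (9 +/- 1 nm).
#' @param sma_rim_nm Radial thickness of the SMA polymer belt (1 nm).
#' @param protein_area_nm2 Membrane cross-section of a typical membrane
#'   protein (20 nm^2).
#' @return Classed parameter list.
#' @export
geometry_params <- function(area_per_lipid = 47.1, circle_radius = 35,
                            slab_half_width = 2, n_wedges = 80L,
                            smalp_diameter_nm = 9, sma_rim_nm = 1,
                            protein_area_nm2 = 20) {
  stopifnot(area_per_lipid > 0, circle_radius > 0, slab_half_width > 0,
            n_wedges >= 8L, smalp_diameter_nm > 0, sma_rim_nm > 0,
            protein_area_nm2 >= 0)
  structure(list(area_per_lipid = area_per_lipid,
                 circle_radius = circle_radius,
                 slab_half_width = slab_half_width,
                 n_wedges = as.integer(n_wedges),
                 smalp_diameter_nm = smalp_diameter_nm,
                 sma_rim_nm = sma_rim_nm,
                 protein_area_nm2 = protein_area_nm2),
            class = "geometry_params")
}

.pdb_field <- function(lines, from, to) trimws(substring(lines, from, to))

#' Read a membrane-positioned structure from a PDB file
#'
#' Parses ATOM/HETATM records (fixed-column PDB format; no parser for
#' this format ships with the installed R stack, so the few needed
#' columns are read directly). Hydrogens and waters are dropped. Leaflet
#' planes come from OPM DUM pseudo-atom layers (z_outer = max DUM z,
#' z_inner = min DUM z) unless explicit overrides are given; overrides
#' take precedence.
#'
#' @param path PDB file.
#' @param z_outer,z_inner Optional explicit leaflet plane heights (A).
#' @param conformation Free-text label carried through to reports.
#' @return `membrane_structure` list: `atoms` data.frame (element, x, y,
#'   z, residue, chain), `z_outer`, `z_inner`, `conformation`.
#' @export
read_membrane_pdb <- function(path, z_outer = NULL, z_inner = NULL,
                              conformation = basename(path)) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substring(lines, 1, 6)
  sel <- trimws(rec) %in% c("ATOM", "HETATM")
  lines <- lines[sel]
  if (length(lines) == 0L) stop("no ATOM/HETATM records in ", path)
  name <- .pdb_field(lines, 13, 16)
  residue <- .pdb_field(lines, 18, 20)
  chain <- .pdb_field(lines, 22, 22)
  x <- as.numeric(substring(lines, 31, 38))
  y <- as.numeric(substring(lines, 39, 46))
  z <- as.numeric(substring(lines, 47, 54))
  element <- .pdb_field(lines, 77, 78)
  noel <- !nzchar(element)
  element[noel] <- sub("[0-9'].*$", "", sub("^[0-9]", "", name[noel]))
  element[noel] <- substring(element[noel], 1, 1)
  atoms <- data.frame(element = element, x = x, y = y, z = z,
                      residue = residue, chain = chain,
                      stringsAsFactors = FALSE)
  dum <- atoms[atoms$residue == "DUM", , drop = FALSE]
  atoms <- atoms[atoms$residue != "DUM" &
                   !atoms$residue %in% c("HOH", "WAT") &
                   toupper(atoms$element) != "H", , drop = FALSE]
  if (is.null(z_outer) || is.null(z_inner)) {
    if (nrow(dum) == 0L) {
      stop("no DUM leaflet markers in ", path,
           " and no explicit plane overrides given")
    }
    if (is.null(z_outer)) z_outer <- max(dum$z)
    if (is.null(z_inner)) z_inner <- min(dum$z)
  }
  if (z_outer <= z_inner) stop("z_outer must exceed z_inner")
  structure(list(atoms = atoms, z_outer = z_outer, z_inner = z_inner,
                 conformation = conformation),
            class = "membrane_structure")
}

#' Leaflet cross-sectional area by polar-wedge integration
#'
#' Atoms within `slab_half_width` of the leaflet plane are projected
#' onto it. A fan of `n_wedges` polar wedges is centered on the x/y
#' centroid of the slab atoms; in each wedge the radius r_i is the
#' distance of the most distant atom (0 for empty wedges). Each wedge
#' contributes the right-triangle pair area r_i^2 tan(theta/2), and the
#' total is the protein's cross-section at that leaflet:
#' A = sum r_i^2 tan(theta/2).
#'
#' @param structure `membrane_structure`.
#' @param leaflet "outer" or "inner".
#' @param params [geometry_params()].
#' @param center Optional fixed `c(x, y)` protein center; by default the
#'   x/y centroid of the slab atoms.
#' @return `leaflet_footprint` list: leaflet, area (A^2), radii (length
#'   `n_wedges`), center (x, y), n_atoms, theta.
#' @export
leaflet_cross_section <- function(structure, leaflet = c("outer", "inner"),
                                  params = geometry_params(),
                                  center = NULL) {
  leaflet <- match.arg(leaflet)
  plane <- if (leaflet == "outer") structure$z_outer else structure$z_inner
  at <- structure$atoms
  slab <- at[abs(at$z - plane) <= params$slab_half_width, , drop = FALSE]
  if (nrow(slab) == 0L) {
    stop("no atoms within ", params$slab_half_width, " A of the ",
         leaflet, " leaflet plane")
  }
  if (is.null(center)) center <- c(mean(slab$x), mean(slab$y))
  cx <- center[1]; cy <- center[2]
  dx <- slab$x - cx; dy <- slab$y - cy
  r <- sqrt(dx^2 + dy^2)
  theta <- 2 * pi / params$n_wedges
  wedge <- floor(((atan2(dy, dx) + 2 * pi) %% (2 * pi)) / theta) + 1L
  radii <- rep(0, params$n_wedges)
  agg <- tapply(r, wedge, max)
  radii[as.integer(names(agg))] <- agg
  area <- sum(radii^2 * tan(theta / 2))
  out <- list(leaflet = leaflet, area = area, radii = radii,
              center = c(x = cx, y = cy), n_atoms = nrow(slab),
              theta = theta)
  class(out) <- "leaflet_footprint"
  out
}

#' Lipids fitting in a circle around the protein
#'
#' The number of lipids within a reference circle of `circle_radius` is
#' the free area (circle minus protein cross-section) divided by the
#' area per lipid, rounded to the nearest integer and floored at zero.
#'
#' @param protein_area Protein cross-sectional area (A^2) at the leaflet.
#' @param params [geometry_params()].
#' @return Integer lipid count.
#' @export
lipid_count_in_circle <- function(protein_area, params = geometry_params()) {
  if (protein_area < 0) stop("negative protein area")
  free <- pi * params$circle_radius^2 - protein_area
  max(0L, as.integer(round(free / params$area_per_lipid)))
}

#' Per-leaflet footprint and lipid count for one conformation
#'
#' Convenience wrapper: integrates both leaflets of a structure and
#' converts areas to lipid counts in the reference circle.
#'
#' @param structure `membrane_structure`.
#' @param params [geometry_params()].
#' @return data.frame: leaflet, area_A2, lipid_count, conformation.
#' @export
conformation_footprints <- function(structure, params = geometry_params()) {
  do.call(rbind, lapply(c("outer", "inner"), function(lf) {
    fp <- leaflet_cross_section(structure, lf, params)
    data.frame(leaflet = lf, area_A2 = fp$area,
               lipid_count = lipid_count_in_circle(fp$area, params),
               conformation = structure$conformation,
               stringsAsFactors = FALSE)
  }))
}

#' Conformational lipid displacement
#'
#' Signed per-leaflet change in the number of lipids accommodated in the
#' reference circle when the protein moves from the inward to the
#' outward conformation: delta = count(outward) - count(inward).
#'
#' @param inward,outward data.frames from [conformation_footprints()]
#'   computed with identical parameters.
#' @return data.frame: leaflet, count_inward, count_outward, delta.
#' @export
conformational_lipid_delta <- function(inward, outward) {
  stopifnot(setequal(inward$leaflet, outward$leaflet))
  m <- match(inward$leaflet, outward$leaflet)
  data.frame(leaflet = inward$leaflet,
             count_inward = inward$lipid_count,
             count_outward = outward$lipid_count[m],
             delta = outward$lipid_count[m] - inward$lipid_count,
             stringsAsFactors = FALSE)
}

#' SMALP lipid capacity
#'
#' Two-leaflet estimate of how many lipids one SMALP disc holds around
#' one protein: the lipid-accessible annulus is the disc radius minus
#' the SMA polymer rim, less the protein cross-section; both leaflets
#' contribute. With the default parameters (9 nm disc, 1 nm rim,
#' 20 nm^2 protein, 0.471 nm^2 per lipid) the estimate is 78 lipids,
#' inside the predicted 60-120 stoichiometry envelope.
#'
#' @param params [geometry_params()] (nm-scale fields are used).
#' @return Integer lipid count (both leaflets).
#' @export
smalp_lipid_capacity <- function(params = geometry_params()) {
  radius <- params$smalp_diameter_nm / 2 - params$sma_rim_nm
  if (radius <= 0) stop("SMA rim exceeds the disc radius")
  free <- pi * radius^2 - params$protein_area_nm2
  apl_nm2 <- params$area_per_lipid / 100   # A^2 -> nm^2
  max(0L, as.integer(round(free * 2 / apl_nm2)))
}
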