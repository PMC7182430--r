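# Monoisotopic element masses (Da), most abundant isotope, NIST/CODATA.
# Pinned here so results never depend on a runtime lookup.
.ELEMENT_MASSES <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  Cl = 34.96885268
)

.PROTON_MASS <- 1.00727646688
.ELECTRON_MASS <- 0.00054857990
# 13C - 12C spacing, used for isotopologue reasoning
.C13_DELTA <- 1.0033548
# CH2 and H2 homolog ladder spacings, exact from the element table
.CH2_MASS <- 12 + 2 * 1.00782503207
.H2_MASS <- 2 * 1.00782503207
# neutral formic acid, the [M+HCOO]- vs [M-H]- spacing
.FORMIC_ACID_MASS <- 12 + 2 * 1.00782503207 + 2 * 15.9949146196
# sodium formate cluster unit (NaCOOH), the classic ESI salt-ladder spacing
.SODIUM_FORMATE_MASS <- 67.98743865

#' Supported lipid classes
#'
#' Class codes used throughout the package: the eight glycerophospholipid
#' classes detected in negative mode (PC, PE, PS, PI, PG, PA, CL, DAG),
#' the yeast sphingolipids IPC and MIPC, and ergosterol (ERG, positive
#' mode only).
#'
#' @return Character vector of class codes in canonical order.
#' @export
lipid_classes <- function() {
  c("PC", "PE", "PS", "PI", "PG", "PA", "CL", "DAG", "IPC", "MIPC", "ERG")
}

#' Supported adducts
#'
#' Singly charged adducts observed on a QToF run with an ammonium-formate
#' mobile phase: deprotonated, formate, protonated, and the deprotonated
#' dimer.
#'
#' @return data.frame with columns `name`, `mass_shift` (Da),
#'   `charge_sign`, `multiplicity`.
#' @export
adduct_table <- function() {
  data.frame(
    name = c("[M-H]-", "[M+HCOO]-", "[M+H]+", "[2M-H]-"),
    mass_shift = c(-.PROTON_MASS,
                   .ELEMENT_MASSES[["C"]] + .ELEMENT_MASSES[["H"]] +
                     2 * .ELEMENT_MASSES[["O"]] + .ELECTRON_MASS,
                   .PROTON_MASS,
                   -.PROTON_MASS),
    charge_sign = c(-1L, -1L, 1L, -1L),
    multiplicity = c(1L, 1L, 1L, 2L),
    stringsAsFactors = FALSE
  )
}

.adduct_shift <- function(name) {
  tab <- adduct_table()
  i <- match(name, tab$name)
  if (anyNA(i)) stop("unknown adduct: ", paste(name[is.na(i)], collapse = ", "))
  tab[i, , drop = FALSE]
}

#' Parse a molecular formula
#'
#' Parses a Hill-style formula string ("C43H81O13P") into a named count
#' vector. Only the elements relevant to lipid ions are supported
#' (C, H, N, O, P, S, Na, Cl).
#'
#' @param text Formula string; element symbols with optional counts.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C28H44O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) stop("formula is NA")
  text <- trimws(text)
  counts <- integer(0)
  if (!nzchar(text)) return(counts)
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  parsed <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(nchar(parsed)) != nchar(text)) {
    stop("malformed formula: '", text, "'")
  }
  for (tok in parsed) {
    sym <- sub("[0-9]*$", "", tok)
    if (!sym %in% names(.ELEMENT_MASSES)) {
      stop("unsupported element symbol: '", sym, "'")
    }
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  counts
}

#' Format element counts as a Hill-order formula string
#'
#' @param counts Named integer vector of element counts.
#' @return Formula string (C first, H second, remainder alphabetical).
#' @export
format_formula <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) return("")
  syms <- names(counts)
  ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  paste0(vapply(ord, function(s) {
    if (counts[[s]] == 1L) s else paste0(s, counts[[s]])
  }, character(1)), collapse = "")
}

#' Monoisotopic mass of a formula
#'
#' Sum of count x most-abundant-isotope mass over all elements, using the
#' mass table pinned in the package.
#'
#' @param counts Named count vector as returned by [parse_formula()], or a
#'   formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O") # 18.010565
#' @export
monoisotopic_mass <- function(counts) {
  if (is.character(counts)) counts <- parse_formula(counts)
  if (length(counts) == 0L) return(0)
  if (any(counts < 0)) stop("negative element count")
  unknown <- setdiff(names(counts), names(.ELEMENT_MASSES))
  if (length(unknown)) stop("unsupported element symbol: ", unknown[1])
  sum(.ELEMENT_MASSES[names(counts)] * as.numeric(counts))
}

.add_counts <- function(a, b) {
  for (s in names(b)) {
    a[s] <- (if (s %in% names(a)) a[[s]] else 0L) + b[[s]]
  }
  a
}

#' Molecular formula of a lipid species
#'
#' Builds the neutral molecular formula for a lipid class and total acyl
#' composition X:Y (carbons:double bonds summed over chains). Diacyl
#' glycerophospholipids derive from the phosphatidic acid backbone
#' PA(c,d) = C(c+3) H(2c-2d+5) O8 P by head-group addition; cardiolipin
#' and DAG have their own rules. IPC is modelled as a tetra-hydroxylated
#' phosphoinositol ceramide (C(c+6) H(2c+12-2d) N O13 P) and MIPC as its
#' mannoside; ergosterol is the fixed sterol C28H44O.
#'
#' @param cls Lipid class code (see [lipid_classes()]).
#' @param carbons Total acyl carbons X (ignored for ERG).
#' @param double_bonds Total double bonds Y (ignored for ERG).
#' @param hydroxyls Hydroxyl count on the ceramide backbone, sphingolipids
#'   only (default 4; contributes `9 + hydroxyls` oxygens).
#' @return Named integer vector of element counts.
#' @examples
#' format_formula(species_formula("PI", 34, 1)) # "C43H81O13P"
#' @export
species_formula <- function(cls, carbons = NA_integer_, double_bonds = NA_integer_,
                            hydroxyls = 4L) {
  cls <- match.arg(cls, lipid_classes())
  if (cls == "ERG") return(parse_formula("C28H44O"))
  c <- as.integer(carbons); d <- as.integer(double_bonds)
  if (is.na(c) || is.na(d) || c < 0 || d < 0) {
    stop("carbons and double_bonds must be non-negative integers")
  }
  pa <- function() c(C = c + 3L, H = 2L * c - 2L * d + 5L, O = 8L, P = 1L)
  f <- switch(cls,
    PA  = pa(),
    PC  = .add_counts(pa(), c(C = 5L, H = 11L, N = 1L)),
    PE  = .add_counts(pa(), c(C = 2L, H = 5L, N = 1L)),
    PS  = .add_counts(pa(), c(C = 3L, H = 5L, N = 1L, O = 2L)),
    PG  = .add_counts(pa(), c(C = 3L, H = 6L, O = 2L)),
    PI  = .add_counts(pa(), c(C = 6L, H = 10L, O = 5L)),
    DAG = c(C = c + 3L, H = 2L * c - 2L * d + 4L, O = 5L),
    CL  = c(C = c + 9L, H = 2L * c - 2L * d + 14L, O = 17L, P = 2L),
    IPC = c(C = c + 6L, H = 2L * c + 12L - 2L * d, N = 1L,
            O = 9L + as.integer(hydroxyls), P = 1L),
    MIPC = .add_counts(
      c(C = c + 6L, H = 2L * c + 12L - 2L * d, N = 1L,
        O = 9L + as.integer(hydroxyls), P = 1L),
      c(C = 6L, H = 10L, O = 5L))
  )
  if (any(f < 0)) stop("negative hydrogen count for ", cls, " ", c, ":", d)
  # drop zero entries, canonical order
  f <- f[f > 0]
  f[order(match(names(f), c("C", "H", names(.ELEMENT_MASSES))))]
}

#' m/z of an adduct ion
#'
#' All ions are treated as singly charged, so
#' m/z = multiplicity x M + mass shift.
#'
#' @param M Neutral monoisotopic mass (Da), > 0.
#' @param adduct Adduct name, one of [adduct_table()]`$name`.
#' @return m/z value.
#' @examples
#' ionize(396.33922, "[M+H]+") # 397.3465, ergosterol
#' @export
ionize <- function(M, adduct) {
  if (any(M <= 0)) stop("neutral mass must be positive")
  a <- .adduct_shift(adduct)
  a$multiplicity * M + a$mass_shift
}

#' Mass accuracy in parts per million
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z, > 0.
#' @return Signed ppm error, 1e6 x (observed - theoretical) / theoretical.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  1e6 * (observed - theoretical) / theoretical
}

#' Default library configuration
#'
#' Enumeration ranges and per-class adducts for [build_library()].
#' Diacyl glycerophospholipids span 26-44 total acyl carbons and 0-6
#' double bonds; cardiolipin (four chains) spans 60-76 carbons, 0-8
#' double bonds; IPC/MIPC span 40-46 carbons, saturated. The zwitterionic
#' PC and neutral DAG are detected as formate adducts in negative mode
#' (ammonium-formate mobile phase); the anionic classes as [M-H]-;
#' ergosterol only as [M+H]+.
#'
#' @return Named list of configuration values.
#' @export
library_config <- function() {
  list(
    classes = lipid_classes(),
    carbons = 26:44,
    double_bonds = 0:6,
    cl_carbons = 60:76,
    cl_double_bonds = 0:8,
    sphingo_carbons = 40:46,
    sphingo_double_bonds = 0L,
    adducts = list(
      PC = "[M+HCOO]-", DAG = "[M+HCOO]-",
      PE = "[M-H]-", PS = "[M-H]-", PI = "[M-H]-", PG = "[M-H]-",
      PA = "[M-H]-", CL = "[M-H]-", IPC = "[M-H]-", MIPC = "[M-H]-",
      ERG = "[M+H]+"
    )
  )
}

#' Build the theoretical lipid ion library
#'
#' Cartesian enumeration of (class, carbons, double bonds, adduct) with
#' theoretical m/z, the accurate-mass reference that molecular events are
#' identified against. Deterministic: ordering is by class (canonical
#' order), carbons, double bonds, adduct.
#'
#' @param config Configuration list, see [library_config()].
#' @return data.frame with columns `class`, `carbons`, `double_bonds`,
#'   `formula`, `adduct`, `mz`.
#' @examples
#' lib <- build_library()
#' subset(lib, class == "PI" & carbons == 34 & double_bonds == 1)
#' @export
build_library <- function(config = library_config()) {
  if (length(config$classes) == 0L) stop("empty library configuration")
  rows <- list()
  for (cls in config$classes) {
    grid <- switch(cls,
      CL = expand.grid(carbons = config$cl_carbons,
                       double_bonds = config$cl_double_bonds),
      IPC = ,
      MIPC = expand.grid(carbons = config$sphingo_carbons,
                         double_bonds = config$sphingo_double_bonds),
      ERG = data.frame(carbons = NA_integer_, double_bonds = NA_integer_),
      expand.grid(carbons = config$carbons,
                  double_bonds = config$double_bonds)
    )
    if (nrow(grid) == 0L) stop("empty enumeration range for class ", cls)
    adducts <- config$adducts[[cls]]
    if (is.null(adducts)) stop("no adduct configured for class ", cls)
    grid <- grid[order(grid$carbons, grid$double_bonds), , drop = FALSE]
    for (i in seq_len(nrow(grid))) {
      f <- species_formula(cls, grid$carbons[i], grid$double_bonds[i])
      M <- monoisotopic_mass(f)
      for (ad in sort(adducts)) {
        rows[[length(rows) + 1L]] <- data.frame(
          class = cls, carbons = grid$carbons[i],
          double_bonds = grid$double_bonds[i],
          formula = format_formula(f), adduct = ad,
          mz = ionize(M, ad), stringsAsFactors = FALSE)
      }
    }
  }
  lib <- do.call(rbind, rows)
  lib <- lib[order(match(lib$class, lipid_classes()), lib$carbons,
                   lib$double_bonds, lib$adduct), , drop = FALSE]
  rownames(lib) <- NULL
  lib
}

#' Write / read a lipid library as CSV
#'
#' m/z is written with six decimal places; round-tripping a library
#' through CSV preserves identification results at any sensible ppm
#' tolerance.
#'
#' @param library data.frame from [build_library()].
#' @param path File path.
#' @return `read_library` returns the library data.frame.
#' @export
write_library <- function(library, path) {
  out <- library
  out$mz <- sprintf("%.6f", out$mz)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("class", "carbons", "double_bonds", "formula", "adduct", "mz")
  missing <- setdiff(needed, names(lib))
  if (length(missing)) stop("library file misses columns: ",
                            paste(missing, collapse = ", "))
  lib$mz <- as.numeric(lib$mz)
  lib
}
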