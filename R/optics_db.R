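#' Tissue label codes
#'
#' Integer codes used throughout the package for voxel labels:
#' 0 outside (ambient air), 1 skin, 2 fat, 3 duct, 4 cancer.
#'
#' @return named integer vector
#' @export
tissue_labels <- function() {
  c(outside = 0L, skin = 1L, fat = 2L, duct = 3L, cancer = 4L)
}

.bands <- c("VIS", "NIR", "SWIR")
.roles <- c("excitation", "emission")

# the six discrete (band, role) wavelengths supported by the optical tables
.band_wavelengths <- data.frame(
  band = rep(.bands, each = 2L),
  role = rep(.roles, 3L),
  wavelength_nm = c(488, 520, 780, 820, 970, 1100)
)

.match_band <- function(band) {
  b <- toupper(as.character(band))
  if (length(b) != 1L || !b %in% .bands)
    stop("unknown band '", band, "'; expected one of ", paste(.bands, collapse = ", "))
  b
}

.match_role <- function(role) {
  r <- match.arg(tolower(as.character(role)), .roles)
  r
}

#' Wavelength of a spectral band in a given role
#'
#' @param band one of `"VIS"`, `"NIR"`, `"SWIR"`
#' @param role `"excitation"` or `"emission"`
#' @return wavelength in nm (488/520, 780/820 or 970/1100)
#' @export
band_wavelength <- function(band, role) {
  band <- .match_band(band); role <- .match_role(role)
  .band_wavelengths$wavelength_nm[.band_wavelengths$band == band &
                                  .band_wavelengths$role == role]
}

.validate_optics_table <- function(tab) {
  need <- c("band", "role", "wavelength_nm", "tissue", "mu_a", "mu_s", "g", "n")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("optical table is missing columns: ", paste(miss, collapse = ", "))
  if (any(tab$mu_a < 0) || any(tab$mu_s < 0))
    stop("mu_a and mu_s must be non-negative")
  if (any(tab$mu_a + tab$mu_s <= 0))
    stop("mu_a + mu_s must be positive for every interior tissue")
  if (any(tab$n < 1 | tab$n > 2))
    stop("refractive indices must lie in [1, 2]")
  if (any(abs(tab$g) >= 1))
    stop("anisotropy g must satisfy |g| < 1")
  for (i in seq_len(nrow(.band_wavelengths))) {
    sel <- tab$band == .band_wavelengths$band[i] & tab$role == .band_wavelengths$role[i]
    if (any(sel) && !all(tab$wavelength_nm[sel] == .band_wavelengths$wavelength_nm[i]))
      stop("wavelength mismatch for (", .band_wavelengths$band[i], ", ",
           .band_wavelengths$role[i], "): expected ",
           .band_wavelengths$wavelength_nm[i], " nm")
  }
  invisible(tab)
}

#' Load the tissue optical-property table
#'
#' Reads the per-tissue, per-wavelength absorption coefficient `mu_a`
#' (cm^-1), scattering coefficient `mu_s` (cm^-1), anisotropy `g` and
#' refractive index `n` from a TSV file. The shipped table covers skin, fat,
#' duct and cancer at the six (band, role) wavelengths 488/520 (VIS),
#' 780/820 (NIR) and 970/1100 nm (SWIR). Anisotropy is not part of the
#' literature table the optical coefficients come from; the shipped file
#' uses g = 0.9 for all tissues (a typical soft-tissue value), and users may
#' substitute their own table.
#'
#' @param path TSV file; defaults to the table shipped with the package
#' @return data.frame with columns band, role, wavelength_nm, tissue,
#'   mu_a, mu_s, g, n
#' @export
load_optics_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "optical_properties.tsv",
                        package = "voxfluor", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  .validate_optics_table(tab)
  tab
}

#' Write an optical-property table
#'
#' @param table data.frame as returned by [load_optics_table()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_optics_table <- function(table, path) {
  .validate_optics_table(table)
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up the optical properties of a tissue at a band/role wavelength
#'
#' @param tissue one of `"skin"`, `"fat"`, `"duct"`, `"cancer"`; the
#'   `"outside"` label is ambient air handled by the transport engine and is
#'   deliberately not in the table
#' @param band one of `"VIS"`, `"NIR"`, `"SWIR"`
#' @param role `"excitation"` or `"emission"`
#' @param table optional substitute table (see [load_optics_table()])
#' @return object of class `optical_properties`: list with `mu_a`, `mu_s`,
#'   `g`, `n` and the resolved `wavelength_nm`
#' @examples
#' get_tissue_optics("skin", "VIS", "excitation")
#' @export
get_tissue_optics <- function(tissue, band, role, table = NULL) {
  tissue <- tolower(as.character(tissue))
  if (identical(tissue, "outside"))
    stop("'outside' is non-scattering ambient air handled by the engine, ",
         "not an entry of the optical table")
  if (!tissue %in% c("skin", "fat", "duct", "cancer"))
    stop("unknown tissue '", tissue, "'")
  band <- .match_band(band); role <- .match_role(role)
  if (is.null(table)) table <- load_optics_table()
  row <- table[table$tissue == tissue & table$band == band & table$role == role, ]
  if (nrow(row) != 1L)
    stop("no optical entry for (", tissue, ", ", band, ", ", role, ")")
  structure(list(mu_a = row$mu_a, mu_s = row$mu_s, g = row$g, n = row$n,
                 wavelength_nm = row$wavelength_nm,
                 tissue = tissue, band = band, role = role),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("<%s, %s %s, %d nm>  mu_a = %g cm-1, mu_s = %g cm-1, g = %g, n = %g\n",
              x$tissue, x$band, x$role, x$wavelength_nm,
              x$mu_a, x$mu_s, x$g, x$n))
  invisible(x)
}

#' Load the fluorophore specification table
#'
#' @param path TSV file; defaults to the shipped table (fluorescein for VIS,
#'   indocyanine green for NIR, PbS quantum dots for SWIR)
#' @return data.frame with columns name, band, ex_nm, em_nm, qy,
#'   conc_molar, epsC
#' @export
load_fluorophore_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "fluorophores.tsv",
                        package = "voxfluor", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "band", "ex_nm", "em_nm", "qy", "conc_molar", "epsC")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("fluorophore table is missing columns: ", paste(miss, collapse = ", "))
  if (any(tab$qy <= 0 | tab$qy > 1)) stop("quantum yield must be in (0, 1]")
  if (any(tab$epsC <= 0)) stop("epsC must be positive")
  if (any(tab$em_nm <= tab$ex_nm)) stop("emission peak must be redder than excitation")
  tab
}

#' Fluorophore used for a spectral band
#'
#' Returns the probe assumed for each band: fluorescein in the VIS
#' (488/520 nm, quantum yield 0.95, 0.75 mM, probe absorption
#' epsC = 12 cm^-1), indocyanine green in the NIR (780/820 nm, QY 0.09,
#' 0.2 mM, epsC = 20 cm^-1) and lead-sulfide quantum dots in the SWIR
#' (970/1100 nm, QY 0.40, 1.0 uM, epsC = 0.63 cm^-1).
#'
#' @param band one of `"VIS"`, `"NIR"`, `"SWIR"`
#' @param table optional substitute table (see [load_fluorophore_table()])
#' @return object of class `fluorophore_spec`
#' @examples
#' get_fluorophore("SWIR")
#' @export
get_fluorophore <- function(band, table = NULL) {
  band <- .match_band(band)
  if (is.null(table)) table <- load_fluorophore_table()
  row <- table[table$band == band, ]
  if (nrow(row) != 1L) stop("no fluorophore entry for band '", band, "'")
  structure(list(name = row$name, band = band,
                 lambda_ex = row$ex_nm, lambda_em = row$em_nm,
                 quantum_yield = row$qy, concentration = row$conc_molar,
                 epsC = row$epsC),
            class = "fluorophore_spec")
}

#' @export
print.fluorophore_spec <- function(x, ...) {
  cat(sprintf("<%s (%s)>  Ex %d / Em %d nm, QY %g, C %g M, epsC %g cm-1\n",
              x$name, x$band, x$lambda_ex, x$lambda_em,
              x$quantum_yield, x$concentration, x$epsC))
  invisible(x)
}

# (n_label x 4) property matrix for the engine: rows are labels 0..4
# (outside, skin, fat, duct, cancer), columns mu_a, mu_s, g, n.
# Outside is non-scattering ambient air with n = 1.
.optics_matrix <- function(band, role, table = NULL) {
  band <- .match_band(band); role <- .match_role(role)
  if (is.null(table)) table <- load_optics_table()
  tissues <- c("skin", "fat", "duct", "cancer")
  m <- matrix(0, nrow = 5L, ncol = 4L,
              dimnames = list(c("outside", tissues), c("mu_a", "mu_s", "g", "n")))
  m["outside", ] <- c(0, 0, 0, 1)
  for (t in tissues) {
    op <- get_tissue_optics(t, band, role, table = table)
    m[t, ] <- c(op$mu_a, op$mu_s, op$g, op$n)
  }
  m
}
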