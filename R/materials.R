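#' Dielectric and thermal material record
#'
#' A material couples the electromagnetic properties that enter the FDTD
#' update (conductivity `sigma`, relative permittivity `eps_r`) with the
#' density and specific heat capacity needed to convert field strength to
#' specific absorption rate (SAR) and temperature rise.
#'
#' @param name character label.
#' @param sigma electrical conductivity (S/m), `>= 0`.
#' @param eps_r relative permittivity (dimensionless), `>= 1`.
#' @param rho mass density (kg/m^3), `> 0`.
#' @param c specific heat capacity (J/kg/degC), `> 0`.
#' @return An object of class `hyp_material` (named list).
#' @export
material <- function(name, sigma, eps_r, rho = 1000, c = 4180) {
  stopifnot(is.character(name), length(name) == 1L)
  if (sigma < 0) stop("sigma must be >= 0")
  if (eps_r < 1) stop("eps_r must be >= 1")
  if (rho <= 0) stop("rho must be > 0")
  if (c <= 0) stop("c must be > 0")
  structure(list(name = name, sigma = sigma, eps_r = eps_r, rho = rho, c = c),
            class = "hyp_material")
}

#' @export
print.hyp_material <- function(x, ...) {
  cat(sprintf("<material %s: sigma=%g S/m, eps_r=%g, rho=%g kg/m3, c=%g J/kg/C>\n",
              x$name, x$sigma, x$eps_r, x$rho, x$c))
  invisible(x)
}

# Sentinel material for perfect electric conductor voxels.  The solver zeroes
# tangential E on every edge touching a metal voxel; sigma/eps here are never
# used in an update and sigma = 0 keeps SAR identically zero in metal.
.metal <- function() {
  m <- material("metal", sigma = 0, eps_r = 1, rho = 8900, c = 385)
  m$pec <- TRUE
  m
}

.supported_frequencies <- c(70, 80, 90, 110, 130)

#' Material table for a given operating frequency
#'
#' Returns the media used by the quality-assurance scenarios at one of the
#' supported operating frequencies (70, 80, 90, 110, 130 MHz).  Dielectric
#' values are the phantom recipes of the published measurement set-ups:
#' saline and wallpaper-paste muscle equivalents for the 70 MHz waveguide
#' systems, butanol-based fat equivalent for the inhomogeneous core, agarose
#' muscle equivalent for the Sigma-30 and the CDRH muscle/fat pair for the
#' Sigma-60.  Densities are standard tissue-equivalent values (1000 kg/m^3
#' muscle/water, 900 fat, 1400 PVC); normalized SAR profiles within a single
#' medium are insensitive to the density choice.
#'
#' @param frequency_MHz operating frequency in MHz; one of 70, 80, 90, 110, 130.
#' @return Named list of [material()] records, always including `air`,
#'   `water` (deionized bolus/waveguide fill), `pvc` and the `metal` sentinel.
#' @export
material_table <- function(frequency_MHz) {
  if (!(frequency_MHz %in% .supported_frequencies)) {
    stop(sprintf("unsupported frequency %s MHz; supported: %s",
                 format(frequency_MHz),
                 paste(.supported_frequencies, collapse = ", ")))
  }
  tab <- list(
    air   = material("air", 0, 1, rho = 1.2, c = 1005),
    water = material("water", 5e-4, 78, rho = 1000, c = 4186),
    pvc   = material("pvc", 0, 2.7, rho = 1400, c = 1000),
    metal = .metal()
  )
  if (frequency_MHz == 70) {
    tab$muscle_amc2 <- material("muscle_amc2", 0.51, 77, rho = 1000, c = 4180)
    tab$muscle_amc4 <- material("muscle_amc4", 0.55, 75, rho = 1000, c = 4180)
    tab$fat_core    <- material("fat_core", 0.035, 18, rho = 900, c = 2430)
  }
  if (frequency_MHz %in% c(70, 80, 90, 110)) {
    # CDRH phantom pair; c not published for this phantom, generic values used
    tab$muscle_cdrh <- material("muscle_cdrh", 0.68, 70, rho = 1000, c = 3850)
    tab$fat_cdrh    <- material("fat_cdrh", 0.05, 8, rho = 900, c = 2430)
  }
  if (frequency_MHz == 130) {
    tab$muscle_sigma30 <- material("muscle_sigma30", 0.7, 80, rho = 1000, c = 4180)
  }
  attr(tab, "frequency_MHz") <- frequency_MHz
  tab
}

#' Export a material table as a data frame / CSV
#'
#' @param tab result of [material_table()].
#' @param path optional CSV output path.
#' @return data.frame with columns name, sigma, eps_r, rho, c, frequency_MHz.
#' @export
material_table_df <- function(tab, path = NULL) {
  df <- do.call(rbind, lapply(tab, function(m) {
    data.frame(name = m$name, sigma = m$sigma, eps_r = m$eps_r,
               rho = m$rho, c = m$c, stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df$frequency_MHz <- attr(tab, "frequency_MHz")
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
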