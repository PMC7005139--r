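#' Head-tissue optical parameters
#'
#' Baseline absorption and scattering properties of the major head tissue
#' types at near-infrared wavelengths, shared by all three measurement
#' wavelengths (780, 805, 830 nm). These drive the photon-diffusion forward
#' model; the reduced scattering coefficient \eqn{\mu_s' = \mu_s (1 - g)} is
#' derived and appended.
#'
#' @param tissue optional tissue name (one of `"scalp_skull"`, `"CSF"`,
#'   `"gray"`, `"white"`); when given, a single-row data frame is returned.
#' @return data frame with columns `tissue`, `mua` (absorption, 1/mm),
#'   `mus` (scattering, 1/mm), `g` (anisotropy), `n` (refractive index) and
#'   `musp` (reduced scattering, 1/mm).
#' @examples
#' optical_parameters()
#' optical_parameters("gray")$musp  # 9.0 * (1 - 0.89)
#' @export
optical_parameters <- function(tissue = NULL) {
  tab <- data.frame(
    tissue = c("scalp_skull", "CSF", "gray", "white"),
    mua    = c(0.019, 0.004, 0.02, 0.08),
    mus    = c(7.8,   0.009, 9.0,  40.9),
    g      = c(0.89,  0.89,  0.89, 0.84),
    n      = c(1.37,  1.37,  1.37, 1.37),
    stringsAsFactors = FALSE
  )
  tab$musp <- tab$mus * (1 - tab$g)
  if (!is.null(tissue)) {
    i <- match(tissue, tab$tissue)
    if (anyNA(i)) {
      stop("unknown tissue type(s): ",
           paste(tissue[is.na(i)], collapse = ", "))
    }
    tab <- tab[i, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Effective attenuation coefficient of a diffusive medium
#'
#' \eqn{\mu_{eff} = \sqrt{3 \mu_a (\mu_a + \mu_s')}} in 1/mm.
#'
#' @param medium single-row data frame as returned by [optical_parameters()].
#' @export
mu_eff <- function(medium) {
  sqrt(3 * medium$mua * (medium$mua + medium$musp))
}

# Effective internal reflection coefficient for a refractive-index mismatch
# (Groenhuis/Egan-Hilgeman polynomial fit), used for the extrapolated
# boundary of the semi-infinite diffusion kernel.
reflection_eff <- function(n) {
  -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
}

#' Hemoglobin extinction table
#'
#' Builds the matrix `E` (wavelengths x species) mapping concentration
#' changes (Delta-oxy-Hb, Delta-deoxy-Hb, in mM) to absorption changes
#' \eqn{\Delta\mu_a} (1/mm) per wavelength. Default coefficients are the
#' widely used compiled in-vivo values converted to mm^-1 mM^-1 and scaled
#' by ln(10), so that \eqn{\Delta\mu_a = E \, (\Delta c_{oxy},
#' \Delta c_{deoxy})^T}. The matrix must have full column rank; with fewer
#' than two wavelengths, or with duplicated rows, the two species cannot be
#' separated.
#'
#' @param wavelengths numeric vector of wavelengths in nm (>= 2 entries).
#' @param table optional matrix (length(wavelengths) x 2) of decadic molar
#'   extinction coefficients in mm^-1 mM^-1, columns `(oxy, deoxy)`;
#'   defaults are shipped for 780, 805 and 830 nm.
#' @return object of class `extinction_table`: list with `wavelengths`,
#'   `E` (the mu_a-scale matrix) and `provenance`.
#' @examples
#' et <- extinction_matrix()
#' et$wavelengths            # 780 805 830
#' qr(et$E)$rank             # 2
#' @export
extinction_matrix <- function(wavelengths = c(780, 805, 830), table = NULL) {
  if (length(wavelengths) < 2) {
    stop("at least two wavelengths are required to unmix two Hb species")
  }
  if (is.null(table)) {
    defaults <- rbind(
      "780" = c(oxy = 0.0710, deoxy = 0.1075),
      "805" = c(oxy = 0.0797, deoxy = 0.0793),
      "830" = c(oxy = 0.0974, deoxy = 0.0693)
    )
    i <- match(as.character(wavelengths), rownames(defaults))
    if (anyNA(i)) {
      stop("no default extinction coefficients for wavelength(s) ",
           paste(wavelengths[is.na(i)], collapse = ", "),
           "; supply `table` explicitly")
    }
    table <- defaults[i, , drop = FALSE]
  }
  table <- as.matrix(table)
  if (nrow(table) != length(wavelengths) || ncol(table) != 2) {
    stop("`table` must be a length(wavelengths) x 2 matrix (oxy, deoxy)")
  }
  E <- log(10) * table
  rownames(E) <- as.character(wavelengths)
  colnames(E) <- c("oxy", "deoxy")
  if (qr(E)$rank < 2) {
    dup <- which(duplicated(round(table / table[1, 1], 10)) |
                   duplicated(round(table / table[1, 1], 10), fromLast = TRUE))
    stop("extinction table is rank deficient; offending wavelengths: ",
         paste(wavelengths[if (length(dup)) dup else seq_along(wavelengths)],
               collapse = ", "))
  }
  structure(
    list(wavelengths = wavelengths, E = E,
         provenance = list(units = "mua (1/mm) per mM, includes ln(10)",
                           source = "compiled literature defaults")),
    class = "extinction_table"
  )
}
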