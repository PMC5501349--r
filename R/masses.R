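# Monoisotopic mass constants.  Atomic values are IUPAC monoisotopic masses
# rounded to 6 dp; everything downstream is derived from these once and frozen.

#' Monoisotopic residue masses
#'
#' Named vector of the 20 canonical amino-acid residue (i.e. dehydrated)
#' monoisotopic masses in Da.
#'
#' @format Named numeric vector, one element per one-letter code.
#' @export
RESIDUE_MASS <- c(
  G =  57.021464, A =  71.037114, S =  87.032028, P =  97.052764,
  V =  99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' Mass constants used throughout the package
#'
#' Monoisotopic masses (Da) of the chemical entities the proteoform model is
#' built from: water, the proton, the methylene unit added per methylation,
#' the acetyl delta (C2H2O), the isotope substitutions behind the metabolic
#' labels, and the frozen ETD c / z-radical ladder offsets.
#'
#' `MASS_HEAVY_METHYL` is the 13CD3-vs-CH3 shift, `(13C - 12C) + 3 (2H - 1H)`;
#' `MASS_HEAVY_K` and `MASS_HEAVY_R` are the K(13C6,15N2) and R(13C6,15N4)
#' SILAC shifts.
#'
#' @name mass-constants
#' @export
MASS_WATER <- 18.010565

#' @rdname mass-constants
#' @export
MASS_PROTON <- 1.007276

#' @rdname mass-constants
#' @export
MASS_CH2 <- 14.015650

#' @rdname mass-constants
#' @export
MASS_AC <- 42.010565

# isotope substitution deltas
DELTA_13C <- 1.003355   # 13C - 12C
DELTA_2H  <- 1.006277   # 2H  - 1H
DELTA_15N <- 0.997035   # 15N - 14N

#' @rdname mass-constants
#' @export
MASS_HEAVY_METHYL <- DELTA_13C + 3 * DELTA_2H         # 4.022186

#' @rdname mass-constants
#' @export
MASS_HEAVY_K <- 6 * DELTA_13C + 2 * DELTA_15N         # 8.014200

#' @rdname mass-constants
#' @export
MASS_HEAVY_R <- 6 * DELTA_13C + 4 * DELTA_15N         # 10.008270

# ETD ladder offsets: c = prefix + NH3, z-dot = suffix net adjustment.
# Their sum satisfies c_i + z_(n-i) = M + MASS_CZ_COMPLEMENT for every i.
C_ION_OFFSET <- 17.026549
Z_ION_OFFSET <- 1.991840

#' @rdname mass-constants
#' @export
MASS_CZ_COMPLEMENT <- C_ION_OFFSET + Z_ION_OFFSET - MASS_WATER  # 1.007824

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a neutral mass to m/z
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param z Positive integer charge state.
#' @return `(neutral_mass + z * 1.007276) / z`.
#' @examples
#' mz(1000, 1)
#' mz(0, 8)
#' @export
mz <- function(neutral_mass, z) {
  if (any(z < 1) || any(z != round(z)))
    stop("charge state must be a positive integer, got ", paste(z, collapse = ", "))
  (neutral_mass + z * MASS_PROTON) / z
}

#' Convert an m/z value back to a neutral mass
#'
#' @param mz_value Observed m/z.
#' @param z Positive integer charge state.
#' @return Neutral mass in Da.
#' @export
neutral_mass <- function(mz_value, z) {
  if (any(z < 1) || any(z != round(z)))
    stop("charge state must be a positive integer, got ", paste(z, collapse = ", "))
  mz_value * z - z * MASS_PROTON
}
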