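# Tail sequences, modification rules and label schemes.

#' Define a polypeptide tail
#'
#' A tail is the unit of middle-down analysis: a proteolytic polypeptide
#' (typically a GluC-released histone N-terminal tail) located in
#' parent-protein coordinates so that modification sites keep their
#' biological names (K4, K9, ..., K36).
#'
#' @param name Text identifier.
#' @param residues One-letter amino-acid string, canonical alphabet only.
#' @param first_position 1-based position of the first residue in the parent
#'   protein.
#' @param cleavage_context Free-text note on how the tail is produced.
#' @return An object of class `tail_sequence`.
#' @examples
#' tail_sequence("toy", "ARTKQTA")
#' @export
tail_sequence <- function(name, residues, first_position = 1L,
                          cleavage_context = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(residues), length(residues) == 1L, nzchar(residues))
  first_position <- as.integer(first_position)
  if (is.na(first_position) || first_position < 1L)
    stop("first_position must be an integer >= 1")
  res <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- which(!res %in% names(RESIDUE_MASS))
  if (length(bad))
    stop("unknown residue letter '", res[bad[1L]], "' at position ",
         first_position + bad[1L] - 1L)
  structure(list(name = name, residues = residues,
                 first_position = first_position,
                 cleavage_context = cleavage_context),
            class = "tail_sequence")
}

#' @export
print.tail_sequence <- function(x, ...) {
  cat("<tail_sequence>", x$name, "\n ", x$residues, "\n  positions ",
      x$first_position, "-", x$first_position + nchar(x$residues) - 1L,
      if (!is.na(x$cleavage_context)) paste0("  (", x$cleavage_context, ")"),
      "\n", sep = "")
  invisible(x)
}

tail_letters <- function(tail) strsplit(tail$residues, "", fixed = TRUE)[[1L]]

tail_length <- function(tail) nchar(tail$residues)

tail_positions <- function(tail)
  seq.int(tail$first_position, length.out = tail_length(tail))

#' The histone H3 1-50 GluC tail
#'
#' The human histone H3 N-terminal tail released by GluC cleavage after E50,
#' the default substrate of the pipeline.  It contains 8 lysines and 7
#' arginines; under full heavy-KR labeling its mass shifts by ~134 Da
#' (16.77 m/z at charge 8+).
#'
#' @return A [tail_sequence] for residues 1-50 of histone H3.
#' @export
h3_tail <- function() {
  tail_sequence("H3_1-50", "ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGTVALRE",
                first_position = 1L, cleavage_context = "GluC after E50")
}

#' Commonly interrogated modification sites on the H3 tail
#'
#' The nine sites routinely carrying methylation/acetylation on the H3 1-50
#' tail: K4, R8, K9, K14, K18, K23, R26, K27, K36.  Used as the default
#' search space to keep candidate enumeration biologically focused.
#'
#' @return Integer vector of parent-protein positions.
#' @export
h3_mod_sites <- function() c(4L, 8L, 9L, 14L, 18L, 23L, 26L, 27L, 36L)

#' Default modification rule set
#'
#' Which modification kinds are allowed on which residues: mono- and
#' dimethylation on K and R, trimethylation and acetylation on K only.
#'
#' @return Named list mapping kind (`me1`, `me2`, `me3`, `ac`) to allowed
#'   residue letters.
#' @export
default_mod_rules <- function() {
  list(me1 = c("K", "R"), me2 = c("K", "R"), me3 = "K", ac = "K")
}

#' Number of methyl groups carried by a modification kind
#'
#' @param kind Character vector of kinds (`me1`, `me2`, `me3`, `ac`).
#' @return Integer vector: 1, 2, 3 for the methylations, 0 for acetylation.
#' @export
methyl_degree <- function(kind) {
  deg <- c(me1 = 1L, me2 = 2L, me3 = 3L, ac = 0L)
  out <- deg[kind]
  if (anyNA(out)) stop("unknown modification kind: ",
                       paste(kind[is.na(out)], collapse = ", "))
  unname(out)
}

#' Metabolic label scheme
#'
#' Describes the two orthogonal labeling channels: heavy-KR sequence labeling
#' (SILAC K(13C6,15N2) / R(13C6,15N4)) and heavy-methyl labeling via
#' methionine-(methyl-13CD3), which shifts each newly deposited methyl group
#' by ~4.0222 Da.
#'
#' Tails containing methionine are rejected when the methyl channel is
#' enabled (the M residues themselves would carry the label), unless
#' `allow_heavy_met = TRUE` is set explicitly.
#'
#' @param sequence_channel Enable the heavy-KR sequence channel.
#' @param methyl_channel Enable heavy-methyl counting on modifications.
#' @param heavy_K_delta,heavy_R_delta,heavy_methyl_delta Label mass shifts in
#'   Da; defaults are the frozen isotope-derived constants.
#' @param allow_heavy_met Permit methionine-containing tails under the methyl
#'   channel.
#' @return An object of class `label_scheme`.
#' @export
label_scheme <- function(sequence_channel = FALSE, methyl_channel = FALSE,
                         heavy_K_delta = MASS_HEAVY_K,
                         heavy_R_delta = MASS_HEAVY_R,
                         heavy_methyl_delta = MASS_HEAVY_METHYL,
                         allow_heavy_met = FALSE) {
  if (any(c(heavy_K_delta, heavy_R_delta, heavy_methyl_delta) < 0))
    stop("label mass deltas must be >= 0")
  structure(list(sequence_channel = isTRUE(sequence_channel),
                 methyl_channel = isTRUE(methyl_channel),
                 heavy_K_delta = heavy_K_delta,
                 heavy_R_delta = heavy_R_delta,
                 heavy_methyl_delta = heavy_methyl_delta,
                 allow_heavy_met = isTRUE(allow_heavy_met)),
            class = "label_scheme")
}
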