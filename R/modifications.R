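# Monoisotopic atomic masses (Da), CODATA/IUPAC values. D = 2H, C13 = 13C.
MONOISOTOPIC_MASS <- c(
  H   = 1.0078250319,
  D   = 2.0141017780,
  C   = 12.0000000000,
  C13 = 13.0033548378,
  N   = 14.0030740052,
  O   = 15.9949146221,
  S   = 31.9720706912
)

#' Define a modification by its elemental composition change
#'
#' @param name modification name.
#' @param delta named integer vector of signed element-count changes;
#'   allowed element symbols are H, D (deuterium), C, C13 (13C), N, O, S.
#' @return An object of class `modification_spec`.
#' @export
modification_spec <- function(name, delta) {
  if (length(delta) > 0L) {
    if (is.null(names(delta)) || any(!nzchar(names(delta)))) {
      stop("delta must be a named vector of element counts")
    }
    unknown <- setdiff(names(delta), names(MONOISOTOPIC_MASS))
    if (length(unknown) > 0L) {
      stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
    }
  }
  structure(list(name = name, delta = delta), class = "modification_spec")
}

#' Monoisotopic mass shift of a modification
#'
#' Computes the signed monoisotopic mass delta as the dot product of the
#' elemental composition change with monoisotopic atomic masses.
#'
#' @param mod a `modification_spec`.
#' @return Mass shift in Da (numeric scalar; 0 for an empty composition).
#' @export
mass_shift <- function(mod) {
  stopifnot(inherits(mod, "modification_spec"))
  if (length(mod$delta) == 0L) return(0)
  sum(mod$delta * MONOISOTOPIC_MASS[names(mod$delta)])
}

#' Standard N-terminal modifications of the dimethyl-labeling workflow
#'
#' The five modifications used in quantitative N-terminome searches:
#' * `dimethyl_light` — reductive dimethylation with light formaldehyde
#'   (CH2O/NaBH3CN): the two amine hydrogens are replaced by two CH3,
#'   a net gain of 2x CH2 (+28.031300 Da).
#' * `dimethyl_heavy` — heavy formaldehyde/deuterated cyanoborohydride
#'   (13CD2O/NaBD3CN): the two amine hydrogens are replaced by two 13CD3,
#'   i.e. +2 13C, +6 D, -2 H (+36.075670 Da).
#' * `acetyl` — endogenous N-terminal acetylation, +C2H2O (+42.010565 Da).
#' * `pyroglu_E` — pyroglutamate from N-terminal Glu, loss of water
#'   (-18.010565 Da).
#' * `pyroglu_Q` — pyroglutamate from N-terminal Gln, loss of ammonia
#'   (-17.026549 Da).
#'
#' @return Named list of `modification_spec` objects.
#' @export
standard_modifications <- function() {
  list(
    dimethyl_light = modification_spec("dimethyl_light", c(C = 2L, H = 4L)),
    dimethyl_heavy = modification_spec("dimethyl_heavy",
                                       c(C13 = 2L, D = 6L, H = -2L)),
    acetyl         = modification_spec("acetyl", c(C = 2L, H = 2L, O = 1L)),
    pyroglu_E      = modification_spec("pyroglu_E", c(H = -2L, O = -1L)),
    pyroglu_Q      = modification_spec("pyroglu_Q", c(N = -1L, H = -3L))
  )
}
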