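# Monoisotopic mass arithmetic: a fixed atomic-mass table (CODATA/IUPAC
# values for the principal isotopes), elemental formula parsing and
# electrospray adduct rules.

# masses of the lightest stable isotopes, Da
.atomic_masses <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268,
  F  = 18.99840322,
  Br = 78.9183371,
  I  = 126.904473,
  Se = 79.9165213,
  Si = 27.9769265325
)

.electron_mass <- 0.000548579909
.proton_mass <- 1.00782503207 - 0.000548579909 # H minus an electron

#' Atomic masses used for monoisotopic mass computation
#'
#' @return Named numeric vector of principal-isotope masses in daltons.
#' @export
atomic_masses <- function() .atomic_masses

#' Parse an elemental formula string
#'
#' Parses Hill-style formulas such as `"C6H12O6"` into element counts.
#' Only unparenthesised formulas over the supported element set are accepted.
#'
#' @param formula A single formula string.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || !nzchar(formula)) {
    stopf("formula must be a single non-empty string")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stopf("cannot parse formula '%s'", formula)
  }
  el <- sub("[0-9]*$", "", tokens)
  n <- as.integer(sub("^[A-Za-z]+", "", tokens))
  n[is.na(n)] <- 1L
  unknown <- setdiff(el, names(.atomic_masses))
  if (length(unknown)) {
    stopf("formula '%s' contains unsupported element(s): %s",
          formula, paste(unknown, collapse = ", "))
  }
  counts <- tapply(n, factor(el, levels = unique(el)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Monoisotopic mass of a neutral molecular formula
#'
#' @param formula Formula string, e.g. `"C6H12O6"`.
#' @return Mass in daltons.
#' @examples
#' monoisotopic_mass("C6H12O6") # 180.06339
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(.atomic_masses[names(counts)] * counts)
}

#' Default electrospray adduct rules
#'
#' The ion forms considered when matching neutral formulas to observed m/z:
#' five positive-mode and four negative-mode adducts. The `shift` column is
#' the total m/z offset (in Da, electron mass included) applied to `n` copies
#' of the neutral mass before division by the charge `z`. `min_h` is the
#' minimum hydrogen count a formula needs for the rule to apply
#' (deprotonation requires an abstractable proton).
#'
#' @return A data.frame with columns `name`, `polarity`, `n`, `shift`, `z`,
#'   `min_h`.
#' @export
adduct_rules <- function() {
  e <- .electron_mass
  H <- .atomic_masses[["H"]]
  data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+NH4]+", "[2M+H]+",
             "[M-H]-", "[M+Cl]-", "[M+HCOO]-", "[2M-H]-"),
    polarity = c(rep("positive", 5), rep("negative", 4)),
    n = c(1, 1, 1, 1, 2, 1, 1, 1, 2),
    shift = c(
      H - e,
      .atomic_masses[["Na"]] - e,
      .atomic_masses[["K"]] - e,
      .atomic_masses[["N"]] + 4 * H - e,
      H - e,
      -H + e,
      .atomic_masses[["Cl"]] + e,
      12.0 + H + 2 * .atomic_masses[["O"]] + e,
      -H + e
    ),
    z = rep(1, 9),
    min_h = c(0, 0, 0, 0, 0, 1, 0, 0, 1),
    stringsAsFactors = FALSE
  )
}

#' Theoretical m/z of an adduct ion
#'
#' Computes `(n * M + shift) / z` for a neutral monoisotopic mass `M` under
#' an adduct rule (one row of [adduct_rules()] or a compatible list).
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param rule A single adduct rule (list or one-row data.frame with `n`,
#'   `shift`, `z`, and optionally `min_h`).
#' @param formula Optional formula string; when given, the rule's
#'   applicability predicate is checked and an error raised if it fails.
#' @return Theoretical m/z.
#' @examples
#' rules <- adduct_rules()
#' theoretical_mz(180.06339, rules[rules$name == "[M+H]+", ]) # 181.07067
#' @export
theoretical_mz <- function(mass, rule, formula = NULL) {
  rule <- as.list(rule)
  if (!is.null(formula)) {
    counts <- parse_formula(formula)
    h <- if ("H" %in% names(counts)) counts[["H"]] else 0L
    if (h < (rule$min_h %||% 0)) {
      stopf("adduct rule %s is not applicable to formula %s (needs >= %d H)",
            rule$name %||% "<unnamed>", formula, rule$min_h)
    }
  }
  (rule$n * mass + rule$shift) / rule$z
}

#' Signed mass accuracy in parts per million
#'
#' `1e6 * (observed - theoretical) / theoretical`. Note the error is not
#' exactly antisymmetric under swapping the arguments (the denominator
#' changes); by convention the theoretical m/z is the reference.
#'
#' @param observed,theoretical m/z values; `theoretical` must be positive.
#' @return Signed ppm error.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stopf("theoretical m/z must be positive")
  1e6 * (observed - theoretical) / theoretical
}
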