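#' Vasoactive-inotrope score
#'
#' Weighted linear combination of the six vasoactive infusion rates used in
#' place of the individual medications:
#' \deqn{VIS = dopamine + dobutamine + 100\,epinephrine + 10\,milrinone +
#'   10000\,vasopressin + 100\,norepinephrine}
#' with dopamine, dobutamine, epinephrine and norepinephrine in mcg/kg/min,
#' milrinone in mcg/kg/min and vasopressin in units/kg/min.
#'
#' @param dopamine,dobutamine,epinephrine,milrinone,vasopressin,norepinephrine
#'   Nonnegative infusion rates; vectors are recycled to a common length.
#' @return Numeric vector of scores (dimensionless).
#' @examples
#' compute_vis(epinephrine = 0.05)                       # 5
#' compute_vis(dopamine = 5, milrinone = 0.5, vasopressin = 5e-4)  # 15
#' @export
compute_vis <- function(dopamine = 0, dobutamine = 0, epinephrine = 0,
                        milrinone = 0, vasopressin = 0, norepinephrine = 0) {
  doses <- list(dopamine = dopamine, dobutamine = dobutamine,
                epinephrine = epinephrine, milrinone = milrinone,
                vasopressin = vasopressin, norepinephrine = norepinephrine)
  for (nm in names(doses)) {
    d <- doses[[nm]]
    if (!is.numeric(d) || anyNA(d) || any(!is.finite(d)))
      stop_validation("dose '", nm, "' must be finite numeric")
    if (any(d < 0))
      stop_validation("dose '", nm, "' must be nonnegative")
  }
  dopamine + dobutamine + 100 * epinephrine + 10 * milrinone +
    10000 * vasopressin + 100 * norepinephrine
}
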