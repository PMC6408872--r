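# Elemental formulas and monoisotopic masses of (cyclic) peptides, with the
# amatoxin modification presets, and ppm matching of candidate masses against
# MS1 peak lists.

#' @importFrom stats setNames
NULL

.ELEMENTS <- c("C", "H", "N", "O", "S")

# Monoisotopic isotope masses (Da): 12C exact, 1H, 14N, 16O, 32S.
.MONO_MASS <- c(
  C = 12,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

# In-chain residue formulas (free amino acid minus one water) for the 20
# standard amino acids, rows C,H,N,O,S.
.RESIDUE_FORMULAS <- local({
  tab <- rbind(
    #     C   H  N  O  S
    A = c(3,  5, 1, 1, 0),
    R = c(6, 12, 4, 1, 0),
    N = c(4,  6, 2, 2, 0),
    D = c(4,  5, 1, 3, 0),
    C = c(3,  5, 1, 1, 1),
    E = c(5,  7, 1, 3, 0),
    Q = c(5,  8, 2, 2, 0),
    G = c(2,  3, 1, 1, 0),
    H = c(6,  7, 3, 1, 0),
    I = c(6, 11, 1, 1, 0),
    L = c(6, 11, 1, 1, 0),
    K = c(6, 12, 2, 1, 0),
    M = c(5,  9, 1, 1, 1),
    F = c(9,  9, 1, 1, 0),
    P = c(5,  7, 1, 1, 0),
    S = c(3,  5, 1, 2, 0),
    T = c(4,  7, 1, 2, 0),
    W = c(11, 10, 2, 1, 0),
    Y = c(9,  9, 1, 2, 0),
    V = c(5,  9, 1, 1, 0)
  )
  colnames(tab) <- .ELEMENTS
  tab
})

#' Construct an elemental formula
#'
#' An elemental formula over C, H, N, O, S with non-negative integer counts.
#'
#' @param C,H,N,O,S element counts (non-negative integers).
#' @return An object of class `elemental_formula` (named integer vector).
#' @examples
#' elemental_formula(C = 39, H = 54, N = 10, O = 14, S = 1)
#' @export
elemental_formula <- function(C = 0, H = 0, N = 0, O = 0, S = 0) {
  x <- c(C = C, H = H, N = N, O = O, S = S)
  if (any(x < 0)) stop("element counts must be non-negative")
  if (any(x != round(x))) stop("element counts must be integers")
  structure(as.integer(round(x)), names = .ELEMENTS,
            class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat(format_formula(x), "\n")
  invisible(x)
}

#' Format an elemental formula in Hill-like style
#'
#' @param formula an `elemental_formula`.
#' @return A string such as `"C39H54N10O14S"` (unit counts unprinted).
#' @export
format_formula <- function(formula) {
  parts <- vapply(.ELEMENTS, function(el) {
    n <- formula[[el]]
    if (n == 0L) "" else if (n == 1L) el else paste0(el, n)
  }, character(1))
  paste0(parts, collapse = "")
}

#' Add or subtract elemental formulas
#'
#' Subtraction errors rather than producing a negative count.
#'
#' @param a,b `elemental_formula` objects.
#' @return An `elemental_formula`.
#' @export
formula_add <- function(a, b) {
  elemental_formula(
    C = a[["C"]] + b[["C"]], H = a[["H"]] + b[["H"]], N = a[["N"]] + b[["N"]],
    O = a[["O"]] + b[["O"]], S = a[["S"]] + b[["S"]]
  )
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  d <- unclass(a) - unclass(b)
  if (any(d < 0)) {
    stop("formula subtraction would give a negative count for: ",
         paste(.ELEMENTS[d < 0], collapse = ", "))
  }
  elemental_formula(C = d[["C"]], H = d[["H"]], N = d[["N"]],
                    O = d[["O"]], S = d[["S"]])
}

.WATER <- function() elemental_formula(H = 2, O = 1)

#' Elemental formula of a peptide
#'
#' Sums in-chain residue formulas; a linear peptide gains one water
#' (terminal H and OH), a head-to-tail cyclic peptide does not.
#'
#' @param aa_seq amino-acid sequence (string, standard 20 residues).
#' @param topology `"linear"` or `"cyclic"` (head-to-tail macrocycle).
#' @return An `elemental_formula`.
#' @examples
#' peptide_formula("G")                       # free glycine, C2H5NO2
#' peptide_formula("IWGIGCNP", "cyclic")      # unmodified alpha-amanitin core
#' @export
peptide_formula <- function(aa_seq, topology = c("linear", "cyclic")) {
  topology <- match.arg(topology)
  stopifnot(is.character(aa_seq), length(aa_seq) == 1L, nzchar(aa_seq))
  aa <- strsplit(toupper(aa_seq), "")[[1]]
  bad <- setdiff(aa, rownames(.RESIDUE_FORMULAS))
  if (length(bad)) {
    stop("non-standard residue(s): ", paste(unique(bad), collapse = ", "))
  }
  counts <- colSums(.RESIDUE_FORMULAS[aa, , drop = FALSE])
  f <- elemental_formula(C = counts[["C"]], H = counts[["H"]],
                         N = counts[["N"]], O = counts[["O"]],
                         S = counts[["S"]])
  if (topology == "linear") f <- formula_add(f, .WATER())
  f
}

#' Named post-translational modification sets
#'
#' A modification set is a signed elemental delta applied to a peptide
#' formula. Presets:
#' \describe{
#'   \item{tryptathionine}{Trp-Cys cross-bridge, net loss of 2 H.}
#'   \item{hydroxylation}{+1 O (use `n` for multiplicity).}
#'   \item{sulfoxide}{+1 O at the thioether sulfur.}
#'   \item{amatoxin}{the full amatoxin decoration: tryptathionine bridge,
#'     four hydroxylations and one sulfoxide, net -2 H +5 O. Applied to
#'     cyclo(IWGIGCNP) this yields the alpha-amanitin formula
#'     C39H54N10O14S.}
#' }
#'
#' @param name preset name.
#' @param n multiplicity (applies the delta `n` times).
#' @return A `mod_set`: list with `add` and `remove` elemental formulas.
#' @export
mod_set <- function(name = c("amatoxin", "tryptathionine", "hydroxylation",
                             "sulfoxide", "none"), n = 1L) {
  name <- match.arg(name)
  base <- switch(name,
    none           = list(add = elemental_formula(), remove = elemental_formula()),
    tryptathionine = list(add = elemental_formula(), remove = elemental_formula(H = 2)),
    hydroxylation  = list(add = elemental_formula(O = 1), remove = elemental_formula()),
    sulfoxide      = list(add = elemental_formula(O = 1), remove = elemental_formula()),
    amatoxin       = list(add = elemental_formula(O = 5), remove = elemental_formula(H = 2))
  )
  out <- list(name = name,
              add = Reduce(formula_add, rep(list(base$add), n)),
              remove = Reduce(formula_add, rep(list(base$remove), n)))
  class(out) <- "mod_set"
  out
}

#' Apply modification sets to a formula
#'
#' Application is additive and order-independent; removals that would drive a
#' count negative raise an error.
#'
#' @param formula an `elemental_formula`.
#' @param ... one or more `mod_set` objects.
#' @return The modified `elemental_formula`.
#' @export
apply_mods <- function(formula, ...) {
  mods <- list(...)
  for (m in mods) {
    stopifnot(inherits(m, "mod_set"))
    formula <- formula_add(formula, m$add)
  }
  for (m in mods) formula <- formula_subtract(formula, m$remove)
  formula
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula an `elemental_formula`.
#' @return Mass in Da, summing monoisotopic isotope masses.
#' @examples
#' monoisotopic_mass(peptide_formula("IWGIGCNP", "cyclic"))
#' @export
monoisotopic_mass <- function(formula) {
  stopifnot(inherits(formula, "elemental_formula"))
  sum(as.numeric(formula) * .MONO_MASS[.ELEMENTS])
}

#' m/z of an adduct ion
#'
#' By default the `"M+H"` convention adds one hydrogen-atom monoisotopic mass
#' (1.0078250 Da) per charge; set `proton = TRUE` to use the proton mass
#' (1.0072765 Da, i.e. hydrogen minus the electron) instead. Multiply-charged
#' ions divide by the charge.
#'
#' @param neutral_mass neutral monoisotopic mass (Da), > 0.
#' @param adduct `"M+H"` or `"M+2H"`.
#' @param charge ion charge (positive integer); defaults to the adduct's
#'   proton count.
#' @param proton use the proton mass instead of the hydrogen-atom mass.
#' @return m/z in Da.
#' @export
adduct_mz <- function(neutral_mass, adduct = c("M+H", "M+2H"), charge = NULL,
                      proton = FALSE) {
  adduct <- match.arg(adduct)
  if (!is.numeric(neutral_mass) || neutral_mass <= 0) {
    stop("neutral_mass must be > 0")
  }
  n_h <- switch(adduct, "M+H" = 1L, "M+2H" = 2L)
  if (is.null(charge)) charge <- n_h
  h <- if (proton) 1.0072765 else 1.0078250
  (neutral_mass + n_h * h) / charge
}

#' Relative mass error in parts per million
#'
#' @param observed,calculated masses (Da); `calculated` must be > 0.
#' @return `1e6 * (observed - calculated) / calculated`.
#' @export
ppm_error <- function(observed, calculated) {
  if (any(calculated <= 0)) stop("calculated mass must be > 0")
  1e6 * (observed - calculated) / calculated
}

#' Match MS1 peaks against candidate masses at ppm tolerance
#'
#' Every (peak, candidate) pair within tolerance is reported; a peak may
#' match several candidates and vice versa.
#'
#' @param peaks a peak list: data frame with columns `mz` (and optionally
#'   `intensity`), e.g. from [read_peak_table()].
#' @param candidates data frame with columns `name` and `mz` (calculated m/z).
#' @param tol_ppm tolerance in ppm (default 10, the study's match criterion).
#' @return Data frame with columns `name`, `calc_mz`, `obs_mz`, `intensity`,
#'   `ppm` for each match.
#' @export
match_peaks <- function(peaks, candidates, tol_ppm = 10) {
  stopifnot(tol_ppm > 0, all(c("name", "mz") %in% names(candidates)))
  if (is.null(peaks$intensity)) peaks$intensity <- rep(1, nrow(peaks))
  out <- list()
  for (i in seq_len(nrow(candidates))) {
    calc <- candidates$mz[i]
    pp <- ppm_error(peaks$mz, calc)
    hit <- which(abs(pp) <= tol_ppm)
    if (length(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        name = candidates$name[i],
        calc_mz = calc,
        obs_mz = peaks$mz[hit],
        intensity = peaks$intensity[hit],
        ppm = pp[hit],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(name = character(), calc_mz = numeric(),
                      obs_mz = numeric(), intensity = numeric(),
                      ppm = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
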