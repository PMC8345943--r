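#' Physical constants of one base type
#'
#' @param I Moment of inertia about the backbone axis (kg m^2).
#' @param R Distance from the base's center of mass to the backbone (m).
#' @param K Torsional constant of the backbone segment (J).
#' @param beta Viscous dissipation coefficient (J s); 0 switches damping
#'   off (used by conservation checks).
#' @return An object of class `base_params`.
#' @export
base_params <- function(I, R, K, beta) {
  vals <- c(I = I, R = R, K = K, beta = beta)
  if (any(!is.finite(vals)) || any(vals[c("I", "R", "K")] <= 0) || beta < 0)
    stop("I, R, K must be strictly positive and beta non-negative, all finite")
  structure(as.list(vals), class = "base_params")
}

#' Assemble a parameter table
#'
#' @param bases Named list (`A`, `C`, `G`, `T`) of [base_params()] objects.
#' @param k12 Named numeric vector `c(AT = ..., GC = ...)` of hydrogen-bond
#'   pair stiffnesses (N/m); a property of the pair, identical seen from
#'   either chain.
#' @return An object of class `param_table`.
#' @export
param_table <- function(bases, k12) {
  need <- c("A", "C", "G", "T")
  if (!is.list(bases) || !all(need %in% names(bases)))
    stop("`bases` must name entries for all of A, C, G, T")
  for (b in need)
    if (!inherits(bases[[b]], "base_params"))
      stop(sprintf("`bases$%s` is not a base_params object", b))
  if (!is.numeric(k12) || !all(c("AT", "GC") %in% names(k12)))
    stop("`k12` must be a named numeric vector with entries AT and GC")
  if (any(k12[c("AT", "GC")] <= 0)) stop("pair stiffnesses must be positive")
  structure(list(bases = bases[need],
                 k12 = c(AT = unname(k12[["AT"]]), GC = unname(k12[["GC"]]))),
            class = "param_table")
}

#' Default mechanical parameters of the four bases
#'
#' All values in SI units: moments of inertia I (kg m^2), center-of-mass
#' distances R (m), backbone torsional constants K (J), pair stiffnesses
#' k12 (N/m, per pair type: two hydrogen bonds for A-T, three for G-C),
#' and dissipation coefficients beta (J s).
#'
#' @return A `param_table`.
#' @examples
#' tab <- default_param_table()
#' tab$bases$A$I   # 7.61e-44 kg m^2
#' tab$k12[["GC"]] # 9.6e-02 N/m
#' @export
default_param_table <- function() {
  param_table(
    bases = list(
      A = base_params(I = 7.61e-44, R = 5.80e-10, K = 2.35e-18, beta = 4.25e-34),
      T = base_params(I = 4.86e-44, R = 4.80e-10, K = 1.61e-18, beta = 2.91e-34),
      G = base_params(I = 8.22e-44, R = 5.70e-10, K = 2.27e-18, beta = 4.10e-34),
      C = base_params(I = 4.11e-44, R = 4.70e-10, K = 1.54e-18, beta = 2.79e-34)),
    k12 = c(AT = 6.20e-2, GC = 9.60e-2))
}

#' Read a parameter table from a YAML file
#'
#' Expected layout (all values already in SI units):
#' ```yaml
#' bases:
#'   A: {I: 7.61e-44, R: 5.80e-10, K: 2.35e-18, beta: 4.25e-34}
#'   ...
#' k12: {AT: 6.20e-2, GC: 9.60e-2}
#' ```
#'
#' @param path Path to the YAML file.
#' @return A `param_table`.
#' @export
read_param_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("parameter file not found: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$bases) || is.null(y$k12))
    stop("parameter file must contain `bases` and `k12` sections")
  bases <- lapply(y$bases, function(b)
    base_params(I = b$I, R = b$R, K = b$K, beta = b$beta))
  param_table(bases = bases, k12 = unlist(y$k12))
}

#' @export
print.param_table <- function(x, ...) {
  cat("<param_table> (SI units)\n")
  m <- t(vapply(x$bases, function(b) unlist(b), numeric(4)))
  print(signif(m, 4))
  cat(sprintf("k12: A-T %.3g N/m, G-C %.3g N/m\n", x$k12[["AT"]], x$k12[["GC"]]))
  invisible(x)
}

#' External drive specification
#'
#' A spatially uniform periodic torque `F0 * cos(omega * t)` applied to
#' every pendulum of both chains. `omega = 0` gives a constant torque of
#' magnitude `F0`.
#'
#' @param F0 Drive amplitude (J). Default 0.5e-22 J.
#' @param omega Angular frequency of the drive (s^-1, >= 0).
#' @return An object of class `force_spec`.
#' @export
force_spec <- function(F0 = 0.5e-22, omega = 0) {
  if (!is.numeric(F0) || length(F0) != 1L || !is.finite(F0) || F0 < 0)
    stop("`F0` must be a single non-negative number (J)")
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) || omega < 0)
    stop("`omega` must be a single non-negative number (s^-1)")
  structure(list(F0 = F0, omega = omega), class = "force_spec")
}
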