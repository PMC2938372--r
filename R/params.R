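#' Default mechanical parameters for a typical cell
#'
#' Units are fixed package-wide: lengths in um, time in s, force in nN,
#' mass in ng.  Spring constants are nN/um, viscosities and drag
#' coefficients nN.s/um, pressures nN/um (force per unit boundary length
#' in 2D).  These are package defaults for a generic epithelial cell;
#' every value can be overridden per cell or per scenario.
#'
#' @param ... named overrides of any listed default.
#' @return Named list of parameters:
#' \describe{
#'   \item{R, r_n}{cell and nucleus radius, um.}
#'   \item{n}{initial node count per ring.}
#'   \item{k_rad, eta_rad}{radial (cytoskeletal) Voigt elements.}
#'   \item{k_chord, eta_chord}{diametral nucleoskeletal chords.}
#'   \item{k_mem, eta_mem}{plasma-membrane ring elements.}
#'   \item{k_nucmem, eta_nucmem}{nuclear-membrane ring elements.}
#'   \item{drag_mem}{reference substrate drag D0 per membrane node.}
#'   \item{drag_nuc}{drag per nucleus node.}
#'   \item{mass, mass_nuc}{total cytoskeleton / nucleus mass, ng
#'     (book-kept per node; unused by the overdamped integrator).}
#'   \item{P_in}{inner (osmotic) pressure, nN/um.}
#'   \item{c_s, c_g}{stop / growth volume-region coefficients,
#'     0 < c_s <= c_g.}
#'   \item{adh_k, adh_eta, adh_L0}{per-cell adhesion element template;
#'     bond parameters between two cells combine in series.}
#'   \item{tau_g}{seconds between growth (node-insertion) attempts.}
#'   \item{F_div_n, F_div_m}{spindle pull per nucleus group (nN) and
#'     contractile-ring magnitude (nN).}
#'   \item{L_div}{nucleus-centroid separation that completes division, um.}
#'   \item{A_min_frac}{apoptotic cells are removed below this fraction of
#'     the initial rest area.}
#' }
#' @export
cell_params <- function(...) {
  p <- list(
    R = 7.5, r_n = 2.5, n = 40L,
    k_rad = 1, eta_rad = 0.5,
    k_chord = 1, eta_chord = 0.5,
    k_mem = 2.5, eta_mem = 0.5,
    k_nucmem = 2.5, eta_nucmem = 0.5,
    drag_mem = 20, drag_nuc = 2,
    mass = 1, mass_nuc = 0.3,
    P_in = 0.4,
    c_s = 0.65, c_g = 0.8,
    adh_k = 2, adh_eta = 0.2, adh_L0 = 0.5,
    tau_g = 2,
    F_div_n = 2, F_div_m = 6, L_div = 5,
    A_min_frac = 0.1
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown cell parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  stopifnot(p$R > 0, p$r_n > 0, p$r_n < p$R, p$n >= 6L,
            p$c_s > 0, p$c_s <= p$c_g)
  p
}

#' Adhesion and repulsion rule
#'
#' Bonds form between nodes of different owners closer than `d_a` and
#' rupture only beyond `d_r > d_a` (hysteresis).  Short-range elastic
#' repulsion ramps linearly from zero at distance `d_rep` to
#' `k_rep * d_rep` at contact.
#'
#' @param d_a bond creation distance, um.
#' @param d_r bond rupture distance, um (must exceed `d_a`).
#' @param d_rep repulsion range, um.
#' @param k_rep repulsion stiffness, nN/um.
#' @param one_bond_per_pair at most one bond per node pair.
#' @return object of class `adhesion_rule`.
#' @export
adhesion_rule <- function(d_a = 1.5, d_r = 3.0, d_rep = 1.0, k_rep = 3,
                          one_bond_per_pair = TRUE) {
  if (!(d_a > 0 && d_a < d_r)) stop("need 0 < d_a < d_r (nonempty hysteresis band)")
  if (d_rep <= 0) stop("d_rep must be positive")
  structure(list(d_a = d_a, d_r = d_r, d_rep = d_rep, k_rep = k_rep,
                 one_bond_per_pair = isTRUE(one_bond_per_pair)),
            class = "adhesion_rule")
}

#' Combine the adhesion templates of two cells
#'
#' Bond stiffness and viscosity between two cells are the series
#' (harmonic-type) combination of the two cells' attachment templates,
#' modeling two half-links in series; symmetric in its arguments.  Set
#' `method = "mean"` for the arithmetic alternative.
#'
#' @param a,b adhesion templates: lists with elements `k` and `eta`.
#' @param method `"series"` (default) or `"mean"`.
#' @return list with combined `k` and `eta`.
#' @examples
#' combine_adhesion_params(list(k = 2, eta = 1), list(k = 2, eta = 1))$k  # 1
#' @export
combine_adhesion_params <- function(a, b, method = c("series", "mean")) {
  method <- match.arg(method)
  if (a$k <= 0 || b$k <= 0 || a$eta < 0 || b$eta < 0 ||
      (a$eta == 0 && b$eta == 0 && method == "series" && FALSE))
    stop("adhesion template parameters must be positive")
  if (a$eta <= 0 || b$eta <= 0) stop("adhesion template parameters must be positive")
  if (method == "series")
    list(k = a$k * b$k / (a$k + b$k), eta = a$eta * b$eta / (a$eta + b$eta))
  else
    list(k = (a$k + b$k) / 2, eta = (a$eta + b$eta) / 2)
}
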