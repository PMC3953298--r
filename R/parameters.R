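# Model parameters: rate constants, totals and the cytoplasm:nucleus volume
# ratio, all in uM and minutes. The default set reproduces the published
# best-fit values; the `fitted` attribute records which parameters were
# estimated from imaging data (and are therefore the subset the genetic
# algorithm perturbs).

.param_names <- c(
  "R0", "k1", "k_minus1", "k2", "k_minus2", "k3", "k_minus3", "GQ_tot",
  "k_exp_act", "k_exp", "k_imp_act", "k_imp",
  "k_mek", "K_MM_MEK", "k_MEK_basal", "ERK_tot", "MEK_tot",
  "kcat_1", "kcat_2", "kcat_3", "kcat_4", "kcat_5",
  "km_1", "km_2", "km_3", "km_4", "km_5", "kd_ppEn",
  "MKP_n", "MKP_c", "C_cn",
  "d_TF1", "k_TF1", "K_MM_TF1", "d_TF1DT", "k_TF1DT", "K_MM_TF1DT"
)

# Michaelis constants must be strictly positive; everything else >= 0.
.michaelis_names <- c("K_MM_MEK", "km_1", "km_2", "km_3", "km_4", "km_5",
                      "kd_ppEn", "K_MM_TF1", "K_MM_TF1DT")

.fitted_default <- c("R0", "k2", "k_minus2", "k_exp_act", "k_exp",
                     "k_imp_act", "k_imp", "k_mek", "K_MM_MEK", "MEK_tot")

.param_defaults <- c(
  R0 = 0.1,          # total GnRH receptor, uM
  k1 = 5000,         # GnRH-receptor association, uM^-1 min^-1
  k_minus1 = 5,      # GnRH-receptor dissociation, min^-1 (Kd = 1 nM)
  k2 = 5,            # HR-GQ association, uM^-1 min^-1
  k_minus2 = 1,      # G-protein pool recovery, min^-1
  k3 = 5.5,          # ppERK feedback on effector, uM^-1 min^-1
  k_minus3 = 0.05,   # effector deactivation, min^-1
  GQ_tot = 1,        # total G protein, uM
  k_exp_act = 0.75,  # nuclear export of ppE_n, min^-1
  k_exp = 0.75,      # nuclear export of E_n, min^-1
  k_imp_act = 0.4,   # nuclear import of ppE_c, min^-1
  k_imp = 0.2,       # nuclear import of E_c, min^-1
  k_mek = 10,        # MEK activation catalysis, min^-1
  K_MM_MEK = 0.05,   # MEK activation Michaelis constant, uM
  k_MEK_basal = 0,   # basal MEK activation, min^-1
  ERK_tot = 0.9,     # total ERK (cytoplasm-referenced), uM
  MEK_tot = 0.6,     # cytosolic MEK, uM
  kcat_1 = 0.6, kcat_2 = 5, kcat_3 = 4, kcat_4 = 4, kcat_5 = 4,   # min^-1
  km_1 = 0.05, km_2 = 0.0339, km_3 = 0.022, km_4 = 0.018, km_5 = 0.0782, # uM
  kd_ppEn = 0.01,    # nuclear dephosphorylation Michaelis constant, uM
  MKP_n = 0.05,      # nuclear phosphatase, uM
  MKP_c = 0.05,      # cytosolic phosphatase, uM
  C_cn = 3,          # cytoplasm:nucleus volume ratio
  d_TF1 = 0.023,     # TF1 degradation, min^-1
  k_TF1 = 0.03,      # TF1 activation Vmax, uM min^-1
  K_MM_TF1 = 0.4,    # TF1 activation Michaelis constant, uM
  d_TF1DT = 0.05,    # transcript degradation, min^-1
  k_TF1DT = 0.03,    # transcript production Vmax, uM min^-1
  K_MM_TF1DT = 0.5   # transcript production Michaelis constant, uM
)

#' Model parameter set
#'
#' Construct the kinetic parameter set of the GnRH-to-ERK model. All rates are
#' per minute, all concentrations in micromolar. Called with no arguments it
#' returns the published best-fit values; individual parameters can be
#' overridden by name.
#'
#' @param ... named parameter overrides, e.g. `R0 = 0.2`. Unknown names are an
#'   error.
#' @param feedback which active-ERK pool exerts negative feedback on the
#'   effector: `"nuclear"` (ppERK in the nucleus, the default — the wiring
#'   the parameter table describes for `k3`, and the one that reproduces the
#'   published upstream-effector frequency response) or `"cytosolic"`.
#' @param fitted character vector of parameter names marking the subset that
#'   the genetic algorithm is allowed to perturb. Defaults to the ten
#'   parameters estimated from imaging data.
#'
#' @return an object of class `gnrh_params`: a named numeric vector with
#'   attributes `feedback` and `fitted`.
#' @examples
#' p <- gnrh_parameters()
#' p["K_MM_TF1"]          # 0.4 uM
#' gnrh_parameters(R0 = 0.2)["R0"]
#' @export
gnrh_parameters <- function(..., feedback = c("nuclear", "cytosolic"),
                            fitted = .fitted_default) {
  feedback <- match.arg(feedback)
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(overrides), .param_names)
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  p <- .param_defaults
  p[names(overrides)] <- vapply(overrides, as.numeric, numeric(1))
  unknown_fit <- setdiff(fitted, .param_names)
  if (length(unknown_fit))
    stop("unknown fitted parameter(s): ", paste(unknown_fit, collapse = ", "))
  validate_parameters(p)
  structure(p, class = "gnrh_params", feedback = feedback, fitted = fitted)
}

validate_parameters <- function(p) {
  stopifnot(is.numeric(p), length(p) == length(.param_names))
  if (any(!is.finite(p)))
    stop("non-finite parameter value(s): ",
         paste(.param_names[!is.finite(p)], collapse = ", "))
  if (any(p < 0))
    stop("negative parameter value(s): ",
         paste(.param_names[p < 0], collapse = ", "))
  mm <- p[.michaelis_names]
  if (any(mm <= 0))
    stop("Michaelis constants must be strictly positive: ",
         paste(.michaelis_names[mm <= 0], collapse = ", "))
  if (p[["C_cn"]] <= 0) stop("C_cn must be strictly positive")
  invisible(p)
}

#' @export
print.gnrh_params <- function(x, ...) {
  cat("GnRH-ERK model parameters (uM, min):\n")
  print(stats::setNames(as.numeric(x), names(unclass(x))))
  cat("feedback via:", attr(x, "feedback"), "ppERK\n")
  cat("fitted subset:", paste(attr(x, "fitted"), collapse = ", "), "\n")
  invisible(x)
}

#' Names of the fitted parameter subset
#'
#' @param params a `gnrh_params` object.
#' @return character vector of parameter names the fitting routine perturbs.
#' @export
fitted_parameters <- function(params) attr(params, "fitted")

# Rebuild a gnrh_params object from a bare numeric vector, keeping the
# feedback mode and fitted flags of a template.
.params_from_vector <- function(x, template) {
  structure(stats::setNames(as.numeric(x), .param_names),
            class = "gnrh_params",
            feedback = attr(template, "feedback"),
            fitted = attr(template, "fitted"))
}

# Numeric vector handed to the compiled right-hand side: the 37 parameters
# followed by the segment-constant GnRH input, the MEK-inhibition flag and
# the nuclear-feedback flag (filled in per integration segment).
.solver_parms <- function(params, gnrh = 0, mek_inhibited = FALSE) {
  c(as.numeric(params), gnrh, as.numeric(mek_inhibited),
    as.numeric(identical(attr(params, "feedback"), "nuclear")))
}
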