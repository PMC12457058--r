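#' Registry of longitudinal variables
#'
#' Nine longitudinal variables are carried through the pipeline: four OGTT
#' measures (fasting and 2 h glucose, fasting and 2 h C-peptide), HbA1c, and
#' four islet autoantibody titer z-scores. OGTT measures and autoantibody
#' titers are analysed on the log(1 + x) scale; HbA1c is analysed raw (% NGSP
#' units).
#'
#' @return A data.frame with columns \code{variable}, \code{label},
#'   \code{kind} ("metabolic" or "titer"), \code{transform} (logical: is the
#'   analysis scale log(1 + x)?) and \code{ogtt} (logical: is the variable
#'   only measured at OGTT visits?).
#' @export
variable_registry <- function() {
  data.frame(
    variable = c("fasting_glu", "glu_2h", "fasting_cp", "cp_2h", "hba1c",
                 "gada_z", "ia2a_z", "iaa_z", "znt8a_z"),
    label = c("Fasting glucose (mg/dL)", "2 h glucose (mg/dL)",
              "Fasting C-peptide (ng/mL)", "2 h C-peptide (ng/mL)",
              "HbA1c (%)", "GADA-z titer", "IA-2A-z titer", "IAA-z titer",
              "ZnT8A-z titer"),
    kind = c(rep("metabolic", 5), rep("titer", 4)),
    transform = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    ogtt = c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 5)),
    stringsAsFactors = FALSE
  )
}

#' log(1 + x) analysis-scale transform
#'
#' OGTT measures and autoantibody titer z-scores enter every model on the
#' log(1 + x) scale. The transform is only defined for x > -1; titer
#' z-scores in practice stay well above that bound.
#'
#' @param x raw value(s), must be > -1
#' @param variable optional variable name used in error messages
#' @return log(1 + x)
#' @seealso [inv_log1p_transform()]
#' @examples
#' log1p_transform(0)       # 0
#' log1p_transform(0.417)   # log(1.417)
#' @export
log1p_transform <- function(x, variable = NULL) {
  bad <- is.finite(x) & x <= -1
  if (any(bad)) {
    stop(sprintf(
      "log(1+x) transform undefined for value(s) <= -1%s: %s",
      if (is.null(variable)) "" else paste0(" in variable '", variable, "'"),
      paste(utils::head(x[bad], 3), collapse = ", ")
    ), call. = FALSE)
  }
  log1p(x)
}

#' Inverse of the log(1 + x) transform
#' @param y analysis-scale value(s)
#' @return exp(y) - 1
#' @export
inv_log1p_transform <- function(y) expm1(y)

#' Apply the per-variable analysis-scale transform
#'
#' @param value raw values
#' @param variable variable names (recycled against \code{value})
#' @return values on the analysis scale (log(1+x) where the registry flags
#'   the variable, raw otherwise)
#' @export
apply_transform <- function(value, variable) {
  reg <- variable_registry()
  unknown <- setdiff(unique(variable), reg$variable)
  if (length(unknown) > 0) {
    stop("unknown longitudinal variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  flag <- reg$transform[match(variable, reg$variable)]
  out <- value
  if (any(flag)) {
    for (v in unique(variable[flag])) {
      idx <- variable == v & flag
      out[idx] <- log1p_transform(value[idx], variable = v)
    }
  }
  out
}
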