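# Model suite and design-matrix construction. The seven standard models
# share the structure: alpha power as a Gaussian response, participant
# random intercept, and fixed effects built from Sleep (0-10, raw scale),
# Group (0 = abstinent reference, 1 = non-abstinent), Eyes (0 = closed
# reference, 1 = open) and the continuous electrode axes ML/AP/IS.
# Interactions always include their non-redundant lower-order constituents.

modelVariables <- c("Sleep", "Group", "Eyes", "ML", "AP", "IS")

standardModelTerms <- list(
  "1" = "Group + Eyes + ML * AP * IS",
  "2" = "Sleep + Eyes + ML * AP * IS",
  "3" = "Sleep * Group + Eyes + ML * AP * IS",
  "4" = "Sleep * Group * Eyes + ML * AP * IS",
  "5" = "Sleep * Group * ML + Eyes + ML * AP * IS",
  "6" = "Sleep * Group * AP + Eyes + ML * AP * IS",
  "7" = "Sleep * Group * IS + Eyes + ML * AP * IS")

#' Fixed-effect formula of a model
#'
#' Models 1-7 are the standard suite; a custom right-hand side over Sleep,
#' Group, Eyes, ML, AP, IS may be given instead (e.g.
#' \code{"Sleep * Group * Eyes * AP + ML * AP * IS"} for an exploratory
#' four-way model). "x" may be used in place of "*".
#'
#' @param model integer 1-7 or a character fixed-effects expression
#' @return a one-sided formula
#' @export
modelFormula <- function(model = 3) {
  rhs <- if (is.numeric(model) || model %in% names(standardModelTerms)) {
    key <- as.character(model)
    if (!key %in% names(standardModelTerms))
      stopLabeled("model", "no standard model ", key, "; use 1-7 or a ",
                  "custom term expression")
    standardModelTerms[[key]]
  } else {
    gsub("(?<=\\s)x(?=\\s)", "*", model, perl = TRUE)
  }
  vars <- all.vars(stats::as.formula(paste("~", rhs)))
  unknown <- setdiff(vars, modelVariables)
  if (length(unknown))
    stopLabeled("model", "unknown model term variable(s): ",
                paste(unknown, collapse = ", "), " (allowed: ",
                paste(modelVariables, collapse = ", "), ")")
  stats::as.formula(paste("~", rhs))
}

#' Build design matrices from the long alpha-power table
#'
#' Treatment coding: Group 0 = abstinent (reference), 1 = non-abstinent;
#' Eyes 0 = closed (reference), 1 = open; Sleep on its raw 0-10 scale;
#' ML/AP/IS the unit-sphere Cartesian coordinates. Interaction columns are
#' products of coded columns, expanded by \code{stats::model.matrix} in a
#' deterministic order with an intercept.
#'
#' @param table long data.frame from \code{\link{buildLongTable}} or
#'   \code{\link{generateAlphaTable}}
#' @param model model id 1-7 or custom term expression (see
#'   \code{\link{modelFormula}})
#' @return list: y (response), X (fixed-effects matrix), pid (participant
#'   factor), formula, coding (reference-level metadata)
#' @export
buildDesign <- function(table, model = 3) {
  if (!nrow(table)) stopLabeled("design", "table is empty")
  need <- c("participant", "log_alpha_power", "group", "sleep_quality",
            "condition", "ml", "ap", "is")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stopLabeled("design", "table missing column(s): ",
                paste(miss, collapse = ", "))
  if (anyNA(table[, need]))
    stopLabeled("design", "covariates or response contain missing values")
  dat <- data.frame(
    Sleep = as.numeric(table$sleep_quality),
    Group = as.numeric(table$group == "non_abstinent"),
    Eyes = as.numeric(table$condition == "open"),
    ML = table$ml, AP = table$ap, IS = table$is)
  fml <- modelFormula(model)
  X <- stats::model.matrix(fml, dat)
  list(y = as.numeric(table$log_alpha_power),
       X = X,
       pid = factor(table$participant, levels = unique(table$participant)),
       formula = fml,
       coding = list(group_reference = "abstinent",
                     eyes_reference = "closed",
                     sleep_scale = "raw 0-10"))
}
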