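#' Declare one outcome dimension of a multivariate mixed model
#'
#' An outcome dimension couples a response column with the covariates entering
#' its fixed-effect design matrix `X_k` and its random-effect design matrix
#' `Z_k`. Both designs always carry a leading intercept column, so an empty
#' `fixed`/`random` means intercept-only. The random part must contain at
#' least the intercept: the model needs a group-level deviation per dimension
#' for the cross-outcome correlation to be defined.
#'
#' @param name Response column name.
#' @param fixed Character vector of fixed-effect covariate columns (the
#'   intercept is implicit and always first).
#' @param random Character vector of random-effect covariate columns (the
#'   random intercept is implicit and always first).
#' @return An object of class `"outcome_spec"`.
#' @examples
#' outcome_spec("weight", fixed = c("sex", "Nscore", "age"), random = "Nscore")
#' @export
outcome_spec <- function(name, fixed = character(), random = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  fixed <- as.character(fixed)
  random <- as.character(random)
  if (anyDuplicated(fixed)) stop("duplicate fixed covariate names in '", name, "'")
  if (anyDuplicated(random)) stop("duplicate random covariate names in '", name, "'")
  structure(list(name = name, fixed = fixed, random = random),
            class = "outcome_spec")
}

#' Declare a multivariate linear mixed model
#'
#' Collects `m >= 2` outcome dimensions sharing a single grouping factor
#' (subject, school, ...). Each group contributes one stacked random-effect
#' vector, jointly Gaussian across dimensions with an unstructured covariance
#' matrix; residuals are homoscedastic and independent across dimensions.
#'
#' @param outcomes List of [outcome_spec()] objects (length `m >= 2`).
#' @param group Name of the grouping column.
#' @return An object of class `"mvlmm_spec"`.
#' @examples
#' spec <- mvlmm_spec(
#'   outcomes = list(
#'     outcome_spec("weight", fixed = c("sex", "Nscore", "age"), random = "Nscore"),
#'     outcome_spec("height", fixed = c("sex", "Nscore", "age"), random = "Nscore")
#'   ),
#'   group = "subject"
#' )
#' @export
mvlmm_spec <- function(outcomes, group) {
  if (inherits(outcomes, "outcome_spec")) outcomes <- list(outcomes)
  stopifnot(is.list(outcomes), is.character(group), length(group) == 1L)
  if (!all(vapply(outcomes, inherits, logical(1), "outcome_spec")))
    stop("'outcomes' must be a list of outcome_spec objects")
  if (length(outcomes) < 2L)
    stop("a multivariate model needs at least two outcomes (m >= 2)")
  nms <- vapply(outcomes, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("outcome names must be distinct")
  structure(list(outcomes = outcomes, group = group), class = "mvlmm_spec")
}

#' @export
print.mvlmm_spec <- function(x, ...) {
  cat("Multivariate linear mixed model specification\n")
  cat("  grouping factor:", x$group, "\n")
  for (o in x$outcomes) {
    cat(sprintf("  %s ~ 1%s | random: 1%s\n", o$name,
                if (length(o$fixed)) paste0(" + ", paste(o$fixed, collapse = " + ")) else "",
                if (length(o$random)) paste0(" + ", paste(o$random, collapse = " + ")) else ""))
  }
  invisible(x)
}

# Extract the bivariate sub-spec for a pair of outcome indices.
subset_spec <- function(spec, idx) {
  structure(list(outcomes = spec$outcomes[idx], group = spec$group),
            class = "mvlmm_spec")
}
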