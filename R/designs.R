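#' Build per-group design matrices from long-format data
#'
#' Turns a long-format dataset (one row per observation occasion) and a model
#' specification into the per-group, per-dimension response vectors and design
#' matrices `y_ki`, `X_ki`, `Z_ki` that the EM estimator consumes. Missingness
#' is handled per dimension: a row whose outcome `k` or any covariate of
#' dimension `k` is missing is dropped from dimension `k` only, leaving the
#' other dimensions untouched. Both `X` and `Z` carry a leading intercept
#' column; categorical covariates are dummy-coded with the first observed
#' level as reference. Row order within a group follows the input order.
#'
#' @param data A data.frame with the group column, outcome columns and
#'   covariate columns. Empty/NA cells mark missing values.
#' @param spec An [mvlmm_spec()].
#' @return An object of class `"mvlmm_designs"`: a list with `groups` (one
#'   entry per group holding `y`, `X`, `Z` and per-dimension row counts `N`),
#'   the dimension counts `p`, `q`, per-dimension totals `N`, the number of
#'   groups `n` and column names.
#' @examples
#' d <- data.frame(subject = rep(1:3, each = 2), x = rnorm(6),
#'                 y1 = rnorm(6), y2 = rnorm(6))
#' spec <- mvlmm_spec(list(outcome_spec("y1", fixed = "x"),
#'                         outcome_spec("y2", fixed = "x")), group = "subject")
#' ds <- build_designs(d, spec)
#' ds$N  # total rows per dimension
#' @export
build_designs <- function(data, spec) {
  stopifnot(inherits(spec, "mvlmm_spec"), is.data.frame(data))
  m <- length(spec$outcomes)
  needed <- unique(c(spec$group,
                     unlist(lapply(spec$outcomes,
                                   function(o) c(o$name, o$fixed, o$random)))))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "))
  gcol <- data[[spec$group]]
  if (anyNA(gcol)) stop("grouping column '", spec$group, "' has missing values")
  group_ids <- unique(gcol)

  covariates <- unique(unlist(lapply(spec$outcomes, function(o) c(o$fixed, o$random))))
  expansions <- lapply(covariates, function(cv) expand_covariate(data[[cv]], cv))
  names(expansions) <- covariates

  groups <- vector("list", length(group_ids))
  N_tot <- integer(m)
  for (gi in seq_along(group_ids)) {
    rows_g <- which(gcol == group_ids[[gi]])
    ys <- Xs <- Zs <- vector("list", m)
    Nk <- integer(m)
    for (k in seq_len(m)) {
      o <- spec$outcomes[[k]]
      used <- c(o$name, o$fixed, o$random)
      keep <- rows_g[stats::complete.cases(data[rows_g, used, drop = FALSE])]
      Nk[k] <- length(keep)
      ys[[k]] <- as.numeric(data[[o$name]][keep])
      Xs[[k]] <- assemble_design(expansions, o$fixed, keep, length(keep))
      Zs[[k]] <- assemble_design(expansions, o$random, keep, length(keep))
    }
    groups[[gi]] <- list(id = group_ids[[gi]], y = ys, X = Xs, Z = Zs, N = Nk)
    N_tot <- N_tot + Nk
  }

  out_names <- vapply(spec$outcomes, `[[`, character(1), "name")
  zero <- which(N_tot == 0L)
  if (length(zero))
    stop("dimension(s) with no usable rows after missing-data removal: ",
         paste(out_names[zero], collapse = ", "))
  n <- length(groups)
  if (n < 2L) stop("at least two groups are required (found ", n, ")")
  if (any(N_tot / n <= 1))
    warning("fewer than two observations per group on average in dimension(s) ",
            paste(out_names[N_tot / n <= 1], collapse = ", "),
            ": the random-effects parameters and the residual variance are ",
            "unidentifiable when N_k/n = 1")

  p <- vapply(seq_len(m), function(k) ncol(groups[[1]]$X[[k]]), integer(1))
  q <- vapply(seq_len(m), function(k) ncol(groups[[1]]$Z[[k]]), integer(1))
  xn <- lapply(seq_len(m), function(k) colnames(groups[[1]]$X[[k]]))
  zn <- lapply(seq_len(m), function(k) colnames(groups[[1]]$Z[[k]]))
  structure(list(groups = groups, m = m, n = n, p = p, q = q, qtot = sum(q),
                 N = N_tot, outcome_names = out_names, group_name = spec$group,
                 xnames = xn, znames = zn),
            class = "mvlmm_designs")
}

# Expand one covariate column to numeric column(s). Categorical covariates are
# dummy coded against the first observed level; a single observed level yields
# no columns (and a degenerate-design warning).
expand_covariate <- function(col, name) {
  if (is.numeric(col)) {
    mat <- matrix(as.numeric(col), ncol = 1, dimnames = list(NULL, name))
    return(mat)
  }
  if (is.logical(col)) {
    mat <- matrix(as.numeric(col), ncol = 1, dimnames = list(NULL, name))
    return(mat)
  }
  lev <- unique(as.character(col[!is.na(col)]))
  if (length(lev) < 2L) {
    warning("covariate '", name, "' has a single observed level ('",
            lev, "'): degenerate design, no contrast column produced")
    mat <- matrix(numeric(length(col) * 0L), nrow = length(col), ncol = 0L)
    # keep NA bookkeeping: a row is missing if the original value is NA
    attr(mat, "na_rows") <- is.na(col)
    return(mat)
  }
  mat <- vapply(lev[-1L], function(l) as.numeric(as.character(col) == l),
                numeric(length(col)))
  mat <- matrix(mat, nrow = length(col),
                dimnames = list(NULL, paste0(name, lev[-1L])))
  mat[is.na(col), ] <- NA_real_
  mat
}

assemble_design <- function(expansions, cov_names, rows, nr) {
  parts <- c(list(`(Intercept)` = matrix(1, nrow = nr, ncol = 1,
                                         dimnames = list(NULL, "(Intercept)"))),
             lapply(expansions[cov_names], function(e) e[rows, , drop = FALSE]))
  do.call(cbind, parts)
}

#' @export
print.mvlmm_designs <- function(x, ...) {
  cat(sprintf("Design set: %d groups, %d outcome dimension(s)\n", x$n, x$m))
  for (k in seq_len(x$m))
    cat(sprintf("  %s: N = %d, p = %d fixed columns, q = %d random columns\n",
                x$outcome_names[k], x$N[k], x$p[k], x$q[k]))
  invisible(x)
}

#' Restrict a design set to a subset of outcome dimensions
#'
#' Used internally to fit dimensions separately (initialization and the null
#' model of the correlation test), where the likelihood factorizes across
#' dimensions.
#'
#' @param designs An `"mvlmm_designs"` object.
#' @param k Integer vector of dimension indices to keep.
#' @return An `"mvlmm_designs"` object over the selected dimensions.
#' @export
subset_designs <- function(designs, k) {
  stopifnot(inherits(designs, "mvlmm_designs"), all(k %in% seq_len(designs$m)))
  groups <- lapply(designs$groups, function(g)
    list(id = g$id, y = g$y[k], X = g$X[k], Z = g$Z[k], N = g$N[k]))
  structure(list(groups = groups, m = length(k), n = designs$n,
                 p = designs$p[k], q = designs$q[k], qtot = sum(designs$q[k]),
                 N = designs$N[k], outcome_names = designs$outcome_names[k],
                 group_name = designs$group_name,
                 xnames = designs$xnames[k], znames = designs$znames[k]),
            class = "mvlmm_designs")
}
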