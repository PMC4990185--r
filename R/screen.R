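#' All-pairs correlation screening across many outcomes
#'
#' Runs the bivariate random-effect correlation test for every unordered pair
#' of outcomes of an `m >= 3` outcome specification, in deterministic
#' (lexicographic by outcome name) order, and applies a Bonferroni adjustment
#' `p_adj = min(1, p * m(m-1)/2)` to the raw asymptotic p-values. A pair
#' whose fit fails is recorded as missing with a warning rather than aborting
#' the screen.
#'
#' @param data Long-format data.frame.
#' @param spec An [mvlmm_spec()] with `m >= 3` outcomes.
#' @param options An [em_options()].
#' @return An object of class `"mvlmm_pairs"`: a results data.frame (`pair`,
#'   `S`, `df`, `p`, `p_adj`) and symmetric matrices `p` and `p_adj` over the
#'   outcomes.
#' @export
pairwise_tests <- function(data, spec, options = em_options()) {
  stopifnot(inherits(spec, "mvlmm_spec"))
  m <- length(spec$outcomes)
  if (m < 3L) stop("pairwise screening needs at least three outcomes")
  nms <- vapply(spec$outcomes, `[[`, character(1), "name")
  ord <- order(nms)
  pairs <- utils::combn(ord, 2L)
  npairs <- ncol(pairs)
  res <- data.frame(outcome1 = character(npairs), outcome2 = character(npairs),
                    S = NA_real_, df = NA_integer_, p = NA_real_,
                    p_adj = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(npairs)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    res$outcome1[j] <- nms[i1]; res$outcome2[j] <- nms[i2]
    tst <- tryCatch(
      bivariate_correlation_test(data, subset_spec(spec, c(i1, i2)),
                                 options = options),
      error = function(e) {
        warning("pair (", nms[i1], ", ", nms[i2], ") failed: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(tst)) next
    res$S[j] <- tst$S
    res$df[j] <- tst$df
    res$p[j] <- tst$p_asymptotic
  }
  res$p_adj <- pmin(1, res$p * npairs)
  P <- Padj <- matrix(NA_real_, m, m, dimnames = list(nms, nms))
  for (j in seq_len(npairs)) {
    a <- res$outcome1[j]; b <- res$outcome2[j]
    P[a, b] <- P[b, a] <- res$p[j]
    Padj[a, b] <- Padj[b, a] <- res$p_adj[j]
  }
  structure(list(results = res, p = P, p_adj = Padj, outcomes = sort(nms),
                 n_pairs = npairs),
            class = "mvlmm_pairs")
}

#' @export
print.mvlmm_pairs <- function(x, digits = 4, ...) {
  cat(sprintf("Pairwise random-effect correlation screen: %d outcomes, %d pairs\n",
              length(x$outcomes), x$n_pairs))
  out <- x$results
  out$S <- round(out$S, digits)
  out$p <- signif(out$p, digits)
  out$p_adj <- signif(out$p_adj, digits)
  print(out)
  invisible(x)
}

#' Hierarchical clustering of outcomes from the correlation screen
#'
#' Builds an agglomerative cluster tree of the outcomes from the pairwise
#' evidence of random-effect correlation, measured on the
#' `-log(max(p, p_floor))` scale: the smaller a pair's p-value, the farther
#' that pair sits from independence and the stronger its association. The
#' tree groups strongly associated outcomes on the same branch (they merge
#' at low heights), while outcomes whose pairwise test is non-significant
#' end up distant. Operationally the agglomeration runs on the reversed
#' association scale, `max(A) - A_ij` with `A_ij = -log(max(p_ij,
#' p_floor))`; the tree topology does not depend on the reversal constant.
#' The floor keeps the scale finite when p-values underflow to zero.
#'
#' @param pmat An `"mvlmm_pairs"` object from [pairwise_tests()].
#' @param use_adjusted Use the Bonferroni-adjusted p-values instead of raw.
#' @param linkage Agglomeration method: `"average"` (default), `"single"` or
#'   `"complete"`.
#' @param p_floor Lower bound applied to p-values before the log.
#' @return An object of class `"mvlmm_tree"`: the `hclust` object, the
#'   association matrix `association` (`-log p`), the clustering
#'   `dissimilarity` actually fed to the agglomeration, and the tree
#'   serialized as a Newick string.
#' @export
cluster_outcomes <- function(pmat, use_adjusted = FALSE,
                             linkage = c("average", "single", "complete"),
                             p_floor = 1e-300) {
  stopifnot(inherits(pmat, "mvlmm_pairs"))
  linkage <- match.arg(linkage)
  P <- if (use_adjusted) pmat$p_adj else pmat$p
  off <- P[upper.tri(P)]
  if (anyNA(off))
    stop("incomplete p-value matrix: rerun or impute the failed pairs ",
         "before clustering")
  A <- -log(pmax(P, p_floor))
  diag(A) <- 0
  D <- max(A) - A
  diag(D) <- 0
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, association = A, dissimilarity = D,
                 newick = newick, linkage = linkage,
                 use_adjusted = use_adjusted, p_floor = p_floor),
            class = "mvlmm_tree")
}

#' @export
print.mvlmm_tree <- function(x, ...) {
  cat("Outcome cluster tree (-log p association scale, ", x$linkage,
      " linkage)\n", sep = "")
  cat(x$newick, "\n")
  invisible(x)
}
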