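#' Select the top fraction of clones by score
#'
#' Returns the `ceiling(fraction * n)` clones with the largest scores
#' ("top" meaning largest, as higher starch and dry matter are the breeding
#' targets). Ties at the cutoff are broken by ascending clone id (stable and
#' documented) with a warning; missing scores are excluded with a warning.
#'
#' @param scores Named numeric vector (names = clone ids).
#' @param fraction Selected fraction (default 0.20).
#' @return Character vector of selected clone ids.
#' @export
select_top_fraction <- function(scores, fraction = 0.20) {
  if (is.null(names(scores))) stopf("scores must be named by clone id")
  if (anyNA(scores)) {
    warnf("%d clone(s) with missing scores excluded from selection", sum(is.na(scores)))
    scores <- scores[!is.na(scores)]
  }
  n <- length(scores)
  if (n == 0) stopf("no scored clones")
  n_sel <- ceiling(fraction * n)
  ord <- order(-scores, names(scores))
  sel <- names(scores)[ord[seq_len(n_sel)]]
  if (n_sel < n) {
    cutoff <- scores[ord[n_sel]]
    if (any(scores[ord[(n_sel + 1):n]] == cutoff)) {
      warnf("tie at the selection cutoff broken by ascending clone id")
    }
  }
  sel
}

#' Cohen's unweighted kappa between two selection sets
#'
#' Builds the 2x2 selected/not-selected confusion matrix over the clone
#' universe and computes observed agreement `po = (both + neither) / n`,
#' chance agreement `pe = pa*pb + (1-pa)*(1-pb)` from the marginal selection
#' rates, and `kappa = (po - pe) / (1 - pe)`. The degenerate case
#' `po = pe = 1` (both methods select everything or nothing) is defined as
#' kappa = 1.
#'
#' @param set_a,set_b Character vectors of selected clone ids.
#' @param universe Character vector of all clone ids (the selection universe),
#'   or a single integer count when ids are irrelevant.
#' @return A `concordance_result`: `confusion` (2x2 matrix), `po`, `pe`,
#'   `kappa`, set sizes.
#' @export
cohen_kappa <- function(set_a, set_b, universe) {
  if (length(universe) == 1 && is.numeric(universe)) {
    n <- as.integer(universe)
  } else {
    universe <- unique(as.character(universe))
    n <- length(universe)
    extra <- setdiff(c(set_a, set_b), universe)
    if (length(extra)) stopf("selected ids outside the clone universe")
    set_a <- intersect(set_a, universe)
    set_b <- intersect(set_b, universe)
  }
  if (n == 0) stopf("empty clone universe")
  both <- length(intersect(set_a, set_b))
  a_only <- length(set_a) - both
  b_only <- length(set_b) - both
  neither <- n - both - a_only - b_only
  confusion <- matrix(c(both, a_only, b_only, neither), 2, 2, byrow = TRUE,
                      dimnames = list(a = c("selected", "not"),
                                      b = c("selected", "not")))
  po <- (both + neither) / n
  pa <- length(set_a) / n
  pb <- length(set_b) / n
  pe <- pa * pb + (1 - pa) * (1 - pb)
  kappa <- if (abs(1 - pe) < 1e-12) {
    if (abs(po - 1) < 1e-12) 1 else NA_real_
  } else {
    (po - pe) / (1 - pe)
  }
  structure(list(confusion = confusion, po = po, pe = pe, kappa = kappa,
                 n = n, n_a = length(set_a), n_b = length(set_b)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> n=%d po=%.3f pe=%.3f kappa=%.4f\n",
              x$n, x$po, x$pe, x$kappa))
  invisible(x)
}

#' Pairwise kappa table over several selection methods
#'
#' Computes Cohen's kappa for every pair of named selection sets over a
#' common clone universe; the diagonal is 1 by convention. Mismatched
#' universes should be intersected by the caller before selection.
#'
#' @param selections Named list of clone-id sets.
#' @param universe Clone universe (ids or count), as in [cohen_kappa()].
#' @return List: `kappa` (symmetric matrix), `long` (data frame
#'   `method_a`, `method_b`, `kappa` for the unique off-diagonal pairs).
#' @export
concordance_matrix <- function(selections, universe) {
  m <- length(selections)
  if (m < 2) stopf("need at least two selection methods")
  nm <- names(selections)
  K <- matrix(1, m, m, dimnames = list(nm, nm))
  long <- NULL
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      k <- cohen_kappa(selections[[i]], selections[[j]], universe)$kappa
      K[i, j] <- K[j, i] <- k
      long <- rbind(long, data.frame(method_a = nm[i], method_b = nm[j],
                                     kappa = k, stringsAsFactors = FALSE))
    }
  }
  list(kappa = K, long = long)
}
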