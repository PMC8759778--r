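## pair-counting helpers: C(n, 2) over subtype count vectors
.pairs2 <- function(n) n * (n - 1) / 2

#' Log-likelihood ratio of subtype sharing within clonotypes
#'
#' P is the probability that two distinct cells drawn (without replacement)
#' from the same TRB clonotype share a Th subtype, pooling all
#' within-clonotype pairs; P0 is the same probability for two cells drawn
#' from all cells of the same patient (the prior, without TCR knowledge).
#' Both are constrained to within-patient pairs.  The statistic is
#' log2(P / P0).  Cells without a subtype are excluded.
#'
#' @param cells data.frame with columns \code{patient_id},
#'   \code{clone_key} (NA allowed), \code{subtype}
#' @return list(P, P0, llr, n_pairs_clone, n_pairs_all)
#' @export
pairLlr <- function(cells) {
  cells <- cells[!is.na(cells$subtype) & cells$subtype != "none", , drop = FALSE]
  if (!nrow(cells)) .stopf("no subtyped cells")
  ## prior: all within-patient pairs
  tot_all <- 0; same_all <- 0
  for (df in split(cells, cells$patient_id)) {
    n <- nrow(df)
    tot_all <- tot_all + .pairs2(n)
    same_all <- same_all + sum(.pairs2(table(df$subtype)))
  }
  ## within-clonotype pairs (patient-scoped clone keys)
  cc <- cells[!is.na(cells$clone_key), , drop = FALSE]
  tot_cl <- 0; same_cl <- 0
  for (df in split(cc, paste(cc$patient_id, cc$clone_key, sep = "\r"))) {
    n <- nrow(df)
    if (n < 2) next
    tot_cl <- tot_cl + .pairs2(n)
    same_cl <- same_cl + sum(.pairs2(table(df$subtype)))
  }
  if (tot_cl == 0) .stopf("no clonotype with >= 2 subtyped cells")
  if (tot_all == 0) .stopf("no eligible within-patient pairs")
  P <- same_cl / tot_cl
  P0 <- same_all / tot_all
  llr <- if (P > 0 && P0 > 0) log2(P / P0) else NA_real_
  list(P = P, P0 = P0, llr = llr,
       n_pairs_clone = tot_cl, n_pairs_all = tot_all)
}

#' Two-sided chi-square proportion test (1 df, no continuity correction)
#'
#' Closed-form 2x2 chi-square n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) for
#' comparing k1/n1 against k2/n2; p from the upper tail of chi-square with
#' one degree of freedom (two-sided by construction).
#'
#' @param k1,n1,k2,n2 successes and totals in the two groups
#' @return list(statistic, p, low_expected flag)
#' @export
chi2ProportionTest <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  a <- k1; b <- n1 - k1; cc <- k2; d <- n2 - k2
  n <- a + b + cc + d
  denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
  stat <- if (denom == 0) 0 else n * (a * d - b * cc)^2 / denom
  expected <- outer(c(a + b, cc + d), c(a + cc, b + d)) / n
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       low_expected = any(expected < 1))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param k successes, 0 <= k <= n
#' @param n trials
#' @param level confidence level, default 0.85
#' @return c(lo, hi); always brackets k/n
#' @export
binomialCi <- function(k, n, level = 0.85) {
  stopifnot(n > 0, k >= 0, k <= n)
  alpha <- 1 - level
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lo = lo, hi = hi)
}

#' Bonferroni adjustment
#' @param p numeric p values
#' @param m family size (default length(p))
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, m * p)

#' TCR-distance-binned convergence statistics
#'
#' For each Th subtype and each TCR-distance bin, the probability that both
#' cells of a within-patient pair at that distance belong to the subtype,
#' normalized to the prior probability that two random within-patient cells
#' both belong to it.  Cell pairs are pairs of cells from distinct
#' clonotypes of the same patient, weighted exactly by clonotype sizes;
#' the default first bin boundary of 9 makes "highly similar" pairs
#' (TCRdist < 9) the leftmost point.  Each point carries a chi-square
#' proportion test against the prior (Bonferroni-adjusted over the subtype
#' x bin family) and an 85% Clopper-Pearson CI.
#'
#' @param clone_pairs data.frame from \code{tcrdistPairs}
#' @param clone_cells data.frame(patient_id, clone_key, subtype): one row
#'   per cell (subtyped cells with a clonotype)
#' @param breaks right-open bin edges over distance, default c(0, 9, 17, 25)
#' @param ci_level binomial CI level, default 0.85
#' @return data.frame(subtype, bin, n_pairs, k_same, proportion, prior,
#'   likelihood, chi2, p, p_adj, ci_lo, ci_hi, empty)
#' @export
binnedConvergence <- function(clone_pairs, clone_cells,
                              breaks = c(0, 9, 17, 25), ci_level = 0.85) {
  cells <- clone_cells[!is.na(clone_cells$subtype) &
                       clone_cells$subtype != "none", , drop = FALSE]
  subtypes <- sort(unique(cells$subtype))
  ## per-(patient, clone) subtype composition
  comp_key <- paste(cells$patient_id, cells$clone_key, sep = "\r")
  comp <- lapply(split(cells$subtype, comp_key), table)
  sizes <- vapply(comp, sum, 0)
  ## prior: both cells of a random within-patient pair in subtype s
  tot_all <- 0
  same_all <- stats::setNames(numeric(length(subtypes)), subtypes)
  for (df in split(cells, cells$patient_id)) {
    n <- nrow(df)
    tot_all <- tot_all + .pairs2(n)
    tb <- table(df$subtype)
    same_all[names(tb)] <- same_all[names(tb)] + .pairs2(as.numeric(tb))
  }
  prior <- same_all / tot_all
  ## bin each clonotype pair; weight by size1*size2 cell pairs
  pk1 <- paste(clone_pairs$patient_id, clone_pairs$cdr3b_1, sep = "\r")
  pk2 <- paste(clone_pairs$patient_id, clone_pairs$cdr3b_2, sep = "\r")
  keep <- pk1 %in% names(comp) & pk2 %in% names(comp)
  cp <- clone_pairs[keep, , drop = FALSE]
  pk1 <- pk1[keep]; pk2 <- pk2[keep]
  bin <- cut(cp$dist, breaks, right = FALSE, include.lowest = FALSE)
  bin_labels <- levels(cut(numeric(), breaks, right = FALSE))
  out <- list()
  for (b in bin_labels) {
    sel <- which(!is.na(bin) & bin == b)
    n_pairs_b <- if (length(sel))
      sum(sizes[pk1[sel]] * sizes[pk2[sel]]) else 0
    for (s in subtypes) {
      k_same <- if (length(sel)) sum(vapply(sel, function(i) {
        c1 <- comp[[pk1[i]]]; c2 <- comp[[pk2[i]]]
        as.numeric(c1[s] %|NA|% 0) * as.numeric(c2[s] %|NA|% 0)
      }, 0)) else 0
      empty <- n_pairs_b == 0
      propn <- if (empty) NA_real_ else k_same / n_pairs_b
      lik <- if (empty) NA_real_ else propn / prior[[s]]
      if (!empty) {
        ct <- chi2ProportionTest(k_same, n_pairs_b,
                                 round(same_all[[s]]), round(tot_all))
        ci <- binomialCi(k_same, n_pairs_b, ci_level)
      } else {
        ct <- list(statistic = NA_real_, p = NA_real_)
        ci <- c(lo = NA_real_, hi = NA_real_)
      }
      out[[length(out) + 1]] <- data.frame(
        subtype = s, bin = b, n_pairs = n_pairs_b, k_same = k_same,
        proportion = propn, prior = prior[[s]], likelihood = lik,
        chi2 = ct$statistic, p = ct$p, ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
        empty = empty, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$p_adj <- bonferroni(res$p, m = sum(!is.na(res$p)))
  rownames(res) <- NULL
  res
}

## NA-coalescing lookup helper for table subscripts
`%|NA|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x
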