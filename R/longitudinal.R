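#' Module clones: clonotypes touched by a module at least once
#'
#' A clonotype belongs to a module's clone set iff at least one of its
#' member cells (any time point, activated compartments) expresses the
#' module.  This keeps cells that gain or lose the phenotype during
#' therapy inside the analysis.
#'
#' @param cells data.frame(barcode, clone_key, subset) of activated
#'   (CD154/CD137) cells with a clonotype
#' @param expressing logical per cell: expresses the module
#' @return character vector of included clone keys
#' @export
defineModuleClones <- function(cells, expressing) {
  stopifnot(nrow(cells) == length(expressing))
  keep <- cells$subset %in% c("CD154", "CD137") & expressing
  sort(unique(cells$clone_key[keep]))
}

#' Mean module score over a clone set, per patient and time point
#'
#' @param cells data.frame(barcode, clone_key, patient_id, time_point)
#' @param scores numeric module score per cell (same order)
#' @param clone_set clone keys from \code{defineModuleClones}
#' @return data.frame(patient_id, time_point, n_cells, mean_score); a
#'   missing patient x time combination is absent (missing, not zero)
#' @export
cloneModuleTrajectory <- function(cells, scores, clone_set) {
  stopifnot(nrow(cells) == length(scores))
  sel <- cells$clone_key %in% clone_set
  if (!any(sel)) .stopf("clone set matches no cells")
  df <- cells[sel, , drop = FALSE]
  sc <- scores[sel]
  key <- interaction(df$patient_id, df$time_point, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_along(sc), key), function(ix) {
    data.frame(patient_id = df$patient_id[ix[1]],
               time_point = df$time_point[ix[1]],
               n_cells = length(ix), mean_score = mean(sc[ix]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fractional clonal module expression over time
#'
#' For each clonotype and time point with at least \code{min_cells} cells
#' in the combined CD154+/CD137+ compartments, the fraction of its cells
#' expressing the relevant module.  The fraction normalizes away clone- and
#' patient-level differences in score dynamic range.
#'
#' @param cells data.frame(barcode, clone_key, patient_id, time_point,
#'   subset) of activated cells with a clonotype
#' @param expressing logical per cell
#' @param clone_subtypes named character, clone key -> assigned subtype
#' @param min_cells eligibility floor per (clone, time point), default 2
#' @return data.frame(clone_key, patient_id, subtype, time_point, n_cells,
#'   n_expressing, fraction)
#' @export
fractionalClonalExpression <- function(cells, expressing, clone_subtypes,
                                       min_cells = 2) {
  stopifnot(nrow(cells) == length(expressing))
  act <- cells$subset %in% c("CD154", "CD137")
  df <- cells[act, , drop = FALSE]
  ex <- expressing[act]
  key <- paste(df$clone_key, df$time_point, sep = "\r")
  out <- do.call(rbind, lapply(split(seq_len(nrow(df)), key), function(ix) {
    if (length(ix) < min_cells) return(NULL)
    ck <- df$clone_key[ix[1]]
    data.frame(clone_key = ck, patient_id = df$patient_id[ix[1]],
               subtype = unname(clone_subtypes[ck] %|NA|% "none"),
               time_point = df$time_point[ix[1]],
               n_cells = length(ix), n_expressing = sum(ex[ix]),
               fraction = mean(ex[ix]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Temporal detection pattern of expanded clonotypes
#'
#' Within one sorted subset, clonotypes with at least \code{min_cells}
#' cells in that subset are classified by the set of time points at which
#' they are detected (e.g. "BL+MN").
#'
#' @param cells data.frame(clone_key, time_point, subset)
#' @param subset_name the sorted subset to analyze ("CD154" or "CD137")
#' @param min_cells minimum cells in the subset, default 4
#' @return data.frame(clone_key, n_cells, pattern)
#' @export
temporalPattern <- function(cells, subset_name, min_cells = 4) {
  df <- cells[cells$subset == subset_name, , drop = FALSE]
  out <- do.call(rbind, lapply(split(seq_len(nrow(df)), df$clone_key), function(ix) {
    if (length(ix) < min_cells) return(NULL)
    tps <- intersect(TIME_POINTS, unique(df$time_point[ix]))
    data.frame(clone_key = df$clone_key[ix[1]], n_cells = length(ix),
               pattern = paste(tps, collapse = "+"), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-patient module suppression ratio between two phases
#'
#' ratio = mean(to) / mean(from), default maintenance over buildup, so
#' suppression gives a ratio below 1.  Patients missing either phase, or
#' with a near-zero denominator, yield NA.
#'
#' @param trajectory data.frame from \code{cloneModuleTrajectory}
#' @param from,to time points, defaults "BU" and "MN"
#' @param eps denominator guard
#' @return named numeric, patient -> ratio (NA where undefined)
#' @export
suppressionRatio <- function(trajectory, from = "BU", to = "MN", eps = 1e-8) {
  pts <- unique(trajectory$patient_id)
  vapply(pts, function(p) {
    a <- trajectory$mean_score[trajectory$patient_id == p &
                               trajectory$time_point == from]
    b <- trajectory$mean_score[trajectory$patient_id == p &
                               trajectory$time_point == to]
    if (!length(a) || !length(b) || abs(a) < eps) return(NA_real_)
    b / a
  }, 0)
}

#' Spearman correlation with ordinal clinical outcome
#'
#' Outcomes are coded tolerance = 2, partial tolerance = 1, treatment
#' failure = 0; placebo patients are excluded.  Average ranks for ties;
#' the unadjusted p value is reported.
#'
#' @param values named numeric, patient -> value
#' @param outcomes named character, patient -> outcome (TO/PT/TF/PL)
#' @return list(rho, p, n)
#' @export
spearmanOutcome <- function(values, outcomes) {
  coding <- c(TO = 2, PT = 1, TF = 0)
  pts <- names(values)[!is.na(values)]
  pts <- pts[outcomes[pts] %in% names(coding)]
  if (length(pts) < 3) .stopf("fewer than 3 treatment-group patients")
  x <- values[pts]
  y <- coding[outcomes[pts]]
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(pts))
}

#' Baseline principal-component outcome signature
#'
#' PCA is fitted on the patient x module matrix of mean module scores at
#' baseline only (centered on baseline column means); PC1 -- the component
#' explaining the most variance -- is then projected onto the module
#' averages of every time point using the baseline centering.  The sign is
#' fixed so the largest-magnitude loading is positive.
#'
#' @param means data.frame(patient_id, time_point, module, mean_score),
#'   complete over retained modules at baseline
#' @param baseline_tp the baseline time point label, default "BL"
#' @param n_top number of top-|loading| modules to report, default 5
#' @return list(loadings named numeric, scores data.frame(patient_id,
#'   time_point, pc1), top_modules, var_explained, center)
#' @export
baselineModulePca <- function(means, baseline_tp = "BL", n_top = 5) {
  wide <- stats::reshape(means, idvar = c("patient_id", "time_point"),
                         timevar = "module", direction = "wide")
  mods <- sub("^mean_score\\.", "", names(wide)[-(1:2)])
  M <- as.matrix(wide[, -(1:2), drop = FALSE])
  colnames(M) <- mods
  bl <- wide$time_point == baseline_tp
  if (!any(bl)) .stopf("no baseline rows")
  B <- M[bl, , drop = FALSE]
  if (anyNA(B)) .stopf("baseline module means incomplete")
  center <- colMeans(B)
  Bc <- sweep(B, 2, center)
  sv <- svd(Bc)
  if (sv$d[1] <= 1e-12) .stopf("zero-variance baseline input")
  v1 <- sv$v[, 1]
  if (v1[which.max(abs(v1))] < 0) v1 <- -v1
  names(v1) <- mods
  pc1 <- drop(sweep(M, 2, center) %*% v1)
  scores <- data.frame(patient_id = wide$patient_id,
                       time_point = wide$time_point, pc1 = pc1,
                       stringsAsFactors = FALSE)
  top <- names(sort(abs(v1), decreasing = TRUE))[seq_len(min(n_top, length(v1)))]
  list(loadings = v1, scores = scores, top_modules = top,
       var_explained = sv$d^2 / sum(sv$d^2), center = center)
}

#' Gene-by-gene Spearman correlation with IgE titers
#'
#' For a chosen cell population (e.g. one Th subtype), the mean normalized
#' expression of each gene is computed per (patient, time point), paired
#' with the allergen-specific IgE titer of that sample, and correlated by
#' Spearman's rank test; Bonferroni adjustment over all tested genes.
#' Genes detected in fewer than \code{min_frac} of the cells, or with
#' fewer than \code{min_pairs} paired observations, are skipped.
#'
#' @param normalized genes x cells normalized layer for the population
#' @param meta metadata rows for the same cells
#' @param ige IgE table (patient_id, time_point, ige_kU_L)
#' @param min_frac minimum detection fraction, default 0.05
#' @param min_pairs minimum paired observations, default 4
#' @return data.frame(gene, rho, p, p_adj, n)
#' @export
igeGeneCorrelation <- function(normalized, meta, ige,
                               min_frac = 0.05, min_pairs = 4) {
  det <- Matrix::rowSums(normalized > 0) / ncol(normalized)
  genes <- rownames(normalized)[det >= min_frac]
  if (!length(genes)) .stopf("no gene passes the detection filter")
  key <- paste(meta$patient_id, meta$time_point)
  ikey <- paste(ige$patient_id, ige$time_point)
  groups <- split(seq_len(ncol(normalized)), key)
  titer <- ige$ige_kU_L[match(names(groups), ikey)]
  ok <- !is.na(titer)
  X <- as.matrix(normalized[genes, , drop = FALSE])
  avg <- vapply(groups[ok], function(ix) rowMeans(X[, ix, drop = FALSE]),
                numeric(length(genes)))
  if (is.null(dim(avg))) avg <- matrix(avg, nrow = length(genes))
  titer <- titer[ok]
  out <- do.call(rbind, lapply(seq_along(genes), function(i) {
    v <- avg[i, ]
    use <- !is.na(v)
    if (sum(use) < min_pairs) return(NULL)
    ct <- suppressWarnings(stats::cor.test(v[use], titer[use],
                                           method = "spearman"))
    data.frame(gene = genes[i], rho = unname(ct$estimate), p = ct$p.value,
               n = sum(use), stringsAsFactors = FALSE)
  }))
  if (is.null(out)) .stopf("no gene with enough paired observations")
  out$p_adj <- bonferroni(out$p, m = nrow(out))
  rownames(out) <- NULL
  out
}

#' Wilcoxon tests with Bonferroni adjustment
#'
#' Unpaired = rank-sum; paired = signed-rank over matched vectors.
#' p values are Bonferroni-adjusted over the declared family.
#'
#' @param x,y numeric vectors (matched when \code{paired})
#' @param paired logical
#' @param family_size Bonferroni family size (default 1: no adjustment)
#' @param alternative passed to \code{wilcox.test}
#' @return list(p, p_adj, statistic)
#' @export
wilcoxonTest <- function(x, y, paired = FALSE, family_size = 1,
                         alternative = "two.sided") {
  if (paired) {
    stopifnot(length(x) == length(y))
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
  } else {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
  }
  if (min(length(x), length(y)) < 3) .stopf("fewer than 3 effective observations")
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                            alternative = alternative))
  list(p = wt$p.value, p_adj = min(1, family_size * wt$p.value),
       statistic = unname(wt$statistic))
}
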