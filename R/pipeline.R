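#' Default reference gene sets used to identify Th/Treg modules
#'
#' Canonical lineage genes used to match discovered sparse-PCA components
#' to the Th1/Th2/Th17/Treg modules (highest Jaccard between a module's
#' support and the reference set).  Configuration, not inference: override
#' for other panels.
#'
#' @return named list of gene-symbol vectors
#' @export
thModuleReferenceSets <- function() {
  list(Th1  = c("IFNG", "STAT4", "IL12RB2", "GZMK", "CCL5", "LTA"),
       Th2  = c("IL4", "IL5", "IL13", "IL9R", "IL1RL1", "CCR4"),
       Th17 = c("IL17A", "IL17F", "RORC", "CCR6", "IL23R", "CCL20"),
       Treg = c("FOXP3", "IKZF2", "CTLA4", "TIGIT", "IL2RA", "TNFRSF9"))
}

#' Pipeline parameter defaults
#'
#' @param min_genes,min_umis QC floors (the full-cohort profile is
#'   1000/2000; the synthetic desk-scale panel uses 100/800)
#' @param scale_factor library-size normalization target
#' @param n_variable variable genes to rank
#' @param pca_k embedding components
#' @param n_components sparse-PCA modules to extract
#' @param l1_budget sparse-PCA L1 budget (NULL = 0.3 * sqrt(p))
#' @param fpr negative-control false-positive rate for thresholds
#' @param treg_threshold fixed Treg module threshold
#' @param max_share patient-dominance removal bound
#' @param k_neighbors,resolution within-class clustering controls
#' @param min_plurality strong-plurality ratio for V/J calls
#' @return parameter list
#' @export
pipelineParams <- function(min_genes = 100, min_umis = 800,
                           scale_factor = 1e4, n_variable = 100,
                           pca_k = 10, n_components = 12, l1_budget = NULL,
                           fpr = 0.002, treg_threshold = 2.0,
                           max_share = 0.60, k_neighbors = 20,
                           resolution = 1.0, min_plurality = 0.6) {
  list(min_genes = min_genes, min_umis = min_umis,
       scale_factor = scale_factor, n_variable = n_variable, pca_k = pca_k,
       n_components = n_components, l1_budget = l1_budget, fpr = fpr,
       treg_threshold = treg_threshold, max_share = max_share,
       k_neighbors = k_neighbors, resolution = resolution,
       min_plurality = min_plurality)
}

.stageDeps <- c(qc = "", preprocess = "qc", modules = "preprocess",
                subtype = "modules", repertoire = "subtype")

.requireStage <- function(state, stage) {
  dep <- .stageDeps[[stage]]
  if (nzchar(dep) && is.null(state$done[[dep]]))
    .stopf("stage '%s' requires stage '%s' to run first", stage, dep)
}

.recordStage <- function(state, stage, out) {
  state[names(out)] <- out
  state$done[[stage]] <- TRUE
  state$manifest$stages[[stage]] <- list(outputs = objectHash(out))
  state
}

#' Run one pipeline stage
#'
#' Stages: \code{qc} (cell filtering), \code{preprocess} (normalize,
#' covariates, gene selection, scaling, regress-out, PCA embedding),
#' \code{modules} (balanced downsampling, sparse PCA, scoring, thresholds,
#' dominance filter), \code{subtype} (Th class + within-class subtype +
#' Treg compartment), \code{repertoire} (V/J filtering, clonotypes,
#' clonotype subtype labels).  A stage refuses to run before its
#' prerequisite and records an entry in the run manifest.
#'
#' @param state pipeline state from \code{pipelineInit} or a previous stage
#' @param stage stage name
#' @return updated state
#' @export
runStage <- function(state, stage) {
  stage <- match.arg(stage, names(.stageDeps))
  .requireStage(state, stage)
  params <- state$params
  out <- switch(stage,
    qc = {
      counts <- qcFilter(cohortCounts(state$cohort),
                         min_genes = params$min_genes,
                         min_umis = params$min_umis)
      cohort <- subsetCohort(state$cohort,
                             keep = state$cohort@meta$barcode %in% colnames(counts))
      list(cohort = cohort)
    },
    preprocess = {
      counts <- cohortCounts(state$cohort)
      covs <- computeCovariates(counts)
      normalized <- normalizeLog(counts, params$scale_factor)
      vg <- selectVariableGenes(normalized,
                                min(params$n_variable, nrow(normalized)))
      genes <- geneFilterUnion(vg, state$immune_genes, rownames(counts))
      norm_f <- normalized[genes, , drop = FALSE]
      residual <- regressOut(norm_f, covs)
      embedding <- pcaEmbed(residual, params$pca_k)$scores
      list(covariates = covs, normalized = normalized, genes = genes,
           residual = residual, embedding = embedding)
    },
    modules = {
      meta <- cellMeta(state$cohort)
      sample_id <- paste(meta$patient_id, meta$time_point, meta$subset)
      ds <- balancedDownsample(meta$barcode, sample_id, seed = state$seed)
      Xd <- scaleGenes(state$normalized[state$genes, ds, drop = FALSE])
      mods <- sparsePca(t(Xd), n_components = params$n_components,
                        c = params$l1_budget)
      scaled <- scaleGenes(state$normalized[state$genes, , drop = FALSE])
      scores <- scoreModules(scaled, mods)
      match_tab <- matchModules(mods, state$module_refs)
      named_mods <- stats::setNames(match_tab$module, match_tab$reference)
      fixed <- NULL
      if ("Treg" %in% names(named_mods))
        fixed <- stats::setNames(params$treg_threshold, named_mods[["Treg"]])
      neg <- meta$barcode[meta$subset == "DN"]
      thresholds <- moduleThresholds(scores[neg, , drop = FALSE],
                                     fpr = params$fpr, fixed = fixed)
      expressing <- classifyExpressing(scores, thresholds)
      dominance <- patientDominanceFilter(expressing, meta$patient_id,
                                          params$max_share)
      list(scaled = scaled, modules = mods, scores = scores,
           thresholds = thresholds, expressing = expressing,
           dominance = dominance, module_match = match_tab,
           named_modules = named_mods)
    },
    subtype = {
      meta <- cellMeta(state$cohort)
      act <- meta$subset %in% c("CD154", "CD137")
      bc <- meta$barcode[act]
      th_mods <- state$named_modules[c("Th1", "Th2", "Th17")]
      cl <- assignThClass(state$scores[bc, , drop = FALSE],
                          state$expressing[bc, , drop = FALSE], th_mods)
      subtype <- stats::setNames(rep("none", length(bc)), bc)
      cluster <- stats::setNames(rep(NA_integer_, length(bc)), bc)
      panel <- defaultMarkerPanel()
      for (klass in names(panel)) {
        sel <- cl$th_class == klass
        if (sum(sel) < 2 * params$k_neighbors && length(panel[[klass]]) > 1) next
        res <- subtypeWithinClass(
          state$embedding[bc[sel], , drop = FALSE],
          state$normalized[, bc[sel], drop = FALSE], panel[[klass]],
          k_neighbors = min(params$k_neighbors, max(2, floor(sum(sel) / 3))),
          resolution = params$resolution, seed = state$seed)
        subtype[bc[sel]] <- res$subtype
        cluster[bc[sel]] <- res$cluster
      }
      class_z <- stats::setNames(rep(NA_real_, length(bc)), bc)
      has_class <- cl$th_class != "none"
      class_z[has_class] <- cl$z[cbind(which(has_class),
                                       match(cl$th_class[has_class],
                                             colnames(cl$z)))]
      treg <- NULL
      if ("Treg" %in% names(state$named_modules)) {
        tscore <- state$scores[bc, state$named_modules[["Treg"]]]
        if (sum(tscore >= params$treg_threshold) >= 3 * params$k_neighbors)
          treg <- tregSubsetAnalysis(tscore,
                                     state$embedding[bc, , drop = FALSE],
                                     state$normalized[, bc, drop = FALSE],
                                     fixed_threshold = params$treg_threshold,
                                     k_neighbors = params$k_neighbors,
                                     seed = state$seed)
      }
      list(th_class = stats::setNames(cl$th_class, bc), class_z = class_z,
           subtype = subtype, cluster = cluster, treg = treg)
    },
    repertoire = {
      tcr <- strongPluralityFilter(tcrTable(state$cohort),
                                   params$min_plurality)
      meta <- cellMeta(state$cohort)
      clonotypes <- buildClonotypes(tcr, meta)
      cc <- cellClonotypes(clonotypes)
      clone_key <- stats::setNames(paste(cc$patient_id, cc$cdr3b_aa, sep = "|"),
                                   cc$barcode)
      bc <- names(state$subtype)
      clone_subtypes <- assignClonotypeSubtype(
        unname(state$subtype), unname(clone_key[bc]), unname(state$class_z))
      list(tcr_filtered = tcr, clonotypes = clonotypes,
           cell_clones = cc, clone_key = clone_key,
           clone_subtypes = clone_subtypes)
    })
  .recordStage(state, stage, out)
}

#' Initialize pipeline state
#'
#' @param cohort a \code{Cohort}
#' @param immune_genes curated immune gene list for the gene filter
#' @param params from \code{pipelineParams}
#' @param module_refs reference sets naming the Th/Treg modules
#' @param seed integer seed used by every stochastic stage
#' @return state list with an empty run manifest
#' @export
pipelineInit <- function(cohort, immune_genes, params = pipelineParams(),
                         module_refs = thModuleReferenceSets(), seed = 1) {
  list(cohort = cohort, immune_genes = immune_genes, params = params,
       module_refs = module_refs, seed = seed, done = list(),
       manifest = list(seed = seed, params_hash = objectHash(params),
                       input_hash = objectHash(cohort), stages = list()))
}

#' Run the full pipeline
#'
#' qc -> preprocess -> modules -> subtype -> repertoire, in order.
#'
#' @inheritParams pipelineInit
#' @return completed state (layers, modules, scores, thresholds, subtype
#'   and clonotype assignments, run manifest)
#' @export
runPipeline <- function(cohort, immune_genes, params = pipelineParams(),
                        module_refs = thModuleReferenceSets(), seed = 1) {
  state <- pipelineInit(cohort, immune_genes, params, module_refs, seed)
  for (stage in names(.stageDeps)) state <- runStage(state, stage)
  state
}

## ---- downstream analyses on a completed state ------------------------------

#' TCR convergence analysis on a completed pipeline state
#'
#' @param state completed state from \code{runPipeline}
#' @param max_dist distance cutoff for pair enumeration
#' @param breaks distance bin edges
#' @return list(llr = pairLlr output, binned = binnedConvergence output,
#'   pairs = the distance pair table)
#' @export
convergenceAnalysis <- function(state, max_dist = 24, breaks = c(0, 9, 17, 25)) {
  bc <- names(state$subtype)
  cells <- data.frame(
    barcode = bc, patient_id = cellMeta(state$cohort)$patient_id[
      match(bc, cellMeta(state$cohort)$barcode)],
    clone_key = unname(state$clone_key[bc]),
    subtype = unname(state$subtype), stringsAsFactors = FALSE)
  llr <- pairLlr(cells)
  ## distance pairs among clonotypes carrying subtyped cells
  cl <- state$clonotypes
  pairs <- tcrdistPairs(cl[, c("patient_id", "cdr3b_aa")], max_dist = max_dist)
  clone_cells <- cells[!is.na(cells$clone_key), , drop = FALSE]
  clone_cells$clone_key <- sub("^[^|]*\\|", "", clone_cells$clone_key)
  binned <- binnedConvergence(pairs, clone_cells, breaks = breaks)
  list(llr = llr, binned = binned, pairs = pairs)
}

#' Module-suppression analysis on a completed pipeline state
#'
#' For each Th module: module clones, their per-patient mean-score
#' trajectory, fractional clonal expression, the buildup-to-maintenance
#' suppression ratio of Th2A-like clones, and its Spearman correlation
#' with ordinal clinical outcome.
#'
#' @param state completed state
#' @return list per Th module plus th2a_ratio and outcome_cor
#' @export
suppressionAnalysis <- function(state) {
  meta <- cellMeta(state$cohort)
  bc <- names(state$subtype)
  m <- meta[match(bc, meta$barcode), ]
  cells <- data.frame(barcode = bc, patient_id = m$patient_id,
                      time_point = m$time_point, subset = m$subset,
                      clone_key = unname(state$clone_key[bc]),
                      stringsAsFactors = FALSE)
  has_clone <- !is.na(cells$clone_key)
  out <- list()
  for (mod in c("Th1", "Th2", "Th17")) {
    mid <- state$named_modules[[mod]]
    expr <- state$expressing[bc, mid]
    clones <- defineModuleClones(cells[has_clone, ], expr[has_clone])
    traj <- cloneModuleTrajectory(cells[has_clone, ],
                                  state$scores[bc, mid][has_clone], clones)
    frac <- fractionalClonalExpression(cells[has_clone, ], expr[has_clone],
                                       state$clone_subtypes)
    out[[mod]] <- list(clones = clones, trajectory = traj, fractional = frac)
  }
  ## Th2A-like suppression ratio vs outcome (treatment patients)
  th2a_clones <- names(state$clone_subtypes)[state$clone_subtypes == "Th2A-like"]
  mid <- state$named_modules[["Th2"]]
  ratio <- NULL; outcome_cor <- NULL
  if (length(th2a_clones)) {
    traj <- try(cloneModuleTrajectory(cells[has_clone, ],
                                      state$scores[bc, mid][has_clone],
                                      th2a_clones), silent = TRUE)
    if (!inherits(traj, "try-error")) {
      ratio <- suppressionRatio(traj)
      outcomes <- stats::setNames(meta$outcome, meta$patient_id)
      outcomes <- outcomes[!duplicated(names(outcomes))]
      outcome_cor <- try(spearmanOutcome(ratio, outcomes), silent = TRUE)
      if (inherits(outcome_cor, "try-error")) outcome_cor <- NULL
    }
  }
  c(out, list(th2a_ratio = ratio, outcome_cor = outcome_cor))
}

#' Baseline outcome signature on a completed pipeline state
#'
#' Mean module scores of retained (non-patient-dominated) modules are
#' computed per patient and time point over CD154+ cells; PCA is fitted at
#' baseline and PC1 projected onto every time point.
#'
#' @param state completed state
#' @return \code{baselineModulePca} output
#' @export
outcomeSignature <- function(state) {
  meta <- cellMeta(state$cohort)
  keep_mods <- state$dominance$module[state$dominance$retained]
  if (!length(keep_mods)) .stopf("no module retained by the dominance filter")
  act <- meta$subset == "CD154"
  bc <- meta$barcode[act]
  S <- state$scores[bc, keep_mods, drop = FALSE]
  key <- paste(meta$patient_id[act], meta$time_point[act])
  means <- do.call(rbind, lapply(split(seq_along(bc), key), function(ix) {
    data.frame(patient_id = meta$patient_id[act][ix[1]],
               time_point = meta$time_point[act][ix[1]],
               module = colnames(S), mean_score = colMeans(S[ix, , drop = FALSE]),
               stringsAsFactors = FALSE)
  }))
  baselineModulePca(means)
}
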