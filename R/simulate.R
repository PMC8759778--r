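#' Simulation configuration
#'
#' Defaults mirror the cohort design being emulated: 12 patients with
#' outcomes 4 tolerance / 3 partial tolerance / 2 treatment failure / 3
#' placebo, 4 time points, 3 sorted subsets, clonally expanded activated
#' repertoires with subtype-specific CDR3 motifs, planted
#' Th1/Th2/Th17/Treg gene modules plus an outcome-linked activation
#' program, therapy-driven suppression of Th2A-like and Th1-conv lineages
#' at maintenance/avoidance (strongest in tolerant patients, absent in
#' placebo), and chain-recovery dropout targeting 60% TRB / 55% TRA / 36%
#' both.
#'
#' @param n_per_sample cells per (patient, time point, subset) sample
#' @param n_genes total gene panel size (modules + markers + mito + filler)
#' @param n_lineages clonotype lineages per patient per activated subset
#' @param expansion_decay geometric decay of lineage sampling weights; the
#'   effective number of expanded lineages is about 1/decay
#' @param expansion if FALSE every cell founds its own singleton clonotype
#' @param activity_scale base Th/Treg module activity in active cells
#' @param marker_scale marker-program activity in subtype cells
#' @param suppression named per-cell retention probabilities by outcome:
#'   at MN/AV a cell of a flagged lineage keeps its module activity with
#'   this probability and is silenced otherwise, so tolerant patients lose
#'   about 60 percent of module activity (and of expressing cells) while
#'   placebo lineages are untouched
#' @param activation_strength outcome-linked activation-program activity
#' @param dispersion negative-binomial dispersion of counts
#' @param lib_mean mean library size (UMIs per cell)
#' @param p_trb,p_tra,p_both chain recovery probabilities
#' @param ambiguous_call_rate fraction of chain records given a second V
#'   candidate strong enough to fail the plurality filter
#' @param shared_lineage_frac fraction of CD137 lineages copied from the
#'   CD154 pool (repertoire sharing target ~1-2%)
#' @param qc_boundary_cells number of constructed cells sitting exactly one
#'   detected gene below the QC floor (for filter tests)
#' @return config list
#' @export
simConfig <- function(n_per_sample = 60, n_genes = 300, n_lineages = 60,
                      expansion_decay = 0.15,
                      expansion = TRUE, activity_scale = 3.0,
                      marker_scale = 2.5,
                      suppression = c(TO = 0.4, PT = 0.6, TF = 0.9, PL = 1.0),
                      activation_strength = c(TF = 2.0, PT = 1.2, TO = 0.5,
                                              PL = 0.3),
                      dispersion = 0.15, lib_mean = 2500,
                      p_trb = 0.60, p_tra = 0.55, p_both = 0.36,
                      ambiguous_call_rate = 0.05,
                      shared_lineage_frac = 0.02,
                      qc_boundary_cells = 0) {
  patients <- sprintf("P%02d", 1:12)
  outcomes <- stats::setNames(
    c("TO", "TO", "TO", "TO", "PT", "PT", "PT", "TF", "TF", "PL", "PL", "PL"),
    patients)
  list(patients = patients, outcomes = outcomes,
       time_points = TIME_POINTS, subsets = SUBSETS,
       n_per_sample = n_per_sample, n_genes = n_genes,
       n_lineages = n_lineages, expansion_decay = expansion_decay,
       expansion = expansion,
       activity_scale = activity_scale, marker_scale = marker_scale,
       suppression = suppression, activation_strength = activation_strength,
       dispersion = dispersion, lib_mean = lib_mean,
       p_trb = p_trb, p_tra = p_tra, p_both = p_both,
       ambiguous_call_rate = ambiguous_call_rate,
       shared_lineage_frac = shared_lineage_frac,
       qc_boundary_cells = qc_boundary_cells,
       ## subtype composition of each activated subset
       comp_cd154 = c("Tfh1-like" = 0.10, "Th1-conv" = 0.12,
                      "Tfh2-like" = 0.14, "Th2A-like" = 0.20,
                      "Th2reg-like" = 0.08, "Th17" = 0.14, none = 0.22),
       comp_cd137 = c(Treg = 0.55, "Th2reg-like" = 0.05, "Tfh1-like" = 0.04,
                      "Tfh2-like" = 0.04, "Th1-conv" = 0.04, Th17 = 0.04,
                      none = 0.24))
}

## planted gene programs; module genes carry the canonical lineage markers
## plus synthetic fillers so support recovery is measurable
simGenePrograms <- function() {
  list(
    modules = list(
      Treg = c("FOXP3", "IKZF2", "CTLA4", "TIGIT", "IL2RA", "TNFRSF9",
               paste0("TRGM", sprintf("%02d", 7:12))),
      Th1  = c("IFNG", "STAT4", "IL12RB2", "GZMK", "CCL5", "LTA",
               paste0("TH1M", sprintf("%02d", 7:12))),
      Th2  = c("IL4", "IL5", "IL13", "IL9R", "IL1RL1", "CCR4",
               paste0("TH2M", sprintf("%02d", 7:12))),
      Th17 = c("IL17A", "IL17F", "RORC", "CCR6", "IL23R", "CCL20",
               paste0("TH17M", sprintf("%02d", 7:12))),
      ACT  = c("CD69", "IL2", "TNF", "EGR1", "NR4A1", "DUSP2",
               paste0("ACTM", sprintf("%02d", 7:12)))),
    markers = list(
      "Tfh1-like"   = c("CXCR5", "PDCD1", "IL21"),
      "Th1-conv"    = c("TBX21", "CXCR3", "CCL4"),
      "Tfh2-like"   = c("CXCR5", "PDCD1", "IL21"),
      "Th2A-like"   = c("GATA3", "IL17RB", "PTGDR2"),
      "Th2reg-like" = c("FOXP3", "TNFRSF9", "IL2RA"),
      "Th17"        = c("RORC", "CCR6", "IL17A"),
      "Treg-conventional" = c("FOXP3", "IKZF2", "IL2RA"),
      "Treg-Tfh-like"     = c("CXCR5", "PDCD1"),
      "Treg-CCR7"         = c("CCR7", "SELL")),
    mito = c("MT-CO1", "MT-CO2", "MT-ND1", "MT-ND2", "MT-CYB"))
}

## CDR3 seed motifs per subtype; lineage CDR3s are 0-2 substitutions away
## from a seed, so same-seed pairs sit below the "highly similar" boundary
simMotifs <- function() {
  list(
    "Tfh1-like"   = c("CASSPGQGAYEQYF", "CASRPDRNTGELFF"),
    "Th1-conv"    = c("CASSLGWGDTQYFF", "CASTPRGSYNEQFF"),
    "Tfh2-like"   = c("CASSYSTGDEQYFF", "CASSFQGNTEAFFF"),
    "Th2A-like"   = c("CASSIRSSYEQYFF", "CASSETGGGYGYTF"),
    "Th2reg-like" = c("CASSLAGGQETQYF", "CASSDRVGNQPQHF"),
    "Th17"        = c("CASSVDRGSYNSPF", "CASSQGLAGVDTQF"))
}

.randomCdr3 <- function(len = NULL) {
  if (is.null(len)) len <- sample(11:15, 1)
  paste0("CAS", paste(sample(AA_ALPHABET, len - 4, replace = TRUE),
                      collapse = ""), "F")
}

.mutateCdr3 <- function(seed, n_mut) {
  x <- strsplit(seed, "")[[1]]
  if (n_mut > 0) {
    pos <- sample(2:(length(x) - 1), n_mut)
    x[pos] <- sample(AA_ALPHABET, n_mut, replace = TRUE)
  }
  paste(x, collapse = "")
}

.vGene <- function(chain) {
  if (chain == "TRB") sprintf("TRBV%d", sample(2:30, 1))
  else sprintf("TRAV%d", sample(1:40, 1))
}
.jGene <- function(chain) {
  if (chain == "TRB") sprintf("TRBJ%d-%d", sample(1:2, 1), sample(1:7, 1))
  else sprintf("TRAJ%d", sample(1:50, 1))
}

## build the per-patient lineage pools for the activated subsets
.simLineages <- function(cfg) {
  motifs <- simMotifs()
  mkLineage <- function(patient, subset, subtype, id) {
    if (subtype %in% names(motifs)) {
      seed <- sample(motifs[[subtype]], 1)
      cdr3b <- .mutateCdr3(seed, sample(0:1, 1))
    } else cdr3b <- .randomCdr3()
    list(patient = patient, subset = subset, subtype = subtype,
         lineage_id = id, cdr3b = cdr3b, cdr3a = .randomCdr3(),
         vb = .vGene("TRB"), jb = .jGene("TRB"),
         va = .vGene("TRA"), ja = .jGene("TRA"))
  }
  pools <- list()
  for (p in cfg$patients) {
    for (ss in c("CD154", "CD137")) {
      comp <- if (ss == "CD154") cfg$comp_cd154 else cfg$comp_cd137
      sub <- sample(names(comp), cfg$n_lineages, replace = TRUE, prob = comp)
      lin <- lapply(seq_len(cfg$n_lineages), function(i)
        mkLineage(p, ss, sub[i], sprintf("%s_%s_L%03d", p, ss, i)))
      ## geometric weight decay produces clonal expansion
      w <- (1 - cfg$expansion_decay)^(seq_len(cfg$n_lineages) - 1)
      pools[[paste(p, ss)]] <- list(lineages = lin, weights = w / sum(w))
    }
    ## share a small fraction of CD154 lineages into the CD137 pool
    n_share <- max(0, round(cfg$shared_lineage_frac * cfg$n_lineages))
    if (n_share > 0) {
      from <- pools[[paste(p, "CD154")]]$lineages
      to <- pools[[paste(p, "CD137")]]
      ix_from <- sample(seq_along(from), n_share)
      ix_to <- sample(seq_along(to$lineages), n_share)
      for (k in seq_len(n_share)) {
        src <- from[[ix_from[k]]]
        dst <- to$lineages[[ix_to[k]]]
        dst$cdr3b <- src$cdr3b; dst$cdr3a <- src$cdr3a
        dst$vb <- src$vb; dst$jb <- src$jb
        to$lineages[[ix_to[k]]] <- dst
      }
      pools[[paste(p, "CD137")]] <- to
    }
  }
  pools
}

#' Simulate the clonal repertoire and cell sheet
#'
#' Draws cells for every (patient, time point, subset) sample; activated
#' cells are assigned to persistent clonotype lineages under a geometric
#' clone-size law (negative-control cells are singletons), lineages carry a
#' true subtype and a motif-derived TRB CDR3, and Th2A-like / Th1-conv
#' lineages of treatment patients are flagged for suppression.
#'
#' @param cfg from \code{simConfig}; the caller seeds the RNG
#' @return list(cells data.frame, lineages data.frame)
#' @keywords internal
simulateRepertoire <- function(cfg) {
  pools <- .simLineages(cfg)
  rows <- list()
  for (p in cfg$patients) for (tp in cfg$time_points) for (ss in cfg$subsets) {
    n <- cfg$n_per_sample
    if (ss == "DN" || !cfg$expansion) {
      lin_id <- sprintf("%s_%s_%s_S%03d", p, tp, ss, seq_len(n))
      sub <- rep("none", n)
      cdr3b <- vapply(seq_len(n), function(i) .randomCdr3(), "")
      cdr3a <- vapply(seq_len(n), function(i) .randomCdr3(), "")
      vb <- vapply(seq_len(n), function(i) .vGene("TRB"), "")
      jb <- vapply(seq_len(n), function(i) .jGene("TRB"), "")
      va <- vapply(seq_len(n), function(i) .vGene("TRA"), "")
      ja <- vapply(seq_len(n), function(i) .jGene("TRA"), "")
      if (!cfg$expansion && ss != "DN") {
        comp <- if (ss == "CD154") cfg$comp_cd154 else cfg$comp_cd137
        sub <- sample(names(comp), n, replace = TRUE, prob = comp)
      }
      df <- data.frame(patient_id = p, time_point = tp, subset = ss,
                       lineage_id = lin_id, true_subtype = sub,
                       cdr3b = cdr3b, cdr3a = cdr3a, vb = vb, jb = jb,
                       va = va, ja = ja, stringsAsFactors = FALSE)
    } else {
      pool <- pools[[paste(p, ss)]]
      ix <- sample(seq_along(pool$lineages), n, replace = TRUE,
                   prob = pool$weights)
      lin <- pool$lineages[ix]
      df <- data.frame(patient_id = p, time_point = tp, subset = ss,
                       lineage_id = vapply(lin, `[[`, "", "lineage_id"),
                       true_subtype = vapply(lin, `[[`, "", "subtype"),
                       cdr3b = vapply(lin, `[[`, "", "cdr3b"),
                       cdr3a = vapply(lin, `[[`, "", "cdr3a"),
                       vb = vapply(lin, `[[`, "", "vb"),
                       jb = vapply(lin, `[[`, "", "jb"),
                       va = vapply(lin, `[[`, "", "va"),
                       ja = vapply(lin, `[[`, "", "ja"),
                       stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1]] <- df
  }
  cells <- do.call(rbind, rows)
  cells$outcome <- cfg$outcomes[cells$patient_id]
  cells$barcode <- sprintf("%s_%s_%s_%05d", cells$patient_id,
                           cells$time_point, cells$subset,
                           seq_len(nrow(cells)))
  ## suppression flags: effector Th2A-like / Th1-conv lineages of treated
  ## patients lose module activity at MN/AV; Tfh-like lineages do not
  cells$suppressed <- cells$true_subtype %in% c("Th2A-like", "Th1-conv") &
    cells$outcome != "PL"
  ## per-cell silencing: at MN/AV a suppressed lineage's cell keeps its
  ## module program with the outcome-specific retention probability
  retain <- cfg$suppression[cells$outcome]
  cells$silenced <- cells$suppressed & cells$time_point %in% c("MN", "AV") &
    stats::runif(nrow(cells)) >= retain
  lineages <- unique(cells[, c("patient_id", "lineage_id", "true_subtype",
                               "cdr3b", "suppressed")])
  list(cells = cells, lineages = lineages)
}

#' Simulate UMI counts, metadata and IgE titers for a drawn repertoire
#'
#' Per-cell gene rates are exp(baseline + sum of planted program
#' activities x loadings); counts are negative-binomial around
#' library-size-scaled rates (log-normal library sizes); mitochondrial
#' genes are included so QC covariates are exercised.  Suppressed lineages
#' have their Th module activity multiplied by the outcome-specific factor
#' at maintenance and avoidance; the activation program scales with
#' outcome (TF > PT > TO) at every time point; IgE titers track mean Th2
#' activity per patient and time point.
#'
#' @param cfg from \code{simConfig}
#' @param rep_out from \code{simulateRepertoire}
#' @return list(counts, meta, ige, activities, programs)
#' @keywords internal
simulateCounts <- function(cfg, rep_out) {
  prog <- simGenePrograms()
  cells <- rep_out$cells
  ncell <- nrow(cells)
  named_genes <- unique(c(unlist(prog$modules), unlist(prog$markers)))
  n_bg <- cfg$n_genes - length(named_genes) - length(prog$mito)
  if (n_bg < 0) .stopf("n_genes too small for the planted programs")
  genes <- c(named_genes, prog$mito, sprintf("BG%04d", seq_len(n_bg)))
  G <- length(genes)
  baseline <- stats::rnorm(G, 0, 0.8)
  names(baseline) <- genes
  baseline[prog$mito] <- 2.6            # mito genes ~ a few percent of UMIs
  ## activity matrix: programs x cells
  programs <- c(names(prog$modules), names(prog$markers))
  A <- matrix(0, length(programs), ncell, dimnames = list(programs, NULL))
  module_of <- c("Tfh1-like" = "Th1", "Th1-conv" = "Th1",
                 "Tfh2-like" = "Th2", "Th2A-like" = "Th2",
                 "Th2reg-like" = "Th2", "Th17" = "Th17", Treg = "Treg")
  treg_flavors <- c("Treg-conventional", "Treg-Tfh-like", "Treg-CCR7")
  flavor <- sample(treg_flavors, ncell, replace = TRUE,
                   prob = c(0.6, 0.2, 0.2))
  noise <- function(n) exp(stats::rnorm(n, 0, 0.25))
  for (i in seq_len(ncell)) {
    st <- cells$true_subtype[i]
    if (st == "none") next
    mod <- module_of[[st]]
    act <- if (cells$silenced[i]) 0 else cfg$activity_scale * noise(1)
    A[mod, i] <- act
    if (st == "Treg") {
      A[flavor[i], i] <- cfg$marker_scale * noise(1)
    } else {
      A[st, i] <- cfg$marker_scale * noise(1)
      if (st == "Th2reg-like") A["Treg", i] <- 0.6 * cfg$activity_scale * noise(1)
    }
  }
  ## outcome-linked activation program in activated cells, all time points
  act_cells <- cells$subset %in% c("CD154", "CD137")
  A["ACT", act_cells] <- cfg$activation_strength[cells$outcome[act_cells]] *
    noise(sum(act_cells))
  ## loadings: program x gene weights (graded so supports are recoverable)
  W <- matrix(0, length(programs), G, dimnames = list(programs, genes))
  for (m in names(prog$modules))
    W[m, prog$modules[[m]]] <- seq(1.2, 0.8, length.out = length(prog$modules[[m]]))
  for (m in names(prog$markers)) W[m, prog$markers[[m]]] <- 1
  lograte <- sweep(crossprod(W, A), 1, baseline, "+")   # genes x cells
  lograte <- pmin(lograte, 30)
  rate <- exp(lograte)
  p_gc <- sweep(rate, 2, colSums(rate), "/")
  lib <- stats::rlnorm(ncell, log(cfg$lib_mean), 0.25)
  mu <- sweep(p_gc, 2, lib, "*")
  counts <- matrix(stats::rnbinom(G * ncell, mu = mu, size = 1 / cfg$dispersion),
                   G, ncell, dimnames = list(genes, cells$barcode))
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  meta <- data.frame(barcode = cells$barcode, patient_id = cells$patient_id,
                     time_point = cells$time_point, subset = cells$subset,
                     outcome = cells$outcome, stringsAsFactors = FALSE)
  ## IgE titers tracking mean Th2 activity per (patient, time point)
  ige <- do.call(rbind, lapply(split(seq_len(ncell),
      paste(cells$patient_id, cells$time_point)), function(ix) {
    th2 <- mean(A["Th2", ix])
    data.frame(patient_id = cells$patient_id[ix[1]],
               time_point = cells$time_point[ix[1]],
               ige_kU_L = exp(1.5 + 1.2 * th2 + stats::rnorm(1, 0, 0.15)),
               stringsAsFactors = FALSE)
  }))
  rownames(ige) <- NULL
  list(counts = counts, meta = meta, ige = ige, activities = A,
       programs = prog)
}

## serialize TCR records with chain dropout and occasional ambiguous calls
.simTcrTable <- function(cfg, cells) {
  ncell <- nrow(cells)
  ## joint chain-recovery law matching the target marginals
  p_b_only <- cfg$p_trb - cfg$p_both
  p_a_only <- cfg$p_tra - cfg$p_both
  p_none <- 1 - cfg$p_both - p_b_only - p_a_only
  draw <- sample(c("both", "b", "a", "none"), ncell, replace = TRUE,
                 prob = c(cfg$p_both, p_b_only, p_a_only, p_none))
  mkSupport <- function(call) {
    reads <- sample(5:30, 1)
    if (stats::runif(1) < cfg$ambiguous_call_rate) {
      alt <- sample(5:30, 1)
      ## second candidate strong enough to fail the plurality filter
      sprintf("%s:%d;ALT%s:%d", call, reads, call, max(reads, alt))
    } else sprintf("%s:%d", call, reads)
  }
  rows <- list()
  for (i in seq_len(ncell)) {
    if (draw[i] %in% c("both", "b"))
      rows[[length(rows) + 1]] <- data.frame(
        barcode = cells$barcode[i], chain = "TRB", v_call = cells$vb[i],
        j_call = cells$jb[i], v_support = mkSupport(cells$vb[i]),
        j_support = sprintf("%s:%d", cells$jb[i], sample(5:30, 1)),
        cdr3_aa = cells$cdr3b[i], stringsAsFactors = FALSE)
    if (draw[i] %in% c("both", "a"))
      rows[[length(rows) + 1]] <- data.frame(
        barcode = cells$barcode[i], chain = "TRA", v_call = cells$va[i],
        j_call = cells$ja[i], v_support = mkSupport(cells$va[i]),
        j_support = sprintf("%s:%d", cells$ja[i], sample(5:30, 1)),
        cdr3_aa = cells$cdr3a[i], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate a full synthetic cohort with ground truth
#'
#' @param cfg from \code{simConfig}
#' @param seed integer seed; the whole simulation is deterministic given it
#' @return list(cohort (a \code{Cohort}), truth, config)
#' @export
simulateCohort <- function(cfg = simConfig(), seed = 1) {
  set.seed(seed)
  rep_out <- simulateRepertoire(cfg)
  cnt <- simulateCounts(cfg, rep_out)
  tcr <- .simTcrTable(cfg, rep_out$cells)
  counts <- cnt$counts
  meta <- cnt$meta
  if (cfg$qc_boundary_cells > 0) {
    ## constructed cells exactly one detected gene below the default QC
    ## floor of the simulation profile (100 genes): 99 genes, ample UMIs
    nb <- cfg$qc_boundary_cells
    extra <- Matrix::Matrix(0, nrow(counts), nb, sparse = TRUE,
                            dimnames = list(rownames(counts),
                                            sprintf("QCB_%03d", seq_len(nb))))
    extra[seq_len(99), ] <- 25
    counts <- cbind(counts, methods::as(extra, "CsparseMatrix"))
    meta <- rbind(meta, data.frame(
      barcode = sprintf("QCB_%03d", seq_len(nb)),
      patient_id = cfg$patients[1], time_point = "BL", subset = "DN",
      outcome = cfg$outcomes[[cfg$patients[1]]]))
  }
  cohort <- buildCohort(counts, meta, tcr, cnt$ige)
  truth <- list(
    cells = rep_out$cells[, c("barcode", "patient_id", "time_point", "subset",
                              "outcome", "lineage_id", "true_subtype",
                              "cdr3b", "suppressed", "silenced")],
    lineages = rep_out$lineages,
    modules = cnt$programs$modules,
    markers = cnt$programs$markers,
    activation_strength = cfg$activation_strength,
    suppression = cfg$suppression)
  list(cohort = cohort, truth = truth, config = cfg)
}

#' Write a simulated cohort to disk in the pipeline input formats
#'
#' Emits MatrixMarket counts + gene/barcode TSVs, metadata and TCR TSVs,
#' IgE CSV, the immune-gene list used by the gene filter, and the ground
#' truth as JSON; the emitted files round-trip through the readers.
#'
#' @param sim output of \code{simulateCohort}
#' @param out_dir output directory (created if needed)
#' @return invisible named list of file paths
#' @export
emitCohort <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ch <- sim$cohort
  paths <- list(
    matrix = file.path(out_dir, "matrix.mtx"),
    genes = file.path(out_dir, "genes.tsv"),
    barcodes = file.path(out_dir, "barcodes.tsv"),
    meta = file.path(out_dir, "meta.tsv"),
    tcr = file.path(out_dir, "tcr.tsv"),
    ige = file.path(out_dir, "ige.csv"),
    immune = file.path(out_dir, "immune_genes.txt"),
    truth = file.path(out_dir, "ground_truth.json"))
  writeCounts(cohortCounts(ch), paths$matrix, paths$genes, paths$barcodes)
  utils::write.table(cellMeta(ch), paths$meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(tcrTable(ch), paths$tcr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(igeTable(ch), paths$ige, row.names = FALSE)
  writeLines(unique(c(unlist(sim$truth$modules), unlist(sim$truth$markers))),
             paths$immune)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
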