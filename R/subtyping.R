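TH_CLASSES <- c("Th1", "Th2", "Th17")
TH_SUBTYPES <- c("Tfh1-like", "Th1-conv", "Tfh2-like", "Th2A-like",
                 "Th2reg-like", "Th17")

#' Default marker panel for Th subtype annotation
#'
#' Positive marker genes per subtype, organized by Th class; encodes the
#' canonical surface/transcription-factor markers of each helper subtype
#' (follicular: CXCR5/PDCD1; Th2A: GATA3/IL17RB/PTGDR2; regulatory-skewed
#' Th2: FOXP3/TNFRSF9; conventional Th1: TBX21/CXCR3; Th17: RORC/CCR6).
#' Override with your own panel of the same shape.
#'
#' @return named list: class -> (subtype -> marker character vector)
#' @export
defaultMarkerPanel <- function() {
  list(
    Th1 = list(
      "Tfh1-like" = c("CXCR5", "PDCD1", "IL21"),
      "Th1-conv"  = c("TBX21", "CXCR3", "CCL4")),
    Th2 = list(
      "Tfh2-like"   = c("CXCR5", "PDCD1", "IL21"),
      "Th2A-like"   = c("GATA3", "IL17RB", "PTGDR2"),
      "Th2reg-like" = c("FOXP3", "TNFRSF9", "IL2RA")),
    Th17 = list(
      "Th17" = c("RORC", "CCR6", "IL17A")))
}

#' Default marker panel for Treg cluster annotation
#' @return named list: subtype -> marker character vector
#' @export
defaultTregMarkerPanel <- function() {
  list("Treg-conventional" = c("FOXP3", "IKZF2", "IL2RA"),
       "Treg-Tfh-like"     = c("CXCR5", "PDCD1"),
       "Treg-CCR7"         = c("CCR7", "SELL"))
}

#' Assign cells to Th classes from module expression
#'
#' Cells expressing exactly one of the Th1/Th2/Th17 modules get that class;
#' cells expressing more than one get the class whose module has the
#' highest z score (z computed against the distribution over all cells
#' supplied, i.e. the combined CD154+/CD137+ compartment); non-expressers
#' get "none".
#'
#' @param scores cells x modules score matrix (activated cells only)
#' @param expressing logical matrix from \code{classifyExpressing}
#' @param th_modules named character: c(Th1=, Th2=, Th17=) module column ids
#' @return list(th_class character per cell, z cells x 3 z-score matrix)
#' @export
assignThClass <- function(scores, expressing, th_modules) {
  stopifnot(all(c("Th1", "Th2", "Th17") %in% names(th_modules)))
  miss <- setdiff(th_modules, colnames(scores))
  if (length(miss)) .stopf("module(s) absent from scores: %s", paste(miss, collapse = ","))
  S <- scores[, th_modules, drop = FALSE]
  sdv <- apply(S, 2, stats::sd)
  if (any(sdv == 0)) .stopf("zero-variance module score; z undefined")
  Z <- scale(S)
  colnames(Z) <- names(th_modules)
  E <- expressing[, th_modules, drop = FALSE]
  colnames(E) <- names(th_modules)
  nExpr <- rowSums(E)
  cls <- rep("none", nrow(S))
  one <- nExpr == 1
  cls[one] <- names(th_modules)[apply(E[one, , drop = FALSE], 1, which.max)]
  multi <- nExpr > 1
  if (any(multi)) {
    Zm <- Z[multi, , drop = FALSE]
    Zm[!E[multi, , drop = FALSE]] <- -Inf
    cls[multi] <- names(th_modules)[apply(Zm, 1, which.max)]
  }
  list(th_class = cls, z = Z)
}

## symmetric kNN graph on an embedding
.knnGraph <- function(embedding, k_neighbors) {
  n <- nrow(embedding)
  if (n < 2 * k_neighbors)
    .stopf("too few cells (%d) for k_neighbors=%d", n, k_neighbors)
  D <- as.matrix(stats::dist(embedding))
  edges <- lapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[2:(k_neighbors + 1)]
    cbind(i, nb)
  })
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g)
}

#' Cluster cells of one Th class on the PCA embedding
#'
#' Builds a k-nearest-neighbor graph on the embedding and partitions it by
#' modularity-maximizing (Louvain) community detection.  Deterministic
#' given the seed.
#'
#' The resolution dial is expressed relative to a package default of 1.0
#' that is calibrated (internal modularity gamma = 0.1 x resolution) so
#' that a single unstructured cloud of cells forms one community and
#' disconnected planted partitions are returned whole, rather than
#' fragmenting dense neighborhoods; raise it to subdivide heterogeneous
#' classes more aggressively.
#'
#' @param embedding cells x k PCA coordinate matrix
#' @param k_neighbors neighbors per cell, default 20
#' @param resolution community resolution, default 1.0 (see Details)
#' @param seed integer seed
#' @return integer cluster label per cell
#' @export
clusterWithinClass <- function(embedding, k_neighbors = 20, resolution = 1.0,
                               seed = 1) {
  g <- .knnGraph(embedding, k_neighbors)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = 0.1 * resolution)
  igraph::membership(cl)
}

#' Annotate clusters against a marker panel
#'
#' Each cluster is assigned the subtype whose markers have the highest mean
#' per-gene z score (genes standardized across the supplied cells); the
#' margin between the best and second-best subtype is reported and clusters
#' below \code{margin_floor} are labeled "unresolved".
#'
#' @param labels integer cluster label per cell
#' @param normalized genes x cells normalized layer for those cells
#' @param panel subtype -> marker character vector
#' @param margin_floor minimum top-minus-runner-up margin
#' @return data.frame(cluster, subtype, margin)
#' @export
annotateClusters <- function(labels, normalized, panel, margin_floor = 0.1) {
  if (!length(panel)) .stopf("empty marker panel")
  Z <- scaleGenes(normalized)
  avail <- lapply(panel, function(g) {
    hit <- rownames(Z)[toupper(rownames(Z)) %in% toupper(g)]
    if (!length(hit)) .warnf("no panel marker present in matrix for a subtype")
    hit
  })
  out <- lapply(sort(unique(labels)), function(cl) {
    ix <- labels == cl
    sc <- vapply(avail, function(g) {
      if (!length(g)) return(-Inf)
      mean(Z[g, ix, drop = FALSE])
    }, 0)
    ord <- order(sc, decreasing = TRUE)
    margin <- if (length(sc) > 1) sc[ord[1]] - sc[ord[2]] else Inf
    subtype <- if (margin < margin_floor) "unresolved" else names(panel)[ord[1]]
    data.frame(cluster = cl, subtype = subtype, margin = margin,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-cell Th subtype assignment for one class
#'
#' Clusters the class's cells and maps each cluster to a subtype by marker
#' annotation.
#'
#' @param embedding cells x k coordinates of the class's cells
#' @param normalized genes x cells normalized layer of the class's cells
#' @param panel subtype -> markers for this class
#' @param k_neighbors,resolution,seed,margin_floor see
#'   \code{clusterWithinClass} / \code{annotateClusters}
#' @return list(subtype per cell, cluster per cell, annotation table)
#' @export
subtypeWithinClass <- function(embedding, normalized, panel,
                               k_neighbors = 20, resolution = 1.0, seed = 1,
                               margin_floor = 0.1) {
  if (length(panel) == 1) {
    ## single-subtype class (Th17): no clustering needed
    n <- nrow(embedding)
    return(list(subtype = rep(names(panel), n), cluster = rep(1L, n),
                annotation = data.frame(cluster = 1L, subtype = names(panel),
                                        margin = Inf)))
  }
  labels <- clusterWithinClass(embedding, k_neighbors, resolution, seed)
  ann <- annotateClusters(labels, normalized, panel, margin_floor)
  subtype <- ann$subtype[match(labels, ann$cluster)]
  list(subtype = subtype, cluster = as.integer(labels), annotation = ann)
}

#' Majority-vote subtype per clonotype
#'
#' Plurality vote over the clonotype's subtyped cells ("none" excluded);
#' ties are broken by the higher mean class-module z score of the tied
#' subtypes' cells, then lexicographically.  Clonotypes with no subtyped
#' cells are labeled "none".
#'
#' @param cell_subtypes character subtype per cell
#' @param clone_keys clonotype key per cell (NA for cells without TRB)
#' @param cell_z numeric per cell: z score of the cell's class module
#'   (used only for tie-breaking; optional)
#' @return named character vector, clonotype key -> subtype
#' @export
assignClonotypeSubtype <- function(cell_subtypes, clone_keys, cell_z = NULL) {
  if (is.null(cell_z)) cell_z <- rep(0, length(cell_subtypes))
  ok <- !is.na(clone_keys)
  out <- vapply(split(which(ok), clone_keys[ok]), function(ix) {
    st <- cell_subtypes[ix]
    keep <- !(st %in% c("none", "unresolved")) & !is.na(st)
    if (!any(keep)) return("none")
    st <- st[keep]; z <- cell_z[ix][keep]
    tab <- table(st)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) return(top)
    mz <- vapply(top, function(s) mean(z[st == s]), 0)
    best <- top[mz == max(mz)]
    sort(best)[1]
  }, "")
  out
}

#' Treg compartment analysis
#'
#' Selects all activated (CD154+/CD137+) cells whose Treg module score
#' meets the fixed threshold (default 2.0) -- cells with Th1/Th2/Th17
#' signatures are not excluded -- then clusters them and annotates the
#' clusters against the Treg marker panel.
#'
#' @param treg_scores numeric Treg-module score per activated cell
#' @param embedding cells x k coordinates (same cells)
#' @param normalized genes x cells normalized layer (same cells)
#' @param fixed_threshold score cutoff, default 2.0
#' @param panel Treg marker panel
#' @param k_neighbors,resolution,seed,margin_floor clustering controls
#' @return list(is_treg logical per cell, subtype per Treg cell, cluster,
#'   annotation)
#' @export
tregSubsetAnalysis <- function(treg_scores, embedding, normalized,
                               fixed_threshold = 2.0,
                               panel = defaultTregMarkerPanel(),
                               k_neighbors = 20, resolution = 1.0, seed = 1,
                               margin_floor = 0.1) {
  sel <- treg_scores >= fixed_threshold
  if (!any(sel)) .stopf("no cell meets the Treg threshold %.2f", fixed_threshold)
  res <- subtypeWithinClass(embedding[sel, , drop = FALSE],
                            normalized[, sel, drop = FALSE], panel,
                            k_neighbors, resolution, seed, margin_floor)
  c(list(is_treg = sel), res)
}
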