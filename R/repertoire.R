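## ---- CDR3 distance ---------------------------------------------------------

.penaltyCache <- new.env(parent = emptyenv())

#' BLOSUM62-derived CDR3 mismatch penalty table
#'
#' Penalty for substituting amino acid i by j is min(4 - BLOSUM62[i, j], 4);
#' identical residues incur no penalty.  Every mismatch penalty lies in
#' [1, 4].  The BLOSUM62 table is taken from Biostrings and restricted to
#' the 20 standard amino acids.
#'
#' @return 20 x 20 integer matrix with amino-acid dimnames; diagonal 0
#' @export
cdr3PenaltyMatrix <- function() {
  if (!is.null(.penaltyCache$P)) return(.penaltyCache$P)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  P <- pmin(4 - B, 4)
  diag(P) <- 0L
  storage.mode(P) <- "integer"
  .penaltyCache$P <- P
  P
}

.encodeAA <- function(s) {
  x <- match(strsplit(s, "", fixed = TRUE)[[1]], AA_ALPHABET)
  if (anyNA(x)) .stopf("invalid amino-acid character in %s", s)
  x
}

#' CDR3 pairwise distance
#'
#' For equal-length sequences, the sum over positions of 0 (match) or the
#' BLOSUM62-derived mismatch penalty min(4 - B62[i,j], 4).  For unequal
#' lengths, the shorter sequence is aligned into the longer in all possible
#' ways (gap positions need not be contiguous), each gap costs 8, and the
#' minimum total penalty is returned.  Implemented by dynamic programming;
#' since any alignment places exactly len(long) - len(short) gaps, the gap
#' cost is constant and the DP minimizes the substitution cost over all
#' order-preserving placements.
#'
#' @param a,b uppercase amino-acid strings (length >= 1)
#' @return nonnegative distance
#' @export
tcrdist <- function(a, b) {
  P <- cdr3PenaltyMatrix()
  x <- .encodeAA(a); y <- .encodeAA(b)
  if (length(x) > length(y)) { tmp <- x; x <- y; y <- tmp }
  m <- length(x); n <- length(y)
  if (m == n) return(sum(P[cbind(x, y)]))
  ## f[j] = min substitution cost of aligning x[1..i] into y[1..j], row-wise;
  ## row update: f_i(j) = min_{j' <= j}( f_{i-1}(j'-1) + P[x_i, y_j'] ).
  ## Row 0 is all zero: leading skipped positions of y are gaps whose total
  ## cost 8*(n-m) is placement-independent and added at the end.
  g <- rep(0, n + 1)                       # 1-based offset
  for (i in seq_len(m)) {
    h <- g[seq_len(n)] + P[x[i], y]        # candidate at each j
    f <- cummin(h)
    g <- c(Inf, f)
  }
  unname(g[n + 1] + 8L * (n - m))
}

#' All close within-patient clonotype pairs
#'
#' Computes CDR3 distances between all unordered pairs of clonotypes within
#' each patient (clonotypes are never pooled across patients) and returns
#' those at distance <= \code{max_dist}.  Self-pairs are excluded.
#'
#' @param clonotypes data.frame with columns \code{patient_id},
#'   \code{cdr3b_aa} (one row per clonotype)
#' @param max_dist inclusive distance cutoff, default 24
#' @return data.frame(patient_id, cdr3b_1, cdr3b_2, dist)
#' @export
tcrdistPairs <- function(clonotypes, max_dist = 24) {
  P <- cdr3PenaltyMatrix()
  out <- lapply(split(clonotypes, clonotypes$patient_id), function(df) {
    seqs <- df$cdr3b_aa
    ns <- length(seqs)
    if (ns < 2) return(NULL)
    enc <- lapply(seqs, .encodeAA)
    len <- lengths(enc)
    res <- vector("list", ns - 1L)
    for (i in seq_len(ns - 1L)) {
      js <- seq.int(i + 1L, ns)
      js <- js[abs(len[js] - len[i]) * 8L <= max_dist]
      if (!length(js)) next
      d <- vapply(js, function(j) tcrdist(seqs[i], seqs[j]), 0)
      keep <- d <= max_dist
      if (any(keep))
        res[[i]] <- data.frame(patient_id = df$patient_id[1],
                               cdr3b_1 = seqs[i], cdr3b_2 = seqs[js[keep]],
                               dist = d[keep], stringsAsFactors = FALSE)
    }
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (is.null(out))
    out <- data.frame(patient_id = character(), cdr3b_1 = character(),
                      cdr3b_2 = character(), dist = numeric())
  out
}

## ---- TCR call filtering and clonotypes -------------------------------------

.pluralityOk <- function(support_str, min_ratio) {
  v <- sort(parseSupport(support_str), decreasing = TRUE)
  if (length(v) == 1) return(TRUE)
  v[1] / (v[1] + v[2]) >= min_ratio
}

#' Strong-plurality filter for V/J gene calls
#'
#' A chain record is accepted when, for both the V and the J call, the top
#' candidate's read share among the top two candidates is at least
#' \code{min_ratio} (default 0.6); a single candidate always passes.
#' (Read literally, "ratio of the most frequent to the second most frequent
#' calls at least 0.6" would accept everything; the share-of-top-two form
#' is the non-vacuous reading and is the one implemented.)
#'
#' @param tcr data.frame from \code{readTcrTable}
#' @param min_ratio minimum top share among the top two candidates
#' @return the accepted subset of \code{tcr}
#' @export
strongPluralityFilter <- function(tcr, min_ratio = 0.6) {
  if (!nrow(tcr)) return(tcr)
  okv <- vapply(tcr$v_support, .pluralityOk, TRUE, min_ratio = min_ratio)
  okj <- vapply(tcr$j_support, .pluralityOk, TRUE, min_ratio = min_ratio)
  tcr[okv & okj, , drop = FALSE]
}

#' Build patient-scoped TCR-beta clonotypes
#'
#' Cells are grouped by (patient, TRB CDR3 amino-acid sequence); the same
#' CDR3 in two patients yields two clonotypes.  Cells with more than one
#' accepted TRB record (likely doublets) are excluded with a logged count;
#' cells without TRB are simply absent.  The dominant paired TRA CDR3
#' (most frequent among members, ties lexicographic) is attached.
#'
#' @param tcr accepted chain records (after \code{strongPluralityFilter})
#' @param meta cell metadata (for the patient of each barcode)
#' @return data.frame(patient_id, cdr3b_aa, size, barcodes, cdr3a_aa) with
#'   \code{barcodes} a list-column of member cell barcodes
#' @export
buildClonotypes <- function(tcr, meta) {
  if (!nrow(tcr)) .stopf("empty TCR table: no clonotypes to build")
  trb <- tcr[tcr$chain == "TRB", , drop = FALSE]
  dup <- unique(trb$barcode[duplicated(trb$barcode)])
  if (length(dup)) {
    .msgf("excluding %d cell(s) with multiple accepted TRB records", length(dup))
    trb <- trb[!trb$barcode %in% dup, , drop = FALSE]
  }
  if (!nrow(trb)) .stopf("no usable TRB records")
  trb$patient_id <- meta$patient_id[match(trb$barcode, meta$barcode)]
  if (anyNA(trb$patient_id)) .stopf("TRB barcode absent from metadata")
  tra <- tcr[tcr$chain == "TRA", , drop = FALSE]
  key <- paste(trb$patient_id, trb$cdr3b_aa %||% trb$cdr3_aa, sep = "\r")
  grp <- split(seq_len(nrow(trb)), key)
  out <- lapply(grp, function(ix) {
    bc <- trb$barcode[ix]
    a <- tra$cdr3_aa[tra$barcode %in% bc]
    dom <- if (length(a)) names(sort(table(a), decreasing = TRUE))[1] else NA_character_
    data.frame(patient_id = trb$patient_id[ix[1]],
               cdr3b_aa = trb$cdr3_aa[ix[1]],
               size = length(ix), cdr3a_aa = dom, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$barcodes <- lapply(grp, function(ix) trb$barcode[ix])
  rownames(res) <- NULL
  res[order(res$patient_id, -res$size, res$cdr3b_aa), ]
}

#' Map cells to their clonotype
#'
#' @param clonotypes output of \code{buildClonotypes}
#' @return data.frame(barcode, patient_id, cdr3b_aa, clone_size)
#' @export
cellClonotypes <- function(clonotypes) {
  n <- lengths(clonotypes$barcodes)
  data.frame(barcode = unlist(clonotypes$barcodes, use.names = FALSE),
             patient_id = rep(clonotypes$patient_id, n),
             cdr3b_aa = rep(clonotypes$cdr3b_aa, n),
             clone_size = rep(clonotypes$size, n),
             stringsAsFactors = FALSE)
}

#' Chain recovery summary
#'
#' Per (patient, time point, subset) sample: the fraction of cells with an
#' accepted TRB record, a TRA record, and both chains; plus medians and
#' standard deviations across samples.
#'
#' @param tcr accepted chain records
#' @param meta cell metadata
#' @return list(per_sample data.frame, summary data.frame)
#' @export
chainRecoverySummary <- function(tcr, meta) {
  if (!nrow(tcr)) .stopf("empty TCR table")
  has_b <- meta$barcode %in% tcr$barcode[tcr$chain == "TRB"]
  has_a <- meta$barcode %in% tcr$barcode[tcr$chain == "TRA"]
  key <- interaction(meta$patient_id, meta$time_point, meta$subset, drop = TRUE)
  per <- do.call(rbind, lapply(split(seq_len(nrow(meta)), key), function(ix) {
    data.frame(patient_id = meta$patient_id[ix[1]],
               time_point = meta$time_point[ix[1]],
               subset = meta$subset[ix[1]], n_cells = length(ix),
               frac_trb = mean(has_b[ix]), frac_tra = mean(has_a[ix]),
               frac_both = mean(has_b[ix] & has_a[ix]),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  summ <- data.frame(
    metric = c("frac_trb", "frac_tra", "frac_both"),
    median = c(stats::median(per$frac_trb), stats::median(per$frac_tra),
               stats::median(per$frac_both)),
    sd = c(stats::sd(per$frac_trb), stats::sd(per$frac_tra),
           stats::sd(per$frac_both)))
  list(per_sample = per, summary = summ)
}

## ---- repertoire statistics -------------------------------------------------

#' Normalized Shannon diversity of a repertoire
#'
#' H = -sum p_i log p_i over clonal proportions, divided by log(S) where S
#' is the number of unique clonotypes; a single-clonotype repertoire has
#' diversity 0 by convention.  1 means perfectly even.
#'
#' @param sizes positive clone sizes
#' @return diversity in [0, 1]
#' @export
normalizedShannon <- function(sizes) {
  if (!length(sizes)) .stopf("empty repertoire")
  stopifnot(all(sizes > 0))
  if (length(sizes) == 1) return(0)
  p <- sizes / sum(sizes)
  H <- -sum(p * log(p))
  H / log(length(sizes))
}

#' Repertoire overlap as percentage of the geometric mean
#'
#' 100 * |A intersect B| / sqrt(|A| * |B|) over unique clonotype keys.
#'
#' @param a,b character vectors of clonotype keys (e.g. TRB CDR3s)
#' @return overlap percentage
#' @export
repertoireOverlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) .stopf("empty repertoire in overlap")
  100 * length(intersect(a, b)) / sqrt(length(a) * length(b))
}

#' Clone-size distributions after equal-depth downsampling
#'
#' Cells in every group are downsampled without replacement to the minimum
#' group size before clone sizes are computed, so size distributions are
#' comparable across groups.  Deterministic given the seed.
#'
#' @param cells data.frame(barcode, group, clone_key)
#' @param seed integer seed
#' @return named list of clone-size tables, one per group
#' @export
equalDownsampleSizes <- function(cells, seed) {
  grp <- split(seq_len(nrow(cells)), cells$group)
  m <- min(lengths(grp))
  set.seed(seed)
  lapply(grp, function(ix) {
    ix <- if (length(ix) == m) ix else sample(ix, m)
    tab <- table(cells$clone_key[ix])
    sort(as.integer(tab), decreasing = TRUE)
  })
}
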