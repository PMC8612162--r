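# Single-cell sequence-variant analysis: identity-threshold clustering,
# dominant-variant proportion, rarefied richness, and error-corrected
# maximum intraindividual divergence.

#' Construct a single-cell variant pool
#'
#' Denoised amplicon sequence variants of one cell's rDNA or rRNA pool,
#' with read counts. Duplicate sequences are merged (counts summed);
#' lowercase bases are uppercased.
#'
#' @param sequences Character vector of A/C/G/T sequences.
#' @param counts Read counts (>= 1), same length.
#' @param cell_id Cell identifier.
#' @param pool_type `"rDNA"` or `"rRNA"`.
#' @param residual_error_rate Fraction of substitution errors remaining
#'   after denoising (0.01 for Colpoda, 0 for the marine species), in
#'   [0, 0.05].
#' @return An object of class `variant_pool` with a `variants` data.frame
#'   (`sequence`, `count`).
#' @export
variant_pool <- function(sequences, counts, cell_id = "cell",
                         pool_type = c("rDNA", "rRNA"),
                         residual_error_rate = 0) {
  pool_type <- match.arg(pool_type)
  stopifnot(length(sequences) == length(counts))
  if (length(sequences) == 0L) stop("variant_pool(): empty pool")
  sequences <- toupper(as.character(sequences))
  bad <- which(!grepl("^[ACGT]+$", sequences))
  if (length(bad)) {
    stop("variant_pool(): non-ACGT characters in sequence(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  counts <- as.integer(counts)
  if (any(is.na(counts)) || any(counts < 1L)) {
    stop("variant_pool(): counts must be integers >= 1")
  }
  if (residual_error_rate < 0 || residual_error_rate > 0.05) {
    stop("variant_pool(): residual_error_rate must be in [0, 0.05]")
  }
  agg <- tapply(counts, sequences, sum)
  variants <- data.frame(sequence = names(agg),
                         count = as.integer(agg),
                         stringsAsFactors = FALSE)
  # canonical order: descending count, ties broken lexicographically
  variants <- variants[order(-variants$count, variants$sequence), ,
                       drop = FALSE]
  rownames(variants) <- NULL
  structure(list(cell_id = cell_id, pool_type = pool_type,
                 variants = variants,
                 residual_error_rate = residual_error_rate),
            class = "variant_pool")
}

#' @export
print.variant_pool <- function(x, ...) {
  cat(sprintf("<variant_pool> %s %s: %d variant(s), %d reads, residual error %.2g\n",
              x$cell_id, x$pool_type, nrow(x$variants),
              sum(x$variants$count), x$residual_error_rate))
  invisible(x)
}

#' Pairwise identity between two sequences
#'
#' Global end-to-end alignment with unit match/mismatch/gap scores
#' (match +1, mismatch -1, gap -1 per position). Identity is the number
#' of matching columns divided by the number of alignment columns,
#' excluding terminal-gap columns; internal gap positions each count as
#' one (non-matching) column.
#'
#' @param a,b Non-empty A/C/G/T sequences.
#' @return Identity fraction in [0, 1].
#' @export
pairwise_identity <- function(a, b) {
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("pairwise_identity(): empty sequence")
  if (identical(a, b)) return(1)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap_a <- pa == "-"
  gap_b <- pb == "-"
  # identify terminal-gap columns (leading/trailing runs of gaps in either)
  either_gap <- gap_a | gap_b
  first <- match(FALSE, either_gap)
  last <- length(either_gap) + 1L - match(FALSE, rev(either_gap))
  keep <- seq(first, last)
  matches <- sum(pa[keep] == pb[keep] & !gap_a[keep])
  matches / length(keep)
}

# Pairwise identity matrix among the (few) unique variants of a pool;
# computed once and reused across the threshold scan and rarefactions.
identity_matrix <- function(sequences) {
  m <- length(sequences)
  M <- diag(1, m)
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        M[i, j] <- M[j, i] <- pairwise_identity(sequences[i], sequences[j])
      }
    }
  }
  M
}

# Greedy centroid clustering on a precomputed identity matrix.
# `order_idx` must list variants by descending count with lexicographic
# tie-break; each variant joins the first centroid with identity >=
# threshold, else founds a new cluster.
greedy_assign <- function(M, order_idx, threshold) {
  centroids <- integer(0)
  assignment <- integer(nrow(M))
  for (v in order_idx) {
    hit <- 0L
    for (k in seq_along(centroids)) {
      if (M[v, centroids[k]] >= threshold - 1e-12) { hit <- k; break }
    }
    if (hit == 0L) {
      centroids <- c(centroids, v)
      hit <- length(centroids)
    }
    assignment[v] <- hit
  }
  list(assignment = assignment, centroids = centroids)
}

#' Greedy centroid clustering of a variant pool
#'
#' Deterministic abundance-sorted greedy clustering: variants are taken in
#' order of descending read count (ties broken lexicographically by
#' sequence); each joins the first existing centroid to which its identity
#' is at least the threshold, otherwise it founds a new cluster. At
#' threshold 1.00 clusters are exact-sequence groups. The sorting rule
#' makes the result invariant to input order.
#'
#' @param pool A [variant_pool()].
#' @param threshold Identity threshold in [0.80, 1.00].
#' @return An object of class `clustering_result` with `threshold`,
#'   `otu_count`, `assignments` (data.frame: sequence, count, cluster) and
#'   `clusters` (data.frame: cluster, centroid, n_variants, reads).
#' @export
greedy_cluster <- function(pool, threshold) {
  stopifnot(inherits(pool, "variant_pool"))
  if (threshold < 0.80 || threshold > 1.00) {
    stop("greedy_cluster(): threshold must be in [0.80, 1.00]")
  }
  v <- pool$variants
  M <- identity_matrix(v$sequence)
  cluster_counts(v, M, threshold)
}

# Core clustering on an explicit variant table + identity matrix; the
# table must already be in canonical order (desc count, lexicographic).
cluster_counts <- function(variants, M, threshold) {
  res <- greedy_assign(M, seq_len(nrow(variants)), threshold)
  assignments <- data.frame(sequence = variants$sequence,
                            count = variants$count,
                            cluster = res$assignment,
                            stringsAsFactors = FALSE)
  reads <- as.integer(tapply(assignments$count, assignments$cluster, sum))
  clusters <- data.frame(
    cluster = seq_along(res$centroids),
    centroid = variants$sequence[res$centroids],
    n_variants = as.integer(table(factor(res$assignment,
                                         levels = seq_along(res$centroids)))),
    reads = reads,
    stringsAsFactors = FALSE)
  structure(list(threshold = threshold,
                 otu_count = length(res$centroids),
                 assignments = assignments, clusters = clusters),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> %d OTU(s) at %.0f%% identity\n",
              x$otu_count, 100 * x$threshold))
  invisible(x)
}

#' OTU counts across a grid of identity thresholds
#'
#' Clusters the pool at each threshold of the grid (default 89% to 100%
#' in 1% steps) and reports the OTU count per threshold.
#'
#' @param pool A [variant_pool()].
#' @param thresholds Identity grid (default `seq(0.89, 1, by = 0.01)`).
#' @return data.frame with columns `threshold`, `otu_count`.
#' @export
threshold_scan <- function(pool, thresholds = seq(0.89, 1.00, by = 0.01)) {
  stopifnot(inherits(pool, "variant_pool"))
  v <- pool$variants
  M <- identity_matrix(v$sequence)
  counts <- vapply(thresholds, function(th) {
    cluster_counts(v, M, th)$otu_count
  }, integer(1))
  data.frame(threshold = thresholds, otu_count = counts)
}

#' Leveling threshold of an OTU-count scan
#'
#' The largest identity threshold at which the pool collapses to a single
#' OTU. If the count never reaches 1 over the scanned grid, the lowest
#' scanned threshold is returned with attribute `"leveled" = FALSE`.
#'
#' @param scan A [threshold_scan()] result.
#' @return Threshold fraction, with attribute `"leveled"`.
#' @export
leveling_threshold <- function(scan) {
  stopifnot(is.data.frame(scan),
            all(c("threshold", "otu_count") %in% names(scan)))
  at_one <- scan$threshold[scan$otu_count == 1L]
  if (length(at_one)) {
    out <- max(at_one)
    attr(out, "leveled") <- TRUE
  } else {
    out <- min(scan$threshold)
    attr(out, "leveled") <- FALSE
    warning("leveling_threshold(): OTU count never reached 1 on the grid")
  }
  out
}

#' Error-corrected maximum intraindividual divergence
#'
#' The nominal divergence implied by the leveling threshold, 1 - L, minus
#' the residual sequencing error rate, floored at zero. E.g. leveling at
#' 89% identity with 1% residual error implies a true maximum divergence
#' of 10%.
#'
#' @param leveling Leveling threshold (identity fraction in [0, 1]).
#' @param residual_error_rate Residual substitution error rate in [0, 1].
#' @return Corrected divergence fraction, >= 0.
#' @export
corrected_divergence <- function(leveling, residual_error_rate) {
  leveling <- as.numeric(leveling)
  if (any(leveling < 0 | leveling > 1) ||
      any(residual_error_rate < 0 | residual_error_rate > 1)) {
    stop("corrected_divergence(): inputs must be in [0, 1]")
  }
  pmax((1 - leveling) - residual_error_rate, 0)
}

#' Relative abundance of the dominant OTU
#'
#' Clusters the pool at the given threshold and returns the read fraction
#' of the largest cluster (ties resolved deterministically by cluster
#' founding order, i.e. by the abundance-sorted greedy rule).
#'
#' @param pool A [variant_pool()].
#' @param threshold Identity threshold.
#' @return Fraction of reads in the most abundant OTU.
#' @export
dominant_proportion <- function(pool, threshold = 0.99) {
  cl <- greedy_cluster(pool, threshold)
  max(cl$clusters$reads) / sum(cl$clusters$reads)
}

#' Rarefied OTU richness at fixed read depth
#'
#' Subsamples `depth` reads without replacement `reps` times, clusters
#' each subsample at the given identity threshold, and returns the mean
#' OTU count. Reproducible under a fixed seed.
#'
#' @param pool A [variant_pool()] with at least `depth` total reads.
#' @param depth Reads per subsample (default 1600).
#' @param threshold Identity threshold (default 0.99).
#' @param reps Number of subsamples (default 100).
#' @param seed Integer seed.
#' @return Mean OTU count over subsamples, with attribute `"counts"`
#'   holding the per-rep values.
#' @export
rarefied_richness <- function(pool, depth = 1600L, threshold = 0.99,
                              reps = 100L, seed = NULL) {
  stopifnot(inherits(pool, "variant_pool"))
  v <- pool$variants
  total <- sum(v$count)
  if (total < depth) {
    stop("rarefied_richness(): pool has ", total, " reads, fewer than depth ",
         depth)
  }
  M <- identity_matrix(v$sequence)
  bounds <- cumsum(v$count)
  counts <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      reads <- sample.int(total, depth)
      tab <- tabulate(findInterval(reads - 1L, c(0L, bounds),
                                   rightmost.closed = FALSE),
                      nbins = nrow(v))
      keep <- tab > 0L
      sub <- data.frame(sequence = v$sequence[keep],
                        count = as.integer(tab[keep]),
                        stringsAsFactors = FALSE)
      ord <- order(-sub$count, sub$sequence)
      sub <- sub[ord, , drop = FALSE]
      cluster_counts(sub, M[keep, keep, drop = FALSE][ord, ord, drop = FALSE],
                     threshold)$otu_count
    }, integer(1))
  })
  out <- mean(counts)
  attr(out, "counts") <- counts
  out
}

#' Regression of per-cell OTU richness on copy number
#'
#' OLS of the OTU count (untransformed) on log10 per-cell copy number;
#' in the single-cell data richness declines with copy number, so a
#' negative slope is expected and its sign is reported.
#'
#' @param otu_counts Per-cell OTU counts.
#' @param cns Per-cell rDNA or rRNA copy numbers (> 0).
#' @return A [power_law_fit()] with `log_response = FALSE` and an
#'   additional `"slope_sign"` attribute.
#' @export
richness_vs_cn_regression <- function(otu_counts, cns) {
  stopifnot(length(otu_counts) == length(cns))
  if (any(!is.finite(cns)) || any(cns <= 0)) {
    stop("richness_vs_cn_regression(): copy numbers must be positive")
  }
  if (length(cns) < 3L) stop("richness_vs_cn_regression(): need n >= 3")
  lx <- log10(cns)
  fit <- stats::lm(otu_counts ~ lx)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  out <- power_law_fit(slope = slope,
                       intercept = unname(stats::coef(fit)[1]),
                       response = "OTU_count", predictor = "CN",
                       r_squared = sm$r.squared,
                       p_value = sm$coefficients[2, 4],
                       n = length(cns), log_response = FALSE)
  attr(out, "slope_sign") <- sign(slope)
  out
}
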