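# Group-comparison statistics: per-feature distribution shifts between a
# candidate set and a background set, and the RG-motif enrichment panel.

#' Compare feature distributions between two protein groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per feature, with
#' Benjamini-Hochberg adjustment across the tested features. The effect
#' direction is the median difference (group A minus group B). A feature
#' constant in both groups is reported with p = 1 and flagged.
#'
#' @param group_a,group_b Feature matrices (e.g. granule candidates vs the
#'   background proteome).
#' @param feature_names Features to test; default: columns shared by both.
#' @return Data frame with one row per requested feature: `feature`,
#'   `median_a`, `median_b`, `direction`, `p`, `p_adj`, `flag`.
#' @export
compare_feature_distributions <- function(group_a, group_b, feature_names = NULL) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (nrow(group_a) == 0L || nrow(group_b) == 0L) stop("both groups must be nonempty")
  if (is.null(feature_names))
    feature_names <- intersect(colnames(group_a), colnames(group_b))
  missing <- setdiff(feature_names,
                     intersect(colnames(group_a), colnames(group_b)))
  if (length(missing) > 0L)
    stop("unknown feature column(s): ", paste(missing, collapse = ", "))
  rows <- lapply(feature_names, function(f) {
    a <- group_a[, f]; b <- group_b[, f]
    constant <- length(unique(c(a, b))) == 1L
    p <- if (constant) 1 else
      stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE)$p.value
    data.frame(feature = f,
               median_a = stats::median(a), median_b = stats::median(b),
               direction = stats::median(a) - stats::median(b),
               p = p, flag = if (constant) "constant" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[, c("feature", "median_a", "median_b", "direction", "p", "p_adj", "flag")]
}

#' k-mer enrichment test between two groups
#'
#' Applies [compare_feature_distributions()] to k-mer fraction columns.
#' The arginine-glycine motif panel (RG, RGG, GRG) can be requested by its
#' plain k-mer names; columns are looked up with their `k2_`/`k3_`
#' prefixes.
#'
#' @param group_a,group_b Feature matrices containing k-mer columns.
#' @param kmers Character vector of k-mers (e.g. `c("RG", "RGG", "GRG")`).
#' @return Data frame as in [compare_feature_distributions()], one row per
#'   requested k-mer, with a `kmer` column; positive `direction` means
#'   enrichment in group A.
#' @export
kmer_enrichment_test <- function(group_a, group_b, kmers = c("RG", "RGG", "GRG")) {
  cols <- paste0("k", nchar(kmers), "_", kmers)
  avail <- intersect(colnames(as.matrix(group_a)), colnames(as.matrix(group_b)))
  missing <- setdiff(cols, avail)
  if (length(missing) > 0L)
    stop("k-mer column(s) not in feature tables: ",
         paste(missing, collapse = ", "))
  out <- compare_feature_distributions(group_a, group_b, cols)
  out <- cbind(kmer = kmers, out)
  rownames(out) <- NULL
  out
}
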