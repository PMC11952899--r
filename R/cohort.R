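# Learning-set assembly: tier-filtered positives from a granule catalogue
# plus seeded, catalogue-excluded negatives from the background proteome.

#' Filter a tier table by granule type and tier rule
#'
#' The tier table is a data frame with columns `accession`, `granule_type`
#' (`"SG"`, `"PB"`, or `"PBSG"`) and `tier` (integer 1-4). The combined
#' class `"PBSG"` ("PB or SG") selects rows of any of the three types; tier
#' rules are `"==1"`, `"<=2"`, `"<=3"`, `"<=4"`.
#'
#' @param table Tier table data frame.
#' @param granule_type `"SG"`, `"PB"`, or `"PBSG"`.
#' @param tier_rule One of `"==1"`, `"<=2"`, `"<=3"`, `"<=4"`.
#' @return Character vector of accessions, deduplicated, input order kept.
#' @export
filter_by_tier <- function(table, granule_type, tier_rule = "==1") {
  stopifnot(all(c("accession", "granule_type", "tier") %in% names(table)))
  if (!granule_type %in% c("SG", "PB", "PBSG"))
    stop("unknown granule_type: ", granule_type)
  if (!tier_rule %in% c("==1", "<=2", "<=3", "<=4"))
    stop("unknown tier_rule: ", tier_rule)
  types <- if (granule_type == "PBSG") c("SG", "PB", "PBSG") else granule_type
  max_tier <- if (tier_rule == "==1") 1L else as.integer(sub("<=", "", tier_rule))
  keep <- table$granule_type %in% types & table$tier <= max_tier
  unique(table$accession[keep])
}

#' Draw negatives from the background proteome
#'
#' Uniform, seeded sampling without replacement from the background pool
#' after removing every excluded accession.
#'
#' @param proteome_accessions Character vector of candidate accessions.
#' @param exclusion Accessions that may never be negatives.
#' @param n Number of negatives to draw.
#' @param seed RNG seed; identical seeds give identical draws.
#' @return Character vector of `n` distinct accessions.
#' @export
sample_negatives <- function(proteome_accessions, exclusion, n, seed = 1L) {
  pool <- setdiff(proteome_accessions, exclusion)
  if (length(pool) < n)
    stop("negative pool too small: need ", n, ", have ", length(pool),
         " (deficit ", n - length(pool), ")")
  with_seed(seed, sample(pool, n))
}

#' Assemble a balanced learning set
#'
#' Positives are the tier-filtered accessions of the requested granule type
#' that have a sequence in the supplied proteome (missing ones are dropped
#' with a warning). Negatives are drawn from the proteome excluding every
#' catalogued accession of any tier and any granule type, so that weaker-
#' evidence candidates can never contaminate the negative class. The set is
#' balanced: as many negatives as surviving positives.
#'
#' @param table Tier table (see [filter_by_tier()]).
#' @param proteome Named character vector of sequences (the background
#'   proteome; positives must be present by accession).
#' @param granule_type,tier_rule Positive-set definition.
#' @param seed RNG seed for the negative draw.
#' @return Object of class `learning_set`: list with `positives`,
#'   `negatives`, `granule_type`, `tier_rule`, `seed`.
#' @export
assemble_learning_set <- function(table, proteome, granule_type = "PBSG",
                                  tier_rule = "==1", seed = 1L) {
  positives <- filter_by_tier(table, granule_type, tier_rule)
  if (length(positives) == 0L) stop("no positives under ", granule_type, " ", tier_rule)
  missing <- setdiff(positives, names(proteome))
  if (length(missing) > 0L) {
    warning("dropping ", length(missing),
            " positive(s) without a sequence in the proteome")
    positives <- setdiff(positives, missing)
  }
  if (length(positives) == 0L)
    stop("no positives left after matching against the proteome")
  negatives <- sample_negatives(names(proteome),
                                exclusion = unique(table$accession),
                                n = length(positives), seed = seed)
  structure(list(positives = positives, negatives = negatives,
                 granule_type = granule_type, tier_rule = tier_rule,
                 seed = seed),
            class = "learning_set")
}

#' @export
print.learning_set <- function(x, ...) {
  cat("Balanced learning set (", x$granule_type, ", tier ", x$tier_rule, ")\n",
      "  positives: ", length(x$positives), "\n",
      "  negatives: ", length(x$negatives), " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.learning_set <- function(x, ...) {
  data.frame(accession = c(x$positives, x$negatives),
             label = rep(c(1L, 0L), c(length(x$positives), length(x$negatives))),
             role = "train",
             stringsAsFactors = FALSE)
}
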