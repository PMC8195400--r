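#' Construct a rare-variant set for one gene window
#'
#' Bundles a dosage matrix (samples by variants, minor-allele counts 0/1/2)
#' with per-variant minor allele frequencies, genomic positions and
#' identifiers. All rare-variant tests in this package consume this
#' container.
#'
#' @param dosages integer matrix, samples in rows, variants in columns;
#'   entries must be 0, 1 or 2 minor-allele counts.
#' @param maf numeric vector of minor allele frequencies, one per variant,
#'   each in `(0, maf_threshold)`. When `NULL`, empirical frequencies
#'   `colMeans(dosages) / 2` are used.
#' @param positions integer vector of 1-based genomic coordinates (optional).
#' @param ids character vector of unique variant identifiers (optional;
#'   defaults to `v1, v2, ...`).
#' @param chrom chromosome label(s), recycled to the number of variants
#'   (optional).
#' @param maf_threshold rarity cutoff; variants must have `maf` strictly
#'   below it. Default 0.05.
#'
#' @return An object of class `variant_set`: a list with elements `dosages`,
#'   `maf`, `positions`, `ids`, `chrom`, `maf_threshold`.
#' @export
#' @examples
#' G <- matrix(rbinom(200, 2, 0.02), nrow = 50)
#' vs <- variant_set(G, maf = rep(0.02, 4))
#' n_variants(vs)
variant_set <- function(dosages, maf = NULL, positions = NULL, ids = NULL,
                        chrom = NULL, maf_threshold = 0.05) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  k <- ncol(dosages)
  if (k < 1) stop("variant_set needs at least one variant", call. = FALSE)
  if (anyNA(dosages) || !all(dosages %in% 0:2)) {
    stop("dosages must be minor-allele counts in {0, 1, 2}", call. = FALSE)
  }
  if (is.null(maf)) maf <- colMeans(dosages) / 2
  if (length(maf) != k) stop("maf length must equal the number of variants",
                             call. = FALSE)
  if (any(maf <= 0) || any(maf >= maf_threshold)) {
    stop("every maf must lie strictly in (0, maf_threshold)", call. = FALSE)
  }
  if (is.null(ids)) ids <- paste0("v", seq_len(k))
  if (anyDuplicated(ids)) stop("variant ids must be unique", call. = FALSE)
  if (!is.null(positions) && length(positions) != k) {
    stop("positions length must equal the number of variants", call. = FALSE)
  }
  if (!is.null(chrom)) chrom <- rep_len(as.character(chrom), k)
  structure(
    list(dosages = dosages, maf = as.numeric(maf),
         positions = if (is.null(positions)) NULL else as.integer(positions),
         ids = as.character(ids), chrom = chrom,
         maf_threshold = maf_threshold),
    class = "variant_set"
  )
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d samples x %d rare variants (MAF < %g)\n",
              nrow(x$dosages), ncol(x$dosages), x$maf_threshold))
  cat(sprintf("  carriers per variant: median %g, max %g\n",
              stats::median(colSums(x$dosages > 0)),
              max(colSums(x$dosages > 0))))
  invisible(x)
}

#' Number of variants / samples in a variant set
#' @param x a `variant_set`.
#' @return integer count.
#' @export
n_variants <- function(x) ncol(x$dosages)

#' @rdname n_variants
#' @export
n_samples <- function(x) nrow(x$dosages)

# Validate a phenotype vector against a variant set.
check_phenotype <- function(variants, phenotype) {
  if (!is.numeric(phenotype)) stop("phenotype must be numeric", call. = FALSE)
  if (!all(is.finite(phenotype))) {
    stop("phenotype values must all be finite", call. = FALSE)
  }
  if (length(phenotype) != nrow(variants$dosages)) {
    stop("phenotype length does not match the number of samples",
         call. = FALSE)
  }
  invisible(TRUE)
}
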