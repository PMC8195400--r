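# Small in-code fixtures shared across test files.

# Random rare-variant set with guaranteed polymorphic columns.
make_vs <- function(N = 80, k = 5, maf = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maf)) maf <- runif(k, 0.005, 0.049)
  G <- matrix(rbinom(N * k, 2, rep(maf, each = N)), nrow = N)
  G[1, colSums(G) == 0] <- 1L  # keep every column polymorphic
  variant_set(G, maf = maf, positions = sort(sample.int(1e6, k)))
}

# Variant set built from an explicit dosage matrix.
vs_from <- function(G, maf = NULL) {
  if (is.null(maf)) maf <- pmax(colMeans(G) / 2, 1e-4)
  variant_set(as.matrix(G), maf = pmin(maf, 0.0499))
}

# Tiny hand-written VCF used by the QC reader tests; returns the path.
write_tiny_vcf <- function(lines_body, samples = sprintf("S%02d", 1:10)) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    lines_body), path)
  path
}
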