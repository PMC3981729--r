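# Small fixture builders shared across the suite.

# a DartPanel from an explicit genotypes x markers matrix
makePanel <- function(m, map = NULL, groups = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("m%03d", seq_len(ncol(m)))
  DartPanel(m, map = map, groups = groups)
}

# panel of independent Bernoulli markers, optional missingness
randomPanel <- function(n, L, f = NULL, missing = 0, seed = 1) {
  set.seed(seed)
  if (is.null(f)) f <- stats::runif(L, 0.2, 0.8)
  m <- sapply(f, function(p) stats::rbinom(n, 1, p))
  if (missing > 0) m[stats::runif(n * L) < missing] <- NA
  makePanel(m)
}

# map placing L markers evenly on one chromosome
lineMap <- function(markers, chrom = "1A", spacing = 1) {
  data.frame(marker = markers, chrom = chrom,
             pos = seq_along(markers) * spacing, stringsAsFactors = FALSE)
}

# align inferred two-group labels to truth; returns fraction agreeing
labelAgreement <- function(inferred, truth) {
  a <- inferred == unique(inferred)[1]
  b <- truth == unique(truth)[1]
  max(mean(a == b), mean(a != b))
}

# StructureFit stub with a prescribed ln-evidence (for Evanno tests)
fitStub <- function(K, lnE, n = 4) {
  q <- matrix(1 / K, n, K,
              dimnames = list(sprintf("g%02d", seq_len(n)), NULL))
  methods::new("StructureFit", K = as.integer(K), q = q,
               p = matrix(0.5, K, 2), alphaTrace = 1,
               loglik = rep(lnE, 5), lnEvidence = lnE, seed = NA_integer_)
}
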