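# Shared fixture builders: all test data is generated in code.

CLASSES6 <- c("SNP", "MITE-DTX", "RLX-RIX", "DEL", "DUP", "INV")

# small five-group panel with all six marker classes
small_panel <- function(seed = 1,
                        n = c(IND = 60, JAP = 40, AUS = 30, ARO = 10, ADM = 10),
                        markers = c(SNP = 300, `MITE-DTX` = 40, `RLX-RIX` = 30,
                                    DEL = 60, DUP = 30, INV = 20),
                        linked = list(), fst = 0.1) {
  simulate_population(population_config(
    n_per_group = n, fst = fst, marker_counts = markers,
    linked_pairs = linked, seed = seed))
}

# bare genotype_matrix from a dosage matrix, all SNPs on one chromosome
toy_G <- function(X, class = "SNP", chrom = "1") {
  m <- ncol(as.matrix(X))
  genotype_matrix(as.matrix(X),
                  data.frame(id = sprintf("m%03d", seq_len(m)), chrom = chrom,
                             pos = seq_len(m) * 100L, class = class,
                             stringsAsFactors = FALSE))
}

# unstructured Hardy-Weinberg SNP panel
hwe_panel <- function(n, m, seed = 1, p_range = c(0.1, 0.9)) {
  set.seed(seed)
  p <- runif(m, p_range[1], p_range[2])
  X <- sapply(p, function(pp) rbinom(n, 2L, pp))
  toy_G(X)
}
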