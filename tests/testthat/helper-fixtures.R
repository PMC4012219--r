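# Shared fixtures for the test suite.  Everything is generated in code;
# no binary files are shipped.

# tiny deterministic genotype matrix with one missing call
tiny_genotypes <- function() {
  genotype_matrix(matrix(c(0L, 1L, 2L, NA, 2L, 0L, 1L, 1L, 0L, 2L, NA, 0L),
                         nrow = 4, ncol = 3))
}

# write a PLINK fileset with a hand-assembled single data byte
write_single_byte_bed <- function(dir, byte = 0xe4) {
  prefix <- file.path(dir, "one")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, byte)), paste0(prefix, ".bed"))
  utils::write.table(data.frame(1, paste0("I", 1:4), 0, 0, 0, -9),
                     paste0(prefix, ".fam"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(1, "snp1", 0, 1, "A", "C"),
                     paste0(prefix, ".bim"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  prefix
}

# grid of valid (p_k, p_l, D) combinations spanning the admissible box
ld_grid <- function() {
  out <- list()
  for (p_k in c(0.1, 0.3, 0.5, 0.7)) for (p_l in c(0.2, 0.5, 0.8)) {
    lo <- max(-p_k * p_l, -(1 - p_k) * (1 - p_l))
    hi <- min(p_k * (1 - p_l), (1 - p_k) * p_l)
    for (f in c(0.25, 0.75)) {
      out[[length(out) + 1]] <- c(p_k = p_k, p_l = p_l, D = lo + f * (hi - lo))
    }
  }
  out
}

# one polygenic replicate and its fits, shared across tests
polygenic_fit <- function(n = 600, m = 80, rho = 0.25, sorted = FALSE) {
  sim <- simulate_polygenic_study(n = n, m = m, rho = rho, sorted = sorted)
  fit <- suppressWarnings(he_fit(sim$phenotype$y, sim$grm))
  list(sim = sim, fit = fit)
}
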