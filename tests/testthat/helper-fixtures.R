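# In-code fixtures: small founder sets built from random haplotypes (no
# coalescent backend), toy designs, and cached expensive objects.

# DH founder set with random haplotypes at uniform allele frequencies
toy_founders <- function(n = 30, n_chr = 2, n_qtn = 20, n_snp = 30,
                         crop = "A", seed = 1) {
  set.seed(seed)
  params <- genome_params(n_chromosomes = n_chr, genetic_length = 1.43,
                          physical_length = 1e6, mutation_rate = 1e-7,
                          n_qtn_per_chr = n_qtn, n_snp_per_chr = n_snp,
                          ne_present = 100, ne_ancient = 100)
  per_chr <- n_qtn + n_snp
  L <- n_chr * per_chr
  p <- runif(L, 0.1, 0.9)
  h <- matrix(0L, 2 * n, L)
  for (i in seq_len(n)) {
    g <- rbinom(L, 1, p)
    h[2 * i - 1, ] <- g
    h[2 * i, ] <- g
  }
  map <- do.call(rbind, lapply(seq_len(n_chr), function(k) {
    role <- rep("SNP", per_chr)
    role[sample.int(per_chr, n_qtn)] <- "QTN"
    data.frame(chr = k, pos = sort(sample.int(1e6, per_chr)), role = role)
  }))
  founder_set(h, map, params, crop)
}

# miniature designs that keep the pipeline structure at toy cost
mini_designs <- function() {
  pheno <- program_design(
    "Pheno", "conventional", n_crosses = 8, dh_per_cross = 6,
    block_size = 8, n_new_parents = 2,
    n_pyt = 16, n_gia1 = 8, n_gia2 = 4, n_sia_lines = 2, n_sia2 = 2,
    n_probes = 3)
  list(
    "Pheno" = pheno,
    "Baseline-GS" = program_design(
      "Baseline-GS", "conventional", n_crosses = 8, dh_per_cross = 6,
      block_size = 8, n_new_parents = 2,
      n_pyt = 16, n_gia1 = 8, n_gia2 = 4, n_sia_lines = 2, n_sia2 = 2,
      n_probes = 3, sel_pyt = "ggia", sel_gia1 = "ggia",
      parent_rule = list(stage = "GIA1", criterion = "ggia", replace = "oldest"),
      genotyping = "pyt"),
    "DH-GS" = program_design(
      "DH-GS", "conventional", n_crosses = 8, dh_per_cross = 6,
      block_size = 16, n_new_parents = 16,
      n_pyt = 16, n_gia1 = 8, n_gia2 = 4, n_sia_lines = 2, n_sia2 = 2,
      n_probes = 3, sel_dh = "ggia", sel_pyt = "ggia", sel_gia1 = "ggia",
      parent_rule = list(stage = "DH", criterion = "ggia", replace = "all"),
      crossing = "max_avoidance", genotyping = "all_dh"),
    "Grid-GS" = program_design(
      "Grid-GS", "grid", n_crosses = 8, dh_per_cross = 6,
      block_size = 16, n_new_parents = 16,
      parent_rule = list(stage = "DH", criterion = "ggia", replace = "all"),
      crossing = "max_avoidance", genotyping = "all_dh",
      grid = list(n_keep = 10, n_field = 12, n_advance = 3,
                  n_sia2 = 2, n_init = 4))
  )
}

# one mini burn-in, cached across test files
mini_burnin <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fA <- toy_founders(n = 30, crop = "A", seed = 11)
      fB <- toy_founders(n = 30, crop = "B", seed = 12)
      arch <- sample_architecture(fA, fB, 0.9, seed = 13)
      cache <<- list(
        fA = fA, fB = fB, arch = arch,
        state = run_burnin(fA, fB, arch, mini_designs()$Pheno,
                           n_years = 12, seed = 14))
    }
    cache
  }
})
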