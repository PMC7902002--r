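test_that("recombination rate is the exact quotient of map lengths", {
  expect_identical(derive_recombination_rate(1.43, 8e8), 1.43 / 8e8)
  expect_equal(derive_recombination_rate(1.43, 8e8), 1.7875e-9)
  expect_equal(format_recombination_rate(derive_recombination_rate(1.43, 8e8)),
               "1.8e-09")
  expect_identical(derive_recombination_rate(1, 1), 1)
  expect_equal(derive_recombination_rate(2.86, 8e8), 3.575e-9)
  expect_error(derive_recombination_rate(0, 8e8), "positive")
  expect_error(derive_recombination_rate(1.43, -1), "positive")
})

test_that("genome parameter validation rejects impossible inputs", {
  expect_error(genome_params(mutation_rate = 0), "mutation_rate")
  expect_error(genome_params(n_chromosomes = 0), "chromosome")
  expect_error(genome_params(ne_present = -5), "positive")
  p <- desk_genome_params()
  expect_equal(p$n_chromosomes, 2L)
  expect_equal(p$recombination_rate, 1.43 / 8e8)
})

test_that("meiosis of a homozygous parent returns the parental haplotype", {
  fs <- toy_founders(n = 5, seed = 1)
  g1 <- fs$pop$haplo[1:2, ]
  set.seed(2)
  for (i in 1:5) expect_identical(meiosis(g1, fs$gm), unname(g1[1, ]))
})

test_that("two-site recombinant fraction follows the Haldane map function", {
  # two sites 0.5 Morgans apart on a 1.43 M chromosome
  params <- genome_params(n_chromosomes = 1, genetic_length = 1.43,
                          physical_length = 1.43e6, mutation_rate = 1e-7,
                          n_qtn_per_chr = 1, n_snp_per_chr = 1)
  map <- data.frame(chr = 1, pos = c(1, 0.5e6), role = c("QTN", "SNP"))
  gm <- build_gmap(map, params)
  f1 <- rbind(c(0L, 0L), c(1L, 1L))
  n <- 4000
  set.seed(31)
  rec <- replicate(n, {
    g <- meiosis(f1, gm)
    g[1] != g[2]
  })
  r_expect <- (1 - exp(-2 * 0.5)) / 2
  se <- sqrt(r_expect * (1 - r_expect) / n)
  expect_lt(abs(mean(rec) - r_expect), 3 * se)
})

test_that("doubled haploids are homozygous and Mendelian", {
  fs <- toy_founders(n = 6, seed = 3)
  gm <- fs$gm
  h1 <- fs$pop$haplo[1, ]
  h2 <- fs$pop$haplo[3, ]
  f1 <- rbind(h1, h2, deparse.level = 0)
  set.seed(4)
  dh <- make_dh(f1, gm)
  expect_identical(dh[1, ], dh[2, ])
  # every locus carries one of the two parental alleles
  expect_true(all(dh[1, ] == h1 | dh[1, ] == h2))
  # DH of a DH reproduces the genotype exactly
  dh2 <- make_dh(dh, gm)
  expect_identical(dh2, dh)
})

test_that("DH allele frequency at a heterozygous locus is binomial around 0.5", {
  params <- genome_params(n_chromosomes = 1, genetic_length = 1.43,
                          physical_length = 1e6, mutation_rate = 1e-7,
                          n_qtn_per_chr = 1, n_snp_per_chr = 1)
  map <- data.frame(chr = 1, pos = c(2e5, 8e5), role = c("QTN", "SNP"))
  gm <- build_gmap(map, params)
  f1 <- rbind(c(0L, 1L), c(1L, 0L))
  n <- 4000
  set.seed(5)
  freq <- mean(replicate(n, make_dh(f1, gm)[1, 1]))
  expect_lt(abs(freq - 0.5), 3 * sqrt(0.25 / n))
})

test_that("coalescent founders have the requested structure and are reproducible", {
  params <- genome_params(n_chromosomes = 2, genetic_length = 1.43,
                          physical_length = 1e6, mutation_rate = 1e-7,
                          n_qtn_per_chr = 15, n_snp_per_chr = 25,
                          ne_present = 1000, ne_ancient = 1000)
  fs1 <- simulate_founders(params, n_founders = 20, crop = "A", seed = 42)
  fs2 <- simulate_founders(params, n_founders = 20, crop = "A", seed = 42)
  expect_identical(fs1$pop$haplo, fs2$pop$haplo)
  expect_identical(fs1$map, fs2$map)
  fs3 <- simulate_founders(params, n_founders = 20, crop = "A", seed = 43)
  expect_false(identical(fs1$pop$haplo, fs3$pop$haplo))
  # site structure: counts per role, disjoint QTN/SNP, DH homozygosity
  expect_equal(sum(fs1$map$role == "QTN"), 2 * 15)
  expect_equal(sum(fs1$map$role == "SNP"), 2 * 25)
  expect_equal(length(intersect(fs1$gm$qtn, fs1$gm$snp)), 0)
  expect_true(all(n_heterozygous(fs1$pop) == 0))
  expect_equal(npop(fs1$pop), 20)
})

test_that("a single founder carries no genetic variance", {
  params <- genome_params(n_chromosomes = 1, genetic_length = 1.43,
                          physical_length = 1e6, mutation_rate = 1e-7,
                          n_qtn_per_chr = 5, n_snp_per_chr = 5,
                          ne_present = 1000, ne_ancient = 1000)
  fs <- simulate_founders(params, n_founders = 1, crop = "A", seed = 7)
  expect_equal(npop(fs$pop), 1)
  expect_true(all(n_heterozygous(fs$pop) == 0))
  d <- dosages(fs$pop)
  expect_true(all(apply(d, 2, function(x) length(unique(x))) == 1))
})

test_that("too few segregating sites raises an informative error", {
  params <- genome_params(n_chromosomes = 1, genetic_length = 1.43,
                          physical_length = 1e4, mutation_rate = 1e-8,
                          n_qtn_per_chr = 500, n_snp_per_chr = 500,
                          ne_present = 100, ne_ancient = 100)
  expect_error(simulate_founders(params, 10, seed = 1),
               "segregating sites")
})

test_that("constant-Ne diversity matches the neutral expectation 4*Ne*mu", {
  ne <- 1000
  mu <- 1e-7
  params <- genome_params(n_chromosomes = 10, genetic_length = 1.43,
                          physical_length = 2e5, mutation_rate = mu,
                          n_qtn_per_chr = 5, n_snp_per_chr = 5,
                          ne_present = ne, ne_ancient = ne)
  set.seed(8)
  seeds <- lapply(1:10, function(i) sample.int(1e6, 2))
  chroms <- icbreedsim:::.run_coalescent(params, 50, seeds)
  pi_chr <- vapply(chroms, function(ch) {
    p <- colMeans(ch$haplo)
    sum(2 * p * (1 - p)) * nrow(ch$haplo) / (nrow(ch$haplo) - 1) /
      params$physical_length
  }, numeric(1))
  expected <- 4 * ne * mu
  se <- sd(pi_chr) / sqrt(length(pi_chr))
  expect_lt(abs(mean(pi_chr) - expected), 3 * se + 1e-12)
})

test_that("population containers preserve pedigree and subset consistently", {
  fs <- toy_founders(n = 10, seed = 9)
  pop <- fs$pop
  s <- pop_subset(pop, c(2, 5, 7))
  expect_equal(npop(s), 3)
  expect_identical(s$haplo, pop$haplo[c(3, 4, 9, 10, 13, 14), ])
  b <- pop_bind(pop_subset(pop, 1:2), pop_subset(pop, 3:4))
  expect_identical(b$haplo, pop$haplo[1:8, ])
  expect_error(new_pop(matrix(2L, 2, 3), id = 1), "0/1")
})
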