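# Genome simulation: founder haplotypes, meiosis and doubled-haploid production.

#' Genome and founder-demography parameters
#'
#' Describes the simulated genome of one component crop: the number of
#' chromosomes, per-chromosome genetic length (Morgans) and physical length
#' (base pairs), the per-base mutation rate, how many QTN and SNP-array sites
#' are drawn per chromosome, and the effective-population-size history used by
#' the coalescent founder simulation. The demography is a linear ramp from
#' `ne_present` at the present to `ne_ancient` at `ne_ancient_time`
#' generations ago; for the coalescent it is discretized into piecewise
#' constant epochs on a log-spaced grid of `ne_steps` breakpoints so that the
#' rapid recent part of the ramp is resolved.
#'
#' The per-base recombination rate is always derived as
#' `genetic_length / physical_length` and cannot be set directly.
#'
#' @param n_chromosomes Number of chromosome pairs.
#' @param genetic_length Genetic length of each chromosome in Morgans.
#' @param physical_length Physical length of each chromosome in base pairs.
#' @param mutation_rate Per-base, per-generation mutation rate.
#' @param n_qtn_per_chr Number of QTN sites sampled per chromosome.
#' @param n_snp_per_chr Number of SNP-array sites sampled per chromosome.
#' @param ne_present Effective population size at present.
#' @param ne_ancient Effective population size at `ne_ancient_time`.
#' @param ne_ancient_time Generations ago at which `ne_ancient` applies.
#' @param ne_steps Number of epochs used to discretize the linear ramp.
#' @return An object of class `genome_params`.
#' @examples
#' p <- genome_params()
#' p$recombination_rate  # 1.7875e-09
#' @export
genome_params <- function(n_chromosomes = 10,
                          genetic_length = 1.43,
                          physical_length = 8e8,
                          mutation_rate = 2e-9,
                          n_qtn_per_chr = 1000,
                          n_snp_per_chr = 2000,
                          ne_present = 50,
                          ne_ancient = 32000,
                          ne_ancient_time = 1e5,
                          ne_steps = 150) {
  if (n_chromosomes < 1 || n_qtn_per_chr < 0 || n_snp_per_chr < 0)
    stop("chromosome and site counts must be non-negative (>= 1 chromosome)")
  if (mutation_rate <= 0) stop("mutation_rate must be positive")
  if (ne_present <= 0 || ne_ancient <= 0 || ne_ancient_time <= 0)
    stop("effective population sizes and times must be positive")
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    genetic_length = genetic_length,
    physical_length = physical_length,
    mutation_rate = mutation_rate,
    recombination_rate = derive_recombination_rate(genetic_length, physical_length),
    n_qtn_per_chr = as.integer(n_qtn_per_chr),
    n_snp_per_chr = as.integer(n_snp_per_chr),
    ne_present = ne_present,
    ne_ancient = ne_ancient,
    ne_ancient_time = ne_ancient_time,
    ne_steps = as.integer(ne_steps)
  ), class = "genome_params")
}

#' Desk-scale genome preset
#'
#' A reduced genome used for fast, replicated comparisons: 2 chromosomes with
#' 100 QTN and 200 SNP each, the same per-chromosome map length, mutation rate
#' and demography as the full genome. The genetic architecture (map length per
#' chromosome, marker:QTN ratio, demography) keeps the shape of the full
#' preset at a fraction of the cost.
#'
#' @return A `genome_params` object.
#' @export
desk_genome_params <- function() {
  genome_params(n_chromosomes = 2, n_qtn_per_chr = 100, n_snp_per_chr = 200)
}

#' Derive the per-base recombination rate
#'
#' The per-base recombination rate is the ratio of genetic length to physical
#' length of a chromosome. The exact quotient is returned;
#' [format_recombination_rate()] rounds to 2 significant figures for display.
#'
#' @param genetic_length Genetic length in Morgans.
#' @param physical_length Physical length in base pairs.
#' @return Recombination rate per base pair.
#' @examples
#' derive_recombination_rate(1.43, 8e8)  # 1.7875e-09, displayed as 1.8e-09
#' @export
derive_recombination_rate <- function(genetic_length, physical_length) {
  if (!is.numeric(genetic_length) || !is.numeric(physical_length) ||
      genetic_length <= 0 || physical_length <= 0)
    stop("genetic_length and physical_length must be positive numbers")
  genetic_length / physical_length
}

#' @rdname derive_recombination_rate
#' @param rate A recombination rate.
#' @export
format_recombination_rate <- function(rate) {
  format(signif(rate, 2), scientific = TRUE)
}

# ---- population container ----------------------------------------------

#' Construct a population of genotypes
#'
#' A population stores phased haplotypes as a `2N x L` 0/1 integer matrix
#' (rows `2i - 1` and `2i` are the two haplotypes of individual `i`), ids,
#' pedigree (mother/father ids), the bi-parental family of origin and the
#' year of creation. Site order must match the site map of the founder set
#' the population descends from.
#'
#' @param haplo Integer 0/1 matrix with two rows per individual.
#' @param id Integer ids, one per individual.
#' @param mother,father Parent ids (NA for founders).
#' @param family Bi-parental family (cross) identifier.
#' @param year Year of creation.
#' @param crop Crop label, `"A"` or `"B"`.
#' @return An object of class `icpop`.
#' @export
new_pop <- function(haplo, id, mother = NA_integer_, father = NA_integer_,
                    family = NA_integer_, year = NA_integer_, crop = "A") {
  haplo <- as.matrix(haplo)
  storage.mode(haplo) <- "integer"
  n <- length(id)
  if (nrow(haplo) != 2L * n)
    stop("haplo must have two rows per individual")
  if (any(haplo != 0L & haplo != 1L)) stop("allele codes must be 0/1")
  structure(list(
    haplo = haplo,
    id = as.integer(id),
    mother = rep_len(as.integer(mother), n),
    father = rep_len(as.integer(father), n),
    family = rep_len(as.integer(family), n),
    year = rep_len(as.integer(year), n),
    crop = crop,
    gv = NULL
  ), class = "icpop")
}

#' @export
print.icpop <- function(x, ...) {
  cat(sprintf("<icpop> crop %s: %d individuals, %d sites\n",
              x$crop, npop(x), ncol(x$haplo)))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop An `icpop`.
#' @export
npop <- function(pop) length(pop$id)

#' Subset a population by individual index
#' @param pop An `icpop`.
#' @param i Integer indices of individuals to keep.
#' @export
pop_subset <- function(pop, i) {
  i <- as.integer(i)
  rows <- as.vector(rbind(2L * i - 1L, 2L * i))
  out <- pop
  out$haplo <- pop$haplo[rows, , drop = FALSE]
  out$id <- pop$id[i]
  out$mother <- pop$mother[i]
  out$father <- pop$father[i]
  out$family <- pop$family[i]
  out$year <- pop$year[i]
  if (!is.null(pop$gv)) out$gv <- pop$gv[i, , drop = FALSE]
  for (f in c("pheno", "joined"))
    if (!is.null(pop[[f]])) out[[f]] <- pop[[f]][i]
  out
}

#' Concatenate two populations of the same crop
#' @param x,y `icpop` objects over the same site map.
#' @export
pop_bind <- function(x, y) {
  stopifnot(x$crop == y$crop, ncol(x$haplo) == ncol(y$haplo))
  out <- x
  out$haplo <- rbind(x$haplo, y$haplo)
  for (f in c("id", "mother", "father", "family", "year"))
    out[[f]] <- c(x[[f]], y[[f]])
  out$gv <- if (!is.null(x$gv) && !is.null(y$gv)) rbind(x$gv, y$gv) else NULL
  for (f in c("pheno", "joined")) {
    out[[f]] <- if (!is.null(x[[f]]) && !is.null(y[[f]])) c(x[[f]], y[[f]]) else NULL
  }
  out
}

#' Allele dosages of a population
#'
#' @param pop An `icpop`.
#' @param sites Optional column indices restricting the returned loci.
#' @return An `N x L` matrix of 0/1/2 allele dosages.
#' @export
dosages <- function(pop, sites = NULL) {
  n <- npop(pop)
  odd <- seq(1L, 2L * n, by = 2L)
  d <- pop$haplo[odd, , drop = FALSE] + pop$haplo[odd + 1L, , drop = FALSE]
  if (!is.null(sites)) d <- d[, sites, drop = FALSE]
  d
}

#' Count heterozygous sites per individual
#' @param pop An `icpop`.
#' @export
n_heterozygous <- function(pop) {
  n <- npop(pop)
  odd <- seq(1L, 2L * n, by = 2L)
  rowSums(pop$haplo[odd, , drop = FALSE] != pop$haplo[odd + 1L, , drop = FALSE])
}

# ---- genetic map index --------------------------------------------------

#' Build a map index for meiosis and trait computation
#'
#' Splits the site map into per-chromosome position vectors and records which
#' columns are QTN and which are SNP-array sites.
#'
#' @param map Data frame with columns `chr`, `pos`, `role`.
#' @param params The `genome_params` the map was generated under.
#' @return An object of class `gmap`.
#' @export
build_gmap <- function(map, params) {
  chr <- factor(map$chr, levels = unique(map$chr))
  structure(list(
    chr_sites = split(seq_len(nrow(map)), chr),
    chr_pos = split(map$pos, chr),
    genetic_length = params$genetic_length,
    physical_length = params$physical_length,
    qtn = which(map$role == "QTN"),
    snp = which(map$role == "SNP"),
    n_loci = nrow(map)
  ), class = "gmap")
}

# ---- meiosis and DH production -----------------------------------------

# Phase vector (0/1) of a single recombinant gamete along one chromosome.
# Crossovers are Poisson with mean = genetic length, placed uniformly
# (no interference); the starting haplotype is chosen at random.
.chromosome_phase <- function(pos, genetic_length, physical_length) {
  n_co <- stats::rpois(1L, genetic_length)
  phase0 <- if (stats::runif(1L) < 0.5) 0L else 1L
  if (n_co == 0L) return(rep.int(phase0, length(pos)))
  xo <- sort(stats::runif(n_co, 0, physical_length))
  (phase0 + findInterval(pos, xo)) %% 2L
}

#' Simulate one meiosis
#'
#' Produces a single recombinant gamete from a genotype. The number of
#' crossovers per chromosome is Poisson with mean equal to the chromosome's
#' genetic length in Morgans and crossovers are placed uniformly along the
#' physical map (no crossover interference).
#'
#' @param genotype A `2 x L` 0/1 matrix (the two haplotypes of one
#'   individual), e.g. one individual's rows of `pop$haplo`.
#' @param gm A `gmap` from [build_gmap()].
#' @return An integer haplotype vector of length `L`.
#' @export
meiosis <- function(genotype, gm) {
  if (!is.matrix(genotype) || nrow(genotype) != 2L || ncol(genotype) != gm$n_loci)
    stop("genotype must be a 2 x n_loci haplotype matrix matching the map")
  h1 <- genotype[1L, ]
  h2 <- genotype[2L, ]
  out <- h1
  for (k in seq_along(gm$chr_sites)) {
    idx <- gm$chr_sites[[k]]
    ph <- .chromosome_phase(gm$chr_pos[[k]], gm$genetic_length, gm$physical_length)
    seg <- out[idx]
    take2 <- ph == 1L
    seg[take2] <- h2[idx][take2]
    out[idx] <- seg
  }
  out
}

#' Produce a doubled haploid from a genotype
#'
#' One meiosis gamete is duplicated into a fully homozygous genotype.
#'
#' @param genotype A `2 x L` 0/1 haplotype matrix (typically an F1).
#' @param gm A `gmap`.
#' @return A `2 x L` matrix with two identical rows.
#' @export
make_dh <- function(genotype, gm) {
  g <- meiosis(genotype, gm)
  rbind(g, g, deparse.level = 0)
}

# Batch DH production from bi-parental crosses of homozygous parents.
# `pairs` is a 2-column matrix of individual indices into `block`; parents are
# assumed fully homozygous (DH), so each parent contributes its single
# distinct haplotype to the F1 and each DH line is a doubled F1 gamete.
# Family ids are globally unique (fam_start + cross index - 1).
.dh_cohort <- function(block, pairs, n_per_cross, gm, year, id_start,
                       fam_start = 1L) {
  n_cross <- nrow(pairs)
  n_new <- n_cross * n_per_cross
  L <- ncol(block$haplo)
  haplo <- matrix(0L, nrow = 2L * n_new, ncol = L)
  mother <- father <- family <- integer(n_new)
  row <- 1L
  ind <- 0L
  for (cx in seq_len(n_cross)) {
    i1 <- pairs[cx, 1L]
    i2 <- pairs[cx, 2L]
    f1 <- rbind(block$haplo[2L * i1 - 1L, ], block$haplo[2L * i2 - 1L, ],
                deparse.level = 0)
    for (d in seq_len(n_per_cross)) {
      g <- meiosis(f1, gm)
      haplo[row, ] <- g
      haplo[row + 1L, ] <- g
      row <- row + 2L
      ind <- ind + 1L
      mother[ind] <- block$id[i1]
      father[ind] <- block$id[i2]
      family[ind] <- fam_start + cx - 1L
    }
  }
  new_pop(haplo, id = seq.int(id_start, length.out = n_new),
          mother = mother, father = father, family = family,
          year = year, crop = block$crop)
}

# ---- founder simulation -------------------------------------------------

.find_python <- function() {
  py <- getOption("icbreedsim.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("no python interpreter found on PATH; the coalescent founder ",
         "simulation requires python with the msprime package")
  py
}

.coalescent_script <- function() {
  p <- system.file("python", "coalescent_founders.py", package = "icbreedsim")
  if (!nzchar(p)) stop("coalescent_founders.py not found in the installed package")
  p
}

# Run the coalescent backend and parse its text output into a list of
# per-chromosome lists with elements `pos` and `haplo` (2n x S_k).
.run_coalescent <- function(params, n_founders, seeds) {
  cfg <- list(
    n_chromosomes = params$n_chromosomes,
    n_founders = n_founders,
    physical_length = params$physical_length,
    recombination_rate = params$recombination_rate,
    mutation_rate = params$mutation_rate,
    ne_present = params$ne_present,
    ne_ancient = params$ne_ancient,
    ne_time = params$ne_ancient_time,
    ne_steps = params$ne_steps,
    seeds = seeds
  )
  cfg_file <- tempfile(fileext = ".json")
  out_file <- tempfile(fileext = ".txt")
  on.exit(unlink(c(cfg_file, out_file)), add = TRUE)
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA)
  status <- system2(.find_python(), c(.coalescent_script(), cfg_file, out_file),
                    stdout = FALSE, stderr = "")
  if (status != 0L) stop("coalescent founder simulation failed (python exit status ",
                         status, ")")
  lines <- readLines(out_file)
  headers <- grep("^#chrom ", lines)
  chroms <- vector("list", length(headers))
  for (k in seq_along(headers)) {
    hdr <- as.integer(strsplit(sub("^#chrom ", "", lines[headers[k]]), " ")[[1]])
    n_sites <- hdr[2L]
    n_hap <- hdr[3L]
    pos <- as.numeric(strsplit(lines[headers[k] + 1L], " ", fixed = TRUE)[[1]])
    hap_lines <- lines[(headers[k] + 2L):(headers[k] + 1L + n_hap)]
    m <- matrix(0L, nrow = n_hap, ncol = n_sites)
    for (h in seq_len(n_hap)) {
      m[h, ] <- utf8ToInt(hap_lines[h]) - utf8ToInt("0")
    }
    chroms[[k]] <- list(pos = pos, haplo = m)
  }
  chroms
}

#' Simulate a founder population for one crop
#'
#' Generates `n_founders` diploid genotypes under the coalescent with the
#' demography in `params`, samples disjoint QTN and SNP site sets uniformly
#' without replacement among the segregating sites of each chromosome, and
#' converts every founder to a doubled haploid (one meiosis gamete duplicated),
#' so the returned founders are fully homozygous. The two component crops are
#' simulated as independent founder sets with identical parameters.
#'
#' @param params A `genome_params` object.
#' @param n_founders Number of founder genotypes (>= 1).
#' @param crop Crop label, `"A"` or `"B"`.
#' @param seed Integer seed; identical `(params, n_founders, seed)` give a
#'   bit-identical founder set.
#' @return An object of class `founder_set` with elements `crop`, `pop`
#'   (the DH founders), `map` (chr, pos, role per site), `params` and `gm`.
#' @export
simulate_founders <- function(params, n_founders = 100, crop = "A", seed = 1L) {
  stopifnot(inherits(params, "genome_params"))
  if (n_founders < 1) stop("n_founders must be >= 1")
  set.seed(seed)
  seeds <- lapply(seq_len(params$n_chromosomes),
                  function(i) sample.int(.Machine$integer.max - 1L, 2L))
  chroms <- .run_coalescent(params, n_founders, seeds)
  n_pick <- params$n_qtn_per_chr + params$n_snp_per_chr
  hap_blocks <- vector("list", length(chroms))
  map_blocks <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    n_seg <- length(chroms[[k]]$pos)
    if (n_seg < n_pick)
      stop(sprintf(paste0(
        "chromosome %d has only %d segregating sites but %d QTN + %d SNP were ",
        "requested; increase the mutation rate or use a scaled genome preset"),
        k, n_seg, params$n_qtn_per_chr, params$n_snp_per_chr))
    keep <- sort(sample.int(n_seg, n_pick))
    role <- rep("SNP", n_pick)
    role[sample.int(n_pick, params$n_qtn_per_chr)] <- "QTN"
    hap_blocks[[k]] <- chroms[[k]]$haplo[, keep, drop = FALSE]
    map_blocks[[k]] <- data.frame(chr = k, pos = chroms[[k]]$pos[keep], role = role)
  }
  haplo <- do.call(cbind, hap_blocks)
  map <- do.call(rbind, map_blocks)
  pop <- new_pop(haplo, id = seq_len(n_founders), year = 0L, crop = crop)
  gm <- build_gmap(map, params)
  # convert to doubled haploids: duplicate one meiosis gamete per founder
  n <- npop(pop)
  dh_haplo <- matrix(0L, nrow = 2L * n, ncol = gm$n_loci)
  for (i in seq_len(n)) {
    g <- meiosis(pop$haplo[c(2L * i - 1L, 2L * i), , drop = FALSE], gm)
    dh_haplo[2L * i - 1L, ] <- g
    dh_haplo[2L * i, ] <- g
  }
  dh <- new_pop(dh_haplo, id = seq_len(n), year = 0L, crop = crop)
  structure(list(crop = crop, pop = dh, map = map, params = params, gm = gm),
            class = "founder_set")
}

#' Assemble a founder set from explicit haplotypes
#'
#' Programmatic constructor used for toy examples and tests: takes an existing
#' haplotype matrix and site map instead of running the coalescent backend.
#'
#' @param haplo `2N x L` 0/1 matrix.
#' @param map Data frame with columns `chr`, `pos`, `role`.
#' @param params A `genome_params`.
#' @param crop Crop label.
#' @return A `founder_set`.
#' @export
founder_set <- function(haplo, map, params, crop = "A") {
  pop <- new_pop(haplo, id = seq_len(nrow(haplo) / 2L), year = 0L, crop = crop)
  structure(list(crop = crop, pop = pop, map = map, params = params,
                 gm = build_gmap(map, params)), class = "founder_set")
}

#' @export
print.founder_set <- function(x, ...) {
  cat(sprintf("<founder_set> crop %s: %d founders, %d QTN + %d SNP sites on %d chromosomes\n",
              x$crop, npop(x$pop), length(x$gm$qtn), length(x$gm$snp),
              x$params$n_chromosomes))
  invisible(x)
}

#' Mean pairwise diversity per site
#'
#' Average proportion of differing sites between two distinct haplotypes,
#' computed over all haplotype pairs at the given sites. Used to check the
#' coalescent backend against the neutral expectation `4 Ne mu` per site
#' under a constant population size.
#'
#' @param haplo A haplotype 0/1 matrix (rows = haplotypes).
#' @return Mean pairwise difference per site.
#' @export
pairwise_diversity <- function(haplo) {
  n <- nrow(haplo)
  p <- colMeans(haplo)
  # mean pairwise difference per site: 2p(1-p) * n/(n-1)
  mean(2 * p * (1 - p)) * n / (n - 1)
}
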