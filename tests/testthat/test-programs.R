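test_that("the 80-parent crossing block spans 3,160 candidate pairs", {
  expect_identical(n_cross_pairs(80), 3160)
})

test_that("random crossing samples distinct pairs uniformly", {
  fs <- toy_founders(n = 6, seed = 41)
  block <- fs$pop
  # exhaustive draw covers every pair exactly once
  set.seed(1)
  all_p <- make_crosses_random(block, n_cross_pairs(6))
  expect_equal(nrow(unique(as.data.frame(all_p))), 15)
  expect_error(make_crosses_random(block, 16), "combinations")
  # inclusion frequency of each pair is close to n_crosses / n_pairs
  set.seed(2)
  counts <- matrix(0, 6, 6)
  for (i in 1:1000) {
    p <- make_crosses_random(block, 3)
    counts[p] <- counts[p] + 1
  }
  freq <- counts[upper.tri(counts)] / 1000
  expected <- 3 / 15
  chi <- sum((freq - expected)^2 / (expected * (1 - expected) / 1000))
  expect_lt(chi, qchisq(0.999, df = 14))
})

test_that("maximum avoidance rotates family pairings across generations", {
  # 4 families with one parent each
  h <- matrix(0L, 8, 4)
  pop <- new_pop(h, id = 1:4, family = 1:4, crop = "A")
  g0 <- make_crosses_max_avoidance(pop, 2, generation = 0)
  expect_equal(sort(pop$family[g0[1, ]]), c(1, 2))
  expect_equal(sort(pop$family[g0[2, ]]), c(3, 4))
  g1 <- make_crosses_max_avoidance(pop, 2, generation = 1)
  expect_equal(sort(pop$family[g1[1, ]]), c(1, 3))
  expect_equal(sort(pop$family[g1[2, ]]), c(2, 4))
})

test_that("maximum avoidance equalizes parent use and avoids sib mating", {
  # 20 families x 2 parents, 20 crosses: every parent used exactly once
  h <- matrix(0L, 80, 4)
  pop <- new_pop(h, id = 1:40, family = rep(1:20, each = 2), crop = "A")
  for (gen in 0:3) {
    p <- make_crosses_max_avoidance(pop, 20, generation = gen)
    use <- tabulate(as.vector(p), 40)
    expect_lte(max(use) - min(use), 1)
    expect_true(all(pop$family[p[, 1]] != pop$family[p[, 2]]))
  }
  # more crosses than parent pairs: usage stays within one
  p2 <- make_crosses_max_avoidance(pop, 35, generation = 0)
  use2 <- tabulate(as.vector(p2), 40)
  expect_lte(max(use2) - min(use2), 1)
  # no family structure: falls back to random with a warning
  pop_nf <- new_pop(h, id = 1:40, crop = "A")
  expect_warning(make_crosses_max_avoidance(pop_nf, 10), "random")
})

test_that("family-equalized selection takes the best members per family", {
  set.seed(43)
  h <- matrix(0L, 40, 4)
  pop <- new_pop(h, id = 1:20, family = rep(1:4, each = 5), crop = "A")
  merit <- rnorm(20)
  sel <- select_max_avoidance(pop, merit, 8)
  expect_equal(npop(sel), 8)
  expect_equal(as.integer(table(sel$family)), rep(2L, 4))
  for (f in 1:4) {
    fam_members <- which(pop$family == f)
    best2 <- fam_members[order(-merit[fam_members])][1:2]
    expect_setequal(sel$id[sel$family == f], pop$id[best2])
  }
  # more families than parents: one from each of the best families
  pop2 <- new_pop(h, id = 1:20, family = 1:20, crop = "A")
  sel2 <- select_max_avoidance(pop2, merit, 6)
  expect_equal(npop(sel2), 6)
  expect_setequal(sel2$id, order(-merit)[1:6])
})

test_that("window census reproduces the printed training population sizes", {
  d <- full_designs()
  conv <- window_census(d$`DH-GS`)
  expect_identical(conv$genotypes, 2500L)
  expect_identical(conv$records, 2739L)
  gi <- window_census(d$`Grid-GS`, phase = "initial")
  expect_identical(gi$genotypes, 115L)
  expect_identical(gi$records, 2645L)
  gs <- window_census(d$`Grid-GS`, phase = "steady")
  expect_identical(gs$genotypes, 2500L)
  expect_identical(gs$records, 4790L)
  # grid candidate-pair universe
  expect_equal(d$`Grid-GS`$grid$n_keep^2, 250000)
})

test_that("grid sampling advances exactly the best predicted pairs", {
  set.seed(44)
  gA <- rnorm(30)
  gB <- rnorm(25)
  res <- grid_sample_and_select(gA, gB, n_keep = 20, n_field = 40, n_advance = 10)
  expect_equal(res$n_pairs, 400)
  expect_equal(nrow(unique(as.data.frame(res$field_pairs))), 40)
  # brute force: enumerate all pairs of the kept sets and sort
  kept_pairs <- expand.grid(iA = seq_along(res$keep_A), iB = seq_along(res$keep_B))
  vals <- (gA[res$keep_A[kept_pairs$iA]] + gB[res$keep_B[kept_pairs$iB]]) / 2
  best <- kept_pairs[order(-vals), ][1:10, ]
  got <- as.data.frame(res$advance_pairs)
  names(got) <- c("iA", "iB")
  expect_setequal(paste(got$iA, got$iB), paste(best$iA, best$iB))
  # degenerate grid
  one <- grid_sample_and_select(c(1, 2), c(3), n_keep = 1, n_field = 1, n_advance = 1)
  expect_equal(one$n_pairs, 1)
  expect_error(grid_sample_and_select(gA, gB, 5, 26, 1), "grid")
})

test_that("the burn-in pipeline reaches the designed steady state", {
  mb <- mini_burnin()
  st <- mb$state
  d <- mini_designs()$Pheno
  for (cr in c("A", "B")) {
    cs <- st$crops[[cr]]
    expect_equal(npop(cs$dh), d$n_crosses * d$dh_per_cross)
    expect_equal(npop(cs$pyt), d$n_pyt)
    expect_equal(npop(cs$gia1), d$n_gia1)
    expect_equal(npop(cs$gia2), d$n_gia2)
    expect_equal(npop(cs$sia_lines), d$n_sia_lines)
    expect_equal(npop(cs$block), d$block_size)
    expect_equal(npop(cs$probes), d$n_probes)
    # every pipeline genotype is a fully homozygous DH
    expect_true(all(n_heterozygous(cs$dh) == 0))
    expect_true(all(n_heterozygous(cs$block) == 0))
  }
  expect_equal(length(st$sia1$pheno), d$n_sia_lines^2)
  expect_equal(length(st$sia2$pheno), d$n_sia2)
  # advancement conserves cohorts: PYT ids came from last year's DH ids
  st2 <- advance_year(st)
  expect_true(all(st2$crops$A$pyt$id %in% st$crops$A$dh$id))
  expect_true(all(st2$crops$A$gia1$id %in% st$crops$A$pyt$id))
  expect_true(all(st2$crops$A$gia2$id %in% st$crops$A$gia1$id))
})

test_that("burn-in is deterministic given the seed", {
  mb <- mini_burnin()
  st2 <- run_burnin(mb$fA, mb$fB, mb$arch, mini_designs()$Pheno,
                    n_years = 12, seed = 14)
  expect_identical(state_metrics(mb$state), state_metrics(st2))
  expect_identical(mb$state$crops$A$dh$haplo, st2$crops$A$dh$haplo)
})

test_that("training windows never exceed five years and match the census", {
  mb <- mini_burnin()
  st <- mb$state
  ts <- build_training_window(st, "A")
  expect_lte(diff(range(ts$records$year)), 4)
  cen <- window_census(mini_designs()$`Baseline-GS`)
  expect_equal(length(ts$ids), cen$genotypes)
  expect_equal(nrow(ts$records), cen$records)
  # steady-state future window of a GS arm keeps the same census
  stb <- run_program(st, mini_designs()$`Baseline-GS`, n_years = 7, seed = 15)
  tsb <- build_training_window(stb, "A")
  expect_lte(diff(range(tsb$records$year)), 4)
  expect_equal(length(tsb$ids), cen$genotypes)
  expect_equal(nrow(tsb$records), cen$records)
})

test_that("the grid arm reproduces its initialization and steady-state census", {
  mb <- mini_burnin()
  d <- mini_designs()$`Grid-GS`
  stg <- branch_program(mb$state, d, seed = 16)
  ts0 <- build_grid_training_window(stg)
  cen0 <- window_census(d, "initial")
  expect_equal(unname(attr(ts0, "census")$genotypes["A"]), cen0$genotypes)
  expect_equal(attr(ts0, "census")$records, cen0$records)
  for (i in 1:7) stg <- advance_year(stg)
  ts1 <- build_grid_training_window(stg)
  cen1 <- window_census(d, "steady")
  expect_equal(unname(attr(ts1, "census")$genotypes["A"]), cen1$genotypes)
  expect_equal(attr(ts1, "census")$records, cen1$records)
  expect_lte(diff(range(ts1$records$year)), 4)
  # cohort geometry of the grid pipeline
  g <- d$grid
  expect_equal(npop(stg$grid_cohort$A), g$n_keep)
  expect_equal(length(stg$sia1$pheno), g$n_advance)
  expect_equal(length(stg$sia2$pheno), g$n_sia2)
})

test_that("generation intervals follow each design's selection stage", {
  mb <- mini_burnin()
  lag_of <- function(st) {
    due <- max(as.integer(names(st$cross_queue)))
    q <- st$cross_queue[[as.character(due)]]
    due - max(q$A$block$year)
  }
  # Pheno: parents chosen on GIA1 results enter the block the next season,
  # giving the 5-year generation interval
  stp <- run_program(mb$state, mini_designs()$Pheno, n_years = 6, seed = 17)
  expect_equal(lag_of(stp), 5)
  std <- run_program(mb$state, mini_designs()$`DH-GS`, n_years = 6, seed = 18)
  expect_equal(lag_of(std), 2)
  stg <- run_program(mb$state, mini_designs()$`Grid-GS`, n_years = 6, seed = 19)
  expect_equal(lag_of(stg), 2)
  # crossing-block residence in the oldest-replacement scheme is four cycles
  expect_equal(sort(unique(stp$year - stp$crops$A$block$joined)), 0:3)
})

test_that("genetic variance erodes over the course of the burn-in", {
  mb <- mini_burnin()
  m <- state_metrics(mb$state)
  expect_lt(mean(tail(m$var_ic, 3)), mean(utils::head(m$var_ic, 3)))
})

test_that("program arms branched from one burn-in share its state", {
  mb <- mini_burnin()
  stb <- branch_program(mb$state, mini_designs()$`Baseline-GS`, seed = 20)
  # the shared burn-in history is untouched by branching
  expect_identical(stb$records[stb$records$year <= 12, ],
                   mb$state$records)
  expect_identical(stb$crops$A$dh$haplo, mb$state$crops$A$dh$haplo)
  expect_error(run_config(programs = "No-Such-GS"), "unknown program")
})
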