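# Year-by-year orchestration of the breeding programs: crossing schemes,
# stage advancement and selection, probe and parent management, sliding
# training windows, and the 20-year phenotypic-selection burn-in shared by
# all compared program arms.

# ---- crossing schemes ---------------------------------------------------

#' Number of possible parent pairs in a crossing block
#' @param block_size Number of parents.
#' @examples
#' n_cross_pairs(80)  # 3160
#' @export
n_cross_pairs <- function(block_size) choose(block_size, 2)

#' Random bi-parental crosses
#'
#' Samples `n_crosses` distinct unordered parent pairs uniformly without
#' replacement from all pairwise combinations of the crossing block.
#'
#' @param block An `icpop` of parents.
#' @param n_crosses Number of crosses.
#' @return A 2-column integer matrix of individual indices into `block`.
#' @export
make_crosses_random <- function(block, n_crosses) {
  n <- npop(block)
  total <- n_cross_pairs(n)
  if (n_crosses > total)
    stop("cannot draw ", n_crosses, " distinct pairs from ", total,
         " possible combinations of ", n, " parents")
  all_pairs <- t(utils::combn(n, 2L))
  all_pairs[sample.int(total, n_crosses), , drop = FALSE]
}

# disjoint family pairs with a target partner offset on the family circle
.family_pairs <- function(nf, off) {
  avail <- seq_len(nf)
  out <- matrix(0L, nrow = 0L, ncol = 2L)
  while (length(avail) >= 2L) {
    i <- avail[1L]
    cand <- avail[-1L]
    target <- i + off
    dist <- pmin((cand - target) %% nf, (target - cand) %% nf)
    j <- cand[which.min(dist)]
    out <- rbind(out, c(i, j))
    avail <- setdiff(avail, c(i, j))
  }
  out
}

#' Maximum-avoidance crosses
#'
#' Deterministic circular-rotation pairing of families: families are paired
#' with a partner offset that increments every generation, so that the least
#' related families meet and every family (and, through a least-used-member
#' rule, every parent) contributes equally, up to the divisibility of the
#' cross count. Parents from the same family are never crossed. Falls back
#' to random crossing with a warning if the parents carry no family
#' identifiers.
#'
#' @param block An `icpop` of parents with `family` identifiers.
#' @param n_crosses Number of crosses to produce.
#' @param generation Generation counter controlling the rotation offset.
#' @return A 2-column integer matrix of individual indices into `block`.
#' @export
make_crosses_max_avoidance <- function(block, n_crosses, generation = 0L) {
  fam <- block$family
  if (all(is.na(fam))) {
    warning("parents carry no family identifiers; falling back to random crossing")
    return(make_crosses_random(block, n_crosses))
  }
  fams <- unique(fam)
  nf <- length(fams)
  if (nf < 2L) stop("maximum avoidance needs at least two families")
  members <- split(seq_len(npop(block)), factor(fam, levels = fams))
  used <- integer(npop(block))
  pairs <- matrix(0L, nrow = 0L, ncol = 2L)
  round <- 0L
  while (nrow(pairs) < n_crosses && round < nf) {
    off <- ((generation + round) %% max(1L, nf - 1L)) + 1L
    fp <- .family_pairs(nf, off)
    for (r in seq_len(nrow(fp))) {
      if (nrow(pairs) >= n_crosses) break
      mi <- members[[fp[r, 1L]]]
      mj <- members[[fp[r, 2L]]]
      p1 <- mi[which.min(used[mi])]
      p2 <- mj[which.min(used[mj])]
      used[p1] <- used[p1] + 1L
      used[p2] <- used[p2] + 1L
      pairs <- rbind(pairs, c(p1, p2))
    }
    round <- round + 1L
  }
  if (nrow(pairs) < n_crosses)
    stop("could not build ", n_crosses, " maximum-avoidance crosses from ",
         nf, " families")
  pairs
}

# ---- selection helpers --------------------------------------------------

# indices of the n best by score; ties broken by id (deterministic)
.top_idx <- function(score, id, n) {
  ord <- order(-score, id)
  ord[seq_len(min(n, length(ord)))]
}

# round-robin within-family selection: best of each family first, then
# second-best of each family, ... until n are chosen
.within_family_idx <- function(pop, score, n) {
  fam <- pop$family
  ord <- order(fam, -score, pop$id)
  rank_in_fam <- stats::ave(seq_along(ord), fam[ord], FUN = seq_along)
  picked <- ord[order(rank_in_fam, fam[ord], pop$id[ord])]
  picked[seq_len(min(n, length(picked)))]
}

#' Family-equalized selection for maximum-avoidance crossing
#'
#' Selects `n_parents` genotypes by merit under the constraint that every
#' family contributes equally (within one): with `f` families each family
#' contributes `floor(n/f)` or `ceiling(n/f)` of its best members; if there
#' are at least `n_parents` families, the single best member of each of the
#' best `n_parents` families is taken.
#'
#' @param pop An `icpop` with family identifiers.
#' @param merit Numeric selection criterion (larger is better).
#' @param n_parents Number of parents to select.
#' @return An `icpop` of the selected parents.
#' @export
select_max_avoidance <- function(pop, merit, n_parents) {
  fam <- pop$family
  if (all(is.na(fam))) {
    warning("no family identifiers; plain truncation selection used")
    return(pop_subset(pop, .top_idx(merit, pop$id, n_parents)))
  }
  fams <- unique(fam)
  members <- split(seq_len(npop(pop)), factor(fam, levels = fams))
  members <- lapply(members, function(ix) ix[order(-merit[ix], pop$id[ix])])
  best <- vapply(members, function(ix) merit[ix[1L]], numeric(1))
  fam_ord <- order(-best)
  nf <- length(fams)
  take <- integer(nf)
  if (nf >= n_parents) {
    take[fam_ord[seq_len(n_parents)]] <- 1L
  } else {
    take[] <- n_parents %/% nf
    rem <- n_parents %% nf
    if (rem > 0L) take[fam_ord[seq_len(rem)]] <- take[fam_ord[seq_len(rem)]] + 1L
  }
  sel <- unlist(lapply(seq_len(nf), function(k) {
    members[[k]][seq_len(min(take[k], length(members[[k]])))]
  }))
  if (length(sel) < n_parents) {
    extra <- setdiff(order(-merit, pop$id), sel)
    sel <- c(sel, extra[seq_len(n_parents - length(sel))])
  }
  pop_subset(pop, sort(sel))
}

# ---- pipeline state -----------------------------------------------------

.empty_records <- function() {
  data.frame(year = integer(), stage = character(), crop = character(),
             id_A = integer(), id_B = integer(), y = numeric(),
             var_e = numeric())
}

.record_rows <- function(year, stage, crop, id_A, y, var_e, id_B = NA_integer_) {
  data.frame(year = year, stage = stage, crop = crop,
             id_A = as.integer(id_A), id_B = as.integer(id_B),
             y = y, var_e = var_e)
}

# record-level residual variance for a stage of the current design
.rv <- function(design, stage) record_error_variance(design$h2[[stage]])

# archive a training cohort: append SNP dosages, true genetic values and the
# archive-time monocrop phenotype to the per-crop genotype store and register
# the cohort's ids under `year` in the training-population index
.archive_cohort <- function(state, cr, pop, year) {
  snp <- dosages(pop, state$gm[[cr]]$snp)
  st <- state$store[[cr]]
  if (is.null(st$snp)) {
    st <- list(ids = pop$id, snp = snp, gv = pop$gv, year = rep(year, npop(pop)),
               pheno = if (!is.null(pop$pheno)) pop$pheno else rep(NA_real_, npop(pop)))
  } else {
    st$ids <- c(st$ids, pop$id)
    st$snp <- rbind(st$snp, snp)
    st$gv <- rbind(st$gv, pop$gv)
    st$year <- c(st$year, rep(year, npop(pop)))
    st$pheno <- c(st$pheno,
                  if (!is.null(pop$pheno)) pop$pheno else rep(NA_real_, npop(pop)))
  }
  state$store[[cr]] <- st
  state$tp_years[[cr]][[as.character(year)]] <- pop$id
  state
}

.store_rows <- function(state, cr, ids) {
  r <- match(ids, state$store[[cr]]$ids)
  if (anyNA(r)) stop("genotype(s) missing from the ", cr, " genotype store")
  r
}

# enqueue next year's crosses: parents snapshot + pairs + cohort parameters
.enqueue_crosses <- function(state, due, per_crop) {
  state$cross_queue[[as.character(due)]] <- per_crop
  state
}

.make_pairs <- function(state, block, design) {
  if (design$crossing == "max_avoidance")
    make_crosses_max_avoidance(block, design$n_crosses, state$ma_gen)
  else
    make_crosses_random(block, design$n_crosses)
}

# build the queue entry for one crop from its current block
.cross_entry <- function(state, cr, design) {
  block <- state$crops[[cr]]$block
  pairs <- .make_pairs(state, block, design)
  entry <- list(block = block, pairs = pairs,
                n_per_cross = design$dh_per_cross,
                fam_start = state$next_fam[[cr]])
  state$next_fam[[cr]] <- state$next_fam[[cr]] + nrow(pairs)
  list(state = state, entry = entry)
}

.queue_new_crosses <- function(state, design) {
  per_crop <- list()
  for (cr in c("A", "B")) {
    res <- .cross_entry(state, cr, design)
    state <- res$state
    per_crop[[cr]] <- res$entry
  }
  if (design$crossing == "max_avoidance") state$ma_gen <- state$ma_gen + 1L
  .enqueue_crosses(state, state$year + 2L, per_crop)
}

#' Initialize a pipeline state from founder sets
#'
#' Sets up the per-crop crossing block (random founders), probe varieties
#' (random founders not in the block), the pending-cross queue for the first
#' two years, and empty training stores.
#'
#' @param founders_A,founders_B `founder_set` objects.
#' @param arch A `trait_arch`.
#' @param design The initial [program_design()] (the burn-in runs Pheno).
#' @return A pipeline state (class `pipeline_state`).
#' @export
init_program_state <- function(founders_A, founders_B, arch, design) {
  founders <- list(A = founders_A, B = founders_B)
  crops <- list()
  state <- structure(list(
    year = 0L, design = design, arch = arch,
    gm = list(A = founders_A$gm, B = founders_B$gm),
    crops = NULL, sia1 = NULL, sia2 = NULL,
    sia1_next = NULL, grid_cohort = NULL,
    pending_parents = list(A = NULL, B = NULL),
    records = .empty_records(),
    store = list(A = list(), B = list()),
    tp_years = list(A = list(), B = list()),
    cross_queue = list(), ma_gen = 0L,
    next_id = list(A = 0L, B = 0L), next_fam = list(A = 1L, B = 1L),
    metrics = list(), released = list(), fit = NULL,
    burnin_end = NA_integer_, center_ic = 0
  ), class = "pipeline_state")
  for (cr in c("A", "B")) {
    fs <- founders[[cr]]
    pop <- .add_gv(fs$pop, arch, fs$gm)
    n <- npop(pop)
    if (n < design$block_size + design$n_probes)
      stop("not enough founders for crossing block plus probes")
    pick <- sample.int(n, design$block_size + design$n_probes)
    block <- pop_subset(pop, sort(pick[seq_len(design$block_size)]))
    block$joined <- rep(0L, npop(block))
    probes <- pop_subset(pop, sort(pick[design$block_size + seq_len(design$n_probes)]))
    crops[[cr]] <- list(dh = NULL, pyt = NULL, gia1 = NULL, gia2 = NULL,
                        sia_lines = NULL, block = block, probes = probes)
    state$next_id[[cr]] <- n + 1L
  }
  state$crops <- crops
  # prime the queue: cohorts of years 1 and 2 descend from the founder block
  for (due in 1:2) {
    per_crop <- list()
    for (cr in c("A", "B")) {
      res <- .cross_entry(state, cr, design)
      state <- res$state
      per_crop[[cr]] <- res$entry
    }
    state <- .enqueue_crosses(state, due, per_crop)
  }
  state
}

#' @export
print.pipeline_state <- function(x, ...) {
  cat(sprintf("<pipeline_state> %s, year %d (burn-in end %s)\n",
              x$design$name, x$year,
              ifelse(is.na(x$burnin_end), "pending", x$burnin_end)))
  invisible(x)
}

# ---- training windows ---------------------------------------------------

.window_years <- function(design, year) (year - design$window):(year - 1L)

#' Training window for the Conventional genomic selection model
#'
#' Returns the sliding-window training set of one crop for a model fitted at
#' the start of `year`: the genotypes of the PYT cohorts of the previous
#' `window` years and all PYT/GIA1/GIA2 records generated in those years
#' whose genotype is in the block (records of cohorts that left the window
#' through the 1- and 2-year stage lags are dropped with them).
#'
#' @param state A `pipeline_state`.
#' @param crop `"A"` or `"B"`.
#' @param year Fitting year (defaults to the year after the state's).
#' @return A [training_set()], or `NULL` when no cohorts are archived yet.
#' @export
build_training_window <- function(state, crop, year = state$year + 1L) {
  w <- .window_years(state$design, year)
  ids <- unlist(state$tp_years[[crop]][as.character(w)], use.names = FALSE)
  if (is.null(ids) || length(ids) == 0L) return(NULL)
  rows <- .store_rows(state, crop, ids)
  st <- state$store[[crop]]
  rec <- state$records
  rec <- rec[rec$crop == crop & rec$year %in% w &
               rec$stage %in% c("PYT", "GIA1", "GIA2") & rec$id_A %in% ids, ,
             drop = FALSE]
  ts <- training_set(st$snp[rows, , drop = FALSE], ids,
                     data.frame(y = rec$y, year = rec$year, stage = rec$stage,
                                id = rec$id_A, var_e = rec$var_e))
  attr(ts, "gv") <- st$gv[rows, , drop = FALSE]
  attr(ts, "gv_year") <- st$year[rows]
  ts
}

# Pooled within-year additive (co)variance of the training genotypes. Year
# is a fixed effect in the genomic models, so the marker effects only ever
# explain within-year contrasts; between-cohort spread (genetic trend and
# selection-set differences) must not inflate the prior marker variance.
.within_year_G <- function(gv, year) {
  tabs <- split(seq_len(nrow(gv)), year)
  tabs <- tabs[vapply(tabs, length, 1L) >= 2L]
  if (length(tabs) == 0L) return(true_variance_components(gv))
  n_tot <- sum(vapply(tabs, length, 1L))
  Reduce(`+`, lapply(tabs, function(ix) {
    length(ix) / n_tot * true_variance_components(gv[ix, , drop = FALSE])
  }))
}

#' Training window for the Grid genomic selection model
#'
#' The genotype block holds the grid-stage genotypes (the gGIA-selected DH
#' sets, or the initialization subsets during/after burn-in) of the previous
#' `window` years for both crops; records are all GRID/SIA1/SIA2 intercrop
#' records of those years. SIA records referencing genotypes from cohorts
#' just outside the genotype window keep their dosages through the genotype
#' store.
#'
#' @inheritParams build_training_window
#' @return A [grid_training_set()], or `NULL` if nothing is archived.
#' @export
build_grid_training_window <- function(state, year = state$year + 1L) {
  w <- .window_years(state$design, year)
  ids <- lapply(c(A = "A", B = "B"), function(cr)
    unlist(state$tp_years[[cr]][as.character(w)], use.names = FALSE))
  if (length(ids$A) == 0L || length(ids$B) == 0L) return(NULL)
  rec <- state$records
  # SIA records feed the grid model only once they come from the grid
  # pipeline itself; the burn-in's phenotypic-selection SIA trials are not
  # part of the initialization training set (which is the 5 x n_init^2 grid)
  own_sia <- !is.na(state$burnin_end) & rec$year > state$burnin_end
  rec <- rec[rec$year %in% w &
               (rec$stage == "GRID" |
                  (rec$stage %in% c("SIA1", "SIA2") & own_sia)), ,
             drop = FALSE]
  all_A <- union(ids$A, rec$id_A)
  all_B <- union(ids$B, rec$id_B)
  rA <- .store_rows(state, "A", all_A)
  rB <- .store_rows(state, "B", all_B)
  ts <- grid_training_set(
    state$store$A$snp[rA, , drop = FALSE], all_A,
    state$store$B$snp[rB, , drop = FALSE], all_B,
    data.frame(y = rec$y, year = rec$year, stage = rec$stage,
               id_A = rec$id_A, id_B = rec$id_B, var_e = rec$var_e))
  # variance components: pooled within-year intercrop variance of the
  # window's grid-stage genotypes (year is a fixed effect in the model)
  attr(ts, "var_ic") <- lapply(list(A = "A", B = "B"), function(cr) {
    r <- .store_rows(state, cr, ids[[cr]])
    st <- state$store[[cr]]
    .within_year_G(st$gv[r, , drop = FALSE], st$year[r])["ic", "ic"]
  })
  attr(ts, "census") <- list(genotypes = c(A = length(ids$A), B = length(ids$B)),
                             records = nrow(rec))
  ts
}

.fit_conventional_crop <- function(state, crop, year) {
  ts <- build_training_window(state, crop, year)
  if (is.null(ts) || nrow(ts$records) == 0L) return(NULL)
  fit_multitrait_rrblup(ts, .within_year_G(attr(ts, "gv"), attr(ts, "gv_year")))
}

.fit_grid_model <- function(state, year) {
  ts <- build_grid_training_window(state, year)
  if (is.null(ts) || nrow(ts$records) == 0L) return(NULL)
  v <- attr(ts, "var_ic")
  fit_grid_rrblup(ts, v$A, v$B)
}

#' Expected training-window census of a design
#'
#' Computes, from the design's stage schedule alone, how many genotypes and
#' phenotypic records its sliding training window holds. For the
#' Conventional designs a stage that lags the PYT stage by `l` years
#' contributes `window - l` cohorts of records. For the Grid design the
#' initial window holds the burn-in initialization subsets
#' (`window x n_init` genotypes per crop, `window x n_init^2` records) and
#' the steady-state window `window x n_keep` genotypes per crop and
#' `window x (n_field + n_advance + n_sia2)` records.
#'
#' @param design A [program_design()].
#' @param phase `"steady"` or `"initial"` (Grid only; identical for
#'   Conventional designs).
#' @return List with elements `genotypes` (per crop) and `records`.
#' @export
window_census <- function(design, phase = c("steady", "initial")) {
  phase <- match.arg(phase)
  W <- design$window
  if (design$type == "conventional") {
    lags <- c(PYT = 0L, GIA1 = 1L, GIA2 = 2L)
    ns <- c(design$n_pyt, design$n_gia1, design$n_gia2)
    list(genotypes = as.integer(W * design$n_pyt),
         records = as.integer(sum(pmax(W - lags, 0L) * ns)))
  } else {
    g <- design$grid
    if (phase == "initial")
      list(genotypes = as.integer(W * g$n_init),
           records = as.integer(W * g$n_init^2))
    else
      list(genotypes = as.integer(W * g$n_keep),
           records = as.integer(W * (g$n_field + g$n_advance + g$n_sia2)))
  }
}

# ---- shared stage mechanics --------------------------------------------

# probe-mean GIA phenotype for candidates of one crop: the mean over the
# serving probe varieties of the pair value, one error draw at the stage's
# effective-rep variance
.gia_phenotype <- function(cand_aic, probe_aic, var_e) {
  phenotype_intercrop(cand_aic, mean(probe_aic), var_e)
}

# SIA pair stage container
.pair_stage <- function(id_A, id_B, aic_A, aic_B, pheno, year) {
  list(id_A = id_A, id_B = id_B, aic_A = aic_A, aic_B = aic_B,
       pheno = pheno, year = year)
}

# advance pair stage: top n of `prev` by phenotype, re-tested at `var_e`
.advance_pairs <- function(prev, n, var_e, year) {
  if (is.null(prev) || length(prev$pheno) == 0L) return(NULL)
  k <- .top_idx(prev$pheno, seq_along(prev$pheno), n)
  ph <- phenotype_intercrop(prev$aic_A[k], prev$aic_B[k], var_e)
  .pair_stage(prev$id_A[k], prev$id_B[k], prev$aic_A[k], prev$aic_B[k], ph, year)
}

.pair_records <- function(stage, ps, var_e) {
  .record_rows(ps$year, stage, "AB", ps$id_A, ps$pheno, var_e, id_B = ps$id_B)
}

.safe_cor <- function(x, y) {
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

.snapshot_metrics <- function(state, t, acc) {
  aA <- state$crops$A$dh$gv[, "ic"]
  aB <- state$crops$B$dh$gv[, "ic"]
  state$metrics[[length(state$metrics) + 1L]] <- data.frame(
    year = t, program = state$design$name,
    mean_ic = (mean(aA) + mean(aB)) / 2,
    var_ic = .var_pop(c(aA, aB)),
    acc = mean(acc, na.rm = TRUE),
    n_dh = length(aA))
  state
}

# pop the queue entry due this year and produce the new DH cohorts
.new_dh_cohorts <- function(state, t) {
  key <- as.character(t)
  q <- state$cross_queue[[key]]
  if (is.null(q)) stop("pipeline integrity error: no crosses queued for the DH stage of year ", t)
  out <- list()
  for (cr in c("A", "B")) {
    e <- q[[cr]]
    dh <- .dh_cohort(e$block, e$pairs, e$n_per_cross, state$gm[[cr]],
                     year = t, id_start = state$next_id[[cr]],
                     fam_start = e$fam_start)
    state$next_id[[cr]] <- state$next_id[[cr]] + npop(dh)
    dh <- .add_gv(dh, state$arch, state$gm[[cr]])
    dh$pheno <- phenotype_monocrop(dh$gv[, "m"], .rv(state$design, "DH"))
    out[[cr]] <- dh
  }
  state$cross_queue[[key]] <- NULL
  list(state = state, dh = out)
}

# ---- one year of a Conventional program ---------------------------------

.advance_year_conventional <- function(state) {
  t <- state$year + 1L
  d <- state$design
  fits <- list(A = NULL, B = NULL)
  if (d$uses_gs)
    for (cr in c("A", "B")) fits[[cr]] <- .fit_conventional_crop(state, cr, t)
  recs <- list()

  # shared SIA stages (fed by the previous year's cohorts)
  sia2_new <- .advance_pairs(state$sia1, d$n_sia2, .rv(d, "SIA2"), t)
  if (!is.null(sia2_new)) {
    recs <- c(recs, list(.pair_records("SIA2", sia2_new, .rv(d, "SIA2"))))
    best <- which.max(sia2_new$pheno)
    state$released[[length(state$released) + 1L]] <- data.frame(
      year = t, id_A = sia2_new$id_A[best], id_B = sia2_new$id_B[best],
      true_value = (sia2_new$aic_A[best] + sia2_new$aic_B[best]) / 2)
  }
  sia1_new <- NULL
  la <- state$crops$A$sia_lines
  lb <- state$crops$B$sia_lines
  if (!is.null(la) && !is.null(lb)) {
    combos <- expand.grid(iA = seq_len(npop(la)), iB = seq_len(npop(lb)))
    aA <- la$gv[combos$iA, "ic"]
    aB <- lb$gv[combos$iB, "ic"]
    ph <- phenotype_intercrop(aA, aB, .rv(d, "SIA1"))
    sia1_new <- .pair_stage(la$id[combos$iA], lb$id[combos$iB], aA, aB, ph, t)
    recs <- c(recs, list(.pair_records("SIA1", sia1_new, .rv(d, "SIA1"))))
  }

  res <- .new_dh_cohorts(state, t)
  state <- res$state
  crops_new <- list()
  acc <- c(A = NA_real_, B = NA_real_)
  for (cr in c("A", "B")) {
    cs <- state$crops[[cr]]
    gm <- state$gm[[cr]]
    other <- if (cr == "A") "B" else "A"
    probes <- state$crops[[other]]$probes  # candidates meet the other crop's probes
    fit <- fits[[cr]]
    ggia <- function(pop) predict_gGIA(fit, dosages(pop, gm$snp))

    # GIA2 <- previous GIA1
    gia2_new <- NULL
    if (!is.null(cs$gia1)) {
      score <- if (d$sel_gia1 == "ggia") ggia(cs$gia1) else cs$gia1$pheno
      gia2_new <- pop_subset(cs$gia1, .top_idx(score, cs$gia1$id, d$n_gia2))
      pr <- probes$gv[, "ic"]
      serve <- if (length(pr) > 1L) pr[-1L] else pr  # probes 2..n serve GIA2
      gia2_new$pheno <- .gia_phenotype(gia2_new$gv[, "ic"], serve, .rv(d, "GIA2"))
      recs <- c(recs, list(.record_rows(t, "GIA2", cr, gia2_new$id,
                                        gia2_new$pheno, .rv(d, "GIA2"))))
    }
    # GIA1 <- previous PYT
    gia1_new <- NULL
    if (!is.null(cs$pyt)) {
      score <- if (d$sel_pyt == "ggia") ggia(cs$pyt) else cs$pyt$pheno
      gia1_new <- pop_subset(cs$pyt, .top_idx(score, cs$pyt$id, d$n_gia1))
      gia1_new$pheno <- .gia_phenotype(gia1_new$gv[, "ic"],
                                       probes$gv[1L, "ic"], .rv(d, "GIA1"))
      recs <- c(recs, list(.record_rows(t, "GIA1", cr, gia1_new$id,
                                        gia1_new$pheno, .rv(d, "GIA1"))))
    }
    # PYT <- previous DH
    pyt_new <- NULL
    if (!is.null(cs$dh)) {
      idx <- if (d$sel_dh == "ggia")
        .top_idx(ggia(cs$dh), cs$dh$id, d$n_pyt)
      else
        .within_family_idx(cs$dh, cs$dh$pheno, d$n_pyt)
      pyt_new <- pop_subset(cs$dh, idx)
      pyt_new$pheno <- phenotype_monocrop(pyt_new$gv[, "m"], .rv(d, "PYT"))
      recs <- c(recs, list(.record_rows(t, "PYT", cr, pyt_new$id,
                                        pyt_new$pheno, .rv(d, "PYT"))))
      state <- .archive_cohort(state, cr, pyt_new, t)
    }
    dh_new <- res$dh[[cr]]
    # SIA lines and probes for next year, from this year's GIA2 phenotypes
    sia_lines_new <- cs$sia_lines
    probes_new <- cs$probes
    if (!is.null(gia2_new)) {
      sia_lines_new <- pop_subset(
        gia2_new, .top_idx(gia2_new$pheno, gia2_new$id, d$n_sia_lines))
      probes_new <- pop_subset(
        gia2_new, .top_idx(gia2_new$pheno, gia2_new$id, d$n_probes))
    }
    # parent update
    upd <- .update_parents(state, d, cr, cs$block, gia1_new, pyt_new, dh_new,
                           fit, gm, t)
    state <- upd$state
    block_new <- upd$block
    acc[cr] <- if (d$uses_gs && !is.null(fit))
      .safe_cor(ggia(dh_new), dh_new$gv[, "ic"])
    else
      .safe_cor(dh_new$pheno, dh_new$gv[, "ic"])
    crops_new[[cr]] <- list(dh = dh_new, pyt = pyt_new, gia1 = gia1_new,
                            gia2 = gia2_new, sia_lines = sia_lines_new,
                            block = block_new, probes = probes_new)
  }
  state$crops <- crops_new
  state$sia1 <- sia1_new
  state$sia2 <- sia2_new
  state$year <- t
  state$fit <- fits
  if (length(recs)) state$records <- rbind(state$records, do.call(rbind, recs))
  state <- .queue_new_crosses(state, d)
  .snapshot_metrics(state, t, acc)
}

# Parent update. Under the GIA1 rule (Pheno, Baseline-GS) the genotypes
# selected on this year's GIA1 results enter the crossing block only next
# season (during their GIA2 year), which gives those programs their 5-year
# generation interval; the PYT- and DH-based rules use new parents as soon
# as they are selected (intervals 3 and 2).
.update_parents <- function(state, d, cr, block, gia1_new, pyt_new, dh_new,
                            fit, gm, t) {
  pr <- d$parent_rule
  ggia <- function(pop) predict_gGIA(fit, dosages(pop, gm$snp))
  if (pr$stage == "GIA1") {
    incoming <- state$pending_parents[[cr]]
    if (!is.null(gia1_new)) {
      score <- if (pr$criterion == "ggia") ggia(gia1_new) else gia1_new$pheno
      state$pending_parents[[cr]] <-
        pop_subset(gia1_new, .top_idx(score, gia1_new$id, d$n_new_parents))
    }
    if (is.null(incoming)) return(list(state = state, block = block))
    incoming$joined <- rep(t, npop(incoming))
    incoming$pheno <- NULL
    drop <- utils::head(order(block$joined, block$id), npop(incoming))
    block <- pop_bind(pop_subset(block, setdiff(seq_len(npop(block)), drop)),
                      incoming)
    return(list(state = state, block = block))
  }
  block <- if (pr$stage == "PYT_BLOCK") {
    if (is.null(pyt_new)) {
      block
    } else {
      cand <- pop_bind(pyt_new, block)
      cand$joined <- NULL
      cand$pheno <- NULL
      score <- ggia(cand)
      newb <- pop_subset(cand, .top_idx(score, cand$id, d$block_size))
      newb$joined <- rep(t, npop(newb))
      newb
    }
  } else if (pr$stage == "DH") {
    score <- ggia(dh_new)
    newb <- select_max_avoidance(dh_new, score, d$block_size)
    newb$joined <- rep(t, npop(newb))
    newb$pheno <- NULL
    newb
  } else stop("unknown parent rule stage: ", pr$stage)
  list(state = state, block = block)
}

# ---- one year of the Grid program ---------------------------------------

.decode_pairs <- function(idx, nA) {
  cbind(((idx - 1L) %% nA) + 1L, ((idx - 1L) %/% nA) + 1L)
}

#' Grid-stage sampling and advancement
#'
#' Given gGIA predictions for the DH cohorts of both crops: keeps the best
#' `n_keep` per crop, samples `n_field` of the `n_keep^2` candidate pairs
#' uniformly without replacement for field testing, computes pair-level gGIA
#' for every candidate pair and advances the best `n_advance` pairs.
#'
#' @param gGIA_A,gGIA_B gGIA values of the two DH cohorts.
#' @param n_keep DH lines kept per crop.
#' @param n_field Pairs sampled for field testing.
#' @param n_advance Pairs advanced on predicted pair gGIA.
#' @return List with per-crop kept indices (`keep_A`, `keep_B`), field-test
#'   pairs and advanced pairs (2-column matrices of indices into the kept
#'   sets), and the candidate-pair count `n_pairs`.
#' @export
grid_sample_and_select <- function(gGIA_A, gGIA_B, n_keep, n_field, n_advance) {
  keep_A <- .top_idx(gGIA_A, seq_along(gGIA_A), n_keep)
  keep_B <- .top_idx(gGIA_B, seq_along(gGIA_B), n_keep)
  nA <- length(keep_A)
  nB <- length(keep_B)
  n_pairs <- nA * nB
  if (n_field > n_pairs)
    stop("cannot field-test ", n_field, " pairs from a ", nA, " x ", nB, " grid")
  field <- .decode_pairs(sample.int(n_pairs, n_field), nA)
  pg <- outer(gGIA_A[keep_A], gGIA_B[keep_B], "+") / 2
  ord <- order(-as.vector(pg), seq_len(n_pairs))
  adv <- .decode_pairs(ord[seq_len(min(n_advance, n_pairs))], nA)
  list(keep_A = keep_A, keep_B = keep_B, field_pairs = field,
       advance_pairs = adv, n_pairs = n_pairs)
}

.advance_year_grid <- function(state) {
  t <- state$year + 1L
  d <- state$design
  g <- d$grid
  fit <- .fit_grid_model(state, t)
  if (is.null(fit))
    stop("pipeline integrity error: Grid model has no training data at year ", t)
  recs <- list()

  # SIA2 <- previous SIA1; release
  sia2_new <- .advance_pairs(state$sia1, g$n_sia2, .rv(d, "SIA2"), t)
  if (!is.null(sia2_new)) {
    recs <- c(recs, list(.pair_records("SIA2", sia2_new, .rv(d, "SIA2"))))
    best <- which.max(sia2_new$pheno)
    state$released[[length(state$released) + 1L]] <- data.frame(
      year = t, id_A = sia2_new$id_A[best], id_B = sia2_new$id_B[best],
      true_value = (sia2_new$aic_A[best] + sia2_new$aic_B[best]) / 2)
  }
  # SIA1 <- pairs picked from last year's grid cohort by pair gGIA
  sia1_new <- NULL
  if (!is.null(state$sia1_next)) {
    p <- state$sia1_next
    ph <- phenotype_intercrop(p$aic_A, p$aic_B, .rv(d, "SIA1"))
    sia1_new <- .pair_stage(p$id_A, p$id_B, p$aic_A, p$aic_B, ph, t)
    recs <- c(recs, list(.pair_records("SIA1", sia1_new, .rv(d, "SIA1"))))
  }
  # grid field test of this year's grid cohort; advance pairs for next SIA1
  sia1_next_new <- NULL
  if (!is.null(state$grid_cohort)) {
    ka <- state$grid_cohort$A
    kb <- state$grid_cohort$B
    nA <- npop(ka)
    n_pairs <- nA * npop(kb)
    field <- .decode_pairs(sample.int(n_pairs, min(g$n_field, n_pairs)), nA)
    aA <- ka$gv[field[, 1L], "ic"]
    aB <- kb$gv[field[, 2L], "ic"]
    ph <- phenotype_intercrop(aA, aB, .rv(d, "GRID"))
    recs <- c(recs, list(.record_rows(t, "GRID", "AB", ka$id[field[, 1L]],
                                      ph, .rv(d, "GRID"),
                                      id_B = kb$id[field[, 2L]])))
    ggA <- predict_gGIA(fit, dosages(ka, state$gm$A$snp), crop = "A")
    ggB <- predict_gGIA(fit, dosages(kb, state$gm$B$snp), crop = "B")
    pg <- outer(ggA, ggB, "+") / 2
    ord <- order(-as.vector(pg), seq_len(n_pairs))
    adv <- .decode_pairs(ord[seq_len(min(g$n_advance, n_pairs))], nA)
    sia1_next_new <- .pair_stage(ka$id[adv[, 1L]], kb$id[adv[, 2L]],
                                 ka$gv[adv[, 1L], "ic"], kb$gv[adv[, 2L], "ic"],
                                 NULL, t + 1L)
  }
  # new DH cohort; gGIA; keep top n_keep per crop as next year's grid cohort
  res <- .new_dh_cohorts(state, t)
  state <- res$state
  acc <- c(A = NA_real_, B = NA_real_)
  grid_next <- list()
  crops_new <- state$crops
  for (cr in c("A", "B")) {
    dh_new <- res$dh[[cr]]
    gg <- predict_gGIA(fit, dosages(dh_new, state$gm[[cr]]$snp), crop = cr)
    acc[cr] <- .safe_cor(gg, dh_new$gv[, "ic"])
    keep <- pop_subset(dh_new, .top_idx(gg, dh_new$id, g$n_keep))
    grid_next[[cr]] <- keep
    state <- .archive_cohort(state, cr, keep, t + 1L)  # grid-stage year label
    block_new <- select_max_avoidance(dh_new, gg, d$block_size)
    block_new$joined <- rep(t, npop(block_new))
    crops_new[[cr]] <- list(dh = dh_new, pyt = NULL, gia1 = NULL, gia2 = NULL,
                            sia_lines = NULL, block = block_new,
                            probes = state$crops[[cr]]$probes)
  }
  state$crops <- crops_new
  state$grid_cohort <- grid_next
  state$sia1 <- sia1_new
  state$sia2 <- sia2_new
  state$sia1_next <- sia1_next_new
  state$year <- t
  state$fit <- fit
  if (length(recs)) state$records <- rbind(state$records, do.call(rbind, recs))
  state <- .queue_new_crosses(state, d)
  .snapshot_metrics(state, t, acc)
}

#' Advance a pipeline by one calendar year
#'
#' Executes one year of the state's current program design: crossing and DH
#' production, phenotyping of every active stage at its replication and
#' heritability, stage advancement under the design's selection criteria,
#' probe and parent updates, training-window bookkeeping, and release of the
#' best SIA2 combination.
#'
#' @param state A `pipeline_state`.
#' @return The advanced state.
#' @export
advance_year <- function(state) {
  if (state$design$type == "grid") .advance_year_grid(state)
  else .advance_year_conventional(state)
}

# ---- burn-in and branching ----------------------------------------------

#' Run the phenotypic-selection burn-in
#'
#' Simulates `n_years` (20 by default) of the phenotypic-selection program
#' to provide the common starting point for all compared program arms: the
#' same seed gives a bit-identical end-of-burn-in state for every arm.
#'
#' @param founders_A,founders_B `founder_set` objects.
#' @param arch A `trait_arch`.
#' @param design The burn-in design (a Pheno [program_design()]).
#' @param n_years Burn-in length in years.
#' @param seed Optional seed for the burn-in stream.
#' @return End-of-burn-in `pipeline_state`.
#' @export
run_burnin <- function(founders_A, founders_B, arch, design, n_years = 20L,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- init_program_state(founders_A, founders_B, arch, design)
  for (i in seq_len(n_years)) state <- advance_year(state)
  state$burnin_end <- state$year
  m <- do.call(rbind, state$metrics)
  state$center_ic <- m$mean_ic[m$year == state$burnin_end]
  state
}

# retrospective Grid-GS training-population initialization: in each of the
# last `window` burn-in years, n_init genotypes per crop are taken from the
# archived PYT cohort (year 1 by monocrop PYT phenotype, later years by gGIA
# from the accumulating grid model) and all n_init^2 intercrop combinations
# are field-tested at grid-stage precision
.grid_initialize <- function(state, design) {
  g <- design$grid
  w <- (state$burnin_end - design$window + 1L):state$burnin_end
  pyt_tp <- state$tp_years  # burn-in PYT index, before replacement
  state$tp_years <- list(A = list(), B = list())
  state$design <- design
  for (y in w) {
    sel <- list()
    fit <- if (y > w[1L]) .fit_grid_model(state, y) else NULL
    for (cr in c("A", "B")) {
      ids <- pyt_tp[[cr]][[as.character(y)]]
      rows <- .store_rows(state, cr, ids)
      st <- state$store[[cr]]
      score <- if (is.null(fit)) st$pheno[rows]
      else predict_gGIA(fit, st$snp[rows, , drop = FALSE], crop = cr)
      k <- .top_idx(score, ids, g$n_init)
      sel[[cr]] <- list(ids = ids[k], aic = st$gv[rows[k], "ic"],
                        snp_rows = rows[k])
      state$tp_years[[cr]][[as.character(y)]] <- ids[k]
    }
    combos <- expand.grid(iA = seq_along(sel$A$ids), iB = seq_along(sel$B$ids))
    aA <- sel$A$aic[combos$iA]
    aB <- sel$B$aic[combos$iB]
    ph <- phenotype_intercrop(aA, aB, .rv(design, "GRID"))
    state$records <- rbind(state$records, .record_rows(
      y, "GRID", "AB", sel$A$ids[combos$iA], ph, .rv(design, "GRID"),
      id_B = sel$B$ids[combos$iB]))
  }
  # seed the running pipeline from the final initialization year
  fit <- .fit_grid_model(state, state$burnin_end + 1L)
  grid_next <- list()
  for (cr in c("A", "B")) {
    dh <- state$crops[[cr]]$dh
    gg <- predict_gGIA(fit, dosages(dh, state$gm[[cr]]$snp), crop = cr)
    keep <- pop_subset(dh, .top_idx(gg, dh$id, g$n_keep))
    grid_next[[cr]] <- keep
    state <- .archive_cohort(state, cr, keep, state$burnin_end + 1L)
    block_new <- select_max_avoidance(dh, gg, design$block_size)
    block_new$joined <- rep(state$burnin_end, npop(block_new))
    state$crops[[cr]]$block <- block_new
  }
  state$grid_cohort <- grid_next
  # first SIA1 cohort: best predicted pairs of the last initialization grid
  last <- lapply(c(A = "A", B = "B"), function(cr) {
    ids <- state$tp_years[[cr]][[as.character(state$burnin_end)]]
    rows <- .store_rows(state, cr, ids)
    list(ids = ids, aic = state$store[[cr]]$gv[rows, "ic"],
         gg = predict_gGIA(fit, state$store[[cr]]$snp[rows, , drop = FALSE],
                           crop = cr))
  })
  nA <- length(last$A$ids)
  pg <- outer(last$A$gg, last$B$gg, "+") / 2
  ord <- order(-as.vector(pg), seq_len(length(pg)))
  adv <- .decode_pairs(ord[seq_len(min(g$n_advance, length(pg)))], nA)
  state$sia1_next <- .pair_stage(
    last$A$ids[adv[, 1L]], last$B$ids[adv[, 2L]],
    last$A$aic[adv[, 1L]], last$B$aic[adv[, 2L]], NULL,
    state$burnin_end + 1L)
  state$sia1 <- NULL
  state$sia2 <- NULL
  state
}

#' Branch a program arm from the shared burn-in state
#'
#' Replaces the design, re-queues the pending crosses from the inherited
#' crossing blocks under the new design's crossing scheme and DH numbers,
#' and, for the Grid design, performs the retrospective training-population
#' initialization over the last burn-in years. Each arm should be branched
#' on its own RNG stream (pass `seed`) so that replicates stay paired
#' through the common burn-in.
#'
#' @param state End-of-burn-in `pipeline_state` from [run_burnin()].
#' @param design The arm's [program_design()].
#' @param seed Optional seed for the arm's stream.
#' @return A `pipeline_state` ready for future-phase [advance_year()] calls.
#' @export
branch_program <- function(state, design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (design$type == "grid") {
    state <- .grid_initialize(state, design)
  } else {
    state$design <- design
  }
  # re-queue the two pending cohorts under the new design
  for (due in state$year + 1:2) {
    per_crop <- list()
    for (cr in c("A", "B")) {
      res <- .cross_entry(state, cr, design)
      state <- res$state
      per_crop[[cr]] <- res$entry
    }
    state <- .enqueue_crosses(state, due, per_crop)
  }
  if (design$crossing == "max_avoidance") state$ma_gen <- state$ma_gen + 1L
  state
}

#' Run one program arm from a burn-in snapshot
#'
#' @param burnin_state State from [run_burnin()].
#' @param design The arm's design.
#' @param n_years Future-phase years to simulate.
#' @param seed Seed for the arm's stream.
#' @return Final `pipeline_state`.
#' @export
run_program <- function(burnin_state, design, n_years = 20L, seed = NULL) {
  state <- branch_program(burnin_state, design, seed)
  for (i in seq_len(n_years)) state <- advance_year(state)
  state
}

#' Per-year metrics of a pipeline state
#'
#' @param state A `pipeline_state`.
#' @return Data frame with year, program, mean intercrop genetic value of
#'   the DH stage (raw and centered at the burn-in end), intercrop genetic
#'   variance and prediction accuracy.
#' @export
state_metrics <- function(state) {
  m <- do.call(rbind, state$metrics)
  m$gain <- m$mean_ic - state$center_ic
  m
}
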