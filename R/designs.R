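# Declarative description of the five breeding program designs and their
# full-scale and desk-scale parameterizations.

#' Construct a breeding program design
#'
#' A `program_design` declares one breeding scheme: crossing-block size and
#' crossing scheme, crosses per year and DH lines per cross, per-stage entry
#' numbers, effective replications and target heritabilities, the selection
#' criterion used at each advancement step, the parent-selection rule, and
#' which samples are genotyped. Two families exist: `"conventional"`
#' (DH - PYT - GIA1 - GIA2 - SIA1 - SIA2 pipeline; Pheno, Baseline-GS,
#' PYT-GS and DH-GS) and `"grid"` (DH - Grid - SIA1 - SIA2; Grid-GS).
#'
#' @param name Program name.
#' @param type `"conventional"` or `"grid"`.
#' @param n_crosses Bi-parental crosses per year per crop.
#' @param dh_per_cross DH lines produced per cross.
#' @param block_size Crossing-block size per crop.
#' @param n_new_parents Parents replaced per year (oldest-replacement rule).
#' @param n_pyt,n_gia1,n_gia2 Stage entries per crop (conventional).
#' @param n_sia_lines Lines per crop advanced to the SIA phase; SIA1 tests
#'   all `n_sia_lines^2` pairwise combinations.
#' @param n_sia2 Combinations advanced to SIA2.
#' @param reps,h2 Named vectors of effective replications and target
#'   heritabilities per stage.
#' @param n_probes Probe varieties per crop (1 serves GIA1, the rest GIA2).
#' @param sel_dh `"family_pheno"` (best single plants within each cross) or
#'   `"ggia"`.
#' @param sel_pyt,sel_gia1 `"pheno"` or `"ggia"` for the PYT- and GIA1-stage
#'   advancement decisions.
#' @param parent_rule List with `stage` (`"GIA1"`, `"PYT_BLOCK"` or `"DH"`),
#'   `criterion` (`"pheno"` or `"ggia"`) and `replace` (`"oldest"` or
#'   `"all"`).
#' @param crossing `"random"` or `"max_avoidance"`.
#' @param genotyping `"none"`, `"pyt"` or `"all_dh"`.
#' @param grid For grid designs, a list with `n_keep` (DH kept per crop),
#'   `n_field` (pairs field-tested per year), `n_advance` (pairs advanced to
#'   SIA1), `n_sia2`, and `n_init` (genotypes per crop in each
#'   training-initialization year of the burn-in).
#' @param window Training-window length in years.
#' @return An object of class `program_design`.
#' @export
program_design <- function(name,
                           type = c("conventional", "grid"),
                           n_crosses, dh_per_cross,
                           block_size, n_new_parents = 0L,
                           n_pyt = 0L, n_gia1 = 0L, n_gia2 = 0L,
                           n_sia_lines = 3L, n_sia2 = 3L,
                           reps = c(DH = 1, PYT = 4, GIA1 = 4, GIA2 = 24,
                                    SIA1 = 16, SIA2 = 32, GRID = 1),
                           h2 = c(DH = 0.10, PYT = 0.33, GIA1 = 0.33,
                                  GIA2 = 0.50, SIA1 = 0.67, SIA2 = 0.80,
                                  GRID = 0.10),
                           n_probes = 4L,
                           sel_dh = "family_pheno",
                           sel_pyt = "pheno",
                           sel_gia1 = "pheno",
                           parent_rule = list(stage = "GIA1",
                                              criterion = "pheno",
                                              replace = "oldest"),
                           crossing = "random",
                           genotyping = "none",
                           grid = NULL,
                           window = 5L) {
  type <- match.arg(type)
  stopifnot(n_crosses >= 1, dh_per_cross >= 1, block_size >= 2,
            genotyping %in% c("none", "pyt", "all_dh"),
            crossing %in% c("random", "max_avoidance"))
  if (type == "grid" && is.null(grid))
    stop("grid designs require the `grid` parameter list")
  structure(list(
    name = name, type = type,
    n_crosses = as.integer(n_crosses), dh_per_cross = as.integer(dh_per_cross),
    block_size = as.integer(block_size), n_new_parents = as.integer(n_new_parents),
    n_pyt = as.integer(n_pyt), n_gia1 = as.integer(n_gia1),
    n_gia2 = as.integer(n_gia2), n_sia_lines = as.integer(n_sia_lines),
    n_sia2 = as.integer(n_sia2),
    reps = reps, h2 = h2, n_probes = as.integer(n_probes),
    sel_dh = sel_dh, sel_pyt = sel_pyt, sel_gia1 = sel_gia1,
    parent_rule = parent_rule, crossing = crossing, genotyping = genotyping,
    grid = grid, window = as.integer(window),
    uses_gs = genotyping != "none"
  ), class = "program_design")
}

#' @export
print.program_design <- function(x, ...) {
  cat(sprintf("<program_design> %s (%s): %d crosses x %d DH, block %d, genotyping %s\n",
              x$name, x$type, x$n_crosses, x$dh_per_cross, x$block_size,
              x$genotyping))
  invisible(x)
}

#' The five medium-budget program designs at full scale
#'
#' Stage sizes, replications, heritabilities and DH numbers of the five
#' compared designs at the ~$500K annual budget: a phenotypic-selection
#' program (Pheno), three Conventional genomic-selection programs
#' (Baseline-GS, PYT-GS, DH-GS) and the Grid genomic-selection program
#' (Grid-GS). The DH-per-cross numbers equalize annual operating cost across
#' designs (see [budget_scale()]).
#'
#' @return Named list of `program_design` objects.
#' @export
full_designs <- function() {
  list(
    "Pheno" = program_design(
      "Pheno", "conventional", n_crosses = 100, dh_per_cross = 50,
      block_size = 80, n_new_parents = 20,
      n_pyt = 500, n_gia1 = 50, n_gia2 = 13, n_sia_lines = 3, n_sia2 = 3),
    "Baseline-GS" = program_design(
      "Baseline-GS", "conventional", n_crosses = 100, dh_per_cross = 47,
      block_size = 80, n_new_parents = 20,
      n_pyt = 500, n_gia1 = 50, n_gia2 = 13, n_sia_lines = 3, n_sia2 = 3,
      sel_pyt = "ggia", sel_gia1 = "ggia",
      parent_rule = list(stage = "GIA1", criterion = "ggia", replace = "oldest"),
      genotyping = "pyt"),
    "PYT-GS" = program_design(
      "PYT-GS", "conventional", n_crosses = 100, dh_per_cross = 47,
      block_size = 80, n_new_parents = 80,
      n_pyt = 500, n_gia1 = 50, n_gia2 = 13, n_sia_lines = 3, n_sia2 = 3,
      sel_pyt = "ggia", sel_gia1 = "ggia",
      parent_rule = list(stage = "PYT_BLOCK", criterion = "ggia", replace = "all"),
      genotyping = "pyt"),
    "DH-GS" = program_design(
      "DH-GS", "conventional", n_crosses = 40, dh_per_cross = 80,
      block_size = 80, n_new_parents = 80,
      n_pyt = 500, n_gia1 = 50, n_gia2 = 13, n_sia_lines = 3, n_sia2 = 3,
      sel_dh = "ggia", sel_pyt = "ggia", sel_gia1 = "ggia",
      parent_rule = list(stage = "DH", criterion = "ggia", replace = "all"),
      crossing = "max_avoidance", genotyping = "all_dh"),
    "Grid-GS" = program_design(
      "Grid-GS", "grid", n_crosses = 40, dh_per_cross = 90,
      block_size = 80, n_new_parents = 80,
      parent_rule = list(stage = "DH", criterion = "ggia", replace = "all"),
      crossing = "max_avoidance", genotyping = "all_dh",
      grid = list(n_keep = 500, n_field = 900, n_advance = 50,
                  n_sia2 = 8, n_init = 23))
  )
}

#' The five designs at desk scale
#'
#' A one-tenth scaling of the full designs used for replicated comparisons:
#' Pheno runs 20 crosses x 25 DH with PYT 50, GIA1 10, GIA2 5, SIA lines 3
#' and a 20-parent crossing block; the genomic-selection arms are re-scaled
#' with [budget_scale()] so that every arm matches the desk Pheno annual
#' cost, exactly as the full designs are matched at the full budget. Stage
#' replications and heritabilities are unchanged.
#'
#' @param costs Unit costs used for the budget matching.
#' @return Named list of `program_design` objects.
#' @export
desk_designs <- function(costs = unit_costs()) {
  pheno <- program_design(
    "Pheno", "conventional", n_crosses = 20, dh_per_cross = 25,
    block_size = 20, n_new_parents = 5,
    n_pyt = 50, n_gia1 = 10, n_gia2 = 5, n_sia_lines = 3, n_sia2 = 3)
  target <- annual_cost(pheno, costs)$total
  d <- list(
    "Pheno" = pheno,
    "Baseline-GS" = program_design(
      "Baseline-GS", "conventional", n_crosses = 20, dh_per_cross = 25,
      block_size = 20, n_new_parents = 5,
      n_pyt = 50, n_gia1 = 10, n_gia2 = 5, n_sia_lines = 3, n_sia2 = 3,
      sel_pyt = "ggia", sel_gia1 = "ggia",
      parent_rule = list(stage = "GIA1", criterion = "ggia", replace = "oldest"),
      genotyping = "pyt"),
    "PYT-GS" = program_design(
      "PYT-GS", "conventional", n_crosses = 20, dh_per_cross = 25,
      block_size = 20, n_new_parents = 20,
      n_pyt = 50, n_gia1 = 10, n_gia2 = 5, n_sia_lines = 3, n_sia2 = 3,
      sel_pyt = "ggia", sel_gia1 = "ggia",
      parent_rule = list(stage = "PYT_BLOCK", criterion = "ggia", replace = "all"),
      genotyping = "pyt"),
    "DH-GS" = program_design(
      "DH-GS", "conventional", n_crosses = 20, dh_per_cross = 25,
      block_size = 40, n_new_parents = 40,
      n_pyt = 50, n_gia1 = 10, n_gia2 = 5, n_sia_lines = 3, n_sia2 = 3,
      sel_dh = "ggia", sel_pyt = "ggia", sel_gia1 = "ggia",
      parent_rule = list(stage = "DH", criterion = "ggia", replace = "all"),
      crossing = "max_avoidance", genotyping = "all_dh"),
    "Grid-GS" = program_design(
      "Grid-GS", "grid", n_crosses = 20, dh_per_cross = 25,
      block_size = 40, n_new_parents = 40,
      parent_rule = list(stage = "DH", criterion = "ggia", replace = "all"),
      crossing = "max_avoidance", genotyping = "all_dh",
      grid = list(n_keep = 50, n_field = 90, n_advance = 5,
                  n_sia2 = 2, n_init = 8))
  )
  for (nm in setdiff(names(d), "Pheno"))
    d[[nm]] <- budget_scale(d[[nm]], target, costs)
  d
}

# per-stage table used by the cost engine: entries, reps and the accounting
# scope of each stage (monocrop plots per crop, intercrop plots per crop,
# shared intercrop plots, or unpriced single plants)
.design_stage_table <- function(design) {
  if (design$type == "conventional") {
    data.frame(
      stage = c("DH", "PYT", "GIA1", "GIA2", "SIA1", "SIA2"),
      n = c(design$n_crosses * design$dh_per_cross, design$n_pyt,
            design$n_gia1, design$n_gia2,
            design$n_sia_lines^2, design$n_sia2),
      reps = unname(design$reps[c("DH", "PYT", "GIA1", "GIA2", "SIA1", "SIA2")]),
      scope = c("unpriced", "mono_per_crop", "ic_per_crop", "ic_per_crop",
                "ic_shared", "ic_shared"))
  } else {
    g <- design$grid
    data.frame(
      stage = c("DH", "GRID", "SIA1", "SIA2"),
      n = c(design$n_crosses * design$dh_per_cross, g$n_field,
            g$n_advance, g$n_sia2),
      reps = unname(design$reps[c("DH", "GRID", "SIA1", "SIA2")]),
      scope = c("unpriced", "ic_shared", "ic_shared", "ic_shared"))
  }
}
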