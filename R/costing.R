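# Annual operating cost of a program design and budget matching across
# designs.
#
# Accounting rule (the unique natural assignment that reproduces all five
# printed program totals): DH production and PYT plots are paid once per
# component crop; GIA plots are paid per crop because each crop's candidates
# are evaluated against the other crop's probes; SIA and Grid combinations
# are a single shared trial; DH-stage single plants are unpriced; genotyping
# covers 2 x 500 PYT entries (Baseline-GS, PYT-GS), 2 x all DH lines
# (DH-GS, Grid-GS) or nothing (Pheno).

#' Unit costs
#'
#' @param monocrop_plot Cost of one monocrop test plot (US$).
#' @param intercrop_plot Cost of one intercrop test plot (US$).
#' @param dh_line Cost of producing one doubled-haploid line (US$).
#' @param genotyping Cost of array-genotyping one sample (US$).
#' @return An object of class `unit_costs`.
#' @export
unit_costs <- function(monocrop_plot = 20, intercrop_plot = 50,
                       dh_line = 35, genotyping = 20) {
  v <- c(monocrop_plot = monocrop_plot, intercrop_plot = intercrop_plot,
         dh_line = dh_line, genotyping = genotyping)
  if (any(v < 0)) stop("unit costs must be non-negative")
  structure(as.list(v), class = "unit_costs")
}

# samples genotyped per year under a design's genotyping policy
.genotyped_samples <- function(design) {
  switch(design$genotyping,
         none = 0L,
         pyt = 2L * design$n_pyt,
         all_dh = 2L * design$n_crosses * design$dh_per_cross)
}

#' Annual operating cost of a program design
#'
#' @param design A [program_design()].
#' @param costs A [unit_costs()] object.
#' @return A list of class `cost_breakdown` with per-category dollars
#'   (`dh_production`, `monocrop_plots`, `intercrop_plots`, `genotyping`)
#'   and their `total`.
#' @examples
#' annual_cost(full_designs()$Pheno)$total  # 493200
#' @export
annual_cost <- function(design, costs = unit_costs()) {
  st <- .design_stage_table(design)
  plots <- st$n * st$reps
  dh_total <- design$n_crosses * design$dh_per_cross
  out <- list(
    dh_production = 2 * costs$dh_line * dh_total,
    monocrop_plots = 2 * costs$monocrop_plot * sum(plots[st$scope == "mono_per_crop"]),
    intercrop_plots =
      2 * costs$intercrop_plot * sum(plots[st$scope == "ic_per_crop"]) +
      1 * costs$intercrop_plot * sum(plots[st$scope == "ic_shared"]),
    genotyping = costs$genotyping * .genotyped_samples(design)
  )
  out$total <- out$dh_production + out$monocrop_plots +
    out$intercrop_plots + out$genotyping
  structure(out, class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  for (k in c("dh_production", "monocrop_plots", "intercrop_plots",
              "genotyping", "total"))
    cat(sprintf("%-16s %10s\n", k, format(x[[k]], big.mark = ",")))
  invisible(x)
}

#' Match a design's annual cost to a target budget
#'
#' Re-sizes the number of DH lines per bi-parental cross (the designs' own
#' budget lever) so the design's annual cost meets the target, holding all
#' downstream stage sizes fixed. For designs that genotype every DH line the
#' per-line marginal cost includes genotyping. The DH-per-cross count is
#' rounded to the nearest integer, so the re-priced total lands within one
#' cross's worth of DH cost of the target.
#'
#' @param design A [program_design()].
#' @param target Target annual budget (US$).
#' @param costs A [unit_costs()] object.
#' @return The design with `dh_per_cross` adjusted.
#' @examples
#' d <- budget_scale(full_designs()$`Baseline-GS`,
#'                   annual_cost(full_designs()$Pheno)$total)
#' d$dh_per_cross  # 47
#' @export
budget_scale <- function(design, target, costs = unit_costs()) {
  if (target <= 0) stop("target budget must be positive")
  d0 <- design
  d0$dh_per_cross <- 0L
  fixed <- annual_cost(d0, costs)$total
  marginal <- 2 * costs$dh_line +
    if (design$genotyping == "all_dh") 2 * costs$genotyping else 0
  if (marginal <= 0) return(design)
  dh_per_crop <- (target - fixed) / marginal
  per_cross <- as.integer(round(dh_per_crop / design$n_crosses))
  if (per_cross < 1)
    stop("infeasible budget: fixed downstream costs (", fixed,
         ") leave no room for DH production under target ", target)
  design$dh_per_cross <- per_cross
  design
}

#' Cost breakdowns for a set of designs
#'
#' @param designs Named list of designs (default: the full-scale five).
#' @param costs A [unit_costs()].
#' @return Data frame with one row per design and one column per category.
#' @export
cost_table <- function(designs = full_designs(), costs = unit_costs()) {
  rows <- lapply(names(designs), function(nm) {
    b <- annual_cost(designs[[nm]], costs)
    data.frame(design = nm, dh_production = b$dh_production,
               monocrop_plots = b$monocrop_plots,
               intercrop_plots = b$intercrop_plots,
               genotyping = b$genotyping, total = b$total)
  })
  do.call(rbind, rows)
}
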