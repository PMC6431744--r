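# -- flux balance analysis and the growth-coupling potential ------------------

#' Maximize growth by flux balance analysis
#'
#' Solves the FBA linear program.  An infeasible model (a cell that cannot
#' satisfy steady state, e.g. a forced maintenance flux knocked out) is
#' reported as zero growth with `infeasible = TRUE` rather than an error, so
#' that lethal designs remain evaluable.  An unbounded program indicates a
#' missing bound and errors.
#'
#' @param x A `linear_program` from [build_fba_lp()] or a
#'   `metabolic_network`.
#' @return A `flux_state`: `flux` (named vector, mmol/gDW/h),
#'   `objective_value` (growth rate, 1/h), `infeasible` flag.
#' @export
fba_max_growth <- function(x) {
  lp <- if (inherits(x, "metabolic_network")) build_fba_lp(x) else x
  stopifnot(inherits(lp, "linear_program"))
  res <- solve_lp(lp)
  if (res$status == "unbounded")
    stop("FBA problem is unbounded; a reaction bound is missing")
  if (res$status %in% c("infeasible", "error") || is.null(res$x)) {
    return(structure(list(flux = stats::setNames(rep(NA_real_, n_vars(lp)),
                                                 lp$vars$id),
                          objective_value = 0,
                          infeasible = TRUE),
                     class = "flux_state"))
  }
  structure(list(flux = res$x, objective_value = res$objective,
                 infeasible = FALSE),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("<flux_state> objective = ", signif(x$objective_value, 6),
      if (x$infeasible) " (infeasible)" else "", "\n", sep = "")
  invisible(x)
}

# Build the pair of LPs behind the coupling potential of one design:
# the perturbed model with the target open (M) and with it blocked (M*).
coupling_lp_pair <- function(network, target, design, pool, config) {
  if (!target %in% names(network$reactions))
    stop("unknown target reaction: ", target)
  net <- apply_design(network, design, pool = pool, config = config)
  lp_open <- build_fba_lp(net)
  net_closed <- set_bounds(net, target, 0, 0)
  list(open = lp_open, closed = build_fba_lp(net_closed))
}

#' Growth-coupling potential of a design
#'
#' The increase in maximal growth rate gained by allowing flux through the
#' target production reaction: `U = f(M) - f(M*)`, where `M` carries the
#' design's knockouts, insertions and supplements and `M*` is the same model
#' with the target reaction blocked.  Since `M*` is a restriction of `M`,
#' `U >= 0`; tiny negative solver noise is clamped to zero.  Production is
#' (weakly) growth-coupled if and only if `U` exceeds the coupling epsilon.
#'
#' @param network A `metabolic_network` containing the target reaction.
#' @param target Target reaction id.
#' @param design A [design()] (default: no modifications).
#' @param pool Named list of heterologous [reaction()]s resolving the
#'   design's insertions.
#' @param config A [run_config()].
#' @return Numeric `U` (1/h) with attributes `f_M`, `f_Mstar` and
#'   `infeasible` (TRUE when even the target-open model cannot grow).
#' @export
coupling_potential <- function(network, target, design = optcoupleR::design(),
                               pool = NULL, config = run_config()) {
  lps <- coupling_lp_pair(network, target, design, pool, config)
  res <- solve_lp_batch(list(lps$open, lps$closed))
  f_M <- if (res[[1]]$status == "optimal") res[[1]]$objective else 0
  f_Ms <- if (res[[2]]$status == "optimal") res[[2]]$objective else 0
  U <- f_M - f_Ms
  if (U < -1e-5)
    warning("negative coupling potential (", signif(U, 4),
            "): numerically inconsistent solves")
  structure(max(U, 0), f_M = f_M, f_Mstar = f_Ms,
            infeasible = res[[1]]$status != "optimal")
}

# Vectorized variant: evaluate U for many designs in one backend call.
# Returns a data.frame with columns U, f_M, f_Mstar.
coupling_potential_batch <- function(network, target, designs, pool = NULL,
                                     config = run_config()) {
  lps <- vector("list", 2L * length(designs))
  for (k in seq_along(designs)) {
    pair <- coupling_lp_pair(network, target, designs[[k]], pool, config)
    lps[[2L * k - 1L]] <- pair$open
    lps[[2L * k]] <- pair$closed
  }
  res <- solve_lp_batch(lps)
  f <- function(r) if (r$status == "optimal") r$objective else 0
  f_M <- vapply(res[seq_along(designs) * 2L - 1L], f, 0)
  f_Ms <- vapply(res[seq_along(designs) * 2L], f, 0)
  data.frame(U = pmax(f_M - f_Ms, 0), f_M = f_M, f_Mstar = f_Ms)
}
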