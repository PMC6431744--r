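# -- from raw solver pools to a curated design report -------------------------

design_without <- function(d, role, id) {
  d[[role]] <- setdiff(d[[role]], id)
  d
}

# deterministic removal order: knockouts, then insertions, then supplements,
# each sorted (the sets are stored sorted)
modification_list <- function(d) {
  rbind(if (length(d$knockouts))
    data.frame(role = "knockouts", id = d$knockouts),
    if (length(d$insertions))
      data.frame(role = "insertions", id = d$insertions),
    if (length(d$supplements))
      data.frame(role = "supplements", id = d$supplements))
}

#' Reduce a design to a minimal growth-coupled set
#'
#' Removes modifications one at a time: if dropping a modification keeps the
#' design growth-coupled (`U > coupling_epsilon`), it is discarded.  Passes
#' repeat until a fixpoint, so the returned design is minimal: no single
#' removal preserves coupling.  A design that is not growth-coupled on entry
#' is returned unchanged with `minimal = FALSE`.
#'
#' @param network A `metabolic_network` with the target present.
#' @param target Target reaction id.
#' @param design A `strain_design`.
#' @param pool Heterologous pool resolving insertions.
#' @param config A [run_config()].
#' @return The reduced design (`minimal = TRUE`, `U` filled).
#' @export
reduce_design <- function(network, target, design, pool = NULL,
                          config = run_config()) {
  eps <- config$coupling_epsilon
  U0 <- as.numeric(coupling_potential(network, target, design, pool, config))
  if (U0 <= eps) {
    design$U <- U0
    design$minimal <- FALSE
    return(design)
  }
  repeat {
    mods <- modification_list(design)
    if (is.null(mods) || nrow(mods) == 0L) break
    cands <- lapply(seq_len(nrow(mods)), function(k)
      design_without(design, mods$role[k], mods$id[k]))
    ev <- coupling_potential_batch(network, target, cands, pool, config)
    drop <- which(ev$U > eps)
    if (!length(drop)) break
    design <- cands[[drop[1]]] # first in deterministic order, then re-pass
    U0 <- ev$U[drop[1]]
  }
  design$U <- U0
  design$minimal <- TRUE
  design
}

#' Merge designs with identical modification sets
#'
#' Deduplicates on set equality of (knockouts, insertions, supplements) and
#' sorts survivors by coupling potential (descending), then minimum
#' production at optimum (descending), then lexicographically.
#'
#' @param designs List of `strain_design`s (normally already reduced).
#' @return Deduplicated, sorted list.
#' @export
merge_designs <- function(designs) {
  if (!length(designs)) return(list())
  keys <- vapply(designs, design_key, "")
  designs <- designs[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  us <- vapply(designs, function(d) ifelse(is.na(d$U), -Inf, d$U), 0)
  prod <- vapply(designs, function(d)
    ifelse(is.na(d$production_at_optimum_min), -Inf,
           d$production_at_optimum_min), 0)
  designs[order(-us, -prod, keys)]
}

#' Verify a design by direct simulation
#'
#' Recomputes the coupling potential with two FBA solves, then fixes growth
#' to its optimum (relative band `mu >= (1 - 1e-6) mu_max`, avoiding LP
#' degeneracy at the vertex) and minimizes/maximizes the target flux.  Checks
#' the weak-coupling equivalence: `U > epsilon` if and only if the minimum
#' production at optimal growth is positive.  The yield denominator is the
#' realized carbon-source uptake at the evaluated optimum (requires
#' `config$carbon_exchange`; otherwise `NA`).
#'
#' @inheritParams reduce_design
#' @return The design with `U`, `growth_at_optimum`,
#'   `production_at_optimum_min`/`_max`, `yield_at_optimum` and `verified`
#'   filled.
#' @export
verify_design <- function(network, target, design, pool = NULL,
                          config = run_config()) {
  eps <- config$coupling_epsilon
  U <- coupling_potential(network, target, design, pool, config)
  design$U <- as.numeric(U)
  mu <- attr(U, "f_M")
  design$growth_at_optimum <- mu
  net <- apply_design(network, design, pool = pool, config = config)
  lp <- build_fba_lp(net)
  bi <- match(net$biomass_id, lp$vars$id)
  lp$vars$lb[bi] <- mu * (1 - 1e-6) - 1e-9
  lp_min <- lp; lp_min$objective <- list(coef = stats::setNames(1, target),
                                         sense = "min")
  lp_max <- lp; lp_max$objective <- list(coef = stats::setNames(1, target),
                                         sense = "max")
  res <- solve_lp_batch(list(lp_min, lp_max))
  pmin_ <- if (res[[1]]$status == "optimal") res[[1]]$objective else NA_real_
  pmax_ <- if (res[[2]]$status == "optimal") res[[2]]$objective else NA_real_
  design$production_at_optimum_min <- pmin_
  design$production_at_optimum_max <- pmax_
  if (!is.null(config$carbon_exchange) && !is.na(pmin_) &&
        config$carbon_exchange %in% names(res[[1]]$x)) {
    uptake <- -res[[1]]$x[[config$carbon_exchange]]
    design$yield_at_optimum <- if (uptake > 1e-9) pmin_ / uptake else NA_real_
  }
  coupled_by_U <- design$U > eps
  coupled_by_flux <- !is.na(pmin_) && pmin_ > eps
  if (!identical(coupled_by_U, coupled_by_flux))
    warning("weak-coupling equivalence violated for design ",
            design_key(design), ": U = ", signif(design$U, 6),
            ", min production at optimum = ", signif(pmin_, 6))
  design$verified <- identical(coupled_by_U, coupled_by_flux)
  design
}

#' Production envelope of a design
#'
#' Minimum and maximum target flux as a function of growth rate, on an
#' ascending grid of `n_points` values spanning 0 to the maximal growth rate
#' (two LPs per grid point, batched into one solver call).  Numerically
#' infeasible grid points are recorded as `NA`.
#'
#' @inheritParams reduce_design
#' @param n_points Number of grid points (>= 2; `n_points = 2` gives exactly
#'   the endpoints).
#' @return A `production_envelope` data.frame with columns `growth`,
#'   `min_production`, `max_production`; maximal growth in
#'   `attr(, "mu_max")`.
#' @export
production_envelope <- function(network, target, design, n_points = 20,
                                pool = NULL, config = run_config()) {
  stopifnot(n_points >= 2)
  net <- apply_design(network, design, pool = pool, config = config)
  fs <- fba_max_growth(net)
  mu_max <- fs$objective_value
  grid <- seq(0, mu_max, length.out = n_points)
  lp0 <- build_fba_lp(net)
  bi <- match(net$biomass_id, lp0$vars$id)
  lps <- vector("list", 2L * n_points)
  for (k in seq_len(n_points)) {
    lp <- lp0
    # pin growth to the grid value (tiny relative slack for vertex stability)
    lp$vars$lb[bi] <- grid[k] * (1 - 1e-9) - 1e-9
    lp$vars$ub[bi] <- grid[k] + 1e-9
    lp$objective <- list(coef = stats::setNames(1, target), sense = "min")
    lps[[2L * k - 1L]] <- lp
    lp$objective$sense <- "max"
    lps[[2L * k]] <- lp
  }
  res <- solve_lp_batch(lps)
  getv <- function(r) if (r$status == "optimal") r$objective else NA_real_
  env <- data.frame(
    growth = grid,
    min_production = vapply(res[2L * seq_len(n_points) - 1L], getv, 0),
    max_production = vapply(res[2L * seq_len(n_points)], getv, 0))
  structure(env, mu_max = mu_max, target = target,
            class = c("production_envelope", "data.frame"))
}

#' Coupling potential read off a production envelope
#'
#' The maximal growth rate minus the largest growth achievable at (near-)zero
#' production; agrees with [coupling_potential()] up to grid resolution.
#'
#' @param envelope A `production_envelope`.
#' @param tol Production level counting as zero.
#' @return Numeric estimate of `U` (1/h).
#' @export
envelope_coupling_potential <- function(envelope, tol = 1e-6) {
  mu_max <- attr(envelope, "mu_max")
  ok <- !is.na(envelope$min_production)
  zero_prod <- envelope$growth[ok & envelope$min_production <= tol]
  if (!length(zero_prod)) return(mu_max)
  mu_max - max(zero_prod)
}

#' Summarize verified designs into report files
#'
#' Writes a TSV table (one row per design: modifications, coupling potential,
#' growth, production, yield), a JSON designs file, per-design envelope CSVs
#' and, optionally, one envelope PNG per design.
#'
#' @param designs List of verified `strain_design`s.
#' @param dir Output directory (created if missing).
#' @param envelopes Optional named list of `production_envelope`s, indexed by
#'   design id (`design_1`, ...).
#' @param plot Also write `envelope_<id>.png` for supplied envelopes.
#' @return Path of the TSV table, invisibly; the in-memory summary table in
#'   `attr(, "table")`.
#' @export
summarize_designs <- function(designs, dir, envelopes = NULL, plot = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(
    design_id = if (length(designs))
      paste0("design_", seq_along(designs)) else character(),
    knockouts = vapply(designs, function(d)
      paste(d$knockouts, collapse = ","), ""),
    insertions = vapply(designs, function(d)
      paste(d$insertions, collapse = ","), ""),
    supplements = vapply(designs, function(d)
      paste(d$supplements, collapse = ","), ""),
    U = vapply(designs, function(d) as.numeric(d$U), 0),
    growth = vapply(designs, function(d) d$growth_at_optimum, 0),
    min_production = vapply(designs, function(d)
      d$production_at_optimum_min, 0),
    yield = vapply(designs, function(d) d$yield_at_optimum, 0))
  tsv <- file.path(dir, "designs.tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    lapply(designs, function(d)
      list(knockouts = d$knockouts, insertions = d$insertions,
           supplements = d$supplements, U = d$U,
           growth_at_optimum = d$growth_at_optimum,
           production_at_optimum_min = d$production_at_optimum_min,
           yield_at_optimum = d$yield_at_optimum,
           verified = d$verified, minimal = d$minimal)),
    file.path(dir, "designs.json"), digits = NA, auto_unbox = TRUE,
    null = "null")
  for (id in names(envelopes %||% list())) {
    env <- envelopes[[id]]
    utils::write.csv(as.data.frame(env),
                     file.path(dir, paste0("envelope_", id, ".csv")),
                     row.names = FALSE)
    if (plot) {
      grDevices::png(file.path(dir, paste0("envelope_", id, ".png")),
                     width = 640, height = 480)
      plot_envelope(env, main = id)
      grDevices::dev.off()
    }
  }
  structure(invisible(tsv), table = tab)
}

#' Plot a production envelope
#'
#' @param envelope A `production_envelope`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_envelope <- function(envelope, ...) {
  graphics::plot(envelope$growth, envelope$max_production, type = "l",
                 xlab = "growth rate (1/h)",
                 ylab = "target flux (mmol/gDW/h)",
                 ylim = range(c(0, envelope$min_production,
                                envelope$max_production), na.rm = TRUE), ...)
  graphics::lines(envelope$growth, envelope$min_production, lty = 2)
  graphics::polygon(c(envelope$growth, rev(envelope$growth)),
                    c(envelope$min_production, rev(envelope$max_production)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  invisible(envelope)
}
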