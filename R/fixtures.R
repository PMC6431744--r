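# -- synthetic fixture networks with analytically known coupling structure ----
#
# Hand-crafted toys, not random networks: growth-coupling structure must be
# auditable by hand, and small integer stoichiometries keep the LP solutions
# exact.  Each fixture records its documented optimum, which the enumeration
# oracle re-establishes in the test suite on every build.

#' Knockout-only toy network ("T1")
#'
#' Five metabolites, five reactions.  Substrate S enters through exchange
#' `EX_S` (uptake capped at 10); `R1` converts it to biomass precursor A plus
#' product P, `R2` to A alone; both regenerate ATP consumed by the biomass
#' drain `RB`.  P has no native export (`EX_P` is closed), so the only drain
#' of P is the target demand `DM_P`.  With the bypass `R2` available the cell
#' grows at 10 without producing (U = 0); knocking out `R2` forces all flux
#' through `R1`, whose by-product P must leave through the target: blocking
#' the target then kills growth entirely, so U = 10.
#'
#' @return A `fixture_spec`: `name`, `network` (target demand already added),
#'   `target`, `config`, `documented_optimum` (`design`, `U`), `notes`.
#' @export
toy_knockout_network <- function() {
  mets <- data.frame(id = c("S_e", "A", "P", "atp", "adp"),
                     compartment = c("e", "c", "c", "c", "c"))
  rxns <- list(
    reaction("EX_S", c(S_e = -1), -10, 1000, kind = "exchange"),
    reaction("R1", c(S_e = -1, adp = -1, A = 1, P = 1, atp = 1), 0, 1000),
    reaction("R2", c(S_e = -1, adp = -1, A = 1, atp = 1), 0, 1000),
    reaction("RB", c(A = -1, atp = -1, adp = 1), 0, 1000, kind = "biomass"),
    reaction("EX_P", c(P = -1), 0, 0, kind = "exchange"))
  net <- metabolic_network("T1", mets, rxns)
  net <- add_target_demand(net, "P")
  opt <- design(knockouts = "R2")
  opt$U <- 10
  structure(list(name = "T1",
                 network = net, target = "DM_P",
                 config = run_config("DM_P", max_knockouts = 1,
                                     carbon_exchange = "EX_S"),
                 space_args = list(),
                 documented_optimum = list(design = opt, U = 10),
                 notes = paste("KO-only fixture: single knockout of the",
                               "bypass R2 couples production to growth")),
            class = "fixture_spec")
}

#' Insertion-requiring toy network
#'
#' The essential biomass precursor B is natively made by the bypass `RBy`.
#' The heterologous pool offers `H1` (A -> B + P, all-native metabolites),
#' whose operation stoichiometrically forces target flux because P has no
#' other drain, and `H2`, which consumes a metabolite foreign to the host (so
#' single-insertion pruning removes it).  With one knockout only, no design
#' couples (best U = 0); with one knockout and one insertion the optimum is
#' {KO RBy, insert H1}, U = 10.
#'
#' @return A `fixture_spec` whose `pool` field holds the two-candidate
#'   heterologous pool.
#' @export
toy_insertion_network <- function() {
  mets <- data.frame(id = c("S_e", "A", "B", "P"),
                     compartment = c("e", "c", "c", "c"))
  rxns <- list(
    reaction("EX_S", c(S_e = -1), -10, 1000, kind = "exchange"),
    reaction("RA", c(S_e = -1, A = 1), 0, 1000),
    reaction("RBy", c(A = -1, B = 1), 0, 1000),
    reaction("RB", c(B = -1), 0, 1000, kind = "biomass"),
    reaction("EX_P", c(P = -1), 0, 0, kind = "exchange"))
  net <- metabolic_network("T-ins", mets, rxns)
  net <- add_target_demand(net, "P")
  pool <- list(
    H1 = reaction("H1", c(A = -1, B = 1, P = 1), 0, 1000,
                  kind = "heterologous"),
    H2 = reaction("H2", c(M_foreign = -1, B = 1), 0, 1000,
                  kind = "heterologous"))
  opt <- design(knockouts = "RBy", insertions = "H1")
  opt$U <- 10
  structure(list(name = "T-ins",
                 network = net, target = "DM_P",
                 config = run_config("DM_P", max_knockouts = 1,
                                     max_insertions = 1,
                                     carbon_exchange = "EX_S"),
                 pool = pool,
                 documented_optimum = list(design = opt, U = 10),
                 notes = paste("insertion fixture: the native bypass must be",
                               "knocked out and H1 inserted; H2 is removed",
                               "by reachability pruning at k = 1")),
            class = "fixture_spec")
}

#' Supplement-requiring toy network
#'
#' Biomass needs precursors A and B in equal amounts.  B comes from the
#' native bypass `RBy` (A -> B) or from the relief pathway `RX`
#' (A + X -> B + P) that consumes supplement X and forces target flux.
#' Knocking out `RBy` creates an auxotrophy relievable only by opening X
#' uptake, and the relief route co-produces P: the optimum at one knockout
#' plus one supplement is {KO RBy, supplement EX_X}, U = 5.  The supplement
#' alone does not couple (the bypass keeps non-producing growth optimal) and
#' the knockout alone is lethal.
#'
#' @return A `fixture_spec`.
#' @export
toy_supplement_network <- function() {
  mets <- data.frame(id = c("S_e", "X_e", "A", "B", "P"),
                     compartment = c("e", "e", "c", "c", "c"))
  rxns <- list(
    reaction("EX_S", c(S_e = -1), -10, 1000, kind = "exchange"),
    reaction("EX_X", c(X_e = -1), 0, 1000, kind = "exchange"),
    reaction("RA", c(S_e = -1, A = 1), 0, 1000),
    reaction("RBy", c(A = -1, B = 1), 0, 1000),
    reaction("RX", c(A = -1, X_e = -1, B = 1, P = 1), 0, 1000),
    reaction("RB", c(A = -1, B = -1), 0, 1000, kind = "biomass"),
    reaction("EX_P", c(P = -1), 0, 0, kind = "exchange"))
  net <- metabolic_network("T-sup", mets, rxns)
  net <- add_target_demand(net, "P")
  opt <- design(knockouts = "RBy", supplements = "EX_X")
  opt$U <- 5
  structure(list(name = "T-sup",
                 network = net, target = "DM_P",
                 config = run_config("DM_P", max_knockouts = 1,
                                     max_supplements = 1,
                                     carbon_exchange = "EX_S"),
                 supplements = "EX_X",
                 documented_optimum = list(design = opt, U = 5),
                 notes = paste("supplement fixture: a knockout-induced",
                               "auxotrophy is relieved by supplement X",
                               "through a production-forcing pathway")),
            class = "fixture_spec")
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat("<fixture_spec> ", x$name, ": target ", x$target,
      ", documented optimum U = ", x$documented_optimum$U, "\n", sep = "")
  invisible(x)
}

#' Design space of a fixture
#'
#' Convenience wrapper assembling the [design_space()] a fixture was designed
#' for (knockout candidates from the filter, its pool pruned to the insertion
#' limit, its supplement candidates).
#'
#' @param fx A `fixture_spec`.
#' @return A `design_space`.
#' @export
fixture_space <- function(fx) {
  pool <- if (!is.null(fx$pool))
    prune_universal_pool(fx$pool, fx$network, fx$config$max_insertions)
  else list()
  design_space(fx$network, fx$config,
               pool = pool,
               supplements = fx$supplements %||% character())
}

#' Seeded random feasible bounded LP
#'
#' Generates a sparse maximization LP that is feasible (the origin satisfies
#' every row) and bounded (finite variable boxes), for strong-duality
#' property tests.  Deterministic for a fixed seed.
#'
#' @param seed Integer seed.
#' @param n_vars,n_rows Problem size (kept small for test speed).
#' @param density Expected fraction of nonzeros per row.
#' @return A `linear_program`.
#' @export
random_lp <- function(seed, n_vars = 12, n_rows = 8, density = 0.4) {
  stopifnot(n_vars <= 200, n_rows <= 200)
  set.seed(seed)
  ids <- sprintf("x%02d", seq_len(n_vars))
  lb <- -stats::runif(n_vars, 0, 5)
  ub <- stats::runif(n_vars, 0, 5)
  sense <- sample(c("L", "G", "E"), n_rows, replace = TRUE,
                  prob = c(0.5, 0.3, 0.2))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (r in seq_len(n_rows)) {
    nz <- which(stats::runif(n_vars) < density)
    if (!length(nz)) nz <- sample.int(n_vars, 1)
    ii <- c(ii, rep.int(r, length(nz)))
    jj <- c(jj, nz)
    xx <- c(xx, stats::rnorm(length(nz)))
  }
  # rhs chosen so the origin is feasible: b >= 0 for <=, b <= 0 for >=,
  # b = 0 for equalities
  rhs <- ifelse(sense == "L", stats::runif(n_rows, 0, 3),
                ifelse(sense == "G", -stats::runif(n_rows, 0, 3), 0))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(n_rows, n_vars))
  linear_program(data.frame(id = ids, lb = lb, ub = ub),
                 A, sense, rhs,
                 objective = list(
                   coef = stats::setNames(stats::rnorm(n_vars), ids),
                   sense = "max"))
}
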