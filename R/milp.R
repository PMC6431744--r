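# -- the single-level growth-coupling MILP -----------------------------------
#
# The search for the design maximizing the growth-coupling potential
# U = f(M) - f(M*) is naturally bi-level (both inner problems are FBA
# maximizations).  It collapses to a single level by replacing the inner
# maximization over M* with its LP dual: weak duality makes any dual-feasible
# point an upper bound on f(M*), and maximizing f(M) - f(M*_D) drives the
# dual half down onto f(M*) while driving the primal half up onto f(M).
# Shared binaries y (1 = reaction usable / supplement open) couple the two
# halves: in the M half through flux-coupling rows, in the dual half through
# bound terms of the dual objective, whose y-times-multiplier products are
# linearized with standard big-M rows.

# variable naming inside the MILP
v_ <- function(id) paste0("v.", id)
y_ <- function(id) paste0("y.", id)
lam_ <- function(id) paste0("lam.", id)
mu_ub_ <- function(id) paste0("uU.", id)
mu_lb_ <- function(id) paste0("uL.", id)
z_ub_ <- function(id) paste0("zU.", id)
z_lb_ <- function(id) paste0("zL.", id)

#' Assemble the growth-coupling MILP
#'
#' Builds the single-level mixed-integer program over a network, a design
#' space and a configuration:
#' * primal half: FBA over the network extended with the (pruned) insertion
#'   pool, with flux-coupling rows `lb_j y_j <= v_j <= ub_j y_j` for every
#'   controlled reaction (supplements couple only the uptake bound:
#'   `v_j >= -supplement_uptake_bound * y_j`);
#' * dual half: the LP dual of the same extended network with the target
#'   blocked, dual multipliers box-bounded by `big_M`, and each product of a
#'   binary with a bound multiplier replaced by an auxiliary variable with
#'   big-M linearization rows;
#' * cardinality rows limiting knockouts (`sum (1 - y) <= K_ko`), insertions
#'   and supplements;
#' * objective: maximize (biomass flux of the primal half) minus (dual
#'   objective of the blocked half), i.e. the growth-coupling potential.
#'
#' @param network A `metabolic_network` containing the target reaction,
#'   medium already applied.
#' @param space A [design_space()] (insertion pool already pruned).
#' @param config A [run_config()] naming the target and limits.
#' @return An `optcouple_problem`.
#' @export
assemble_optcouple <- function(network, space, config) {
  target <- config$target_reaction
  if (is.null(target) || !target %in% reaction_ids(network))
    stop("config$target_reaction must name a reaction of the network")
  ko <- space$knockout_candidates
  ins <- names(space$insertion_pool)
  sup <- space$supplement_candidates
  if (target %in% c(ko, ins, sup))
    stop("the target reaction cannot be a modification candidate")

  # extended network: native + all pool candidates
  ext <- network
  for (r in space$insertion_pool)
    ext <- add_reaction(ext, r, allow_new_metabolites = TRUE)
  rids <- reaction_ids(ext)
  mids <- ext$metabolites$id
  lbs <- vapply(ext$reactions, `[[`, 0, "lb")
  ubs <- vapply(ext$reactions, `[[`, 0, "ub")
  lbs <- pmax(lbs, -config$big_M * 1e6) # bounds are finite surrogates already
  ubs <- pmin(ubs, config$big_M * 1e6)
  if (config$big_M < max(abs(c(lbs, ubs, config$supplement_uptake_bound))))
    stop("big_M (", config$big_M, ") is smaller than a reaction bound; ",
         "increase config$big_M")

  controlled <- c(ko, ins, sup)
  role <- c(rep("knockout", length(ko)), rep("insertion", length(ins)),
            rep("supplement", length(sup)))
  if (anyDuplicated(controlled))
    stop("a reaction may carry at most one perturbation variable")

  M <- config$big_M
  supb <- config$supplement_uptake_bound
  S <- stoichiometric_matrix(ext)

  # ---- variables -----------------------------------------------------------
  # supplements: uptake reachable only when y = 1, via coupling row; the
  # variable bound must admit it
  v_lb <- lbs; v_ub <- ubs
  v_lb[match(sup, rids)] <- pmin(v_lb[match(sup, rids)], -supb)
  vars <- rbind(
    data.frame(id = v_(rids), lb = unname(v_lb), ub = unname(v_ub)),
    data.frame(id = y_(controlled), lb = 0, ub = 1),
    data.frame(id = lam_(mids), lb = -M, ub = M),
    data.frame(id = mu_ub_(rids), lb = 0, ub = M),
    data.frame(id = mu_lb_(rids), lb = 0, ub = M),
    data.frame(id = z_ub_(c(ko, ins)), lb = 0, ub = M),
    data.frame(id = z_lb_(controlled), lb = 0, ub = M))
  vid <- stats::setNames(seq_len(nrow(vars)), vars$id)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  sense <- character(0); rhs <- numeric(0); row_ids <- character(0)
  nrows <- 0L
  add_row <- function(ids, coefs, sn, b, rid) {
    nrows <<- nrows + 1L
    ii <<- c(ii, rep.int(nrows, length(ids)))
    jj <<- c(jj, unname(vid[ids]))
    xx <<- c(xx, coefs)
    sense <<- c(sense, sn); rhs <<- c(rhs, b); row_ids <<- c(row_ids, rid)
  }

  # ---- primal half: S v = 0 ------------------------------------------------
  Tm <- methods::as(S, "TsparseMatrix")
  ii <- Tm@i + 1L
  jj <- unname(vid[v_(rids[Tm@j + 1L])])
  xx <- Tm@x
  nrows <- nrow(S)
  sense <- rep("E", nrows); rhs <- rep(0, nrows)
  row_ids <- paste0("ss.", mids)

  # flux-coupling rows
  for (k in seq_along(controlled)) {
    id <- controlled[k]
    if (role[k] == "supplement") {
      add_row(c(v_(id), y_(id)), c(1, supb), "G", 0, paste0("cplo.", id))
    } else {
      add_row(c(v_(id), y_(id)), c(1, -ubs[[id]]), "L", 0, paste0("cphi.", id))
      add_row(c(v_(id), y_(id)), c(1, -lbs[[id]]), "G", 0, paste0("cplo.", id))
    }
  }

  # ---- dual half of the target-blocked model -------------------------------
  # dual feasibility: S' lam + uU - uL = c*  (c* = biomass indicator)
  St <- methods::as(Matrix::t(S), "TsparseMatrix")
  for (k in seq_along(rids)) {
    sel <- which(St@i + 1L == k)
    add_row(c(lam_(mids[St@j[sel] + 1L]), mu_ub_(rids[k]), mu_lb_(rids[k])),
            c(St@x[sel], 1, -1), "E",
            if (rids[k] == ext$biomass_id) 1 else 0,
            paste0("dfeas.", rids[k]))
  }

  # big-M linearization of z = y * mu (mu in [0, M], y binary):
  #   z <= M y, z <= mu, z >= mu - M (1 - y)   (z >= 0 by bound)
  lin_rows <- function(zid, muid, yid, id) {
    add_row(c(zid, yid), c(1, -M), "L", 0, paste0("zM.", id))
    add_row(c(zid, muid), c(1, -1), "L", 0, paste0("zmu.", id))
    add_row(c(zid, muid, yid), c(1, -1, -M), "G", -M, paste0("zlo.", id))
  }
  for (id in c(ko, ins)) {
    lin_rows(z_ub_(id), mu_ub_(id), y_(id), paste0("U.", id))
    lin_rows(z_lb_(id), mu_lb_(id), y_(id), paste0("L.", id))
  }
  for (id in sup)
    lin_rows(z_lb_(id), mu_lb_(id), y_(id), paste0("L.", id))

  # ---- cardinality rows ----------------------------------------------------
  if (length(ko))
    add_row(y_(ko), rep(1, length(ko)), "G",
            length(ko) - config$max_knockouts, "card.ko")
  if (length(ins))
    add_row(y_(ins), rep(1, length(ins)), "L", config$max_insertions,
            "card.ins")
  if (length(sup))
    add_row(y_(sup), rep(1, length(sup)), "L", config$max_supplements,
            "card.sup")

  # ---- objective: f(M) - dual objective of M* ------------------------------
  # dual objective = sum_j ub*_j uU_j - sum_j lb*_j uL_j with the
  # binary-dependent bounds substituted by z variables; the target
  # contributes nothing (both bounds are 0 in M*).
  obj <- stats::setNames(1, v_(ext$biomass_id))
  uncontrolled <- setdiff(rids, c(controlled, target))
  for (id in uncontrolled) {
    if (ubs[[id]] != 0) obj[mu_ub_(id)] <- -ubs[[id]]
    if (lbs[[id]] != 0) obj[mu_lb_(id)] <- lbs[[id]]
  }
  for (id in c(ko, ins)) {
    if (ubs[[id]] != 0) obj[z_ub_(id)] <- -ubs[[id]]
    if (lbs[[id]] != 0) obj[z_lb_(id)] <- lbs[[id]]
  }
  for (id in sup) {
    if (ubs[[id]] != 0) obj[mu_ub_(id)] <- -ubs[[id]]
    obj[z_lb_(id)] <- -supb # -(-supb * y) * uL
  }

  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrows, nrow(vars)))
  lp <- linear_program(vars, A, sense, rhs,
                       objective = list(coef = obj[obj != 0], sense = "max"),
                       row_ids = row_ids)
  structure(list(lp = lp,
                 binaries = data.frame(var_id = y_(controlled),
                                       reaction_id = controlled,
                                       role = role),
                 network = ext, base_network = network, target = target,
                 space = space, config = config),
            class = "optcouple_problem")
}

#' @export
print.optcouple_problem <- function(x, ...) {
  cat("<optcouple_problem> target ", x$target, ": ",
      n_vars(x$lp), " variables (", nrow(x$binaries), " binary), ",
      length(x$lp$rhs), " rows\n", sep = "")
  invisible(x)
}

# Fix the binaries of a problem to the assignment implied by a design and
# return the resulting LP (used for validation: its optimum is the design's
# coupling potential, provided the dual multipliers fit their big_M boxes).
fix_binaries <- function(problem, design) {
  lp <- problem$lp
  b <- problem$binaries
  val <- ifelse(b$role == "knockout",
                !(b$reaction_id %in% design$knockouts),
                b$reaction_id %in% c(design$insertions, design$supplements))
  idx <- match(b$var_id, lp$vars$id)
  lp$vars$lb[idx] <- as.numeric(val)
  lp$vars$ub[idx] <- as.numeric(val)
  lp
}

assignment_to_design <- function(problem, assignment) {
  b <- problem$binaries
  stopifnot(length(assignment) == nrow(b))
  on <- assignment > 0.5
  design(knockouts = b$reaction_id[b$role == "knockout" & !on],
         insertions = b$reaction_id[b$role == "insertion" & on],
         supplements = b$reaction_id[b$role == "supplement" & on])
}

#' Solve the growth-coupling MILP with solution-pool harvesting
#'
#' Phase 1 solves to optimality (or the time limit).  Phase 2 harvests
#' additional integer solutions by iterated no-good cuts for a time budget of
#' `pool_time_factor` times the first solve (capped by `time_limit_s`),
#' stopping once objectives fall to `coupling_epsilon` (non-coupled designs).
#' With `n_runs > 1` the search is repeated under seeded permutations of the
#' variable order and the pools are united, which diversifies the harvested
#' designs; all pools are deduplicated and sorted by objective (ties broken
#' lexicographically by modification ids, for deterministic reports).
#'
#' @param problem An `optcouple_problem` from [assemble_optcouple()].
#' @param config A [run_config()] (defaults to the problem's own).
#' @return A `solver_report`: `status`, `best_objective`, `pool` (list of
#'   entries with `design`, `objective`, `assignment`), `wall_time_s`,
#'   `seed`.
#' @export
solve_optcouple <- function(problem, config = problem$config) {
  t0 <- Sys.time()
  lp <- problem$lp
  bin_ids <- problem$binaries$var_id
  pool_spec <- list(binaries = match(bin_ids, lp$vars$id) - 1L,
                    max_solutions = config$pool_max,
                    time_budget_factor = config$pool_time_factor,
                    time_cap = config$time_limit_s,
                    obj_floor = config$coupling_epsilon)
  set.seed(config$seed)
  entries <- list()
  status <- "error"; best <- NA_real_
  for (run in seq_len(config$n_runs)) {
    perm <- if (run == 1L) seq_len(n_vars(lp)) else sample.int(n_vars(lp))
    plp <- lp
    plp$vars <- lp$vars[perm, , drop = FALSE]
    if (!is.null(lp$A)) plp$A <- lp$A[, perm, drop = FALSE]
    res <- backend_solve(list(lp_to_backend(
      plp, integer_ids = bin_ids,
      pool = list(binaries = match(bin_ids, plp$vars$id) - 1L,
                  max_solutions = pool_spec$max_solutions,
                  time_budget_factor = pool_spec$time_budget_factor,
                  time_cap = pool_spec$time_cap,
                  obj_floor = pool_spec$obj_floor),
      time_limit = config$time_limit_s)))[[1]]
    if (run == 1L) {
      status <- res$status
      best <- res$objective
    } else if (!is.na(res$objective) && !is.na(best) &&
                 res$objective > best + 1e-9) {
      best <- res$objective
    }
    for (p in res$pool) {
      d <- assignment_to_design(problem, p$assignment)
      entries[[design_key(d)]] <-
        list(design = d, objective = p$objective, assignment = p$assignment)
    }
  }
  entries <- unname(entries)
  if (length(entries)) {
    # exact re-simulation of every harvested assignment: the MILP objective
    # at near-integer points can drift by big-M times the solver's
    # integrality tolerance, so each design's potential is recomputed by two
    # clean LP solves; discrepancies are flagged, never silently kept
    ev <- coupling_potential_batch(problem$base_network, problem$target,
                                   lapply(entries, `[[`, "design"),
                                   pool = problem$space$insertion_pool,
                                   config = config)
    for (k in seq_along(entries)) {
      entries[[k]]$milp_objective <- entries[[k]]$objective
      entries[[k]]$flagged <- abs(entries[[k]]$objective - ev$U[k]) > 1e-5
      entries[[k]]$objective <- ev$U[k]
    }
    n_flag <- sum(vapply(entries, `[[`, FALSE, "flagged"))
    if (n_flag > 0)
      message(n_flag, " pool entr", if (n_flag == 1) "y" else "ies",
              " corrected after exact re-simulation (big-M/integrality",
              " artifacts)")
    keys <- vapply(entries, function(e) design_key(e$design), "")
    objs <- vapply(entries, `[[`, 0, "objective")
    entries <- entries[order(-objs, keys)]
    best <- max(objs)
  }
  structure(list(status = status,
                 best_objective = best,
                 pool = entries,
                 wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")),
                 seed = config$seed),
            class = "solver_report")
}

#' @export
print.solver_report <- function(x, ...) {
  cat("<solver_report> status ", x$status, ", best objective ",
      signif(x$best_objective, 6), ", pool of ", length(x$pool),
      " design(s)\n", sep = "")
  invisible(x)
}

#' Exhaustive enumeration oracle
#'
#' Enumerates every admissible combination of modifications within the design
#' space limits, evaluates the growth-coupling potential of each by direct
#' two-LP simulation, and returns the best design and the full table.  A
#' guard on the number of candidate modifications (default 16) keeps the
#' enumeration tractable; this is the independent reference the MILP is
#' tested against.
#'
#' @param network A `metabolic_network` with the target present.
#' @param space A [design_space()].
#' @param config A [run_config()] naming the target.
#' @param guard Maximum candidate-modification count.
#' @return List with `best_design`, `best_U` and `table` (one row per
#'   enumerated design).
#' @export
brute_force_oracle <- function(network, space, config, guard = 16L) {
  n_cand <- length(space$knockout_candidates) +
    length(space$insertion_pool) + length(space$supplement_candidates)
  if (n_cand > guard)
    stop("design space has ", n_cand, " candidate modifications; ",
         "the enumeration guard is ", guard)
  subsets <- function(ids, kmax) {
    out <- list(character(0))
    for (k in seq_len(min(kmax, length(ids))))
      out <- c(out, utils::combn(ids, k, simplify = FALSE))
    out
  }
  kos <- subsets(space$knockout_candidates, config$max_knockouts)
  inss <- subsets(names(space$insertion_pool), config$max_insertions)
  sups <- subsets(space$supplement_candidates, config$max_supplements)
  designs <- list()
  for (a in kos) for (b in inss) for (d in sups)
    designs[[length(designs) + 1L]] <-
      design(knockouts = a, insertions = b, supplements = d)
  ev <- coupling_potential_batch(network, config$target_reaction, designs,
                                 pool = space$insertion_pool, config = config)
  keys <- vapply(designs, design_key, "")
  ord <- order(-ev$U, keys)
  tab <- data.frame(
    knockouts = vapply(designs, function(d)
      paste(d$knockouts, collapse = ","), ""),
    insertions = vapply(designs, function(d)
      paste(d$insertions, collapse = ","), ""),
    supplements = vapply(designs, function(d)
      paste(d$supplements, collapse = ","), ""),
    U = ev$U, f_M = ev$f_M, f_Mstar = ev$f_Mstar)[ord, ]
  rownames(tab) <- NULL
  best <- designs[[ord[1]]]
  best$U <- ev$U[ord[1]]
  list(best_design = best, best_U = ev$U[ord[1]], table = tab)
}
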