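# FBA construction, LP duality, coupling potential

test_that("the FBA LP has one variable per reaction, one row per metabolite", {
  for (fx in all_fixtures()) {
    lp <- build_fba_lp(fx$network)
    expect_identical(nrow(lp$vars), length(fx$network$reactions),
                     info = fx$name)
    expect_identical(length(lp$rhs), nrow(fx$network$metabolites),
                     info = fx$name)
    expect_true(all(lp$sense == "E"), info = fx$name)
    expect_true(all(lp$rhs == 0), info = fx$name)
    expect_identical(names(lp$objective$coef), fx$network$biomass_id)
  }
  # T1 with its target demand: 6 variables, 5 steady-state rows
  lp <- build_fba_lp(toy_knockout_network()$network)
  expect_identical(nrow(lp$vars), 6L)
  expect_identical(length(lp$rhs), 5L)
})

test_that("FBA solves the knockout toy as derived by hand", {
  fx <- toy_knockout_network()
  fs <- fba_max_growth(fx$network)
  expect_equal(fs$objective_value, 10, tolerance = 1e-6)
  expect_false(fs$infeasible)
  # steady state holds at the optimum
  S <- stoichiometric_matrix(fx$network)
  expect_lt(max(abs(as.numeric(S %*% fs$flux[colnames(S)]))), 1e-6)
  # closing both routes to biomass stops growth
  dead <- set_bounds(set_bounds(fx$network, "R1", 0, 0), "R2", 0, 0)
  expect_equal(fba_max_growth(dead)$objective_value, 0, tolerance = 1e-9)
  # a forced flux with no feasible route is reported infeasible, growth 0
  forced <- fx$network
  forced$reactions[["R1"]]$lb <- 1
  forced$reactions[["R1"]]$ub <- 1
  forced <- set_bounds(forced, "DM_P", 0, 0)
  forced <- set_bounds(forced, "EX_P", 0, 0)
  fs2 <- fba_max_growth(forced)
  expect_true(fs2$infeasible)
  expect_identical(fs2$objective_value, 0)
})

test_that("textbook duals: analytic optima and degenerate objectives", {
  # max x s.t. x <= 3, x >= 0  -> dual optimum 3
  lp <- linear_program(data.frame(id = "x", lb = 0, ub = 3),
                       objective = list(coef = c(x = 1), sense = "max"))
  expect_equal(optcoupleR:::solve_lp(dualize(lp))$objective, 3,
               tolerance = 1e-9)
  # empty objective -> feasibility problem, optimum 0
  lp0 <- linear_program(data.frame(id = c("a", "b"), lb = c(-1, -2),
                                   ub = c(5, 5)),
                        A = Matrix::sparseMatrix(i = 1, j = 1, x = 1,
                                                 dims = c(1, 2)),
                        sense = "L", rhs = 4,
                        objective = list(coef = c(a = 0), sense = "max"))
  expect_equal(optcoupleR:::solve_lp(dualize(lp0))$objective, 0,
               tolerance = 1e-9)
  expect_error(dualize(linear_program(
    data.frame(id = "x", lb = 0, ub = 1),
    objective = list(coef = c(x = 1), sense = "min"))), "maximization")
})

test_that("strong duality holds on seeded random LPs", {
  lps <- lapply(1:12, function(s) random_lp(s))
  duals <- lapply(lps, dualize)
  res <- optcoupleR:::solve_lp_batch(c(lps, duals))
  for (k in seq_along(lps)) {
    expect_identical(res[[k]]$status, "optimal", info = paste("seed", k))
    expect_equal(res[[k]]$objective, res[[k + length(lps)]]$objective,
                 tolerance = 1e-6, info = paste("seed", k))
  }
})

test_that("weak duality: dual-feasible points bound the primal optimum", {
  # any dual-feasible point's objective >= the (max-)primal optimum
  for (s in c(3, 11)) {
    lp <- random_lp(s)
    dual <- dualize(lp)
    p_opt <- optcoupleR:::solve_lp(lp)$objective
    # sample dual-feasible points by optimizing random objectives subject to
    # the dual constraints
    set.seed(s)
    for (j in 1:3) {
      probe <- dual
      # box the free multipliers so the probe is bounded; any feasible point
      # of the boxed problem is still dual-feasible
      probe$vars$lb <- pmax(probe$vars$lb, -50)
      probe$vars$ub <- pmin(probe$vars$ub, 50)
      w <- stats::rnorm(nrow(probe$vars))
      probe$objective <- list(coef = stats::setNames(w, probe$vars$id),
                              sense = "min")
      r <- optcoupleR:::solve_lp(probe)
      expect_identical(r$status, "optimal")
      dual_obj <- sum(dual$objective$coef[names(r$x)] * r$x)
      expect_gte(dual_obj, p_opt - 1e-6)
    }
  }
})

test_that("an exported LP re-solves identically under GLPK", {
  # independent round trip: our CPLEX-LP writer -> GLPK reader/solver
  lp <- random_lp(42)
  path <- tempfile(fileext = ".lp")
  write_lp(lp, path)
  script <- paste0(
    "import swiglpk as g\n",
    "p = g.glp_create_prob()\n",
    "assert g.glp_read_lp(p, None, '", path, "') == 0\n",
    "par = g.glp_smcp(); g.glp_init_smcp(par); par.msg_lev = g.GLP_MSG_OFF\n",
    "g.glp_simplex(p, par)\n",
    "print(repr(g.glp_get_obj_val(p)))\n")
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- system2("python", shQuote(sf), stdout = TRUE)
  glpk_obj <- as.numeric(out[length(out)])
  ours <- optcoupleR:::solve_lp(lp)$objective
  expect_equal(glpk_obj, ours, tolerance = 1e-6)
})

test_that("coupling potential matches hand-derived values on the toy", {
  fx <- toy_knockout_network()
  u0 <- coupling_potential(fx$network, "DM_P")
  expect_equal(as.numeric(u0), 0, tolerance = 1e-9)
  u2 <- coupling_potential(fx$network, "DM_P", design(knockouts = "R2"))
  expect_equal(as.numeric(u2), 10, tolerance = 1e-6)
  expect_equal(attr(u2, "f_M"), 10, tolerance = 1e-6)
  expect_equal(attr(u2, "f_Mstar"), 0, tolerance = 1e-9)
  u1 <- coupling_potential(fx$network, "DM_P", design(knockouts = "R1"))
  expect_equal(as.numeric(u1), 0, tolerance = 1e-9)
  expect_error(coupling_potential(fx$network, "DM_P",
                                  design(knockouts = "NOPE")), "NOPE")
})

test_that("U is non-negative and zero when the target is already closed", {
  for (fx in all_fixtures()) {
    closed <- set_bounds(fx$network, fx$target, 0, 0)
    for (d in list(design(),
                   design(knockouts = fx$network$reactions[[3]]$id))) {
      u <- coupling_potential(closed, fx$target, d,
                              pool = fx$pool, config = fx$config)
      expect_lt(abs(as.numeric(u)), 1e-9)
    }
    u <- coupling_potential(fx$network, fx$target, design(),
                            pool = fx$pool, config = fx$config)
    expect_gte(as.numeric(u), 0)
  }
})
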