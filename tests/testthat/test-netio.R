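# model / design / configuration I/O and model preparation

test_that("the knockout toy loads and round-trips through COBRA JSON", {
  fx <- toy_knockout_network()
  # fixture counts before the target demand is appended
  expect_identical(nrow(fx$network$metabolites), 5L)
  expect_identical(length(fx$network$reactions), 6L) # 5 + target demand
  path <- tempfile(fileext = ".json")
  write_model(fx$network, path)
  net2 <- load_model(path)
  expect_identical(length(net2$reactions), length(fx$network$reactions))
  expect_identical(net2$biomass_id, "RB")
  for (id in names(fx$network$reactions)) {
    a <- fx$network$reactions[[id]]; b <- net2$reactions[[id]]
    expect_equal(sort(names(a$stoich)), sort(names(b$stoich)), info = id)
    expect_equal(a$stoich[sort(names(a$stoich))],
                 b$stoich[sort(names(b$stoich))], info = id)
    expect_equal(c(a$lb, a$ub), c(b$lb, b$ub), info = id)
  }
})

test_that("round-trip preserves all fixture networks", {
  for (fx in all_fixtures()) {
    path <- tempfile(fileext = ".json")
    write_model(fx$network, path)
    net2 <- load_model(path)
    expect_identical(sort(names(net2$reactions)),
                     sort(names(fx$network$reactions)), info = fx$name)
    expect_identical(net2$biomass_id, fx$network$biomass_id, info = fx$name)
    S1 <- stoichiometric_matrix(fx$network)
    S2 <- stoichiometric_matrix(net2)
    expect_equal(as.matrix(S1), as.matrix(S2)[rownames(S1), colnames(S1)],
                 info = fx$name)
  }
})

test_that("a reaction referencing an undeclared metabolite is rejected", {
  mets <- data.frame(id = "A", compartment = "c")
  rxns <- list(reaction("R", c(A = -1, GHOST = 1), 0, 10),
               reaction("RB", c(A = -1), 0, 10, kind = "biomass"))
  expect_error(metabolic_network("bad", mets, rxns), "GHOST")
  # and through the JSON loader
  doc <- list(id = "bad", metabolites = list(list(id = "A", compartment = "c")),
              reactions = list(
                list(id = "R", metabolites = list(A = -1, GHOST = 1),
                     lower_bound = 0, upper_bound = 10,
                     objective_coefficient = 0),
                list(id = "RB", metabolites = list(A = -1),
                     lower_bound = 0, upper_bound = 10,
                     objective_coefficient = 1)))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(load_model(path), "GHOST")
})

test_that("a model without an objective reaction is rejected", {
  doc <- list(id = "noobj",
              metabolites = list(list(id = "A", compartment = "c")),
              reactions = list(list(id = "R", metabolites = list(A = -1),
                                    lower_bound = 0, upper_bound = 10,
                                    objective_coefficient = 0)))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(load_model(path), "objective")
})

test_that("add_target_demand appends without touching existing reactions", {
  fx <- toy_supplement_network()
  net <- fx$network
  before <- lapply(net$reactions, function(r) c(r$lb, r$ub))
  net2 <- add_target_demand(net, "A", id = "DM_A")
  expect_identical(length(net2$reactions), length(net$reactions) + 1L)
  expect_identical(net2$reactions[["DM_A"]]$lb, 0)
  expect_identical(net2$reactions[["DM_A"]]$kind, "target")
  for (id in names(net$reactions))
    expect_identical(c(net2$reactions[[id]]$lb, net2$reactions[[id]]$ub),
                     before[[id]])
  # a metabolite that already has a boundary reaction still gets a demand
  net3 <- add_target_demand(net, "P", id = "DM_P2")
  expect_true("DM_P2" %in% names(net3$reactions))
  expect_error(add_target_demand(net, "nope"), "unknown metabolite")
})

test_that("apply_medium sets uptake bounds, closes supplements, idempotent", {
  fx <- toy_supplement_network()
  cfg <- fx$config
  net <- fx$network
  net$reactions[["EX_X"]]$lb <- -5 # pretend uptake was open
  m1 <- apply_medium(net, cfg, supplement_exchanges = "EX_X")
  expect_identical(m1$reactions[["EX_S"]]$lb, -cfg$carbon_uptake_bound)
  expect_identical(m1$reactions[["EX_X"]]$lb, 0) # closed until enabled
  m2 <- apply_medium(m1, cfg, supplement_exchanges = "EX_X")
  expect_identical(m1, m2)
  cfg$carbon_exchange <- "EX_missing"
  expect_error(apply_medium(net, cfg), "EX_missing")
})

test_that("design files round-trip for random designs", {
  for (seed in 1:10) {
    d <- random_design(seed)
    path <- tempfile(fileext = ".json")
    write_design(d, path)
    expect_design_equal(read_design(path), d)
  }
  # empty design file -> all-empty sets
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(), path, auto_unbox = TRUE)
  d0 <- read_design(path)
  expect_identical(design_size <- length(d0$knockouts) +
                     length(d0$insertions) + length(d0$supplements), 0L)
})

test_that("run_config validates its fields and reads from JSON", {
  expect_error(run_config(coupling_epsilon = 0))
  expect_error(run_config(pool_time_factor = 0.5))
  expect_error(run_config(max_knockouts = -1))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(target_reaction = "DM_P", max_knockouts = 3,
                            supplement_uptake_bound = 5),
                       path, auto_unbox = TRUE)
  cfg <- read_run_config(path)
  expect_identical(cfg$max_knockouts, 3L)
  expect_identical(cfg$supplement_uptake_bound, 5)
  expect_type(cfg$supplement_uptake_bound, "double")
  expect_identical(cfg$carbon_uptake_bound, 10) # default retained
  jsonlite::write_json(list(bogus_field = 1), path, auto_unbox = TRUE)
  expect_error(read_run_config(path), "bogus_field")
})
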