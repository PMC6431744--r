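# reduction, merging, verification, production envelopes, reports

test_that("reduction strips harmless modifications and reaches a fixpoint", {
  fx <- toy_knockout_network()
  # variant with a dead-end side reaction: knocking it out never matters,
  # so a padded design {R2, R3} must reduce to the true coupler {R2}
  net <- add_reaction(fx$network,
                      reaction("R3", c(S_e = -1, W = 1), 0, 1000),
                      allow_new_metabolites = TRUE)
  padded <- design(knockouts = c("R2", "R3"))
  red <- reduce_design(net, fx$target, padded, config = fx$config)
  expect_identical(red$knockouts, "R2")
  expect_true(red$minimal)
  expect_gt(red$U, fx$config$coupling_epsilon)
  # brute-force check of minimality: every single removal kills coupling
  for (k in seq_along(red$knockouts)) {
    cand <- design(knockouts = red$knockouts[-k],
                   insertions = red$insertions,
                   supplements = red$supplements)
    u <- as.numeric(coupling_potential(net, fx$target, cand,
                                       config = fx$config))
    expect_lte(u, fx$config$coupling_epsilon)
  }
  # an already-minimal design is returned unchanged
  again <- reduce_design(net, fx$target, red, config = fx$config)
  expect_design_equal(again, red)
  # a non-coupled input comes back unchanged and flagged
  flat <- reduce_design(fx$network, fx$target, design(knockouts = "R1"),
                        config = fx$config)
  expect_false(flat$minimal)
  expect_identical(flat$knockouts, "R1")
})

test_that("reduction also prunes insertions and supplements", {
  fx <- toy_supplement_network()
  sp <- fixture_space(fx)
  padded <- design(knockouts = c("RBy"), supplements = "EX_X")
  red <- reduce_design(fx$network, fx$target, padded,
                       pool = sp$insertion_pool, config = fx$config)
  expect_design_equal(red, padded) # both needed: already minimal
  ins_fx <- toy_insertion_network()
  ins_sp <- fixture_space(ins_fx)
  red2 <- reduce_design(ins_fx$network, ins_fx$target,
                        design(knockouts = "RBy", insertions = "H1"),
                        pool = ins_sp$insertion_pool, config = ins_fx$config)
  expect_identical(red2$insertions, "H1")
  expect_true(red2$minimal)
})

test_that("merging deduplicates on set equality and orders by U", {
  d1 <- design(knockouts = "R2"); d1$U <- 10
  d2 <- design(knockouts = c("R2")); d2$U <- 10
  d3 <- design(knockouts = "R1"); d3$U <- 2
  merged <- merge_designs(list(d3, d1, d2))
  expect_length(merged, 2L)
  expect_identical(merged[[1]]$knockouts, "R2")
  expect_identical(merge_designs(list()), list())
  # property: n random designs with duplicates -> distinct count survives
  set.seed(99)
  pool <- lapply(1:6, random_design)
  dup <- c(pool, pool[sample(6, 10, replace = TRUE)])
  out <- merge_designs(dup)
  expect_length(out, length(unique(vapply(pool, optcoupleR:::design_key,
                                          ""))))
  keys <- vapply(out, optcoupleR:::design_key, "")
  expect_false(anyDuplicated(keys) > 0)
})

test_that("verification fills the hand-derived metrics on the toy", {
  fx <- toy_knockout_network()
  vd <- verify_design(fx$network, fx$target, design(knockouts = "R2"),
                      config = fx$config)
  expect_true(vd$verified)
  expect_equal(vd$U, 10, tolerance = 1e-6)
  expect_equal(vd$growth_at_optimum, 10, tolerance = 1e-6)
  expect_equal(vd$production_at_optimum_min, 10, tolerance = 1e-5)
  expect_equal(vd$yield_at_optimum, 1, tolerance = 1e-5)
  v0 <- verify_design(fx$network, fx$target, design(), config = fx$config)
  expect_true(v0$verified)
  expect_equal(v0$U, 0, tolerance = 1e-9)
  expect_equal(v0$production_at_optimum_min, 0, tolerance = 1e-9)
  expect_error(verify_design(fx$network, fx$target,
                             design(knockouts = "NOPE"),
                             config = fx$config), "NOPE")
})

test_that("the coupling iff holds across all enumerated fixture designs", {
  # U > eps if and only if the minimum production at optimal growth is
  # positive, with both sides computed independently
  for (fx in all_fixtures()) {
    sp <- fixture_space(fx)
    orc <- brute_force_oracle(fx$network, sp, fx$config)
    for (r in seq_len(nrow(orc$table))) {
      d <- design(
        knockouts = strsplit(orc$table$knockouts[r], ",")[[1]],
        insertions = strsplit(orc$table$insertions[r], ",")[[1]],
        supplements = strsplit(orc$table$supplements[r], ",")[[1]])
      vd <- suppressWarnings(
        verify_design(fx$network, fx$target, d,
                      pool = sp$insertion_pool, config = fx$config))
      expect_true(vd$verified,
                  label = paste(fx$name, optcoupleR:::design_key(d)))
      expect_identical(vd$U > fx$config$coupling_epsilon,
                       vd$production_at_optimum_min >
                         fx$config$coupling_epsilon,
                       info = paste(fx$name, optcoupleR:::design_key(d)))
    }
  }
})

test_that("production envelopes match hand-derived endpoints on the toy", {
  fx <- toy_knockout_network()
  d <- design(knockouts = "R2")
  env <- production_envelope(fx$network, fx$target, d, n_points = 3,
                             config = fx$config)
  expect_identical(nrow(env), 3L)
  expect_equal(attr(env, "mu_max"), 10, tolerance = 1e-6)
  expect_equal(env$min_production[1], 0, tolerance = 1e-6)
  expect_equal(env$min_production[3], 10, tolerance = 1e-4)
  # n = 2 gives exactly the endpoints
  env2 <- production_envelope(fx$network, fx$target, d, n_points = 2,
                              config = fx$config)
  expect_equal(env2$growth, c(0, 10), tolerance = 1e-6)
  # pointwise min <= max wherever both are defined
  ok <- !is.na(env$min_production) & !is.na(env$max_production)
  expect_true(all(env$min_production[ok] <= env$max_production[ok] + 1e-6))
  # envelope-derived U agrees with the direct two-LP evaluation
  u_env <- envelope_coupling_potential(
    production_envelope(fx$network, fx$target, d, n_points = 21,
                        config = fx$config))
  u_dir <- as.numeric(coupling_potential(fx$network, fx$target, d,
                                         config = fx$config))
  expect_equal(u_env, u_dir, tolerance = 10 / 20 + 1e-6) # grid resolution
  # at mu_max: min production positive iff coupled
  env0 <- production_envelope(fx$network, fx$target, design(), n_points = 5,
                              config = fx$config)
  expect_lte(env0$min_production[5], 1e-6)
})

test_that("summaries round-trip through the TSV report", {
  fx <- toy_knockout_network()
  vd <- verify_design(fx$network, fx$target, design(knockouts = "R2"),
                      config = fx$config)
  vd$minimal <- TRUE
  dir <- file.path(tempdir(), "opc_sum")
  env <- production_envelope(fx$network, fx$target, vd, n_points = 4,
                             config = fx$config)
  tsv <- summarize_designs(list(vd), dir,
                           envelopes = list(design_1 = env))
  tab <- utils::read.delim(file.path(dir, "designs.tsv"))
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$knockouts, "R2")
  expect_equal(tab$U, vd$U, tolerance = 1e-9)
  expect_equal(tab$yield, vd$yield_at_optimum, tolerance = 1e-9)
  env2 <- utils::read.csv(file.path(dir, "envelope_design_1.csv"))
  expect_equal(env2$min_production, env$min_production, tolerance = 1e-9)
  # empty design list -> header-only table
  dir2 <- file.path(tempdir(), "opc_sum_empty")
  summarize_designs(list(), dir2)
  tab0 <- utils::read.delim(file.path(dir2, "designs.tsv"))
  expect_identical(nrow(tab0), 0L)
  expect_identical(names(tab0)[1:4],
                   c("design_id", "knockouts", "insertions", "supplements"))
})
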