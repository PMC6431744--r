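# Shared fixtures and small utilities for the test suite.  Everything is
# generated in code; nothing is read from disk except files the tests
# themselves write to tempdir().

all_fixtures <- function() {
  list(toy_knockout_network(), toy_insertion_network(),
       toy_supplement_network())
}

# a random design over a fixed candidate alphabet, for round-trip tests
random_design <- function(seed) {
  set.seed(seed)
  ids <- sprintf("RX%02d", 1:12)
  design(knockouts = sample(ids, sample(0:3, 1)),
         insertions = sample(sprintf("H%02d", 1:5), sample(0:2, 1)),
         supplements = sample(sprintf("EX_s%02d", 1:5), sample(0:2, 1)))
}

# write a tiny universal-pool COBRA JSON for designspace tests; includes an
# id collision with T1 ("R1"), a 2x-scaled duplicate pair, a chain HA -> HB
# (HB consumes HA's novel product) and an isolated-foreign-substrate entry
write_pruning_pool <- function(path) {
  rx <- function(id, mets, lb = 0, ub = 1000)
    list(id = id, metabolites = mets, lower_bound = lb, upper_bound = ub)
  pool <- list(reactions = list(
    rx("HA", list(A = -1, M1 = 1)),
    rx("HB", list(M1 = -1, P = 1)),
    rx("HC", list(Mx = -1, A = 1)),
    rx("HD", list(S_e = -1, A = 1)),
    rx("HD2", list(S_e = -2, A = 2)),
    rx("R1", list(S_e = -1, A = 1))))
  jsonlite::write_json(pool, path, auto_unbox = TRUE, digits = NA)
  path
}

# path of the iJO1366 SBML bundled with the installed cobra python package
ijo1366_path <- function() {
  out <- suppressWarnings(system2(
    "python",
    c("-c", shQuote(paste0(
      "import cobra, os; print(os.path.join(os.path.dirname(",
      "cobra.__file__), 'data', 'iJO1366.xml.gz'))"))),
    stdout = TRUE, stderr = FALSE))
  if (length(out) && file.exists(out[1])) out[1] else NA_character_
}

expect_design_equal <- function(a, b) {
  expect_identical(a$knockouts, b$knockouts)
  expect_identical(a$insertions, b$insertions)
  expect_identical(a$supplements, b$supplements)
}
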