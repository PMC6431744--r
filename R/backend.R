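# -- HiGHS (SciPy) solver backend --------------------------------------------
#
# Linear and mixed-integer programs are solved by the HiGHS solver through
# scipy.optimize, driven by the bundled inst/python/lp_backend.py script.
# Problems are batched: one subprocess invocation solves a whole list, which
# keeps the per-solve overhead (interpreter start-up) negligible for the
# many-small-LP workloads of enumeration oracles and production envelopes.

INF_JSON <- 1e30

backend_python <- function() {
  getOption("optcoupleR.python",
            Sys.getenv("OPTCOUPLER_PYTHON", unset = "python"))
}

backend_script <- function() {
  system.file("python", "lp_backend.py", package = "optcoupleR",
              mustWork = TRUE)
}

encode_inf <- function(x) {
  x[x == Inf] <- INF_JSON
  x[x == -Inf] <- -INF_JSON
  x
}

# serialize one linear_program into the backend's problem schema
lp_to_backend <- function(lp, integer_ids = character(), pool = NULL,
                          time_limit = NULL) {
  cvec <- objective_vector(lp)
  prob <- list(
    lb = encode_inf(as.numeric(lp$vars$lb)),
    ub = encode_inf(as.numeric(lp$vars$ub)),
    obj = as.numeric(cvec),
    maximize = lp$objective$sense == "max",
    integer = match(integer_ids, lp$vars$id) - 1L,
    nrow = length(lp$rhs)
  )
  if (anyNA(prob$integer))
    stop("unknown integer variable id(s)")
  if (!is.null(lp$A) && nrow(lp$A) > 0) {
    Tm <- methods::as(lp$A, "TsparseMatrix")
    prob$A <- list(i = Tm@i, j = Tm@j, x = Tm@x)
    prob$sense <- lp$sense
    prob$rhs <- as.numeric(lp$rhs)
  }
  if (!is.null(pool)) prob$pool <- pool
  if (!is.null(time_limit)) prob$time_limit <- time_limit
  prob
}

#' Solve a batch of linear/mixed-integer programs
#'
#' Low-level entry point to the HiGHS backend.  Most users will call
#' [fba_max_growth()], [solve_optcouple()] or the post-processing helpers
#' instead.
#'
#' @param problems List of problem descriptions from `lp_to_backend()`.
#' @return List of results: `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`, `"time_limit"`, `"error"`), `objective`, `x` (solution
#'   vector) and `pool` (list of `assignment`/`objective` pairs).
#' @keywords internal
backend_solve <- function(problems) {
  stopifnot(length(problems) > 0)
  infile <- tempfile("opc_in_", fileext = ".json")
  outfile <- tempfile("opc_out_", fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(list(problems = problems), infile,
                       auto_unbox = FALSE, digits = NA, null = "null")
  status <- system2(backend_python(),
                    c(shQuote(backend_script()), shQuote(infile),
                      shQuote(outfile)),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0)
    stop("LP backend failed (exit ", code, "):\n",
         paste(status, collapse = "\n"))
  res <- jsonlite::fromJSON(outfile, simplifyVector = FALSE)$results
  lapply(res, function(r) {
    list(status = r$status[[1]] %||% r$status,
         objective = if (is.null(r$objective)) NA_real_ else
           as.numeric(r$objective),
         x = if (is.null(r$x)) NULL else as.numeric(unlist(r$x)),
         pool = lapply(r$pool, function(p)
           list(assignment = as.integer(unlist(p$assignment)),
                objective = as.numeric(p$objective))),
         wall_time_s = as.numeric(r$wall_time_s))
  })
}

# solve a single linear_program; returns status/objective/named solution
solve_lp <- function(lp, integer_ids = character(), pool = NULL,
                     time_limit = NULL) {
  res <- backend_solve(list(lp_to_backend(lp, integer_ids, pool,
                                          time_limit)))[[1]]
  if (!is.null(res$x)) names(res$x) <- lp$vars$id
  res
}

# solve many linear_programs in one backend call
solve_lp_batch <- function(lps) {
  res <- backend_solve(lapply(lps, lp_to_backend))
  for (k in seq_along(res))
    if (!is.null(res[[k]]$x)) names(res[[k]]$x) <- lps[[k]]$vars$id
  res
}
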