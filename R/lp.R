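# -- linear programs and LP duality ------------------------------------------

#' Construct a linear program
#'
#' Internal container: variables with box bounds, a sparse constraint block
#' with row senses (`"E"`, `"L"`, `"G"`) and right-hand sides, and a linear
#' objective over a subset of the variables.
#'
#' @param vars `data.frame` with columns `id`, `lb`, `ub`.
#' @param A Sparse constraint matrix (`nrow(A)` rows, one column per
#'   variable), or `NULL` for a box-only program.
#' @param sense Character vector of row senses.
#' @param rhs Numeric right-hand sides.
#' @param objective List with `coef` (named numeric, on variable ids) and
#'   `sense` (`"max"` or `"min"`).
#' @param row_ids Optional row identifiers.
#' @return A `linear_program`.
#' @export
linear_program <- function(vars, A = NULL, sense = character(),
                           rhs = numeric(), objective,
                           row_ids = NULL) {
  stopifnot(is.data.frame(vars), all(c("id", "lb", "ub") %in% names(vars)),
            objective$sense %in% c("max", "min"))
  if (!is.null(A)) {
    A <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
    stopifnot(ncol(A) == nrow(vars), nrow(A) == length(sense),
              length(sense) == length(rhs), all(sense %in% c("E", "L", "G")))
  } else {
    stopifnot(length(sense) == 0L, length(rhs) == 0L)
  }
  bad <- setdiff(names(objective$coef), vars$id)
  if (length(bad))
    stop("objective references undeclared variable(s): ",
         paste(bad, collapse = ", "))
  if (is.null(row_ids))
    row_ids <- if (is.null(A)) character() else paste0("row", seq_along(rhs))
  structure(list(vars = vars, A = A, sense = sense, rhs = rhs,
                 row_ids = row_ids, objective = objective),
            class = "linear_program")
}

#' @export
print.linear_program <- function(x, ...) {
  cat("<linear_program> ", nrow(x$vars), " variables, ",
      length(x$rhs), " rows, ", x$objective$sense, " objective (",
      length(x$objective$coef), " terms)\n", sep = "")
  invisible(x)
}

n_vars <- function(lp) nrow(lp$vars)

objective_vector <- function(lp) {
  c0 <- stats::setNames(numeric(n_vars(lp)), lp$vars$id)
  c0[names(lp$objective$coef)] <- lp$objective$coef
  unname(c0)
}

#' Build the flux balance analysis LP of a network
#'
#' One flux variable per reaction with the reaction's bounds, one steady-state
#' equality row per metabolite (`S v = 0`), and maximization of the biomass
#' flux.
#'
#' @param network A `metabolic_network`.
#' @return A `linear_program` whose variables are the reaction ids.
#' @export
build_fba_lp <- function(network) {
  S <- stoichiometric_matrix(network)
  vars <- data.frame(id = reaction_ids(network),
                     lb = vapply(network$reactions, `[[`, 0, "lb"),
                     ub = vapply(network$reactions, `[[`, 0, "ub"))
  rownames(vars) <- NULL
  linear_program(vars, A = S,
                 sense = rep("E", nrow(S)), rhs = rep(0, nrow(S)),
                 objective = list(coef = stats::setNames(1, network$biomass_id),
                                  sense = "max"),
                 row_ids = rownames(S))
}

# Lift finite variable bounds into explicit rows (x_j <= ub as "L",
# x_j >= lb as "G"); variables become free.  The uniform row treatment is
# what lets the knockout/insertion binaries later attach to these rows'
# dual multipliers.
lift_bounds <- function(lp) {
  nv <- n_vars(lp)
  has_ub <- is.finite(lp$vars$ub)
  has_lb <- is.finite(lp$vars$lb)
  eye <- Matrix::sparseMatrix(i = seq_len(nv), j = seq_len(nv), x = 1,
                              dims = c(nv, nv))
  blocks <- list(lp$A, eye[has_ub, , drop = FALSE],
                 eye[has_lb, , drop = FALSE])
  blocks <- blocks[!vapply(blocks, is.null, FALSE)]
  A2 <- do.call(rbind, blocks)
  sense2 <- c(lp$sense, rep("L", sum(has_ub)), rep("G", sum(has_lb)))
  rhs2 <- c(lp$rhs, lp$vars$ub[has_ub], lp$vars$lb[has_lb])
  row_ids2 <- c(lp$row_ids,
                paste0("ub_", lp$vars$id[has_ub]),
                paste0("lb_", lp$vars$id[has_lb]))
  vars2 <- lp$vars
  vars2$lb <- -Inf
  vars2$ub <- Inf
  linear_program(vars2, A2, sense2, rhs2, lp$objective, row_ids = row_ids2)
}

#' LP dual of a maximization program
#'
#' Finite variable bounds are first lifted into explicit constraint rows, so
#' the primal has the uniform shape `max c'x  s.t.  A x {=,<=,>=} b`, `x`
#' free.  The dual is then `min b'y  s.t.  A'y = c` with `y` free on equality
#' rows, `y >= 0` on `<=` rows and `y <= 0` on `>=` rows.  For every feasible
#' bounded primal the two optima coincide (strong duality).
#'
#' @param lp A `linear_program` with `objective$sense == "max"`.
#' @return A `dual_program` (subclass of `linear_program`, `min` sense); the
#'   mapping from dual variables to primal rows is in `attr(, "row_map")`.
#' @export
dualize <- function(lp) {
  if (lp$objective$sense != "max")
    stop("dualize() expects a maximization problem")
  p <- lift_bounds(lp)
  dv <- data.frame(id = paste0("dual_", p$row_ids),
                   lb = ifelse(p$sense == "L", 0, -Inf),
                   ub = ifelse(p$sense == "G", 0, Inf))
  cvec <- objective_vector(p)
  dual <- linear_program(
    vars = dv,
    A = Matrix::t(p$A),
    sense = rep("E", n_vars(p)),
    rhs = cvec,
    objective = list(coef = stats::setNames(p$rhs, dv$id),
                     sense = "min"),
    row_ids = paste0("dfeas_", p$vars$id))
  attr(dual, "row_map") <- data.frame(dual_var = dv$id,
                                      primal_row = p$row_ids,
                                      sense = p$sense)
  class(dual) <- c("dual_program", "linear_program")
  dual
}

#' Export a linear program in CPLEX LP text format
#'
#' Debugging aid: the file is readable by independent solvers (GLPK, HiGHS,
#' CPLEX).  Integer variables can be declared via `integer_ids`.
#'
#' @param lp A `linear_program`.
#' @param path Output file.
#' @param integer_ids Variable ids to list in the `General` integer section.
#' @return `path`, invisibly.
#' @export
write_lp <- function(lp, path, integer_ids = character()) {
  term_str <- function(coef, ids) {
    stopifnot(length(coef) == length(ids))
    if (!length(coef)) return("0 ")
    paste0(ifelse(coef < 0, "- ", "+ "), abs(coef), " ", ids,
           collapse = " ")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("\\ written by optcoupleR",
               if (lp$objective$sense == "max") "Maximize" else "Minimize"),
             con)
  oc <- lp$objective$coef[lp$objective$coef != 0]
  writeLines(paste0(" obj: ", term_str(unname(oc), names(oc))), con)
  writeLines("Subject To", con)
  if (!is.null(lp$A) && nrow(lp$A) > 0) {
    Tm <- methods::as(lp$A, "TsparseMatrix")
    rows <- split(data.frame(j = Tm@j + 1L, x = Tm@x), Tm@i + 1L)
    op <- c(E = "=", L = "<=", G = ">=")
    for (r in seq_along(lp$rhs)) {
      tab <- rows[[as.character(r)]]
      lhs <- if (is.null(tab)) "0 " else
        term_str(tab$x, lp$vars$id[tab$j])
      writeLines(paste0(" ", lp$row_ids[r], ": ", lhs, " ",
                        op[[lp$sense[r]]], " ", lp$rhs[r]), con)
    }
  }
  writeLines("Bounds", con)
  for (k in seq_len(n_vars(lp))) {
    lb <- lp$vars$lb[k]; ub <- lp$vars$ub[k]
    id <- lp$vars$id[k]
    line <- if (!is.finite(lb) && !is.finite(ub)) paste0(" ", id, " free")
    else if (!is.finite(lb)) paste0(" -inf <= ", id, " <= ", ub)
    else if (!is.finite(ub)) paste0(" ", lb, " <= ", id, " <= +inf")
    else paste0(" ", lb, " <= ", id, " <= ", ub)
    writeLines(line, con)
  }
  if (length(integer_ids)) {
    writeLines("General", con)
    writeLines(paste0(" ", paste(integer_ids, collapse = " ")), con)
  }
  writeLines("End", con)
  invisible(path)
}
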