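# -- model, design and configuration I/O -------------------------------------

INF_SURROGATE <- 1000

#' Load a metabolic model
#'
#' Reads a genome-scale model from COBRA JSON or SBML Level 3 (fbc).  Reaction
#' kinds are inferred on load: single-metabolite boundary reactions become
#' `"exchange"` (`EX_`/`SK_` prefixes), `"demand"` (`DM_` prefix) or
#' `"exchange"` otherwise; the declared objective reaction becomes
#' `"biomass"`; everything else is `"native"`.  Infinite bounds are replaced
#' by the finite surrogate +/-1000 mmol/gDW/h.
#'
#' @param path Model file (`.json`, `.xml`, `.sbml`, optionally gzipped SBML).
#' @param format `"sbml"`, `"cobra-json"` or `"auto"` (by extension).
#' @return A [metabolic_network()].
#' @export
load_model <- function(path, format = c("auto", "cobra-json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE))
      "cobra-json" else "sbml"
  }
  switch(format,
         "cobra-json" = load_cobra_json(path),
         "sbml" = load_sbml(path))
}

clamp_bound <- function(x) {
  x[!is.finite(x)] <- sign(x[!is.finite(x)]) * INF_SURROGATE
  pmin(pmax(x, -INF_SURROGATE * 1e6), INF_SURROGATE * 1e6)
}

infer_kind <- function(id, stoich, is_objective) {
  if (is_objective) return("biomass")
  if (length(stoich) <= 1L) {
    if (grepl("^DM_", id)) return("demand")
    return("exchange")
  }
  "native"
}

load_cobra_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("failed to parse COBRA JSON '", path, "': ",
                         conditionMessage(e)))
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("COBRA JSON '", path, "' lacks metabolites/reactions")
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) m$id, ""),
    compartment = vapply(doc$metabolites, function(m) {
      cp <- m$compartment
      if (is.null(cp) || !nzchar(cp))
        cp <- sub("^.*_([a-zA-Z0-9]+)$", "\\1", m$id)
      if (!nzchar(cp) || cp == m$id) cp <- "c"
      cp
    }, ""))
  objective_ids <- character(0)
  rxns <- vector("list", length(doc$reactions))
  for (k in seq_along(doc$reactions)) {
    r <- doc$reactions[[k]]
    st <- unlist(r$metabolites)
    if (is.null(st)) st <- stats::setNames(numeric(0), character(0))
    oc <- if (is.null(r$objective_coefficient)) 0 else r$objective_coefficient
    if (oc != 0) objective_ids <- c(objective_ids, r$id)
    lb <- clamp_bound(if (is.null(r$lower_bound)) -INF_SURROGATE else
      as.numeric(r$lower_bound))
    ub <- clamp_bound(if (is.null(r$upper_bound)) INF_SURROGATE else
      as.numeric(r$upper_bound))
    rxns[[k]] <- reaction(r$id, st, lb, ub,
                          kind = infer_kind(r$id, st, oc != 0))
  }
  if (length(objective_ids) != 1L)
    stop("model '", path, "' must declare exactly one objective reaction, ",
         "found ", length(objective_ids))
  name <- if (!is.null(doc$id)) doc$id else basename(path)
  metabolic_network(name, mets, rxns, biomass_id = objective_ids)
}

#' Write a network as COBRA JSON
#'
#' Round-trip companion of [load_model()]: stoichiometry, bounds and the
#' objective survive a write/load cycle.
#'
#' @param network A `metabolic_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(network, path) {
  mets <- lapply(seq_len(nrow(network$metabolites)), function(i)
    list(id = jsonlite::unbox(network$metabolites$id[i]),
         compartment = jsonlite::unbox(network$metabolites$compartment[i])))
  rxns <- lapply(network$reactions, function(r) {
    st <- as.list(r$stoich)
    names(st) <- names(r$stoich)
    list(id = jsonlite::unbox(r$id),
         metabolites = lapply(st, jsonlite::unbox),
         lower_bound = jsonlite::unbox(r$lb),
         upper_bound = jsonlite::unbox(r$ub),
         objective_coefficient =
           jsonlite::unbox(if (r$id == network$biomass_id) 1 else 0))
  })
  comps <- unique(network$metabolites$compartment)
  doc <- list(id = jsonlite::unbox(network$name), metabolites = mets,
              reactions = unname(rxns), genes = list(),
              compartments = stats::setNames(
                lapply(comps, jsonlite::unbox), comps))
  jsonlite::write_json(doc, path, digits = NA, null = "null")
  invisible(path)
}

# -- designs ------------------------------------------------------------------

#' Construct a strain design
#'
#' A candidate strategy: sets of reaction knockouts, heterologous insertions
#' and medium supplements, together with evaluated metrics (filled by
#' [verify_design()]).
#'
#' @param knockouts,insertions,supplements Character vectors of reaction ids
#'   (supplements are exchange reaction ids).
#' @param U Growth-coupling potential (1/h) if already evaluated.
#' @return A `strain_design` object.
#' @export
design <- function(knockouts = character(), insertions = character(),
                   supplements = character(), U = NA_real_) {
  structure(list(knockouts = sort(unique(as.character(knockouts))),
                 insertions = sort(unique(as.character(insertions))),
                 supplements = sort(unique(as.character(supplements))),
                 U = U,
                 growth_at_optimum = NA_real_,
                 production_at_optimum_min = NA_real_,
                 production_at_optimum_max = NA_real_,
                 yield_at_optimum = NA_real_,
                 verified = FALSE,
                 minimal = NA),
            class = "strain_design")
}

#' @export
print.strain_design <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "-"
  cat("<strain_design> KO: ", fmt(x$knockouts),
      " | IN: ", fmt(x$insertions),
      " | SUP: ", fmt(x$supplements), "\n", sep = "")
  if (!is.na(x$U))
    cat("  U = ", signif(x$U, 6), " 1/h",
        if (isTRUE(x$verified)) " (verified)" else "", "\n", sep = "")
  invisible(x)
}

design_size <- function(d)
  length(d$knockouts) + length(d$insertions) + length(d$supplements)

design_key <- function(d)
  paste(paste(d$knockouts, collapse = ","),
        paste(d$insertions, collapse = ","),
        paste(d$supplements, collapse = ","), sep = "|")

#' Read / write a design file
#'
#' Designs are stored as JSON objects with `knockouts`, `insertions` and
#' `supplements` id arrays.  Unknown ids are flagged at verification time,
#' not at load time.  `write_design(read_design(p))` is the identity.
#'
#' @param path JSON file.
#' @return A `strain_design`.
#' @export
read_design <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  design(knockouts = as.character(doc$knockouts %||% character()),
         insertions = as.character(doc$insertions %||% character()),
         supplements = as.character(doc$supplements %||% character()))
}

#' @rdname read_design
#' @param x A `strain_design`.
#' @export
write_design <- function(x, path) {
  jsonlite::write_json(list(knockouts = x$knockouts,
                            insertions = x$insertions,
                            supplements = x$supplements),
                       path, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- run configuration --------------------------------------------------------

#' Run configuration
#'
#' Collects the tunables of a growth-coupling search.  Defaults follow common
#' aerobic glucose minimal-medium practice: glucose uptake capped at 10 and
#' oxygen at 1000 mmol/gDW/h; supplement uptake, when a supplement binary is
#' switched on, is capped at 10 mmol/gDW/h (a knob, deliberately prominent).
#'
#' @param target_reaction Id of the production target reaction.
#' @param max_knockouts,max_insertions,max_supplements Modification limits
#'   (K_ko, K_ins, K_sup).
#' @param carbon_exchange,oxygen_exchange Exchange reaction ids used by
#'   [apply_medium()]; `NULL` skips the corresponding bound.
#' @param carbon_uptake_bound,oxygen_uptake_bound,supplement_uptake_bound
#'   Uptake caps in mmol/gDW/h.
#' @param coupling_epsilon Growth-rate tolerance below which a design does
#'   not count as growth-coupled (1/h).
#' @param big_M Box bound for dual multipliers and big-M linearization rows.
#' @param time_limit_s Wall-time cap for one MILP solve.
#' @param pool_time_factor Budget for solution-pool harvesting, as a multiple
#'   of the first solve's running time.
#' @param pool_max Maximum number of pooled integer solutions per run.
#' @param n_runs Number of seeded solver runs whose pools are united.
#' @param seed Integer seed (drives variable-order permutation across runs).
#' @return A `run_config` list.
#' @export
run_config <- function(target_reaction = NULL,
                       max_knockouts = 0L, max_insertions = 0L,
                       max_supplements = 0L,
                       carbon_exchange = NULL, oxygen_exchange = NULL,
                       carbon_uptake_bound = 10,
                       oxygen_uptake_bound = 1000,
                       supplement_uptake_bound = 10,
                       coupling_epsilon = 1e-6,
                       big_M = 1000,
                       time_limit_s = 600,
                       pool_time_factor = 10,
                       pool_max = 20L,
                       n_runs = 1L,
                       seed = 1L) {
  cfg <- list(target_reaction = target_reaction,
              max_knockouts = as.integer(max_knockouts),
              max_insertions = as.integer(max_insertions),
              max_supplements = as.integer(max_supplements),
              carbon_exchange = carbon_exchange,
              oxygen_exchange = oxygen_exchange,
              carbon_uptake_bound = as.numeric(carbon_uptake_bound),
              oxygen_uptake_bound = as.numeric(oxygen_uptake_bound),
              supplement_uptake_bound = as.numeric(supplement_uptake_bound),
              coupling_epsilon = as.numeric(coupling_epsilon),
              big_M = as.numeric(big_M),
              time_limit_s = as.numeric(time_limit_s),
              pool_time_factor = as.numeric(pool_time_factor),
              pool_max = as.integer(pool_max),
              n_runs = as.integer(n_runs),
              seed = as.integer(seed))
  stopifnot(cfg$max_knockouts >= 0, cfg$max_insertions >= 0,
            cfg$max_supplements >= 0,
            cfg$carbon_uptake_bound > 0, cfg$oxygen_uptake_bound > 0,
            cfg$supplement_uptake_bound > 0,
            cfg$coupling_epsilon > 0, cfg$coupling_epsilon < 1e-2,
            cfg$big_M > 0, cfg$time_limit_s > 0, cfg$pool_time_factor >= 1,
            cfg$pool_max >= 1, cfg$n_runs >= 1)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' The file holds a flat mapping of [run_config()] fields; missing fields
#' take their defaults.
#'
#' @param path Configuration file (`.json`, `.yml`/`.yaml`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}
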