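# -- the universe of allowed modifications -----------------------------------

#' Knockout candidate reactions
#'
#' All native internal reactions minus the biomass reaction, target
#' reactions, boundary reactions (exchanges, demands, sinks), ATP maintenance
#' and user exclusions.  ATP maintenance is recognised by id (`ATPM*`) or by
#' a strictly positive lower bound (a forced flux can never be knocked out
#' without killing the model).
#'
#' @param network A `metabolic_network`.
#' @param exclusions Additional reaction ids to exclude.
#' @return Character vector of reaction ids.
#' @export
knockout_candidates <- function(network, exclusions = character()) {
  keep <- vapply(network$reactions, function(r) {
    r$kind == "native" &&
      !is_boundary_reaction(r) &&
      r$lb <= 0 &&
      !grepl("^ATPM", r$id)
  }, FALSE)
  ids <- names(network$reactions)[keep]
  sort(setdiff(ids, c(exclusions, network$biomass_id,
                      target_reactions(network))))
}

#' Load a universal (heterologous) reaction pool
#'
#' Reads a model-like COBRA JSON file of candidate reactions.  Entries whose
#' ids collide with native reaction ids are dropped; duplicates with
#' identical stoichiometry up to positive scaling are deduplicated (first id
#' wins, ids sorted).  When `bigg_filter` is on and the pool carries
#' annotations, only entries with a BiGG cross-reference are kept; a pool
#' without annotations degrades gracefully with a warning and no filtering.
#'
#' @param path Pool file (COBRA JSON; the objective requirement is waived).
#' @param network Host network whose ids define collisions.
#' @param bigg_filter Restrict to entries carrying a BiGG cross-reference.
#' @return Named list of [reaction()]s with kind `"heterologous"`.
#' @export
load_universal_pool <- function(path, network, bigg_filter = FALSE) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("failed to parse pool '", path, "': ",
                         conditionMessage(e)))
  if (is.null(doc$reactions))
    stop("pool '", path, "' lacks a reactions list")
  entries <- doc$reactions
  if (bigg_filter) {
    has_ann <- vapply(entries, function(r)
      !is.null(r$annotation) && length(r$annotation) > 0, FALSE)
    if (!any(has_ann)) {
      warning("pool carries no annotations; BiGG filter not applied")
    } else {
      entries <- Filter(function(r)
        !is.null(r$annotation) &&
          any(grepl("bigg", names(r$annotation), ignore.case = TRUE)),
        entries)
    }
  }
  rxns <- lapply(entries, function(r) {
    st <- unlist(r$metabolites)
    if (is.null(st)) st <- stats::setNames(numeric(0), character(0))
    reaction(r$id, st,
             clamp_bound(as.numeric(r$lower_bound %||% 0)),
             clamp_bound(as.numeric(r$upper_bound %||% INF_SURROGATE)),
             kind = "heterologous")
  })
  names(rxns) <- vapply(rxns, `[[`, "", "id")
  rxns <- rxns[!names(rxns) %in% reaction_ids(network)]
  rxns <- rxns[order(names(rxns))]
  # dedup identical stoichiometry up to positive scaling
  canon <- vapply(rxns, function(r) {
    st <- r$stoich[order(names(r$stoich))]
    if (!length(st)) return(r$id)
    st <- st / abs(st[[1]])
    paste(names(st), signif(st, 10), sep = ":", collapse = ";")
  }, "")
  rxns[!duplicated(canon)]
}

#' Prune a heterologous pool by metabolite reachability
#'
#' Iterative expansion over at most `k` rounds (the number of allowed
#' insertions).  A pool reaction is admitted in a round when every metabolite
#' it can consume is native to the host or producible by previously admitted
#' pool reactions; for reversible reactions every metabolite counts as
#' consumable (and producible), a deliberately conservative superset so the
#' pruning never excludes a feasible insertion.  `k = 0` returns an empty
#' pool; `k = 1` restricts to reactions whose substrates are native host
#' metabolites.
#'
#' @param pool Named list of [reaction()]s (from [load_universal_pool()]).
#' @param network Host network.
#' @param k Number of allowed insertions (non-negative).
#' @return The admitted sublist, with `attr(, "round")` giving the round in
#'   which each survivor entered.
#' @export
prune_universal_pool <- function(pool, network, k) {
  stopifnot(k >= 0)
  if (k == 0 || length(pool) == 0)
    return(structure(pool[integer(0)], round = integer(0)))
  consumable <- lapply(pool, function(r) {
    if (r$lb < 0 && r$ub > 0) names(r$stoich)
    else if (r$ub > 0) names(r$stoich)[r$stoich < 0]
    else names(r$stoich)[r$stoich > 0]
  })
  producible <- lapply(pool, function(r) {
    if (r$lb < 0 && r$ub > 0) names(r$stoich)
    else if (r$ub > 0) names(r$stoich)[r$stoich > 0]
    else names(r$stoich)[r$stoich < 0]
  })
  reached <- network$metabolites$id
  kept <- character(0)
  entered <- integer(0)
  for (round in seq_len(k)) {
    new <- names(pool)[!names(pool) %in% kept &
                         vapply(seq_along(pool), function(j)
                           all(consumable[[j]] %in% reached), FALSE)]
    if (!length(new)) break
    kept <- c(kept, new)
    entered <- c(entered, rep.int(round, length(new)))
    reached <- union(reached, unlist(producible[new]))
  }
  structure(pool[kept], round = stats::setNames(entered, kept))
}

#' Supplement exchange candidates
#'
#' Maps a list of metabolite ids (compartment suffix optional) to the
#' exchange reactions that take them up.  Metabolites without an exchange in
#' the network are reported and skipped; an entirely empty result for a
#' non-empty request raises a warning, not an error.
#'
#' @param network A `metabolic_network`.
#' @param metabolite_list Metabolite ids, e.g. `"glu__L"` or `"glu__L_e"`.
#'   Defaults to [default_supplements()].
#' @return Character vector of exchange reaction ids, named by metabolite;
#'   skipped metabolites in `attr(, "missing")`.
#' @export
supplement_candidates <- function(network,
                                  metabolite_list = default_supplements()) {
  exch <- Filter(function(r)
    r$kind == "exchange" && length(r$stoich) == 1L, network$reactions)
  exch_met <- vapply(exch, function(r) names(r$stoich), "")
  strip <- function(x) sub("_[a-zA-Z0-9]+$", "", x)
  found <- stats::setNames(character(0), character(0))
  missing <- character(0)
  for (met in metabolite_list) {
    hit <- names(exch_met)[exch_met == met]
    if (!length(hit)) # tolerate missing compartment suffix: match base id
      hit <- names(exch_met)[strip(exch_met) == strip(met) &
                               grepl("_e$", exch_met)]
    if (length(hit)) {
      found[met] <- hit[1]
    } else {
      missing <- c(missing, met)
    }
  }
  if (length(missing))
    message("no exchange found for: ", paste(missing, collapse = ", "))
  if (!length(found) && length(metabolite_list))
    warning("none of the requested supplements has an exchange reaction")
  structure(found, missing = missing)
}

#' Default supplement list
#'
#' Fructose, lactate, acetate and the 20 proteinogenic L-amino acids, as BiGG
#' extracellular metabolite ids (lactate as D-lactate, the fermentation
#' product of *E. coli*).
#'
#' @return Character vector of 23 metabolite ids.
#' @export
default_supplements <- function() {
  c("fru_e", "lac__D_e", "ac_e",
    "ala__L_e", "arg__L_e", "asn__L_e", "asp__L_e", "cys__L_e",
    "gln__L_e", "glu__L_e", "gly_e", "his__L_e", "ile__L_e",
    "leu__L_e", "lys__L_e", "met__L_e", "phe__L_e", "pro__L_e",
    "ser__L_e", "thr__L_e", "trp__L_e", "tyr__L_e", "val__L_e")
}

#' Assemble a design space
#'
#' The candidate modification universe with its cardinality limits.
#'
#' @param network A `metabolic_network` (target already added).
#' @param config A [run_config()] carrying the limits.
#' @param knockouts Knockout candidate ids (default
#'   [knockout_candidates()]).
#' @param pool Heterologous pool, already pruned to
#'   `config$max_insertions` rounds (default: pruned empty pool).
#' @param supplements Supplement exchange reaction ids.
#' @return A `design_space` object.
#' @export
design_space <- function(network, config,
                         knockouts = knockout_candidates(network),
                         pool = list(),
                         supplements = character()) {
  supplements <- unname(supplements)
  stopifnot(all(knockouts %in% reaction_ids(network)),
            all(supplements %in% reaction_ids(network)))
  if (length(pool)) {
    if (any(names(pool) %in% reaction_ids(network)))
      stop("insertion pool ids collide with native reaction ids")
  }
  bad_sup <- supplements[!vapply(network$reactions[supplements],
                                 function(r) r$kind == "exchange", FALSE)]
  if (length(bad_sup))
    stop("supplement candidate(s) are not exchange reactions: ",
         paste(bad_sup, collapse = ", "))
  structure(list(knockout_candidates = sort(knockouts),
                 insertion_pool = pool,
                 supplement_candidates = sort(supplements),
                 limits = c(K_ko = config$max_knockouts,
                            K_ins = config$max_insertions,
                            K_sup = config$max_supplements)),
            class = "design_space")
}

#' @export
print.design_space <- function(x, ...) {
  cat("<design_space> ", length(x$knockout_candidates), " KO candidates, ",
      length(x$insertion_pool), " insertion candidates, ",
      length(x$supplement_candidates), " supplement candidates; limits (",
      paste(x$limits, collapse = ", "), ")\n", sep = "")
  invisible(x)
}
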