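# -- metabolic network container ---------------------------------------------

#' Construct a reaction
#'
#' A reaction is a named stoichiometry vector (negative coefficients =
#' consumed), flux bounds in mmol/gDW/h and a kind tag.  Exchange, demand and
#' target reactions are written in single-metabolite form (`met -> nothing`);
#' negative flux through an exchange denotes uptake.
#'
#' @param id Reaction identifier (unique within a network).
#' @param stoich Named numeric vector of metabolite coefficients.
#' @param lb,ub Lower/upper flux bound.
#' @param kind One of `"native"`, `"heterologous"`, `"exchange"`, `"demand"`,
#'   `"biomass"`, `"target"`.
#' @return A `reaction` object.
#' @export
reaction <- function(id, stoich, lb, ub,
                     kind = c("native", "heterologous", "exchange", "demand",
                              "biomass", "target")) {
  kind <- match.arg(kind)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoich) == 0L && !kind %in% c("exchange", "demand", "target"))
    stop("reaction '", id, "': empty stoichiometry only allowed for sinks")
  if (is.null(names(stoich)) && length(stoich) > 0L)
    stop("reaction '", id, "': stoichiometry must be a named vector")
  if (lb > ub)
    stop("reaction '", id, "': lower bound ", lb, " exceeds upper bound ", ub)
  structure(list(id = id, stoich = stoich, lb = as.numeric(lb),
                 ub = as.numeric(ub), kind = kind),
            class = "reaction")
}

#' Construct a metabolic network
#'
#' @param name Network name.
#' @param metabolites `data.frame` with columns `id` and `compartment`.
#' @param reactions List of [reaction()] objects (exactly one of kind
#'   `"biomass"`).
#' @param biomass_id Identifier of the biomass reaction; defaults to the
#'   single reaction of kind `"biomass"`.
#' @return A `metabolic_network` object.
#' @export
metabolic_network <- function(name, metabolites, reactions, biomass_id = NULL) {
  stopifnot(is.data.frame(metabolites),
            all(c("id", "compartment") %in% names(metabolites)))
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  net <- structure(list(name = name,
                        metabolites = metabolites[c("id", "compartment")],
                        reactions = reactions,
                        biomass_id = biomass_id),
                   class = "metabolic_network")
  if (is.null(biomass_id)) {
    bm <- names(reactions)[vapply(reactions, function(r) r$kind == "biomass",
                                  FALSE)]
    if (length(bm) != 1L)
      stop("network must declare exactly one biomass reaction, found ",
           length(bm))
    net$biomass_id <- bm
  }
  validate_network(net)
  net
}

#' Validate network invariants
#'
#' Checks id uniqueness, stoichiometry resolution, bound ordering and the
#' presence of exactly one biomass reaction.
#'
#' @param network A `metabolic_network`.
#' @return The network, invisibly; errors on violation.
#' @export
validate_network <- function(network) {
  mets <- network$metabolites$id
  if (anyDuplicated(mets))
    stop("duplicate metabolite ids: ",
         paste(unique(mets[duplicated(mets)]), collapse = ", "))
  rids <- names(network$reactions)
  if (anyDuplicated(rids))
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  if (any(!nzchar(network$metabolites$compartment)))
    stop("empty compartment tag")
  for (r in network$reactions) {
    unknown <- setdiff(names(r$stoich), mets)
    if (length(unknown))
      stop("reaction '", r$id, "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    if (r$lb > r$ub)
      stop("reaction '", r$id, "': lb > ub")
  }
  if (!network$biomass_id %in% rids)
    stop("biomass reaction '", network$biomass_id, "' not present")
  invisible(network)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", x$name, ": ",
      nrow(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions; biomass = ", x$biomass_id, "\n",
      sep = "")
  invisible(x)
}

#' Sparse stoichiometric matrix
#'
#' One row per metabolite, one column per reaction.
#'
#' @param network A `metabolic_network`.
#' @return A `dgCMatrix` with dimnames (metabolite ids, reaction ids).
#' @export
stoichiometric_matrix <- function(network) {
  mets <- network$metabolites$id
  rids <- names(network$reactions)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in seq_along(network$reactions)) {
    st <- network$reactions[[k]]$stoich
    if (!length(st)) next
    ii <- c(ii, match(names(st), mets))
    jj <- c(jj, rep.int(k, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mets), length(rids)),
                       dimnames = list(mets, rids))
}

reaction_ids <- function(network) names(network$reactions)

is_boundary_reaction <- function(r) {
  length(r$stoich) <= 1L || r$kind %in% c("exchange", "demand", "target")
}

#' Find the target reaction(s) of a network
#'
#' @param network A `metabolic_network`.
#' @return Character vector of reaction ids with kind `"target"`.
#' @export
target_reactions <- function(network) {
  names(network$reactions)[vapply(network$reactions,
                                  function(r) r$kind == "target", FALSE)]
}

#' Set flux bounds of a reaction
#'
#' @param network A `metabolic_network`.
#' @param id Reaction id.
#' @param lb,ub New bounds (either may be `NULL` to keep the current value).
#' @return The modified network.
#' @export
set_bounds <- function(network, id, lb = NULL, ub = NULL) {
  if (!id %in% names(network$reactions))
    stop("unknown reaction id: ", id)
  if (!is.null(lb)) network$reactions[[id]]$lb <- as.numeric(lb)
  if (!is.null(ub)) network$reactions[[id]]$ub <- as.numeric(ub)
  if (network$reactions[[id]]$lb > network$reactions[[id]]$ub)
    stop("reaction '", id, "': lb > ub after update")
  network
}

#' Add a reaction to a network
#'
#' @param network A `metabolic_network`.
#' @param rxn A [reaction()].
#' @param allow_new_metabolites Add metabolites referenced by `rxn` that are
#'   not yet declared (compartment inferred from a trailing `_<tag>` id
#'   suffix, else `"c"`).  Used when inserting heterologous reactions.
#' @return The extended network.
#' @export
add_reaction <- function(network, rxn, allow_new_metabolites = FALSE) {
  if (rxn$id %in% names(network$reactions))
    stop("reaction id already present: ", rxn$id)
  new_mets <- setdiff(names(rxn$stoich), network$metabolites$id)
  if (length(new_mets)) {
    if (!allow_new_metabolites)
      stop("reaction '", rxn$id, "' references undeclared metabolite(s): ",
           paste(new_mets, collapse = ", "))
    comp <- sub("^.*_([a-zA-Z0-9]+)$", "\\1", new_mets)
    comp[comp == new_mets] <- "c"
    network$metabolites <- rbind(network$metabolites,
                                 data.frame(id = new_mets, compartment = comp))
  }
  network$reactions[[rxn$id]] <- rxn
  network
}

# -- spec-level operations ----------------------------------------------------

#' Append a demand reaction and mark it as the production target
#'
#' Adds an irreversible drain `metabolite -> nothing` with bounds
#' `[0, inf_surrogate]` and kind `"target"`.  Pre-existing reactions are never
#' modified, and no deduplication is attempted if the metabolite already has a
#' boundary reaction.
#'
#' @param network A `metabolic_network`.
#' @param metabolite_id Metabolite to drain.
#' @param id Id of the new reaction (default `DM_<metabolite>`).
#' @param inf_surrogate Finite stand-in for an open upper bound.
#' @return The network with the demand appended; the new id is stored in
#'   `attr(, "target_id")`.
#' @export
add_target_demand <- function(network, metabolite_id,
                              id = paste0("DM_", metabolite_id),
                              inf_surrogate = 1000) {
  if (!metabolite_id %in% network$metabolites$id)
    stop("unknown metabolite: ", metabolite_id)
  rxn <- reaction(id, stats::setNames(-1, metabolite_id), 0, inf_surrogate,
                  kind = "target")
  network <- add_reaction(network, rxn)
  attr(network, "target_id") <- id
  network
}

#' Apply growth-medium bounds
#'
#' Sets the carbon-source uptake to `-carbon_uptake_bound`, oxygen uptake to
#' `-oxygen_uptake_bound` and closes every supplement exchange to uptake
#' (lower bound 0) so that uptake is only opened by the corresponding
#' supplement binary (or by [apply_design()]).  Idempotent.
#'
#' @param network A `metabolic_network`.
#' @param config A [run_config()]; `carbon_exchange` / `oxygen_exchange` name
#'   the exchange reactions (skipped when `NULL`).
#' @param supplement_exchanges Exchange reaction ids to close to uptake.
#' @return The modified network.
#' @export
apply_medium <- function(network, config, supplement_exchanges = character()) {
  close_uptake <- function(net, id) {
    net$reactions[[id]]$lb <- max(net$reactions[[id]]$lb, 0)
    net
  }
  for (nm in c("carbon_exchange", "oxygen_exchange")) {
    ex <- config[[nm]]
    if (is.null(ex)) next
    if (!ex %in% names(network$reactions))
      stop("configured ", nm, " '", ex, "' not present in network")
    bound <- if (nm == "carbon_exchange") config$carbon_uptake_bound else
      config$oxygen_uptake_bound
    network$reactions[[ex]]$lb <- -bound
  }
  for (ex in supplement_exchanges) {
    if (!ex %in% names(network$reactions))
      stop("supplement exchange '", ex, "' not present in network")
    network <- close_uptake(network, ex)
  }
  network
}

#' Apply a design (knockouts, insertions, supplements) to a network
#'
#' Knockouts close both flux bounds to zero; insertions add the named pool
#' reactions (new metabolites allowed); supplements open exchange uptake to
#' `-config$supplement_uptake_bound`.
#'
#' @param network A `metabolic_network`.
#' @param design A [design()].
#' @param pool Named list of heterologous [reaction()]s for resolving
#'   insertions.
#' @param config A [run_config()] (supplies the supplement uptake bound).
#' @return The modified network.
#' @export
apply_design <- function(network, design, pool = NULL, config = run_config()) {
  bad <- setdiff(design$knockouts, names(network$reactions))
  if (length(bad))
    stop("design knockout(s) not in network: ", paste(bad, collapse = ", "))
  for (id in design$knockouts)
    network <- set_bounds(network, id, 0, 0)
  if (length(design$insertions)) {
    pool_ids <- vapply(pool, `[[`, "", "id")
    bad <- setdiff(design$insertions, pool_ids)
    if (length(bad))
      stop("design insertion(s) not in pool: ", paste(bad, collapse = ", "))
    for (id in design$insertions)
      network <- add_reaction(network, pool[[match(id, pool_ids)]],
                              allow_new_metabolites = TRUE)
  }
  bad <- setdiff(design$supplements, names(network$reactions))
  if (length(bad))
    stop("design supplement(s) not in network: ", paste(bad, collapse = ", "))
  for (id in design$supplements)
    network <- set_bounds(network, id,
                          lb = -config$supplement_uptake_bound)
  network
}
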