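# -- SBML Level 3 (fbc) reader -----------------------------------------------
#
# Minimal, read-only support for the subset of SBML L3 + fbc that COBRA-style
# genome-scale reconstructions use: listOfSpecies / listOfReactions with
# speciesReference stoichiometries, flux bounds as fbc attributes referencing
# global parameters, and the active fbc objective.  Identifiers keep the
# community convention of stripping the "M_"/"R_" SBML prefixes so reaction
# ids match their BiGG names.  Gzipped files are handled transparently by
# libxml2.

load_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("failed to parse SBML '", path, "': ",
                         conditionMessage(e)))
  ns <- xml2::xml_ns(doc)
  if (!any(grepl("fbc", names(ns))))
    stop("SBML file '", path, "' lacks the fbc package; flux bounds and the ",
         "objective cannot be recovered")
  fbc <- names(ns)[grepl("^fbc", names(ns))][1]
  a <- function(nodes, attr) xml2::xml_attr(nodes, attr)

  strip_prefix <- function(x, prefix) sub(paste0("^", prefix, "_"), "", x)

  # global parameters (flux bound values)
  pars <- xml2::xml_find_all(doc, ".//d1:listOfParameters/d1:parameter", ns)
  par_val <- stats::setNames(as.numeric(a(pars, "value")), a(pars, "id"))

  sp <- xml2::xml_find_all(doc, ".//d1:listOfSpecies/d1:species", ns)
  sp_id_raw <- a(sp, "id")
  boundary <- a(sp, "boundaryCondition") %in% "true"
  mets <- data.frame(id = strip_prefix(sp_id_raw[!boundary], "M"),
                     compartment = a(sp, "compartment")[!boundary])
  met_lookup <- stats::setNames(mets$id, sp_id_raw[!boundary])

  rx <- xml2::xml_find_all(doc, ".//d1:listOfReactions/d1:reaction", ns)
  rx_id_raw <- a(rx, "id")
  rx_id <- strip_prefix(rx_id_raw, "R")
  # xml2 exposes attribute local names without their namespace prefix
  lb_ref <- a(rx, "lowerFluxBound")
  ub_ref <- a(rx, "upperFluxBound")
  lbs <- clamp_bound(unname(par_val[lb_ref]))
  ubs <- clamp_bound(unname(par_val[ub_ref]))
  if (anyNA(lbs) || anyNA(ubs))
    stop("SBML '", path, "': unresolved flux-bound parameter reference")

  # stoichiometry, vectorized: reactions, their reactant/product lists and
  # the speciesReference nodes all come back in document order, so each list
  # maps to the most recent reaction (cumsum) and each reference to its list
  # (child counts).  xml_parent() cannot be used here: it deduplicates.
  mix <- xml2::xml_find_all(
    doc, paste0(".//d1:reaction | .//d1:reaction/d1:listOfReactants",
                " | .//d1:reaction/d1:listOfProducts"), ns)
  mix_name <- xml2::xml_name(mix)
  owner_rxn <- cumsum(mix_name == "reaction")[mix_name != "reaction"]
  lists <- mix[mix_name != "reaction"]
  sign <- ifelse(xml2::xml_name(lists) == "listOfReactants", -1, 1)
  n_child <- xml2::xml_length(lists)
  srefs <- xml2::xml_find_all(
    doc, ".//d1:listOfReactions//d1:speciesReference", ns)
  stopifnot(length(srefs) == sum(n_child))
  sref_tab <- data.frame(
    rxn = rep.int(owner_rxn, n_child),
    sp = a(srefs, "species"),
    coef = rep.int(sign, n_child) *
      ifelse(is.na(as.numeric(a(srefs, "stoichiometry"))), 1,
             as.numeric(a(srefs, "stoichiometry"))))
  sref_tab <- sref_tab[sref_tab$sp %in% names(met_lookup), , drop = FALSE]
  by_rxn <- split(sref_tab[c("sp", "coef")], sref_tab$rxn)
  rxn_stoich <- function(k) {
    tab <- by_rxn[[as.character(k)]]
    if (is.null(tab) || !nrow(tab))
      return(stats::setNames(numeric(0), character(0)))
    agg <- tapply(tab$coef, unname(met_lookup[tab$sp]), sum)
    stats::setNames(as.numeric(agg), names(agg))
  }

  # active objective
  obj_nodes <- xml2::xml_find_all(
    doc, paste0(".//", fbc, ":listOfObjectives//", fbc, ":fluxObjective"), ns)
  obj_rxn <- a(obj_nodes, "reaction")
  obj_coef <- as.numeric(a(obj_nodes, "coefficient"))
  obj_rxn <- strip_prefix(obj_rxn[obj_coef != 0], "R")
  if (length(obj_rxn) != 1L)
    stop("SBML '", path, "' must declare exactly one nonzero flux objective, ",
         "found ", length(obj_rxn))

  rxns <- vector("list", length(rx_id))
  for (k in seq_along(rx_id)) {
    st <- rxn_stoich(k)
    rxns[[k]] <- reaction(rx_id[k], st, lbs[k], ubs[k],
                          kind = infer_kind(rx_id[k], st,
                                            rx_id[k] == obj_rxn))
  }
  name <- xml2::xml_attr(xml2::xml_find_first(doc, ".//d1:model", ns), "id")
  if (is.na(name)) name <- basename(path)
  metabolic_network(name, mets, rxns, biomass_id = obj_rxn)
}
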