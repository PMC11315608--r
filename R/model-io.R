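## Condition helpers: typed errors so callers (and the CLI) can distinguish
## parse problems, convention violations and table-format problems.

condStop <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "communet_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

parseError <- function(msg) condStop("communet_parse_error", msg)
conventionError <- function(msg) condStop("communet_convention_error", msg)
formatError <- function(msg) condStop("communet_format_error", msg)
parameterError <- function(msg) condStop("communet_parameter_error", msg)

DEFAULT_BOUNDS <- c(-1000, 1000)

xattr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) xml2::xml_attr(node, paste0("fbc:", name)) else v
}

#' Read a community metabolic model from SBML
#'
#' Parses an SBML Level 3 document (FBC optional) into a
#' [CommunityModel-class]. Community members are inferred from the
#' `"<member>_"` prefixes of compartment and metabolite IDs (see
#' [inferMembers()]); the shared external compartment is detected via
#' [detectSharedCompartment()].
#'
#' Flux bounds are taken from FBC `lowerFluxBound`/`upperFluxBound`
#' parameter references where present, otherwise from `-1000/1000` defaults
#' with a warning.
#'
#' @param path path to the SBML file.
#' @param member_override optional character vector of member IDs; when
#'   given, inference is skipped and compartments are attributed to these
#'   members (a convention error is raised for unattributable compartments).
#' @param shared_override optional compartment ID to use as the shared
#'   external compartment instead of detecting it.
#' @return A validated [CommunityModel-class].
#' @examples
#' spec <- fixtureSpec(n_members = 2, n_private = 1, n_pair = 1, seed = 1)
#' fx <- generateToyCommunity(spec, tempdir())
#' model <- readCommunitySBML(fx$sbml_path)
#' members(model)
#' @export
readCommunitySBML <- function(path, member_override = NULL,
                              shared_override = NULL) {
  if (!file.exists(path)) parseError(paste0("file not found: ", path))
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) parseError(paste0("malformed SBML: ", conditionMessage(e)))
  )
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model_node, "xml_missing")) {
    parseError("malformed SBML: no <model> element found")
  }
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- "community_model"

  comp_nodes <- xml2::xml_find_all(doc, ".//listOfCompartments/compartment")
  compartments <- xml2::xml_attr(comp_nodes, "id")

  if (is.null(shared_override)) {
    shared <- detectSharedCompartment(doc)
  } else {
    if (!shared_override %in% compartments) {
      conventionError(paste0("shared_override '", shared_override,
                             "' is not a compartment of the model"))
    }
    shared <- shared_override
  }

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  species <- data.frame(
    species_id = xml2::xml_attr(sp_nodes, "id"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")), "",
                  xml2::xml_attr(sp_nodes, "name")),
    stringsAsFactors = FALSE
  )

  if (is.null(member_override)) {
    sp_ids <- species$species_id
    attr(sp_ids, "compartments") <- species$compartment
    mem <- inferMembers(compartments, sp_ids, shared)
  } else {
    mem <- sort(unique(as.character(member_override)))
    nonshared <- setdiff(compartments, shared)
    hit <- vapply(nonshared, function(cid)
      sum(startsWith(cid, paste0(mem, "_"))), integer(1))
    if (any(hit == 0L)) {
      conventionError(paste0(
        "compartments not attributable to any member in member_override: ",
        paste(nonshared[hit == 0L], collapse = ", ")
      ))
    }
  }

  comp_member <- vapply(compartments, function(cid) {
    if (cid == shared) return(SHARED_MEMBER)
    hits <- mem[startsWith(cid, paste0(mem, "_"))]
    if (!length(hits)) {
      conventionError(paste0("compartment not attributable to any member: ", cid))
    }
    hits[which.max(nchar(hits))]
  }, character(1))
  species$member <- unname(comp_member[species$compartment])

  ## parameter table for FBC bound resolution
  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  par_vals <- suppressWarnings(as.numeric(xml2::xml_attr(par_nodes, "value")))
  names(par_vals) <- xml2::xml_attr(par_nodes, "id")

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  n_default <- 0L
  rx <- lapply(rx_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    reac <- xml2::xml_find_all(node, "./listOfReactants/speciesReference")
    prod <- xml2::xml_find_all(node, "./listOfProducts/speciesReference")
    coef <- c(
      -getStoich(reac),
      getStoich(prod)
    )
    ## sum duplicated species references
    coef <- tapply(coef, names(coef), sum)
    stoich <- as.numeric(coef)
    names(stoich) <- names(coef)

    lb_ref <- xattr(node, "lowerFluxBound")
    ub_ref <- xattr(node, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && !is.na(par_vals[lb_ref])) par_vals[[lb_ref]] else NA_real_
    ub <- if (!is.na(ub_ref) && !is.na(par_vals[ub_ref])) par_vals[[ub_ref]] else NA_real_
    if (is.na(lb) || is.na(ub)) {
      n_default <<- n_default + 1L
      if (is.na(lb)) lb <- DEFAULT_BOUNDS[1]
      if (is.na(ub)) ub <- DEFAULT_BOUNDS[2]
    }
    list(reaction_id = rid, stoichiometry = stoich,
         lower_bound = lb, upper_bound = ub)
  })
  if (n_default > 0L) {
    warning(n_default, " reaction(s) without resolvable FBC bounds; ",
            "defaults (-1000, 1000) applied", call. = FALSE)
  }
  reactions <- data.frame(
    reaction_id = vapply(rx, `[[`, character(1), "reaction_id"),
    lower_bound = vapply(rx, `[[`, numeric(1), "lower_bound"),
    upper_bound = vapply(rx, `[[`, numeric(1), "upper_bound"),
    stringsAsFactors = FALSE
  )
  reactions$stoichiometry <- lapply(rx, `[[`, "stoichiometry")

  new("CommunityModel",
      modelId = model_id,
      members = mem,
      sharedCompartment = shared,
      compartments = compartments,
      species = species,
      reactions = reactions)
}

getStoich <- function(refs) {
  if (!length(refs)) return(setNames(numeric(0), character(0)))
  st <- suppressWarnings(as.numeric(xml2::xml_attr(refs, "stoichiometry")))
  st[is.na(st)] <- 1
  setNames(st, xml2::xml_attr(refs, "species"))
}

#' Detect the shared external compartment of a community model
#'
#' The compartment through which all community members exchange metabolites.
#' An SBML parameter with id `shared_compartment_id` overrides the default;
#' its `value` attribute is honoured when it names an existing compartment
#' (some writers bend the numeric-value schema), otherwise its `name`
#' attribute. Without the parameter, a compartment literally called
#' `"medium"` is required.
#'
#' @param doc a parsed SBML document (`xml2::xml_document`) or a file path.
#' @return character(1), the shared compartment ID.
#' @export
detectSharedCompartment <- function(doc) {
  if (is.character(doc)) {
    doc <- tryCatch(xml2::read_xml(doc), error = function(e)
      parseError(paste0("malformed SBML: ", conditionMessage(e))))
    xml2::xml_ns_strip(doc)
  }
  comp <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//listOfCompartments/compartment"), "id")
  par <- xml2::xml_find_first(
    doc, ".//listOfParameters/parameter[@id='shared_compartment_id']")
  if (!inherits(par, "xml_missing")) {
    val <- xml2::xml_attr(par, "value")
    nm <- xml2::xml_attr(par, "name")
    cand <- c(val, nm)
    cand <- cand[!is.na(cand) & cand %in% comp]
    if (length(cand)) return(cand[[1]])
    conventionError(paste0(
      "parameter 'shared_compartment_id' does not name an existing ",
      "compartment (value=", val, ", name=", nm, ")"))
  }
  if ("medium" %in% comp) return("medium")
  conventionError(
    "no shared external compartment: neither parameter 'shared_compartment_id' nor a compartment 'medium' found")
}

#' Infer community member IDs from compartment and species prefixes
#'
#' Community models prefix each member's compartment and metabolite IDs with
#' the member ID followed by an underscore. Member IDs may themselves contain
#' underscores, so every underscore position is a candidate boundary. For
#' each non-shared compartment the longest prefix consistent with all of the
#' compartment's species is taken, then prefixes are merged to the smallest
#' consistent set (a compartment's prefix is shortened when a shorter
#' candidate is already another compartment's member ID). Result is
#' lexicographically sorted and independent of input order.
#'
#' @param compartment_ids character vector of compartment IDs.
#' @param species_ids character vector of species IDs (used to restrict
#'   candidate prefixes; may be empty). Species in the shared compartment are
#'   not constrained. If the vector carries a `compartment` attribute (named
#'   by [readCommunitySBML()]'s species table), the mapping species ->
#'   compartment is taken from names(species_ids); otherwise species are
#'   matched to compartments by the `"_<compartment suffix>"` convention.
#' @param shared the shared compartment ID.
#' @return character vector of member IDs (sorted).
#' @export
inferMembers <- function(compartment_ids, species_ids, shared) {
  nonshared <- sort(setdiff(unique(compartment_ids), shared))
  if (!length(nonshared)) {
    conventionError("no non-shared compartments: cannot infer community members")
  }
  ## species grouped by compartment when a mapping is available
  sp_by_comp <- attr(species_ids, "compartments")

  candidates <- lapply(nonshared, function(cid) {
    pos <- gregexpr("_", cid, fixed = TRUE)[[1]]
    pos <- pos[pos > 1 & pos < nchar(cid)]
    pref <- vapply(pos, function(p) substr(cid, 1L, p - 1L), character(1))
    if (!is.null(sp_by_comp)) {
      sp <- species_ids[sp_by_comp == cid]
      keep <- vapply(pref, function(p)
        all(startsWith(sp, paste0(p, "_"))), logical(1))
      pref <- pref[keep]
    }
    pref
  })
  names(candidates) <- nonshared
  empty <- nonshared[lengths(candidates) == 0L]
  if (length(empty)) {
    conventionError(paste0(
      "no consistent member prefix for compartment(s) ",
      paste(empty, collapse = ", "),
      "; consider passing member_override"))
  }
  ## longest candidate per compartment
  chosen <- vapply(candidates, function(p) p[which.max(nchar(p))], character(1))

  ## reduction pass: shorten a compartment's prefix when a shorter candidate
  ## is already used by a different compartment (merges e.g. alpha_c_x into
  ## member alpha); iterate to fixpoint, deterministic order
  repeat {
    changed <- FALSE
    for (cid in nonshared) {
      others <- unique(chosen[setdiff(nonshared, cid)])
      cur <- chosen[[cid]]
      if (cur %in% others) next
      alt <- candidates[[cid]]
      alt <- alt[alt %in% others & nchar(alt) < nchar(cur)]
      if (length(alt)) {
        chosen[[cid]] <- alt[which.max(nchar(alt))]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  mem <- sort(unique(unname(chosen)))

  ## every non-shared species must start with some member prefix
  if (length(species_ids) && is.null(sp_by_comp)) {
    ok <- vapply(species_ids, function(s) {
      endsWith(s, paste0("_", shared)) ||
        any(startsWith(s, paste0(mem, "_")))
    }, logical(1))
    if (!all(ok)) {
      conventionError(paste0(
        "species not attributable to any inferred member: ",
        paste(utils::head(species_ids[!ok], 5L), collapse = ", "),
        "; consider passing member_override"))
    }
  }
  mem
}

readDelimChecked <- function(path, required) {
  if (!file.exists(path)) formatError(paste0("file not found: ", path))
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      colClasses = "character", check.names = FALSE,
                      fileEncoding = "UTF-8"),
    error = function(e) formatError(paste0("unreadable TSV: ",
                                           conditionMessage(e)))
  )
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    formatError(paste0("missing required column(s): ",
                       paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  if (anyDuplicated(df$reaction_id)) {
    formatError(paste0("duplicate reaction_id: ",
                       paste(unique(df$reaction_id[duplicated(df$reaction_id)]),
                             collapse = ", ")))
  }
  df[required]
}

numCol <- function(df, col) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(v) & !is.na(df[[col]]))
  bad <- c(bad, which(is.na(df[[col]])))
  if (length(bad)) {
    formatError(paste0("non-numeric ", col, " in row(s) ",
                       paste(sort(unique(bad)), collapse = ", ")))
  }
  v
}

#' Read a flux vector (FBA solution) from a two-column TSV
#'
#' Expects a tab-separated file with header columns `reaction_id` and
#' `flux` in any order; extra columns are ignored with a warning.
#'
#' @param path path to the TSV file.
#' @return named numeric vector of fluxes, names are reaction IDs.
#' @export
readFluxTSV <- function(path) {
  df <- readDelimChecked(path, c("reaction_id", "flux"))
  setNames(numCol(df, "flux"), df$reaction_id)
}

#' Read flux ranges (FVA output) from a three-column TSV
#'
#' Expects tab-separated columns `reaction_id`, `min_flux`, `max_flux` in
#' any order. Each row must satisfy `min_flux <= max_flux`.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `reaction_id`, `min_flux`, `max_flux`.
#' @export
readFVATSV <- function(path) {
  df <- readDelimChecked(path, c("reaction_id", "min_flux", "max_flux"))
  out <- data.frame(
    reaction_id = df$reaction_id,
    min_flux = numCol(df, "min_flux"),
    max_flux = numCol(df, "max_flux"),
    stringsAsFactors = FALSE
  )
  bad <- which(out$min_flux > out$max_flux)
  if (length(bad)) {
    formatError(paste0("min_flux > max_flux in row(s) ",
                       paste(bad, collapse = ", ")))
  }
  out
}

#' Collect transport reactions touching the shared compartment
#'
#' Gathers every reaction involving at least one shared-compartment species.
#' Reactions moving a single external metabolite for a single member become
#' member transports (the future network edges); reactions whose species all
#' lie in the shared compartment are community boundary exchanges
#' (`member == SHARED_MEMBER`). Reactions touching more than one external
#' metabolite violate the single-metabolite transport assumption and are
#' excluded with a warning.
#'
#' @param model a [CommunityModel-class].
#' @return data.frame with columns `reaction_id`, `member`,
#'   `external_species`, `external_coefficient`, `lower_bound`,
#'   `upper_bound`.
#' @export
collectTransportReactions <- function(model) {
  sp_member <- setNames(model@species$member, model@species$species_id)
  sp_comp <- setNames(model@species$compartment, model@species$species_id)
  shared <- model@sharedCompartment

  rows <- lapply(seq_len(nrow(model@reactions)), function(i) {
    st <- model@reactions$stoichiometry[[i]]
    rid <- model@reactions$reaction_id[[i]]
    in_shared <- sp_comp[names(st)] == shared
    if (!any(in_shared)) return(NULL)
    if (sum(in_shared) > 1L) {
      warning("reaction ", rid, " touches ", sum(in_shared),
              " shared-compartment metabolites; excluded from the network",
              call. = FALSE)
      return(NULL)
    }
    ext <- names(st)[in_shared]
    mem_sp <- unique(sp_member[names(st)[!in_shared]])
    if (length(mem_sp) > 1L) {
      conventionError(paste0(
        "reaction ", rid, " connects species of several members: ",
        paste(mem_sp, collapse = ", ")))
    }
    data.frame(
      reaction_id = rid,
      member = if (length(mem_sp)) mem_sp else SHARED_MEMBER,
      external_species = ext,
      external_coefficient = unname(st[[ext]]),
      lower_bound = model@reactions$lower_bound[[i]],
      upper_bound = model@reactions$upper_bound[[i]],
      stringsAsFactors = FALSE
    )
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  if (is.null(out)) {
    out <- data.frame(
      reaction_id = character(), member = character(),
      external_species = character(), external_coefficient = numeric(),
      lower_bound = numeric(), upper_bound = numeric(),
      stringsAsFactors = FALSE)
  }
  out <- out[out$external_coefficient != 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_reaction_ids") <- model@reactions$reaction_id
  out
}
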