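MEMBER_POOL <- c("alpha", "beta", "gamma", "delta",
                 "epsilon", "zeta", "eta", "theta")

#' Describe a synthetic toy community
#'
#' Parameters of the seeded toy-community generator. Topology is fully
#' deterministic from the counts; the seed only drives which members are
#' planted as producers/consumers and the flux magnitudes.
#'
#' @param n_members number of community members (>= 1).
#' @param n_private external metabolites private to each member.
#' @param n_pair external metabolites shared by each member pair.
#' @param n_core external metabolites shared by all members (requires
#'   `n_members >= 3`).
#' @param seed integer seed for flux-state planting.
#' @param flux_scale positive flux unit of planted states.
#' @param bidir_fraction fraction of member transfers planted BIDIRECTIONAL
#'   in FVA states (rounded to a whole count).
#' @param inactive_fraction fraction of the remaining transfers planted
#'   INACTIVE in FVA states.
#' @param shared_compartment ID of the shared compartment; values other
#'   than `"medium"` are declared via the SBML parameter
#'   `shared_compartment_id`.
#' @param member_names optional character vector overriding the default
#'   member names (greek-letter pool, then `memNN`).
#' @return a `communet_fixture_spec` list.
#' @export
fixtureSpec <- function(n_members, n_private = 0L, n_pair = 0L, n_core = 0L,
                        seed = 1L, flux_scale = 2,
                        bidir_fraction = 0.5, inactive_fraction = 0.1,
                        shared_compartment = "medium",
                        member_names = NULL) {
  stopifnot(n_members >= 1, n_private >= 0, n_pair >= 0, n_core >= 0,
            flux_scale > 0, bidir_fraction >= 0, bidir_fraction <= 1,
            inactive_fraction >= 0, inactive_fraction <= 1)
  if (n_core > 0 && n_members < 3) {
    parameterError("core metabolites need at least 3 members")
  }
  if (is.null(member_names)) {
    member_names <- c(MEMBER_POOL,
                      sprintf("mem%02d", seq_len(max(0, n_members - 8)) + 8L)
                      )[seq_len(n_members)]
  }
  stopifnot(length(member_names) == n_members,
            !anyDuplicated(member_names), !grepl("_", member_names))
  structure(
    list(n_members = as.integer(n_members),
         n_private = as.integer(n_private),
         n_pair = as.integer(n_pair),
         n_core = as.integer(n_core),
         seed = as.integer(seed),
         flux_scale = flux_scale,
         bidir_fraction = bidir_fraction,
         inactive_fraction = inactive_fraction,
         shared_compartment = shared_compartment,
         member_names = member_names),
    class = "communet_fixture_spec"
  )
}

## metabolite incidence table of a fixture: one row per external metabolite,
## list column of incident members; topology is deterministic
fixtureTopology <- function(spec) {
  mem <- spec$member_names
  m <- spec$n_members
  base <- character()
  incident <- list()
  for (j in seq_len(m)) {
    for (k in seq_len(spec$n_private)) {
      base <- c(base, sprintf("priv%s%d", mem[j], k))
      incident[[length(incident) + 1L]] <- mem[j]
    }
  }
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) {
      for (j in seq((i + 1L), m)) {
        for (k in seq_len(spec$n_pair)) {
          base <- c(base, sprintf("pair%dx%dn%d", i, j, k))
          incident[[length(incident) + 1L]] <- mem[c(i, j)]
        }
      }
    }
  }
  for (k in seq_len(spec$n_core)) {
    base <- c(base, sprintf("core%d", k))
    incident[[length(incident) + 1L]] <- mem
  }
  list(base = base, incident = incident)
}

#' Generate a synthetic toy community model with ground truth
#'
#' Writes an SBML Level 3 + FBC model following the community conventions:
#' one internal compartment per member, a shared external compartment, a
#' reversible single-metabolite transfer reaction `TR_<member>_<met>` for
#' every member/metabolite incidence, one boundary exchange `EX_<met>` per
#' external metabolite, and an internal source/sink `SRC_<member>_<met>`
#' making every transfer feasible. The accompanying ground-truth record
#' (also written as JSON next to the model) carries the expected members,
#' per-metabolite member degrees and closed-formula node/edge counts.
#'
#' @param spec a [fixtureSpec()].
#' @param out_dir output directory (created if needed).
#' @return list with `sbml_path`, `ground_truth_path` and the
#'   `ground_truth` record.
#' @export
generateToyCommunity <- function(spec, out_dir) {
  stopifnot(inherits(spec, "communet_fixture_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  topo <- fixtureTopology(spec)
  mem <- spec$member_names
  shared <- spec$shared_compartment
  m <- spec$n_members

  n_mets <- length(topo$base)
  n_incidence <- sum(lengths(topo$incident))

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "xmlns:fbc=\"http://www.sbml.org/sbml/level3/version1/fbc/version2\" ",
           "level=\"3\" version=\"1\" fbc:required=\"false\">"),
    sprintf("  <model id=\"toy_community_%dm\" fbc:strict=\"true\">", m),
    "    <listOfCompartments>",
    sprintf("      <compartment id=\"%s\" constant=\"true\"/>", shared),
    sprintf("      <compartment id=\"%s_c\" constant=\"true\"/>", mem),
    "    </listOfCompartments>",
    "    <listOfSpecies>"
  )
  ext_species <- sprintf("%s_%s", topo$base, shared)
  lines <- c(lines, sprintf(
    paste0("      <species id=\"%s\" name=\"%s\" compartment=\"%s\" ",
           "hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" ",
           "constant=\"false\"/>"),
    ext_species, topo$base, shared))
  for (i in seq_len(n_mets)) {
    for (mn in topo$incident[[i]]) {
      lines <- c(lines, sprintf(
        paste0("      <species id=\"%s_%s_c\" compartment=\"%s_c\" ",
               "hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" ",
               "constant=\"false\"/>"),
        mn, topo$base[i], mn))
    }
  }
  lines <- c(lines,
    "    </listOfSpecies>",
    "    <listOfParameters>",
    "      <parameter id=\"cm_lb\" value=\"-1000\" constant=\"true\"/>",
    "      <parameter id=\"cm_ub\" value=\"1000\" constant=\"true\"/>")
  if (!identical(shared, "medium")) {
    lines <- c(lines, sprintf(
      paste0("      <parameter id=\"shared_compartment_id\" name=\"%s\" ",
             "value=\"0\" constant=\"true\"/>"), shared))
  }
  lines <- c(lines,
    "    </listOfParameters>",
    "    <listOfReactions>")

  rxn <- function(id, reactants, products) {
    out <- sprintf(
      paste0("      <reaction id=\"%s\" reversible=\"true\" fast=\"false\" ",
             "fbc:lowerFluxBound=\"cm_lb\" fbc:upperFluxBound=\"cm_ub\">"), id)
    if (length(reactants)) {
      out <- c(out, "        <listOfReactants>", sprintf(
        paste0("          <speciesReference species=\"%s\" ",
               "stoichiometry=\"1\" constant=\"true\"/>"), reactants),
        "        </listOfReactants>")
    }
    if (length(products)) {
      out <- c(out, "        <listOfProducts>", sprintf(
        paste0("          <speciesReference species=\"%s\" ",
               "stoichiometry=\"1\" constant=\"true\"/>"), products),
        "        </listOfProducts>")
    }
    c(out, "      </reaction>")
  }

  transfer_ids <- character()
  transfer_member <- character()
  transfer_species <- character()
  for (i in seq_len(n_mets)) {
    for (mn in topo$incident[[i]]) {
      tid <- sprintf("TR_%s_%s", mn, topo$base[i])
      transfer_ids <- c(transfer_ids, tid)
      transfer_member <- c(transfer_member, mn)
      transfer_species <- c(transfer_species, ext_species[i])
      lines <- c(lines, rxn(tid,
                            sprintf("%s_%s_c", mn, topo$base[i]),
                            ext_species[i]))
      lines <- c(lines, rxn(sprintf("SRC_%s_%s", mn, topo$base[i]),
                            character(), sprintf("%s_%s_c", mn, topo$base[i])))
    }
  }
  boundary_ids <- sprintf("EX_%s", topo$base)
  for (i in seq_len(n_mets)) {
    lines <- c(lines, rxn(boundary_ids[i], ext_species[i], character()))
  }
  lines <- c(lines,
    "    </listOfReactions>",
    "  </model>",
    "</sbml>")

  sbml_path <- file.path(out_dir, sprintf("toy_community_m%d_s%d.xml",
                                          m, spec$seed))
  writeLines(lines, sbml_path, useBytes = TRUE)

  gt <- list(
    members = sort(mem),
    shared_compartment = shared,
    metabolites = data.frame(
      base = topo$base,
      species_id = ext_species,
      member_degree = lengths(topo$incident),
      stringsAsFactors = FALSE
    ),
    incident_members = topo$incident,
    transfer_reactions = data.frame(
      reaction_id = transfer_ids,
      member = transfer_member,
      external_species = transfer_species,
      external_coefficient = rep(1, length(transfer_ids)),
      stringsAsFactors = FALSE
    ),
    boundary_reactions = data.frame(
      reaction_id = boundary_ids,
      external_species = ext_species,
      external_coefficient = rep(-1, n_mets),
      stringsAsFactors = FALSE
    ),
    ## closed formulas
    n_metabolite_nodes = spec$n_members * spec$n_private +
      choose(spec$n_members, 2) * spec$n_pair + spec$n_core,
    n_edges = spec$n_members * spec$n_private +
      2 * choose(spec$n_members, 2) * spec$n_pair +
      spec$n_members * spec$n_core,
    n_boundary_reactions = n_mets,
    n_species = n_mets + n_incidence,
    n_reactions = 2L * n_incidence + n_mets
  )
  gt_path <- file.path(out_dir, sprintf("toy_community_m%d_s%d_truth.json",
                                        m, spec$seed))
  jsonlite::write_json(
    gt[c("members", "shared_compartment", "n_metabolite_nodes", "n_edges",
         "n_boundary_reactions", "n_species", "n_reactions")],
    gt_path, auto_unbox = TRUE, digits = NA)
  list(sbml_path = sbml_path, ground_truth_path = gt_path, ground_truth = gt)
}

withFixtureSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a planted flux state for a toy community
#'
#' FBA mode plants, for every pair/core metabolite, one producing member
#' and one or more distinct consuming members with fluxes balancing exactly
#' in the medium (boundary exchange flux 0 for shared metabolites; equal to
#' the transfer flux for private ones), so mass balance of every shared
#' metabolite holds to machine precision. FVA mode plants a
#' `bidir_fraction` of member transfers with ranges strictly straddling
#' zero, splits the remainder between production-only, consumption-only
#' and inactive ranges, and gives boundary exchanges the symmetric range
#' `(-flux_scale, flux_scale)`.
#'
#' @param spec the [fixtureSpec()] used for the model.
#' @param ground_truth ground-truth record from [generateToyCommunity()].
#' @param mode `"FBA"` or `"FVA"`.
#' @param out_dir output directory.
#' @return list with `path` (the TSV) and `ground_truth` extended with the
#'   planted per-reaction fluxes/classes and per-metabolite
#'   producer/consumer sets (`planted_crossfeeding`).
#' @export
generateFluxState <- function(spec, ground_truth, mode = c("FBA", "FVA"),
                              out_dir) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gt <- ground_truth
  tr <- gt$transfer_reactions
  fs <- spec$flux_scale

  if (mode == "FBA") {
    res <- withFixtureSeed(spec$seed, plantFBA(spec, gt, fs))
    path <- file.path(out_dir, sprintf("flux_m%d_s%d.tsv",
                                       spec$n_members, spec$seed))
    df <- res$fluxes
    writeLines(c("reaction_id\tflux",
                 sprintf("%s\t%.10g", df$reaction_id, df$flux)),
               path, useBytes = TRUE)
    gt$planted_fluxes <- df
    gt$planted_classes <- res$classes
    gt$planted_crossfeeding <- res$crossfeeding
  } else {
    res <- withFixtureSeed(spec$seed + 1L, plantFVA(spec, gt, fs))
    path <- file.path(out_dir, sprintf("fva_m%d_s%d.tsv",
                                       spec$n_members, spec$seed))
    df <- res$ranges
    writeLines(c("reaction_id\tmin_flux\tmax_flux",
                 sprintf("%s\t%.10g\t%.10g", df$reaction_id,
                         df$min_flux, df$max_flux)),
               path, useBytes = TRUE)
    gt$planted_ranges <- df
    gt$planted_classes <- res$classes
    gt$planted_crossfeeding <- res$crossfeeding
  }
  list(path = path, ground_truth = gt)
}

plantFBA <- function(spec, gt, fs) {
  tr <- gt$transfer_reactions
  flux <- setNames(rep(0, nrow(tr)), tr$reaction_id)
  producers <- vector("list", nrow(gt$metabolites))
  consumers <- vector("list", nrow(gt$metabolites))
  ex_flux <- setNames(rep(0, nrow(gt$boundary_reactions)),
                      gt$boundary_reactions$reaction_id)

  for (i in seq_len(nrow(gt$metabolites))) {
    inc <- gt$incident_members[[i]]
    base <- gt$metabolites$base[i]
    if (length(inc) == 1L) {
      dirn <- sample(c(1, -1), 1L)
      tid <- sprintf("TR_%s_%s", inc, base)
      flux[tid] <- dirn * fs
      ex_flux[sprintf("EX_%s", base)] <- dirn * fs
      if (dirn > 0) producers[[i]] <- inc else consumers[[i]] <- inc
    } else {
      prod <- sample(inc, 1L)
      others <- setdiff(inc, prod)
      n_cons <- if (length(others) == 1L) 1L else sample(seq_along(others), 1L)
      cons <- if (length(others) == 1L) others else sample(others, n_cons)
      flux[sprintf("TR_%s_%s", prod, base)] <- length(cons) * fs
      flux[sprintf("TR_%s_%s", cons, base)] <- -fs
      producers[[i]] <- prod
      consumers[[i]] <- sort(cons)
    }
  }
  src_flux <- flux
  names(src_flux) <- sub("^TR_", "SRC_", names(flux))
  all_flux <- c(flux, src_flux, ex_flux)
  classes <- ifelse(flux > 0, "PRODUCTION",
                    ifelse(flux < 0, "CONSUMPTION", "INACTIVE"))
  cf <- mapply(function(p, c) {
    length(p) > 0L && length(c) > 0L && length(union(p, c)) >= 2L
  }, producers, consumers)
  list(
    fluxes = data.frame(reaction_id = names(all_flux),
                        flux = unname(all_flux),
                        stringsAsFactors = FALSE),
    classes = setNames(unname(classes), tr$reaction_id),
    crossfeeding = data.frame(
      species_id = gt$metabolites$species_id,
      cross_fed = unname(cf),
      producers = I(lapply(producers, function(x) sort(as.character(x)))),
      consumers = I(lapply(consumers, function(x) sort(as.character(x)))),
      stringsAsFactors = FALSE
    )
  )
}

plantFVA <- function(spec, gt, fs) {
  tr <- gt$transfer_reactions
  n <- nrow(tr)
  n_bidir <- round(spec$bidir_fraction * n)
  idx <- seq_len(n)
  bidir_idx <- if (n_bidir > 0) sort(sample(idx, n_bidir)) else integer()
  rest <- setdiff(idx, bidir_idx)
  n_inact <- round(spec$inactive_fraction * length(rest))
  inact_idx <- if (n_inact > 0) sort(sample(rest, n_inact)) else integer()
  rest <- setdiff(rest, inact_idx)
  prod_idx <- rest[seq_along(rest) %% 2L == 1L]
  cons_idx <- setdiff(rest, prod_idx)

  lo <- hi <- numeric(n)
  lo[bidir_idx] <- -fs * stats::runif(length(bidir_idx), 0.5, 1.5)
  hi[bidir_idx] <- fs * stats::runif(length(bidir_idx), 0.5, 1.5)
  lo[prod_idx] <- fs * stats::runif(length(prod_idx), 0.25, 0.75)
  hi[prod_idx] <- lo[prod_idx] + fs * stats::runif(length(prod_idx), 0.25, 0.75)
  hi[cons_idx] <- -fs * stats::runif(length(cons_idx), 0.25, 0.75)
  lo[cons_idx] <- hi[cons_idx] - fs * stats::runif(length(cons_idx), 0.25, 0.75)

  classes <- rep("INACTIVE", n)
  classes[bidir_idx] <- "BIDIRECTIONAL"
  classes[prod_idx] <- "PRODUCTION"
  classes[cons_idx] <- "CONSUMPTION"
  names(classes) <- tr$reaction_id

  ranges <- data.frame(
    reaction_id = c(tr$reaction_id, gt$boundary_reactions$reaction_id),
    min_flux = c(lo, rep(-fs, nrow(gt$boundary_reactions))),
    max_flux = c(hi, rep(fs, nrow(gt$boundary_reactions))),
    stringsAsFactors = FALSE
  )

  ## feasible producers/consumers from the planted classes
  can_prod <- classes %in% c("PRODUCTION", "BIDIRECTIONAL")
  can_cons <- classes %in% c("CONSUMPTION", "BIDIRECTIONAL")
  producers <- consumers <- vector("list", nrow(gt$metabolites))
  for (i in seq_len(nrow(gt$metabolites))) {
    sel <- tr$external_species == gt$metabolites$species_id[i]
    producers[[i]] <- sort(tr$member[sel & can_prod])
    consumers[[i]] <- sort(tr$member[sel & can_cons])
  }
  cf <- mapply(function(p, c) {
    length(p) > 0L && length(c) > 0L && length(union(p, c)) >= 2L
  }, producers, consumers)
  list(
    ranges = ranges,
    classes = classes,
    crossfeeding = data.frame(
      species_id = gt$metabolites$species_id,
      cross_fed = unname(cf),
      producers = I(producers),
      consumers = I(consumers),
      stringsAsFactors = FALSE
    )
  )
}
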