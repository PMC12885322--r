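# Genome-scale metabolic model container and I/O.
#
# A metabolic_network holds the stoichiometric matrix S (metabolites x
# reactions), flux bounds, the FBA objective, GPR rules and subsystem labels.
# Reading supports SBML Level 3 with the fbc package (bounds, gene products,
# objective; groups for subsystems) and COBRA-style JSON.

#' Construct a metabolic network
#'
#' @param metabolite_ids Character vector of metabolite ids (length m).
#' @param reaction_ids Character vector of reaction ids (length n).
#' @param S m x n numeric stoichiometric matrix.
#' @param lb,ub Numeric flux bounds per reaction (mmol/gDW/h by convention).
#' @param obj_coef Objective coefficients; the biomass reaction carries a
#'   non-zero entry.
#' @param gene_ids Character vector of model genes.
#' @param rules List of [gpr_rule][parse_gpr] ASTs or `NULL` per reaction.
#' @param subsystem Character subsystem label per reaction.
#' @return An object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolite_ids, reaction_ids, S, lb, ub,
                              obj_coef = NULL, gene_ids = NULL,
                              rules = NULL, subsystem = NULL) {
  m <- length(metabolite_ids); n <- length(reaction_ids)
  S <- as.matrix(S)
  if (!all(dim(S) == c(m, n))) {
    stop("S must be ", m, " x ", n, " to match metabolite/reaction ids",
         call. = FALSE)
  }
  if (length(lb) != n || length(ub) != n) {
    stop("bounds must have one entry per reaction", call. = FALSE)
  }
  if (any(lb > ub)) {
    bad <- reaction_ids[lb > ub]
    stop("lower bound exceeds upper bound for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(obj_coef)) obj_coef <- numeric(n)
  if (is.null(rules)) rules <- vector("list", n)
  if (is.null(subsystem)) subsystem <- rep("unassigned", n)
  subsystem[is.na(subsystem) | !nzchar(subsystem)] <- "unassigned"
  if (is.null(gene_ids)) {
    gene_ids <- unique(unlist(lapply(rules, rule_genes)))
    if (is.null(gene_ids)) gene_ids <- character()
  }
  used <- unique(unlist(lapply(rules, rule_genes)))
  missing <- setdiff(used, gene_ids)
  if (length(missing)) {
    stop("GPR rules reference genes absent from the gene list: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  structure(list(
    metabolite_ids = metabolite_ids, reaction_ids = reaction_ids, S = S,
    lb = stats::setNames(as.numeric(lb), reaction_ids),
    ub = stats::setNames(as.numeric(ub), reaction_ids),
    obj_coef = stats::setNames(as.numeric(obj_coef), reaction_ids),
    gene_ids = gene_ids,
    rules = stats::setNames(rules, reaction_ids),
    subsystem = stats::setNames(as.character(subsystem), reaction_ids)
  ), class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<", class(x)[1], "> ", length(x$metabolite_ids), " metabolites, ",
      length(x$reaction_ids), " reactions, ", length(x$gene_ids), " genes\n",
      sep = "")
  nrev <- sum(x$lb < 0)
  cat("  reversible reactions: ", nrev,
      "; rule-bearing reactions: ", sum(!vapply(x$rules, is.null, logical(1))),
      "\n", sep = "")
  if (!is.null(x$re_pairs)) {
    cat("  split direction pairs: ", nrow(x$re_pairs), "\n", sep = "")
  }
  invisible(x)
}

#' Load a genome-scale metabolic model
#'
#' Reads SBML Level 3 (fbc bounds/objective/gene associations, groups
#' subsystems) or COBRA-style JSON. Reactions without a GPR string get a
#' `NULL` rule; missing subsystems default to `"unassigned"`.
#'
#' @param path Path to the model file.
#' @param format `"auto"` (by extension), `"sbml"`, or `"json"`.
#' @return A [metabolic_network()].
#' @export
load_network <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  switch(format, json = load_network_json(path), sbml = load_network_sbml(path))
}

load_network_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("unreadable JSON model: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("not a COBRA-style JSON model (missing metabolites/reactions)",
         call. = FALSE)
  }
  met_ids <- vapply(doc$metabolites, function(m) m$id, character(1))
  rxn_ids <- vapply(doc$reactions, function(r) r$id, character(1))
  gene_ids <- vapply(doc$genes %||% list(), function(g) g$id, character(1))
  n <- length(rxn_ids); m <- length(met_ids)
  S <- matrix(0, m, n, dimnames = list(met_ids, rxn_ids))
  lb <- numeric(n); ub <- numeric(n); obj <- numeric(n)
  rules <- vector("list", n); subsys <- character(n)
  for (j in seq_len(n)) {
    r <- doc$reactions[[j]]
    coeffs <- r$metabolites %||% list()
    if (length(coeffs)) {
      unknown <- setdiff(names(coeffs), met_ids)
      if (length(unknown)) {
        stop("reaction ", r$id, " references unknown metabolite(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      S[names(coeffs), j] <- vapply(coeffs, as.numeric, numeric(1))
    }
    lb[j] <- r$lower_bound %||% 0
    ub[j] <- r$upper_bound %||% 1000
    obj[j] <- r$objective_coefficient %||% 0
    rules[j] <- list(parse_gpr(r$gene_reaction_rule %||% ""))
    subsys[j] <- r$subsystem %||% "unassigned"
  }
  metabolic_network(met_ids, rxn_ids, S, lb, ub, obj, gene_ids, rules, subsys)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_network_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unreadable SBML file: ",
                                           conditionMessage(e), call. = FALSE))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
          g = "http://www.sbml.org/sbml/level3/version1/groups/version1")
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model, "xml_missing")) {
    stop("not an SBML Level 3 document", call. = FALSE)
  }
  params <- xml2::xml_find_all(model, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  species <- xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns)
  met_ids <- xml2::xml_attr(species, "id")
  gps <- xml2::xml_find_all(model, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_label <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(gps, "label")),
           xml2::xml_attr(gps, "id"), xml2::xml_attr(gps, "label")),
    xml2::xml_attr(gps, "id"))
  rxn_nodes <- xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns)
  rxn_ids <- xml2::xml_attr(rxn_nodes, "id")
  n <- length(rxn_ids); m <- length(met_ids)
  S <- matrix(0, m, n, dimnames = list(met_ids, rxn_ids))
  lb <- numeric(n); ub <- numeric(n)
  rules <- vector("list", n)
  for (j in seq_len(n)) {
    rn <- rxn_nodes[[j]]
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(rn, paste0("./s:", side, "/s:speciesReference"), ns)
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        if (!sp %in% met_ids) {
          stop("reaction ", rxn_ids[j], " references unknown metabolite: ", sp,
               call. = FALSE)
        }
        st <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
        if (is.na(st)) st <- 1
        S[sp, j] <- S[sp, j] + sgn * st
      }
    }
    lbref <- xml2::xml_attr(rn, "lowerFluxBound")
    ubref <- xml2::xml_attr(rn, "upperFluxBound")
    lb[j] <- if (!is.na(lbref) && lbref %in% names(pval)) pval[[lbref]] else {
      if (identical(xml2::xml_attr(rn, "reversible"), "true")) -1000 else 0
    }
    ub[j] <- if (!is.na(ubref) && ubref %in% names(pval)) pval[[ubref]] else 1000
    gpa <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation", ns)
    if (!inherits(gpa, "xml_missing")) {
      rules[[j]] <- sbml_gpa_to_rule(xml2::xml_child(gpa), gp_label, ns)
    }
  }
  obj <- numeric(n)
  flux_obj <- xml2::xml_find_all(
    model, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  for (fo in flux_obj) {
    rid <- xml2::xml_attr(fo, "reaction")
    if (rid %in% rxn_ids) {
      obj[match(rid, rxn_ids)] <- as.numeric(xml2::xml_attr(fo, "coefficient"))
    }
  }
  subsys <- rep("unassigned", n)
  groups <- xml2::xml_find_all(model, ".//g:listOfGroups/g:group", ns)
  for (gr in groups) {
    gname <- xml2::xml_attr(gr, "name")
    if (is.na(gname)) gname <- xml2::xml_attr(gr, "id")
    members <- xml2::xml_attr(
      xml2::xml_find_all(gr, "./g:listOfMembers/g:member", ns), "idRef")
    subsys[rxn_ids %in% members] <- gname
  }
  gene_ids <- unname(gp_label)
  metabolic_network(met_ids, rxn_ids, S, lb, ub, obj, gene_ids, rules, subsys)
}

sbml_gpa_to_rule <- function(node, gp_label, ns) {
  name <- xml2::xml_name(node)
  if (name == "geneProductRef") {
    gid <- xml2::xml_attr(node, "geneProduct")
    lbl <- if (gid %in% names(gp_label)) gp_label[[gid]] else gid
    return(gpr_gene(lbl))
  }
  children <- lapply(xml2::xml_children(node), sbml_gpa_to_rule,
                     gp_label = gp_label, ns = ns)
  if (name == "and") gpr_node("and", children)
  else if (name == "or") gpr_node("or", children)
  else stop("unsupported gene association element: ", name, call. = FALSE)
}

#' Write a metabolic network to SBML or COBRA-style JSON
#'
#' The writer is deterministic: the same network always produces byte-identical
#' output, so serialized fixtures can be compared directly.
#'
#' @param net A [metabolic_network()].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"sbml"`, or `"json"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  if (format == "json") write_network_json(net, path) else write_network_sbml(net, path)
  invisible(path)
}

write_network_json <- function(net, path) {
  rxns <- lapply(seq_along(net$reaction_ids), function(j) {
    col <- net$S[, j]
    nz <- which(col != 0)
    list(id = net$reaction_ids[j],
         metabolites = as.list(stats::setNames(col[nz], net$metabolite_ids[nz])),
         lower_bound = unname(net$lb[j]), upper_bound = unname(net$ub[j]),
         objective_coefficient = unname(net$obj_coef[j]),
         gene_reaction_rule = gpr_serialize(net$rules[[j]]),
         subsystem = unname(net$subsystem[j]))
  })
  doc <- list(
    id = "model",
    metabolites = lapply(net$metabolite_ids, function(id) list(id = id)),
    reactions = rxns,
    genes = lapply(net$gene_ids, function(id) list(id = id))
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
}

write_network_sbml <- function(net, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) formatC(x, format = "g", digits = 15)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
           ' xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
           ' xmlns:groups="http://www.sbml.org/sbml/level3/version1/groups/version1"',
           ' level="3" version="1" fbc:required="false" groups:required="false">'),
    '  <model id="model" fbc:strict="true">')
  # bound parameters: one per distinct value
  bvals <- sort(unique(c(net$lb, net$ub)))
  pid <- stats::setNames(paste0("par_", seq_along(bvals)), num(bvals))
  lines <- c(lines, '    <listOfParameters>')
  for (v in bvals) {
    lines <- c(lines, paste0('      <parameter id="', pid[[num(v)]],
                             '" value="', num(v), '" constant="true"/>'))
  }
  lines <- c(lines, '    </listOfParameters>',
             '    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
             '    <listOfSpecies>')
  for (mid in net$metabolite_ids) {
    lines <- c(lines, paste0('      <species id="', esc(mid),
                             '" compartment="c" hasOnlySubstanceUnits="false"',
                             ' boundaryCondition="false" constant="false"/>'))
  }
  lines <- c(lines, '    </listOfSpecies>',
             '    <fbc:listOfGeneProducts>')
  for (g in net$gene_ids) {
    lines <- c(lines, paste0('      <fbc:geneProduct fbc:id="gp_', esc(g),
                             '" fbc:label="', esc(g), '"/>'))
  }
  lines <- c(lines, '    </fbc:listOfGeneProducts>',
             '    <listOfReactions>')
  for (j in seq_along(net$reaction_ids)) {
    rid <- net$reaction_ids[j]
    rev <- if (net$lb[j] < 0) "true" else "false"
    lines <- c(lines, paste0(
      '      <reaction id="', esc(rid), '" reversible="', rev,
      '" fast="false" fbc:lowerFluxBound="', pid[[num(net$lb[j])]],
      '" fbc:upperFluxBound="', pid[[num(net$ub[j])]], '">'))
    col <- net$S[, j]
    for (side in c(-1, 1)) {
      nz <- which(sign(col) == side)
      if (!length(nz)) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      lines <- c(lines, paste0('        <', tag, '>'))
      for (i in nz) {
        lines <- c(lines, paste0(
          '          <speciesReference species="', esc(net$metabolite_ids[i]),
          '" stoichiometry="', num(abs(col[i])), '" constant="true"/>'))
      }
      lines <- c(lines, paste0('        </', tag, '>'))
    }
    if (!is.null(net$rules[[j]])) {
      lines <- c(lines, '        <fbc:geneProductAssociation>',
                 sbml_rule_xml(net$rules[[j]], indent = 10),
                 '        </fbc:geneProductAssociation>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>')
  nzobj <- which(net$obj_coef != 0)
  lines <- c(lines,
             '    <fbc:listOfObjectives fbc:activeObjective="obj">',
             '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
             '        <fbc:listOfFluxObjectives>')
  for (j in nzobj) {
    lines <- c(lines, paste0(
      '          <fbc:fluxObjective fbc:reaction="', esc(net$reaction_ids[j]),
      '" fbc:coefficient="', num(net$obj_coef[j]), '"/>'))
  }
  lines <- c(lines, '        </fbc:listOfFluxObjectives>',
             '      </fbc:objective>',
             '    </fbc:listOfObjectives>')
  subs <- unique(net$subsystem)
  lines <- c(lines, '    <groups:listOfGroups>')
  for (k in seq_along(subs)) {
    members <- net$reaction_ids[net$subsystem == subs[k]]
    lines <- c(lines, paste0('      <groups:group groups:id="sg_', k,
                             '" groups:name="', esc(subs[k]),
                             '" groups:kind="partonomy">'),
               '        <groups:listOfMembers>')
    for (rid in members) {
      lines <- c(lines, paste0('          <groups:member groups:idRef="',
                               esc(rid), '"/>'))
    }
    lines <- c(lines, '        </groups:listOfMembers>',
               '      </groups:group>')
  }
  lines <- c(lines, '    </groups:listOfGroups>',
             '  </model>', '</sbml>')
  writeLines(lines, path)
}

sbml_rule_xml <- function(rule, indent) {
  pad <- strrep(" ", indent)
  if (rule$kind == "gene") {
    return(paste0(pad, '<fbc:geneProductRef fbc:geneProduct="gp_', rule$gene, '"/>'))
  }
  tag <- paste0("fbc:", rule$kind)
  c(paste0(pad, "<", tag, ">"),
    unlist(lapply(rule$children, sbml_rule_xml, indent = indent + 2)),
    paste0(pad, "</", tag, ">"))
}

#' Convert a network to irreversible form
#'
#' Reversible reactions (`lb < 0 < ub`) are split into a forward (`_f`) and a
#' backward (`_b`) column with negated stoichiometry; the pair indices are
#' recorded in `re_pairs` so that at most one direction may carry flux in the
#' expression-integration MILP. Backward-only reactions (`ub <= 0`) are
#' flipped rather than split. All lower bounds of the result are zero. GPR
#' rules and subsystem labels are duplicated onto both directions, and a
#' provenance table maps every column back to (original reaction, sign).
#'
#' @param net A [metabolic_network()].
#' @return An `irreversible_network` (subclass of `metabolic_network`) with
#'   fields `re_pairs` (2-column matrix of forward/backward indices) and
#'   `provenance` (data.frame irr_id, orig_id, sign).
#' @export
to_irreversible <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  if (inherits(net, "irreversible_network")) return(net)
  n0 <- length(net$reaction_ids)
  ids <- character(); lb <- numeric(); ub <- numeric(); obj <- numeric()
  cols <- list(); rules <- list(); subsys <- character()
  prov_irr <- character(); prov_orig <- character(); prov_sign <- numeric()
  pair_f <- integer(); pair_b <- integer()
  add_col <- function(id, col, l, u, o, rule, ss, orig, sgn) {
    ids[length(ids) + 1L] <<- id
    cols[[length(cols) + 1L]] <<- col
    lb[length(lb) + 1L] <<- l; ub[length(ub) + 1L] <<- u
    obj[length(obj) + 1L] <<- o
    rules[length(rules) + 1L] <<- list(rule)   # list() so NULL rules append
    subsys[length(subsys) + 1L] <<- ss
    prov_irr[length(prov_irr) + 1L] <<- id
    prov_orig[length(prov_orig) + 1L] <<- orig
    prov_sign[length(prov_sign) + 1L] <<- sgn
    length(ids)
  }
  for (j in seq_len(n0)) {
    id <- net$reaction_ids[j]; col <- net$S[, j]
    l <- net$lb[j]; u <- net$ub[j]
    if (l >= 0) {                         # already irreversible
      add_col(id, col, l, u, net$obj_coef[j], net$rules[[j]], net$subsystem[j],
              id, 1)
    } else if (u <= 0) {                  # backward-only: flip, do not split
      add_col(paste0(id, "_b"), -col, -u, -l, -net$obj_coef[j],
              net$rules[[j]], net$subsystem[j], id, -1)
    } else {                              # genuinely reversible: split
      f <- add_col(paste0(id, "_f"), col, 0, u, net$obj_coef[j],
                   net$rules[[j]], net$subsystem[j], id, 1)
      b <- add_col(paste0(id, "_b"), -col, 0, -l, 0,
                   net$rules[[j]], net$subsystem[j], id, -1)
      pair_f[length(pair_f) + 1L] <- f
      pair_b[length(pair_b) + 1L] <- b
    }
  }
  S <- do.call(cbind, cols)
  out <- metabolic_network(net$metabolite_ids, ids, S, lb, ub, obj,
                           net$gene_ids, rules, subsys)
  out$re_pairs <- cbind(forward = pair_f, backward = pair_b)
  out$provenance <- data.frame(irr_id = prov_irr, orig_id = prov_orig,
                               sign = prov_sign, stringsAsFactors = FALSE)
  out$original_reaction_ids <- net$reaction_ids
  class(out) <- c("irreversible_network", class(out))
  out
}

#' Collapse split-direction fluxes back to net fluxes on original reactions
#'
#' For each split pair the net flux is forward minus backward; flipped
#' backward-only reactions change sign; untouched reactions pass through.
#'
#' @param net An `irreversible_network`.
#' @param flux Numeric flux vector on the irreversible reactions.
#' @return Named numeric vector over the original reaction ids.
#' @export
collapse_fluxes <- function(net, flux) {
  stopifnot(inherits(net, "irreversible_network"))
  if (length(flux) != length(net$reaction_ids)) {
    stop("flux vector has length ", length(flux), ", expected ",
         length(net$reaction_ids), call. = FALSE)
  }
  out <- stats::setNames(numeric(length(net$original_reaction_ids)),
                         net$original_reaction_ids)
  contrib <- net$provenance$sign * as.numeric(flux)
  agg <- tapply(contrib, net$provenance$orig_id, sum)
  out[names(agg)] <- agg
  out
}
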