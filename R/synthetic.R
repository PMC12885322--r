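# Deterministic toy-network generator with known ground truth.
#
# The motifs stand in for a genome-scale model at desk scale: an uptake
# exchange, an interior with the structural feature under test (parallel
# isozyme branches, a futile cycle, nested GPR logic), at least one
# reversible reaction (to exercise direction splitting), and a biomass sink.
# Designed per-condition flux routings satisfy mass balance by construction;
# expression tables are generated from the designed relative fluxes, the
# quantity the integration MILP aligns fluxes with.

#' Generate a toy metabolic network
#'
#' Motifs:
#' * `linear_chain`: uptake -> A -> B <-> C -> D -> biomass; unique flux.
#' * `parallel_branches`: `n_branches` isozyme routes A -> B, then
#'   B <-> C -> D -> E -> biomass (5 metabolites / 7 reactions at the default
#'   two branches).
#' * `branched_with_loop`: parallel branches plus a rule-less futile cycle
#'   C -> F -> C carrying no expression signal (alternate optima for the L1
#'   step to remove).
#' * `diamond_gpr`: two two-step routes with nested AND/OR rules.
#'
#' Uptake is bounded by `uptake_bound` (mmol/gDW/h); interior reactions use a
#' wide default bound of 1000. The builder is deterministic: the same
#' arguments always produce the identical network.
#'
#' @param motif One of the four motif names.
#' @param n_branches Number of parallel branches (branch motifs; >= 2).
#' @param uptake_bound Upper bound on the uptake exchange (default 10).
#' @return A [metabolic_network()] with GPR rules and subsystem labels.
#' @export
make_network <- function(motif = c("parallel_branches", "linear_chain",
                                   "branched_with_loop", "diamond_gpr"),
                         n_branches = 2, uptake_bound = 10) {
  motif <- match.arg(motif)
  stopifnot(n_branches >= 2, uptake_bound > 0)
  U <- 1000
  rx <- list()  # id -> list(mets, lb, ub, obj, rule, subsystem)
  add <- function(id, mets, lb = 0, ub = U, obj = 0, rule = "",
                  subsystem = "Core") {
    rx[[id]] <<- list(mets = mets, lb = lb, ub = ub, obj = obj,
                      rule = rule, subsystem = subsystem)
  }
  if (motif %in% c("parallel_branches", "branched_with_loop")) {
    add("EX_A", c(A = 1), ub = uptake_bound, subsystem = "Exchange")
    for (i in seq_len(n_branches)) {
      add(paste0("BR", i), c(A = -1, B = 1), rule = paste0("gb", i),
          subsystem = "Branches")
    }
    add("TRANS", c(B = -1, C = 1), lb = -U, rule = "gt1 and gt2")
    add("R3", c(C = -1, D = 1), rule = "gc1 or gc2")
    add("R4", c(D = -1, E = 1), rule = "(gn1 and gn2) or gn3")
    add("BIOMASS", c(E = -1), obj = 1, subsystem = "Biomass")
    if (motif == "branched_with_loop") {
      add("L1", c(C = -1, F = 1), subsystem = "Loop")
      add("L2", c(F = -1, C = 1), subsystem = "Loop")
    }
  } else if (motif == "linear_chain") {
    add("EX_A", c(A = 1), ub = uptake_bound, subsystem = "Exchange")
    add("R1", c(A = -1, B = 1), rule = "g1", subsystem = "Upper")
    add("TRANS", c(B = -1, C = 1), lb = -U, rule = "g2 and g3")
    add("R3", c(C = -1, D = 1), rule = "g4 or g5")
    add("BIOMASS", c(D = -1), obj = 1, subsystem = "Biomass")
  } else {
    add("EX_A", c(A = 1), ub = uptake_bound, subsystem = "Exchange")
    add("R1", c(A = -1, B = 1), rule = "(gA and gB) or gC", subsystem = "North")
    add("R2", c(A = -1, C = 1), rule = "gD and (gE or gF)", subsystem = "South")
    add("R3", c(B = -1, D = 1), rule = "gG", subsystem = "North")
    add("R4", c(C = -1, D = 1), rule = "gH or (gI and gJ)", subsystem = "South")
    add("TRANS", c(D = -1, E = 1), lb = -U, rule = "gK")
    add("BIOMASS", c(E = -1), obj = 1, subsystem = "Biomass")
  }
  mets <- unique(unlist(lapply(rx, function(r) names(r$mets))))
  S <- matrix(0, length(mets), length(rx), dimnames = list(mets, names(rx)))
  for (j in seq_along(rx)) S[names(rx[[j]]$mets), j] <- rx[[j]]$mets
  rules <- lapply(rx, function(r) parse_gpr(r$rule))
  metabolic_network(
    metabolite_ids = mets, reaction_ids = names(rx), S = S,
    lb = vapply(rx, `[[`, numeric(1), "lb"),
    ub = vapply(rx, `[[`, numeric(1), "ub"),
    obj_coef = vapply(rx, `[[`, numeric(1), "obj"),
    rules = rules,
    subsystem = vapply(rx, `[[`, character(1), "subsystem"))
}

#' Generate conditions with designed ground-truth flux routings
#'
#' Condition `d` takes uptake `uptake_bound * (1 - 0.1 * ((d - 1) %% 5))` —
#' distinct values on the scale of typical measured glucose uptake — and, on
#' branch motifs, routes 80% of flux through a preferred branch (cycling
#' through the branches with `d`) and splits the remaining 20% evenly.
#' Designed routings satisfy mass balance exactly; futile-cycle reactions are
#' designed at zero flux.
#'
#' @param net A [make_network()] network (original, reversible form).
#' @param D Number of conditions (>= 1).
#' @return list(conditions = list of [condition_spec()],
#'   designed = reactions x conditions matrix of designed net fluxes).
#' @export
make_condition_set <- function(net, D) {
  stopifnot(D >= 1)
  rxn <- net$reaction_ids
  uptake_bound <- unname(net$ub["EX_A"])
  branches <- grep("^BR", rxn, value = TRUE)
  designed <- matrix(0, length(rxn), D,
                     dimnames = list(rxn, paste0("C", seq_len(D))))
  conditions <- vector("list", D)
  for (d in seq_len(D)) {
    u <- uptake_bound * (1 - 0.1 * ((d - 1) %% 5))
    v <- stats::setNames(numeric(length(rxn)), rxn)
    v["EX_A"] <- u
    if (length(branches)) {
      pref <- branches[((d - 1) %% length(branches)) + 1]
      rest <- setdiff(branches, pref)
      v[pref] <- 0.8 * u
      if (length(rest)) v[rest] <- 0.2 * u / length(rest)
      v[c("TRANS", "R3", "R4", "BIOMASS")] <- u
    } else if ("R1" %in% rxn && "R2" %in% rxn) {   # diamond
      north <- if (d %% 2 == 1) 0.8 else 0.2
      v[c("R1", "R3")] <- north * u
      v[c("R2", "R4")] <- (1 - north) * u
      v[c("TRANS", "BIOMASS")] <- u
    } else {                                       # linear chain
      v[c("R1", "TRANS", "R3", "BIOMASS")] <- u
    }
    designed[, d] <- v
    conditions[[d]] <- condition_spec(paste0("C", d), uptake = c(EX_A = u))
  }
  names(conditions) <- colnames(designed)
  list(conditions = conditions, designed = designed)
}

#' Generate an expression table from designed fluxes
#'
#' Each reaction's designed flux profile is scaled to its cross-condition
#' maximum; each gene inherits the highest relative profile among the
#' reactions it participates in (a gene must be expressed wherever any of its
#' reactions carries flux; under AND every subunit is needed, under OR the
#' generator expresses each isozyme gene with its own branch). Genes attached
#' to no reaction get a constant baseline of 0.5. Values are scaled to a
#' platform-like magnitude (`scale`, default 100) and perturbed by
#' multiplicative log-normal noise with standard deviation `noise_sd` on the
#' log scale.
#'
#' @param net A [make_network()] network.
#' @param designed Designed flux matrix from [make_condition_set()].
#' @param noise_sd Log-scale noise standard deviation (0 = noiseless).
#' @param seed Mandatory RNG seed for the noise.
#' @param scale Expression magnitude of a fully active gene.
#' @return Numeric gene x condition matrix.
#' @export
make_expression <- function(net, designed, noise_sd = 0, seed, scale = 100) {
  stopifnot(!missing(seed))
  rel <- abs(designed)
  rmax <- apply(rel, 1, max)
  ok <- rmax > 0
  rel[ok, ] <- rel[ok, , drop = FALSE] / rmax[ok]
  genes <- net$gene_ids
  E <- matrix(0.5, length(genes), ncol(designed),
              dimnames = list(genes, colnames(designed)))
  for (g in genes) {
    in_rxn <- which(vapply(net$rules, function(r) g %in% rule_genes(r),
                           logical(1)))
    if (length(in_rxn)) {
      E[g, ] <- apply(rel[net$reaction_ids[in_rxn], , drop = FALSE], 2, max)
    }
  }
  T <- scale * E
  if (noise_sd > 0) {
    old <- .Random.seed__save()
    on.exit(.Random.seed__restore(old), add = TRUE)
    set.seed(seed)
    T <- T * matrix(exp(stats::rnorm(length(T), 0, noise_sd)),
                    nrow(T), ncol(T))
  }
  T
}

.Random.seed__save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed__restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a complete fixture set to a directory
#'
#' Emits the model (SBML + JSON), the expression table, the per-condition
#' measured-uptake table, and the designed net fluxes, all as plain text.
#'
#' @param dir Output directory (created if needed).
#' @param motif,n_branches,uptake_bound Passed to [make_network()].
#' @param D Number of conditions.
#' @param noise_sd,seed Passed to [make_expression()].
#' @return Invisibly, the list of written paths.
#' @export
write_fixtures <- function(dir, motif = "parallel_branches", n_branches = 2,
                           uptake_bound = 10, D = 3, noise_sd = 0, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- make_network(motif, n_branches, uptake_bound)
  cs <- make_condition_set(net, D)
  expr <- make_expression(net, cs$designed, noise_sd, seed)
  paths <- list(
    sbml = file.path(dir, "model.xml"),
    json = file.path(dir, "model.json"),
    expression = file.path(dir, "expression.tsv"),
    conditions = file.path(dir, "conditions.tsv"),
    designed = file.path(dir, "designed_fluxes.tsv"))
  write_network(net, paths$sbml, "sbml")
  write_network(net, paths$json, "json")
  write_expression(expr, paths$expression)
  cond_df <- do.call(rbind, lapply(cs$conditions, function(cd) {
    data.frame(condition_id = cd$condition_id,
               reaction_id = names(cd$uptake),
               value = unname(cd$uptake), stringsAsFactors = FALSE)
  }))
  utils::write.table(cond_df, paths$conditions, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  des_df <- data.frame(reaction = rownames(cs$designed),
                       as.data.frame(cs$designed), check.names = FALSE)
  utils::write.table(des_df, paths$designed, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a conditions table written by [write_fixtures()]
#'
#' @param path TSV with columns condition_id, reaction_id, value.
#' @return Named list of [condition_spec()] objects.
#' @export
read_conditions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("condition_id", "reaction_id", "value") %in% names(df)))
  out <- lapply(split(df, df$condition_id), function(d) {
    condition_spec(d$condition_id[1],
                   uptake = stats::setNames(d$value, d$reaction_id))
  })
  out[unique(df$condition_id)]
}
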