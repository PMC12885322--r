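# Model container, GPR parsing, SBML/JSON round trips, irreversible split.

test_that("GPR parsing respects parentheses, precedence, and flattening", {
  ast <- parse_gpr("g1 and g2")
  expect_equal(ast$kind, "and")
  expect_equal(vapply(ast$children, `[[`, character(1), "gene"), c("g1", "g2"))

  ast <- parse_gpr("(g1 and g2) or g3")
  expect_equal(ast$kind, "or")
  expect_equal(ast$children[[1]]$kind, "and")
  expect_equal(ast$children[[2]]$gene, "g3")

  # AND binds tighter than OR when unparenthesised
  ast <- parse_gpr("g1 or g2 and g3")
  expect_equal(ast$kind, "or")
  expect_equal(ast$children[[1]]$gene, "g1")
  expect_equal(ast$children[[2]]$kind, "and")

  # flattening: runs collapse into one >=2-child node
  ast <- parse_gpr("g1 and g2 and g3 and g4")
  expect_length(ast$children, 4)

  # tolerated operator spellings
  expect_equal(gpr_serialize(parse_gpr("g1 AND g2 Or g3")),
               "(g1 and g2) or g3")
  expect_null(parse_gpr(""))
})

test_that("GPR parse errors carry a position", {
  expect_error(parse_gpr("(g1 and g2"), "unbalanced")
  expect_error(parse_gpr("g1 and"), "dangling")
  expect_error(parse_gpr("g1 ) g2"), "position")
})

test_that("parser agrees with R's own boolean parser on random rules", {
  # independent oracle: translate to &&/|| and let R's parser (same AND-over-
  # OR precedence) evaluate both on random truth assignments
  set.seed(42)
  genes <- paste0("g", 1:5)
  for (rep in 1:50) {
    n_tok <- sample(3:7, 1)
    toks <- sample(genes, n_tok, replace = TRUE)
    ops <- sample(c("and", "or"), n_tok - 1, replace = TRUE)
    rule <- paste(c(rbind(toks[-n_tok], ops)), collapse = " ")
    rule <- paste(rule, toks[n_tok])
    ast <- parse_gpr(rule)
    r_expr <- str2lang(gsub(" or ", " | ", gsub(" and ", " & ", rule)))
    for (k in 1:5) {
      vals <- stats::setNames(sample(c(0, 1), 5, replace = TRUE), genes)
      mine <- evaluate_rule(ast, vals)
      rs <- eval(r_expr, envir = as.list(vals == 1))
      expect_equal(mine, as.numeric(rs))
    }
  }
})

test_that("serialize/parse is the identity on ASTs", {
  set.seed(7)
  for (rep in 1:25) {
    # canonical form: same-operator runs flattened (what parse_gpr emits)
    ast <- parse_gpr(gpr_serialize(random_ast(paste0("b", 1:6))))
    expect_equal(parse_gpr(gpr_serialize(ast)), ast)
  }
})

test_that("JSON and SBML encodings of the same fixture load identically", {
  net <- make_network("parallel_branches")
  tmp_json <- withr::local_tempfile(fileext = ".json")
  tmp_sbml <- withr::local_tempfile(fileext = ".xml")
  write_network(net, tmp_json)
  write_network(net, tmp_sbml)
  nj <- load_network(tmp_json)
  ns <- load_network(tmp_sbml)
  expect_equal(dim(nj$S), c(5L, 7L))
  # identical up to row/column ordering by id
  ord_m <- order(nj$metabolite_ids); ord_r <- order(nj$reaction_ids)
  expect_equal(nj$S[ord_m, ord_r], ns$S[order(ns$metabolite_ids),
                                        order(ns$reaction_ids)])
  expect_equal(nj$lb[ord_r], ns$lb[ord_r])
  expect_equal(nj$ub[ord_r], ns$ub[ord_r])
  expect_equal(nj$obj_coef[ord_r], ns$obj_coef[ord_r])
  expect_equal(nj$subsystem[ord_r], ns$subsystem[ord_r])
  expect_equal(lapply(nj$rules, gpr_serialize), lapply(ns$rules, gpr_serialize))
  expect_equal(sort(nj$gene_ids), sort(ns$gene_ids))
})

test_that("models without GPR strings load with all rules empty", {
  mets <- c("A", "B")
  S <- matrix(c(1, 0, -1, 1, 0, -1), 2, 3,
              dimnames = list(mets, c("EX", "R", "OUT")))
  net <- metabolic_network(mets, c("EX", "R", "OUT"), S,
                           lb = c(0, 0, 0), ub = c(10, 1000, 1000),
                           obj_coef = c(0, 0, 1))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_network(net, tmp)
  re <- load_network(tmp)
  expect_true(all(vapply(re$rules, is.null, logical(1))))
  expect_equal(re$subsystem, stats::setNames(rep("unassigned", 3),
                                             re$reaction_ids))
})

test_that("loading errors are informative", {
  expect_error(load_network("/no/such/file.json"), "not found")
  tmp <- withr::local_tempfile(fileext = ".json")
  writeLines('{"reactions": [{"id": "R1", "metabolites": {"ghost": 1}}],
              "metabolites": [{"id": "A"}], "genes": []}', tmp)
  expect_error(load_network(tmp), "unknown metabolite")
})

test_that("irreversible split tracks pairs, flips backward-only reactions", {
  net <- census_network()
  irr <- to_irreversible(net)
  expect_equal(length(irr$reaction_ids), 6L)      # 1 reversible split
  expect_equal(nrow(irr$re_pairs), 1L)
  expect_true(all(irr$lb == 0))
  f <- irr$re_pairs[1, "forward"]; b <- irr$re_pairs[1, "backward"]
  expect_equal(irr$S[, f], -irr$S[, b])
  # rules and subsystems duplicated onto both directions
  expect_equal(irr$subsystem[f], irr$subsystem[b], ignore_attr = TRUE)

  # backward-only reaction is flipped, not split
  mets <- c("A", "B")
  S <- matrix(c(1, 0, 1, -1, 0, -1), 2, 3,
              dimnames = list(mets, c("EX", "RBACK", "OUT")))
  net2 <- metabolic_network(mets, c("EX", "RBACK", "OUT"), S,
                            lb = c(0, -5, 0), ub = c(10, 0, 1000),
                            obj_coef = c(0, 0, 1))
  irr2 <- to_irreversible(net2)
  expect_equal(length(irr2$reaction_ids), 3L)
  expect_equal(nrow(irr2$re_pairs), 0L)
  j <- match("RBACK_b", irr2$reaction_ids)
  expect_equal(unname(irr2$lb[j]), 0)
  expect_equal(unname(irr2$ub[j]), 5)
  expect_equal(irr2$provenance$sign[j], -1)

  # fully irreversible network passes through
  net3 <- make_network("linear_chain")
  net3$lb["TRANS"] <- 0
  irr3 <- to_irreversible(net3)
  expect_equal(irr3$reaction_ids, net3$reaction_ids)
  expect_equal(nrow(irr3$re_pairs), 0L)
})

test_that("FBA optimum is preserved by the irreversible conversion", {
  # oracle: solve the reversible LP directly, compare objectives
  set.seed(11)
  motifs <- c("parallel_branches", "linear_chain", "diamond_gpr",
              "branched_with_loop")
  for (rep in 1:20) {
    up <- stats::runif(1, 4, 15)
    net <- make_network(motifs[(rep - 1) %% 4 + 1], uptake_bound = up)
    lp <- fluxweaver:::new_lp()
    fluxweaver:::lp_add_vars(lp, net$reaction_ids, lb = net$lb, ub = net$ub,
                             obj = net$obj_coef)
    for (i in seq_along(net$metabolite_ids)) {
      nz <- which(net$S[i, ] != 0)
      fluxweaver:::lp_add_constr(lp, nz, net$S[i, nz], "=", 0)
    }
    direct <- fluxweaver:::lp_solve(lp, maximize = TRUE)
    irr <- to_irreversible(net)
    split <- solve_fba(irr)
    expect_equal(split$objective, direct$objective, tolerance = 1e-6)
    # mass balance of the collapsed solution on the original model
    v <- collapse_fluxes(irr, split$flux)
    expect_lt(max(abs(net$S %*% v[net$reaction_ids])), 1e-8)
  }
})

test_that("collapse_fluxes nets split pairs and round-trips", {
  net <- census_network()
  irr <- to_irreversible(net)
  n <- length(irr$reaction_ids)
  f <- irr$re_pairs[1, "forward"]; b <- irr$re_pairs[1, "backward"]
  v <- numeric(n); v[f] <- 3
  expect_equal(unname(collapse_fluxes(irr, v)["TRANS"]), 3)
  v <- numeric(n); v[b] <- 2
  expect_equal(unname(collapse_fluxes(irr, v)["TRANS"]), -2)
  expect_error(collapse_fluxes(irr, numeric(n + 1)), "length")

  # split-consistent vectors round-trip: one direction active at a time
  set.seed(3)
  for (rep in 1:20) {
    target <- stats::setNames(stats::runif(5, -4, 4), net$reaction_ids)
    target[net$lb >= 0] <- abs(target[net$lb >= 0])
    v <- numeric(n)
    for (r in seq_len(n)) {
      orig <- irr$provenance$orig_id[r]; sgn <- irr$provenance$sign[r]
      val <- target[[orig]]
      v[r] <- if (sign(val) == sgn || (val == 0)) abs(val) else 0
    }
    expect_equal(collapse_fluxes(irr, v), target)
  }
})
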