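# The expression-integration MILP: assembly, solving, variants, invariants.

test_that("the balance constant B follows (2k + 2n) / v_biomass_max", {
  net <- to_irreversible(make_network("linear_chain", uptake_bound = 10))
  cfg <- integration_config(exp_mode = "upper")
  B <- compute_B(net, cfg = cfg)
  k <- length(net$gene_ids); n <- length(net$reaction_ids)
  f_star <- solve_fba(net)$objective
  expect_equal(B, (2 * k + 2 * n) / f_star, tolerance = 1e-9)
  # doubling the optimum halves B
  net2 <- to_irreversible(make_network("linear_chain", uptake_bound = 20))
  expect_equal(compute_B(net2, cfg = cfg), B / 2, tolerance = 1e-9)
  # B * v_max equals the deviation-variable budget 2k + 2n
  expect_equal(B * f_star, 2 * k + 2 * n, tolerance = 1e-9)
})

test_that("problem assembly emits the expected variable census", {
  net <- to_irreversible(census_network())
  cond <- condition_spec("c1", uptake = c(EX_A = 10))
  # two conditions so the envelope has spread (a unique-flux chain under a
  # single condition is pinned, hence degenerate)
  cond_b <- condition_spec("c2", uptake = c(EX_A = 7))
  env <- build_envelope(list(run_fva(net, cond, p = 1),
                             run_fva(net, cond_b, p = 1)))
  gtilde <- stats::setNames(c(0.8, 0.6, 0.4), net$gene_ids)
  B <- compute_B(net, cond)
  prob <- build_integration(net, env, gtilde, cond, integration_config(), ctilde = B)
  vn <- prob$lp$var_name
  n <- length(net$reaction_ids)
  expect_equal(sum(startsWith(vn, "v_")), n)              # 6 fluxes
  expect_equal(sum(startsWith(vn, "b_")), 2)              # only the split pair
  expect_equal(sum(startsWith(vn, "g_")), 3)              # 3 genes
  expect_equal(sum(grepl("_aux", vn)), 2)                 # 2 rule-bearing rxns
  expect_equal(sum(startsWith(vn, "delta")), 6)           # 2 per measured gene
  expect_equal(sum(startsWith(vn, "eps")), 4)             # 2 per matched rxn

  # unmeasured gene loses its anchoring row and deviations
  gt2 <- gtilde; gt2[2] <- NA
  prob2 <- build_integration(net, env, gt2, cond, integration_config(), ctilde = B)
  expect_equal(sum(startsWith(prob2$lp$var_name, "delta")), 4)

  # degenerate envelope entry loses its matching row and deviations
  env3 <- env
  env3$degenerate[match("R1", net$reaction_ids)] <- TRUE
  prob3 <- build_integration(net, env3, gtilde, cond, integration_config(), ctilde = B)
  expect_equal(sum(startsWith(prob3$lp$var_name, "eps")), 2)
})

test_that("expression routes flux through the favoured isozyme branch", {
  # oracle: exhaustive binary enumeration confirms the optimum; with branch
  # activities 1 vs 0, the favoured branch must carry (nearly) all flux
  net <- to_irreversible(make_network("parallel_branches", uptake_bound = 10))
  cond <- condition_spec("c1", uptake = c(EX_A = 10))
  fva <- run_fva(net, cond, p = 1)
  env <- build_envelope(list(fva))
  gtilde <- stats::setNames(rep(1, length(net$gene_ids)), net$gene_ids)
  gtilde["gb2"] <- 0                       # second isozyme branch silent
  cfg <- integration_config()
  prob <- build_integration(net, env, gtilde, cond, cfg,
                    ctilde = compute_B(net, cond))
  sol <- solve_integration(prob)
  total <- sol$flux_net[["EX_A"]]
  expect_gte(sol$flux_net[["BR1"]], 0.9 * total)
  expect_lte(sol$flux_net[["BR2"]], 0.1 * total)
  expect_equal(sol$z_star, enumerate_milp_optimum(prob$lp), tolerance = 1e-6)
})

test_that("with a dominant biomass weight the MILP reaches the FBA optimum", {
  net0 <- make_network("parallel_branches")
  net <- to_irreversible(net0)
  cs <- make_condition_set(net0, 2)
  # uniform expression 0.5 carries no routing signal
  expr <- matrix(50, length(net$gene_ids), 2,
                 dimnames = list(net$gene_ids, c("C1", "C2")))
  cfg <- integration_config(transform = "minmax", ctilde = "2B")
  run <- run_multi_condition(net, expr, cs$conditions, cfg)
  for (id in names(run$solutions)) {
    fba <- solve_fba(net, cs$conditions[[id]])
    expect_equal(run$solutions[[id]]$biomass, fba$objective, tolerance = 1e-6)
  }
})

test_that("a vanishing biomass weight drives predicted biomass toward zero", {
  # fixture where zero flux zeroes every deviation: envelope floors at 0
  # (free-objective FVA), uptake only bounded above, silent expression
  net <- to_irreversible(make_network("linear_chain"))
  cond <- condition_spec("c1", uptake = c(EX_A = 10))
  fva <- run_fva(net, cond, p = 0, retention = "ge", exp_mode = "upper")
  env <- build_envelope(list(fva))
  gtilde <- stats::setNames(rep(0, length(net$gene_ids)), net$gene_ids)
  cfg <- integration_config(exp_mode = "upper")
  fba <- solve_fba(net, cond, exp_mode = "upper")
  B <- compute_B(net, cond, cfg)
  tiny <- build_integration(net, env, gtilde, cond, cfg, ctilde = B / 1e6)
  expect_lt(solve_integration(tiny)$biomass, 0.01 * fba$objective)
  # same fixture at a dominant weight recovers full growth
  big <- build_integration(net, env, gtilde, cond, cfg, ctilde = 2 * B)
  expect_equal(solve_integration(big)$biomass, fba$objective, tolerance = 1e-6)
})

test_that("biomass never exceeds FBA and grows with the biomass weight", {
  for (seed in 1:2) {
    net0 <- make_network(c("parallel_branches", "linear_chain")[seed %% 2 + 1],
                         uptake_bound = 6 + seed)
    net <- to_irreversible(net0)
    cs <- make_condition_set(net0, 2)
    expr <- make_expression(net0, cs$designed, noise_sd = 0.05, seed = seed)
    fba <- solve_fba(net, cs$conditions[[1]])
    biomasses <- c()
    for (ct in c("B/1000", "B/100", "B/10", "B", "2B")) {
      cfg <- integration_config(transform = "max_reference", ctilde = ct)
      run <- run_multi_condition(net, expr, cs$conditions[1], cfg)
      b <- run$solutions[["C1"]]$biomass
      expect_lte(b, fba$objective + 1e-6)
      biomasses <- c(biomasses, b)
    }
    expect_true(all(diff(biomasses) >= -1e-6))
  }
})

test_that("split pairs are integer-exact: one direction per pair", {
  fix <- branch_run(D = 3, transform = "max_reference")
  net <- fix$run$net
  for (sol in fix$run$solutions) {
    for (r in seq_len(nrow(net$re_pairs))) {
      f <- sol$flux[net$re_pairs[r, "forward"]]
      b <- sol$flux[net$re_pairs[r, "backward"]]
      expect_lt(min(f, b), 1e-9)
    }
  }
})

test_that("deviation pairs are complementary at optimality", {
  fix <- branch_run(D = 3, transform = "max_reference")
  for (sol in fix$run$solutions) {
    x <- attr(sol, "x_full")
    nm <- fix$run$net$gene_ids
    for (g in nm) {
      d1 <- x[paste0("delta1_", g)]; d2 <- x[paste0("delta2_", g)]
      if (!is.na(d1)) expect_lt(d1 * d2, 1e-10)
    }
  }
})

test_that("MILP optimum matches exhaustive binary enumeration", {
  for (seed in 1:3) {
    motif <- c("parallel_branches", "linear_chain")[seed %% 2 + 1]
    net0 <- make_network(motif, uptake_bound = 5 + seed)
    net <- to_irreversible(net0)
    D <- 2
    cs <- make_condition_set(net0, D)
    expr <- make_expression(net0, cs$designed, noise_sd = 0.1, seed = seed)
    cfg <- integration_config(transform = "max_reference")
    rel <- align_to_model(relative_expression(expr, "max_reference"), net)
    fvas <- lapply(cs$conditions, function(cd) run_fva(net, cd, p = 1))
    env <- build_envelope(fvas)
    cond <- cs$conditions[[1]]
    B <- compute_B(net, cond)
    prob <- build_integration(net, env, rel[, 1], cond, cfg, ctilde = B)
    expect_lte(sum(prob$lp$integer), 12)
    sol <- solve_integration(prob)
    oracle <- enumerate_milp_optimum(prob$lp)
    expect_equal(sol$z_star, oracle, tolerance = 1e-6)
  }
})

test_that("the L1 step empties futile cycles and preserves the optimum", {
  net0 <- make_network("branched_with_loop")
  net <- to_irreversible(net0)
  cs <- make_condition_set(net0, 2)
  expr <- make_expression(net0, cs$designed, 0, seed = 1)
  cfg <- integration_config(transform = "max_reference")
  rel <- align_to_model(relative_expression(expr, "max_reference"), net)
  fvas <- lapply(cs$conditions, function(cd) run_fva(net, cd, p = 1))
  env <- build_envelope(fvas)
  cond <- cs$conditions[[1]]
  prob <- build_integration(net, env, rel[, 1], cond, cfg,
                    ctilde = compute_B(net, cond))
  base <- solve_integration(prob)
  l1 <- solve_integration_l1(prob, cfg, base = base)
  # loop reactions carry no flux after the L1 step
  expect_equal(unname(l1$flux_net[["L1"]]), 0, tolerance = 1e-7)
  expect_equal(unname(l1$flux_net[["L2"]]), 0, tolerance = 1e-7)
  expect_lte(sum(l1$flux), sum(base$flux) + 1e-7)
  # objective retention: recomputed step-1 objective stays within tolerance
  recomputed <- -prob$ctilde * l1$biomass + l1$deviation_gene +
    l1$deviation_flux
  expect_equal(recomputed, base$z_star,
               tolerance = 1e-5 * max(1, abs(base$z_star)))
})

test_that("L1 leaves an already-unique optimum untouched", {
  net0 <- make_network("linear_chain")
  net <- to_irreversible(net0)
  cs <- make_condition_set(net0, 2)
  expr <- make_expression(net0, cs$designed, 0, seed = 1)
  cfg <- integration_config(transform = "max_reference")
  rel <- align_to_model(relative_expression(expr, "max_reference"), net)
  env <- build_envelope(lapply(cs$conditions, function(cd)
    run_fva(net, cd, p = 1)))
  cond <- cs$conditions[[1]]
  prob <- build_integration(net, env, rel[, 1], cond, cfg,
                    ctilde = compute_B(net, cond))
  base <- solve_integration(prob)
  l1 <- solve_integration_l1(prob, cfg, base = base)
  expect_equal(l1$flux, base$flux, tolerance = 1e-6)
})

test_that("the L2 step splits symmetric parallel branches evenly", {
  # closed form: min x^2 + (T - x)^2 over a fixed total T is x = T/2
  net0 <- make_network("parallel_branches")
  net <- to_irreversible(net0)
  cond <- condition_spec("c1", uptake = c(EX_A = 10))
  # both branch genes equally expressed -> no preference
  expr <- matrix(c(80, 60, 80, 60, 90, 70, 90, 70, 50, 40, 50, 40, 30, 20,
                   30, 20, 70, 50),
                 nrow = 9, ncol = 2, byrow = TRUE,
                 dimnames = list(net$gene_ids, c("c1", "c2")))
  cfg <- integration_config(transform = "max_reference")
  rel <- align_to_model(relative_expression(expr, "max_reference"), net)
  cond2 <- condition_spec("c2", uptake = c(EX_A = 8))
  env <- build_envelope(list(run_fva(net, cond, p = 1),
                             run_fva(net, cond2, p = 1)))
  prob <- build_integration(net, env, rel[, 1], cond, cfg,
                    ctilde = compute_B(net, cond))
  base <- solve_integration(prob)
  l2 <- solve_integration_l2(prob, cfg, base = base)
  total <- l2$flux_net[["EX_A"]]
  expect_equal(unname(l2$flux_net[["BR1"]]), total / 2, tolerance = 1e-4)
  expect_equal(unname(l2$flux_net[["BR2"]]), total / 2, tolerance = 1e-4)
  # smoothness: the L2 solution's sum of squares never exceeds L1's
  l1 <- solve_integration_l1(prob, cfg, base = base)
  expect_lte(sum(l2$flux^2), sum(l1$flux^2) + 1e-6)
})

test_that("two-step variants retain the step-1 objective on varied fixtures", {
  for (seed in 1:5) {
    motif <- c("parallel_branches", "branched_with_loop")[seed %% 2 + 1]
    net0 <- make_network(motif, uptake_bound = 6 + seed)
    net <- to_irreversible(net0)
    cs <- make_condition_set(net0, 2)
    expr <- make_expression(net0, cs$designed, noise_sd = 0.05, seed = seed)
    cfg <- integration_config(transform = "max_reference")
    rel <- align_to_model(relative_expression(expr, "max_reference"), net)
    env <- build_envelope(lapply(cs$conditions, function(cd)
      run_fva(net, cd, p = 1)))
    cond <- cs$conditions[[1]]
    prob <- build_integration(net, env, rel[, 1], cond, cfg,
                      ctilde = compute_B(net, cond))
    base <- solve_integration(prob)
    for (variant in c("l1", "l2")) {
      sol <- if (variant == "l1") solve_integration_l1(prob, cfg, base = base)
             else solve_integration_l2(prob, cfg, base = base)
      recomputed <- -prob$ctilde * sol$biomass + sol$deviation_gene +
        sol$deviation_flux
      expect_equal(recomputed, base$z_star,
                   tolerance = 2e-6 * max(1, abs(base$z_star)))
    }
  }
})

test_that("condition order does not affect per-condition solutions", {
  fix <- branch_run(D = 3, transform = "max_reference")
  net0 <- fix$net0
  cfg <- fix$cfg
  rev_run <- run_multi_condition(to_irreversible(net0), fix$expr,
                                 rev(fix$cs$conditions), cfg)
  for (id in names(fix$run$solutions)) {
    expect_equal(rev_run$solutions[[id]]$z_star,
                 fix$run$solutions[[id]]$z_star, tolerance = 1e-7)
    expect_equal(rev_run$solutions[[id]]$flux_net,
                 fix$run$solutions[[id]]$flux_net, tolerance = 1e-6)
  }
})

test_that("noiseless designed routings are recovered per condition", {
  fix <- branch_run(D = 3, transform = "max_reference")
  for (id in names(fix$run$solutions)) {
    designed <- fix$cs$designed[, id]
    solved <- fix$run$solutions[[id]]$flux_net[names(designed)]
    expect_gte(uncentered_pearson(solved, designed), 0.9)
  }
})
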