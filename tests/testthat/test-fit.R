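test_that("model specs count free parameters and encode sharing", {
  tags <- c("0", "1", "2", "3")
  expect_equal(omegarelax:::.n_free_params(spec_neutral(tags)), 1)  # kappa
  expect_equal(omegarelax:::.n_free_params(spec_single_omega(tags)), 2)
  expect_equal(omegarelax:::.n_free_params(spec_clade_omega(tags)), 4)
  expect_equal(omegarelax:::.n_free_params(spec_forced_neutral("3", tags)), 3)
  sp <- spec_clade_omega(tags)
  expect_identical(unname(sp$omega[["0"]]), "w1")  # backbone shares clade 1
  expect_error(model_spec("x", c(0.5, 0.5)), "named")
  expect_error(model_spec("x", c("0" = -1)), ">= 0")
})

test_that("single-omega fit recovers the generating parameters", {
  tr <- fixture_ingroup_tree()
  sc <- fixture_scenario()
  aln <- simulate_codon_alignment(tr, 500, kappa = 2, omega = 0.3, pi = sc$pi,
                                  seed = 77)
  f <- fit_model(aln, tr, spec_single_omega(c("0", "1", "2", "3")),
                 branch_lengths = "optimize", pi = sc$pi, seed = 1)
  expect_true(f$converged)
  expect_gt(f$omega_hat[["0"]], 0.25)
  expect_lt(f$omega_hat[["0"]], 0.36)
  expect_gt(f$kappa_hat, 1.4)
  expect_lt(f$kappa_hat, 2.8)
  expect_equal(f$n_restarts_used, 3)
  # nesting: neutral lnL never exceeds the single-omega lnL
  fn <- fit_model(aln, f$tree, spec_neutral(c("0", "1", "2", "3")),
                  branch_lengths = "fixed", pi = sc$pi, n_starts = 1)
  expect_lte(fn$lnL, f$lnL + 1e-6)
  expect_equal(fn$n_free_params, 1)
})

test_that("fitted lnL is monotone along the declared nesting chain", {
  tr <- fixture_ingroup_tree()
  sc <- fixture_scenario()
  tags <- c("0", "1", "2", "3")
  aln <- simulate_codon_alignment(tr, 300, kappa = 2,
                                  omega = c("0" = 0.3, "1" = 0.3, "2" = 0.2,
                                            "3" = 1.0),
                                  pi = sc$pi, seed = 78)
  ref <- fit_model(aln, tr, spec_single_omega(tags),
                   branch_lengths = "optimize", pi = sc$pi, seed = 2)
  fixed <- ref$tree
  neutral <- fit_model(aln, fixed, spec_neutral(tags), pi = sc$pi, n_starts = 1)
  single <- fit_model(aln, fixed, spec_single_omega(tags), pi = sc$pi,
                      n_starts = 1, init = c(list(kappa = ref$kappa_hat),
                                             as.list(ref$free_omega)))
  clade <- fit_model(aln, fixed, spec_clade_omega(tags), pi = sc$pi,
                     n_starts = 2, seed = 2)
  forced <- fit_model(aln, fixed, spec_forced_neutral("3", tags), pi = sc$pi,
                      n_starts = 2, seed = 2)
  expect_lte(neutral$lnL, single$lnL + 1e-6)
  expect_lte(single$lnL, clade$lnL + 1e-6)
  expect_lte(forced$lnL, clade$lnL + 1e-6)
  # clade fit separates the neutralized clade from the purifying ones
  expect_gt(clade$omega_hat[["3"]], 0.55)
  expect_lt(clade$omega_hat[["2"]], 0.45)
})

test_that("branch-site Model A respects nesting and its mixture contract", {
  tr <- parse_newick(paste0("(((A:0.08,B:0.08):0.06,(C:0.08,D:0.08):0.06):0.05,",
                            "((E:0.08,F:0.08):0.06,(G:0.08,H:0.08):0.06):0.05);"))
  groups <- list(strain_group("fg", c("E", "F", "G", "H")),
                 strain_group("bg", c("A", "B", "C", "D")))
  lab <- label_clades(tr, groups)
  aln <- simulate_codon_alignment(lab, 150, kappa = 2, omega = 0.3, seed = 33)
  null <- fit_branch_site(aln, lab, "1", "null", seed = 1)
  # the alternative is seeded from the null solution (the cascade's chain),
  # which guarantees the nesting contract
  alt <- fit_branch_site(aln, lab, "1", "alt", seed = 1,
                         init = list(kappa = null$kappa_hat,
                                     p0 = unname(null$mixture$proportions["p0"]),
                                     p1 = unname(null$mixture$proportions["p1"]),
                                     omega0 = null$mixture$omega0,
                                     omega2 = 1 + 1e-4))
  expect_gte(alt$lnL, null$lnL - 1e-6)
  expect_equal(alt$n_free_params - null$n_free_params, 1)
  expect_equal(sum(alt$mixture$proportions), 1, tolerance = 1e-9)
  expect_true(all(alt$mixture$proportions >= 0))
  expect_gte(alt$mixture$omega2, 1)
  expect_equal(null$omega_hat[["omega2"]], 1)
  expect_lte(alt$mixture$omega0, 1)
  l <- lrt(null, alt)
  expect_equal(l$df, 1)
  expect_gte(l$stat, 0)
  expect_error(fit_branch_site(aln, lab, "9", "alt"), "not present")
})

test_that("branch-site LRT detects planted foreground positive selection", {
  tr <- parse_newick(paste0("(((A:0.08,B:0.08):0.06,(C:0.08,D:0.08):0.06):0.05,",
                            "((E:0.08,F:0.08):0.06,(G:0.08,H:0.08):0.06):0.05);"))
  groups <- list(strain_group("fg", c("E", "F", "G", "H")),
                 strain_group("bg", c("A", "B", "C", "D")))
  lab <- label_clades(tr, groups)
  sig <- vapply(1:4, function(s) {
    a <- simulate_codon_alignment(
      lab, 300, kappa = 2, omega = c("0" = 0.3, "1" = 0.3, "2" = 0.3),
      site_classes = list(p0 = 0.81, p1 = 0.09, omega0 = 0.3, omega2 = 4,
                          foreground = "1"), seed = 1000 + s)
    null <- fit_branch_site(a, lab, "1", "null", seed = s)
    alt <- fit_branch_site(a, lab, "1", "alt", seed = s,
                           init = list(kappa = null$kappa_hat,
                                       p0 = unname(null$mixture$proportions["p0"]),
                                       p1 = unname(null$mixture$proportions["p1"]),
                                       omega0 = null$mixture$omega0,
                                       omega2 = 1 + 1e-4))
    lrt(null, alt)$p < 0.05
  }, logical(1))
  expect_gte(sum(sig), 3)
})
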