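test_that("link decomposition: full-rank, conserved-moiety, and rank cases", {
  ## full row rank: L is the identity
  N <- matrix(c(1, -1, 0, 0, 1, -1), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("r1", "r2", "r3")))
  ld <- link_decomposition(N)
  expect_equal(unname(ld$L), diag(2))
  expect_equal(ld$N_R, N)
  expect_length(ld$dependent, 0L)
  ## moiety pair a + b conserved: one dependent row with partner weight -1
  Nm <- matrix(c(-1, 1), 2, 1, dimnames = list(c("a", "b"), "r1"))
  ldm <- link_decomposition(Nm)
  expect_length(ldm$dependent, 1L)
  expect_equal(dim(ldm$N_R), c(1L, 1L))
  dep_row <- setdiff(rownames(Nm), rownames(ldm$N_R))
  expect_equal(unname(ldm$L[dep_row, 1]), -1)
  expect_equal(Nm, ldm$L %*% ldm$N_R)
  ## rank is preserved on the full model (CoA moiety)
  Nfull <- stoichiometric_matrix(default_km()$model, internal_only = TRUE)
  ldf <- link_decomposition(Nfull)
  expect_equal(qr(ldf$N_R)$rank, qr(Nfull)$rank)
  expect_equal(Nfull, ldf$L %*% ldf$N_R, tolerance = 1e-10)
  expect_error(link_decomposition(matrix(numeric(0), 0, 0)), "empty")
})

test_that("control coefficients: closed form for the two-step pathway", {
  N <- matrix(c(1, -1), 1, 2, dimnames = list("s", c("SUPPLY", "DEMAND")))
  E <- matrix(c(-1, 1), 2, 1, dimnames = list(c("SUPPLY", "DEMAND"), "s"))
  ca <- control_coefficients(N, E, J = c(SUPPLY = 1, DEMAND = 1),
                             conc = c(s = 1))
  expect_equal(unname(ca$C_J), matrix(0.5, 2, 2), tolerance = 1e-12)
  expect_equal(unname(ca$C_S), matrix(c(0.5, -0.5), 1, 2), tolerance = 1e-12)
  ## connectivity theorem on this conservation-free fixture
  expect_lt(max(abs(ca$C_J %*% E)), 1e-12)
  expect_equal(unname(ca$C_S %*% E), -diag(1), tolerance = 1e-12)
})

test_that("summation theorems hold on the full reduced-model fixture", {
  ca <- default_mca()
  expect_lt(max(abs(rowSums(ca$C_J) - 1)), 1e-6)
  expect_lt(max(abs(rowSums(ca$C_S))), 1e-6)
})

test_that("MCA agrees with the finite-difference oracle within 1e-3", {
  ca <- default_mca()
  tc <- oracle_cc()
  expect_lt(max(abs(ca$C_J - tc$C_J)), 1e-3)
  expect_lt(max(abs(ca$C_S - tc$C_S)), 1e-3)
})

test_that("degenerate inputs are rejected with informative errors", {
  N <- matrix(c(1, -1), 1, 2, dimnames = list("s", c("R1", "R2")))
  Ezero <- matrix(0, 2, 1, dimnames = list(c("R1", "R2"), "s"))
  expect_error(control_coefficients(N, Ezero, c(R1 = 1, R2 = 1), c(s = 1)),
               "singular")
  E <- matrix(c(-1, 1), 2, 1, dimnames = list(c("R1", "R2"), "s"))
  expect_error(control_coefficients(N, E, c(R1 = 0, R2 = 1), c(s = 1)),
               "nonzero")
  expect_error(control_coefficients(N, E, c(R1 = 1, R2 = 1), c(s = -1)),
               "positive")
})

test_that("Monte Carlo: degenerate noise collapses to the point estimate", {
  km <- default_km()
  ds <- clean_dataset()
  th <- default_thermo()
  mc <- monte_carlo_mca(ds, km$model, th, n_iter = 5, noise_cv = 0,
                        seed = 11)
  expect_equal(mc$n_dropped, 0L)
  expect_lt(max(mc$summary$hi97.5 - mc$summary$lo2.5), 1e-12)
  sJ <- mc$summary[mc$summary$matrix == "C_J", ]
  for (k in sample(nrow(sJ), 25))
    expect_equal(sJ$median[k], mc$point$C_J[sJ$row[k], sJ$col[k]],
                 tolerance = 1e-12)
})

test_that("Monte Carlo summaries are seed-reproducible and well-formed", {
  km <- default_km()
  ds <- clean_dataset()
  th <- default_thermo()
  m1 <- monte_carlo_mca(ds, km$model, th, n_iter = 25, noise_cv = 0.05,
                        seed = 4)
  m2 <- monte_carlo_mca(ds, km$model, th, n_iter = 25, noise_cv = 0.05,
                        seed = 4)
  expect_identical(m1$summary, m2$summary)
  expect_true(all(m1$summary$lo2.5 <= m1$summary$median + 1e-12))
  expect_true(all(m1$summary$median <= m1$summary$hi97.5 + 1e-12))
  ok <- !is.na(m1$summary$sign_stability)
  expect_true(all(m1$summary$sign_stability[ok] >= 0.5 - 1e-12))
  expect_true(all(m1$summary$sign_stability[ok] <= 1))
})

test_that("Monte Carlo interval width shrinks as the noise CV vanishes", {
  km <- default_km()
  ds <- clean_dataset()
  th <- default_thermo()
  width <- vapply(c(0.1, 0.01, 0.001), function(cv) {
    mc <- monte_carlo_mca(ds, km$model, th, n_iter = 40, noise_cv = cv,
                          seed = 8)
    s <- mc$summary[mc$summary$matrix == "C_J", ]
    stats::median(s$hi97.5 - s$lo2.5)
  }, numeric(1))
  expect_true(all(diff(width) < 0))
  expect_lt(width[3], width[1] / 10)
})

test_that("control pattern report ranks enzymes over the export flux", {
  ca <- default_mca()
  rep <- control_pattern_report(ca, target = "YdeD")
  expect_equal(nrow(rep), ncol(ca$C_J))
  expect_true(all(diff(rep$C_J) <= 1e-12))       # sorted descending
  expect_true(all(is.finite(rep$C_J)))
  expect_error(control_pattern_report(ca, target = "NOPE"), "unknown")
  ## deterministic tie-break by enzyme id
  rep2 <- control_pattern_report(ca, target = "YdeD")
  expect_identical(rep, rep2)
})

test_that("competing cysteine-forming enzymes show mutual negative control", {
  ## CYSS and SLCYSS both consume O-acetylserine; raising one steals
  ## precursor from the other
  ca <- default_mca()
  expect_lt(ca$C_J["CYSS", "SLCYSS"], 0)
  expect_lt(ca$C_J["SLCYSS", "CYSS"], 0)
  expect_gt(ca$C_J["CYSS", "CYSS"], 0)
  expect_gt(ca$C_J["SLCYSS", "SLCYSS"], 0)
  ## the S-sulfocysteine lyase flux mirrors its upstream synthase
  expect_equal(sign(ca$C_J["SCYSSL", "SLCYSS"]),
               sign(ca$C_J["SLCYSS", "SLCYSS"]))
})
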