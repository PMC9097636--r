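# Chemical-shift perturbation, correlation, residue matching, titration.

test_that("CSP follows the composite formula with nitrogen scaling", {
  free <- make_shift_fixture(5)
  expect_true(all(compute_csp(free, free)$csp == 0))
  bound <- shift_table(free$residue, free$aa, free$dH + 0.1,
                       free$dN + 0.7)
  expect_equal(compute_csp(free, bound)$csp,
               rep(sqrt(0.01 + 0.01), 5), tolerance = 1e-12)
  bound2 <- shift_table(free$residue, free$aa, free$dH, free$dN + 7)
  expect_equal(compute_csp(free, bound2)$csp, rep(1, 5), tolerance = 1e-12)
  # magnitude-symmetric in the two states
  b3 <- shift_table(free$residue, free$aa, free$dH + rnorm(5, sd = .05),
                    free$dN + rnorm(5, sd = .3))
  expect_equal(compute_csp(free, b3)$csp, compute_csp(b3, free)$csp)
  # alternate variance reading for sensitivity analysis
  expect_equal(compute_csp(free, bound2, n_mode = "variance")$csp,
               rep(sqrt(49 / 7), 5))
})

test_that("residues missing from the bound state are marked broadened", {
  free <- make_shift_fixture(6)
  bound <- shift_table(free$residue[-3], free$aa[-3], free$dH[-3],
                       free$dN[-3])
  prof <- compute_csp(free, bound)
  expect_true(prof$broadened[prof$residue == 3])
  expect_true(is.na(prof$csp[prof$residue == 3]))
  disjoint <- shift_table(101:106, free$aa, free$dH, free$dN)
  expect_error(compute_csp(free, disjoint), class = "foxdyn_empty_overlap")
})

test_that("shift correlation reproduces identity, sign flips and affine law", {
  tab <- make_shift_fixture(30, seed = 2)
  expect_equal(correlate_shifts(tab, tab), 1.0)
  flipped <- shift_table(tab$residue, tab$aa, 2 * mean(tab$dH) - tab$dH,
                         tab$dN)
  expect_equal(correlate_shifts(tab, flipped, nucleus = "H"), -1.0)
  # invariance under y -> a y + b (a > 0), sign flip for a < 0
  aff <- shift_table(tab$residue, tab$aa, 3 * tab$dH + 2, tab$dN)
  r0 <- correlate_shifts(tab, make_shift_fixture(30, seed = 9))
  expect_equal(correlate_shifts(tab, aff), 1.0)
  neg <- shift_table(tab$residue, tab$aa, -0.5 * tab$dH + 1, tab$dN)
  expect_equal(correlate_shifts(tab, neg), -1.0)
  expect_true(abs(r0) <= 1)
  const <- shift_table(tab$residue, tab$aa, rep(8, 30), tab$dN)
  expect_error(correlate_shifts(tab, const, nucleus = "H"),
               class = "foxdyn_undefined_correlation")
})

test_that("generated homolog tables recover the target correlation", {
  base <- make_shift_fixture(100, seed = 3)
  gh <- gen_homolog_shift_tables(base, 0.8, seed = 14)
  r <- correlate_shifts(gh$table_a, gh$table_b, nucleus = "H")
  # 95% CI of r at rho = 0.8, n = 100 via the Fisher transform
  ci <- tanh(atanh(0.8) + c(-1, 1) * 1.96 / sqrt(97))
  expect_gt(r, ci[1]); expect_lt(r, ci[2])
  perfect <- gen_homolog_shift_tables(base, 1, seed = 15)
  expect_equal(correlate_shifts(perfect$table_a, perfect$table_b), 1.0)
  null <- gen_homolog_shift_tables(base, 0, seed = 16)
  expect_lt(abs(correlate_shifts(null$table_a, null$table_b)), 0.2)
})

test_that("correlation matrices are symmetric with unit diagonal", {
  tabs <- list(a = make_shift_fixture(40, 4),
               b = gen_homolog_shift_tables(make_shift_fixture(40, 4), 0.9,
                                            seed = 5)$table_b,
               c = make_shift_fixture(40, 6))
  m <- shift_correlation_matrix(tabs, nucleus = "N", align = FALSE)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_true(all(m >= -1 & m <= 1))
})

test_that("residue matching aligns sequences and scores identity", {
  m <- match_residues("ACDEF", "ACDEF")
  expect_equal(m$identity_pct, 100)
  expect_equal(nrow(m$pairs), 5L)
  m2 <- match_residues("ACDEF", "ACDQF")
  expect_equal(nrow(m2$pairs), 5L)
  expect_equal(m2$identity_pct, 80)
  # symmetry of identity
  m3 <- match_residues("ACDQF", "ACDEF")
  expect_equal(m3$identity_pct, m2$identity_pct)
  # author numbering offsets propagate into the mapping
  m4 <- match_residues("ACD", "ACD", offset_a = 100, offset_b = 200)
  expect_equal(m4$pairs$res_a, 100:102)
  expect_equal(m4$pairs$res_b, 200:202)
  expect_error(match_residues("", "ACD"),
               class = "foxdyn_precondition_error")
})

test_that("FOXO forkhead domains are highly conserved", {
  fh <- foxo_fh_sequences()
  expect_setequal(fh$isoform, c("FOXO1", "FOXO3", "FOXO4", "FOXO6"))
  m <- match_residues(fh$sequence[fh$isoform == "FOXO1"],
                      fh$sequence[fh$isoform == "FOXO3"])
  expect_gt(m$identity_pct, 90)
})

test_that("titration classification recovers generated response patterns", {
  base <- make_shift_fixture(40, seed = 7)
  tt <- gen_titration_tables(base, strong_set = c(3, 7, 11, 15),
                             weak_set = c(20, 22), broadened_set = 30:33,
                             seed = 8)
  call <- classify_titration(tt$free, tt$bound, tt$free_intensities,
                             tt$bound_intensities)
  expect_gte(mean(as.character(call$category) == tt$truth$category), 0.95)
  expect_equal(attr(call, "summary"), "line broadening")
  # identical endpoints: all unaffected
  quiet <- classify_titration(base, base,
                              setNames(rep(1, 40), base$residue),
                              setNames(rep(1, 40), base$residue))
  expect_true(all(quiet$category == "unaffected"))
  expect_equal(attr(quiet, "summary"), "no binding")
  # intensity-ratio based broadening dominates the summary
  many_broad <- gen_titration_tables(base, broadened_set = 1:12, seed = 9)
  cb <- classify_titration(many_broad$free, many_broad$bound,
                           many_broad$free_intensities,
                           many_broad$bound_intensities)
  expect_true(all(cb$category[cb$residue %in% 1:12] == "broadened"))
  expect_equal(attr(cb, "summary"), "line broadening")
  expect_error(gen_titration_tables(base, strong_set = 1:3,
                                    weak_set = 3:5, seed = 1),
               class = "foxdyn_precondition_error")
})
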