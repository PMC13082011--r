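`%||%` <- function(a, b) if (is.null(a)) b else a

mk_ebs <- function(values, ids = NULL, peps = NULL) {
  m <- if (is.matrix(values)) values else matrix(values, nrow = 1)
  rownames(m) <- ids %||% sprintf("ind%d", seq_len(nrow(m)))
  colnames(m) <- peps %||% sprintf("p%d", seq_len(ncol(m)))
  m
}
asn_all <- function(peps, group = "CE1_VP1") {
  data.frame(peptide_id = peps, group = group)
}

test_that("ARB hits its analytic limits", {
  ebs <- mk_ebs(rbind(c(2, 2, 2, 2), c(5, 0, 0, 0)))
  asn <- asn_all(colnames(ebs))
  res <- compute_arb(ebs, asn, "CE1_VP1")
  expect_equal(res$arb[1], 1, tolerance = 1e-12)
  expect_equal(res$arb[2], 0, tolerance = 1e-12)

  ebs3 <- mk_ebs(c(0.5, 0.25, 0.25) * 8) # proportions (0.5, 0.25, 0.25)
  res3 <- compute_arb(ebs3, asn_all(colnames(ebs3)), "CE1_VP1")
  expect_equal(res3$arb, oracle_arb(c(0.5, 0.25, 0.25)), tolerance = 1e-12)
  expect_equal(res3$arb, 1.5 * log(2) / log(3), tolerance = 1e-12)
})

test_that("ARB matches the direct-entropy oracle on random profiles", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:30, 1)
    v <- stats::rexp(n) * stats::rbinom(n, 1, 0.7)
    if (sum(v) == 0) v[1] <- 1
    ebs <- mk_ebs(v)
    got <- compute_arb(ebs, asn_all(colnames(ebs)), "CE1_VP1")$arb
    expect_equal(got, oracle_arb(v), tolerance = 1e-12)
  }
})

test_that("ARB is scale- and permutation-invariant and bounded in [0, 1]", {
  set.seed(5)
  v <- stats::rexp(12) * stats::rbinom(12, 1, 0.6)
  v[1] <- 1 # ensure signal
  ebs <- mk_ebs(v)
  asn <- asn_all(colnames(ebs))
  base <- compute_arb(ebs, asn, "CE1_VP1")$arb
  for (c_ in c(0.001, 3, 1e6)) {
    expect_equal(compute_arb(mk_ebs(c_ * v), asn, "CE1_VP1")$arb, base,
                 tolerance = 1e-12)
  }
  perm <- sample(12)
  ebs_p <- mk_ebs(v[perm], peps = colnames(ebs)[perm])
  expect_equal(compute_arb(ebs_p, asn, "CE1_VP1")$arb, base, tolerance = 1e-12)
  expect_true(base >= 0 && base <= 1)
})

test_that("ARB is undefined for zero total signal or singleton groups", {
  ebs <- mk_ebs(rbind(c(0, 0, 0), c(1, 2, 3)))
  res <- compute_arb(ebs, asn_all(colnames(ebs)), "CE1_VP1")
  expect_false(res$defined[1])
  expect_true(is.na(res$arb[1]))
  expect_true(res$defined[2])
  one <- mk_ebs(5)
  res1 <- compute_arb(one, asn_all(colnames(one)), "CE1_VP1")
  expect_false(res1$defined)
  neg <- mk_ebs(c(1, -1))
  expect_error(compute_arb(neg, asn_all(colnames(neg)), "CE1_VP1"),
               "non-negative")
})

test_that("group EBS means match element-wise recomputation", {
  ebs <- mk_ebs(c(2, 4))
  asn <- asn_all(colnames(ebs))
  expect_equal(group_ebs_summary(ebs, asn)$mean_ebs[1], 3)

  set.seed(3)
  m <- mk_ebs(matrix(stats::rexp(30), 5, 6))
  asn2 <- data.frame(peptide_id = colnames(m),
                     group = rep(peptide_groups(), each = 2))
  got <- group_ebs_summary(m, asn2)
  for (g in peptide_groups()) {
    cols <- asn2$peptide_id[asn2$group == g]
    want <- apply(m[, cols], 1, function(r) sum(r) / length(r))
    expect_equal(got$mean_ebs[got$group == g], unname(want))
  }
  zero <- mk_ebs(matrix(0, 1, 6))
  expect_true(all(group_ebs_summary(zero, asn2)$mean_ebs == 0))
})

test_that("strict mode errors on unassigned peptides; lenient mode drops them", {
  ebs <- mk_ebs(matrix(1, 2, 3))
  asn <- asn_all(colnames(ebs)[1:2])
  expect_error(group_ebs_summary(ebs, asn), "missing from the assignment")
  expect_warning(got <- group_ebs_summary(ebs, asn, strict = FALSE),
                 "excluded")
  expect_equal(got$n_peptides[got$group == "CE1_VP1"][1], 2)
})

test_that("ARB categories and the >0.5 indicator use the documented boundaries", {
  got <- arb_category(c(0.51, 0.5, 0, 1, 0.25))
  expect_equal(as.integer(got$category), c(3L, 2L, 1L, 4L, 1L))
  expect_equal(got$above_cutoff, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_error(arb_category(1.2), "outside")
})

test_that("seroreactivity: fixed panel averages, data-driven panel equals exhaustive choice", {
  ebs <- mk_ebs(matrix(1, 1, 40))
  expect_equal(ce1_seroreactivity(ebs, colnames(ebs))$score, 1)

  set.seed(9)
  m <- mk_ebs(matrix(stats::rexp(5 * 6), 5, 6))
  got <- ce1_seroreactivity(m, colnames(m), k = 3, mode = "data_driven")
  # exhaustive: the best k-subset by cohort mean is the top-k of column means
  combos <- utils::combn(colnames(m), 3, simplify = FALSE)
  mus <- vapply(combos, function(cc) mean(colMeans(m[, cc])), numeric(1))
  best <- combos[[which.max(mus)]]
  expect_equal(got$score, unname(rowMeans(m[, best])))
  expect_equal(got$k_used[1], 3)

  expect_warning(all40 <- ce1_seroreactivity(m, colnames(m), k = 40,
                                             mode = "data_driven"),
                 "using all")
  expect_equal(all40$score, unname(rowMeans(m)))
  expect_error(ce1_seroreactivity(m, character(0)), "non-empty")
})

test_that("raising a panel peptide's EBS never lowers the seroreactivity score", {
  set.seed(2)
  m <- mk_ebs(matrix(stats::rexp(8), 1, 8))
  base <- ce1_seroreactivity(m, colnames(m))$score
  m[1, 3] <- m[1, 3] + 5
  expect_gte(ce1_seroreactivity(m, colnames(m))$score, base)
})
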