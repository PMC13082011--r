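mk_intensities <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(cell_line = r[[1]], antibody = r[[2]], protein_id = r[[3]],
               target = as.numeric(r[[4]]), control = as.numeric(r[[5]]))
  }))
}

test_that("fold changes apply the pseudocount and the strict >100 rule", {
  tb <- mk_intensities(list("c1", "rB9", "P1", 1010, 10),
                       list("c1", "rB9", "P2", 10100, 100),
                       list("c1", "rB9", "P3", 699, 6)) # FC exactly 100
  got <- compute_fold_changes(tb)
  expect_equal(got$fold_change, c(1011 / 11, 10101 / 101, 100))
  expect_equal(got$pass, c(FALSE, TRUE, FALSE))
  expect_error(compute_fold_changes(tb, pseudocount = 0), "pseudocount")
  tb$target[1] <- -1
  expect_error(compute_fold_changes(tb), "non-negative")
})

test_that("raising the cutoff never grows the enriched set", {
  set.seed(4)
  tb <- mk_intensities()
  for (i in 1:50) {
    tb <- rbind(tb, data.frame(cell_line = "c1", antibody = "rB9",
                               protein_id = sprintf("P%02d", i),
                               target = rlnorm(1, 8, 2), control = rlnorm(1, 4, 1)))
  }
  sets <- lapply(c(10, 100, 1000), function(cut) {
    intersect_enriched(compute_fold_changes(tb, cutoff = cut))
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("cross-cell-line and cross-antibody intersection modes", {
  tb <- mk_intensities(list("c1", "rB9", "P1", 1e6, 1),   # pass in c1 only
                       list("c2", "rB9", "P1", 50, 1),
                       list("c1", "rB9", "P2", 1e6, 1),   # pass in both
                       list("c2", "rB10", "P2", 1e6, 1),
                       list("c2", "rB9", "P2", 10, 1))
  v <- compute_fold_changes(tb)
  expect_equal(intersect_enriched(v, cell_line_mode = "all"), "P2")
  expect_equal(intersect_enriched(v, cell_line_mode = "any"), c("P1", "P2"))
  # P2 passes c2 only under rB10: antibody any keeps it, all drops it
  expect_equal(intersect_enriched(v, antibody_mode = "all"), character(0))
})

test_that("surface filtering normalizes case and isoform suffixes", {
  expect_equal(filter_surface(c("P12345-2", "q99999", "A00001"),
                              c("P12345", "Q99999")),
               c("P12345-2", "q99999"))
  expect_equal(filter_surface("P12345-2", "P12345", strip_isoform = FALSE),
               character(0))
  expect_warning(out <- filter_surface("P1", character(0)), "empty surface")
  expect_equal(out, character(0))
})

test_that("self-alignment of the CE1 query is all-identity with the diagonal score", {
  q <- ce1_query()
  rep_ <- align_query(q, q)
  expect_true(all(rep_$flags == "identity"))
  # independent lookup: Biostrings' copy of BLOSUM62
  b62 <- local({ e <- new.env(); data("BLOSUM62", package = "Biostrings",
                                    envir = e); e$BLOSUM62 })
  chars <- strsplit(q, "")[[1]]
  expect_equal(rep_$raw_score, sum(b62[cbind(chars, chars)]))
  expect_equal(rep_$query_range, c(1L, nchar(q)))
})

test_that("conservation flags follow the BLOSUM62 > 0 rule", {
  # force a D/E and a D/W column via gapless same-length alignment
  rep1 <- align_query("CCDCC", "CCECC")
  expect_equal(rep1$flags[3], "conserved") # BLOSUM62[D,E] = 2 > 0
  rep2 <- align_query("CCCDCCC", "CCCWCCC")
  expect_equal(rep2$flags[4], "mismatch") # BLOSUM62[D,W] = -4
  expect_equal(blosum62()["D", "E"], 2L)
  expect_lt(blosum62()["D", "W"], 0L)
  expect_error(align_query("ACX", "ACD"), "position 3")
})

test_that("alignment scores equal the memoized-recursion oracle on short pairs", {
  set.seed(33)
  aas <- rownames(blosum62())
  for (i in 1:60) {
    q <- paste(sample(aas, sample(2:8, 1), TRUE), collapse = "")
    s <- paste(sample(aas, sample(2:8, 1), TRUE), collapse = "")
    expect_equal(align_query(q, s)$raw_score,
                 oracle_sw(q, s, blosum62()),
                 info = paste(q, s))
  }
  # the recursion oracle itself agrees with full path enumeration on tiny pairs
  for (i in 1:10) {
    q <- paste(sample(aas, 3, TRUE), collapse = "")
    s <- paste(sample(aas, 4, TRUE), collapse = "")
    expect_equal(oracle_sw(q, s, blosum62()),
                 max(0, oracle_sw_enum(q, s, blosum62())))
  }
})

test_that("alignment raw score is symmetric and E decreases with score", {
  set.seed(8)
  aas <- rownames(blosum62())
  for (i in 1:20) {
    a <- paste(sample(aas, 10, TRUE), collapse = "")
    b <- paste(sample(aas, 14, TRUE), collapse = "")
    expect_equal(align_query(a, b)$raw_score, align_query(b, a)$raw_score)
  }
  r1 <- align_query("CSESVPAL", "CSESVPAL")
  r2 <- align_query("CSESVPAL", "CSESVPAM")
  expect_gt(r1$raw_score, r2$raw_score)
  expect_lt(r1$expect, r2$expect)
})

test_that("candidate ranking sorts by E, then raw score, then id", {
  seqs <- c(good = "ACSESVPALTAVETGHTSAA",
            same1 = "WWWCSESVWWW", same2 = "WWWCSESVWWW",
            weak = "MNQRK")
  got <- rank_candidates(names(seqs), seqs, ce1_query())
  expect_equal(got$table$protein_id[1], "good")
  i1 <- which(got$table$protein_id == "same1")
  i2 <- which(got$table$protein_id == "same2")
  expect_equal(i2, i1 + 1L) # identical scores: lexicographic id order
  expect_equal(got$table$expect[i1], got$table$expect[i2])
  empty <- rank_candidates(character(0), seqs, ce1_query())
  expect_equal(nrow(empty$table), 0L)
  expect_warning(dropped <- rank_candidates(c("good", "ghost"), seqs,
                                            ce1_query()),
                 "without a sequence")
  expect_equal(nrow(dropped$table), 1L)
})

test_that("two-way ANOVA matches the balanced closed form and flat data gives p ~ 1", {
  # balanced 2x2 with 2 replicates: hand sums of squares
  d <- expand.grid(cond = c("a", "b"), dose = c("lo", "hi"),
                   rep = 1:2, KEEP.OUT.ATTRS = FALSE)
  d$y <- c(1, 2, 3, 4, 1.5, 2.5, 3.5, 4.5)
  got <- competition_summary(d$y, d$cond, d$dose)
  cm <- tapply(d$y, d$cond, mean); dm <- tapply(d$y, d$dose, mean)
  ss_cond <- 4 * sum((cm - mean(d$y))^2)
  ss_dose <- 4 * sum((dm - mean(d$y))^2)
  expect_equal(got$sum_sq[got$term == "condition"], ss_cond, tolerance = 1e-10)
  expect_equal(got$sum_sq[got$term == "dose"], ss_dose, tolerance = 1e-10)
  # identical condition means: condition and interaction F ~ 0
  set.seed(12)
  d2 <- expand.grid(cond = c("a", "b"), dose = c("lo", "hi"), rep = 1:5)
  d2$y <- rep(c(1, 1, 2, 2), 5) + rnorm(20, 0, 0.01)
  got2 <- competition_summary(d2$y, d2$cond, d2$dose)
  expect_lt(got2$F[got2$term == "condition"], 4)
  expect_gt(got2$p[got2$term == "condition"], 0.05)
  # unbalanced design: Type-II equals the model-comparison oracle
  d3 <- d2[-c(1, 5, 9), ]
  got3 <- competition_summary(d3$y, d3$cond, d3$dose)
  full <- lm(y ~ cond + dose, data = d3)
  no_cond <- lm(y ~ dose, data = d3)
  ss_oracle <- sum(residuals(no_cond)^2) - sum(residuals(full)^2)
  expect_equal(got3$sum_sq[got3$term == "condition"], ss_oracle,
               tolerance = 1e-8)
})

test_that("the funnel is monotone and logs stage counts", {
  set.seed(44)
  ip <- generate_ipms_tables(mimicry_spec(n_background_proteins = 150,
                                          seed = 5))
  fun <- mimicry_funnel(ip$intensities, ip$surface_list, ip$sequences,
                        ce1_query())
  expect_true(all(fun$surface %in% fun$enriched))
  expect_true(all(fun$ranking$table$protein_id %in% fun$surface))
  expect_equal(unname(fun$counts["ranked"]), length(fun$surface))
  expect_true(fun$counts["enriched"] <= fun$counts["proteins"])
})
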