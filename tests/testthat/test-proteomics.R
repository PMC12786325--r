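# Small hand-built table: 4 + 4 samples, two conditions.
hand_table <- function(mat, conds = rep(c("A", "B"), each = 4)) {
  abundance_table(mat, conditions = conds)
}

test_that("presence filter applies the strict >75% rule per condition", {
  m <- matrix(1, nrow = 4, ncol = 8,
              dimnames = list(paste0("P", 1:4),
                              paste0("s", 1:8)))
  m[1, 1] <- NA          # P1: 3/4 in A (== 0.75, strict >) and 4/4 in B
  m[2, 1:4] <- NA        # P2: 0/4 in A, 4/4 in B
  m[3, c(1, 5)] <- NA    # P3: 3/4 in both conditions
  m[4, 5:8] <- NA        # P4: 4/4 in A only
  tab <- hand_table(m)
  kept <- presence_filter(tab)$protein_ids
  expect_equal(kept, c("P1", "P2", "P4")) # P3 dropped: 0.75 is not > 0.75

  # exactly 3/4 in every condition -> dropped
  m2 <- matrix(1, 1, 8, dimnames = list("Q1", paste0("s", 1:8)))
  m2[1, c(1, 5)] <- NA
  expect_equal(nrow(presence_filter(hand_table(m2))$abundance), 0)

  # hand enumeration on a 10-protein constructed pattern
  set.seed(8)
  m3 <- matrix(rexp(10 * 8), 10, 8,
               dimnames = list(sprintf("R%02d", 1:10), paste0("s", 1:8)))
  drop_pat <- rbind(c(1, 2, 5), c(2, 3, 6), c(1, 5, 6), c(3, 4, 7),
                    c(2, 6, 7), c(1, 2, 3), c(5, 6, 7), c(4, 5, 8),
                    c(1, 6, 8), c(2, 5, 8))
  for (i in 1:10) m3[i, drop_pat[i, ]] <- NA
  tab3 <- hand_table(m3)
  expected <- vapply(1:10, function(i) {
    da <- mean(!is.na(m3[i, 1:4]))
    db <- mean(!is.na(m3[i, 5:8]))
    da > 0.75 || db > 0.75
  }, TRUE)
  expect_equal(presence_filter(tab3)$protein_ids,
               sprintf("R%02d", which(expected)))

  # monotonicity: a stricter threshold never adds proteins
  for (f in c(0, 0.25, 0.5, 0.75, 0.9)) {
    lo <- presence_filter(tab3, min_frac = f)$protein_ids
    hi <- presence_filter(tab3, min_frac = min(f + 0.25, 0.99))$protein_ids
    expect_true(all(hi %in% lo))
  }
})

test_that("low-quantile imputation is per-sample and order-exact", {
  # no missing values: identity
  m <- matrix(seq_len(12) + 0.5, 3, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  tab <- abundance_table(m, conditions = rep("A", 4))
  expect_equal(impute_low_quantile(tab)$abundance, tab$abundance)

  # detected grid 1..100: imputed constant equals quantile(1:100, 0.025)
  m2 <- matrix(NA_real_, 105, 2, dimnames = list(NULL, c("s1", "s2")))
  m2[1:100, 1] <- 1:100
  m2[1:100, 2] <- 10 * (1:100) # different scale in the second sample
  tab2 <- abundance_table(m2, conditions = c("A", "A"))
  imp <- impute_low_quantile(tab2)
  expect_equal(unname(imp$abundance[101, 1]),
               unname(quantile(1:100, 0.025)))
  expect_equal(unname(imp$abundance[101, 2]),
               unname(quantile(10 * (1:100), 0.025)))
  expect_false(anyNA(imp$abundance))
  # the detection mask keeps recording what was actually measured
  expect_identical(imp$detected, tab2$detected)
  expect_equal(sum(attr(imp, "imputed")), sum(is.na(m2)))

  # filtering and imputation agree on the surviving set: identical survivor
  # rosters, identical detected values; the imputed constant shifts only as
  # far as filtering shifts each sample's detected 2.5% quantile
  tab3 <- generate_protein_table(n_proteins = 200,
                                 n_samples_per_condition = 4,
                                 missing_rate = 0.15, seed = 3)
  a <- impute_low_quantile(presence_filter(tab3))
  b <- presence_filter(impute_low_quantile(tab3))
  expect_identical(a$protein_ids, b$protein_ids)
  det <- presence_filter(tab3)$detected
  expect_equal(a$abundance[det], b$abundance[det])
  expect_equal(a$abundance, b$abundance, tolerance = 0.1)

  # an all-missing sample cannot be imputed
  m4 <- cbind(s1 = c(1, 2), s2 = c(NA, NA))
  expect_error(impute_low_quantile(abundance_table(m4, c("A", "A"))),
               "no detected values")
})

test_that("TMM factors are scale-equivariant with geometric mean one", {
  tab <- generate_protein_table(n_proteins = 800,
                                n_samples_per_condition = 2,
                                conditions = c("A", "B"), seed = 13)
  # identical duplicated samples
  x <- tab$abundance[, 1]
  dup <- abundance_table(cbind(s1 = x, s2 = x), conditions = c("A", "A"))
  expect_equal(as.vector(tmm_factors(dup)), c(1, 1))

  # sample B = 4 x sample A: factor ratio exactly 4
  quad <- abundance_table(cbind(s1 = x, s2 = 4 * x), conditions = c("A", "A"))
  fq <- tmm_factors(quad)
  expect_lt(abs(fq[[2]] / fq[[1]] - 4), 1e-6)

  f <- tmm_factors(tab)
  expect_equal(exp(mean(log(f))), 1)

  # equivariance: rescaling one sample rescales its factor (the precision
  # weights are abundance-dependent, so equivariance is near- rather than
  # bit-exact away from the pure two-sample case)
  tab_s <- tab
  tab_s$abundance[, 3] <- 7 * tab_s$abundance[, 3]
  fs <- tmm_factors(tab_s)
  expect_lt(abs((fs[[3]] / fs[[1]]) / (f[[3]] / f[[1]]) / 7 - 1), 0.03)

  # a 10x loaded twin gets a ~10x factor
  tw <- generate_protein_table(n_proteins = 800,
                               n_samples_per_condition = 3,
                               conditions = c("A", "B"),
                               loading_factors = c(1, 10, 1, 1, 1, 1),
                               seed = 2)
  ftw <- tmm_factors(tw)
  expect_lt(abs(ftw[[2]] / ftw[[1]] / 10 - 1), 0.1)

  expect_error(tmm_factors(abundance_table(cbind(s1 = c(1, NA), s2 = c(1, 2)),
                                           c("A", "A"))), "impute")
})

test_that("TMM matches the published reference implementation", {
  tab <- generate_protein_table(n_proteins = 1500,
                                n_samples_per_condition = 3,
                                conditions = c("A", "B"),
                                loading_factors = c(1, 2, 0.5, 1, 4, 1),
                                enriched_set = 1:150, effect = 4, seed = 11)
  f <- tmm_factors(tab)
  x <- tab$abundance
  eff <- colSums(x) * edgeR::calcNormFactors(x, method = "TMM")
  eff <- eff / exp(mean(log(eff)))
  expect_lt(max(abs(f / eff - 1)), 0.02)
})

test_that("ranking is top-down, tie-averaged and monotone-invariant", {
  m <- cbind(s1 = c(10, 5, 1), s2 = c(7, 7, 1), s3 = c(2, 8, NA))
  tab <- abundance_table(m, conditions = c("A", "A", "B"),
                         protein_ids = c("p1", "p2", "p3"))
  rk <- rank_proteins(tab)
  expect_equal(unname(rk$ranks[, "s1"]), c(1, 2, 3))
  expect_equal(unname(rk$ranks[, "s2"]), c(1.5, 1.5, 3)) # tied top pair
  expect_equal(unname(rk$ranks[, "s3"]), c(2, 1, 3)) # undetected ranks last
  expect_equal(unname(rk$cond_mean[, "A"]),
               unname(rowMeans(rk$ranks[, c("s1", "s2")])))

  # undetected proteins share the worst tied rank
  m2 <- cbind(s1 = c(5, NA, NA, 1))
  rk2 <- rank_proteins(abundance_table(m2, "A"))
  expect_equal(unname(rk2$ranks[, 1]), c(1, 3.5, 3.5, 2))

  # any per-sample monotone transform leaves ranks untouched
  tab3 <- generate_protein_table(n_proteins = 300,
                                 n_samples_per_condition = 3,
                                 missing_rate = 0.05, seed = 17)
  r_raw <- rank_proteins(tab3)
  tab_t <- tab3
  tab_t$abundance[, 1] <- 1000 * tab_t$abundance[, 1]
  tab_t$abundance[, 2] <- tab_t$abundance[, 2]^1.7
  tab_t$abundance[, 3] <- log1p(tab_t$abundance[, 3])
  r_t <- rank_proteins(tab_t)
  expect_identical(r_raw$ranks, r_t$ranks)
})

test_that("rank test flags the enriched truth and nothing under the null", {
  # identical conditions: all differences zero, nothing significant
  x <- generate_protein_table(n_proteins = 100,
                              n_samples_per_condition = 3,
                              conditions = "A", seed = 5)$abundance
  dup <- abundance_table(cbind(x, x),
                         conditions = rep(c("A", "B"), each = 3),
                         protein_ids = rownames(x))
  colnames(dup$abundance) <- paste0("s", 1:6)
  res0 <- differential_rank_test(rank_proteins(dup), "A", "B")
  expect_true(all(res0$mean_rank_diff == 0))
  expect_true(all(!res0$significant))

  # strong enrichment: >= 90% recall at q < 0.05 and top-100 dominance
  tabE <- generate_protein_table(n_proteins = 1000,
                                 n_samples_per_condition = 8,
                                 conditions = c("A", "B"),
                                 enriched_set = 1:50, effect = 6,
                                 enriched_condition = "B", seed = 19)
  rkE <- rank_proteins(tabE)
  resE <- differential_rank_test(rkE, "A", "B")
  hits <- resE$protein_id[resE$significant]
  truth <- attr(tabE, "enriched_ids")
  expect_gte(length(intersect(truth, hits)) / length(truth), 0.9)

  # the 50 enriched dominate the top-100 rank differential
  top100 <- head(resE$protein_id, 100)
  expect_gte(length(intersect(truth, top100)), 45)

  expect_error(differential_rank_test(rkE, "A", "Z"), "absent")
})

test_that("null rank tests are calibrated at the nominal level", {
  tab0 <- generate_protein_table(n_proteins = 1000,
                                 n_samples_per_condition = 8,
                                 conditions = c("A", "B"),
                                 effect = 1, seed = 23)
  res <- differential_rank_test(rank_proteins(tab0), "A", "B")
  frac <- mean(res$p_value < 0.05)
  # competitive ranking couples the per-protein tests, roughly doubling the
  # scatter of the rejection fraction relative to the independent binomial
  expect_lt(abs(frac - 0.05), 2 * 1.96 * sqrt(0.05 * 0.95 / 1000))
})

test_that("top lists and overlaps follow the printed arithmetic", {
  tab <- generate_protein_table(n_proteins = 60,
                                n_samples_per_condition = 3, seed = 29)
  rk <- rank_proteins(tab)
  expect_length(top_n_list(rk, "Stag", 60), 60)
  expect_error(top_n_list(rk, "Stag", 61), "protein count")

  # dominance: globally top proteins appear in any top-10
  m <- matrix(rexp(50 * 4), 50, 4, dimnames = list(sprintf("d%02d", 1:50),
                                                   paste0("s", 1:4)))
  m[1:10, ] <- m[1:10, ] + 1000
  rkd <- rank_proteins(abundance_table(m, rep("A", 4)))
  expect_setequal(top_n_list(rkd, "A", 10), sprintf("d%02d", 1:10))

  # stability under sample-column reordering
  m_perm <- m[, c(3, 1, 4, 2)]
  rkp <- rank_proteins(abundance_table(m_perm, rep("A", 4)))
  expect_equal(top_n_list(rkp, "A", 25), top_n_list(rkd, "A", 25))

  # overlap arithmetic: 95 shared over a 117 union -> 81%
  a <- sprintf("u%03d", 1:100)
  b <- c(sprintf("u%03d", 6:100), sprintf("v%03d", 1:17)) # shared 95
  ov <- overlap_percent(a, b)
  expect_equal(ov$shared, 95)
  expect_equal(ov$union, 117)
  expect_equal(ov$percent, 81L)

  expect_equal(overlap_percent(a, a)$percent, 100L)
  expect_equal(overlap_percent(a, sprintf("w%d", 1:30))$percent, 0L)
  expect_lte(ov$shared, min(ov$size_a, ov$size_b))
  expect_gte(ov$union, max(ov$size_a, ov$size_b))
  expect_error(overlap_percent(c("x", "x"), "y"), "unique")
})
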