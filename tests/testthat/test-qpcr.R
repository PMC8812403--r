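test_that("geNorm M is zero for constant-offset profiles and shift-invariant", {
  base <- matrix(rnorm(8, 24, 1), 1, 8)
  cq <- rbind(G1 = base[1, ], G2 = base[1, ] + 2, G3 = base[1, ] - 1.5)
  colnames(cq) <- paste0("S", 1:8)
  res <- genorm_stability(cq)
  expect_equal(unname(res$M), rep(0, 3), tolerance = 1e-12)

  cq2 <- random_cq(5, 10, seed = 2)
  shifted <- cq2 + matrix(c(1, -3, 0.5, 2, 7), 5, 10)
  expect_equal(genorm_stability(cq2)$M, genorm_stability(shifted)$M,
               tolerance = 1e-10)
})

test_that("geNorm matches the brute-force mean-of-SD-of-log-ratio formula", {
  set.seed(7)
  cq <- random_cq(4, 6)
  res <- genorm_stability(cq)
  for (j in 1:4) {
    sds <- c()
    for (k in setdiff(1:4, j)) sds <- c(sds, sd(cq[k, ] - cq[j, ]))
    expect_equal(unname(res$M[j]), mean(sds), tolerance = 1e-12)
  }
})

test_that("geNorm excludes the noisy gene first", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(100 + s)
    n <- 12
    shared <- rnorm(n, 25, 1.5)
    cq <- rbind(A = shared + rnorm(n, 0, 0.1),
                B = shared + rnorm(n, 0, 0.1),
                C = shared + rnorm(n, 0, 0.1),
                NOISY = shared + rnorm(n, 0, 2))
    colnames(cq) <- paste0("S", seq_len(n))
    if (genorm_stability(cq)$exclusion_order[1] == "NOISY") hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("geNorm preconditions", {
  expect_error(genorm_stability(random_cq(2, 5)), "3 candidate")
  cq <- random_cq(3, 5)
  cq[2, ] <- NA
  expect_error(genorm_stability(cq), "entirely missing")
})

test_that("NormFinder: zero-variance gene is at the panel minimum", {
  set.seed(9)
  cq <- random_cq(4, 12)
  cq[1, ] <- 23  # perfectly stable relative to... sample centering shifts it
  groups <- rep(c("g1", "g2"), each = 6)
  st <- normfinder_stability(cq, groups)$stability
  expect_true(all(st >= 0))
  # a gene with no variance within or across groups after centering:
  # build a panel where gene 1 tracks the sample mean exactly
  base <- rnorm(12, 25, 1)
  cq2 <- rbind(G1 = base, G2 = base + rnorm(12, 0, 0.8),
               G3 = base + rnorm(12, 0, 0.8), G4 = base + rnorm(12, 0, 0.8))
  colnames(cq2) <- paste0("S", 1:12)
  st2 <- normfinder_stability(cq2, groups)$stability
  expect_identical(names(which.min(st2)), "G1")
})

test_that("NormFinder flags a planted intergroup shift as least stable", {
  # realistic candidate panel: a shared per-sample loading effect plus
  # ~0.3-cycle gene-specific noise; one gene shifted by 2 cycles in group b
  hits <- 0L
  for (s in 1:100) {
    set.seed(200 + s)
    n <- 12
    loading <- rnorm(n, 25, 1.5)
    cq <- t(vapply(1:4, function(i) loading + rnorm(n, 0, 0.3),
                   numeric(n)))
    dimnames(cq) <- list(paste0("G", 1:4), paste0("S", 1:n))
    groups <- rep(c("a", "b"), each = n / 2)
    cq[2, groups == "b"] <- cq[2, groups == "b"] + 2
    st <- normfinder_stability(cq, groups)$stability
    if (names(which.max(st)) == "G2") hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("NormFinder agrees with a direct loop-based evaluation", {
  set.seed(13)
  cq <- random_cq(4, 12)
  groups <- rep(c("a", "b", "c"), each = 4)
  st <- normfinder_stability(cq, groups)
  z <- cq
  for (j in 1:12) z[, j] <- cq[, j] - mean(cq[, j])
  for (g_i in 1:4) {
    per_group <- c()
    grand <- sum(vapply(c("a", "b", "c"), function(g)
      mean(z[g_i, groups == g]) * sum(groups == g), numeric(1))) / 12
    for (g in c("a", "b", "c")) {
      zz <- z[g_i, groups == g]
      per_group <- c(per_group,
                     abs(mean(zz) - grand) + sqrt(var(zz) / length(zz)))
    }
    expect_equal(unname(st$stability[g_i]), mean(per_group), tolerance = 1e-12)
  }
  # single group falls back to intragroup-only, flagged
  st1 <- normfinder_stability(cq, rep("only", 12))
  expect_true(st1$intragroup_only)
  expect_equal(unname(st1$stability), unname(apply(z, 1, sd)),
               tolerance = 1e-12)
})

test_that("BestKeeper statistics match direct arithmetic", {
  set.seed(17)
  cq <- random_cq(5, 10)
  bk <- bestkeeper_stats(cq)
  index <- colMeans(cq)
  for (i in 1:5) {
    expect_equal(bk$sd[i], sd(cq[i, ]), tolerance = 1e-12)
    expect_equal(bk$cv[i], 100 * sd(cq[i, ]) / mean(cq[i, ]), tolerance = 1e-12)
    expect_equal(bk$index_r[i], cor(cq[i, ], index), tolerance = 1e-12)
  }
  # identical rows: common SD, index correlations all 1
  cq_same <- matrix(rep(rnorm(6, 24, 1.2), each = 3), 3, 6,
                    dimnames = list(c("A", "B", "C"), paste0("S", 1:6)))
  bk2 <- bestkeeper_stats(cq_same)
  expect_equal(bk2$sd, rep(sd(cq_same[1, ]), 3), tolerance = 1e-12)
  expect_equal(bk2$index_r, rep(1, 3), tolerance = 1e-12)
  # the 1-cycle advisory threshold
  cq3 <- rbind(STABLE = rnorm(20, 25, 0.2), WILD = rnorm(20, 25, 3))
  colnames(cq3) <- paste0("S", 1:20)
  bk3 <- bestkeeper_stats(cq3)
  expect_false(bk3$flagged[bk3$gene == "STABLE"])
  expect_true(bk3$flagged[bk3$gene == "WILD"])
  # zero-variance gene: index correlation undefined -> NA
  cq4 <- rbind(FLAT = rep(24, 6), VAR = rnorm(6, 24, 1))
  colnames(cq4) <- paste0("S", 1:6)
  expect_true(is.na(bestkeeper_stats(cq4)$index_r[1]))
})

test_that("select_reference_pair finds planted stable genes", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(300 + s)
    n <- 12
    cq <- rbind(GOOD1 = rnorm(n, 22, 0.02), GOOD2 = rnorm(n, 20, 0.02),
                BAD1 = rnorm(n, 24, 1.5), BAD2 = rnorm(n, 23, 1.5),
                BAD3 = rnorm(n, 25, 1.5))
    colnames(cq) <- paste0("S", seq_len(n))
    rep <- stability_report(cq, rep(c("x", "y"), each = n / 2))
    if (setequal(select_reference_pair(rep), c("GOOD1", "GOOD2")))
      hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("select_reference_pair tie rule is lexicographic", {
  # all-equal stabilities: constant-offset profiles, identical variances
  base <- rnorm(8, 24, 1)
  cq <- rbind(ZC = base, ZA = base + 1, ZB = base - 1)
  colnames(cq) <- paste0("S", 1:8)
  rep <- stability_report(cq)
  expect_identical(select_reference_pair(rep), c("ZA", "ZB"))
  expect_error(select_reference_pair(rep[1:2, ]), "3 candidates")
})

test_that("stability report on the 9-candidate panel returns a 2-subset", {
  cfg <- cohort_config(seed = 51L)
  coh <- generate_cohort(cfg)
  cand <- default_reference_spec()$gene
  rep <- stability_report(coh$cq[cand, ],
                          coh$samples$group)
  pair <- select_reference_pair(rep)
  expect_length(pair, 2)
  expect_true(all(pair %in% cand))
  expect_true(all(sort(rep$aggregate_rank) == rep$aggregate_rank))
  # ranks are a permutation of 1..9 per method (allowing average ties)
  expect_equal(sort(rank(rep$genorm_M)), 1:9, tolerance = 1e-12)
})

test_that("relative_expression implements 2^-ddCq", {
  genes <- c("T1", "T2", "R1", "R2")
  cq <- matrix(0, 4, 4, dimnames = list(genes, paste0("S", 1:4)))
  cq["R1", ] <- c(20, 21, 20, 22)
  cq["R2", ] <- c(22, 21, 24, 20)
  ref_mean <- colMeans(cq[c("R1", "R2"), ])
  cq["T1", ] <- ref_mean            # dCq = 0 everywhere -> expression 1
  cq["T2", ] <- ref_mean + 5
  cq["T2", 2] <- ref_mean[2] + 4    # one cycle below calibrator dCq -> 2
  expr <- relative_expression(cq, c("T1", "T2"), c("R1", "R2"),
                              calibrator_samples = c("S1", "S3", "S4"))
  expect_equal(unname(expr["T1", ]), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(expr["T2", "S2"]), 2, tolerance = 1e-12)

  # brute-force spreadsheet oracle on a random instance
  set.seed(23)
  cq2 <- random_cq(5, 4)
  rownames(cq2) <- c("A", "B", "C", "R1", "R2")
  expr2 <- relative_expression(cq2, c("A", "B", "C"), c("R1", "R2"), "S1")
  for (g in c("A", "B", "C")) for (s in colnames(cq2)) {
    dcq <- cq2[g, s] - mean(cq2[c("R1", "R2"), s])
    dcq_cal <- cq2[g, "S1"] - mean(cq2[c("R1", "R2"), "S1"])
    expect_equal(unname(expr2[g, s]), 2^-(dcq - dcq_cal), tolerance = 1e-12)
  }

  # invariant to swapping the reference pair
  expr3 <- relative_expression(cq2, c("A", "B", "C"), c("R2", "R1"), "S1")
  expect_equal(unclass(expr2), unclass(expr3), tolerance = 1e-12,
               ignore_attr = TRUE)

  # missing reference propagates NA with a warning
  cq2["R1", "S3"] <- NA
  expect_warning(e4 <- relative_expression(cq2, "A", c("R1", "R2"), "S1"),
                 "missing reference")
  expect_true(all(is.na(e4[, "S3"])))
})

test_that("the three stability methods agree when one gene is noisy", {
  set.seed(31)
  n <- 16
  shared <- rnorm(n, 24, 0.8)
  cq <- rbind(A = shared + rnorm(n, 0, 0.05),
              B = shared + rnorm(n, 0, 0.05),
              C = shared + rnorm(n, 0, 0.05),
              LOUD = shared + rnorm(n, 0, 3))
  colnames(cq) <- paste0("S", seq_len(n))
  rep <- stability_report(cq, rep(c("u", "v"), each = n / 2))
  worst <- rep$gene[which.max(rep$aggregate_rank)]
  expect_identical(worst, "LOUD")
  expect_identical(rep$gene[rep$rank_genorm == 4], "LOUD")
  expect_identical(rep$gene[rep$rank_normfinder == 4], "LOUD")
  expect_identical(rep$gene[rep$rank_bestkeeper == 4], "LOUD")
})
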