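test_that("performance change is the per-participant baseline ratio", {
  sc <- data.frame(
    participant = rep(c("p1", "p2"), each = 3),
    condition = "active",
    test = rep(c("baseline", "post_nap", "delayed"), 2),
    percent = c(80, 70, 40, 100, 90, 100))
  pc <- performanceChange(sc)
  per <- pc$perParticipant
  expect_equal(per$change[per$participant == "p1" &
                            per$test == "delayed"], 50)
  expect_equal(per$change[per$participant == "p2" &
                            per$test == "delayed"], 100)
  grp <- pc$group
  expect_equal(grp$change[grp$test == "delayed"], 75)
  # baseline == test -> 100
  expect_equal(per$change[per$participant == "p2" &
                            per$test == "post_nap"], 90)

  sc0 <- sc; sc0$percent[sc0$participant == "p1" &
                           sc0$test == "baseline"] <- 0
  pc0 <- performanceChange(sc0)
  expect_identical(attr(pc0$perParticipant, "excluded"), "p1")
  expect_false("p1" %in% pc0$perParticipant$participant)
})

test_that("channel topography test reproduces BH step-up decisions", {
  set.seed(42)
  np <- 12; nch <- 8
  chs <- paste0("ch", seq_len(nch))
  sham <- matrix(rnorm(np * nch), np, nch, dimnames = list(NULL, chs))
  act <- sham + matrix(rnorm(np * nch, 0, 0.3), np, nch)
  act[, 1:3] <- act[, 1:3] + 1.5            # real effects on 3 channels
  res <- channelTopographyTest(act, sham)
  # oracle: hand-rolled BH step-up on the same p-values
  p <- res$p
  o <- order(p)
  thr <- 0.05 * seq_len(nch) / nch
  kmax <- suppressWarnings(max(which(p[o] <= thr)))
  bhSet <- if (is.finite(kmax)) sort(o[seq_len(kmax)]) else integer()
  expect_identical(which(res$significant), bhSet)
  expect_true(all(res$significant[1:3]))
  # Bonferroni set is a subset of the BH set
  bonf <- which(p <= 0.05 / nch)
  expect_true(all(bonf %in% which(res$significant)))
})

test_that("zero-variance channels are flagged, not declared", {
  np <- 6
  sham <- matrix(rnorm(np * 2), np, 2, dimnames = list(NULL, c("a", "b")))
  act <- sham
  act[, 1] <- act[, 1] + 2                   # constant difference
  res <- channelTopographyTest(act, sham)
  expect_true(is.na(res$p[1]))
  expect_false(res$significant[1])
})

test_that("topography false-positive rate is controlled under the null", {
  set.seed(99)
  reps <- 200; np <- 10; nch <- 6
  fp <- replicate(reps, {
    sham <- matrix(rnorm(np * nch), np, nch,
                   dimnames = list(NULL, paste0("c", 1:nch)))
    act <- sham + matrix(rnorm(np * nch), np, nch)
    mean(channelTopographyTest(act, sham)$significant)
  })
  mc <- sqrt(0.05 * 0.95 / (reps * nch))
  expect_lte(mean(fp), 0.05 + 2 * mc)
})

test_that("repeated-measures ANOVA matches the aov oracle", {
  set.seed(3)
  d <- expand.grid(participant = paste0("s", 1:8),
                   A = c("a1", "a2", "a3"), B = c("b1", "b2"))
  d$value <- rnorm(nrow(d)) +
    as.numeric(d$A == "a2") * 0.8 + as.numeric(d$B == "b2") * 0.5
  res <- rmAnovaGG(d, dv = "value", subject = "participant",
                   factors = c("A", "B"))
  fit <- summary(stats::aov(value ~ A * B +
                              Error(participant / (A * B)), data = d))
  getF <- function(stratum, term) {
    tab <- fit[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, c("F value", "Pr(>F)")]
  }
  oA <- getF("Error: participant:A", "A")
  oB <- getF("Error: participant:B", "B")
  oAB <- getF("Error: participant:A:B", "A:B")
  expect_equal(res$F[res$effect == "A"], oA[[1]], tolerance = 1e-8)
  expect_equal(res$F[res$effect == "B"], oB[[1]], tolerance = 1e-8)
  expect_equal(res$F[res$effect == "A:B"], oAB[[1]], tolerance = 1e-8)
  expect_equal(res$p_uncorrected[res$effect == "A"], oA[[2]],
               tolerance = 1e-8)
  # two-level factor: epsilon exactly 1, GG p equals uncorrected p
  expect_equal(res$epsilon[res$effect == "B"], 1)
  expect_equal(res$p_gg[res$effect == "B"],
               res$p_uncorrected[res$effect == "B"])
  # partial eta squared within [0, 1]
  expect_true(all(res$pes >= 0 & res$pes <= 1))
})

test_that("GG epsilon approaches 1 under compound symmetry", {
  set.seed(8)
  s <- 200
  subj <- factor(rep(seq_len(s), each = 8))
  A <- factor(rep(rep(1:4, each = 2), s))
  B <- factor(rep(1:2, 4 * s))
  common <- rnorm(s)[as.integer(subj)]       # exchangeable structure
  d <- data.frame(participant = subj, A = A, B = B,
                  value = common + rnorm(8 * s))
  res <- rmAnovaGG(d, factors = c("A", "B"))
  expect_equal(res$epsilon[res$effect == "A"], 1, tolerance = 0.05)
  expect_true(res$epsilon[res$effect == "A"] <= 1 + 1e-9)
})

test_that("rmAnovaGG rejects incomplete designs", {
  d <- expand.grid(participant = paste0("s", 1:4), A = c("a1", "a2"),
                   B = c("b1", "b2"))
  d$value <- rnorm(nrow(d))
  expect_error(rmAnovaGG(d[-1, ], factors = c("A", "B")), "balanced")
})

test_that("paired descriptive battery matches hand arithmetic", {
  x <- c(2, 4, 6, 8, 10); y <- c(1, 2, 3, 4, 5)
  out <- descriptiveTests(x, y)
  expect_equal(out$d, mean(1:5) / sd(1:5))
  expect_equal(out$d, 1.897, tolerance = 1e-3)
  expect_equal(out$spearman$r, 1)            # monotone pairs

  rev <- descriptiveTests(c(1, 2, 3), c(3, 2, 1))
  expect_equal(rev$spearman$r, -1)

  same <- descriptiveTests(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$d, 0)
  expect_true(is.na(same$wilcoxon$V))

  # large-n path (normal approximation with continuity correction)
  set.seed(10)
  xl <- rnorm(40); yl <- xl - 0.5 + rnorm(40, 0, 0.2)
  big <- descriptiveTests(xl, yl)
  expect_lt(big$wilcoxon$p, 0.01)
})

test_that("noncentral-t power analysis matches a grid-search oracle", {
  # oracle: smallest n whose exact power crosses the target, found by
  # an independent search seeded from the closed-form solver
  oracle <- function(d, alpha, power) {
    nApprox <- stats::power.t.test(delta = d, sd = 1, power = power,
                                   sig.level = alpha,
                                   type = "one.sample")$n
    for (n in seq(max(2, floor(nApprox) - 3), ceiling(nApprox) + 3)) {
      tc <- qt(1 - alpha / 2, n - 1)
      pw <- 1 - pt(tc, n - 1, d * sqrt(n)) + pt(-tc, n - 1, d * sqrt(n))
      if (pw >= power) return(n)
    }
  }
  expect_identical(sampleSizePairedT(0.5, 0.05, 0.80),
                   as.integer(oracle(0.5, 0.05, 0.80)))
  expect_identical(sampleSizePairedT(1.2, 0.05, 0.90),
                   as.integer(oracle(1.2, 0.05, 0.90)))
  # saturation at the minimal admissible n for huge effects
  expect_identical(sampleSizePairedT(25, 0.05, 0.80), 2L)
  # monotonicity: non-increasing in d and alpha, non-decreasing in power
  expect_gte(sampleSizePairedT(0.4, 0.05, 0.80),
             sampleSizePairedT(0.6, 0.05, 0.80))
  expect_gte(sampleSizePairedT(0.5, 0.01, 0.80),
             sampleSizePairedT(0.5, 0.05, 0.80))
  expect_gte(sampleSizePairedT(0.5, 0.05, 0.90),
             sampleSizePairedT(0.5, 0.05, 0.80))
})
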