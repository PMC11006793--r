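test_that("a feature equal to the label ranks first", {
  set.seed(401L)
  y <- rep(c(TRUE, FALSE), each = 50L)
  X <- cbind(oracle_f = as.numeric(y) + rnorm(100L, sd = 0.01),
             junk_a = rnorm(100L), junk_b = rnorm(100L))
  ranked <- mrmr_rank(X, y)
  expect_equal(ranked[1L], "oracle_f")
  expect_setequal(ranked, colnames(X))
})

test_that("a duplicated informative feature is pushed down by redundancy", {
  set.seed(411L)
  y <- rep(c(TRUE, FALSE), each = 60L)
  f1 <- 2 * as.numeric(y) + rnorm(120L, sd = 0.6)
  f2 <- 1.2 * as.numeric(y) + rnorm(120L, sd = 0.6)  # weaker second signal
  X <- cbind(a_info = f1, a_copy = f1, b_info = f2)
  ranked <- mrmr_rank(X, y)
  # one twin ranks first on relevance; the other is fully redundant with it
  # and must fall behind the independent informative feature
  expect_true(ranked[1L] %in% c("a_info", "a_copy"))
  expect_true("b_info" %in% ranked[1:2])
  expect_true(ranked[3L] %in% c("a_info", "a_copy"))
})

test_that("MIQ ranking equals a naive reference implementation", {
  set.seed(421L)
  for (rep_i in 1:5) {
    y <- runif(80L) > 0.5
    X <- matrix(rnorm(80L * 4L), ncol = 4L,
                dimnames = list(NULL, c("w", "x", "yf", "z")))
    X[, 1L] <- X[, 1L] + 1.5 * y
    X[, 3L] <- X[, 3L] + 0.8 * y
    expect_equal(mrmr_rank(X, y), oracle_mrmr(X, y))
  }
})

test_that("constant features carry zero information and rank by name", {
  set.seed(431L)
  y <- rep(c(TRUE, FALSE), each = 30L)
  X <- cbind(informative = 3 * as.numeric(y) + rnorm(60L),
             const_b = rep(1, 60L), const_a = rep(2, 60L))
  ranked <- mrmr_rank(X, y)
  expect_equal(ranked[1L], "informative")
  expect_equal(ranked[2:3], c("const_a", "const_b"))
})

test_that("IFS returns a full curve and a compact best size on planted data", {
  d <- generate_feature_matrix(n_per_class = 60L, n_informative = 2L,
                               n_noise = 6L, effect = 3, seed = 441L)
  ranked <- mrmr_rank(d$X, d$y)
  res <- ifs_select(ranked, X = d$X, y = d$y,
                    hyperparameters = list(ntree = 60L), k = 4L, seed = 3L)
  expect_equal(nrow(res$ifs_curve), ncol(d$X))
  expect_lte(res$best_size, 4L)
  # parsimony rule: the chosen subset sits within one SE of the best MCC
  i_max <- which.max(res$ifs_curve$MCC)
  expect_gte(res$ifs_curve$MCC[res$best_size],
             res$ifs_curve$MCC[i_max] - res$ifs_curve$MCC_se[i_max] - 1e-9)
  # strict argmax remains available
  res_max <- ifs_select(ranked, X = d$X, y = d$y,
                        hyperparameters = list(ntree = 60L), k = 4L,
                        seed = 3L, rule = "max")
  expect_equal(res_max$best_size, i_max)
  # n = 1 degenerates to best_size 1: curve computed on single feature
  res1 <- ifs_select(ranked[1L], X = d$X, y = d$y,
                     hyperparameters = list(ntree = 40L), k = 3L, seed = 4L)
  expect_equal(res1$best_size, 1L)
})

test_that("ablation removes a pure-noise component first", {
  sets <- tiny_training_sets(n = 30L, strength = 1, seed = 451L)
  # candidate components: two informative (nucleotide_bias, codon_bias via
  # in-frame usage) and the 4-mer block, which at this scale is noise-like
  trace <- ablate_components(sets$pos, sets$neg,
                             components = c("nucleotide_bias", "codon_bias",
                                            "mer4"),
                             stop_size = 1L, method = "RF",
                             hyperparameters = list(ntree = 60L),
                             k = 3L, seed = 21L)
  expect_equal(nrow(trace), 2L)
  expect_equal(trace$removed_component[1L], "mer4")
  # each step removes exactly one component; remaining count decreases
  expect_equal(length(strsplit(trace$remaining[1L], ",")[[1L]]), 2L)
  expect_equal(length(strsplit(trace$remaining[2L], ",")[[1L]]), 1L)
})

test_that("precision-targeted cutoffs meet the target or reject all", {
  # perfectly separated: the smallest qualifying threshold sits at the
  # lowest positive score
  cut <- choose_cutoff(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE),
                       0.95)
  expect_equal(cut, 0.8)
  cm <- confusion(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE), cut)
  expect_gte(compute_metrics(cm)$PRE, 0.95)

  # an inseparable false positive above every true positive: target 1
  # unattainable -> reject-all cutoff 1.0
  expect_equal(choose_cutoff(c(0.95, 0.6, 0.5), c(FALSE, TRUE, TRUE), 1.0),
               1.0)

  # brute-force agreement on random score sets
  set.seed(461L)
  for (i in 1:10) {
    scores <- round(runif(50L), 2L)
    truth <- runif(50L) > 0.4
    if (!any(truth) || all(truth)) next
    for (target in c(0.6, 0.9)) {
      got <- choose_cutoff(scores, truth, target)
      cand <- sort(unique(c(0, scores, 1)))
      ok <- cand[vapply(cand, function(th) {
        tp <- sum(scores >= th & truth)
        fp <- sum(scores >= th & !truth)
        tp + fp > 0 && tp / (tp + fp) >= target
      }, logical(1L))]
      want <- if (length(ok) == 0L) 1.0 else min(ok)
      expect_equal(got, want)
    }
  }
})

test_that("cutoffs are monotone in the precision target", {
  set.seed(471L)
  scores <- runif(80L)
  truth <- runif(80L) > 0.5
  cuts <- vapply(c(0.5, 0.7, 0.9, 0.99), function(t)
    choose_cutoff(scores, truth, t), numeric(1L))
  expect_true(all(diff(cuts) >= 0))
})
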