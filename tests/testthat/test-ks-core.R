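sig_at_ranks <- function(inst, ranks) inst$genes[ranks]

test_that("ks_score matches hand-worked and enumerated cases", {
  inst <- toy_instance(10)

  top <- ks_score(inst, sig_at_ranks(inst, c(1, 2)))
  expect_equal(top$a, 0.8)
  expect_equal(top$b, 0.1)
  expect_equal(top$value, 0.8)

  bottom <- ks_score(inst, sig_at_ranks(inst, c(9, 10)))
  expect_equal(bottom$a, 0)
  expect_equal(bottom$b, 0.9)
  expect_equal(bottom$value, -0.9)

  # exact tie a == b resolves to -b
  tie <- ks_score(inst, sig_at_ranks(inst, c(3, 7)))
  expect_equal(tie$a, 0.3)
  expect_equal(tie$b, 0.3)
  expect_equal(tie$value, -0.3)

  inst6 <- toy_instance(6)
  mid <- ks_score(inst6, sig_at_ranks(inst6, c(2, 3, 5)))
  expect_equal(mid$a, 1 / 6)
  expect_equal(mid$b, 1 / 3)
  expect_equal(mid$value, -1 / 3)
})

test_that("ks_score validates its contract", {
  inst <- toy_instance(5)
  expect_error(ks_score(inst, character(0)), "empty signature")
  expect_error(ks_score(inst, c("g1", "nope")), "not in instance")
})

test_that("ks_score agrees with the direct-evaluation oracle on random cases", {
  set.seed(401)
  for (i in 1:200) {
    n <- sample(3:60, 1)
    t <- sample(seq_len(n), 1)
    ranks <- sort(sample.int(n, t))
    inst <- toy_instance(n)
    got <- ks_score(inst, sig_at_ranks(inst, ranks))
    expect_identical(got$value, ks_oracle(ranks, n))
    expect_gte(got$a, 0)
    expect_gt(got$b, 0)
    expect_lte(got$value, 1 - t / n + 1e-12)
    expect_gte(got$value, -(n - t + 1) / n - 1e-12)
  }
})

test_that("ks_score depends only on rank positions, not labels or scores", {
  set.seed(402)
  n <- 40
  ranks <- sort(sample.int(n, 6))
  a <- toy_instance(n)
  b <- ranked_instance(sprintf("XX%02d", 1:n),
                       scores = sort(rexp(n)))
  expect_identical(ks_score(a, a$genes[ranks])$value,
                   ks_score(b, b$genes[ranks])$value)
  # scoreless instance too
  c_ <- ranked_instance(a$genes)
  expect_identical(ks_score(c_, a$genes[ranks])$value,
                   ks_score(a, a$genes[ranks])$value)
})

test_that("promoting a signature gene never decreases a nor increases b", {
  # full enumeration at small n: move one gene to any strictly better rank
  violations <- 0L
  moves <- 0L
  for (n in c(6, 8, 10)) {
    inst <- toy_instance(n)
    for (t in 1:3) {
      subsets <- utils::combn(n, t)
      for (ci in seq_len(ncol(subsets))) {
        ranks <- subsets[, ci]
        base <- ks_score(inst, sig_at_ranks(inst, ranks))
        for (gi in seq_len(t)) {
          better <- setdiff(seq_len(ranks[gi] - 1L), ranks)
          for (newr in better) {
            moved <- sort(c(ranks[-gi], newr))
            ms <- ks_score(inst, sig_at_ranks(inst, moved))
            moves <- moves + 1L
            if (ms$a < base$a - 1e-12 || ms$b > base$b + 1e-12) {
              violations <- violations + 1L
            }
          }
        }
      }
    }
  }
  expect_gt(moves, 1000L)
  expect_equal(violations, 0L)
})

test_that("bootstrap_null stratifies by unique length and is reproducible", {
  inst <- make_instance(200, seed = 1)
  nulls <- bootstrap_null(inst, c(2, 2, 3), B = 50, seed = 9)
  expect_named(nulls, c("2", "3"))
  expect_length(nulls[["2"]]$scores, 50L)

  again <- bootstrap_null(inst, c(3, 2), B = 50, seed = 9)
  expect_identical(nulls[["2"]]$scores, again[["2"]]$scores)
  expect_identical(nulls[["3"]]$scores, again[["3"]]$scores)

  # full-length resamples are all the whole instance
  deg <- bootstrap_null(inst, 200, B = 10, seed = 4)[["200"]]
  expect_true(all(deg$scores == deg$scores[1]))
  expect_equal(deg$scores[1], -1 / 200)

  expect_error(bootstrap_null(inst, 0, B = 10, seed = 1), ">= 1")
  expect_error(bootstrap_null(inst, 201, B = 10, seed = 1), "exceeds")
})

test_that("null scores respect the KS score bounds for their length", {
  inst <- make_instance(100, seed = 2)
  nulls <- bootstrap_null(inst, c(1, 5, 50), B = 200, seed = 3)
  for (nl in nulls) {
    expect_true(all(nl$scores <= 1 - nl$length / 100))
    expect_true(all(nl$scores >= -(100 - nl$length + 1) / 100))
  }
})

test_that("empirical_p counts strict exceedances, add-one shifts it", {
  inst <- toy_instance(100)
  null <- bootstrap_null(inst, 5, B = 100, seed = 6)[["5"]]

  hi <- ks_score(inst, sig_at_ranks(inst, 1:5))      # a = 0.95, above all
  expect_true(all(null$scores < hi$value))
  expect_equal(empirical_p(hi, null), 0)
  expect_equal(empirical_p(hi, null, add_one = TRUE), 1 / 101)

  lo <- ks_score(inst, sig_at_ranks(inst, 96:100))   # -0.96, below all
  expect_equal(empirical_p(lo, null), 1)

  # direct counting oracle on a stored null vector
  obs <- ks_score(inst, sig_at_ranks(inst, c(10, 30, 55, 70, 90)))
  expect_equal(empirical_p(obs, null),
               sum(null$scores > obs$value) / 100)
  med <- stats::median(null$scores)
  p_med <- sum(null$scores > med) / 100
  expect_lt(abs(p_med - 0.5), 0.15)

  wrong <- bootstrap_null(inst, 4, B = 100, seed = 6)[["4"]]
  expect_error(empirical_p(hi, wrong), "does not match")
})

test_that("fdr_adjust reproduces textbook BH step-up values", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(c(1, 1)), c(1, 1))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(77)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= 0 & adj <= 1))
    # monotone: adjusted values ordered like p
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("repo recovers a planted top signature and keeps accounting", {
  inst <- make_instance(300, seed = 10)
  planted_genes <- inst$genes[1:10]
  db <- make_null_db(inst, m = 20, length_pool = 5:20, seed = 11)
  sets <- c(list(winner = planted_genes), db$sets)
  db2 <- signature_db(sets, source = "test")
  res <- repo(inst, db2, B = 500, seed = 12)
  expect_s3_class(res, "repo_results")
  expect_equal(res$compound_id[1], "winner")
  expect_equal(res$t[match("winner", res$compound_id)], 10L)
  expect_equal(nrow(res) + attr(res, "meta")$n_dropped, n_compounds(db2))
  # fdr column is BH of the p column, in displayed order
  expect_equal(res$fdr, fdr_adjust(res$p_value))
  expect_true(!is.unsorted(res$p_value))
})

test_that("identical signatures receive identical scores and q-values", {
  inst <- make_instance(100, seed = 20)
  genes <- inst$genes[c(3, 17, 40, 66)]
  db <- signature_db(list(cpd_a = genes, cpd_b = genes, cpd_c = genes),
                     source = "test")
  res <- repo(inst, db, B = 300, seed = 21)
  expect_equal(length(unique(res$ks)), 1L)
  expect_equal(length(unique(res$p_value)), 1L)
  expect_equal(length(unique(res$fdr)), 1L)
  # deterministic tie-break: sorted by compound_id
  expect_equal(res$compound_id, c("cpd_a", "cpd_b", "cpd_c"))
})

test_that("repo is deterministic for identical inputs and seed", {
  inst <- make_instance(150, seed = 30)
  db <- make_null_db(inst, m = 15, length_pool = 3:12, seed = 31)
  r1 <- repo(inst, db, B = 200, seed = 32)
  r2 <- repo(inst, db, B = 200, seed = 32)
  expect_identical(r1, r2)
  r3 <- repo(inst, db, B = 200, seed = 33)
  expect_false(identical(r1$p_value, r3$p_value))
})

test_that("result files round-trip with metadata sidecar", {
  inst <- make_instance(100, seed = 40)
  db <- make_null_db(inst, m = 10, length_pool = 4:10, seed = 41)
  res <- repo(inst, db, B = 100, seed = 42)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_repo_results(res, path)
  expect_true(file.exists(paste0(path, ".meta.json")))
  back <- read_repo_results(path)
  expect_equal(back$compound_id, res$compound_id)
  expect_equal(back$p_value, res$p_value, tolerance = 1e-5)
  meta <- attr(back, "meta")
  expect_equal(meta$B, 100L)
  expect_equal(meta$seed, 42L)
})
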