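make_panel <- function(calls, samples = sprintf("s%02d", seq_len(nrow(calls)))) {
  m <- ncol(calls)
  genotype_panel(calls, samples,
                 marker_map(sprintf("m%03d", 1:m), "1", seq_len(m) * 1000L,
                            rep("A", m), rep("G", m)))
}

test_that("MAF is the folded allele2 frequency over non-missing calls", {
  p <- make_panel(cbind(c(0L, 0L, 0L, 0L), c(0L, 1L, 1L, 2L)))
  expect_equal(compute_maf(p), c(m001 = 0, m002 = 0.5))
  # 3 copies of allele2 in 10 diploids
  calls <- matrix(0L, 10, 1); calls[1:3, 1] <- 1L
  expect_equal(unname(compute_maf(make_panel(calls))), 0.15)
  calls[, 1] <- NA_integer_
  expect_true(is.na(compute_maf(make_panel(calls))))
})

test_that("exact HWE test matches the enumeration oracle", {
  expect_equal(hwe_exact_p(17, 0, 0), 1.0)
  expect_equal(hwe_exact_p(25, 50, 25), oracle_hwe_p(25, 50, 25), tolerance = 1e-12)
  p5050 <- hwe_exact_p(50, 0, 50)
  expect_equal(p5050, oracle_hwe_p(50, 0, 50), tolerance = 1e-12)
  expect_lt(p5050, 1e-6)  # such a marker fails the HWE filter
  set.seed(9)
  for (i in 1:60) {
    n <- sample(1:200, 1)
    parts <- sort(sample(0:n, 2))
    tab <- c(parts[1], parts[2] - parts[1], n - parts[2])
    expect_equal(hwe_exact_p(tab[1], tab[2], tab[3]),
                 oracle_hwe_p(tab[1], tab[2], tab[3]), tolerance = 1e-12)
  }
})

test_that("call rates count non-missing fractions by marker and sample", {
  calls <- matrix(1L, 10, 10)
  p <- make_panel(calls)
  cr <- call_rates(p)
  expect_true(all(cr$snp == 1) && all(cr$ind == 1))
  calls[4, 7] <- NA_integer_
  cr <- call_rates(make_panel(calls))
  expect_equal(unname(cr$snp[7]), 0.9)
  expect_equal(unname(cr$ind[4]), 0.9)
  calls[, 2] <- NA_integer_
  expect_equal(unname(call_rates(make_panel(calls))$snp[2]), 0)
})

test_that("QC drops the engineered failures, keeps boundary cases, idempotent", {
  set.seed(5)
  n <- 50
  calls <- matrix(rbinom(n * 6, 2, 0.4), n, 6)
  calls[, 2] <- c(rep(1L, 2), rep(0L, n - 2))            # MAF 0.02 -> drop
  calls[, 3] <- c(rep(1L, 3), rep(0L, n - 3))            # MAF exactly 0.03 -> keep
  calls[, 4] <- rep(c(0L, 2L), n / 2)                    # perfect het deficit -> HWE fail
  calls[1:6, 5] <- NA_integer_                           # CR 0.88 -> drop
  p <- make_panel(calls)
  res <- apply_qc(p)
  kept <- res$panel$markers$marker_id
  expect_false("m002" %in% kept)
  expect_true("m003" %in% kept)   # threshold is inclusive
  expect_false("m004" %in% kept)
  expect_false("m005" %in% kept)
  expect_true(all(c("m001", "m006") %in% kept))
  res2 <- apply_qc(res$panel)
  expect_identical(res2$panel$calls, res$panel$calls)    # idempotent
  expect_equal(res2$report$markers_dropped, 0)

  mono <- make_panel(matrix(0L, 20, 3))
  err <- tryCatch(apply_qc(mono), error = function(e) e)
  expect_s3_class(err, "error")
  expect_equal(err$report$fail_maf, 3)
})

test_that("sample call-rate filter runs after marker filters", {
  set.seed(6)
  calls <- matrix(rbinom(200, 2, 0.5), 10, 20)
  # sample 1 is missing only on markers that fail MAF; must survive
  calls[, 1:4] <- 0L
  calls[1, 1:4] <- NA_integer_
  p <- make_panel(calls)
  res <- apply_qc(p)
  expect_true("s01" %in% res$panel$samples)
  expect_equal(res$report$fail_cr_ind, 0)
})

test_that("PI_HAT recovers duplicates, unrelated and parent-offspring", {
  set.seed(21)
  M <- 5000
  f <- runif(M, 0.1, 0.9)
  draw <- function() rbinom(M, 1, f) + rbinom(M, 1, f)
  # duplicate pair
  a <- draw()
  calls <- rbind(a, a, replicate(8, draw()) |> t())
  p <- make_dense_panel(calls)
  est <- estimate_pi_hat(p, pairs = cbind("s01", "s02"))
  expect_lt(abs(est$pi_hat - 1), 0.02)
  expect_true(est$reliable)
  # unrelated pairs, 20 replicates
  devs <- replicate(20, {
    h <- matrix(rbinom(4 * M, 1, rep(f, each = 4)), 4)
    calls2 <- rbind(h[1, ] + h[2, ], h[3, ] + h[4, ], calls[3:10, ])
    estimate_pi_hat(make_dense_panel(calls2), pairs = cbind("s01", "s02"))$pi_hat
  })
  expect_lt(max(abs(devs)), 0.05)
  # parent-offspring: child inherits one parental haplotype
  hp <- matrix(rbinom(2 * M, 1, rep(f, each = 2)), 2)
  child <- hp[1, ] + rbinom(M, 1, f)
  parent <- hp[1, ] + hp[2, ]
  calls3 <- rbind(parent, child, calls[3:10, ])
  est3 <- estimate_pi_hat(make_dense_panel(calls3), pairs = cbind("s01", "s02"))
  expect_lt(abs(est3$pi_hat - 0.5), 0.1)
})

test_that("relatedness pruning is greedy, deterministic and complete", {
  p <- random_genotype_panel(n_samples = 6, n_markers = 30, seed = 8)
  est <- data.frame(sample_a = c("s01", "s03", "s03", "s04"),
                    sample_b = c("s02", "s04", "s05", "s05"),
                    pi_hat = c(0.95, 0.3, 0.3, 0.3))
  out <- prune_related(p, est, pi_hat_max = 0.2)
  removed <- attr(out, "removed")
  # one duplicate pair -> one of them removed; triangle s03-s04-s05 -> two removed
  expect_length(intersect(removed, c("s01", "s02")), 1L)
  expect_length(intersect(removed, c("s03", "s04", "s05")), 2L)
  # no surviving pair above threshold
  surv <- est[!(est$sample_a %in% removed) & !(est$sample_b %in% removed), ]
  expect_true(all(surv$pi_hat <= 0.2))
  # nothing above threshold: unchanged
  est$pi_hat <- 0.1
  expect_identical(prune_related(p, est, 0.2)$calls, p$calls)
})

test_that("marker intersection preserves order and matches the set oracle", {
  p <- random_genotype_panel(n_samples = 4, n_markers = 20, seed = 13)
  a <- subset_markers(p, 1:15)
  b <- subset_markers(p, 6:20)
  out <- intersect_markers(list(a = a, b = b))
  expect_identical(out$a$markers$marker_id, p$markers$marker_id[6:15])
  expect_identical(out$a$markers$marker_id, out$b$markers$marker_id)
  expect_identical(intersect_markers(list(p, p))[[1]]$calls, p$calls)
  expect_error(intersect_markers(list(subset_markers(p, 1:5),
                                      subset_markers(p, 6:10))), "no markers")
  set.seed(3)
  subs <- lapply(1:4, function(i) sort(sample(20, 12)))
  panels <- lapply(subs, function(s) subset_markers(p, s))
  shared <- Reduce(intersect, lapply(subs, function(s) p$markers$marker_id[s]))
  out4 <- intersect_markers(panels)
  expect_identical(out4[[1]]$markers$marker_id, shared)
})
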