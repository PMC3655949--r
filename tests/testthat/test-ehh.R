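test_that("allele-conditioned EHH matches hand-built configurations", {
  # 4 derived carriers split into two identical pairs over the span
  mm <- marker_map(c("a", "b", "c"), "1", c(100L, 200L, 300L),
                   rep("A", 3), rep("G", 3), ancestral = "A")
  hap <- rbind(c(0L, 1L, 0L),
               c(0L, 1L, 0L),
               c(1L, 1L, 1L),
               c(1L, 1L, 1L),
               c(0L, 0L, 0L),
               c(1L, 0L, 1L))
  hp <- haplotype_panel(hap, c("s1", "s2", "s3"), mm)
  cur <- ehh(hp, core = 2, allele = "derived")
  expect_equal(cur$ehh[2], 1)                        # target = core
  expect_equal(cur$ehh[3], (1 + 1) / choose(4, 2))   # two identical pairs -> 1/3
  expect_equal(attr(cur, "carrier_count"), 4L)
  # all carriers mutually distinct over a 2-marker span -> 0
  mm4 <- marker_map(c("a", "b", "c", "d"), "1", c(100L, 200L, 300L, 400L),
                    rep("A", 4), rep("G", 4), ancestral = "A")
  hap2 <- rbind(c(0L, 1L, 0L, 0L), c(0L, 1L, 0L, 1L),
                c(1L, 1L, 1L, 0L), c(1L, 1L, 1L, 1L))
  hp2 <- haplotype_panel(hap2, c("s1", "s2"), mm4)
  expect_equal(ehh(hp2, 2, "derived")$ehh[4], 0)
  # fewer than two carriers: curve undefined
  expect_true(all(is.na(ehh(hp2, 2, "ancestral")$ehh)))
})

test_that("site EHHS is 1 at the core and on identical panels", {
  hp <- random_panel(10, 20, seed = 2)
  cur <- ehh(hp, 7, "site")
  expect_equal(cur$ehh[7], 1)
  same <- haplotype_panel(matrix(rep(c(0L, 1L), each = 6 * 10)[1:60], 6, 10),
                          sprintf("s%d", 1:3),
                          marker_map(sprintf("m%d", 1:10), "1", 1:10 * 100L,
                                     rep("A", 10), rep("G", 10)))
  expect_true(all(ehh(same, 5, "site")$ehh == 1))
})

test_that("EHH and EHHS agree exactly with the pairwise-identity oracle", {
  set.seed(31)
  for (rep in 1:30) {
    n_hap <- sample(c(4, 10, 20), 1)
    n_mk <- sample(10:50, 1)
    hp <- random_panel(n_hap, n_mk, seed = 1000 + rep)
    core <- sample(n_mk, 1)
    for (allele in c(0L, 1L)) {
      impl <- ehh(hp, core, if (allele == 1L) "derived" else "ancestral")$ehh
      expect_equal(impl, oracle_ehh_curve(hp$hap, core, allele))
    }
    expect_equal(ehh(hp, core, "site")$ehh, oracle_ehhs_curve(hp$hap, core))
  }
})

test_that("EHH curves are non-increasing away from the core", {
  for (rep in 1:5) {
    hp <- random_panel(16, 40, seed = 400 + rep)
    cur <- ehh(hp, 20, "derived")$ehh
    if (all(is.na(cur))) next
    expect_true(all(diff(cur[20:40]) <= 1e-12))
    expect_true(all(diff(rev(cur[1:20])) <= 1e-12))
  }
})

test_that("trapezoid integration follows the floor, gap and border policies", {
  # constant EHH = 1, core in the middle, truncate at borders: rectangle
  expect_equal(integrate_ehh(c(1, 1, 1), positions = c(0, 5000, 10000),
                             core_index = 2,
                             policy = integration_policy(border_rule = "truncate")),
               10000)
  # one-sided triangle: 1 at pos 0, 0 at pos 1000
  expect_equal(integrate_ehh(c(1, 0), positions = c(0, 1000), core_index = 1,
                             policy = integration_policy(border_rule = "truncate")),
               500)
  # same curve under discard: left side hits the border before the floor
  expect_true(is.na(integrate_ehh(c(1, 0), positions = c(0, 1000), core_index = 1,
                                  policy = integration_policy(border_rule = "discard"))))
  # a gap larger than max_gap_bp discards the whole statistic
  expect_true(is.na(integrate_ehh(c(0, 1, 0), positions = c(0, 300000, 600000),
                                  core_index = 2,
                                  policy = integration_policy(max_gap_bp = 200000))))
  # floor crossing includes the crossing marker as final vertex
  val <- integrate_ehh(c(0.01, 0.5, 1, 0.5, 0.01), positions = c(0, 1000, 2000, 3000, 4000),
                       core_index = 3, policy = integration_policy())
  expect_equal(val, 2 * (1000 * 0.75 + 1000 * 0.255))
})

test_that("the C++ scan equals the R curve-and-integrate route", {
  hp <- as_polarized(random_panel(18, 60, seed = 55))
  pol <- integration_policy(border_rule = "discard")
  sc <- ehh_scan(hp, pol)
  for (core in c(5, 20, 41, 58)) {
    for (al in c("ancestral", "derived", "site")) {
      ref <- integrate_ehh(ehh(hp, core, al), policy = pol)
      got <- switch(al, ancestral = sc$ihh_a[core], derived = sc$ihh_d[core],
                    site = sc$ies[core])
      expect_equal(got, ref)
    }
  }
})

test_that("iHH is shift-invariant and scales linearly in positions", {
  hp <- as_polarized(random_panel(20, 50, seed = 77))
  pol <- integration_policy(border_rule = "truncate", max_gap_bp = 1e9)
  base <- ehh_scan(hp, pol)
  shift <- hp
  shift$markers$pos <- shift$markers$pos + 12345L
  scaled <- hp
  scaled$markers$pos <- hp$markers$pos * 3L
  expect_equal(ehh_scan(shift, pol)$ihh_d, base$ihh_d)
  expect_equal(ehh_scan(scaled, pol)$ihh_d, 3 * base$ihh_d)
})

test_that("bifurcation edge lists partition the carriers at every step", {
  hp <- random_panel(20, 30, seed = 91)
  core <- 15
  edges <- bifurcation(hp, core, "derived")
  n_car <- sum(hp$hap[, core] == 1L)
  expect_gt(n_car, 1)
  for (side in unique(edges$side)) {
    e <- edges[edges$side == side, ]
    for (p in unique(e$position)) {
      expect_equal(sum(e$haplotype_count[e$position == p]), n_car)
    }
  }
  # root edges emanate from node 0 at the first off-core marker
  first <- edges[edges$side == "right", ]
  expect_true(all(first$parent_node[first$position == min(first$position)] == 0))
})
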