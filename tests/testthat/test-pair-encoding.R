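test_that("indicator takes +1 on ties and regulator-dominant samples", {
  m <- rbind(M = c(5, 3, 4), G = c(3, 5, 4))
  colnames(m) <- c("S1", "S2", "S3")
  cat1 <- tibble::tibble(regulator = "M", target = "G")
  ind <- encode_pairs(make_expr(m), cat1)
  expect_equal(unname(unlist(ind[1, c("S1", "S2", "S3")])), c(1L, -1L, 1L))

  cat_bad <- tibble::tibble(regulator = "M", target = "H")
  expect_error(encode_pairs(make_expr(m), cat_bad), "H")
})

test_that("encoding is invariant under strictly increasing per-sample transforms", {
  set.seed(9)
  n_genes <- 12; n_samp <- 15
  m <- matrix(stats::rnorm(n_genes * n_samp, mean = 8), n_genes,
              dimnames = list(c(sprintf("R%d", 1:3), sprintf("G%d", 1:9)),
                              sprintf("S%02d", 1:n_samp)))
  cat1 <- expand.grid(regulator = sprintf("R%d", 1:3),
                      target = sprintf("G%d", 1:9),
                      stringsAsFactors = FALSE)
  base <- encode_pairs(make_expr(m), cat1)
  transforms <- list(function(x) exp(x), function(x) x^3,
                     function(x) log(x - min(x) + 1), function(x) 5 * x - 100,
                     function(x) atan(x), function(x) rank(x))
  for (rep in 1:100) {
    m2 <- m
    for (s in seq_len(n_samp)) {
      f <- transforms[[sample(length(transforms), 1)]]
      m2[, s] <- f(m[, s])
    }
    expect_identical(encode_pairs(make_expr(m2), cat1), base)
  }
})

test_that("contingency counts split +1/-1 by diagnosis group", {
  ind_m <- rbind(c(1, 1, 1, -1, -1),      # 3 LGG all +1, 2 GBM all -1
                 c(1, 1, 1, 1, 1),
                 c(1, -1, 1, -1, 1))
  colnames(ind_m) <- sprintf("S%d", 1:5)
  ind <- make_indicators(ind_m)
  cl <- make_clinical(sprintf("S%d", 1:5), rep(10, 5), rep(1, 5),
                      grade = c("LGG", "LGG", "LGG", "GBM", "GBM"))
  cc <- contingency_counts(ind, cl)
  expect_equal(unlist(cc[1, c("a", "b", "c", "d")], use.names = FALSE),
               c(3L, 0L, 0L, 2L))
  expect_equal(unlist(cc[2, c("a", "b", "c", "d")], use.names = FALSE),
               c(3L, 0L, 2L, 0L))
  expect_equal(cc$a[3] + cc$b[3], 3L)  # margins are the group sizes
  expect_true(all(cc$a + cc$b + cc$c + cc$d == 5L))

  cl_bad <- cl; cl_bad$grade[5] <- "unknown"
  expect_error(contingency_counts(ind, cl_bad), "neither group")
})

test_that("Fisher point probability matches direct factorial evaluation", {
  expect_equal(fisher_point_log10(1, 1, 1, 1), log10(2 / 3), tolerance = 1e-12)
  expect_equal(fisher_point_log10(2, 0, 0, 2), log10(1 / 6), tolerance = 1e-12)
  for (k in c(1, 5, 50)) expect_equal(fisher_point_log10(k, 0, 0, 0), 0)
  expect_error(fisher_point_log10(-1, 1, 1, 1), "negative")
})

test_that("two-sided p matches enumeration on worked tables", {
  # margins (2,2)/(2,2): tables have probs 1/6, 2/3, 1/6
  expect_equal(fisher_two_sided_log10(2, 0, 0, 2), log10(1 / 3),
               tolerance = 1e-12)
  expect_equal(fisher_two_sided_log10(1, 1, 1, 1), 0, tolerance = 1e-12)
  # perfectly separated 50/50 is astronomically unlikely under the null
  expect_lt(fisher_two_sided_log10(50, 0, 0, 50), -28)
})

test_that("point and two-sided log10 p agree with the exact oracle (n <= 20)", {
  for (n in c(1:10, 12, 16, 20)) {
    tabs <- all_tables(n)
    lp <- fisher_point_log10(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4])
    lp2 <- fisher_two_sided_log10(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4])
    for (i in seq_len(nrow(tabs))) {
      t0 <- tabs[i, ]
      expect_equal(lp[i], log10(oracle_fisher_point(t0[1], t0[2], t0[3], t0[4])),
                   tolerance = 1e-12)
      expect_equal(lp2[i],
                   log10(oracle_fisher_two_sided(t0[1], t0[2], t0[3], t0[4])),
                   tolerance = 1e-12)
    }
  }
})

test_that("two-sided p agrees with stats::fisher.test on random tables", {
  set.seed(33)
  for (i in 1:40) {
    t0 <- sample(0:25, 4, replace = TRUE)
    if (sum(t0) == 0) next
    ft <- stats::fisher.test(matrix(t0, 2, byrow = TRUE))
    expect_equal(10^fisher_two_sided_log10(t0[1], t0[2], t0[3], t0[4]),
                 ft$p.value, tolerance = 1e-7)
  }
})

test_that("Fisher p-values obey exactness and symmetry invariants", {
  set.seed(14)
  # point probabilities over fixed margins sum to 1 (log-space total = 0)
  for (rep in 1:10) {
    t0 <- sample(0:8, 4, replace = TRUE)
    r1 <- t0[1] + t0[2]; ac <- t0[1] + t0[3]; n <- sum(t0)
    if (n == 0) next
    lo <- max(0, ac - (n - r1)); hi <- min(r1, ac)
    aa <- lo:hi
    lp <- fisher_point_log10(aa, r1 - aa, ac - aa, n - r1 - ac + aa)
    expect_equal(sum(10^lp), 1, tolerance = 1e-12)
  }
  for (rep in 1:25) {
    t0 <- sample(0:30, 4, replace = TRUE)
    if (sum(t0) == 0) next
    p0 <- fisher_two_sided_log10(t0[1], t0[2], t0[3], t0[4])
    # swapping the groups and swapping +1/-1 leave p unchanged
    expect_equal(fisher_two_sided_log10(t0[3], t0[4], t0[1], t0[2]), p0)
    expect_equal(fisher_two_sided_log10(t0[2], t0[1], t0[4], t0[3]), p0)
    # two-sided p >= point probability
    expect_gte(p0, fisher_point_log10(t0[1], t0[2], t0[3], t0[4]) - 1e-12)
    expect_lte(p0, 0)
  }
})

test_that("reversal selection applies the strict log10 cutoff and sorts", {
  res <- tibble::tibble(pair = c("A|B", "C|D", "E|F"),
                        regulator = c("A", "C", "E"), target = c("B", "D", "F"),
                        a = 1L, b = 1L, c = 1L, d = 1L,
                        log10_p_point = c(-81, -61, -90),
                        log10_p_two_sided = c(-80, -60, -89),
                        selected = NA)
  sel <- select_reversed_pairs(res)
  expect_equal(sel$pair, c("E|F", "A|B"))
  expect_equal(nrow(select_reversed_pairs(res[0, ])), 0L)
})

test_that("reversal proportion reports per-group +1 fractions", {
  ind_m <- rbind(c(1, 1, 1, -1, 1, 1, -1, -1),
                 c(-1, -1, -1, -1, 1, 1, 1, 1))
  colnames(ind_m) <- sprintf("S%d", 1:8)
  ind <- make_indicators(ind_m)
  cl <- make_clinical(sprintf("S%d", 1:8), rep(10, 8), rep(1, 8),
                      grade = c(rep("normal", 4), rep("LGG", 2), rep("GBM", 2)))
  pr <- reversal_proportion(ind, cl)
  expect_equal(pr$proportion[pr$pair == "R1|T1" & pr$group == "normal"], 0.75)
  expect_equal(pr$proportion[pr$pair == "R2|T2" & pr$group == "normal"], 0)
  expect_error(reversal_proportion(ind, cl, groups = c("normal", "WHO-V")),
               "empty group")
})

test_that("planted monotone reversal yields decreasing proportions across grades", {
  # normal-like, LGG-like and GBM-like groups with the regulator-target
  # gap shifted from +2 through 0 to -2: the +1 fraction must fall
  set.seed(55)
  n_per <- 60
  gap_shift <- rep(c(2, 0, -2), each = n_per)
  reg <- stats::rnorm(3 * n_per, mean = 8 + gap_shift / 2)
  tgt <- stats::rnorm(3 * n_per, mean = 8 - gap_shift / 2)
  m <- rbind(R1 = reg, T1 = tgt)
  colnames(m) <- sprintf("S%03d", seq_len(3 * n_per))
  ind <- encode_pairs(make_expr(m), tibble::tibble(regulator = "R1", target = "T1"))
  cl <- make_clinical(colnames(m), rep(10, 3 * n_per), rep(1, 3 * n_per),
                      grade = rep(c("normal", "LGG", "GBM"), each = n_per))
  pr <- reversal_proportion(ind, cl)
  props <- pr$proportion[order(pr$group)]
  expect_true(all(diff(props) < 0))
})
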