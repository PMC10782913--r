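test_that("published signature carries the five printed pairs and coefficients", {
  sig <- published_mrgps()
  expect_s3_class(sig, "pair_signature")
  expect_equal(nrow(sig$entries), 5L)
  expect_equal(sig$provenance, "published")
  co <- stats::setNames(sig$entries$coefficient,
                        paste(sig$entries$regulator, sig$entries$target, sep = "|"))
  expect_equal(unname(co["EIF3A|AK2"]), -0.204)
  expect_equal(unname(co["EIF3A|EMP3"]), -0.266)
  expect_equal(unname(co["YTHDC1|IGFBP2"]), -0.439)
  expect_equal(unname(co["YTHDC1|TUBA1C"]), -0.140)
  expect_equal(unname(co["IGF2BP3|CYP17A1"]), 0.647)
  expect_equal(sum(co), -0.402, tolerance = 1e-12)
})

test_that("risk scores are the signed coefficient sums with median-split groups", {
  sig <- published_mrgps()
  ind_m <- matrix(c(rep(1L, 5), rep(-1L, 5), c(1L, 1L, -1L, -1L, 1L)), 5)
  colnames(ind_m) <- c("ALLPOS", "ALLNEG", "MIX")
  ind <- make_indicators(ind_m, sig$entries$regulator, sig$entries$target)
  rs <- risk_score(sig, ind)
  expect_equal(rs$score[rs$sample_id == "ALLPOS"], -0.402, tolerance = 1e-12)
  expect_equal(rs$score[rs$sample_id == "ALLNEG"], 0.402, tolerance = 1e-12)
  # mixed sample: -0.204 - 0.266 + 0.439 + 0.140 + 0.647
  expect_equal(rs$score[rs$sample_id == "MIX"], 0.756, tolerance = 1e-12)

  # missing pair is a hard error, never silently dropped
  expect_error(risk_score(sig, ind[-3, ]), "IGFBP2")

  # linearity and sign symmetry
  sig2 <- sig; sig2$entries$coefficient <- 2 * sig$entries$coefficient
  expect_equal(risk_score(sig2, ind)$score, 2 * rs$score)
  ind_neg <- ind
  for (cn in c("ALLPOS", "ALLNEG", "MIX")) ind_neg[[cn]] <- -ind_neg[[cn]]
  expect_equal(risk_score(sig, ind_neg)$score, -rs$score)

  sig0 <- sig; sig0$entries$coefficient <- rep(0, 5)
  expect_true(all(risk_score(sig0, ind)$score == 0))
})

test_that("median split assigns ties to low and balances groups", {
  sig <- published_mrgps()
  set.seed(8)
  ind_m <- matrix(sample(c(-1L, 1L), 5 * 101, replace = TRUE), 5)
  colnames(ind_m) <- sprintf("S%03d", 1:101)
  ind <- make_indicators(ind_m, sig$entries$regulator, sig$entries$target)
  rs <- risk_score(sig, ind)
  med <- stats::median(rs$score)
  n_tied <- sum(rs$score == med)
  # ties go to low; the split is balanced up to the tied samples
  expect_true(all(rs$group[rs$score == med] == "low"))
  expect_equal(sum(rs$group == "high"), sum(rs$score > med))
  expect_lte(abs(sum(rs$group == "high") - sum(rs$group == "low")),
             max(1, 2 * n_tied - 1))
})

test_that("signature JSON serialization round-trips", {
  sig <- published_mrgps()
  tf <- withr::local_tempfile(fileext = ".json")
  write_signature(sig, tf)
  sig2 <- read_signature(tf)
  expect_equal(sig2$entries$coefficient, sig$entries$coefficient)
  expect_equal(sig2$entries$regulator, sig$entries$regulator)
  expect_equal(sig2$provenance, "published")
})

test_that("tidy and glance summarize signatures", {
  sig <- published_mrgps()
  td <- tidy(sig)
  expect_equal(td$pair[5], "IGF2BP3|CYP17A1")
  gl <- glance(sig)
  expect_equal(gl$n_pairs, 5L)
  expect_equal(gl$coef_sum, -0.402, tolerance = 1e-12)
})

test_that("Cox refit recovers planted coefficients and flags degenerate designs", {
  set.seed(101)
  n <- 1000
  ind_m <- matrix(sample(c(-1L, 1L), 2 * n, replace = TRUE), 2)
  colnames(ind_m) <- sprintf("S%04d", 1:n)
  ind <- make_indicators(ind_m)
  cl <- simulate_surv(ind_m, c(0.8, -0.5), cens_rate = 0.2, seed = 102)
  sel <- tibble::tibble(regulator = c("R1", "R2"), target = c("T1", "T2"))
  sig <- cox_refit(sel, ind, cl)
  expect_equal(sig$provenance, "fitted")
  expect_lt(abs(sig$entries$coefficient[1] - 0.8), 0.15)
  expect_lt(abs(sig$entries$coefficient[2] + 0.5), 0.15)
  expect_equal(sig$entries$hr, exp(sig$entries$coefficient))
  expect_lt(sig$global_p, 1e-10)

  # null pair: coefficient near zero
  cl0 <- simulate_surv(ind_m, c(0, 0), cens_rate = 0.2, seed = 103)
  sig0 <- cox_refit(sel, ind, cl0)
  expect_lt(max(abs(sig0$entries$coefficient)), 0.15)

  # perfectly collinear columns are an error naming the pair
  ind_dup <- make_indicators(rbind(ind_m[1, ], ind_m[1, ]),
                             c("R1", "R9"), c("T1", "T9"))
  sel_dup <- tibble::tibble(regulator = c("R1", "R9"), target = c("T1", "T9"))
  expect_error(cox_refit(sel_dup, ind_dup, cl), "collinear")
})

test_that("LASSO finds a planted prognostic pair among nulls and shrinks to empty", {
  n <- 400
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed + 400)
    ind_m <- matrix(sample(c(-1L, 1L), 21 * n, replace = TRUE), 21)
    colnames(ind_m) <- sprintf("S%04d", 1:n)
    ind <- make_indicators(ind_m)
    cl <- simulate_surv(ind_m, c(1, rep(0, 20)), cens_rate = 0.2,
                        seed = seed + 800)
    sel <- lasso_cox_select(ind, cl, seed = seed)
    if ("R1|T1" %in% sel$pair) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # selection is reproducible under a fixed seed
  set.seed(77)
  ind_m <- matrix(sample(c(-1L, 1L), 10 * 300, replace = TRUE), 10)
  colnames(ind_m) <- sprintf("S%03d", 1:300)
  ind <- make_indicators(ind_m)
  cl <- simulate_surv(ind_m, c(1, rep(0, 9)), seed = 78)
  s1 <- lasso_cox_select(ind, cl, seed = 5)
  s2 <- lasso_cox_select(ind, cl, seed = 5)
  expect_identical(s1, s2)
  expect_error(lasso_cox_select(ind, cl), "seed")

  # no events is an error
  cl_none <- cl; cl_none$event <- 0
  expect_error(lasso_cox_select(ind, cl_none, seed = 1), "events")
})

test_that("large-n LASSO at tiny penalty approaches the unpenalized Cox fit", {
  set.seed(202)
  n <- 2000
  ind_m <- matrix(sample(c(-1L, 1L), 2 * n, replace = TRUE), 2)
  colnames(ind_m) <- sprintf("S%04d", 1:n)
  ind <- make_indicators(ind_m)
  cl <- simulate_surv(ind_m, c(0.7, -0.4), cens_rate = 0, seed = 203)
  x <- t(ind_m)
  y <- survival::Surv(cl$time_months, cl$event)
  fit_glm <- glmnet::glmnet(x, y, family = "cox", standardize = FALSE,
                            lambda = c(0.05, 1e-8))
  co_l <- as.vector(stats::coef(fit_glm, s = 1e-8))
  sel <- tibble::tibble(regulator = c("R1", "R2"), target = c("T1", "T2"))
  co_cox <- cox_refit(sel, ind, cl)$entries$coefficient
  expect_equal(co_l, co_cox, tolerance = 0.02)
})

test_that("clinical covariates enter the combined model and recover an age effect", {
  # age drives hazard at log HR 0.05/yr alongside two pair indicators
  set.seed(301)
  n <- 800
  ind_m <- matrix(sample(c(-1L, 1L), 2 * n, replace = TRUE), 2)
  colnames(ind_m) <- sprintf("S%04d", 1:n)
  age <- round(stats::runif(n, 20, 80))
  lp <- 0.5 * ind_m[1, ] + 0.05 * (age - 50)
  t_event <- stats::rexp(n, 0.02 * exp(lp))
  cl <- make_clinical(colnames(ind_m), pmax(t_event, 1e-6), 1L,
                      age = age,
                      radiotherapy = sample(c("yes", "no"), n, TRUE))
  ind <- make_indicators(ind_m)
  sel <- tibble::tibble(regulator = c("R1", "R2"), target = c("T1", "T2"))
  sig <- cox_refit(sel, ind, cl)
  cmb <- combine_clinical(sig, ind, cl)
  age_row <- cmb$terms[cmb$terms$term == "age", ]
  expect_gt(age_row$hr_high, exp(0.05))  # true HR/year inside the Wald CI
  expect_lt(age_row$hr_low, exp(0.05))
  expect_equal(nrow(cmb$index), n)

  # no covariates reduces to the pairs-only fit
  cmb0 <- combine_clinical(sig, ind, cl, covariates = character(0))
  expect_equal(sort(cmb0$terms$coefficient), sort(sig$entries$coefficient),
               tolerance = 1e-8)

  # constant covariate and collinear covariate are errors
  cl_const <- cl; cl_const$radiotherapy <- "yes"
  expect_error(combine_clinical(sig, ind, cl_const), "constant")
  cl_dup <- cl; cl_dup$dup <- ind_m[1, ]
  expect_error(combine_clinical(sig, ind, cl_dup, covariates = "dup"),
               "collinear")
})

test_that("single-gene LASSO baseline recovers prognostic genes", {
  set.seed(501)
  n <- 500; g <- 100
  m <- matrix(stats::rnorm(g * n, mean = 8), g,
              dimnames = list(sprintf("G%03d", 1:g), sprintf("S%04d", 1:n)))
  lp <- 1 * (m["G001", ] - 8) - 1 * (m["G002", ] - 8)
  t_event <- stats::rexp(n, 0.02 * exp(lp))
  cens <- stats::runif(n, 0, stats::quantile(t_event, 0.9) * 2.5)
  cl <- make_clinical(colnames(m), pmax(pmin(t_event, cens), 1e-6),
                      as.integer(t_event <= cens))
  found <- 0
  for (seed in 1:5) {
    bl <- baseline_gene_signature(make_expr(m), cl, seed = seed)
    found <- found + all(c("G001", "G002") %in% bl$genes$gene)
    expect_lte(nrow(bl$genes), 20L)
  }
  expect_gte(found, 4)

  # adding a constant to one gene leaves scores unchanged up to centering
  m2 <- m; m2["G050", ] <- m2["G050", ] + 100
  bl1 <- baseline_gene_signature(make_expr(m), cl, seed = 3)
  bl2 <- baseline_gene_signature(make_expr(m2), cl, seed = 3)
  expect_equal(bl1$genes$gene, bl2$genes$gene)
  expect_equal(bl1$scores$group, bl2$scores$group)
})
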