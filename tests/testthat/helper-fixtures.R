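# fixtures are built in code; no binary data is stored

# tiny expression tibble from a named matrix
make_expr <- function(m) {
  dplyr::bind_cols(tibble::tibble(gene = rownames(m)),
                   tibble::as_tibble(as.data.frame(m, check.names = FALSE)))
}

# clinical tibble with minimal required columns
make_clinical <- function(sample_id, time, event, grade = "LGG", ...) {
  tibble::tibble(sample_id = sample_id, time_months = time,
                 event = event, grade = grade, ...)
}

# indicator tibble from a pairs x samples matrix of +/-1
make_indicators <- function(m, regulator = NULL, target = NULL) {
  if (is.null(regulator)) {
    regulator <- sprintf("R%d", seq_len(nrow(m)))
    target <- sprintf("T%d", seq_len(nrow(m)))
  }
  dplyr::bind_cols(
    tibble::tibble(regulator = regulator, target = target,
                   pair = paste(regulator, target, sep = "|")),
    tibble::as_tibble(as.data.frame(m, check.names = FALSE)))
}

# ---- exact Fisher oracle via prime factorization of factorials ----
# point probability of a 2x2 table, computed as prod(p^e) over primes
# with Legendre exponents of the factorials: an exact rational value
# evaluated in double (error only in the final few multiplications)

.primes_upto <- function(n) {
  if (n < 2) return(integer(0))
  s <- rep(TRUE, n); s[1] <- FALSE
  p <- 2
  while (p * p <= n) {
    if (s[p]) s[seq(p * p, n, by = p)] <- FALSE
    p <- p + 1
  }
  which(s)
}

# exponent of prime p in k!
.legendre <- function(k, p) {
  e <- 0; q <- p
  while (q <= k) { e <- e + k %/% q; q <- q * p }
  e
}

oracle_fisher_point <- function(a, b, c, d) {
  n <- a + b + c + d
  pr <- .primes_upto(max(n, 2))
  num <- c(a + b, c + d, a + c, b + d)
  den <- c(a, b, c, d, n)
  val <- 1
  for (p in pr) {
    e <- sum(vapply(num, .legendre, 0, p = p)) -
      sum(vapply(den, .legendre, 0, p = p))
    val <- val * p^e
  }
  val
}

# two-sided p: sum of point probabilities <= observed, enumerated
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; ac <- a + c; n <- a + b + c + d
  lo <- max(0, ac - (n - r1)); hi <- min(r1, ac)
  probs <- vapply(lo:hi, function(aa)
    oracle_fisher_point(aa, r1 - aa, ac - aa, n - r1 - ac + aa), 0)
  obs <- probs[(lo:hi) == a]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# all 2x2 tables with total n (a+b+c+d = n)
all_tables <- function(n) {
  out <- list()
  for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
    d <- n - a - b - c
    out[[length(out) + 1]] <- c(a, b, c, d)
  }
  do.call(rbind, out)
}

# exponential PH survival on given indicator rows (pairs x samples)
simulate_surv <- function(ind_m, betas, baseline = 0.02, cens_rate = 0.2,
                          seed = 1) {
  set.seed(seed)
  n <- ncol(ind_m)
  lp <- as.vector(crossprod(ind_m, betas))
  t_event <- stats::rexp(n, rate = baseline * exp(lp))
  if (cens_rate > 0) {
    cens <- stats::runif(n, 0, stats::quantile(t_event, 0.9) * 2.5)
    time <- pmin(t_event, cens); event <- as.integer(t_event <= cens)
  } else {
    time <- t_event; event <- rep(1L, n)
  }
  make_clinical(colnames(ind_m), pmax(time, 1e-6), event)
}
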