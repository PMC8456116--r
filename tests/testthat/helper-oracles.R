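# Shared fixtures and independent oracles used across test files.

# independent logistic fit by damped Newton iterations (oracle for glm IRLS)
newton_logistic <- function(y, X, iter = 50, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    step <- solve(crossprod(X, X * W), crossprod(X, y - mu))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, mu = plogis(drop(X %*% beta)))
}

# exact HWE conditional distribution by direct multinomial enumeration:
# weight every genotype table (a, b, c) with a + b + c = n by its
# multinomial probability under HW frequencies, condition on the
# minor-allele count, and sum the tables no more probable than observed
hwe_enum_oracle <- function(a, b, c, p_minor = 0.3) {
  n <- a + b + c
  m <- b + 2 * c
  probs <- c((1 - p_minor)^2, 2 * p_minor * (1 - p_minor), p_minor^2)
  tabs <- expand.grid(a = 0:n, b = 0:n)
  tabs$c <- n - tabs$a - tabs$b
  tabs <- tabs[tabs$c >= 0 & (tabs$b + 2 * tabs$c) == m, ]
  w <- apply(tabs, 1, function(t) dmultinom(t, prob = probs))
  w <- w / sum(w)
  obs <- which(tabs$a == a & tabs$b == b)
  sum(w[w <= w[obs] + 1e-10])
}

# build a combined unit directly from matrices (positions synthesized)
make_unit <- function(snv = NULL, cnv = NULL, id = "unit",
                      chrom = "1", start = 1, end = 10000) {
  n <- if (!is.null(snv)) nrow(snv) else nrow(cnv)
  if (is.null(snv)) snv <- matrix(0, n, 0)
  if (is.null(cnv)) cnv <- matrix(0, n, 0)
  q1 <- ncol(snv); q2 <- ncol(cnv)
  snv_info <- data.frame(
    id = if (q1) paste0("s", seq_len(q1)) else character(0),
    chrom = rep(chrom, q1),
    pos = if (q1) seq(start + 10, by = 7, length.out = q1) else integer(0),
    stringsAsFactors = FALSE)
  cnv_info <- data.frame(
    id = if (q2) paste0("c", seq_len(q2)) else character(0),
    chrom = rep(chrom, q2),
    start = rep(start, q2),
    end = rep(end, q2),
    stringsAsFactors = FALSE)
  incoloc:::new_unit_matrix(id, as.character(seq_len(n)), snv, cnv,
                            snv_info, cnv_info,
                            c(chrom = chrom, start = start, end = end),
                            empty = q1 + q2 == 0)
}

# random small SNV + CNV panels on one chromosome
random_panels <- function(n = 30, q1 = 8, q2 = 4, seed = 1,
                          chrom_len = 10000) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(n))
  mk <- data.frame(id = paste0("snv", seq_len(q1)), chrom = "1",
                   pos = sort(sample.int(chrom_len, q1)),
                   stringsAsFactors = FALSE)
  g <- sapply(runif(q1, 0.05, 0.5), function(f) rbinom(n, 2, f))
  st <- sample.int(chrom_len - 500, q2)
  sg <- data.frame(id = paste0("seg", seq_len(q2)), chrom = "1",
                   start = st, end = st + sample.int(500, q2),
                   stringsAsFactors = FALSE)
  s <- sapply(rep(0.2, q2), function(f) rbinom(n, 1, f))
  list(snv = snv_panel(ids, mk, g), cnv = cnv_panel(ids, sg, s))
}

# permutation null distribution of Q_rho under an intercept-only binary
# null (mu is permutation invariant there, so only the residual vector
# permutes); returns the permutation p-value of the observed statistic
perm_pvalue_q <- function(G, w, y, rho, B = 10000, seed = 42) {
  set.seed(seed)
  mu <- mean(y)
  r_obs <- y - mu
  q_of <- function(r_mat) {
    Sw <- w * crossprod(G, r_mat)          # m x B
    (1 - rho) * colSums(Sw^2) + rho * colSums(Sw)^2
  }
  q_obs <- q_of(matrix(r_obs, ncol = 1))
  perm <- replicate(B, sample(y)) - mu     # n x B
  q_perm <- q_of(perm)
  # mid-p tie handling: the statistic lives on a lattice, the analytic
  # reference is continuous
  (sum(q_perm > q_obs + 1e-9) + 0.5 * sum(abs(q_perm - q_obs) <= 1e-9)) / B
}

# small intercept-only binary null, shared by several files
fixed_binary_null <- function(n = 100, frac_case = 0.4, seed = 5) {
  set.seed(seed)
  y <- sample(rep(c(1, 0), c(round(n * frac_case),
                             n - round(n * frac_case))))
  fit_null(y, NULL, "binary")
}
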