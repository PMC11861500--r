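# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation paths they verify.

# small labeled expression matrix
toy_expr <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("G%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("S%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Welch two-sample t-test p-value from first principles
oracle_welch_p <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  v1 <- var(x1); v0 <- var(x0)
  se2 <- v1 / n1 + v0 / n0
  tstat <- (mean(x1) - mean(x0)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  2 * pt(-abs(tstat), df)
}

# ssGSEA score by an explicit walk down the ranking
oracle_ssgsea <- function(values, gene_set, alpha = 0.25) {
  n <- length(values)
  r <- rank(values, ties.method = "average")
  ord <- order(-values, names(values))
  in_set <- names(values)[ord] %in% gene_set
  w_total <- sum(r[ord][in_set]^alpha)
  n_out <- n - sum(in_set)
  score <- 0; p_in <- 0; p_out <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) p_in <- p_in + r[ord][i]^alpha / w_total
    else p_out <- p_out + 1 / n_out
    score <- score + (p_in - p_out)
  }
  unname(score)
}

# TOM by an explicit triple loop
oracle_tom <- function(adj) {
  p <- nrow(adj)
  k <- rowSums(adj)
  tom <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(p)) if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
    tom[i, j] <- (l + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
  }
  tom
}

# Efron-corrected Cox partial log-likelihood for a single covariate
oracle_efron_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d_idx <- which(time == t & event == 1)
    r_idx <- which(time >= t)
    d <- length(d_idx)
    eta <- beta * x
    sum_r <- sum(exp(eta[r_idx]))
    sum_d <- sum(exp(eta[d_idx]))
    ll <- ll + sum(eta[d_idx])
    for (l in seq_len(d)) {
      ll <- ll - log(sum_r - (l - 1) / d * sum_d)
    }
  }
  ll
}

# log-rank chi-squared by hand tabulation over pooled event times (2 groups)
oracle_logrank <- function(group, time, event) {
  g <- as.integer(as.factor(group))
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Mann-Whitney AUC of scores against a binary outcome, ties credited 0.5
oracle_mw_auc <- function(scores, outcome) {
  pos <- scores[outcome == 1]
  neg <- scores[outcome == 0]
  total <- 0
  for (a in pos) for (b in neg) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# Harrell's C by exhaustive pair enumeration
oracle_cindex <- function(scores, time, event) {
  n <- length(scores)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # the pair is comparable if the earlier time is an event
    ti <- time[i]; tj <- time[j]
    if (ti == tj && event[i] == 0 && event[j] == 0) next
    if (ti < tj || (ti == tj && event[j] == 0)) {
      early <- i; late <- j
    } else if (tj < ti || (ti == tj && event[i] == 0)) {
      early <- j; late <- i
    } else next  # tied event times: ordering unknown
    if (event[early] == 0) next
    den <- den + 1
    if (scores[early] > scores[late]) num <- num + 1
    else if (scores[early] == scores[late]) num <- num + 0.5
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of arrangements
oracle_wilcox_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- combn(n + m, n)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  mu <- n * m / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# strictly increasing per-sample transforms for invariance checks
monotone_transforms <- list(
  log1p = function(x) log1p(x),
  affine = function(x) 3.7 * x + 11,
  rank = function(x) rank(x, ties.method = "average"),
  cube = function(x) x^3 + x
)

small_survival_cohort <- function(n = 60, seed = 42) {
  set.seed(seed)
  list(time = rexp(n, 0.1) * 365, event = rbinom(n, 1, 0.7),
       scores = rnorm(n))
}
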