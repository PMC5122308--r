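# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# random posture vector with controllable run structure
random_postures <- function(n, labels = default_repertoire()$label,
                            k = length(labels)) {
  sample(labels[seq_len(k)], n, replace = TRUE)
}

# adjacent-pair scan for versatility, written as a plain loop
scan_changes <- function(p) {
  changes <- 0L
  for (i in seq_along(p)[-1]) {
    if (p[i] != p[i - 1]) changes <- changes + 1L
  }
  changes
}

scan_distinct_transitions <- function(p) {
  seen <- character(0)
  for (i in seq_along(p)[-1]) {
    if (p[i] != p[i - 1]) {
      seen <- union(seen, paste(p[i - 1], p[i], sep = "->"))
    }
  }
  length(seen)
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
enumerate_wmw_p <- function(x, y, sides = "two") {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_of)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  switch(sides,
    two = min(1, 2 * min(p_le, p_ge)),
    greater = p_ge,
    less = p_le
  )
}

# exact two-sided signed-rank p by enumeration of all sign patterns
enumerate_signed_rank_p <- function(d, sides = "two") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  switch(sides,
    two = min(1, 2 * min(p_le, p_ge)),
    greater = p_ge,
    less = p_le
  )
}

# least squares + gaussian log-likelihood from the normal equations
ols_loglik <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y)
  s2 <- sum(res^2) / n # ML variance
  ll <- -n / 2 * (log(2 * pi * s2) + 1)
  list(beta = as.vector(beta), loglik = ll)
}

# brute-force enumeration of hierarchical term subsets
enumerate_term_sets <- function(terms, exclusions = list()) {
  n <- length(terms)
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  requires <- function(tm) {
    if (grepl(":", tm)) {
      strsplit(tm, ":", fixed = TRUE)[[1]]
    } else if (grepl("2$", tm) && sub("2$", "", tm) %in% terms) {
      sub("2$", "", tm)
    } else {
      character(0)
    }
  }
  ok <- apply(grid, 1, function(row) {
    inc <- terms[row]
    for (tm in inc) {
      if (!all(requires(tm) %in% inc)) return(FALSE)
    }
    for (pair in exclusions) {
      if (all(pair %in% inc)) return(FALSE)
    }
    TRUE
  })
  sum(ok)
}

# tiny valid event tibble builder
make_events <- function(id, postures, span = 300, window = 300) {
  behavior_sequence(
    id,
    seq(0, window - 1, length.out = length(postures)),
    postures,
    span = span, window_length = window
  )
}
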