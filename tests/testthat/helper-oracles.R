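# Independent brute-force oracles used to cross-check the statistical
# routines. These deliberately avoid the code paths under test.

# OLS by grid search minimizing the sum of squared errors, refined around
# the best cell over several passes.
grid_ols <- function(x, y, passes = 6L, width = NULL, centre = NULL) {
  if (is.null(centre)) centre <- c(slope = 0, intercept = mean(y))
  if (is.null(width)) {
    width <- c(4 * (max(abs(y)) + 1) / (diff(range(x)) + 1e-9),
               4 * (max(abs(y)) + 1))
  }
  for (pass in seq_len(passes)) {
    slopes <- seq(centre[1] - width[1], centre[1] + width[1], length.out = 41)
    ints <- seq(centre[2] - width[2], centre[2] + width[2], length.out = 41)
    sse <- outer(slopes, ints, Vectorize(function(a, b) sum((y - a * x - b)^2)))
    best <- arrayInd(which.min(sse), dim(sse))
    centre <- c(slopes[best[1]], ints[best[2]])
    width <- width / 10
  }
  centre
}

# Exact permutation p value for the Pearson correlation of small samples:
# proportion of permutations of y with |r| at least the observed |r|.
perm_pearson_p <- function(x, y) {
  perms <- all_perms(seq_along(y))
  r_obs <- abs(cor(x, y))
  rs <- vapply(perms, function(p) abs(cor(x, y[p])), numeric(1))
  mean(rs >= r_obs - 1e-12)
}

all_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# Exact Kruskal-Wallis p by complete enumeration, with the H statistic
# written out directly from the rank-sum definition (tie-corrected).
oracle_kw_H <- function(values, group_index) {
  n <- length(values)
  rk <- rank(values)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(rk, group_index, sum)^2 / tabulate(group_index)) - 3 * (n + 1)
  tie <- table(values)
  H / (1 - sum(tie^3 - tie) / (n^3 - n))
}

oracle_kw_exact_p <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  sizes <- vapply(groups, length, 1L)
  gi <- rep.int(seq_along(sizes), sizes)
  H_obs <- oracle_kw_H(values, gi)
  combos <- combn(seq_along(values), sizes[1L], simplify = FALSE)
  stopifnot(length(sizes) == 2L)  # oracle covers the two-group case
  hs <- vapply(combos, function(first) {
    oracle_kw_H(values[c(first, setdiff(seq_along(values), first))], gi)
  }, numeric(1))
  mean(hs >= H_obs - 1e-12)
}
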