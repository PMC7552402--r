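# Independent oracles and shared fixtures for the test suite. Each oracle
# deliberately uses a different algorithm / code path than the package
# implementation it checks.

# --- per-base reference-coordinate walk over a CIGAR -----------------------
# Scans the CIGAR character by character, then advances a reference cursor
# one base at a time, recording the bases consumed by each N operation.
oracle_walk_junctions <- function(cigar, pos) {
  ops <- character()
  lens <- integer()
  num <- ""
  for (ch in strsplit(cigar, "")[[1]]) {
    if (ch >= "0" && ch <= "9") {
      num <- paste0(num, ch)
    } else {
      stopifnot(nchar(num) > 0)
      ops <- c(ops, ch)
      lens <- c(lens, as.integer(num))
      num <- ""
    }
  }
  cursor <- pos
  out <- NULL
  for (k in seq_along(ops)) {
    consumes <- ops[k] %in% c("M", "D", "N", "=", "X")
    if (ops[k] == "N") {
      first <- NA_integer_
      last <- NA_integer_
      for (b in seq_len(lens[k])) {       # one base at a time
        if (is.na(first)) first <- cursor
        last <- cursor
        cursor <- cursor + 1L
      }
      out <- rbind(out, data.frame(intron_start = first, intron_end = last))
    } else if (consumes) {
      for (b in seq_len(lens[k])) cursor <- cursor + 1L
    }
  }
  if (is.null(out)) data.frame(intron_start = integer(),
                               intron_end = integer())
  else out
}

# Random valid CIGAR strings (M always present so records stay plausible).
random_cigar <- function() {
  n_ops <- sample(1:7, 1)
  ops <- sample(c("M", "I", "D", "N", "S", "=", "X"), n_ops, replace = TRUE,
                prob = c(0.4, 0.1, 0.1, 0.2, 0.1, 0.05, 0.05))
  ops[1] <- "M"
  lens <- sample(1:120, n_ops, replace = TRUE)
  paste0(lens, ops, collapse = "")
}

# --- Mann-Whitney exact two-sided p by bitmask enumeration -----------------
# U from the pairwise-count definition (not the rank-sum formula); group
# assignments enumerated as bitmasks over 2^(n1+n2).
oracle_mw_exact <- function(x, y) {
  u_pairs <- function(a, b) {
    u <- 0
    for (ai in a) for (bi in b) {
      u <- u + (ai > bi) + 0.5 * (ai == bi)
    }
    u
  }
  pooled <- c(x, y)
  n <- length(pooled)
  n1 <- length(x)
  u_obs <- u_pairs(x, y)
  us <- numeric(0)
  for (mask in 0:(2^n - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (sum(bits) != n1) next
    us <- c(us, u_pairs(pooled[bits], pooled[!bits]))
  }
  tol <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + tol), mean(us >= u_obs - tol)))
}

# Faster exact oracle for larger enumerations: U from the pairwise-count
# definition via a precomputed comparison matrix, subsets from combn.
oracle_mw_exact_fast <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  n1 <- length(x)
  C <- outer(pooled, pooled, function(a, b) (a > b) + 0.5 * (a == b))
  rs <- rowSums(C)
  u_of <- function(ii) {
    # sum over i in S, j not in S of C[i, j]
    sum(rs[ii]) - sum(C[ii, ii])
  }
  u_obs <- u_of(seq_len(n1))
  idx <- utils::combn(n, n1)
  us <- apply(idx, 2, u_of)
  tol <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + tol), mean(us >= u_obs - tol)))
}

# --- OLS via explicit normal equations for the QTL model -------------------
oracle_ols <- function(y, X) {
  xtx <- t(X) %*% X
  beta <- solve(xtx, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(xtx)) * sigma2)
  t_stat <- beta[, 1] / se
  list(beta = beta[, 1], se = se,
       p = 2 * pt(-abs(t_stat), df))
}

# --- small shared fixtures -------------------------------------------------
tiny_gene <- function() default_gene_model()

# A small flip-scenario world: genotypes with one focal SNP, covariates,
# default flip effects.
flip_world <- function(n = 200, seed = 1, maf = 0.3) {
  gt <- simulate_genotypes(n, n_independent = 1, seed = seed,
                           independent_mafs = maf,
                           independent_ids = "rs_flip")
  cov <- simulate_cohort(n, n_copd = floor(n / 2), seed = seed + 1000)
  list(genotypes = gt, covariates = cov, gene = tiny_gene(),
       spec = default_flip_spec("rs_flip"))
}
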