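# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# -- graph metrics by exhaustive pair loops ---------------------------------

oracle_threshold <- function(C, p) {
  N <- nrow(C)
  pairs <- NULL
  for (i in 1:(N - 1))
    for (j in (i + 1):N)
      pairs <- rbind(pairs, c(i, j, C[i, j]))
  L <- floor(p * N * (N - 1) / 2)
  ord <- order(-pairs[, 3])
  A <- matrix(0L, N, N)
  for (q in seq_len(L)) {
    i <- pairs[ord[q], 1]; j <- pairs[ord[q], 2]
    A[i, j] <- 1L; A[j, i] <- 1L
  }
  A
}

oracle_degrees <- function(A) {
  N <- nrow(A)
  deg <- integer(N)
  for (i in 1:N)
    for (j in 1:N)
      if (i != j && A[i, j] == 1) deg[i] <- deg[i] + 1L
  deg
}

oracle_within <- function(A, members) {
  deg <- oracle_degrees(A)
  mean(deg[members])
}

oracle_between <- function(A, mem_a, mem_b) {
  cnt <- 0L
  for (i in mem_a)
    for (j in mem_b)
      if (A[i, j] == 1) cnt <- cnt + 1L
  cnt
}

# -- exact nonparametric reference distributions ----------------------------

# two-sided exact p of the paired Wilcoxon signed-rank statistic by
# enumerating all 2^n sign assignments of the |differences| ranks
oracle_wilcoxon_exact_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  ev <- n * (n + 1) / 4
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-12)
}

# exact permutation distribution of the Friedman statistic over all
# (k!)^n within-row orderings of a small table
oracle_friedman_exact_p <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  stat_of <- function(m) {
    R <- t(apply(m, 1, rank))
    cs <- colSums(R)
    # tie-corrected chi-square form (matches the standard definition)
    num <- (12 * sum((cs - n * (k + 1) / 2)^2))
    ties <- sum(apply(m, 1, function(r) {
      tt <- table(r); sum(tt^3 - tt)
    }))
    den <- n * k * (k + 1) - ties / (k - 1)
    num / den
  }
  s_obs <- stat_of(tab)
  perms <- perms_of(k)
  idx <- rep(list(seq_len(nrow(perms))), n)
  grid <- expand.grid(idx)
  stats <- apply(grid, 1, function(g) {
    m <- tab
    for (i in seq_len(n)) m[i, ] <- tab[i, perms[g[i], ]]
    stat_of(m)
  })
  mean(stats >= s_obs - 1e-12)
}

perms_of <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- perms_of(k - 1)
  out <- NULL
  for (i in 1:k) {
    rest <- (1:k)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# exact Friedman null for k = 3, tie-free rows, any n: dynamic programming
# over the joint column rank sums (equivalent to enumerating all (3!)^n
# within-row orderings)
oracle_friedman3_exact_p <- function(tab) {
  stopifnot(ncol(tab) == 3)
  n <- nrow(tab)
  R <- t(apply(tab, 1, rank))
  stopifnot(all(abs(sort(unlist(R[1, ])) - 1:3) < 1e-9))  # tie-free
  obs <- colSums(R)
  stat_of <- function(s1, s2) {
    s3 <- 6 * n - s1 - s2
    12 / (n * 3 * 4) * ((s1 - 2 * n)^2 + (s2 - 2 * n)^2 + (s3 - 2 * n)^2)
  }
  perms <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  dist <- matrix(0, 3 * n + 1, 3 * n + 1)  # P(S1 = i, S2 = j), offset 1
  dist[1, 1] <- 1
  for (subj in seq_len(n)) {
    nxt <- matrix(0, 3 * n + 1, 3 * n + 1)
    nz <- which(dist > 0, arr.ind = TRUE)
    for (q in seq_len(nrow(nz))) {
      i <- nz[q, 1]; j <- nz[q, 2]; pr <- dist[i, j] / 6
      for (p in 1:6)
        nxt[i + perms[p, 1], j + perms[p, 2]] <-
          nxt[i + perms[p, 1], j + perms[p, 2]] + pr
    }
    dist <- nxt
  }
  s_obs <- stat_of(obs[1], obs[2])
  total <- 0
  nz <- which(dist > 0, arr.ind = TRUE)
  for (q in seq_len(nrow(nz))) {
    s1 <- nz[q, 1] - 1; s2 <- nz[q, 2] - 1
    if (stat_of(s1, s2) >= s_obs - 1e-12) total <- total + dist[nz[q, 1], nz[q, 2]]
  }
  total
}

# Spearman by rank-then-Pearson
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# -- reduced-scale simulation presets ---------------------------------------

# 50-node cohort used for simulation-heavy checks: same default effect sizes,
# scaled node counts and run length
small_sim_config <- function(n_subjects = 15L, ...) {
  sim_config(n_subjects = n_subjects, n_dmn = 13L, n_fpn = 6L, n_other = 31L,
             n_volumes = 120L, ...)
}

null_sim_config <- function(n_subjects = 15L) {
  zero <- c(rest = 0, el_learn = 0, te_learn = 0, el_test = 0, te_test = 0)
  small_sim_config(n_subjects = n_subjects, dmn_boost = zero, fpn_boost = zero,
                   between_boost = zero, tau = 0)
}

# metrics for one simulated run without the preprocessing overhead
quick_metrics <- function(cfg, cond, parc, p = 0.25, shifts = c(0, 0, 0)) {
  S <- make_covariance(cfg, cond, between_shift = shifts[3],
                       dmn_shift = shifts[1], fpn_shift = shifts[2])
  ts <- simulate_subject(cfg, cond, chol_factor = chol(S))
  A <- proportional_threshold(correlation_matrix(ts), p)
  c(dmn = within_network_connectivity(A, parc, "DMN"),
    fpn = within_network_connectivity(A, parc, "FPN"),
    bet = between_network_connectivity(A, parc, "DMN", "FPN"))
}

# within-DMN cohort table (subjects x conditions) computed without filtering,
# for simulation-heavy statistical checks
fast_cohort_tables <- function(cfg, conditions, metric_rows = c("dmn", "fpn", "bet")) {
  parc <- make_parcellation(cfg)
  d <- rnorm(cfg$n_subjects, 0, cfg$tau)
  shift_for <- function(cond, di) switch(cond, el_learn = -di / 2,
                                         te_learn = +di / 2, 0)
  out <- lapply(metric_rows, function(.) matrix(NA_real_, cfg$n_subjects,
                                                length(conditions),
                                                dimnames = list(NULL, conditions)))
  names(out) <- metric_rows
  for (i in seq_len(cfg$n_subjects)) {
    for (cond in conditions) {
      eta <- rnorm(3, 0, cfg$omega)
      v <- quick_metrics(cfg, cond, parc,
                         shifts = c(eta[1], eta[2], eta[3] + shift_for(cond, d[i])))
      for (mr in metric_rows) out[[mr]][i, cond] <- v[[mr]]
    }
  }
  out$subject_effects <- d
  out
}
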