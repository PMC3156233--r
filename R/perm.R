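# Group-label permutation machinery for two-sample survival statistics.
#
# Subjects are exchangeable within cells of identical (time, status), so a
# random relabelling is equivalent to drawing a random two-way table with
# fixed margins (cell sizes x group sizes); stats::r2dtable supplies those
# tables. All per-permutation quantities are then computed by matrix
# algebra over the pooled event times, which keeps large permutation
# counts affordable.

# Precompute the pooled structure shared by every permutation.
perm_structure <- function(ds1, ds2) {
  s1 <- subject_level(ds1); s2 <- subject_level(ds2)
  all_t <- c(s1$time, s2$time)
  all_s <- c(s1$status, s2$status)
  cells <- unique(data.frame(time = all_t, status = all_s))
  cells <- cells[order(cells$time, -cells$status), , drop = FALSE]
  cid <- match(paste(all_t, all_s), paste(cells$time, cells$status))
  r <- tabulate(cid, nbins = nrow(cells))   # cell sizes (pooled)
  obs1 <- tabulate(cid[seq_len(nrow(s1))], nbins = nrow(cells))

  tt <- sort(unique(all_t[all_s == 1L]))
  M_geq <- outer(tt, cells$time, `<=`) * 1          # at risk at tt[j]
  M_death <- outer(tt, cells$time, `==`) *
    matrix(cells$status, nrow = length(tt), ncol = nrow(cells),
           byrow = TRUE)
  n_pool <- drop(M_geq %*% r)
  d_pool <- drop(M_death %*% r)
  list(tt = tt, r = r, obs1 = obs1, n1_tot = nrow(s1), n2_tot = nrow(s2),
       M_geq = M_geq, M_death = M_death, n_pool = n_pool, d_pool = d_pool,
       Ltri = lower.tri(diag(length(tt)), diag = TRUE) * 1)
}

# Per-group at-risk/death counts for a matrix A (cells x B) of group-1
# cell counts; returns T x B matrices.
perm_counts <- function(st, A) {
  n1 <- st$M_geq %*% A
  d1 <- st$M_death %*% A
  list(n1 = n1, d1 = d1, n2 = st$n_pool - n1, d2 = st$d_pool - d1)
}

# KM survival curves for both groups at the pooled event times, T x B.
# Where a group has no one at risk the curve simply carries its last
# value (factor 1).
perm_km_curves <- function(st, cnt) {
  lf <- function(d, n) {
    f <- ifelse(n > 0, 1 - d / n, 1)
    lg <- log(f)
    lg[!is.finite(lg)] <- -700            # S hits exactly 0
    exp(st$Ltri %*% lg)
  }
  list(S1 = lf(cnt$d1, cnt$n1), S2 = lf(cnt$d2, cnt$n2))
}

# Supremum |S1 - S2| per permutation (column).
perm_ks_stat <- function(st, A) {
  cnt <- perm_counts(st, A)
  km <- perm_km_curves(st, cnt)
  apply(abs(km$S1 - km$S2), 2L, max)
}

# Draw B random group-1 cell-count vectors (cells x B). The margins are
# passed to r2dtable in a canonical (sorted) order so that the same seed
# yields the same permutation set regardless of which group is labelled
# first; every statistic computed downstream is symmetric under taking
# the complement, so label-swap invariance is exact.
perm_tables <- function(st, B) {
  sizes <- c(st$n1_tot, st$n2_tot)
  o <- order(sizes)
  tabs <- r2dtable(B, st$r, sizes[o])
  pos <- match(1L, o)
  vapply(tabs, function(m) m[, pos], numeric(length(st$r)))
}

# Run a seeded computation without clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

perm_pvalue <- function(obs, perm) {
  (1 + sum(perm >= obs - 1e-12)) / (length(perm) + 1)
}
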