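# Independent oracles used to cross-check the implementation. These are
# deliberately naive/brute-force and share no code with R/.

# Plain alternating median sweeps (no effect reallocation); the probeset
# summary is column effect + median of the probe effects.
oracle_median_polish <- function(z, eps = 0.01, maxiter = 10L) {
  r <- numeric(nrow(z))
  cc <- numeric(ncol(z))
  oldsum <- 0
  for (it in seq_len(maxiter)) {
    rd <- apply(z, 1L, stats::median)
    z <- z - rd
    r <- r + rd
    cd <- apply(z, 2L, stats::median)
    z <- sweep(z, 2L, cd)
    cc <- cc + cd
    newsum <- sum(abs(z))
    if (newsum == 0 || abs(newsum - oldsum) < eps * newsum) break
    oldsum <- newsum
  }
  cc + stats::median(r)
}

# Literal step-up definition: q_(i) = min(1, min_{j>=i} p_(j) * n / j),
# mapped back to input order.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  scaled <- (n / seq_len(n)) * ps
  q <- numeric(n)
  for (i in seq_len(n)) q[i] <- min(1, min(scaled[i:n]))
  out <- numeric(n)
  out[o] <- q
  out
}

# Exhaustive upper-tail hypergeometric: enumerate every k-subset of an
# n-gene universe whose first m genes carry the term.
oracle_hypergeom <- function(x, k, m, n) {
  if (k == 0) return(as.numeric(x == 0))
  sets <- utils::combn(n, k)
  mean(colSums(sets <= m) >= x)
}

# Reachability closure of the is_a graph by boolean matrix iteration;
# returns a logical terms x terms matrix, self-reachability included.
oracle_reachability <- function(dag) {
  ids <- dag$terms$id
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (id in ids) adj[id, dag$parents[[id]]] <- TRUE
  reach <- diag(n) > 0
  dimnames(reach) <- list(ids, ids)
  repeat {
    nxt <- reach | ((reach %*% adj) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

# Build a three-contrast result list with prescribed q-values, for
# classification tests. `q` is a matrix with columns cx, T, F.
fake_results <- function(q, genes = sprintf("g%03d", seq_len(nrow(q))),
                         lfc = NULL) {
  if (is.null(lfc)) lfc <- matrix(1, nrow(q), 3L)
  mk <- function(j, cmp) data.frame(
    gene_id = genes, tissue = rep("t1", nrow(q)),
    comparison = rep(cmp, nrow(q)),
    log2fc = lfc[, j], t_mod = rep(1, nrow(q)), p = q[, j], q = q[, j],
    stringsAsFactors = FALSE)
  list(cx_vs_sham = mk(1L, "cx_vs_sham"),
       T_vs_cx = mk(2L, "T_vs_cx"),
       F_vs_cx = mk(3L, "F_vs_cx"))
}

# A single-tissue null (no planted effects) synthetic configuration.
null_config <- function(n_genes, seed, tissue = "levator_ani") {
  synth_config(
    n_genes = n_genes,
    tissue_params = data.frame(tissue = tissue, frac_androgen = 0,
                               overlap_follistatin = 0,
                               frac_follistatin_only = 0),
    seed = seed)
}
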