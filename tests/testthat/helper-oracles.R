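# Independent brute-force oracles. These deliberately avoid the package's
# internal representations: matrices are handled as cell-token strings and
# Mk transition probabilities come from a matrix exponential, so agreement
# with the package is a genuine cross-check.

# decode a cell token into a state vector; NULL when unscored
oracle_cell <- function(tok) {
  if (tok %in% c("?", "-")) return(NULL)
  body <- gsub("[(){}]", "", tok)
  as.integer(strsplit(body, "")[[1]])
}

# character-by-character GC/MORD between two rows of a token matrix
oracle_pair <- function(tokens, ordering, i, j, metric = "MORD") {
  nc <- ncol(tokens)
  # observed range per character over the whole matrix
  rng <- sapply(seq_len(nc), function(k) {
    st <- unlist(lapply(tokens[, k], oracle_cell))
    if (is.null(st) || length(st) == 0) c(NA, NA) else range(st)
  })
  sumd <- summax <- 0; ncomp <- 0
  for (k in seq_len(nc)) {
    a <- oracle_cell(tokens[i, k]); b <- oracle_cell(tokens[j, k])
    if (is.null(a) || is.null(b)) next
    dk <- min(abs(outer(a, b, "-")))
    if (ordering[k] != "ordered") dk <- as.numeric(dk > 0)
    mk <- if (ordering[k] == "ordered") rng[2, k] - rng[1, k] else 1
    sumd <- sumd + dk; summax <- summax + mk; ncomp <- ncomp + 1
  }
  if (ncomp == 0) return(NA_real_)
  if (metric == "GC") sumd / ncomp else if (summax == 0) 0 else sumd / summax
}

# ER Mk transition matrix by matrix exponential (independent of the closed
# form used in the package)
oracle_mk_P <- function(q, t, k) {
  Q <- matrix(q, k, k); diag(Q) <- -(k - 1) * q
  as.matrix(Matrix::expm(Q * t))
}

# full-enumeration likelihood and node marginals for a small tree.
# tip_states: list (by tip index) of state vectors (NULL = missing), states
# coded 1..k here.
oracle_mk_enumeration <- function(phy, q, tip_states, k) {
  n_tip <- ape::Ntip(phy)
  n_node <- phy$Nnode
  edges <- phy$edge
  Ps <- lapply(seq_len(nrow(edges)), function(e) oracle_mk_P(q, phy$edge.length[e], k))
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), n_node)))
  weights <- numeric(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    assign_state <- function(v) combos[r, v - n_tip]
    w <- 1 / k # flat root prior
    for (e in seq_len(nrow(edges))) {
      p <- edges[e, 1]; ch <- edges[e, 2]
      sp <- assign_state(p)
      if (ch <= n_tip) {
        st <- tip_states[[ch]]
        w <- w * if (is.null(st)) 1 else sum(Ps[[e]][sp, st])
      } else {
        w <- w * Ps[[e]][sp, assign_state(ch)]
      }
    }
    weights[r] <- w
  }
  lik <- sum(weights)
  marg <- matrix(0, n_node, k)
  for (v in seq_len(n_node))
    for (s in seq_len(k))
      marg[v, s] <- sum(weights[combos[, v] == s]) / lik
  list(loglik = log(lik), marginals = marg)
}

# small ultrametric balanced trees
balanced_tree8 <- function() {
  read_newick_tree("(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);")
}

# quick token matrix -> character_matrix
cm_from_tokens <- function(tokens, ordering = NULL) {
  character_matrix(tokens, ordering = ordering)
}

# tokens of a character_matrix (re-exported for oracle use)
tokens_of <- function(m) morphodtt:::cm_tokens(m)
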