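# Ancestral state reconstruction under the equal-rates Mk model --------------
#
# One rate q per character, estimated by maximum likelihood (bounded search
# on log q) with Felsenstein pruning over branch durations. Node
# probabilities are the marginal (rerooting) probabilities obtained by a
# second, root-to-tip message pass; the flat root prior cancels in the
# normalisation. For the equal-rates model the transition probabilities have
# the closed form
#   P(same)  = 1/k + (k-1)/k * exp(-k q t)
#   P(other) = 1/k -     1/k * exp(-k q t)
# so a matrix-vector product reduces to m + e*(v - m) with m = mean(v),
# e = exp(-k q t).

er_propagate <- function(v, q, t, k) {
  m <- sum(v) / k
  m + exp(-k * q * t) * (v - m)
}

# Postorder down-pass; returns conditional likelihoods per node (rescaled)
# plus the total log-likelihood under a flat root prior.
mk_down_pass <- function(edge, edge_len, n_tip, n_node, tiplik, q) {
  k <- ncol(tiplik)
  L <- matrix(1, n_tip + n_node, k)
  L[seq_len(n_tip), ] <- tiplik
  logscale <- 0
  msg <- matrix(NA_real_, nrow(edge), k) # P(t_e) L[child_e], reused by up-pass
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    msg[e, ] <- er_propagate(L[ch, ], q, edge_len[e], k)
    L[p, ] <- L[p, ] * msg[e, ]
    mx <- max(L[p, ])
    if (mx < 1e-100) mx <- 1e-100
    if (mx < 1) { L[p, ] <- L[p, ] / mx; logscale <- logscale + log(mx) }
  }
  root <- n_tip + 1L
  list(L = L, msg = msg,
       loglik = log(sum(L[root, ]) / k) + logscale)
}

# Marginal ASR for a single character on a time tree.
asr_one_character <- function(tt, masks) {
  phy <- tt$phy
  n_tip <- ape::Ntip(phy)
  scored <- which(!is.na(masks))
  if (length(scored) < 2L)
    return(NULL)
  obs <- sort(unique(unlist(lapply(masks[scored], decode_states))))
  k <- length(obs)
  n_node <- phy$Nnode
  if (k == 1L) {
    prob <- matrix(1, n_node, 1, dimnames = list(phy$node.label, obs))
    return(list(probabilities = prob,
                states = stats::setNames(rep(obs, n_node), phy$node.label),
                q = 0, loglik = 0))
  }
  tiplik <- matrix(1, n_tip, k)
  for (i in scored) {
    st <- decode_states(masks[i])
    tiplik[i, ] <- as.numeric(obs %in% st)
  }
  po <- ape::reorder.phylo(phy, "postorder")
  edge <- po$edge; edge_len <- po$edge.length

  ll <- function(logq) mk_down_pass(edge, edge_len, n_tip, n_node, tiplik, exp(logq))$loglik
  opt <- stats::optimize(ll, interval = c(log(1e-7), log(20)), maximum = TRUE, tol = 1e-6)
  q <- exp(opt$maximum)

  dp <- mk_down_pass(edge, edge_len, n_tip, n_node, tiplik, q)
  # up-pass (preorder: parents before children). For a bifurcating tree each
  # internal node has exactly two child edges; the message to one child
  # combines the above-likelihood of the parent with the sibling's message.
  A <- matrix(1, n_tip + n_node, k)
  child_edges <- split(seq_len(nrow(edge)), edge[, 1])
  for (e in rev(seq_len(nrow(edge)))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    sibs <- setdiff(child_edges[[as.character(p)]], e)
    up <- A[p, ]
    for (s in sibs) up <- up * dp$msg[s, ]
    A[ch, ] <- er_propagate(up, q, edge_len[e], k)
    A[ch, ] <- A[ch, ] / max(A[ch, ])
  }
  nodes <- n_tip + seq_len(n_node)
  prob <- dp$L[nodes, , drop = FALSE] * A[nodes, , drop = FALSE]
  prob <- prob / rowSums(prob)
  dimnames(prob) <- list(phy$node.label, obs)
  # argmax with ties broken to the lowest state label (which.max is first-max
  # and columns are in ascending state order)
  assigned <- obs[apply(prob, 1, which.max)]
  list(probabilities = prob,
       states = stats::setNames(assigned, phy$node.label),
       q = q, loglik = dp$loglik)
}

#' Marginal ancestral states of one character
#'
#' Fits an equal-rates Mk model to a single discrete character by maximum
#' likelihood and returns marginal (rerooting) state probabilities for every
#' internal node, with a flat root prior. Missing tips contribute a flat
#' partial likelihood; polymorphic tips contribute 1 for each state in their
#' set. The assigned state is the most probable one, ties going to the
#' lowest state label.
#'
#' @param tt A [time_tree()].
#' @param x The character: a vector named by tip label, with entries in cell
#'   token form (`"0"`, `"(01)"`, `"?"`, `"-"`) or integers (NA = missing).
#' @return `NULL` when fewer than 2 tips are scored; otherwise a list with
#'   `probabilities` (nodes x states), `states` (assigned state per node),
#'   `q` (ML rate, changes per Ma) and `loglik`.
#' @export
mk_marginal_asr <- function(tt, x) {
  tips <- tt$phy$tip.label
  if (is.null(names(x))) stop("'x' must be named by tip label")
  if (!setequal(names(x), tips)) stop("names of 'x' must match the tree's tips")
  x <- x[tips]
  masks <- vapply(x, function(v) {
    if (is.na(v)) NA_integer_
    else if (is.numeric(v)) encode_states(v)
    else parse_cell(as.character(v))$mask
  }, integer(1))
  asr_one_character(tt, masks)
}

#' Reconstruct ancestral states for every character
#'
#' Runs [mk_marginal_asr()] on every character and returns the
#' node-augmented character matrix: tip rows first (in the tree's tip
#' order), then one row per internal node (root first) holding each node's
#' assigned most-probable state. For a bifurcating tree with `n` tips the
#' result has `2n - 1` rows. Characters scored for fewer than 2 tips yield
#' MISSING node cells.
#'
#' @param tt A [time_tree()] whose tips match the matrix taxa.
#' @param m A [character_matrix()] of the tips.
#' @return A [character_matrix()] with tip and node rows; per-character ML
#'   rates and node probability tables are attached as attributes `q` and
#'   `node_probabilities`.
#' @export
reconstruct_all <- function(tt, m) {
  tips <- tt$phy$tip.label
  if (!setequal(taxon_labels(m), tips))
    stop("tip labels of tree and matrix do not match")
  m <- m[tips]
  nodes <- tt$phy$node.label
  node_states <- matrix(NA_integer_, length(nodes), n_char(m),
                        dimnames = list(nodes, colnames(m$states)))
  probs <- vector("list", n_char(m))
  qs <- rep(NA_real_, n_char(m))
  for (j in seq_len(n_char(m))) {
    fit <- asr_one_character(tt, m$states[, j])
    if (is.null(fit)) next
    node_states[, j] <- vapply(fit$states[nodes], encode_states, integer(1))
    probs[[j]] <- fit$probabilities
    qs[j] <- fit$q
  }
  node_cm <- new_character_matrix(node_states, ordering = m$ordering)
  out <- cm_bind_rows(m, node_cm)
  attr(out, "node_probabilities") <- probs
  attr(out, "q") <- qs
  out
}

#' Write node state probabilities to TSV
#'
#' Long-format audit table: node, character, state, probability.
#'
#' @param augmented Result of [reconstruct_all()].
#' @param path Output path.
#' @export
write_asr_tsv <- function(augmented, path) {
  probs <- attr(augmented, "node_probabilities")
  if (is.null(probs)) stop("no node probabilities attached")
  rows <- list()
  for (j in seq_along(probs)) {
    pj <- probs[[j]]
    if (is.null(pj)) next
    rows[[j]] <- data.frame(
      node = rep(rownames(pj), ncol(pj)),
      character = j,
      state = rep(colnames(pj), each = nrow(pj)),
      probability = as.vector(pj)
    )
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
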