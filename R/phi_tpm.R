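#' Logic networks and transition probability matrices
#'
#' The IIT engine works on small binary logic networks in *node form*: a
#' `2^n x n` matrix giving, for every current network state (rows, state
#' index convention of [state_to_bits()]), the probability that each node
#' is ON at the next timestep. Deterministic networks have 0/1 entries;
#' unidirectional system cuts introduce fractional entries. Node form is
#' equivalent to the full `2^n x 2^n` state-by-state TPM for networks
#' whose nodes update independently given the previous state, which holds
#' for all networks built here.
#'
#' @name tpm
NULL

#' Construct a generic logic network
#'
#' A network of `n` binary nodes, each optionally carrying a gate
#' (`list(inputs, table)` with the first listed input as the least
#' significant table bit). A node without a gate (or with an empty input
#' list) outputs the constant stored in its length-1 table (default off).
#' Unlike [markov_brain()], a `logic_network` has no sensor/motor roles:
#' any node may be an input and any node may be a candidate-system member.
#'
#' @param gates list of length `n`; elements `NULL` or
#'   `list(inputs = <ids>, table = <0/1 vector of length 2^k>)`.
#' @return a `logic_network`.
#' @examples
#' # one node that copies itself:
#' net <- logic_network(list(list(inputs = 1L, table = c(0L, 1L))))
#' @export
logic_network <- function(gates) {
  n <- length(gates)
  stopifnot(n >= 1L)
  gates <- lapply(gates, function(g) {
    if (is.null(g)) g <- list(inputs = integer(0), table = 0L)
    g$inputs <- as.integer(g$inputs)
    g$table <- as.integer(g$table)
    stopifnot(all(g$inputs >= 1L), all(g$inputs <= n),
              length(g$table) == 2^length(g$inputs),
              all(g$table %in% c(0L, 1L)))
    g
  })
  structure(list(n = n, gates = gates), class = "logic_network")
}

# Gate list of length n for any supported network type. Sensor nodes of a
# brain get NULL gates (their next state is set by the world, not the
# network; they are always background in the IIT analysis).
network_gates <- function(network) {
  if (inherits(network, "markov_brain"))
    c(list(NULL, NULL), network$gates)
  else if (inherits(network, "logic_network"))
    network$gates
  else stop("expected a markov_brain or logic_network", call. = FALSE)
}

network_size <- function(network) {
  if (inherits(network, "markov_brain")) N_NODES else network$n
}

#' Full node-form TPM of a network
#'
#' @param network a [markov_brain()] or [logic_network()].
#' @return a `tpm` object over all nodes: fields `nodes` (original ids),
#'   `n`, `probs` (`2^n x n` matrix of P(node on at t+1 | state at t)).
#'   Gateless nodes (e.g. a brain's sensors) are modelled as constant-off;
#'   they are clamped as background in any analysis so the entry is inert.
#' @export
full_tpm <- function(network) {
  gates <- network_gates(network)
  n <- network_size(network)
  sm <- state_matrix(n)
  probs <- matrix(0, nrow = 2^n, ncol = n)
  for (j in seq_len(n)) {
    g <- gates[[j]]
    if (is.null(g)) next
    k <- length(g$inputs)
    idx <- if (k == 0L) rep(1L, 2^n)
           else 1L + as.integer(sm[, g$inputs, drop = FALSE] %*%
                                  2L^(0:(k - 1L)))
    probs[, j] <- g$table[idx]
  }
  new_tpm(seq_len(n), probs, bg_nodes = integer(0), bg_state = integer(0))
}

new_tpm <- function(nodes, probs, bg_nodes, bg_state) {
  k <- length(nodes)
  stopifnot(nrow(probs) == 2^k, ncol(probs) == k)
  structure(list(nodes = as.integer(nodes), n = k, probs = probs,
                 bg_nodes = as.integer(bg_nodes),
                 bg_state = as.integer(bg_state),
                 conn = tpm_connectivity(probs, k)),
            class = "tpm")
}

# conn[i, j] = TRUE iff node i's current value can change node j's
# next-state probability (holding the other nodes fixed).
tpm_connectivity <- function(probs, k) {
  conn <- matrix(FALSE, k, k)
  if (k == 0L) return(conn)
  s <- 0:(2^k - 1)
  for (i in seq_len(k)) {
    off <- which(bitwAnd(bitwShiftR(s, i - 1L), 1L) == 0L)
    on <- off + 2^(i - 1L)
    for (j in seq_len(k))
      conn[i, j] <- any(abs(probs[off, j] - probs[on, j]) > 1e-12)
  }
  conn
}

#' Condition a TPM on a candidate system and background state
#'
#' Nodes outside the candidate set (for brains this always includes the
#' sensors) are the background conditions: they are clamped to their
#' current state on the input side and dropped from the output side,
#' leaving a candidate-only TPM.
#'
#' @param tpm a full `tpm` from [full_tpm()] (or a network, which is
#'   converted first).
#' @param candidate integer node ids forming the candidate system.
#' @param state full network state: either an integer state index or a
#'   0/1 vector over *all* nodes.
#' @return a conditioned `tpm` over the candidate nodes.
#' @export
condition_tpm <- function(tpm, candidate, state) {
  if (!inherits(tpm, "tpm")) tpm <- full_tpm(tpm)
  n <- tpm$n
  if (length(state) == 1L) state <- state_to_bits(state, n)
  if (length(state) != n)
    stop("state must specify all ", n, " nodes", call. = FALSE)
  candidate <- sort(as.integer(candidate))
  stopifnot(length(candidate) >= 1L, all(candidate %in% tpm$nodes))
  if (length(candidate) == n)
    return(new_tpm(tpm$nodes, tpm$probs, integer(0), integer(0)))
  bg <- setdiff(seq_len(n), candidate)
  sm <- state_matrix(n)
  rows <- which(colSums(abs(t(sm[, bg, drop = FALSE]) - state[bg])) == 0L)
  # rows, restricted to candidate bit patterns, enumerate candidate states
  # in ascending order because bg bits are fixed
  new_tpm(tpm$nodes[candidate], tpm$probs[rows, candidate, drop = FALSE],
          bg_nodes = bg, bg_state = state[bg])
}

#' Apply a unidirectional system cut to a conditioned TPM
#'
#' Severs the connections from the nodes in `from` to the nodes in `to`
#' (a partition of the candidate set): for every target node, the severed
#' inputs are replaced by independent maximum-entropy noise, i.e. its
#' next-state probability is averaged uniformly over the cut nodes'
#' states. The cut TPM is generally probabilistic even for deterministic
#' networks.
#'
#' @param tpm a conditioned `tpm`.
#' @param from,to original node ids; must partition `tpm$nodes`.
#' @return the cut `tpm`.
#' @export
cut_tpm <- function(tpm, from, to) {
  stopifnot(inherits(tpm, "tpm"))
  k <- tpm$n
  fpos <- match(sort(as.integer(from)), tpm$nodes)
  tpos <- match(sort(as.integer(to)), tpm$nodes)
  stopifnot(!anyNA(fpos), !anyNA(tpos),
            length(fpos) + length(tpos) == k,
            length(intersect(fpos, tpos)) == 0L)
  probs <- tpm$probs
  grp <- marg_group_index(k, fpos) # state index with `from` bits cleared
  for (j in tpos) {
    avg <- rowsum(probs[, j], grp) / 2^length(fpos)
    probs[, j] <- avg[match(grp, sort(unique(grp)))]
  }
  new_tpm(tpm$nodes, probs, tpm$bg_nodes, tpm$bg_state)
}

# For each of the 2^k states, the state index with the bits at positions
# `drop_pos` cleared (used to group states that agree outside drop_pos).
marg_group_index <- function(k, drop_pos) {
  s <- 0:(2^k - 1)
  mask <- sum(2^(drop_pos - 1L))
  bitwAnd(s, bitwNot(as.integer(mask)))
}

#' Export / import a TPM
#'
#' CSV holds the `2^n x n` node-form matrix (state-indexed rows); JSON
#' additionally carries the node order and background assignment.
#'
#' @param tpm a `tpm`.
#' @param path output file (`.csv` or `.json` by extension).
#' @export
tpm_write <- function(tpm, path) {
  if (grepl("\\.json$", path)) {
    obj <- list(nodes = tpm$nodes, probs = tpm$probs,
                bg_nodes = tpm$bg_nodes, bg_state = tpm$bg_state)
    writeLines(jsonlite::toJSON(obj, digits = NA), path)
  } else {
    df <- as.data.frame(tpm$probs)
    names(df) <- paste0("node", tpm$nodes)
    df <- cbind(state = 0:(2^tpm$n - 1), df)
    write_csv_meta(df, path,
                   c(nodes = paste(tpm$nodes, collapse = " "),
                     bg_nodes = paste(tpm$bg_nodes, collapse = " "),
                     bg_state = paste(tpm$bg_state, collapse = " ")))
  }
  invisible(path)
}

#' @rdname tpm_write
#' @export
tpm_read <- function(path) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::fromJSON(path)
    return(new_tpm(obj$nodes, matrix(obj$probs, ncol = length(obj$nodes)),
                   obj$bg_nodes %||% integer(0),
                   obj$bg_state %||% integer(0)))
  }
  hdr <- grep("^# ", readLines(path, n = 10L), value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^# ", "", h), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- if (length(kv) > 1L && nzchar(kv[2]))
      as.integer(strsplit(kv[2], " ")[[1]]) else integer(0)
  }
  df <- read_csv_meta(path)
  new_tpm(meta$nodes, as.matrix(df[, -1, drop = FALSE]),
          meta$bg_nodes %||% integer(0), meta$bg_state %||% integer(0))
}
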