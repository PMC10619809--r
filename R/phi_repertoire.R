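#' Cause and effect repertoires
#'
#' Repertoires follow the IIT 3.0 definitions for node-form TPMs. An
#' *effect repertoire* of a mechanism (in its current state) over a
#' purview is the product, over purview nodes, of each node's next-state
#' distribution with the mechanism clamped and all other candidate inputs
#' marginalized uniformly. A *cause repertoire* is the Bayesian inversion
#' under a uniform perturbation prior, computed per mechanism node and
#' combined as a normalized product. The empty mechanism yields the
#' unconstrained repertoire (uniform for causes; the perturbed forward
#' marginals for effects).
#'
#' @name repertoires
NULL

.phi_maps <- new.env(parent = emptyenv())

# Map from each of the 2^k states to the 1-based index of its restriction
# to the bit positions `keep` (ascending); cached.
collapse_map <- function(k, keep) {
  key <- paste0(k, ":", paste(keep, collapse = ","))
  m <- .phi_maps[[key]]
  if (!is.null(m)) return(m)
  s <- 0:(2^k - 1)
  m <- rep(1L, 2^k)
  for (j in seq_along(keep))
    m <- m + bitwAnd(bitwShiftR(s, keep[j] - 1L), 1L) * 2L^(j - 1L)
  assign(key, m, envir = .phi_maps)
  m
}

# Rows (state indices, 1-based) whose bits at `pos` equal `bits`.
match_rows <- function(k, pos, bits) {
  if (length(pos) == 0L) return(seq_len(2^k))
  which(collapse_map(k, pos) == bits_to_state(bits) + 1L)
}

# Internal cause repertoire over purview *positions*; returns the
# normalized vector over 2^|purv_pos| states, or NULL when the mechanism
# state is unreachable (zero probability under every past state), the
# documented "unconstrained by convention" case.
crep <- function(tpm, mech_pos, mech_bits, purv_pos) {
  k <- tpm$n
  b <- length(purv_pos)
  if (length(mech_pos) == 0L) return(rep(1 / 2^b, 2^b))
  cmap <- collapse_map(k, purv_pos)
  v <- rep(1, 2^b)
  for (i in seq_along(mech_pos)) {
    pm <- tpm$probs[, mech_pos[i]]
    if (mech_bits[i] == 0L) pm <- 1 - pm
    v <- v * as.vector(rowsum(pm, cmap)) / 2^(k - b)
  }
  s <- sum(v)
  if (s < 1e-12) return(NULL)
  v / s
}

# Internal effect repertoire over purview positions, represented by its
# per-node ON-probability marginals (effect repertoires are product
# distributions, so the marginals are a complete description).
erep_marginals <- function(tpm, mech_pos, mech_bits, purv_pos) {
  rows <- match_rows(tpm$n, mech_pos, mech_bits)
  colMeans(tpm$probs[rows, purv_pos, drop = FALSE])
}

# Expand product marginals (LSB-first node order) to the full vector.
marginals_to_vec <- function(marg) {
  v <- 1
  for (q in marg) v <- c(v * (1 - q), v * q)
  v
}

# Tensor-combine vectors over two disjoint position sets p1, p2 into a
# vector over their union (ascending order).
tensor_combine <- function(p1, v1, p2, v2) {
  all_pos <- sort(c(p1, p2))
  b <- length(all_pos)
  if (length(p1) == 0L) return(v2)
  if (length(p2) == 0L) return(v1)
  m1 <- collapse_map(b, match(sort(p1), all_pos))
  m2 <- collapse_map(b, match(sort(p2), all_pos))
  v1[m1] * v2[m2]
}

as_repertoire <- function(p, purview, direction) {
  structure(list(purview = as.integer(purview), direction = direction,
                 p = as.numeric(p)), class = "repertoire")
}

# Positions (within tpm$nodes) of original node ids.
node_pos <- function(tpm, ids) {
  p <- match(sort(as.integer(ids)), tpm$nodes)
  if (anyNA(p)) stop("node not in candidate system", call. = FALSE)
  p
}

candidate_state_bits <- function(tpm, state) {
  if (length(state) == 1L) state <- state_to_bits(state, tpm$n)
  stopifnot(length(state) == tpm$n, all(state %in% c(0L, 1L)))
  as.integer(state)
}

#' Compute a cause repertoire
#'
#' @param tpm a conditioned `tpm` (see [condition_tpm()]).
#' @param mechanism integer node ids of the mechanism (possibly empty).
#' @param purview integer node ids of the purview (nonempty).
#' @param state current candidate-system state (index or 0/1 vector over
#'   `tpm$nodes`); the mechanism's state is taken from it.
#' @return a `repertoire`: purview, direction, probability vector over
#'   purview states (state index convention of [state_to_bits()]). A
#'   mechanism state that is unreachable under the TPM specifies no cause
#'   information; the uniform (unconstrained) repertoire is returned with
#'   attribute `unconstrained = TRUE`.
#' @export
cause_repertoire <- function(tpm, mechanism, purview, state) {
  bits <- candidate_state_bits(tpm, state)
  pp <- node_pos(tpm, purview)
  mp <- node_pos(tpm, if (length(mechanism)) mechanism else integer(0))
  v <- crep(tpm, mp, bits[mp], pp)
  if (is.null(v)) {
    out <- as_repertoire(rep(1 / 2^length(pp), 2^length(pp)),
                         purview, "cause")
    attr(out, "unconstrained") <- TRUE
    return(out)
  }
  as_repertoire(v, purview, "cause")
}

#' Compute an effect repertoire
#'
#' @inheritParams cause_repertoire
#' @return a `repertoire` over purview states at the next timestep.
#' @export
effect_repertoire <- function(tpm, mechanism, purview, state) {
  bits <- candidate_state_bits(tpm, state)
  pp <- node_pos(tpm, purview)
  mp <- node_pos(tpm, if (length(mechanism)) mechanism else integer(0))
  as_repertoire(marginals_to_vec(erep_marginals(tpm, mp, bits[mp], pp)),
                purview, "effect")
}

#' Earth mover's distance between repertoires
#'
#' Exact EMD with Hamming ground distance between binary purview states,
#' solved as a transportation problem (only the signed difference between
#' the distributions is transported).
#'
#' @param p,q `repertoire` objects over the same purview, or plain
#'   probability vectors of equal power-of-two length.
#' @return the distance (>= 0).
#' @examples
#' emd_hamming(c(1, 0), c(0, 1))   # 1
#' emd_hamming(c(1, 0), c(.5, .5)) # 0.5
#' @export
emd_hamming <- function(p, q) {
  if (inherits(p, "repertoire") || inherits(q, "repertoire")) {
    stopifnot(inherits(p, "repertoire"), inherits(q, "repertoire"),
              identical(p$purview, q$purview))
    p <- p$p; q <- q$p
  }
  stopifnot(length(p) == length(q))
  n <- as.integer(round(log2(length(p))))
  stopifnot(2^n == length(p))
  emd_hamming_cpp(p, q, n)
}
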