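#' Mechanism-level integrated information
#'
#' For a mechanism in a state, every purview is scored in both temporal
#' directions: the integrated information of a purview is the earth
#' mover's distance between the whole repertoire and the repertoire of
#' the minimum-information partition (MIP), minimized over all IIT 3.0
#' mechanism/purview bipartitions. The core cause (effect) is the purview
#' maximizing phi_cause (phi_effect); the mechanism's phi is
#' `min(phi_cause, phi_effect)`, and a concept exists iff it is positive.
#'
#' Conventions (documented, applied consistently): partitions are
#' enumerated in ascending (mechanism-mask, purview-mask) order and MIP
#' ties keep the first; core-purview ties prefer the larger purview, then
#' the earlier in ascending-mask order; phi below 1e-8 is treated as 0
#' (transportation-solver noise floor).
#'
#' @name mechanism_phi
NULL

PHI_EPS <- 1e-8

mask_to_pos <- function(mask, k) which(bitwAnd(mask, 2L^(0:(k - 1L))) > 0L)

# phi of one purview in one direction, with its MIP.
# mp/pp are positions within the candidate; bits is the candidate state.
purview_phi <- function(tpm, mp, mbits, pp, direction) {
  a <- length(mp); b <- length(pp)
  if (direction == "cause") {
    whole <- crep(tpm, mp, mbits, pp)
    if (is.null(whole)) return(list(phi = 0, mip = NULL, rep = NULL))
  } else {
    whole_m <- erep_marginals(tpm, mp, mbits, pp)
  }
  best <- Inf; best_mip <- NULL
  for (am in 0:(2^a - 1L)) {
    m1 <- mp[mask_to_pos(am, a)]; b1 <- mbits[mask_to_pos(am, a)]
    m2 <- setdiff(mp, m1); b2 <- mbits[match(m2, mp)]
    for (bm in 0:(2^b - 1L)) {
      p1 <- pp[mask_to_pos(bm, b)]
      p2 <- setdiff(pp, p1)
      if (length(m1) == 0L && length(p1) == 0L) next
      if (length(m2) == 0L && length(p2) == 0L) next
      if (direction == "cause") {
        r1 <- if (length(p1)) crep(tpm, m1, b1, p1) else NULL
        r2 <- if (length(p2)) crep(tpm, m2, b2, p2) else NULL
        # a part's repertoire cannot be unreachable when the whole isn't
        part <- tensor_combine(p1, r1, p2, r2)
        d <- emd_hamming_cpp(whole, part, b)
      } else {
        q1 <- if (length(p1)) erep_marginals(tpm, m1, b1, p1) else NULL
        q2 <- if (length(p2)) erep_marginals(tpm, m2, b2, p2) else NULL
        part_m <- numeric(b)
        part_m[match(p1, pp)] <- q1
        part_m[match(p2, pp)] <- q2
        d <- sum(abs(whole_m - part_m)) # exact EMD for products
      }
      if (d < best - 1e-12) {
        best <- d
        best_mip <- list(m1 = tpm$nodes[m1], p1 = tpm$nodes[p1],
                         m2 = tpm$nodes[m2], p2 = tpm$nodes[p2])
        if (best < PHI_EPS) {
          return(list(phi = 0, mip = best_mip,
                      rep = if (direction == "cause") whole
                            else marginals_to_vec(whole_m),
                      marg = if (direction == "effect") whole_m))
        }
      }
    }
  }
  list(phi = best, mip = best_mip,
       rep = if (direction == "cause") whole else marginals_to_vec(whole_m),
       marg = if (direction == "effect") whole_m)
}

# Connectivity-based pruning: a purview can only bear phi if every
# mechanism node and every purview node participates in a relevant edge.
purview_relevant <- function(conn, mp, pp, direction) {
  if (direction == "cause") {
    all(vapply(mp, function(m) any(conn[pp, m]), logical(1))) &&
      all(vapply(pp, function(p) any(conn[p, mp]), logical(1)))
  } else {
    all(vapply(mp, function(m) any(conn[m, pp]), logical(1))) &&
      all(vapply(pp, function(p) any(conn[mp, p]), logical(1)))
  }
}

core_purview <- function(tpm, mp, mbits, direction) {
  k <- tpm$n
  best <- list(phi = 0, purview = NULL, rep = NULL, marg = NULL, mip = NULL)
  for (pm in 1:(2^k - 1L)) {
    pp <- mask_to_pos(pm, k)
    if (!purview_relevant(tpm$conn, mp, pp, direction)) next
    res <- purview_phi(tpm, mp, mbits, pp, direction)
    if (res$phi > best$phi + 1e-10 ||
        (res$phi > PHI_EPS && abs(res$phi - best$phi) <= 1e-10 &&
         length(pp) > length(best$purview))) {
      best <- list(phi = res$phi, purview = tpm$nodes[pp], rep = res$rep,
                   marg = res$marg, mip = res$mip)
    }
  }
  best
}

#' Find a mechanism's concept
#'
#' Searches all purviews and partitions in both directions; returns the
#' concept (mechanism, core cause, core effect, phi values) or `NULL`
#' when `min(phi_cause, phi_effect) = 0`.
#'
#' @param tpm a conditioned `tpm`.
#' @param mechanism nonempty integer node ids.
#' @param state current candidate-system state (index or bit vector).
#' @return a `concept` (list with `mechanism`, `phi`, `cause`, `effect`)
#'   or `NULL`.
#' @export
mechanism_phi <- function(tpm, mechanism, state) {
  stopifnot(length(mechanism) >= 1L)
  bits <- candidate_state_bits(tpm, state)
  mp <- node_pos(tpm, mechanism)
  mbits <- bits[mp]
  ca <- core_purview(tpm, mp, mbits, "cause")
  if (ca$phi <= PHI_EPS) return(NULL)
  ef <- core_purview(tpm, mp, mbits, "effect")
  if (ef$phi <= PHI_EPS) return(NULL)
  structure(list(
    mechanism = tpm$nodes[mp], phi = min(ca$phi, ef$phi),
    cause = list(purview = ca$purview, rep = ca$rep, phi = ca$phi,
                 mip = ca$mip),
    effect = list(purview = ef$purview, rep = ef$rep, marg = ef$marg,
                  phi = ef$phi, mip = ef$mip)
  ), class = "concept")
}

#' All concepts of a candidate system
#'
#' Evaluates the full powerset of nonempty mechanisms of the conditioned
#' candidate TPM and returns those with positive phi, each annotated with
#' its repertoires expanded over the whole candidate (needed for the
#' extended EMD between conceptual structures).
#'
#' @inheritParams mechanism_phi
#' @return list of `concept`s (possibly empty).
#' @export
constellation <- function(tpm, state) {
  bits <- candidate_state_bits(tpm, state)
  k <- tpm$n
  out <- list()
  for (mm in 1:(2^k - 1L)) {
    mech <- tpm$nodes[mask_to_pos(mm, k)]
    cpt <- mechanism_phi(tpm, mech, bits)
    if (!is.null(cpt)) out[[length(out) + 1L]] <- expand_concept(cpt, tpm)
  }
  out
}

# Expand a concept's repertoires over the full candidate system:
# cause tensored with the uniform repertoire over the remaining nodes,
# effect with the unconstrained effect marginals of its own TPM.
expand_concept <- function(cpt, tpm) {
  k <- tpm$n
  cpos <- node_pos(tpm, cpt$cause$purview)
  rest_c <- setdiff(seq_len(k), cpos)
  cpt$exp_cause <- tensor_combine(
    cpos, cpt$cause$rep,
    rest_c, if (length(rest_c)) rep(1 / 2^length(rest_c), 2^length(rest_c)))
  epos <- node_pos(tpm, cpt$effect$purview)
  marg_all <- colMeans(tpm$probs) # unconstrained forward marginals
  marg_all[epos] <- cpt$effect$marg
  cpt$exp_eff_marg <- marg_all
  cpt
}
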