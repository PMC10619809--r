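# Naive exhaustive IIT 3.0 reference implementation, independent of the
# package engine: works on explicit 2^k x 2^k state-by-state matrices
# built straight from the gates, uses plain loops everywhere, and solves
# every earth mover's distance (including effect-side ones) as a linear
# program with boot::simplex. Only intended for tiny fixture networks
# (<= 3-4 nodes).

oracle_bits <- function(s, n) {
  out <- integer(n)
  for (j in seq_len(n)) { out[j] <- s %% 2L; s <- s %/% 2L }
  out
}
oracle_unbits <- function(bits) {
  s <- 0L
  for (j in rev(seq_along(bits))) s <- s * 2L + bits[j]
  s
}

# P(node ON next | full past state), with inputs in `noise_nodes` replaced
# by uniform noise (same draw for repeated occurrences of one node).
oracle_node_p <- function(gates, node, full_past, noise_nodes = integer(0)) {
  g <- gates[[node]]
  if (is.null(g)) return(0)
  if (length(g$inputs) == 0L) return(g$table[1L])
  sev_nodes <- intersect(unique(g$inputs), noise_nodes)
  if (length(sev_nodes) == 0L) {
    vals <- full_past[g$inputs]
    return(g$table[1L + oracle_unbits(vals)])
  }
  tot <- 0
  for (a in 0:(2^length(sev_nodes) - 1L)) {
    abits <- oracle_bits(a, length(sev_nodes))
    past <- full_past
    past[sev_nodes] <- abits
    vals <- past[g$inputs]
    tot <- tot + g$table[1L + oracle_unbits(vals)]
  }
  tot / 2^length(sev_nodes)
}

oracle_gates <- function(network) {
  if (inherits(network, "markov_brain")) c(list(NULL, NULL), network$gates)
  else network$gates
}

# Conditioned state-by-state TPM over the candidate (rows: past candidate
# state, cols: next candidate state), background clamped to full_state.
# cut_from/cut_to: unidirectional cut, inputs from cut_from noised for
# nodes in cut_to.
oracle_sbs <- function(network, candidate, full_state,
                       cut_from = NULL, cut_to = NULL) {
  gates <- oracle_gates(network)
  candidate <- sort(candidate)
  k <- length(candidate)
  T <- matrix(0, 2^k, 2^k)
  for (i in 0:(2^k - 1L)) {
    past <- full_state
    past[candidate] <- oracle_bits(i, k)
    pon <- numeric(k)
    for (ci in seq_len(k)) {
      noise <- if (!is.null(cut_to) && candidate[ci] %in% cut_to)
        cut_from else integer(0)
      pon[ci] <- oracle_node_p(gates, candidate[ci], past, noise)
    }
    for (j in 0:(2^k - 1L)) {
      jb <- oracle_bits(j, k)
      T[i + 1L, j + 1L] <- prod(ifelse(jb == 1L, pon, 1 - pon))
    }
  }
  T
}

# marginal P(candidate node at position p is ON next | past row i)
oracle_marg <- function(T, i, p, k) {
  tot <- 0
  for (j in 0:(2^k - 1L))
    if (oracle_bits(j, k)[p] == 1L) tot <- tot + T[i + 1L, j + 1L]
  tot
}

oracle_erep <- function(T, k, mech_pos, mbits, purv_pos) {
  match_rows <- c()
  for (i in 0:(2^k - 1L)) {
    ib <- oracle_bits(i, k)
    if (length(mech_pos) == 0L || all(ib[mech_pos] == mbits))
      match_rows <- c(match_rows, i)
  }
  b <- length(purv_pos)
  q <- numeric(b)
  for (pi in seq_len(b))
    q[pi] <- mean(sapply(match_rows, function(i)
      oracle_marg(T, i, purv_pos[pi], k)))
  rep_v <- numeric(2^b)
  for (u in 0:(2^b - 1L)) {
    ub <- oracle_bits(u, b)
    rep_v[u + 1L] <- prod(ifelse(ub == 1L, q, 1 - q))
  }
  rep_v
}

oracle_crep <- function(T, k, mech_pos, mbits, purv_pos) {
  b <- length(purv_pos)
  if (length(mech_pos) == 0L) return(rep(1 / 2^b, 2^b))
  v <- rep(1, 2^b)
  for (mi in seq_along(mech_pos)) {
    cm <- numeric(2^b)
    cnt <- numeric(2^b)
    for (i in 0:(2^k - 1L)) {
      u <- oracle_unbits(oracle_bits(i, k)[purv_pos])
      pm <- oracle_marg(T, i, mech_pos[mi], k)
      if (mbits[mi] == 0L) pm <- 1 - pm
      cm[u + 1L] <- cm[u + 1L] + pm
      cnt[u + 1L] <- cnt[u + 1L] + 1
    }
    v <- v * cm / cnt
  }
  if (sum(v) < 1e-12) return(NULL)
  v / sum(v)
}

# LP-based exact EMD with Hamming ground distance.
oracle_emd <- function(p, q, n_nodes) {
  cost <- outer(0:(2^n_nodes - 1L), 0:(2^n_nodes - 1L),
                Vectorize(function(x, y) sum(oracle_bits(bitwXor(x, y),
                                                         n_nodes))))
  oracle_emd_lp(p, q, cost)
}

oracle_emd_lp <- function(a, b, cost) {
  keep_a <- which(a > 1e-15); keep_b <- which(b > 1e-15)
  a <- a[keep_a]; b <- b[keep_b]
  cost <- cost[keep_a, keep_b, drop = FALSE]
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) return(0)
  if (n == 1L) return(sum(cost[1, ] * b))
  if (m == 1L) return(sum(cost[, 1] * a))
  cvec <- as.vector(t(cost))
  rows <- t(sapply(1:n, function(i) as.numeric(rep(1:n, each = m) == i)))
  cols <- t(sapply(1:m, function(j) as.numeric(rep(1:m, times = n) == j)))
  A3 <- rbind(rows, cols[-m, , drop = FALSE])
  b3 <- c(a, b[-m])
  unname(boot::simplex(a = cvec, A3 = A3, b3 = b3, maxi = FALSE)$value)
}

# all subsets of a vector as a list (by increasing mask, like the engine)
oracle_subsets <- function(v, include_empty = TRUE) {
  n <- length(v)
  out <- list()
  for (m in (if (include_empty) 0L else 1L):(2^n - 1L))
    out[[length(out) + 1L]] <- v[oracle_bits(m, n) == 1L]
  out
}

oracle_purview_phi <- function(T, k, mp, mbits, pp, direction) {
  rep_fn <- if (direction == "cause") oracle_crep else oracle_erep
  whole <- rep_fn(T, k, mp, mbits, pp)
  if (is.null(whole)) return(list(phi = 0))
  b <- length(pp)
  best <- Inf
  for (m1 in oracle_subsets(mp)) {
    m2 <- setdiff(mp, m1)
    for (p1 in oracle_subsets(pp)) {
      p2 <- setdiff(pp, p1)
      if (length(m1) == 0L && length(p1) == 0L) next
      if (length(m2) == 0L && length(p2) == 0L) next
      b1 <- mbits[match(m1, mp)]; b2 <- mbits[match(m2, mp)]
      r1 <- if (length(p1)) rep_fn(T, k, m1, b1, p1)
      r2 <- if (length(p2)) rep_fn(T, k, m2, b2, p2)
      # assemble over pp in ascending order by explicit state loop
      part <- numeric(2^b)
      for (u in 0:(2^b - 1L)) {
        ub <- oracle_bits(u, b)
        u1 <- oracle_unbits(ub[match(p1, pp)])
        u2 <- oracle_unbits(ub[match(p2, pp)])
        v1 <- if (length(p1)) r1[u1 + 1L] else 1
        v2 <- if (length(p2)) r2[u2 + 1L] else 1
        part[u + 1L] <- v1 * v2
      }
      d <- oracle_emd(whole, part, b)
      if (d < best) best <- d
    }
  }
  list(phi = if (best < 1e-8) 0 else best, rep = whole)
}

oracle_core <- function(T, k, mp, mbits, direction) {
  best <- list(phi = 0, purview = NULL, rep = NULL)
  for (pp in oracle_subsets(seq_len(k), include_empty = FALSE)) {
    res <- oracle_purview_phi(T, k, mp, mbits, pp, direction)
    if (res$phi > best$phi + 1e-10 ||
        (res$phi > 1e-8 && abs(res$phi - best$phi) <= 1e-10 &&
         length(pp) > length(best$purview)))
      best <- list(phi = res$phi, purview = pp, rep = res$rep)
  }
  best
}

oracle_concept <- function(T, k, mp, mbits) {
  ca <- oracle_core(T, k, mp, mbits, "cause")
  if (ca$phi <= 1e-8) return(NULL)
  ef <- oracle_core(T, k, mp, mbits, "effect")
  if (ef$phi <= 1e-8) return(NULL)
  # expand over the full candidate
  rest_c <- setdiff(seq_len(k), ca$purview)
  exp_cause <- numeric(2^k)
  for (s in 0:(2^k - 1L)) {
    sb <- oracle_bits(s, k)
    u <- oracle_unbits(sb[ca$purview])
    exp_cause[s + 1L] <- ca$rep[u + 1L] *
      (if (length(rest_c)) 1 / 2^length(rest_c) else 1)
  }
  uncon <- oracle_erep(T, k, integer(0), integer(0), seq_len(k))
  marg_all <- sapply(seq_len(k), function(p) {
    tot <- 0
    for (s in 0:(2^k - 1L))
      if (oracle_bits(s, k)[p] == 1L) tot <- tot + uncon[s + 1L]
    tot
  })
  eff_marg <- sapply(seq_along(ef$purview), function(pi) {
    tot <- 0
    b <- length(ef$purview)
    for (u in 0:(2^b - 1L))
      if (oracle_bits(u, b)[pi] == 1L) tot <- tot + ef$rep[u + 1L]
    tot
  })
  marg_all[ef$purview] <- eff_marg
  exp_eff <- numeric(2^k)
  for (s in 0:(2^k - 1L)) {
    sb <- oracle_bits(s, k)
    exp_eff[s + 1L] <- prod(ifelse(sb == 1L, marg_all, 1 - marg_all))
  }
  list(mechanism_pos = mp, phi = min(ca$phi, ef$phi),
       phi_cause = ca$phi, phi_effect = ef$phi,
       cause_purview = ca$purview, effect_purview = ef$purview,
       exp_cause = exp_cause, exp_eff = exp_eff)
}

oracle_constellation <- function(T, k, bits) {
  out <- list()
  for (mp in oracle_subsets(seq_len(k), include_empty = FALSE)) {
    cpt <- oracle_concept(T, k, mp, bits[mp])
    if (!is.null(cpt)) out[[length(out) + 1L]] <- cpt
  }
  out
}

oracle_null_concept <- function(T, k) {
  uncon <- oracle_erep(T, k, integer(0), integer(0), seq_len(k))
  list(phi = 0, exp_cause = rep(1 / 2^k, 2^k), exp_eff = uncon)
}

oracle_constellation_distance <- function(C1, C2, nullc, k) {
  n1 <- length(C1); n2 <- length(C2)
  if (n1 == 0L && n2 == 0L) return(0)
  phi1 <- sapply(C1, `[[`, "phi"); phi2 <- sapply(C2, `[[`, "phi")
  if (n1 == 0L) phi1 <- numeric(0)
  if (n2 == 0L) phi2 <- numeric(0)
  s1 <- sum(phi1); s2 <- sum(phi2)
  supply <- c(phi1, max(0, s2 - s1))
  demand <- c(phi2, max(0, s1 - s2))
  pts1 <- c(C1, list(nullc)); pts2 <- c(C2, list(nullc))
  cost <- matrix(0, n1 + 1L, n2 + 1L)
  for (i in seq_len(n1 + 1L))
    for (j in seq_len(n2 + 1L))
      cost[i, j] <- oracle_emd(pts1[[i]]$exp_cause, pts2[[j]]$exp_cause, k) +
        oracle_emd(pts1[[i]]$exp_eff, pts2[[j]]$exp_eff, k)
  oracle_emd_lp(supply, demand, cost)
}

oracle_big_phi <- function(network, candidate, full_state) {
  candidate <- sort(candidate)
  k <- length(candidate)
  bits <- full_state[candidate]
  T <- oracle_sbs(network, candidate, full_state)
  C <- oracle_constellation(T, k, bits)
  if (length(C) == 0L) return(list(phi = 0, constellation = C))
  nullc <- oracle_null_concept(T, k)
  if (k == 1L)
    return(list(phi = oracle_constellation_distance(C, list(), nullc, k),
                constellation = C))
  best <- Inf
  for (from in oracle_subsets(candidate, include_empty = FALSE)) {
    to <- setdiff(candidate, from)
    if (length(to) == 0L) next
    Tc <- oracle_sbs(network, candidate, full_state,
                     cut_from = from, cut_to = to)
    Cc <- oracle_constellation(Tc, k, bits)
    d <- oracle_constellation_distance(C, Cc, nullc, k)
    if (d < best) best <- d
  }
  list(phi = if (best < 1e-8) 0 else best, constellation = C)
}

oracle_main_complex <- function(network, full_state, eligible) {
  best <- list(phi = -1, nodes = NULL)
  for (cand in oracle_subsets(eligible, include_empty = FALSE)) {
    res <- oracle_big_phi(network, cand, full_state)
    if (res$phi > best$phi + 1e-10 ||
        (abs(res$phi - best$phi) <= 1e-10 &&
         length(cand) > length(best$nodes)))
      best <- list(phi = res$phi, nodes = sort(cand),
                   constellation = res$constellation)
  }
  best
}
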